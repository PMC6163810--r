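---
title: "Analysing voltage-sensor gating as proton transport"
author: "protonGating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing voltage-sensor gating as proton transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonGating)
```

## The scientific question

Voltage-gated potassium channels open when the membrane depolarizes. The
opening is preceded by a small capacitative *gating current*, whose time
integral — the gating charge, roughly 10–13 elementary charges for the
whole channel — has traditionally been attributed to an outward movement
of the positively charged S4 helix of each voltage-sensing domain (VSD).
An alternative reading attributes the gating charge to *proton*
displacement inside the VSD: ionizable side chains (tyrosine, glutamate,
and crucially the amphoteric arginine, whose NH nitrogens can donate a
proton while the unprotonated NE nitrogen can accept one) form hydrogen-
bonded chains along which protons hop when the field changes, moving
charge through the membrane field without large backbone motion.

This package implements the quantitative analyses that such a proposal
rests on, in a reusable and fully tested form:

1. **Charge bookkeeping** — partition a cluster of atoms with partial
   charges into slabs along the membrane normal, compute the center of
   charge, and convert its displacement between two states into an
   effective gating charge.
2. **Protonation-state energetics** — tabulate state energies on a
   voltage grid, find minimum-energy states, locate the voltage where two
   states cross, and compare energy-decomposition terms.
3. **Thermal and kinetic arithmetic** — Q10 ↔ Arrhenius activation
   energy, kJ/mol ↔ kBT, the kBT/h vibrational-mode cutoff, 3N−6 mode
   counting, and gating-cycle counts.
4. **Gating curves** — the two-state Boltzmann open-probability model,
   its fit, a Gaussian-threshold alternative, and the conductance versus
   log-concentration single-barrier diagnostic.
5. **Proton-path graphs** — hydrogen-bond donor/acceptor site typing,
   distance-cutoff graphs, Y-R-E / R-E-R triad detection, and simple-path
   enumeration between residues.

Quantum-chemistry outputs (per-atom partial charges, state energies) are
treated purely as *inputs*; a synthetic-data module generates
substitutes with planted, recoverable ground truth so that every stage
can be verified without external software or downloads.

## Models and conventions

### Membrane frame and slab partition

The membrane normal is the z axis, increasing toward the extracellular
side; the frame origin defaults to the minimum z of the selection, which
makes slab indices reproducible without external membrane annotation.
Slabs are half-open intervals $[z_0 + kt,\, z_0 + (k+1)t)$ so every atom
falls in exactly one slab and boundary atoms go to the upper-indexed
slab. The default partition is eleven 3 Å slices. Atoms outside the
partition raise an error rather than being silently dropped.

### Center of charge and gating-charge surrogate

For slab charges $Q_s$ at midpoints $z_s$ the (slab-binned) center of
charge is $\bar z = \sum_s Q_s z_s / \sum_s Q_s$; the atomwise centroid
$\sum_i q_i z_i / \sum_i q_i$ is computed alongside. Two numerical facts
matter and are covered by tests:

* For charges of one sign the binned center is within $t/2$ of the
  atomwise centroid. For *signed* charges the bound is
  $(t/2)\,\sum|q_i| / |\sum q_i|$, which can be large when cancellation
  is strong; both centers are therefore reported, and `displacement()`
  lets the caller choose (`"slabwise"` is the default for fidelity to
  the original slice-and-sum procedure; `"atomwise"` is exact).
* A signed-charge centroid is a ratio of signed sums: it is undefined at
  zero total charge (an error, not an NA), and it need not lie inside
  the atom cloud when positive and negative charge nearly cancel.

The effective gating charge of a shift $\Delta$ under a field dropping
over distance $d$ is $q_\mathrm{eff} = Q_\mathrm{net}\,\Delta/d$. The
field-drop distance is deliberately an explicit user parameter: how much
of the membrane potential drops across the relevant region is itself a
contested quantity, so no default is imposed.

### State energetics

Energies are *relative* (kJ/mol); absolute quantum-chemical totals carry
no meaning here, and tables may be supplied already shifted. Between
grid voltages the energy difference of two states is interpolated
linearly — the natural choice for a five-point grid with no functional
form to prefer. The crossing height is measured above the grid minimum
of an explicit reference state (defaulting to the first state of the
pair, the closed-state convention), which makes the height invariant
under swapping the two states. A difference that never changes sign is
a distinguishable no-crossing *result*, not an error; exact ties at a
voltage are an error listing the tied states rather than an arbitrary
pick.

### Thermal arithmetic

Q10 and activation energy are linked through the Arrhenius form
$Q_{10} = \exp\!\big[(E_a/R)(1/T_1 - 1/T_2)\big]$ over a stated 10 K
interval; the convention adopted here is that "Q10 at $T\,^\circ$C"
refers to the decade $[T-10, T]\,^\circ$C, which reproduces the linked
literature values (40 kJ/mol over 290–300 K ↔ Q10 ≈ 1.7; Q10 2.2 ending
at 10 °C ↔ ≈ 50 kJ/mol; Q10 1.3 ending at 40 °C ↔ ≈ 20 kJ/mol). Thermal
energy is molar ($RT$), since the field freely mixes kJ/mol and kBT;
room temperature defaults to 300 K, consistent with kBT/h ≈ 6 × 10¹² Hz.
Constants are CODATA 2018 exact values.

### Gating curves

The two-state Boltzmann is
$P_o(V) = \big[1 + e^{-q e (V - V_{1/2})/k_B T}\big]^{-1}$. The midpoint
offset $V_{1/2}$ extends the textbook zero-centred form because real
datasets are not centred at 0 mV; the printed form is the
$V_{1/2} = 0$ case. The fit is nonlinear least squares on the
probability scale (robust to saturated points, unlike a logit
transform), initialised from a clipped logit-scale linear fit.

Standard errors are **HC3 sandwich (heteroscedasticity-robust)**
estimates computed from the analytic jacobian. On the probability scale
the observation noise necessarily shrinks toward the plateaus (values
are clipped to [0, 1]), so ordinary least-squares errors understate the
sampling spread of the gating charge; in simulation the robust errors
match the empirical spread of the estimator while the OLS errors run
about 20% low.

The Gaussian-threshold alternative posits a transition threshold drawn
from a Gaussian of width about one kBT:
$P_o(V) = \Phi\big[(q e V / k_B T - \mu)/w\big]$. Comparing it to the
Boltzmann, the package equates midpoints and *fits* the slope scale by
minimising the supremum deviation; the classic probit-to-logistic scale
factor ≈ 1.702 emerges from this match rather than being hard-coded,
and the matched curves differ by less than 0.01 in probability
everywhere. (Equating midpoint slopes analytically instead gives scale
4φ(0) ≈ 1.596 and a larger deviation, ≈ 0.018; that option is kept as
`matchScale = "slope"`.) Because best matching is scale-invariant, the
width-sensitivity check compares a mismatched-width model against a
*fixed* matched Boltzmann.

The conductance diagnostic uses $-RT\ln([\mathrm{K}^+]/c_\mathrm{ref})
= \Delta\Delta G$: a single conduction barrier predicts ln-conductance
linear in ln-concentration, and the R² of that regression is the
linearity measure.

### Proton-path graphs

Sites are typed per residue: Tyr OH, Ser/Thr OG, Cys SG, His ring
nitrogens and water O are donor *and* acceptor; Arg NH1/NH2 are always
donors while NE is a donor when the arginine is protonated and an
acceptor when neutral (the amphoteric rule); Glu/Asp carboxylate
oxygens are acceptors when charged, with one oxygen both when neutral.
Nominal charges default to solution conditions (Arg +, Glu/Asp −) and
can be overridden per residue — the scientific point being precisely
that such overrides matter.

Edges require donor/acceptor complementarity between different residues
and a heavy-atom distance ≤ 3.5 Å. No donor–H–acceptor angle term is
used: path reasoning at this level is distance-based, and hydrogens may
be absent from inputs. Triad detection (Y-R-E and R-E-R/R-D-R) uses the
minimum pairwise distance between side-chain functional atoms with a
6 Å window, chosen to admit with margin the ~5.1–5.4 Å arginine-N to
carboxylate-O spacings observed in voltage-sensor and bacteriorhodopsin
triads. Paths are reported residue-collapsed (a residue is one node
regardless of how many of its atoms carry sites), each water molecule is
one node and hence one hop, and enumeration returns all simple paths up
to a hop limit in lexicographic order, making results independent of
input ordering.

## The synthetic-data module

`genStructure()` emulates the analysis target: a ~10³-atom cluster
(default 976 atoms — 11 side-chain motif atoms, 24 waters in an
extracellular cleft, apolar filler) with signed partial charges summing
exactly to +2 e. The motif plants the two-route topology
R303–Y266–R300 / R303–E226–R300 → R300–E183 with 2.5–3.2 Å
hydrogen-bond contacts, so the pipeline must find exactly two proton
paths from R303 to E183 and exactly one after deleting Y266 (the
phenylalanine-mutation scenario). Triangle inequalities at hydrogen-bond
length scales make four additional Y-R-E/R-E-R triples unavoidable
inside the 6 Å window; the manifest therefore lists the complete,
analytically derived six-triad set as ground truth. Charges are drawn
randomly (sd 0.3 e, the scale of typical population-analysis partial
charges) and balanced exactly on the filler atoms; the whole cluster is
then translated rigidly so the atomwise centroid sits exactly at the
planted value. `genStructurePair()` applies a rigid 11.3 Å shift for the
closed/open pair (centers 19.6 Å / 8.3 Å by default).

`genEnergyTable()` plants two globally linear state-energy curves
crossing exactly at the requested point (default −20 mV, 60 kJ/mol above
the closed minimum) on the −70…+70 mV grid, with 27 further states
strictly above both and constant exchange-correlation terms (96.0 and
25.2 kJ/mol) for the designated pair. `genGatingDataset()` evaluates the
Boltzmann at 41 voltages spanning the transition (default q = 13,
V½ = −30 mV) and adds Gaussian noise clipped to [0, 1];
`genConductanceDataset()` produces a log-log-linear conductance series
with multiplicative noise. Every generator takes one integer seed,
restores the caller's RNG state, and records its planted truths in a
manifest that the corresponding pipeline stage must recover — the
package's integration test.

What the generators deliberately do **not** emulate: force-field-quality
geometry, realistic charge correlations beyond the sum constraint,
multi-state gating kinetics, or voltage-dependent structural change.
Passing tests therefore demonstrate the correctness of the bookkeeping,
fitting and graph analysis — not the validity of any quantum-chemical
energy or the biological hypothesis itself.

## Numerical choices and degenerate inputs

* Altloc conformers: highest occupancy wins, ties go to the first
  encountered — deterministic.
* PDB coordinates round-trip at the format's 3-decimal precision; for a
  signed-charge centroid that rounding is amplified by
  $\sum|q|/|\sum q|$, which stays below 0.1 Å at the default fixture
  scale.
* `boltzmannPo()` saturates smoothly (no overflow) via the standard
  logistic CDF; a width-zero threshold model degenerates to a step.
* Zero total charge, empty selections, absent states or terms,
  non-identifiable (constant) gating data, fewer than three conductance
  points, and non-positive cutoffs/windows are all explicit errors with
  named quantities rather than silent NA propagation.
* Problem sizes in the shipped tests: 200 random slab fixtures of 20–80
  atoms, 100 planted energy tables, 50 gating-fit replicates (41 points
  each), 100 random graphs of up to 12 nodes against a brute-force DFS
  oracle, and one full 976-atom fixture piped end to end through the
  on-disk formats. The complete suite runs in well under a minute.

## A worked pass through the pipeline

```{r pipeline, eval = FALSE}
library(protonGating)

## structure with planted truth
fix <- genStructure(seed = 1)
netCharge(fix$structure)            # 2 (exact)

## gating-charge surrogate from a rigid 11.3 A shift
pair <- genStructurePair(delta = 11.3, plantedCoc = 8.3, seed = 1)
joint <- slabPartition(3, 16L, membraneFrame(pair$stateB)$origin)
displacement(slabProfile(pair$stateA, joint),
             slabProfile(pair$stateB, joint), method = "atomwise")  # 11.3
effectiveGatingCharge(11.3, 2, 30)  # 0.753 e per sensor

## energetics: crossing at -20 mV, 60 kJ/mol = 24.1 kBT
en <- genEnergyTable(seed = 1)
cp <- crossingPoint(en$table, "Y266:0|R300:0|E183:0",
                    "Y266:-|R300:+|E183:0")
energyInKbt(cp$height, 300)

## gating curve fit and the two-path / one-path graph result
fitBoltzmann(genGatingDataset(seed = 7)$dataset)
g <- buildGraph(assignSites(fix$structure))
formatPaths(enumeratePaths(g, "R303", "E183"))
formatPaths(enumeratePaths(dropResidues(g, "Y266"), "R303", "E183"))
```

## Known limitations

* No quantum-chemistry, molecular-dynamics or pKa computation: charge
  tables and state energies are consumed, never produced.
* The stored source data cannot adjudicate the literature's own internal
  tensions (e.g. a crossing height quoted both as ~16 kBT and ~24 kBT,
  and one closed-state label assignment that conflicts between
  sections); state labels are stored verbatim and both conversions are
  provided.
* Graph edges ignore donor–H–acceptor geometry; a short heavy-atom
  distance with hopeless angles still counts as a candidate hydrogen
  bond.
* Paths are not energy-ranked; ranking requires the quantum energies
  that are out of scope.
* The Boltzmann fit is a descriptive two-state summary; real gating has
  multiple states, and the fitted q should be read accordingly.
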