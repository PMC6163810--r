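#' @import methods
NULL

# Column layout shared by every atom table; charge stays NA until attached.
.atomCols <- c("serial", "elety", "element", "resid", "resno", "chain",
               "x", "y", "z", "charge")

#' ChargedStructure: atoms in a membrane frame with partial charges
#'
#' An ordered collection of atoms (coordinates in angstrom) together with
#' membrane-frame metadata. The z axis is the membrane normal and increases
#' toward the extracellular side; the frame origin defaults to the minimum z
#' of the selection. Partial charges (elementary-charge units) are optional
#' until attached with [attachCharges()].
#'
#' @slot atoms data.frame with columns `serial`, `elety` (atom name),
#'   `element`, `resid` (3-letter residue code), `resno`, `chain`,
#'   `x`, `y`, `z` (angstrom) and `charge` (e; `NA` until attached).
#' @slot frame list with `origin` (z of the intracellular-most atom) and
#'   free-text `note`.
#'
#' @seealso [readStructure()], [attachCharges()], [selectRegion()]
#' @export
setClass("ChargedStructure",
  representation(atoms = "data.frame", frame = "list"),
  prototype(atoms = data.frame(), frame = list(origin = NA_real_, note = ""))
)

setValidity("ChargedStructure", function(object) {
  a <- object@atoms
  if (nrow(a) == 0L) return("structure contains no atoms")
  missing <- setdiff(.atomCols, names(a))
  if (length(missing))
    return(paste("atom table lacks columns:", paste(missing, collapse = ", ")))
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("atom coordinates must be finite")
  if (any(is.na(a$element) | a$element == ""))
    return("every atom needs an element symbol")
  TRUE
})

#' SlabPartition: division of the membrane normal into slabs
#'
#' Half-open intervals `[z0 + k*t, z0 + (k+1)*t)` for `k = 0 .. nSlabs-1`;
#' an atom on a boundary belongs to the upper-indexed slab. Defaults follow
#' the eleven 3-angstrom-slice convention.
#'
#' @slot thickness slab thickness, angstrom (> 0).
#' @slot nSlabs number of slabs (>= 1).
#' @slot z0 lower boundary of the first slab, angstrom.
#' @export
setClass("SlabPartition",
  representation(thickness = "numeric", nSlabs = "integer", z0 = "numeric"),
  prototype(thickness = 3, nSlabs = 11L, z0 = 0)
)

setValidity("SlabPartition", function(object) {
  if (length(object@thickness) != 1L || !is.finite(object@thickness) ||
      object@thickness <= 0) return("thickness must be a single positive number")
  if (length(object@nSlabs) != 1L || object@nSlabs < 1L)
    return("nSlabs must be >= 1")
  if (length(object@z0) != 1L || is.nan(object@z0) || is.infinite(object@z0))
    return("z0 must be a single finite number or NA (anchor at structure minimum)")
  TRUE
})

#' ChargeProfile: per-slab summed charges and centers of charge
#'
#' Result of [slabProfile()]. Carries both the slab-binned (paper-faithful)
#' center of charge and the exact atomwise charge-weighted centroid.
#'
#' @slot slabCharges summed charge per slab, e.
#' @slot slabMidpoints slab midpoints, angstrom.
#' @slot totalCharge sum of all atomic charges, e.
#' @slot centerSlabwise charge-weighted mean of slab midpoints, angstrom
#'   (`NA` when totalCharge is 0).
#' @slot centerAtomwise atomwise charge-weighted centroid, angstrom.
#' @slot partition the [SlabPartition-class] used.
#' @export
setClass("ChargeProfile",
  representation(slabCharges = "numeric", slabMidpoints = "numeric",
                 totalCharge = "numeric", centerSlabwise = "numeric",
                 centerAtomwise = "numeric", partition = "SlabPartition")
)

setValidity("ChargeProfile", function(object) {
  if (length(object@slabCharges) != length(object@slabMidpoints))
    return("slabCharges and slabMidpoints differ in length")
  if (abs(sum(object@slabCharges) - object@totalCharge) > 1e-6)
    return("slab charges do not sum to totalCharge (within 1e-6 e)")
  TRUE
})

#' ProtonationState: nominal side-chain charge assignment
#'
#' Maps residue labels (e.g. `"Y266"`) to nominal charge tags from
#' `"-"`, `"0"`, `"+"`.
#'
#' @slot charges named character vector; names are residue labels, values
#'   one of `"-"`, `"0"`, `"+"`.
#' @seealso [protonationState()], [parseProtonationState()]
#' @export
setClass("ProtonationState", representation(charges = "character"))

setValidity("ProtonationState", function(object) {
  ch <- object@charges
  if (length(ch) && (is.null(names(ch)) || any(names(ch) == "")))
    return("every charge tag needs a residue label")
  if (anyDuplicated(names(ch))) return("residue labels must be unique")
  if (!all(ch %in% c("-", "0", "+")))
    return("charge tags must be one of '-', '0', '+'")
  TRUE
})

#' StateEnergyTable: protonation-state energies across applied voltages
#'
#' Rows keyed by (state label, voltage). Energies are relative (kJ/mol);
#' an optional exchange-correlation column `xc` may be carried.
#'
#' @slot table data.frame with columns `state` (label), `voltage` (mV),
#'   `energy` (kJ/mol) and `xc` (kJ/mol, may be `NA`).
#' @slot states named list of [ProtonationState-class] objects keyed by
#'   state label (may be empty).
#' @seealso [stateEnergyTable()], [minEnergyState()], [crossingPoint()]
#' @export
setClass("StateEnergyTable",
  representation(table = "data.frame", states = "list"),
  prototype(states = list())
)

setValidity("StateEnergyTable", function(object) {
  tb <- object@table
  need <- c("state", "voltage", "energy", "xc")
  if (!all(need %in% names(tb)))
    return("table needs columns state, voltage, energy, xc")
  if (anyDuplicated(tb[c("state", "voltage")]))
    return("(state, voltage) pairs must be unique")
  if (!all(is.finite(tb$voltage)) || !all(is.finite(tb$energy)))
    return("voltages and energies must be finite")
  TRUE
})

#' GatingDataset: open probability versus applied voltage
#'
#' @slot voltage applied voltages, mV.
#' @slot po open probabilities in `[0, 1]`.
#' @slot temperature absolute temperature, K.
#' @seealso [gatingDataset()], [fitBoltzmann()]
#' @export
setClass("GatingDataset",
  representation(voltage = "numeric", po = "numeric", temperature = "numeric"),
  prototype(temperature = 300)
)

setValidity("GatingDataset", function(object) {
  if (length(object@voltage) != length(object@po))
    return("voltage and po differ in length")
  if (!all(is.finite(object@voltage))) return("voltages must be finite")
  if (any(object@po < 0 | object@po > 1))
    return("open probabilities must lie in [0, 1]")
  if (object@temperature <= 0) return("temperature must be positive")
  TRUE
})

#' BoltzmannFit: fitted two-state gating curve
#'
#' @slot q gating charge estimate, elementary charges.
#' @slot vHalf midpoint voltage estimate, mV.
#' @slot se named standard errors for `q` and `vHalf`.
#' @slot covariance 2x2 covariance matrix of the estimates.
#' @slot residuals fit residuals on the probability scale.
#' @slot temperature temperature the fit was evaluated at, K.
#' @export
setClass("BoltzmannFit",
  representation(q = "numeric", vHalf = "numeric", se = "numeric",
                 covariance = "matrix", residuals = "numeric",
                 temperature = "numeric")
)

#' ThresholdModel: Gaussian-distributed transition threshold
#'
#' Open probability as the probability that the voltage-coupled energy drive
#' exceeds a Gaussian-distributed threshold of the given width (thermal
#' units, default one kBT).
#'
#' @slot meanThreshold mean threshold energy, kBT units.
#' @slot width threshold distribution width, kBT units (> 0).
#' @slot q charges coupling voltage to energy, elementary charges.
#' @seealso [thresholdPo()], [thresholdVsBoltzmannDeviation()]
#' @export
setClass("ThresholdModel",
  representation(meanThreshold = "numeric", width = "numeric", q = "numeric"),
  prototype(width = 1)
)

setValidity("ThresholdModel", function(object) {
  if (object@width <= 0) return("width must be positive")
  TRUE
})

#' ConductanceDataset: relative conductance versus ion concentration
#'
#' @slot concentration ion concentrations, mM (> 0).
#' @slot conductance relative conductances.
#' @slot temperature absolute temperature, K.
#' @slot referenceConcentration concentration the free-energy shift is
#'   referred to, mM.
#' @seealso [freeEnergyShift()], [barrierLinearity()]
#' @export
setClass("ConductanceDataset",
  representation(concentration = "numeric", conductance = "numeric",
                 temperature = "numeric", referenceConcentration = "numeric"),
  prototype(temperature = 298)
)

setValidity("ConductanceDataset", function(object) {
  if (length(object@concentration) != length(object@conductance))
    return("concentration and conductance differ in length")
  if (any(object@concentration <= 0))
    return("concentrations must be positive")
  if (object@referenceConcentration <= 0)
    return("referenceConcentration must be positive")
  TRUE
})

#' SiteGraph: hydrogen-bond donor/acceptor sites with distance edges
#'
#' Nodes are proton-capable sites (side-chain or water atoms with a
#' donor/acceptor/both role); edges connect donor-capable to
#' acceptor-capable sites of different residues within a heavy-atom
#' distance cutoff.
#'
#' @slot sites data.frame with columns `residue` (label such as `"Y266"`),
#'   `resid`, `resno`, `chain`, `atom`, `role` (`"donor"`, `"acceptor"`,
#'   `"both"`), `x`, `y`, `z`.
#' @slot edges data.frame with columns `i`, `j` (row indices into `sites`)
#'   and `distance` (angstrom).
#' @slot cutoff heavy-atom distance cutoff used, angstrom.
#' @seealso [assignSites()], [buildGraph()], [enumeratePaths()]
#' @export
setClass("SiteGraph",
  representation(sites = "data.frame", edges = "data.frame",
                 cutoff = "numeric"),
  prototype(cutoff = 3.5)
)

#' FixtureManifest: planted ground truth for generated fixtures
#'
#' @slot seed integer seed the fixture was generated from.
#' @slot truths named list of planted values (net charge, centers of
#'   charge, crossing point, true gating parameters, triads, paths, ...).
#' @export
setClass("FixtureManifest",
  representation(seed = "integer", truths = "list")
)
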