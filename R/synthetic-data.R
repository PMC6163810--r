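# run expr with a private RNG stream; the global .Random.seed is restored
.withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Planted side-chain motif: minimal functional-atom proxies laid out so the
# residue-level hydrogen-bond graph is
#   R303-Y266, R303-E226, Y266-R300, E226-R300, R300-E183
# (two simple paths R303 -> E183; one after deleting Y266). Coordinates are
# in-plane at the motif z; hydrogen-bond contacts are 2.5-3.2 A and
# non-bonded pairs exceed the 3.5 A cutoff.
.motifAtoms <- function(zMotif = 15) {
  data.frame(
    elety = c("NE", "NH1", "NH2", "NE", "NH1", "NH2", "OH",
              "OE1", "OE2", "OE1", "OE2"),
    element = c("N", "N", "N", "N", "N", "N", "O", "O", "O", "O", "O"),
    resid = c(rep("ARG", 3), rep("ARG", 3), "TYR",
              rep("GLU", 2), rep("GLU", 2)),
    resno = c(rep(303L, 3), rep(300L, 3), 266L, rep(226L, 2), rep(183L, 2)),
    chain = "A",
    x = c(0, 0.3, -0.3, 3.0, 3.3, 2.7, 1.5, 1.5, 1.7, 5.511, 5.711),
    y = c(0, 0.2, 0.2, 0, 0.2, 0.2, 2.482, -2.482, -2.6, 1.45, 1.59),
    z = zMotif,
    stringsAsFactors = FALSE
  )
}

# triad set implied by the motif geometry above (window 6 A), derived
# analytically from the planted coordinates
.motifTriads <- function() {
  data.frame(
    pattern = c("RER", "RER", "YRE", "YRE", "YRE", "YRE"),
    res1 = c("R300", "R300", "Y266", "Y266", "Y266", "Y266"),
    res2 = c("E183", "E226", "R300", "R300", "R303", "R303"),
    res3 = c("R303", "R303", "E183", "E226", "E183", "E226"),
    stringsAsFactors = FALSE
  )
}

#' Generate a charged structure with planted geometry
#'
#' Builds a synthetic cluster shaped like the voltage-sensor analysis
#' target: a Y266/R300/E183 + R303/E226 side-chain motif whose
#' hydrogen-bond graph carries exactly two proton paths from R303 to E183
#' (one surviving a Y266 deletion), a cleft of water molecules at the
#' extracellular end, and apolar filler atoms. Atomic charges are drawn
#' randomly and balanced so they sum exactly to `netCharge`; all
#' coordinates are then rigidly translated along the membrane normal so
#' the charge-weighted centroid sits exactly at `plantedCoc`.
#'
#' Motif proxies use real residue and atom names (TYR OH, ARG NE/NH1/NH2,
#' GLU OE1/OE2), so the site-typing rules of [assignSites()] apply
#' unchanged. The default size mirrors a ~10^3-atom cluster with 24
#' waters and net charge +2.
#'
#' @param nAtoms total atom count (default 976); must cover the 11 motif
#'   atoms plus `nWaters`.
#' @param netCharge exact sum of atomic charges, e (default +2).
#' @param plantedCoc planted atomwise center of charge, angstrom
#'   (ignored when `netCharge` is 0).
#' @param nWaters number of water molecules in the extracellular cleft.
#' @param seed integer seed; identical seeds give identical fixtures.
#' @param dir optional directory: when given, `structure.pdb`,
#'   `charges.tsv` and `manifest.json` (if jsonlite is available) are
#'   written there.
#' @return List with `structure` (a [ChargedStructure-class], charges
#'   attached), `chargeTable` (data.frame serial/charge) and `manifest`
#'   (a [FixtureManifest-class] recording every planted truth).
#' @examples
#' fix <- genStructure(seed = 1)
#' nAtoms(fix$structure)
#' netCharge(fix$structure)
#' @export
genStructure <- function(nAtoms = 976L, netCharge = 2, plantedCoc = 15,
                         nWaters = 24L, seed = 1L, dir = NULL) {
  motif <- .motifAtoms()
  nMotif <- nrow(motif)
  nFiller <- nAtoms - nMotif - nWaters
  if (nFiller < 0L)
    stop("infeasible spec: nAtoms = ", nAtoms, " cannot hold ", nMotif,
         " motif atoms plus ", nWaters, " waters")
  .withSeed(seed, {
    parts <- list(motif)
    if (nWaters > 0L)
      parts$water <- data.frame(
        elety = "O", element = "O", resid = "HOH",
        resno = 500L + seq_len(nWaters), chain = "W",
        x = stats::runif(nWaters, -10, 10),
        y = stats::runif(nWaters, -10, 10),
        z = stats::runif(nWaters, 26, 29.5),
        stringsAsFactors = FALSE)
    if (nFiller > 0L)
      parts$filler <- data.frame(
        elety = "CB", element = "C", resid = "ALA",
        resno = seq_len(nFiller), chain = "B",
        x = stats::runif(nFiller, -12, 12),
        y = stats::runif(nFiller, -12, 12),
        z = stats::runif(nFiller, 0.2, 29.8),
        stringsAsFactors = FALSE)
    a <- do.call(rbind, parts)
    a <- data.frame(serial = seq_len(nrow(a)), a, charge = NA_real_,
                    stringsAsFactors = FALSE)
    rownames(a) <- NULL

    ch <- stats::rnorm(nrow(a), 0, 0.3)
    balanceIdx <- if (nFiller > 0L) which(a$resid == "ALA") else seq_len(nrow(a))
    ch[balanceIdx] <- ch[balanceIdx] - (sum(ch) - netCharge) / length(balanceIdx)
    a$charge <- ch

    if (netCharge != 0 && !is.na(plantedCoc)) {
      coc <- sum(a$charge * a$z) / sum(a$charge)
      a$z <- a$z + (plantedCoc - coc)
    }
  })

  s <- new("ChargedStructure", atoms = a[, .atomCols],
           frame = list(origin = min(a$z),
                        note = "z = membrane normal, increasing extracellular"))
  chargeTable <- data.frame(serial = a$serial, charge = a$charge)
  counts <- table(.residueLabel(a$resid, a$resno))
  manifest <- new("FixtureManifest", seed = as.integer(seed), truths = list(
    nAtoms = nrow(a), netCharge = netCharge,
    centerOfCharge = if (netCharge != 0 && !is.na(plantedCoc)) plantedCoc
                     else if (netCharge != 0) sum(a$charge * a$z) / sum(a$charge)
                     else NA_real_,
    nWaters = nWaters, nMotifAtoms = nMotif,
    motifAtomCounts = as.list(counts[c("R303", "R300", "Y266", "E226", "E183")]),
    atomsResno290to310 = sum(a$resno >= 290 & a$resno <= 310 & a$chain == "A"),
    edges = list(c("R303", "Y266"), c("R303", "E226"), c("Y266", "R300"),
                 c("E226", "R300"), c("R300", "E183")),
    triads = .motifTriads(),
    paths = list(c("R303", "E226", "R300", "E183"),
                 c("R303", "Y266", "R300", "E183")),
    pathCount = 2L, pathCountWithoutY266 = 1L
  ))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeStructure(s, file.path(dir, "structure.pdb"))
    utils::write.table(
      data.frame(serial = chargeTable$serial,
                 charge = sprintf("%.10f", chargeTable$charge)),
      file.path(dir, "charges.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    .writeManifest(manifest, file.path(dir, "manifest.json"))
  }
  list(structure = attachCharges(s, chargeTable),
       chargeTable = chargeTable, manifest = manifest)
}

.writeManifest <- function(manifest, path) {
  if (requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(c(list(seed = manifest@seed), manifest@truths),
                         path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' Generate a rigidly shifted pair of charged structures
#'
#' Produces two structures identical up to a rigid translation of `delta`
#' angstrom along the membrane normal, emulating the closed/open pair of
#' charge distributions: state A (polarized) sits `delta` extracellular of
#' state B, so the center-of-charge displacement A - B equals `delta`
#' exactly.
#'
#' @param delta planted displacement, angstrom (default 11.3).
#' @param plantedCoc center of charge of state B, angstrom (default 8.3,
#'   so state A sits at 19.6 by construction).
#' @param ... passed to [genStructure()] (`nAtoms`, `netCharge`, ...).
#' @param seed integer seed.
#' @return List with `stateA`, `stateB` (both [ChargedStructure-class])
#'   and `manifest` recording `delta` and both centers.
#' @examples
#' pair <- genStructurePair(seed = 1)
#' centerOfCharge(pair$stateA) - centerOfCharge(pair$stateB)
#' @export
genStructurePair <- function(delta = 11.3, plantedCoc = 8.3, seed = 1L, ...) {
  fix <- genStructure(plantedCoc = plantedCoc, seed = seed, ...)
  stateB <- fix$structure
  stateA <- stateB
  stateA@atoms$z <- stateA@atoms$z + delta
  stateA@frame$origin <- stateA@frame$origin + delta
  manifest <- new("FixtureManifest", seed = as.integer(seed), truths = list(
    delta = delta, centerA = plantedCoc + delta, centerB = plantedCoc,
    netCharge = fix$manifest@truths$netCharge))
  list(stateA = stateA, stateB = stateB, manifest = manifest)
}

#' Generate a state-energy table with a planted crossing
#'
#' Two designated protonation states -- an all-neutral "closed" state and
#' a tyrosine-ionized "open" state -- receive energies linear in voltage
#' that cross exactly at the planted point; since both are globally
#' linear, piecewise-linear interpolation on the grid recovers the planted
#' crossing exactly. All remaining states are strictly above both
#' everywhere on the grid. The closed state attains its grid minimum at
#' the most negative voltage, and the crossing height is measured above
#' that minimum. Exchange-correlation terms are planted as constants for
#' the two designated states.
#'
#' @param crossingVoltage planted crossing voltage, mV; must lie inside
#'   the grid span (default -20).
#' @param crossingHeight planted height above the closed-state minimum,
#'   kJ/mol (default 60).
#' @param voltageGrid voltage grid, mV (default -70, -35, 0, +35, +70).
#' @param nStates total number of states including the two planted ones
#'   (default 29).
#' @param xcClosed,xcOpen planted exchange-correlation terms, kJ/mol.
#' @param seed integer seed.
#' @return List with `table` (a [StateEnergyTable-class]) and `manifest`
#'   (planted crossing, state labels, xc difference).
#' @examples
#' tab <- genEnergyTable(seed = 1)
#' crossingPoint(tab$table, "Y266:0|R300:0|E183:0", "Y266:-|R300:+|E183:0")
#' @export
genEnergyTable <- function(crossingVoltage = -20, crossingHeight = 60,
                           voltageGrid = c(-70, -35, 0, 35, 70),
                           nStates = 29L,
                           xcClosed = 96.0, xcOpen = 25.2, seed = 1L) {
  voltageGrid <- sort(voltageGrid)
  vMin <- min(voltageGrid); vMax <- max(voltageGrid)
  if (crossingVoltage <= vMin || crossingVoltage >= vMax)
    stop("infeasible spec: crossing voltage ", crossingVoltage,
         " mV outside the grid span (", vMin, ", ", vMax, ")")
  if (crossingHeight <= 0) stop("crossing height must be positive")
  if (nStates < 2L) stop("need at least the two planted states")
  closedLabel <- "Y266:0|R300:0|E183:0"
  openLabel <- "Y266:-|R300:+|E183:0"

  .withSeed(seed, {
    slopeClosed <- crossingHeight / (crossingVoltage - vMin)
    eClosed <- slopeClosed * (voltageGrid - vMin)
    slopeOpen <- stats::runif(1, 0.5, 2) * slopeClosed
    eOpen <- crossingHeight + slopeOpen * (crossingVoltage - voltageGrid)

    state <- c(rep(closedLabel, length(voltageGrid)),
               rep(openLabel, length(voltageGrid)))
    voltage <- c(voltageGrid, voltageGrid)
    energy <- c(eClosed, eOpen)
    xc <- c(rep(xcClosed, length(voltageGrid)),
            rep(xcOpen, length(voltageGrid)))

    tags <- c("-", "0", "+")
    extraLabels <- character(0)
    while (length(extraLabels) < nStates - 2L) {
      lab <- paste0("Y266:", sample(tags, 1), "|R300:", sample(tags, 1),
                    "|E183:", sample(tags, 1), "|H418:", sample(tags, 1))
      if (!(lab %in% c(closedLabel, openLabel, extraLabels)))
        extraLabels <- c(extraLabels, lab)
    }
    for (lab in extraLabels) {
      offset <- stats::runif(1, 5, 80)
      state <- c(state, rep(lab, length(voltageGrid)))
      voltage <- c(voltage, voltageGrid)
      energy <- c(energy, pmax(eClosed, eOpen) + offset)
      xc <- c(xc, rep(stats::runif(1, 10, 120), length(voltageGrid)))
    }
  })

  tab <- stateEnergyTable(state, voltage, energy, xc)
  manifest <- new("FixtureManifest", seed = as.integer(seed), truths = list(
    crossingVoltage = crossingVoltage, crossingHeight = crossingHeight,
    stateClosed = closedLabel, stateOpen = openLabel,
    xcDelta = xcClosed - xcOpen, voltageGrid = voltageGrid,
    nStates = nStates))
  list(table = tab, manifest = manifest)
}

#' Generate a noisy Boltzmann gating dataset
#'
#' Open probabilities are Boltzmann evaluations at `nVoltages` voltages
#' spanning the transition, plus Gaussian noise clipped to `[0, 1]`.
#'
#' @param q true gating charge, e (default 13).
#' @param vHalf true midpoint, mV (default -30).
#' @param noiseSd Gaussian noise standard deviation on the probability
#'   scale (default 0.02).
#' @param nVoltages number of voltages (default 41).
#' @param t temperature, K.
#' @param span half-width of the voltage window around `vHalf`, mV.
#' @param seed integer seed.
#' @return List with `dataset` (a [GatingDataset-class]) and `manifest`
#'   recording the true parameters.
#' @examples
#' d <- genGatingDataset(noiseSd = 0, seed = 1)
#' gatingCharge(fitBoltzmann(d$dataset))
#' @export
genGatingDataset <- function(q = 13, vHalf = -30, noiseSd = 0.02,
                             nVoltages = 41L, t = 300, span = 20,
                             seed = 1L) {
  if (nVoltages < 3L) stop("need at least 3 voltages")
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  v <- seq(vHalf - span, vHalf + span, length.out = nVoltages)
  po <- boltzmannPo(v, q, vHalf, t)
  if (noiseSd > 0)
    po <- .withSeed(seed, pmin(pmax(po + stats::rnorm(nVoltages, 0, noiseSd),
                                    0), 1))
  manifest <- new("FixtureManifest", seed = as.integer(seed), truths = list(
    q = q, vHalf = vHalf, noiseSd = noiseSd, temperature = t))
  list(dataset = gatingDataset(v, po, t), manifest = manifest)
}

#' Generate a power-law conductance dataset
#'
#' Log-conductance is linear in log-concentration (a single conduction
#' barrier) with multiplicative log-normal noise; conductance is 1 at the
#' reference (lowest) concentration.
#'
#' @param slope true log-log slope (default 1).
#' @param nPoints number of concentrations, log-spaced (default 10).
#' @param noise multiplicative noise level (standard deviation of log
#'   conductance, default 0.05).
#' @param concRange concentration range, mM.
#' @param t temperature, K.
#' @param seed integer seed.
#' @return List with `dataset` (a [ConductanceDataset-class]) and
#'   `manifest` recording the true slope.
#' @examples
#' d <- genConductanceDataset(noise = 0, seed = 1)
#' barrierLinearity(d$dataset)$rSquared
#' @export
genConductanceDataset <- function(slope = 1, nPoints = 10L, noise = 0.05,
                                  concRange = c(1, 1000), t = 298,
                                  seed = 1L) {
  if (nPoints < 3L) stop("need at least 3 points")
  conc <- exp(seq(log(concRange[1]), log(concRange[2]),
                  length.out = nPoints))
  g <- (conc / conc[1])^slope
  if (noise > 0)
    g <- .withSeed(seed, g * exp(stats::rnorm(nPoints, 0, noise)))
  manifest <- new("FixtureManifest", seed = as.integer(seed), truths = list(
    slope = slope, noise = noise))
  list(dataset = conductanceDataset(conc, g, temperature = t,
                                    referenceConcentration = conc[1]),
       manifest = manifest)
}

#' @describeIn FixtureManifest-accessors planted truths of a fixture
#' @export
truths <- function(x) {
  stopifnot(is(x, "FixtureManifest"))
  x@truths
}

#' Accessors for FixtureManifest
#' @param x a [FixtureManifest-class].
#' @name FixtureManifest-accessors
NULL

setMethod("show", "FixtureManifest", function(object) {
  cat("FixtureManifest (seed", object@seed, "):",
      paste(names(object@truths), collapse = ", "), "\n")
})
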