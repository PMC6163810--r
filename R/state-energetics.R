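#' Construct a protonation state
#'
#' @param ... residue = tag pairs, e.g. `protonationState(Y266 = "-",
#'   R300 = "+", E183 = "0")`, or a single named character vector.
#' @return A [ProtonationState-class].
#' @export
protonationState <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.character(args[[1]]) && length(args[[1]]) > 1L)
    charges <- args[[1]]
  else charges <- unlist(args)
  new("ProtonationState", charges = charges)
}

#' Parse a protonation state from a compact label
#'
#' Labels take the form `"Y266:-|R300:+|E183:0"`; this is the label syntax
#' the synthetic-data generator writes into state-energy tables.
#'
#' @param label character label.
#' @return A [ProtonationState-class].
#' @examples
#' parseProtonationState("Y266:0|R300:0|E183:0")
#' @export
parseProtonationState <- function(label) {
  parts <- strsplit(label, "|", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("malformed state label: ", label)
  charges <- vapply(kv, `[`, character(1), 2)
  names(charges) <- vapply(kv, `[`, character(1), 1)
  new("ProtonationState", charges = charges)
}

#' @describeIn ProtonationState-utils charge tags of a state
#' @export
residueCharges <- function(x) {
  stopifnot(is(x, "ProtonationState"))
  x@charges
}

#' Utilities for ProtonationState
#' @param x a [ProtonationState-class].
#' @name ProtonationState-utils
NULL

setMethod("show", "ProtonationState", function(object) {
  cat("ProtonationState:",
      paste(names(object@charges), object@charges, sep = ":", collapse = " "),
      "\n")
})

#' Construct a state-energy table
#'
#' Energies are treated as relative (kJ/mol); the optional `xc` column
#' carries an exchange-correlation decomposition term.
#'
#' @param state character vector of state labels.
#' @param voltage applied voltages, mV.
#' @param energy energies, kJ/mol.
#' @param xc optional exchange-correlation energies, kJ/mol.
#' @param states optional named list of [ProtonationState-class] objects
#'   keyed by label; labels of the form parsed by
#'   [parseProtonationState()] are decoded automatically.
#' @return A [StateEnergyTable-class].
#' @seealso [readStateEnergyTable()], [minEnergyState()], [crossingPoint()]
#' @export
stateEnergyTable <- function(state, voltage, energy, xc = NA_real_,
                             states = NULL) {
  tb <- data.frame(state = as.character(state), voltage = as.numeric(voltage),
                   energy = as.numeric(energy), xc = as.numeric(xc),
                   stringsAsFactors = FALSE)
  if (is.null(states)) {
    states <- list()
    for (lab in unique(tb$state)) {
      ps <- tryCatch(parseProtonationState(lab), error = function(e) NULL)
      if (!is.null(ps)) states[[lab]] <- ps
    }
  }
  new("StateEnergyTable", table = tb, states = states)
}

#' Read a state-energy table from delimited text
#'
#' Expects columns `state_label`, `voltage_mV`, `energy_kJ_mol` and
#' optionally `xc_kJ_mol` (header required; TSV or CSV).
#'
#' @param path file path.
#' @param sep field separator (default: tab or whitespace).
#' @return A [StateEnergyTable-class].
#' @export
readStateEnergyTable <- function(path, sep = "") {
  tb <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("state_label", "voltage_mV", "energy_kJ_mol")
  if (!all(need %in% names(tb)))
    stop("state-energy table needs columns ", paste(need, collapse = ", "))
  stateEnergyTable(tb$state_label, tb$voltage_mV, tb$energy_kJ_mol,
                   if ("xc_kJ_mol" %in% names(tb)) tb$xc_kJ_mol else NA_real_)
}

#' Write a state-energy table to tab-delimited text
#'
#' @param x a [StateEnergyTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStateEnergyTable <- function(x, path) {
  stopifnot(is(x, "StateEnergyTable"))
  out <- x@table
  names(out) <- c("state_label", "voltage_mV", "energy_kJ_mol", "xc_kJ_mol")
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn StateEnergyTable-accessors distinct voltages in the table, mV
#' @export
setMethod("voltages", "StateEnergyTable",
          function(x) sort(unique(x@table$voltage)))

#' Accessors for StateEnergyTable
#' @param x a [StateEnergyTable-class].
#' @name StateEnergyTable-accessors
NULL

#' @describeIn StateEnergyTable-accessors distinct state labels
#' @export
setMethod("stateLabels", "StateEnergyTable",
          function(x) unique(x@table$state))

#' @rdname StateEnergyTable-accessors
#' @export
energyTable <- function(x) {
  stopifnot(is(x, "StateEnergyTable"))
  x@table
}

#' Minimum-energy protonation state at a voltage
#'
#' Returns the label of the state with the lowest energy at the given
#' voltage. Exact ties are an error listing the tied states (the caller
#' must disambiguate); adding a constant to all energies at a voltage does
#' not change the result.
#'
#' @param x a [StateEnergyTable-class].
#' @param voltage applied voltage, mV (must be present in the table).
#' @return State label (character); the decoded
#'   [ProtonationState-class], when known, is attached as attribute
#'   `"protonationState"`.
#' @export
setMethod("minEnergyState", "StateEnergyTable", function(x, voltage, ...) {
  rows <- x@table[x@table$voltage == voltage, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no states tabulated at voltage ", voltage, " mV")
  emin <- min(rows$energy)
  winners <- rows$state[rows$energy == emin]
  if (length(winners) > 1L)
    stop("tied minimum energy at ", voltage, " mV between states: ",
         paste(winners, collapse = ", "))
  out <- winners
  if (!is.null(x@states[[out]]))
    attr(out, "protonationState") <- x@states[[out]]
  out
})

#' Voltage at which two protonation states cross in energy
#'
#' Interpolates the energy difference `E_A(V) - E_B(V)` piecewise-linearly
#' over the voltages common to both states and locates its sign change.
#' The crossing height is the interpolated energy at the crossing minus
#' the minimum grid energy of the reference state (default: state A, the
#' closed-state convention). A difference that never changes sign is a
#' no-crossing result, not an error.
#'
#' @param x a [StateEnergyTable-class].
#' @param stateA,stateB state labels; both must be tabulated at two or
#'   more common voltages.
#' @param reference label of the state whose grid minimum anchors the
#'   height (default `stateA`).
#' @return A list with `crossing` (logical), `voltage` (mV) and `height`
#'   (kJ/mol above the reference minimum); `voltage` and `height` are `NA`
#'   when there is no crossing.
#' @examples
#' tab <- genEnergyTable(seed = 1)
#' crossingPoint(tab$table, tab$manifest@truths$stateClosed,
#'               tab$manifest@truths$stateOpen)
#' @export
setMethod("crossingPoint", "StateEnergyTable",
  function(x, stateA, stateB, reference = stateA, ...) {
    tb <- x@table
    a <- tb[tb$state == stateA, , drop = FALSE]
    b <- tb[tb$state == stateB, , drop = FALSE]
    if (nrow(a) == 0L) stop("state not in table: ", stateA)
    if (nrow(b) == 0L) stop("state not in table: ", stateB)
    v <- sort(intersect(a$voltage, b$voltage))
    if (length(v) < 2L)
      stop("insufficient data: states share fewer than 2 voltages")
    ea <- a$energy[match(v, a$voltage)]
    eb <- b$energy[match(v, b$voltage)]
    d <- ea - eb
    refRows <- tb[tb$state == reference, , drop = FALSE]
    if (nrow(refRows) == 0L) stop("reference state not in table: ", reference)
    refMin <- min(refRows$energy)

    vStar <- NA_real_
    for (i in seq_len(length(v) - 1L)) {
      if (d[i] == 0) { vStar <- v[i]; break }
      if (d[i] * d[i + 1L] < 0) {
        vStar <- v[i] - d[i] * (v[i + 1L] - v[i]) / (d[i + 1L] - d[i])
        break
      }
    }
    if (is.na(vStar) && d[length(d)] == 0) vStar <- v[length(v)]
    if (is.na(vStar))
      return(list(crossing = FALSE, voltage = NA_real_, height = NA_real_))
    eStar <- stats::approx(v, ea, xout = vStar)$y
    list(crossing = TRUE, voltage = vStar, height = eStar - refMin)
  })

#' Difference of an energy-decomposition term between two states
#'
#' Looks up the named term (e.g. the exchange-correlation column `"xc"`)
#' for both states at one voltage and returns `term(A) - term(B)` in
#' kJ/mol.
#'
#' @param x a [StateEnergyTable-class].
#' @param stateA,stateB state labels.
#' @param voltage applied voltage, mV.
#' @param term column name of the decomposition term (default `"xc"`).
#' @return Difference, kJ/mol.
#' @export
setMethod("decompositionDelta", "StateEnergyTable",
  function(x, stateA, stateB, voltage, term = "xc", ...) {
    tb <- x@table
    if (!term %in% names(tb)) stop("unknown decomposition term: ", term)
    pick <- function(s) {
      row <- tb[tb$state == s & tb$voltage == voltage, , drop = FALSE]
      if (nrow(row) == 0L)
        stop("state ", s, " not tabulated at ", voltage, " mV")
      val <- row[[term]]
      if (is.na(val)) stop("term '", term, "' absent for state ", s,
                           " at ", voltage, " mV")
      val
    }
    pick(stateA) - pick(stateB)
  })

setMethod("show", "StateEnergyTable", function(object) {
  tb <- object@table
  cat("StateEnergyTable:", length(unique(tb$state)), "states x",
      length(unique(tb$voltage)), "voltages (",
      paste(sort(unique(tb$voltage)), collapse = ", "), "mV )\n")
  cat("  energy range:", paste(round(range(tb$energy), 2), collapse = " .. "),
      "kJ/mol;", if (all(is.na(tb$xc))) "no" else "with",
      "xc decomposition\n")
})
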