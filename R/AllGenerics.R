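#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @export
setGeneric("netCharge", function(x) standardGeneric("netCharge"))

#' @export
setGeneric("attachCharges", function(x, table, ...)
  standardGeneric("attachCharges"))

#' @export
setGeneric("selectRegion", function(x, ...) standardGeneric("selectRegion"))

#' @export
setGeneric("slabProfile", function(x, partition = slabPartition(), ...)
  standardGeneric("slabProfile"))

#' @export
setGeneric("centerOfCharge", function(x, ...)
  standardGeneric("centerOfCharge"))

#' @export
setGeneric("totalCharge", function(x) standardGeneric("totalCharge"))

#' @export
setGeneric("displacement", function(a, b, ...) standardGeneric("displacement"))

#' @export
setGeneric("minEnergyState", function(x, voltage, ...)
  standardGeneric("minEnergyState"))

#' @export
setGeneric("crossingPoint", function(x, stateA, stateB, ...)
  standardGeneric("crossingPoint"))

#' @export
setGeneric("decompositionDelta",
  function(x, stateA, stateB, voltage, term = "xc", ...)
    standardGeneric("decompositionDelta"))

#' @export
setGeneric("voltages", function(x) standardGeneric("voltages"))

#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @export
setGeneric("fitBoltzmann", function(x, ...) standardGeneric("fitBoltzmann"))

#' @export
setGeneric("freeEnergyShift", function(concentration, x, ...)
  standardGeneric("freeEnergyShift"))

#' @export
setGeneric("barrierLinearity", function(x, ...)
  standardGeneric("barrierLinearity"))

#' @export
setGeneric("assignSites", function(x, protonation = NULL, ...)
  standardGeneric("assignSites"))

#' @export
setGeneric("buildGraph", function(x, cutoff = 3.5, ...)
  standardGeneric("buildGraph"))

#' @export
setGeneric("findTriads", function(x, window = 6.0, ...)
  standardGeneric("findTriads"))

#' @export
setGeneric("enumeratePaths", function(x, from, to, maxHops = 6L, ...)
  standardGeneric("enumeratePaths"))
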