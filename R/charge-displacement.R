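#' Construct a slab partition of the membrane normal
#'
#' Defaults to eleven 3-angstrom slices; `z0` defaults (at profile time) to
#' the minimum z of the structure being profiled. Slabs are half-open
#' intervals `[z0 + k*t, z0 + (k+1)*t)`, so a boundary atom belongs to the
#' upper-indexed slab.
#'
#' @param thickness slab thickness, angstrom.
#' @param nSlabs number of slabs.
#' @param z0 lower boundary of the first slab, angstrom (`NA` = take the
#'   structure minimum).
#' @return A [SlabPartition-class].
#' @export
slabPartition <- function(thickness = 3, nSlabs = 11L, z0 = NA_real_) {
  new("SlabPartition", thickness = as.numeric(thickness),
      nSlabs = as.integer(nSlabs), z0 = as.numeric(z0))
}

#' Per-slab charge profile along the membrane normal
#'
#' Sums atomic partial charges within each slab of the partition and
#' derives the center of charge two ways: from the slab sums and midpoints
#' (the paper-faithful, binned estimate) and directly from the atoms (the
#' exact charge-weighted centroid). Atoms falling outside the partition are
#' an error, never silently dropped.
#'
#' @param x a [ChargedStructure-class] with charges attached.
#' @param partition a [SlabPartition-class]; if its `z0` is `NA` it is
#'   anchored at the structure's minimum z.
#' @return A [ChargeProfile-class].
#' @examples
#' s <- genStructure(seed = 1)$structure
#' prof <- slabProfile(s)
#' centerOfCharge(prof)
#' @export
setMethod("slabProfile", "ChargedStructure",
  function(x, partition = slabPartition(), ...) {
    stopifnot(is(partition, "SlabPartition"))
    ch <- x@atoms$charge
    if (anyNA(ch)) stop("charges not attached; see attachCharges()")
    z <- x@atoms$z
    if (is.na(partition@z0)) partition@z0 <- min(z)
    t <- partition@thickness
    n <- partition@nSlabs
    z0 <- partition@z0
    idx <- floor((z - z0) / t)
    out <- idx < 0 | idx >= n
    if (any(out))
      stop("atom(s) outside the slab partition [", z0, ", ", z0 + n * t,
           "): z = ", paste(signif(z[out][seq_len(min(3, sum(out)))], 6),
                            collapse = ", "))
    slabCharges <- vapply(seq_len(n) - 1L,
                          function(k) sum(ch[idx == k]), numeric(1))
    mids <- z0 + (seq_len(n) - 0.5) * t
    tot <- sum(ch)
    new("ChargeProfile",
        slabCharges = slabCharges, slabMidpoints = mids, totalCharge = tot,
        centerSlabwise = if (tot != 0) sum(slabCharges * mids) / tot else NA_real_,
        centerAtomwise = if (tot != 0) sum(ch * z) / tot else NA_real_,
        partition = partition)
  })

#' Center of charge of a profile or structure
#'
#' For a [ChargeProfile-class], returns the charge-weighted mean position
#' along the membrane normal, `sum(Q_s * z_s) / sum(Q_s)`, either from the
#' slab sums (`method = "slabwise"`, the default) or from the atoms
#' (`method = "atomwise"`, exact; bounded within half a slab thickness of
#' the slabwise value). For a [ChargedStructure-class] the atomwise
#' centroid is returned directly. The signed-charge centroid is undefined
#' for zero total charge, which is an error.
#'
#' @param x a [ChargeProfile-class] or [ChargedStructure-class].
#' @param method `"slabwise"` or `"atomwise"`.
#' @return Position along the membrane normal, angstrom.
#' @export
setMethod("centerOfCharge", "ChargeProfile",
  function(x, method = c("slabwise", "atomwise"), ...) {
    method <- match.arg(method)
    if (x@totalCharge == 0)
      stop("center of charge undefined: total charge is zero")
    if (method == "slabwise") x@centerSlabwise else x@centerAtomwise
  })

#' @rdname centerOfCharge-ChargeProfile-method
#' @export
setMethod("centerOfCharge", "ChargedStructure", function(x, ...) {
  ch <- x@atoms$charge
  if (anyNA(ch)) stop("charges not attached; see attachCharges()")
  tot <- sum(ch)
  if (tot == 0) stop("center of charge undefined: total charge is zero")
  sum(ch * x@atoms$z) / tot
})

#' @describeIn ChargeProfile-accessors total charge, e
#' @export
setMethod("totalCharge", "ChargeProfile", function(x) x@totalCharge)

#' Accessors for ChargeProfile
#'
#' `slabCharges()` returns the per-slab charge table (slab index, z range,
#' charge); `totalCharge()` the summed charge.
#'
#' @param x a [ChargeProfile-class].
#' @name ChargeProfile-accessors
NULL

#' @rdname ChargeProfile-accessors
#' @export
slabCharges <- function(x) {
  stopifnot(is(x, "ChargeProfile"))
  p <- x@partition
  data.frame(slab = seq_along(x@slabCharges),
             zLower = p@z0 + (seq_along(x@slabCharges) - 1L) * p@thickness,
             zUpper = p@z0 + seq_along(x@slabCharges) * p@thickness,
             charge = x@slabCharges)
}

#' Displacement of the center of charge between two states
#'
#' Returns `center(A) - center(B)`, signed so that a positive value means
#' an extracellular shift of state A relative to state B. This shift is
#' the gating-charge surrogate: the measured centers 19.6 and 8.3 angstrom
#' for the polarized and depolarized states give a shift of 11.3 angstrom.
#' Profiles must share a partition; the `numeric` method takes two
#' already-measured center positions directly.
#'
#' @param a,b two [ChargeProfile-class] objects on the same partition, or
#'   two center positions (angstrom).
#' @param method which center to difference, `"slabwise"` (default) or
#'   `"atomwise"`.
#' @return Signed displacement, angstrom; antisymmetric in its arguments.
#' @examples
#' displacement(19.6, 8.3)
#' @export
setMethod("displacement", signature("ChargeProfile", "ChargeProfile"),
  function(a, b, method = c("slabwise", "atomwise"), ...) {
    method <- match.arg(method)
    pa <- a@partition; pb <- b@partition
    if (pa@thickness != pb@thickness || pa@nSlabs != pb@nSlabs ||
        !isTRUE(all.equal(pa@z0, pb@z0)))
      stop("incompatible partitions: profiles must share thickness, nSlabs and z0")
    centerOfCharge(a, method) - centerOfCharge(b, method)
  })

#' @rdname displacement-ChargeProfile-ChargeProfile-method
#' @export
setMethod("displacement", signature("numeric", "numeric"),
  function(a, b, ...) a - b)

#' Effective gating charge from a center-of-charge shift
#'
#' If the net charge `netCharge` (e) shifts its center by `delta`
#' (angstrom) through a membrane field dropping over `fieldDropDistance`
#' (angstrom), the equivalent charge moved fully across the field is
#' `netCharge * delta / fieldDropDistance`.
#'
#' @param delta center-of-charge displacement, angstrom.
#' @param netCharge net charge of the system, e.
#' @param fieldDropDistance distance over which the membrane field drops,
#'   angstrom (> 0).
#' @return Effective gating charge, elementary charges.
#' @examples
#' effectiveGatingCharge(11.3, 2, 30)
#' @export
effectiveGatingCharge <- function(delta, netCharge, fieldDropDistance) {
  if (any(fieldDropDistance <= 0))
    stop("fieldDropDistance must be positive")
  netCharge * delta / fieldDropDistance
}

setMethod("show", "ChargeProfile", function(object) {
  p <- object@partition
  cat("ChargeProfile:", p@nSlabs, "slabs x", p@thickness, "A from z0 =",
      round(p@z0, 3), "\n")
  cat("  total charge:", format(object@totalCharge, digits = 6), "e\n")
  if (object@totalCharge != 0)
    cat("  center of charge:", round(object@centerSlabwise, 3),
        "A (slabwise),", round(object@centerAtomwise, 3), "A (atomwise)\n")
})
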