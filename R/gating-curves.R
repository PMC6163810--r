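#' Thermal voltage kB*T/e in millivolts
#'
#' The voltage scale over which one elementary charge picks up one kBT of
#' energy; about 25.9 mV at 300 K.
#'
#' @param t absolute temperature, K.
#' @return Thermal voltage, mV.
#' @export
thermalVoltage <- function(t = 300) {
  if (any(t <= 0)) stop("temperature must be positive")
  1000 * .constants$kB * t / .constants$e
}

#' Construct a gating dataset
#'
#' @param voltage applied voltages, mV.
#' @param po open probabilities in `[0, 1]`.
#' @param temperature absolute temperature, K.
#' @return A [GatingDataset-class].
#' @export
gatingDataset <- function(voltage, po, temperature = 300) {
  new("GatingDataset", voltage = as.numeric(voltage), po = as.numeric(po),
      temperature = as.numeric(temperature))
}

#' Two-state Boltzmann open probability
#'
#' `Po(V) = 1 / (1 + exp(-q e (V - Vhalf) / kB T))`. The classic printed
#' form is the `vHalf = 0` case; the offset accommodates datasets whose
#' transition is not centred at 0 mV. Evaluation saturates smoothly
#' without overflow.
#'
#' @param v applied voltage, mV (vectorised).
#' @param q gating charge, elementary charges.
#' @param vHalf midpoint voltage, mV.
#' @param t absolute temperature, K.
#' @return Open probability in `[0, 1]`.
#' @examples
#' boltzmannPo(c(-60, -30, 0), q = 13, vHalf = -30)
#' @export
boltzmannPo <- function(v, q, vHalf = 0, t = 300) {
  stats::plogis(q * (v - vHalf) / thermalVoltage(t))
}

#' Fit a Boltzmann gating curve
#'
#' Nonlinear least squares on the probability scale (robust to points
#' saturated at 0 or 1), initialised from a logit-scale linear fit.
#' Standard errors are heteroscedasticity-robust (HC3 sandwich): on the
#' probability scale the noise shrinks toward the saturated plateaus, so
#' ordinary least-squares errors understate the sampling spread of the
#' gating charge. Fitting a noiseless Boltzmann recovers its parameters
#' exactly.
#'
#' @param x a [GatingDataset-class] with at least 3 distinct voltages
#'   spanning the transition.
#' @return A [BoltzmannFit-class].
#' @examples
#' d <- genGatingDataset(q = 13, vHalf = -30, noiseSd = 0, seed = 1)$dataset
#' fitBoltzmann(d)
#' @export
setMethod("fitBoltzmann", "GatingDataset", function(x, ...) {
  v <- x@voltage; po <- x@po; t <- x@temperature
  if (length(unique(v)) < 3L)
    stop("need at least 3 distinct voltages to fit")
  if (stats::sd(po) == 0)
    stop("non-identifiable: all open probabilities are equal")
  vT <- thermalVoltage(t)

  # logit-scale linear fit for starting values, with clipped probabilities
  eps <- 1e-6
  lg <- stats::qlogis(pmin(pmax(po, eps), 1 - eps))
  lf <- stats::lm(lg ~ v)
  q0 <- unname(stats::coef(lf)[2]) * vT
  if (!is.finite(q0) || q0 == 0) q0 <- 1
  vh0 <- -unname(stats::coef(lf)[1]) * vT / q0
  if (!is.finite(vh0)) vh0 <- stats::median(v)

  df <- data.frame(v = v, po = po)
  fit <- minpack.lm::nlsLM(
    po ~ stats::plogis(q * (v - vHalf) / vT),
    data = df, start = list(q = q0, vHalf = vh0),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  est <- stats::coef(fit)
  qh <- unname(est["q"]); vh <- unname(est["vHalf"])

  # HC3 sandwich covariance from the analytic jacobian of the sigmoid
  p <- stats::plogis(qh * (v - vh) / vT)
  r <- po - p
  J <- cbind(q = (v - vh) / vT * p * (1 - p),
             vHalf = -qh / vT * p * (1 - p))
  covm <- tryCatch({
    bread <- solve(crossprod(J))
    lev <- pmin(rowSums((J %*% bread) * J), 1 - 1e-8)
    covm <- bread %*% crossprod(J * r / (1 - lev)) %*% bread
    dimnames(covm) <- list(c("q", "vHalf"), c("q", "vHalf"))
    covm
  }, error = function(e)
    matrix(NA_real_, 2, 2, dimnames = list(c("q", "vHalf"), c("q", "vHalf"))))
  new("BoltzmannFit",
      q = qh, vHalf = vh,
      se = c(q = sqrt(covm["q", "q"]), vHalf = sqrt(covm["vHalf", "vHalf"])),
      covariance = covm, residuals = as.numeric(r),
      temperature = t)
})

#' @describeIn BoltzmannFit-accessors gating-charge estimate, e
#' @export
gatingCharge <- function(x) {
  stopifnot(is(x, "BoltzmannFit"))
  x@q
}

#' Accessors for BoltzmannFit
#'
#' `gatingCharge()` and `vHalf()` return the estimates, `fitSE()` their
#' standard errors, and `midpointSlope()` the slope dPo/dV at the
#' midpoint (per mV), which is proportional to the gating charge:
#' `q / (4 kB T / e)`.
#'
#' @param x a [BoltzmannFit-class].
#' @name BoltzmannFit-accessors
NULL

#' @rdname BoltzmannFit-accessors
#' @export
vHalf <- function(x) {
  stopifnot(is(x, "BoltzmannFit"))
  x@vHalf
}

#' @rdname BoltzmannFit-accessors
#' @export
fitSE <- function(x) {
  stopifnot(is(x, "BoltzmannFit"))
  x@se
}

#' @rdname BoltzmannFit-accessors
#' @export
midpointSlope <- function(x) {
  stopifnot(is(x, "BoltzmannFit"))
  x@q / (4 * thermalVoltage(x@temperature))
}

setMethod("show", "BoltzmannFit", function(object) {
  cat("BoltzmannFit: q =", round(object@q, 4), "+/-",
      round(object@se["q"], 4), "e; Vhalf =", round(object@vHalf, 3),
      "+/-", round(object@se["vHalf"], 3), "mV at",
      object@temperature, "K\n")
})

#' Construct a Gaussian-threshold gating model
#'
#' @param meanThreshold mean threshold energy, kBT units.
#' @param width threshold distribution width, kBT units (default 1).
#' @param q charges coupling voltage to energy, elementary charges.
#' @return A [ThresholdModel-class].
#' @export
thresholdModel <- function(meanThreshold, width = 1, q = 1) {
  new("ThresholdModel", meanThreshold = as.numeric(meanThreshold),
      width = as.numeric(width), q = as.numeric(q))
}

#' Open probability under a Gaussian-distributed threshold
#'
#' The energy drive `q e V / kB T` must exceed a threshold drawn from a
#' Gaussian of mean `meanThreshold` and width `width` (both in kBT units),
#' giving `Po(V) = Phi((q e V / kB T - mean) / width)`. With width near
#' one kBT this is nearly indistinguishable from the Boltzmann sigmoid.
#'
#' @param v applied voltage, mV (vectorised).
#' @param model a [ThresholdModel-class].
#' @param t absolute temperature, K.
#' @return Open probability in `[0, 1]`.
#' @export
thresholdPo <- function(v, model, t = 300) {
  stopifnot(is(model, "ThresholdModel"))
  drive <- model@q * v / thermalVoltage(t)
  stats::pnorm((drive - model@meanThreshold) / model@width)
}

#' Maximum deviation between threshold and Boltzmann gating curves
#'
#' Compares the Gaussian-threshold sigmoid with a Boltzmann on a voltage
#' grid. When `q`/`vHalf` are not supplied, the Boltzmann is matched to
#' the threshold model: midpoints are equated and the slope scale is
#' fitted by minimising the supremum deviation (the probit-to-logistic
#' scale factor of about 1.702 emerges from this match rather than being
#' hard-coded). With `matchScale = "slope"` the midpoint slopes are
#' equated analytically instead. Supplying `q` and `vHalf` compares
#' against that fixed Boltzmann with no matching.
#'
#' @param model a [ThresholdModel-class].
#' @param q,vHalf optional Boltzmann parameters for an unmatched
#'   comparison.
#' @param t absolute temperature, K.
#' @param vGrid voltage grid, mV; must span both transitions. Default: a
#'   dense grid over +/- 12 thermal widths around the midpoint.
#' @param matchScale `"best"` (fit the scale, default) or `"slope"`
#'   (equate midpoint slopes).
#' @return List with `deviation` (supremum of the absolute probability
#'   difference), the matched `q` and `vHalf`, and the implied
#'   probit-to-logistic `scaleFactor` (matched q x width / threshold q).
#' @examples
#' m <- thresholdModel(meanThreshold = 5, width = 1, q = 2)
#' thresholdVsBoltzmannDeviation(m)$deviation
#' @export
thresholdVsBoltzmannDeviation <- function(model, q = NULL, vHalf = NULL,
                                          t = 300, vGrid = NULL,
                                          matchScale = c("best", "slope")) {
  stopifnot(is(model, "ThresholdModel"))
  matchScale <- match.arg(matchScale)
  vT <- thermalVoltage(t)
  vMid <- model@meanThreshold * vT / model@q
  if (is.null(vGrid)) {
    halfSpan <- 12 * model@width * vT / abs(model@q)
    vGrid <- seq(vMid - halfSpan, vMid + halfSpan, length.out = 4001L)
  }
  if (length(vGrid) == 0L) stop("empty voltage grid")
  pt <- thresholdPo(vGrid, model, t)

  if (is.null(q) || is.null(vHalf)) {
    vHalf <- vMid
    devFor <- function(qb) max(abs(pt - boltzmannPo(vGrid, qb, vHalf, t)))
    qSlope <- 4 * stats::dnorm(0) * model@q / model@width
    q <- if (matchScale == "slope") qSlope
         else stats::optimize(devFor, qSlope * c(0.7, 1.5))$minimum
  }
  dev <- max(abs(pt - boltzmannPo(vGrid, q, vHalf, t)))
  list(deviation = dev, q = q, vHalf = vHalf,
       scaleFactor = q * model@width / model@q)
}

#' Construct a conductance dataset
#'
#' @param concentration ion concentrations, mM.
#' @param conductance relative conductances.
#' @param temperature absolute temperature, K.
#' @param referenceConcentration reference concentration for free-energy
#'   shifts, mM (default: the lowest concentration).
#' @return A [ConductanceDataset-class].
#' @export
conductanceDataset <- function(concentration, conductance,
                               temperature = 298,
                               referenceConcentration = min(concentration)) {
  new("ConductanceDataset", concentration = as.numeric(concentration),
      conductance = as.numeric(conductance),
      temperature = as.numeric(temperature),
      referenceConcentration = as.numeric(referenceConcentration))
}

#' Free-energy shift of an ion with concentration
#'
#' `-R T ln(c / c_ref)` in kJ/mol: the free energy of the ion in solution
#' relative to the reference concentration (the x axis of the
#' conductance-versus-free-energy barrier plot). Raising the concentration
#' tenfold at 298 K lowers the free energy by about 5.7 kJ/mol.
#'
#' @param concentration concentration, mM (> 0; vectorised).
#' @param x a [ConductanceDataset-class] supplying the temperature and
#'   reference concentration.
#' @return Free-energy shift, kJ/mol.
#' @export
setMethod("freeEnergyShift", signature("numeric", "ConductanceDataset"),
  function(concentration, x, ...) {
    if (any(concentration <= 0)) stop("concentration must be positive")
    -.constants$R * x@temperature *
      log(concentration / x@referenceConcentration) / 1000
  })

#' Single-barrier linearity diagnostic of conductance data
#'
#' Ordinary least squares of `ln(conductance)` on `ln(concentration)`.
#' A single conduction barrier predicts a straight line (conductance
#' proportional to the solution free energy of the ion, hence to the log
#' concentration); R-squared is reported as the linearity diagnostic.
#'
#' @param x a [ConductanceDataset-class] with at least 3 points.
#' @return List with `slope`, `intercept`, `rSquared`, `slopeSE` and the
#'   underlying `lm` fit. R-squared is `NA` for exactly constant
#'   conductance.
#' @export
setMethod("barrierLinearity", "ConductanceDataset", function(x, ...) {
  if (length(x@concentration) < 3L)
    stop("insufficient data: need at least 3 points")
  if (any(x@conductance <= 0))
    stop("conductances must be positive for log-log analysis")
  logg <- log(x@conductance); logc <- log(x@concentration)
  fit <- stats::lm(logg ~ logc)
  sm <- summary(fit)
  r2 <- if (stats::var(logg) == 0) NA_real_ else sm$r.squared
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       rSquared = r2,
       slopeSE = sm$coefficients["logc", "Std. Error"],
       fit = fit)
})

setMethod("show", "GatingDataset", function(object) {
  cat("GatingDataset:", length(object@voltage), "observations,",
      paste(round(range(object@voltage), 1), collapse = " .. "), "mV at",
      object@temperature, "K\n")
})

setMethod("show", "ConductanceDataset", function(object) {
  cat("ConductanceDataset:", length(object@concentration), "points,",
      paste(signif(range(object@concentration), 3), collapse = " .. "),
      "mM (reference", object@referenceConcentration, "mM) at",
      object@temperature, "K\n")
})
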