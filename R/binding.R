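# Exact 2:1 binding isotherm and titration fitting.
#
# The protein binds its DNA probe as a preformed dimer, so a titration at
# fixed labeled-DNA concentration follows the exact (quadratic) bound
# fraction rather than the dilute-ligand hyperbola:
#
#   theta = (cDNA + Kd + cP - sqrt((cDNA + cP + Kd)^2 - 4 cDNA cP)) / (2 cDNA)
#
# where cP is the total protein (dimer) concentration.

#' Exact bound fraction of the DNA probe
#'
#' Closed-form solution of the mass-action equilibrium P + D <-> PD at
#' total concentrations `cMitf` and `cDna`, i.e. the fraction of probe
#' molecules bound. Evaluated in the conjugate form
#' theta = 2 cMitf / (b + sqrt(b^2 - 4 cDna cMitf)), b = cDna + cMitf + Kd,
#' which is algebraically identical to the quadratic formula but avoids
#' catastrophic cancellation when Kd is far below the concentrations.
#'
#' @param cDna total labeled-DNA concentration (nM), > 0.
#' @param cMitf total protein concentration(s) (nM), >= 0; vectorized.
#' @param kd dissociation constant (nM), >= 0.
#' @return Bound fraction(s) in `[0, 1]`.
#' @examples
#' isothermTheta(0.5, 2, 1.9)
#' isothermTheta(0.5, 0, 1.9)   # no protein: 0
#' @export
isothermTheta <- function(cDna, cMitf, kd) {
  stopifnot(length(cDna) == 1L, length(kd) == 1L)
  if (cDna <= 0) stop("cDna must be positive")
  if (kd < 0) stop("kd must be >= 0")
  if (any(cMitf < 0)) stop("cMitf must be >= 0")
  b <- cDna + cMitf + kd
  disc <- b * b - 4 * cDna * cMitf
  # disc >= (cDna - cMitf)^2 + kd^2 >= 0 analytically; guard rounding
  root <- sqrt(pmax(disc, 0))
  theta <- ifelse(cMitf == 0, 0, 2 * cMitf / (b + root))
  pmin(theta, 1)
}

#' Normalize a readout shift to a bound fraction
#'
#' theta_i = (x_i - xFree) / (xBound - xFree).
#'
#' @param x raw readout values.
#' @param xFree,xBound endpoint readouts at zero and saturating protein.
#' @return numeric vector of normalized shifts.
#' @export
normalizedShift <- function(x, xFree, xBound) {
  span <- xBound - xFree
  if (abs(span) < 1e-12 * max(abs(xFree), abs(xBound), 1))
    stop("degenerate endpoints: xBound and xFree are (nearly) equal")
  (x - xFree) / span
}

#' Fit the exact 2:1 isotherm to a titration
#'
#' Least-squares fit of [isothermTheta()] to a [TitrationSeries-class]
#' (or a plain data frame with columns `cMitf` and `theta`). With
#' `endpoints = "fixed"` the series is first normalized by its stored
#' endpoint values and Kd is the only parameter; with
#' `endpoints = "fitted"` the free and bound readout levels are co-fitted
#' with Kd on the raw readout. The Kd error is reported as 2 SD from the
#' fit covariance; optionally a residual bootstrap is run as well.
#'
#' A fitted Kd below half the probe concentration is flagged as tight
#' binding: in that regime the titration curve is set by probe depletion
#' rather than by Kd, so affinities are too high to compare accurately.
#'
#' @param series a [TitrationSeries-class], or a data.frame with columns
#'   `cMitf` and `theta`.
#' @param cDna probe concentration (nM); defaults to the series' value.
#' @param endpoints `"fixed"` or `"fitted"`.
#' @param startKd starting value for Kd (nM); default: concentration at
#'   half-maximal normalized shift.
#' @param bootstrap number of residual-bootstrap replicates (0 = none).
#' @param seed seed for the bootstrap.
#' @return An [IsothermFit-class].
#' @examples
#' s <- simulateTitration(kd = 1.9, cDna = 0.5,
#'                        concentrations = 10^seq(-2, 2, length.out = 12),
#'                        noiseSd = 0, seed = 1)
#' fitKd(s)
#' @export
fitKd <- function(series, cDna = NULL, endpoints = c("fixed", "fitted"),
                  startKd = NULL, bootstrap = 0, seed = 1) {
  endpoints <- match.arg(endpoints)
  if (is(series, "TitrationSeries")) {
    cMitf <- series@cMitf
    raw <- series@readout
    ep <- series@endpoints
    if (is.null(cDna)) cDna <- series@cDna
  } else {
    cMitf <- series$cMitf
    raw <- series$theta
    ep <- c(0, 1)
    if (is.null(cDna)) stop("cDna must be given for a plain data frame")
  }
  if (length(cMitf) < 5L)
    stop("need at least 5 titration points spanning the transition")

  if (endpoints == "fixed") {
    theta <- normalizedShift(raw, ep[1], ep[2])
    if (is.null(startKd)) startKd <- .halfShiftConc(cMitf, theta)
    fit <- minpack.lm::nlsLM(
      theta ~ isothermTheta(cDna, cMitf, kd),
      start = list(kd = startKd),
      lower = 0, control = minpack.lm::nls.lm.control(maxiter = 200))
    kd <- coef(fit)[["kd"]]
    kdSe <- sqrt(vcov(fit)[1, 1])
    epOut <- ep
    res <- stats::residuals(fit)
  } else {
    thetaGuess <- normalizedShift(raw, min(raw), max(raw))
    if (is.null(startKd)) startKd <- .halfShiftConc(cMitf, thetaGuess)
    sgn <- if (raw[which.max(cMitf)] >= raw[which.min(cMitf)]) 1 else -1
    fit <- minpack.lm::nlsLM(
      raw ~ xf + (xb - xf) * isothermTheta(cDna, cMitf, kd),
      start = list(kd = startKd,
                   xf = if (sgn > 0) min(raw) else max(raw),
                   xb = if (sgn > 0) max(raw) else min(raw)),
      lower = c(0, -Inf, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    kd <- coef(fit)[["kd"]]
    kdSe <- sqrt(vcov(fit)["kd", "kd"])
    epOut <- unname(coef(fit)[c("xf", "xb")])
    res <- stats::residuals(fit)
  }

  if (bootstrap > 0) {
    set.seed(seed)
    n <- length(res)
    fitted0 <- if (endpoints == "fixed") {
      isothermTheta(cDna, cMitf, kd)
    } else {
      epOut[1] + (epOut[2] - epOut[1]) * isothermTheta(cDna, cMitf, kd)
    }
    xf <- epOut[1]; xb <- epOut[2]
    bootForm <- if (endpoints == "fixed") {
      yb ~ isothermTheta(cDna, cMitf, kd)
    } else {
      yb ~ xf + (xb - xf) * isothermTheta(cDna, cMitf, kd)
    }
    boot <- vapply(seq_len(bootstrap), function(b) {
      yb <- fitted0 + sample(res, n, replace = TRUE)
      fb <- try(minpack.lm::nlsLM(bootForm, start = list(kd = kd), lower = 0,
                                  data = list(yb = yb, cDna = cDna,
                                              cMitf = cMitf, xf = xf, xb = xb)),
                silent = TRUE)
      if (inherits(fb, "try-error")) NA_real_ else coef(fb)[["kd"]]
    }, numeric(1))
    kdSe <- stats::sd(boot, na.rm = TRUE)
  }

  new("IsothermFit", kd = kd, kdError = 2 * kdSe, endpoints = epOut,
      endpointsFitted = endpoints == "fitted", residuals = unname(res),
      tightBinding = kd < cDna / 2, converged = TRUE)
}

# concentration nearest the half-maximal shift; crude but robust start value
.halfShiftConc <- function(cMitf, theta) {
  ord <- order(cMitf)
  i <- which.min(abs(theta[ord] - 0.5))
  max(cMitf[ord][i], 1e-3)
}
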