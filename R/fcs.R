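# Fluorescence correlation spectroscopy: photon-stream correlation on a
# quasi-logarithmic (multi-tau) lag grid and weighted fits of the
# single-species 3D diffusion + triplet model.

.roleIndex <- function(stream, role) {
  map <- channelMap(stream)
  det <- photonDetectors(stream)
  switch(role,
         donor = which(det %in% map@donorChannels),
         acceptor = which(det %in% map@acceptorChannels),
         stop("unknown channel role: ", role))
}

#' Cross-correlate two detection channels of a photon stream
#'
#' Multiple-tau estimator of the normalized intensity correlation
#' G(tau) = <n_i(t) n_j(t + tau)> / (<n_i> <n_j>) (baseline 1): photons
#' are binned at `binWidth`, correlated at `pointsPerOctave` lags per
#' octave, and the trace is re-binned by factors of two between octaves,
#' giving a quasi-logarithmic lag grid from `minLag` to `maxLag`.
#' `normalization = "printed"` divides by `<n_i>^2` instead of the
#' conventional `<n_i><n_j>` (they coincide for equally bright channels).
#'
#' @param stream a [PhotonStream-class].
#' @param pair character(2) channel roles, from `"donor"`, `"acceptor"`.
#' @param binWidth initial bin width, s (default 1 us).
#' @param minLag,maxLag lag range, s; `maxLag` beyond 10% of the trace
#'   duration is rejected.
#' @param pointsPerOctave lags per octave (default 16).
#' @param normalization `"cross"` (default) or `"printed"`.
#' @return A [CorrelationCurve-class] with per-point SE estimates.
#' @export
crossCorrelate <- function(stream, pair = c("donor", "acceptor"),
                           binWidth = 1e-6, minLag = 1e-6, maxLag = 1,
                           pointsPerOctave = 16L,
                           normalization = c("cross", "printed")) {
  normalization <- match.arg(normalization)
  dur <- traceDuration(stream)
  if (maxLag > 0.1 * dur)
    stop(sprintf("maxLag %.3g s exceeds 10%% of the trace duration (%.3g s)",
                 maxLag, dur))
  tSec <- photonTimes(stream)
  i1 <- .roleIndex(stream, pair[1])
  i2 <- .roleIndex(stream, pair[2])
  nBins <- ceiling(dur / binWidth)
  x <- tabulate(pmin(floor(tSec[i1] / binWidth), nBins - 1) + 1L, nBins)
  y <- tabulate(pmin(floor(tSec[i2] / binWidth), nBins - 1) + 1L, nBins)

  m <- as.integer(pointsPerOctave)
  lag <- numeric(0); G <- numeric(0); se <- numeric(0)
  bw <- binWidth
  level <- 0L
  repeat {
    ks <- if (level == 0L) seq_len(m) else (m %/% 2L + 1L):m
    n <- length(x)
    if (n < 4L * m) break
    for (k in ks) {
      tk <- k * bw
      if (tk < minLag) next
      if (tk > maxLag) break
      xa <- x[seq_len(n - k)]
      yb <- y[(k + 1L):n]
      mx <- mean(xa); my <- mean(yb)
      if (mx == 0 || my == 0) next
      norm <- if (normalization == "cross") mx * my else mx^2
      prod <- xa * yb
      g <- mean(prod) / norm
      lag <- c(lag, tk)
      G <- c(G, g)
      se <- c(se, stats::sd(prod) / (sqrt(length(prod)) * norm))
    }
    # coarsen by 2 for the next octave
    if (n %% 2L == 1L) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
    x <- x[seq(1L, n, 2L)] + x[seq(2L, n, 2L)]
    y <- y[seq(1L, n, 2L)] + y[seq(2L, n, 2L)]
    bw <- bw * 2
    level <- level + 1L
    if (bw * (m %/% 2L + 1L) > maxLag) break
  }
  ord <- order(lag)
  new("CorrelationCurve", lag = lag[ord], G = G[ord], se = se[ord],
      pair = pair, nPhotons = c(length(i1), length(i2)))
}

# single-species 3D diffusion + triplet correlation model
.fcsModel <- function(tau, a, nT, tauT, tauD, s) {
  1 + a * (1 + nT * exp(-tau / tauT)) /
    ((1 + tau / tauD) * sqrt(1 + tau / (s^2 * tauD)))
}

#' Fit the diffusion + triplet model to a correlation curve
#'
#' Weighted least squares of
#' G(tau) = 1 + a (1 + nT exp(-tau/tauT)) /
#'          ((1 + tau/tauD) (1 + tau/(s^2 tauD))^(1/2))
#' - amplitude `a`, triplet amplitude `nT` and time `tauT`, diffusion
#' time `tauD`, and axial aspect ratio `s` of the 3D Gaussian detection
#' volume (fixed by default; release with `fixS = FALSE`). Points are
#' weighted by their inverse squared SE when the curve carries SEs.
#'
#' When the fitted triplet amplitude is consistent with zero the triplet
#' time is unidentifiable; it is then flagged via `tripletTime = NA`.
#'
#' @param curve a [CorrelationCurve-class] spanning at least 3 decades
#'   of lag.
#' @param fixS hold the aspect ratio fixed (default TRUE).
#' @param s aspect-ratio value (default 5).
#' @param fitTriplet fit the triplet term (default TRUE); with FALSE the
#'   triplet amplitude is held at 0.
#' @return An [FcsFit-class].
#' @export
fitFcs <- function(curve, fixS = TRUE, s = 5, fitTriplet = TRUE) {
  tau <- curve@lag; G <- curve@G
  if (log10(max(tau) / min(tau)) < 3)
    stop("correlation curve must span at least 3 decades of lag")
  w <- if (length(curve@se) == length(G) && all(curve@se > 0))
    1 / curve@se^2 else rep(1, length(G))

  a0 <- max(max(G) - 1, 1e-3)
  gHalf <- 1 + a0 / 2
  tauD0 <- tau[which.min(abs(G - gHalf))]
  start <- list(a = a0, tauD = max(tauD0, min(tau) * 5))
  lower <- c(a = 1e-6, tauD = min(tau))
  upper <- c(a = Inf, tauD = max(tau))
  form <- "G ~ 1 + a * (1 + nT * exp(-tau/tauT)) / ((1 + tau/tauD) * sqrt(1 + tau/(sPar^2 * tauD)))"
  dat <- list(G = G, tau = tau, sPar = s)
  if (fitTriplet) {
    start <- c(start, list(nT = 0.1, tauT = 5e-6))
    lower <- c(lower, nT = 0, tauT = min(tau) / 2)
    upper <- c(upper, nT = 10, tauT = max(tau) / 10)
  } else {
    dat$nT <- 0; dat$tauT <- 1e-6
  }
  if (!fixS) {
    form <- sub("sPar\\^2", "sFit^2", form)
    start <- c(start, list(sFit = s))
    lower <- c(lower, sFit = 1)
    upper <- c(upper, sFit = 100)
    dat$sPar <- NULL
  }
  fit <- try(minpack.lm::nlsLM(
    stats::as.formula(form), start = start, data = dat, weights = w,
    lower = lower[names(start)], upper = upper[names(start)],
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop(structure(
      class = c("fretBurstNonConvergence", "error", "condition"),
      list(message = paste("FCS fit failed:", attr(fit, "condition")$message),
           call = sys.call(-1))))
  cf <- coef(fit)
  ses <- sqrt(pmax(diag(vcov(fit)), 0))
  names(ses) <- names(cf)
  nT <- if (fitTriplet) cf[["nT"]] else 0
  tauT <- if (fitTriplet) cf[["tauT"]] else NA_real_
  tripletFlag <- fitTriplet &&
    (nT < 2 * ses[["nT"]] || !is.finite(ses[["tauT"]]))
  new("FcsFit",
      amplitude = cf[["a"]],
      tripletAmplitude = nT,
      tripletTime = if (tripletFlag) NA_real_ else tauT,
      diffusionTime = cf[["tauD"]],
      aspectRatio = if (fixS) s else cf[["sFit"]],
      se = ses, sFixed = fixS, converged = TRUE,
      fitted = predict(fit))
}

#' Normalized diffusion-time shift
#'
#' theta = (tauSample - tauFree) / (tauBound - tauFree), the bound
#' fraction proxy from diffusion times; values outside `[0, 1]` are
#' clipped and flagged via the `"clipped"` attribute.
#'
#' @param fitFree,fitBound,fitSample [FcsFit-class] objects or plain
#'   diffusion times (s).
#' @return numeric(1) in `[0, 1]`.
#' @export
diffusionShift <- function(fitFree, fitBound, fitSample) {
  tv <- function(x) if (is(x, "FcsFit")) x@diffusionTime else as.numeric(x)
  tf <- tv(fitFree); tb <- tv(fitBound); ts <- tv(fitSample)
  if (abs(tb - tf) < 1e-12) stop("degenerate endpoints: tauBound == tauFree")
  theta <- (ts - tf) / (tb - tf)
  out <- min(max(theta, 0), 1)
  attr(out, "clipped") <- theta < 0 || theta > 1
  out
}
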