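# Photons -> bursts -> corrected observables.
#
# The path from a raw photon stream to a transfer-efficiency histogram:
# aggregate removal, delta-T burst search, per-burst gated counting,
# the correction chain (background -> crosstalk -> direct excitation ->
# gamma), transfer efficiency, PIE stoichiometry, asymmetry filtering,
# burst anisotropy and Gaussian population fits.

#' Remove aggregate events from a photon stream
#'
#' Bins the trace into `binSeconds` bins, computes the per-bin photon
#' count mean and SD once on the input, and drops every photon falling
#' in a bin whose count exceeds mean + `k` SD. Slowly diffusing
#' aggregates produce seconds-long bright stretches that would otherwise
#' be chopped into spurious bursts.
#'
#' @param stream a [PhotonStream-class].
#' @param binSeconds bin width in seconds (default 2).
#' @param k cut threshold in SDs above the mean (default 6).
#' @return The cleaned [PhotonStream-class]; attribute `removedBins`
#'   holds the dropped bin indices, `keptIndex` the original indices of
#'   the surviving photons. Streams spanning fewer than 2 bins are
#'   returned unchanged.
#' @export
removeAggregates <- function(stream, binSeconds = 2, k = 6) {
  n <- length(stream)
  if (n == 0L) stop("stream is empty")
  tSec <- photonTimes(stream)
  nBins <- ceiling(traceDuration(stream) / binSeconds)
  if (nBins < 2L) {
    attr(stream, "removedBins") <- integer(0)
    return(stream)
  }
  binIdx <- pmin(floor(tSec / binSeconds), nBins - 1L) + 1L
  counts <- tabulate(binIdx, nbins = nBins)
  cut <- mean(counts) + k * stats::sd(counts)
  bad <- which(counts > cut)
  if (!length(bad)) {
    out <- stream
    keep <- seq_len(n)
  } else {
    keep <- which(!binIdx %in% bad)
    out <- stream[keep]
  }
  attr(out, "removedBins") <- bad
  attr(out, "keptIndex") <- keep
  out
}

#' Delta-T burst search
#'
#' Finds maximal runs of consecutive photons (over all detectors; PIE
#' analysis needs the acceptor-excitation photons inside the same burst)
#' whose inter-photon gaps are all at most `dtMicro` microseconds, and
#' keeps runs of `minPhotons` to `maxPhotons` photons. Bursts are
#' non-overlapping and time-ordered by construction.
#'
#' @param stream a [PhotonStream-class] (aggregate-cleaned).
#' @param dtMicro maximal inter-photon gap inside a burst, us (default 100).
#' @param minPhotons,maxPhotons accepted burst size range (30, 1000).
#' @return data.frame with one row per burst: `firstIndex`, `lastIndex`
#'   (photon indices into the stream), `nPhotons`, `start` (s),
#'   `duration` (s).
#' @export
callBursts <- function(stream, dtMicro = 100, minPhotons = 30,
                       maxPhotons = 1000) {
  n <- length(stream)
  empty <- data.frame(firstIndex = integer(0), lastIndex = integer(0),
                      nPhotons = integer(0), start = numeric(0),
                      duration = numeric(0))
  if (n == 0L) return(empty)
  ts <- photonTimestamps(stream)
  dtTicks <- dtMicro * 1e-6 / timestampResolution(stream)
  brk <- which(diff(ts) > dtTicks)           # run boundaries
  first <- c(1L, brk + 1L)
  last <- c(brk, n)
  size <- last - first + 1L
  ok <- size >= minPhotons & size <= maxPhotons
  if (!any(ok)) return(empty)
  res <- timestampResolution(stream)
  data.frame(firstIndex = first[ok], lastIndex = last[ok],
             nPhotons = size[ok],
             start = ts[first[ok]] * res,
             duration = (ts[last[ok]] - ts[first[ok]]) * res)
}

#' Count gated photons and arrival-time statistics per burst
#'
#' Classifies each burst photon by excitation gate (microtime window)
#' and detection channel into the PIE classes: `nDD` (donor excitation,
#' donor channels), `nDA` (donor excitation, acceptor channels), `nAA`
#' (acceptor excitation, acceptor channels); splits `nDD` into the
#' polarization counts `iPar`, `iPerp`; and records the mean arrival
#' times (relative to burst start) and mean donor microtime needed for
#' asymmetry filtering and lifetime analysis.
#'
#' @param stream a [PhotonStream-class].
#' @param bursts data.frame from [callBursts()].
#' @return The input data.frame with columns added: `nDD`, `nDA`, `nAA`,
#'   `iPar`, `iPerp`, `tMeanDD`, `tMeanDA`, `tMeanAA` (s, relative to
#'   burst start), `microMeanD` (ns, donor-channel donor-gate microtime
#'   mean), `nMicroD`.
#' @export
countBursts <- function(stream, bursts) {
  if (!nrow(bursts)) {
    for (cl in c("nDD", "nDA", "nAA", "iPar", "iPerp", "tMeanDD", "tMeanDA",
                 "tMeanAA", "microMeanD", "nMicroD"))
      bursts[[cl]] <- numeric(0)
    return(bursts)
  }
  map <- channelMap(stream)
  micro <- photonMicrotimesNs(stream)
  det <- photonDetectors(stream)
  ts <- photonTimestamps(stream)
  res <- timestampResolution(stream)

  len <- bursts$lastIndex - bursts$firstIndex + 1L
  idx <- sequence(len, from = bursts$firstIndex)
  bid <- rep.int(seq_len(nrow(bursts)), len)

  inDGate <- micro[idx] >= map@donorGate[1] & micro[idx] < map@donorGate[2]
  inAGate <- micro[idx] >= map@acceptorGate[1] & micro[idx] < map@acceptorGate[2]
  isDch <- det[idx] %in% map@donorChannels
  isAch <- det[idx] %in% map@acceptorChannels
  DD <- inDGate & isDch
  DA <- inDGate & isAch
  AA <- inAGate & isAch
  tRel <- (ts[idx] - ts[bursts$firstIndex][bid]) * res

  m <- cbind(nDD = DD, nDA = DA, nAA = AA,
             iPar = inDGate & det[idx] == map@donorChannels[1],
             iPerp = inDGate & det[idx] == map@donorChannels[2],
             tDD = tRel * DD, tDA = tRel * DA, tAA = tRel * AA,
             micD = micro[idx] * DD)
  agg <- rowsum(m, bid)

  bursts$nDD <- agg[, "nDD"]
  bursts$nDA <- agg[, "nDA"]
  bursts$nAA <- agg[, "nAA"]
  bursts$iPar <- agg[, "iPar"]
  bursts$iPerp <- agg[, "iPerp"]
  bursts$tMeanDD <- ifelse(agg[, "nDD"] > 0, agg[, "tDD"] / agg[, "nDD"], NA)
  bursts$tMeanDA <- ifelse(agg[, "nDA"] > 0, agg[, "tDA"] / agg[, "nDA"], NA)
  bursts$tMeanAA <- ifelse(agg[, "nAA"] > 0, agg[, "tAA"] / agg[, "nAA"], NA)
  bursts$microMeanD <- ifelse(agg[, "nDD"] > 0, agg[, "micD"] / agg[, "nDD"], NA)
  bursts$nMicroD <- agg[, "nDD"]
  bursts
}

#' Apply the PIE correction chain to burst counts
#'
#' Fixed correction order: (1) background, subtracting rate x duration
#' per counting class; (2) spectral crosstalk, `nDA - l * nDD`;
#' (3) direct acceptor excitation, subtracting `alpha/(1-alpha) * nAA`;
#' (4) detection-efficiency gamma, `nPrimeD = gamma * nDD`,
#' `nPrimeA = nDA`. Corrected counts falling below zero are floored at 0
#' and the burst flagged.
#'
#' @param bursts data.frame from [countBursts()].
#' @param corrections a [CorrectionSet-class].
#' @return The data.frame with columns added: `nDDcorr`, `nDAcorr`,
#'   `nAAcorr` (background-corrected raw classes), `nPrimeD`, `nPrimeA`
#'   (fully corrected donor/acceptor counts) and `flagFloored`.
#' @export
correctCounts <- function(bursts, corrections) {
  bg <- corrections@background
  nDD <- bursts$nDD - bg[["DD"]] * bursts$duration
  nDA <- bursts$nDA - bg[["DA"]] * bursts$duration
  nAA <- bursts$nAA - bg[["AA"]] * bursts$duration
  floored <- nDD < 0 | nDA < 0 | nAA < 0
  nDD <- pmax(nDD, 0); nDA <- pmax(nDA, 0); nAA <- pmax(nAA, 0)
  nDA2 <- nDA - corrections@leakage * nDD
  nDA3 <- nDA2 - corrections@alpha / (1 - corrections@alpha) * nAA
  floored <- floored | nDA3 < 0
  nDA3 <- pmax(nDA3, 0)
  bursts$nDDcorr <- nDD
  bursts$nDAcorr <- nDA
  bursts$nAAcorr <- nAA
  bursts$nPrimeD <- corrections@gammaDet * nDD
  bursts$nPrimeA <- nDA3
  bursts$flagFloored <- floored
  bursts
}

#' Transfer efficiency from corrected counts
#'
#' E = nPrimeA / (nPrimeA + nPrimeD). Not clipped: shot noise and
#' corrections legitimately push burst values slightly outside `[0, 1]`.
#'
#' @param nPrimeD,nPrimeA corrected donor/acceptor counts (vectorized).
#' @return numeric; NA where the denominator is zero (such bursts are
#'   excluded from histograms).
#' @export
fretEfficiency <- function(nPrimeD, nPrimeA) {
  den <- nPrimeA + nPrimeD
  ifelse(den > 0, nPrimeA / den, NA_real_)
}

#' PIE stoichiometry
#'
#' S = (nDA + nDD - delta nAA) / (nDA + nDD + gammaPIE nAA - delta nAA)
#' with delta = gammaPIE alpha / (1 - alpha), evaluated on
#' background-corrected class counts. A 1:1 donor-acceptor pair sits
#' near S = 0.5, donor-only species near 1, acceptor-only near 0.
#'
#' The last term of the printed denominator is ambiguous between
#' delta * nAA and delta * nDA; the default resolves it as delta * nAA
#' (mirroring the numerator), `denominator = "literal"` keeps delta * nDA.
#'
#' @param bursts data.frame from [correctCounts()] (or any frame with
#'   `nDDcorr`, `nDAcorr`, `nAAcorr`).
#' @param corrections a [CorrectionSet-class].
#' @param denominator `"symmetric"` (default) or `"literal"`.
#' @return numeric vector of S; NA where the denominator is zero.
#' @export
stoichiometry <- function(bursts, corrections,
                          denominator = c("symmetric", "literal")) {
  denominator <- match.arg(denominator)
  delta <- correctionDelta(corrections)
  num <- bursts$nDAcorr + bursts$nDDcorr - delta * bursts$nAAcorr
  lastTerm <- if (denominator == "symmetric") bursts$nAAcorr else bursts$nDAcorr
  den <- bursts$nDAcorr + bursts$nDDcorr +
    corrections@gammaPIE * bursts$nAAcorr - delta * lastTerm
  ifelse(abs(den) > 0, num / den, NA_real_)
}

#' Burst asymmetry confidence levels
#'
#' For each burst, the difference between the mean arrival times of two
#' photon classes (relative to burst start) divided by its null SD
#' sigma = T / (2 sqrt(3)) * sqrt(1/N1 + 1/N2), the SD of the difference
#' of means of uniformly distributed arrival times. Acceptor
#' photobleaching during the transit makes acceptor photons arrive early
#' and inflates the statistic.
#'
#' Two variants are computed: donor-excitation donor vs acceptor
#' emission (`asymDonor`), and acceptor-excitation acceptor emission vs
#' donor-excitation donor emission (`asymPIE`).
#'
#' @param bursts data.frame from [countBursts()].
#' @return The data.frame with columns `asymDonor`, `asymPIE` added
#'   (NA where one class is empty: such bursts pass vacuously but carry
#'   the NA as flag).
#' @export
asymmetryStatistics <- function(bursts) {
  sig <- function(T, n1, n2) T / (2 * sqrt(3)) * sqrt(1 / n1 + 1 / n2)
  bursts$asymDonor <- ifelse(
    bursts$nDD > 0 & bursts$nDA > 0,
    abs(bursts$tMeanDA - bursts$tMeanDD) /
      sig(bursts$duration, bursts$nDD, bursts$nDA),
    NA_real_)
  bursts$asymPIE <- ifelse(
    bursts$nDD > 0 & bursts$nAA > 0,
    abs(bursts$tMeanAA - bursts$tMeanDD) /
      sig(bursts$duration, bursts$nDD, bursts$nAA),
    NA_real_)
  bursts
}

#' Burst-wise fluorescence anisotropy
#'
#' r = (iPar - G iPerp) / (iPar + 2 G iPerp), the standard steady-state
#' relation on the polarization-resolved donor-excitation donor counts.
#'
#' @param iPar,iPerp parallel/perpendicular counts (vectorized).
#' @param gFactor polarization G-factor (default 1).
#' @return numeric; NA where the denominator is zero.
#' @export
burstAnisotropy <- function(iPar, iPerp, gFactor = 1) {
  den <- iPar + 2 * gFactor * iPerp
  ifelse(den > 0, (iPar - gFactor * iPerp) / den, NA_real_)
}

#' Select the FRET-active burst population
#'
#' Keeps bursts whose stoichiometry lies inside the window (default
#' `[0.3, 0.7]`, "around 0.5" for a 1:1 pair) and which pass both
#' asymmetry tests at the threshold. Bursts with an NA asymmetry
#' statistic (one class empty) pass vacuously.
#'
#' @param bursts data.frame holding columns `S`, `asymDonor`, `asymPIE`.
#' @param sWindow stoichiometry window, numeric(2).
#' @param threshold asymmetry confidence cutoff (default 1.5).
#' @return logical vector: selected bursts.
#' @export
selectFretPopulation <- function(bursts, sWindow = c(0.3, 0.7),
                                 threshold = 1.5) {
  sOK <- !is.na(bursts$S) & bursts$S >= sWindow[1] & bursts$S <= sWindow[2]
  aOK <- (is.na(bursts$asymDonor) | bursts$asymDonor <= threshold) &
         (is.na(bursts$asymPIE) | bursts$asymPIE <= threshold)
  sel <- sOK & aOK
  if (!any(sel))
    warning("empty FRET selection; downstream fits will refuse to run")
  sel
}

#' Fit Gaussian populations to burst efficiencies
#'
#' Maximum-likelihood fit of one or two Gaussian components to unbinned
#' burst-wise transfer efficiencies (histograms are display only). With
#' two components and `pinDonorOnly = TRUE` the first component's mean
#' is constrained to `[-0.05, 0.05]`, absorbing the residual donor-only
#' population near zero efficiency. Component SDs are bounded below by
#' half the display bin width. Mean errors are reported as the standard
#' error from the observed information; `show()` prints them as 2 SE.
#' Starting values are deterministic, so the fit is reproducible.
#'
#' @param e burst efficiencies (NAs dropped).
#' @param nComponents 1 or 2.
#' @param pinDonorOnly constrain the first component mean near 0.
#' @param minBursts refuse to fit fewer values (default 100).
#' @param sdFloor lower bound on component SDs (default 0.0125, half the
#'   default display bin width).
#' @return A [PopulationFit-class].
#' @export
fitPopulations <- function(e, nComponents = 2, pinDonorOnly = TRUE,
                           minBursts = 100, sdFloor = 0.0125) {
  e <- e[is.finite(e)]
  n <- length(e)
  if (n < minBursts)
    stop(sprintf("only %d bursts; at least %d required for a population fit",
                 n, minBursts))
  stopifnot(nComponents %in% 1:2)

  if (nComponents == 1L) {
    mu <- mean(e); s <- max(sd(e), sdFloor)
    return(new("PopulationFit", means = mu, sds = s, weights = 1,
               se = s / sqrt(n), donorOnlyComponent = NA_integer_,
               logLik = sum(dnorm(e, mu, s, log = TRUE)),
               n = as.integer(n), converged = TRUE))
  }

  nll <- function(p) {
    d <- p[1] * dnorm(e, p[2], p[3]) + (1 - p[1]) * dnorm(e, p[4], p[5])
    -sum(log(pmax(d, 1e-300)))
  }
  hi <- e[e > 0.15]
  muHi <- if (length(hi) > 10) mean(hi) else max(mean(e), 0.2)
  wLo <- min(max(mean(e <= 0.1), 0.05), 0.9)
  start <- c(w = wLo, mu0 = if (pinDonorOnly) 0 else 0.05, sd0 = 0.05,
             mu1 = muHi, sd1 = max(sd(hi), 0.05))
  lower <- c(1e-3, if (pinDonorOnly) -0.05 else -0.2, sdFloor, -0.1, sdFloor)
  upper <- c(0.999, if (pinDonorOnly) 0.05 else 1.2, 0.5, 1.1, 0.5)
  start <- pmin(pmax(start, lower), upper)
  opt <- optim(start, nll, method = "L-BFGS-B", lower = lower, upper = upper,
               hessian = TRUE)
  p <- opt$par
  se <- rep(NA_real_, 2)
  h <- try(solve(opt$hessian), silent = TRUE)
  if (!inherits(h, "try-error")) {
    v <- diag(h)[c(2, 4)]
    se <- sqrt(pmax(v, 0))
  }
  conv <- opt$convergence == 0L
  if (!conv)
    warning(structure(
      class = c("fretBurstNonConvergence", "warning", "condition"),
      list(message = paste("population fit did not converge:", opt$message),
           call = sys.call(-1))))
  new("PopulationFit",
      means = unname(p[c(2, 4)]), sds = unname(p[c(3, 5)]),
      weights = unname(c(p[1], 1 - p[1])), se = se,
      donorOnlyComponent = if (pinDonorOnly) 1L else NA_integer_,
      logLik = -opt$value, n = as.integer(n), converged = conv)
}

#' Run the full burst pipeline on a photon stream
#'
#' Aggregate removal, delta-T burst search, gated counting, the
#' correction chain, transfer efficiency, stoichiometry, asymmetry
#' statistics, anisotropy and FRET-population selection, driven by an
#' [AnalysisConfig-class]. Deterministic given stream + config.
#'
#' @param stream a [PhotonStream-class].
#' @param config an [AnalysisConfig-class].
#' @return data.frame with one row per burst: indices, timing, raw and
#'   corrected counts, `E`, `S`, `asymDonor`, `asymPIE`, `r`
#'   (anisotropy), `flagFloored` and the logical `selected`.
#' @examples
#' sim <- simulateBurstDataset(nBursts = 300, trueE = 0.5, seed = 1)
#' cfg <- AnalysisConfig(corrections = sim$corrections)
#' tab <- burstPipeline(sim$stream, cfg)
#' mean(tab$E[tab$selected])
#' @export
burstPipeline <- function(stream, config = AnalysisConfig()) {
  clean <- removeAggregates(stream, config@aggregateBin, config@aggregateK)
  bursts <- callBursts(clean, config@burstDT, config@minPhotons,
                       config@maxPhotons)
  bursts <- countBursts(clean, bursts)
  bursts <- correctCounts(bursts, config@corrections)
  bursts <- asymmetryStatistics(bursts)
  bursts$E <- fretEfficiency(bursts$nPrimeD, bursts$nPrimeA)
  bursts$S <- stoichiometry(bursts, config@corrections)
  bursts$r <- burstAnisotropy(bursts$iPar, bursts$iPerp, config@gFactor)
  bursts$selected <- if (nrow(bursts)) {
    selectFretPopulation(bursts, config@stoichiometryWindow,
                         config@asymmetryThreshold)
  } else logical(0)
  bursts
}
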