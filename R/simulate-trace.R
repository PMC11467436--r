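# Trace-level confocal diffusion simulator: reflecting Brownian motion of
# point emitters through a 3D Gaussian detection volume, inhomogeneous
# Poisson photon emission, two-state triplet blinking, and uniform
# background. Ground truth for burst calling and FCS.

# fold coordinates into [lo, hi] by reflection
.reflect <- function(x, lo, hi) {
  L <- hi - lo
  y <- (x - lo) %% (2 * L)
  lo + ifelse(y > L, 2 * L - y, y)
}

# two-state telegraph (bright/dark) sampled on a regular step grid;
# returns 0/1 per step. Equilibrium dark fraction f, dark dwell tauT.
.telegraphOnGrid <- function(nSteps, dt, darkFraction, tauT) {
  if (darkFraction <= 0) return(rep.int(1L, nSteps))
  total <- nSteps * dt
  meanBright <- tauT * (1 - darkFraction) / darkFraction
  # alternate bright/dark dwells until the trace is covered
  nDwell <- ceiling(2.5 * total / (meanBright + tauT)) + 20L
  repeat {
    bright <- rexp(nDwell, 1 / meanBright)
    dark <- rexp(nDwell, 1 / tauT)
    edges <- cumsum(as.vector(rbind(bright, dark)))
    if (edges[length(edges)] >= total) break
    nDwell <- nDwell * 2L
  }
  startBright <- runif(1) < (1 - darkFraction)
  idx <- findInterval((seq_len(nSteps) - 0.5) * dt, c(0, edges)) # 1-based dwell
  state <- idx %% 2L  # 1 = first dwell, alternating
  if (startBright) as.integer(state == 1L) else as.integer(state == 0L)
}

#' Simulate a confocal diffusion photon trace
#'
#' `nMolecules` point emitters perform reflecting Brownian motion in a
#' cubic box; the detected emission rate of each follows a 3D Gaussian
#' detection profile with lateral 1/e^2 waist `waist` and axial
#' elongation `aspectRatio`. Photons are drawn per time step from an
#' inhomogeneous Poisson process, with optional two-state triplet
#' blinking (dark dwell `tauT`, equilibrium dark fraction
#' `tripletFraction`) and uniform background. Each photon is assigned to
#' the donor- or acceptor-excitation pathway with equal probability,
#' emulating a double-labeled species observed in both PIE gates, so
#' donor x acceptor cross-correlation reflects the common diffusion.
#'
#' The theoretical diffusion time through the focus is
#' `tauDiff = waist^2 / (4 D)`.
#'
#' @param nMolecules number of molecules in the box.
#' @param boxSize cube edge length, um (must exceed 10x the waist).
#' @param diffusionCoefficient D, um^2/s.
#' @param waist lateral 1/e^2 focal waist, um.
#' @param aspectRatio axial elongation s of the detection volume.
#' @param duration trace length, s.
#' @param timeStep propagation step, s; must resolve both the triplet
#'   dwell and the focal transit.
#' @param brightnessAtCenter detected photons/ms for a molecule at the
#'   focus center.
#' @param tripletFraction,tauT triplet dark-state population and dwell (s).
#' @param backgroundRates per-detector background rates, Hz (length 4).
#' @param anisotropy polarization split, as in [simulateBurstDataset()].
#' @param tauFluor fluorescence lifetime used for microtimes, ns.
#' @param channelMap a [ChannelMap-class].
#' @param timestampResolution,nanotimeResolution clock resolutions, s.
#' @param seed integer seed.
#' @return A [PhotonStream-class]; metadata records the scenario and the
#'   theoretical `tauDiff`.
#' @examples
#' st <- simulateDiffusionTrace(nMolecules = 5, duration = 0.5, seed = 1)
#' @export
simulateDiffusionTrace <- function(nMolecules = 10, boxSize = 3,
                                   diffusionCoefficient = 22.5,
                                   waist = 0.3, aspectRatio = 5,
                                   duration = 10, timeStep = 1e-5,
                                   brightnessAtCenter = 100,
                                   tripletFraction = 0, tauT = 5e-5,
                                   backgroundRates = rep(0, 4),
                                   anisotropy = 0.1, tauFluor = 2,
                                   channelMap = ChannelMap(),
                                   timestampResolution = 12.5e-9,
                                   nanotimeResolution = 16e-12,
                                   seed = 1) {
  stopifnot(nMolecules >= 1, duration > 0, timeStep > 0,
            diffusionCoefficient > 0, waist > 0, aspectRatio >= 1,
            brightnessAtCenter > 0, length(backgroundRates) == 4L)
  if (boxSize < 10 * waist)
    stop("boxSize must exceed 10x the focal waist")
  tauDiffTheory <- waist^2 / (4 * diffusionCoefficient)
  if (timeStep > tauDiffTheory / 10)
    warning("timeStep does not resolve the focal transit time")
  if (tripletFraction > 0 && timeStep > tauT / 2)
    warning("timeStep does not resolve the triplet dwell")
  set.seed(seed)

  nSteps <- ceiling(duration / timeStep)
  lo <- -boxSize / 2; hi <- boxSize / 2
  sdStep <- sqrt(2 * diffusionCoefficient * timeStep)
  wz <- aspectRatio * waist
  rateCenter <- brightnessAtCenter * 1e3  # Hz

  intensity <- numeric(nSteps)
  for (m in seq_len(nMolecules)) {
    x <- .reflect(runif(1, lo, hi) + cumsum(rnorm(nSteps, sd = sdStep)), lo, hi)
    y <- .reflect(runif(1, lo, hi) + cumsum(rnorm(nSteps, sd = sdStep)), lo, hi)
    z <- .reflect(runif(1, lo, hi) + cumsum(rnorm(nSteps, sd = sdStep)), lo, hi)
    w <- exp(-2 * (x * x + y * y) / waist^2 - 2 * z * z / wz^2)
    if (tripletFraction > 0)
      w <- w * .telegraphOnGrid(nSteps, timeStep, tripletFraction, tauT)
    intensity <- intensity + w
  }
  expPhotons <- rateCenter * timeStep * sum(intensity)
  if (expPhotons < 1e5)
    warning(sprintf(
      "expected signal photons %.3g < 1e5; correlation curves will be noisy",
      expPhotons))

  counts <- rpois(nSteps, rateCenter * timeStep * intensity)
  stepIdx <- rep.int(which(counts > 0L), counts[counts > 0L])
  tSig <- (stepIdx - 1L) * timeStep + runif(length(stepIdx)) * timeStep

  map <- channelMap
  dGate <- map@donorGate; aGate <- map@acceptorGate
  donorExc <- runif(length(tSig)) < 0.5
  microSig <- numeric(length(tSig))
  microSig[donorExc] <- dGate[1] +
    .truncExp(sum(donorExc), tauFluor, dGate[2] - dGate[1])
  microSig[!donorExc] <- aGate[1] +
    .truncExp(sum(!donorExc), tauFluor, aGate[2] - aGate[1])
  pPar <- .parFraction(anisotropy)
  pickPol <- function(n, ids) ids[2L - (runif(n) < pPar)]
  detSig <- integer(length(tSig))
  detSig[donorExc] <- pickPol(sum(donorExc), map@donorChannels)
  detSig[!donorExc] <- pickPol(sum(!donorExc), map@acceptorChannels)

  bgT <- list(); bgDet <- list()
  for (ch in seq_len(4L) - 1L) {
    nb <- rpois(1, backgroundRates[ch + 1L] * duration)
    bgT[[ch + 1L]] <- runif(nb) * duration
    bgDet[[ch + 1L]] <- rep.int(ch, nb)
  }
  bgT <- unlist(bgT); bgDet <- as.integer(unlist(bgDet))
  bgMicro <- runif(length(bgT)) * map@piePeriod

  allT <- c(tSig, bgT)
  allMicro <- c(microSig, bgMicro)
  allDet <- c(detSig, bgDet)
  ord <- order(allT)
  ticks <- round(allT[ord] / timestampResolution)
  ord2 <- order(ticks)
  nano <- pmin(floor(allMicro[ord][ord2] / (nanotimeResolution * 1e9)),
               floor(map@piePeriod / (nanotimeResolution * 1e9)) - 1)

  PhotonStream(
    timestamps = ticks[ord2],
    nanotimes = as.integer(nano),
    detectors = allDet[ord][ord2],
    timestampResolution = timestampResolution,
    nanotimeResolution = nanotimeResolution,
    channelMap = map,
    metadata = list(seed = seed, generator = "simulateDiffusionTrace",
                    duration = duration, tauDiffTheory = tauDiffTheory,
                    aspectRatio = aspectRatio, waist = waist,
                    diffusionCoefficient = diffusionCoefficient,
                    version = as.character(packageVersion("fretBurst"))))
}
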