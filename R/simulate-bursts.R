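# Burst-level photon-stream generator.
#
# Emulates a confocal PIE measurement at the photon level: bursts of
# 30-1000 photons from single molecules transiting the focus, with
# donor-excitation photons split between donor and acceptor channels
# according to the transfer efficiency, spectral crosstalk, direct
# acceptor excitation and the detection-efficiency ratio gamma;
# acceptor-excitation (AA) photons for acceptor-bearing species; donor
# microtimes exponential with mean tauD*(1-E); and homogeneous Poisson
# background. The generative model is the exact inverse of the
# correction chain applied by the analysis, so corrected efficiencies
# are unbiased estimates of the ground truth.

# inverse-CDF sample from an exponential truncated to [0, L)
.truncExp <- function(n, mean, L) {
  u <- runif(n)
  -mean * log1p(-u * (1 - exp(-L / mean)))
}

# par/perp split achieving steady-state anisotropy r (G = 1):
# I_par / I_perp = (1 + 2 r) / (1 - r)
.parFraction <- function(r) (1 + 2 * r) / (2 + r)

# per-class background rates seen by the burst counter, from per-detector
# rates (Hz) and the gate fractions of the PIE period
.classBackground <- function(backgroundRates, map) {
  gateFrac <- function(g) (g[2] - g[1]) / map@piePeriod
  dIdx <- as.character(map@donorChannels)
  aIdx <- as.character(map@acceptorChannels)
  bg <- backgroundRates
  names(bg) <- as.character(seq_along(bg) - 1L)
  c(DD = sum(bg[dIdx]) * gateFrac(map@donorGate),
    DA = sum(bg[aIdx]) * gateFrac(map@donorGate),
    AA = sum(bg[aIdx]) * gateFrac(map@acceptorGate))
}

#' Simulate a burst-resolved PIE photon stream with ground truth
#'
#' Generates a time-ordered photon stream emulating freely diffusing
#' labeled molecules under pulsed interleaved excitation, together with
#' complete ground truth (per-burst species and efficiency, per-photon
#' labels). Each burst holds an exponential duration (mean
#' `meanBurstDuration`), Poisson photon counts, and photon-level physics:
#' every donor-excitation event carries an instantaneous efficiency E
#' (fixed at `trueE`, or redrawn per photon from the `chain` distance
#' distribution in the fast-exchange limit), transfers with probability
#' E, and is routed through detection efficiency, crosstalk and
#' direct-excitation channels whose expectations invert the correction
#' chain exactly. Donor-channel microtimes are exponential with mean
#' `tauD * (1 - E)` inside the donor PIE gate.
#'
#' @param nBursts number of bursts to generate.
#' @param trueE ground-truth transfer efficiency of the FRET species
#'   (mutually exclusive with `chain`).
#' @param chain a [ChainModel-class]: per-photon E is drawn from the
#'   Gaussian-chain distance distribution (fast exchange).
#' @param donorOnlyFraction,acceptorOnlyFraction fractions of bursts from
#'   singly labeled species.
#' @param meanBrightnessD donor-excitation signal brightness, photons/ms.
#' @param meanBrightnessA acceptor-excitation brightness, photons/ms.
#' @param meanBurstDuration mean burst (transit) duration, s.
#' @param burstRate burst occurrence rate, 1/s.
#' @param tauD donor-only fluorescence lifetime, ns.
#' @param tauA acceptor fluorescence lifetime, ns.
#' @param anisotropy steady-state anisotropy used to split parallel and
#'   perpendicular detection channels.
#' @param leakage,alpha,gammaDet,gammaPIE ground-truth correction factors
#'   (crosstalk l, direct excitation alpha, detection-efficiency gamma,
#'   PIE balance).
#' @param backgroundRates per-detector background rates, Hz (length 4).
#' @param tripletFraction,tauT triplet (dark-state) population and dwell
#'   (s). In this burst-level generator the triplet acts as brightness
#'   thinning by `1 - tripletFraction`; time-correlated blinking is
#'   modeled in [simulateDiffusionTrace()].
#' @param bleachFraction fraction of FRET bursts given a mid-burst
#'   acceptor bleach (asymmetric bursts for filter tests).
#' @param aggregateSpikes number of bright, long aggregate events to
#'   inject (for aggregate-removal tests).
#' @param channelMap a [ChannelMap-class].
#' @param timestampResolution,nanotimeResolution clock resolutions, s.
#' @param seed integer seed; recorded in the output metadata.
#' @return A list with elements `stream` ([PhotonStream-class]),
#'   `bursts` (ground-truth data.frame: species, mean E, start, duration,
#'   photon count), `photonLabel` (integer per photon: burst index, 0 for
#'   background, -1 for aggregate photons), `photonE` (per-photon true E
#'   for donor-excitation signal photons, NA otherwise), and
#'   `corrections` (a [CorrectionSet-class] holding the ground-truth
#'   factors and matching per-class background rates).
#' @examples
#' sim <- simulateBurstDataset(nBursts = 50, trueE = 0.5, seed = 1)
#' sim$stream
#' @export
simulateBurstDataset <- function(nBursts = 1000,
                                 trueE = NULL, chain = NULL,
                                 donorOnlyFraction = 0,
                                 acceptorOnlyFraction = 0,
                                 meanBrightnessD = 100,
                                 meanBrightnessA = 80,
                                 meanBurstDuration = 1e-3,
                                 burstRate = 20,
                                 tauD = 3.5, tauA = 1.0,
                                 anisotropy = 0.15,
                                 leakage = 0, alpha = 0,
                                 gammaDet = 1, gammaPIE = 1,
                                 backgroundRates = rep(0, 4),
                                 tripletFraction = 0, tauT = 2e-6,
                                 bleachFraction = 0,
                                 aggregateSpikes = 0,
                                 channelMap = ChannelMap(),
                                 timestampResolution = 12.5e-9,
                                 nanotimeResolution = 16e-12,
                                 seed = 1) {
  if (is.null(trueE) == is.null(chain))
    stop("exactly one of trueE and chain must be given")
  if (!is.null(trueE) && (trueE < 0 || trueE > 1))
    stop("trueE must lie in [0, 1]")
  stopifnot(donorOnlyFraction >= 0, donorOnlyFraction <= 1,
            acceptorOnlyFraction >= 0, acceptorOnlyFraction <= 1,
            donorOnlyFraction + acceptorOnlyFraction <= 1,
            meanBrightnessD > 0, meanBrightnessA > 0,
            meanBurstDuration > 0, burstRate > 0, tauD > 0, tauA > 0,
            leakage >= 0, alpha >= 0, alpha < 1, gammaDet > 0, gammaPIE > 0,
            tripletFraction >= 0, tripletFraction < 1,
            length(backgroundRates) == 4L)
  bdHz <- meanBrightnessD * 1e3 * (1 - tripletFraction)
  baHz <- meanBrightnessA * 1e3 * (1 - tripletFraction)
  if (bdHz * meanBurstDuration < 1)
    stop("expected burst size below 1 photon; raise brightness or duration")
  set.seed(seed)

  map <- channelMap
  dGate <- map@donorGate; aGate <- map@acceptorGate
  dW <- dGate[2] - dGate[1]; aW <- aGate[2] - aGate[1]
  pPar <- .parFraction(anisotropy)
  # detection probabilities inverting the correction chain (see header)
  etaD <- 1 / (max(1, gammaDet) * (1 + leakage))
  etaA <- gammaDet * etaD
  dPrime <- alpha / (1 - alpha)

  t0 <- cumsum(rexp(nBursts, burstRate))
  Tdur <- rexp(nBursts, 1 / meanBurstDuration)
  tEnd <- t0 + Tdur
  duration <- tEnd[nBursts] + 1 / burstRate

  species <- sample(c("fret", "donor_only", "acceptor_only"), nBursts,
                    replace = TRUE,
                    prob = c(1 - donorOnlyFraction - acceptorOnlyFraction,
                             donorOnlyFraction, acceptorOnlyFraction))
  isFret <- species == "fret"
  isDonly <- species == "donor_only"
  hasAcc <- !isDonly
  bleach <- isFret & (runif(nBursts) < bleachFraction)
  tBleach <- ifelse(bleach, runif(nBursts) * Tdur, Tdur)  # acceptor alive until

  ## donor-excitation pathway (fret + donor-only species)
  nAtt <- rpois(nBursts, bdHz * Tdur * (isFret | isDonly))
  bi <- rep.int(seq_len(nBursts), nAtt)
  nA <- length(bi)
  tRel <- runif(nA) * Tdur[bi]
  accAlive <- tRel < tBleach[bi]
  if (!is.null(chain)) {
    r2 <- chain@rmsDistance^2 / 3 * stats::rchisq(nA, df = 3)
    Ei <- 1 / (1 + (sqrt(r2) / chain@forsterRadius)^6)
  } else {
    Ei <- rep(trueE, nA)
  }
  Ei[!isFret[bi] | !accAlive] <- 0
  transfer <- runif(nA) < Ei
  detected <- runif(nA) < ifelse(transfer, etaA, etaD * (1 + leakage))
  leaked <- !transfer & (runif(nA) < leakage / (1 + leakage))
  keep <- detected
  sig <- list(
    t = t0[bi[keep]] + tRel[keep],
    burst = bi[keep],
    isAcceptorCh = (transfer | leaked)[keep],
    E = Ei[keep],
    donorEmitted = !transfer[keep]
  )
  # microtimes (ns within donor gate)
  micro <- numeric(length(sig$t))
  de <- sig$donorEmitted
  micro[de] <- .truncExp(sum(de), pmax(tauD * (1 - sig$E[de]), 1e-3), dW)
  micro[!de] <- .truncExp(sum(!de), tauA, dW)
  sig$micro <- dGate[1] + micro

  ## direct acceptor excitation by the donor laser (acceptor-bearing only)
  effT <- pmin(tBleach, Tdur) * hasAcc
  nDir <- rpois(nBursts, dPrime * baHz * effT)
  biD <- rep.int(seq_len(nBursts), nDir)
  dir <- list(t = t0[biD] + runif(length(biD)) * pmin(tBleach, Tdur)[biD],
              burst = biD,
              micro = dGate[1] + .truncExp(length(biD), tauA, dW))

  ## acceptor-excitation photons (AA)
  nAA <- rpois(nBursts, baHz * effT)
  biA <- rep.int(seq_len(nBursts), nAA)
  aa <- list(t = t0[biA] + runif(length(biA)) * pmin(tBleach, Tdur)[biA],
             burst = biA,
             micro = aGate[1] + .truncExp(length(biA), tauA, aW))

  ## background, homogeneous Poisson per detector over the whole trace
  bgT <- list(); bgDet <- list()
  for (ch in seq_len(4L) - 1L) {
    nb <- rpois(1, backgroundRates[ch + 1L] * duration)
    bgT[[ch + 1L]] <- runif(nb) * duration
    bgDet[[ch + 1L]] <- rep.int(ch, nb)
  }
  bgT <- unlist(bgT); bgDet <- as.integer(unlist(bgDet))
  bgMicro <- runif(length(bgT)) * map@piePeriod

  ## aggregate spikes: long (50 ms), bright (100x) multichannel events
  agT <- numeric(0)
  if (aggregateSpikes > 0) {
    for (k in seq_len(aggregateSpikes)) {
      s0 <- runif(1) * max(duration - 0.05, 0)
      nk <- rpois(1, 100 * bdHz * 0.05)
      agT <- c(agT, s0 + runif(nk) * 0.05)
    }
  }
  agMicro <- runif(length(agT)) * map@piePeriod
  agDet <- sample(c(map@donorChannels, map@acceptorChannels),
                  length(agT), replace = TRUE)

  ## detector assignment with polarization split
  pickPol <- function(n, ids) ids[2L - (runif(n) < pPar)]
  sigDet <- integer(length(sig$t))
  sigDet[sig$isAcceptorCh] <- pickPol(sum(sig$isAcceptorCh), map@acceptorChannels)
  sigDet[!sig$isAcceptorCh] <- pickPol(sum(!sig$isAcceptorCh), map@donorChannels)
  dirDet <- pickPol(length(dir$t), map@acceptorChannels)
  aaDet <- pickPol(length(aa$t), map@acceptorChannels)

  allT <- c(sig$t, dir$t, aa$t, bgT, agT)
  allMicro <- c(sig$micro, dir$micro, aa$micro, bgMicro, agMicro)
  allDet <- c(sigDet, dirDet, aaDet, bgDet, agDet)
  allLabel <- c(sig$burst, dir$burst, aa$burst,
                rep.int(0L, length(bgT)), rep.int(-1L, length(agT)))
  allE <- c(sig$E, rep(NA_real_, length(dir$t) + length(aa$t) +
                         length(bgT) + length(agT)))

  ord <- order(allT)
  ticks <- round(allT[ord] / timestampResolution)
  ord2 <- order(ticks)  # rounding can swap near-coincident photons
  ticks <- ticks[ord2]
  nano <- pmin(floor(allMicro[ord][ord2] / (nanotimeResolution * 1e9)),
               floor(map@piePeriod / (nanotimeResolution * 1e9)) - 1)

  stream <- PhotonStream(
    timestamps = ticks,
    nanotimes = as.integer(nano),
    detectors = allDet[ord][ord2],
    timestampResolution = timestampResolution,
    nanotimeResolution = nanotimeResolution,
    channelMap = map,
    metadata = list(seed = seed, generator = "simulateBurstDataset",
                    duration = duration,
                    forsterRadius = if (!is.null(chain)) chain@forsterRadius else NA,
                    version = as.character(packageVersion("fretBurst"))))

  meanE <- if (!is.null(chain)) chainMoments(chain)[["meanE"]] else trueE
  truth <- data.frame(
    burst = seq_len(nBursts),
    species = species,
    trueE = ifelse(isFret, meanE, ifelse(isDonly, 0, NA)),
    start = t0, duration = Tdur, bleached = bleach)

  corr <- CorrectionSet(
    background = .classBackground(backgroundRates, map),
    leakage = leakage, alpha = alpha,
    gammaDet = gammaDet, gammaPIE = gammaPIE)

  list(stream = stream,
       bursts = truth,
       photonLabel = allLabel[ord][ord2],
       photonE = allE[ord][ord2],
       corrections = corr)
}

#' Simulate bursts from a fast-exchanging Gaussian chain
#'
#' Convenience wrapper around [simulateBurstDataset()] for the dynamic
#' case: every donor-excitation photon redraws its instantaneous E from
#' the chain's distance distribution (fast-exchange limit, distances
#' fluctuating much faster than the burst duration).
#'
#' @param nBursts number of bursts.
#' @param chain a [ChainModel-class].
#' @param ... further arguments passed to [simulateBurstDataset()].
#' @return See [simulateBurstDataset()].
#' @export
simulateDynamicChainBursts <- function(nBursts = 1000, chain, ...) {
  simulateBurstDataset(nBursts = nBursts, chain = chain, ...)
}
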