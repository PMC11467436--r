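# Donor-lifetime versus transfer-efficiency analysis.
#
# The mean donor microtime of a burst estimates the donor lifetime in
# the presence of the acceptor. Normalized by the intrinsic donor
# lifetime (from the donor-only population) it separates static
# inter-dye distances, which fall on rho = 1 - E, from distances
# fluctuating faster than the transit, which are lifted above the line
# by the variance of the efficiency distribution:
# rho = 1 - E + sigma^2 / (1 - <E>).

#' Intrinsic donor lifetime from the donor-only population
#'
#' Photon-weighted mean donor-channel donor-gate microtime over bursts
#' whose stoichiometry identifies them as donor-only (S near 1), minus
#' the donor-gate start and the instrument-response offset.
#'
#' @param bursts data.frame from [burstPipeline()] (needs `S`,
#'   `microMeanD`, `nMicroD`).
#' @param stream the [PhotonStream-class] the bursts came from (for the
#'   gate start).
#' @param sMin minimal stoichiometry for the donor-only class (default 0.8).
#' @param irfOffset instrument-response microtime offset, ns.
#' @param minBursts minimal number of donor-only bursts (default 50).
#' @return numeric(1), donor-only lifetime in ns.
#' @export
donorOnlyLifetime <- function(bursts, stream, sMin = 0.8, irfOffset = 0,
                              minBursts = 50) {
  donly <- !is.na(bursts$S) & bursts$S >= sMin & bursts$nMicroD > 0
  if (sum(donly) < minBursts)
    stop(sprintf("only %d donor-only bursts (S >= %g); %d required",
                 sum(donly), sMin, minBursts))
  gateStart <- channelMap(stream)@donorGate[1]
  w <- bursts$nMicroD[donly]
  sum(bursts$microMeanD[donly] * w) / sum(w) - gateStart - irfOffset
}

#' Static-distance lifetime line
#'
#' For a fixed inter-dye distance the normalized donor lifetime is
#' rho = 1 - E.
#'
#' @param E transfer efficiency in `[0, 1]` (vectorized).
#' @return numeric, rho.
#' @export
staticLine <- function(E) {
  stopifnot(all(E >= 0 & E <= 1))
  1 - E
}

#' Mean and variance of the chain's efficiency distribution
#'
#' <E> = int E(r) P(r) dr and sigma^2 = int (E(r) - <E>)^2 P(r) dr by
#' adaptive quadrature over r in (0, 10 sqrt(<r^2>)], with the 3D
#' Gaussian-chain density P(r) proportional to
#' r^2 exp(-3 r^2 / (2 <r^2>)) and the Foerster relation
#' E(r) = 1 / (1 + (r/R0)^6).
#'
#' @param chain a [ChainModel-class].
#' @param absTol absolute quadrature tolerance (default 1e-8).
#' @return named numeric: `meanE`, `varE`.
#' @export
chainMoments <- function(chain, absTol = 1e-8) {
  rms <- chain@rmsDistance
  R0 <- chain@forsterRadius
  upper <- 10 * rms
  dens <- function(r) r^2 * exp(-3 * r^2 / (2 * rms^2))
  Efun <- function(r) 1 / (1 + (r / R0)^6)
  quad <- function(f) {
    out <- integrate(f, 0, upper, abs.tol = absTol, rel.tol = absTol,
                     subdivisions = 500L, stop.on.error = FALSE)
    if (out$message != "OK" && out$message != "roundoff error was detected")
      stop("quadrature failed: ", out$message)
    out$value
  }
  Z <- quad(dens)
  meanE <- quad(function(r) Efun(r) * dens(r)) / Z
  varE <- quad(function(r) (Efun(r) - meanE)^2 * dens(r)) / Z
  c(meanE = meanE, varE = varE)
}

#' Dynamic-chain lifetime line
#'
#' Sweeps a family of Gaussian chains over root-mean-square distances
#' and evaluates the fast-exchange relation
#' rho = 1 - <E> + sigma^2 / (1 - <E>) per chain. For sigma^2 = 0 the
#' relation collapses onto the static line; for any chain it lies at or
#' above it.
#'
#' @param rmsDistances root-mean-square distances to sweep, nm.
#' @param forsterRadius Foerster radius R0, nm.
#' @param maxRho cap on rho as <E> approaches 1 (flagged).
#' @return data.frame: `rmsDistance`, `meanE`, `varE`, `rhoStatic`,
#'   `rhoDynamic`, `capped`.
#' @export
dynamicLine <- function(rmsDistances, forsterRadius = 6, maxRho = 10) {
  rows <- lapply(rmsDistances, function(rms) {
    m <- chainMoments(ChainModel(rms, forsterRadius))
    rho <- 1 - m[["meanE"]] + m[["varE"]] / max(1 - m[["meanE"]], 1e-12)
    data.frame(rmsDistance = rms, meanE = m[["meanE"]], varE = m[["varE"]],
               rhoStatic = 1 - m[["meanE"]],
               rhoDynamic = min(rho, maxRho), capped = rho > maxRho)
  })
  do.call(rbind, rows)
}

#' Burst-wise lifetime ratio and deviation from the static line
#'
#' For each FRET-selected burst with at least `minDonorPhotons` donor
#' photons, estimates the normalized donor lifetime
#' rho = (mean donor microtime - gate start - IRF offset) / tauDonly
#' and the per-burst (E, rho) cloud, and summarizes the mean signed
#' deviation of rho from the static line 1 - E. Static distances give a
#' mean deviation near zero; fast-exchanging chains sit above the line
#' by sigma^2 / (1 - <E>).
#'
#' @param bursts data.frame from [burstPipeline()].
#' @param stream the source [PhotonStream-class].
#' @param tauDonly intrinsic donor lifetime, ns
#'   (from [donorOnlyLifetime()]).
#' @param irfOffset instrument-response offset, ns.
#' @param minDonorPhotons minimal donor photons per burst (default 10).
#' @param selected logical: bursts to use (default the `selected` column).
#' @return list: `bursts` (data.frame `E`, `rho`, `deviation`),
#'   `meanDeviation`, `seDeviation`, `n`.
#' @export
classifyBursts <- function(bursts, stream, tauDonly, irfOffset = 0,
                           minDonorPhotons = 10, selected = bursts$selected) {
  stopifnot(tauDonly > 0)
  keep <- selected & bursts$nMicroD >= minDonorPhotons & is.finite(bursts$E)
  gateStart <- channelMap(stream)@donorGate[1]
  E <- bursts$E[keep]
  rho <- (bursts$microMeanD[keep] - gateStart - irfOffset) / tauDonly
  dev <- rho - (1 - E)
  list(bursts = data.frame(E = E, rho = rho, deviation = dev),
       meanDeviation = mean(dev),
       seDeviation = sd(dev) / sqrt(length(dev)),
       n = length(dev))
}
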