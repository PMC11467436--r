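# Accessors and show methods for the core containers.

#' Number of photons in a stream
#' @param x a [PhotonStream-class].
#' @export
setMethod("length", "PhotonStream", function(x) length(x@timestamps))

#' @name photon-accessors
#' @title Accessors for PhotonStream slots
#' @description Read the macrotime ticks, microtime channels, detector ids,
#'   resolutions, channel map or metadata of a [PhotonStream-class].
#' @param x a [PhotonStream-class].
#' @return Numeric/integer vectors, a [ChannelMap-class], or a list.
NULL

#' @rdname photon-accessors
#' @export
photonTimestamps <- function(x) x@timestamps

#' @rdname photon-accessors
#' @export
photonNanotimes <- function(x) x@nanotimes

#' @rdname photon-accessors
#' @export
photonDetectors <- function(x) x@detectors

#' @rdname photon-accessors
#' @export
timestampResolution <- function(x) x@timestampResolution

#' @rdname photon-accessors
#' @export
nanotimeResolution <- function(x) x@nanotimeResolution

#' @rdname photon-accessors
#' @export
channelMap <- function(x) x@channelMap

#' @rdname photon-accessors
#' @export
streamMetadata <- function(x) x@metadata

#' Macrotime in seconds
#' @param x a [PhotonStream-class].
#' @return numeric vector of arrival times (s).
#' @export
photonTimes <- function(x) x@timestamps * x@timestampResolution

#' Microtime in ns
#' @param x a [PhotonStream-class].
#' @return numeric vector of microtimes (ns).
#' @export
photonMicrotimesNs <- function(x) x@nanotimes * (x@nanotimeResolution * 1e9)

#' Trace duration in seconds
#' @param x a [PhotonStream-class].
#' @return numeric(1); 0 for an empty stream.
#' @export
traceDuration <- function(x) {
  if (!length(x@timestamps)) return(0)
  md <- x@metadata
  if (!is.null(md$duration)) return(md$duration)
  max(x@timestamps) * x@timestampResolution
}

#' Subset a photon stream by photon index
#'
#' @param x a [PhotonStream-class].
#' @param i integer or logical index.
#' @param j,...,drop ignored.
#' @return A [PhotonStream-class] with the selected photons.
#' @export
setMethod("[", "PhotonStream", function(x, i, j, ..., drop = TRUE) {
  initialize(x, timestamps = x@timestamps[i], nanotimes = x@nanotimes[i],
             detectors = x@detectors[i])
})

setMethod("show", "PhotonStream", function(object) {
  cat(sprintf("PhotonStream with %d photons over %.3f s\n",
              length(object), traceDuration(object)))
  cat(sprintf("  timestamp resolution %.3g ns, nanotime resolution %.3g ps\n",
              object@timestampResolution * 1e9,
              object@nanotimeResolution * 1e12))
  cat(sprintf("  PIE period %g ns; donor gate [%g, %g) ns, acceptor gate [%g, %g) ns\n",
              object@channelMap@piePeriod,
              object@channelMap@donorGate[1], object@channelMap@donorGate[2],
              object@channelMap@acceptorGate[1], object@channelMap@acceptorGate[2]))
  if (!is.null(object@metadata$seed))
    cat(sprintf("  seed: %s\n", object@metadata$seed))
})

setMethod("show", "CorrectionSet", function(object) {
  cat("CorrectionSet\n")
  cat(sprintf("  background (Hz): DD=%g DA=%g AA=%g\n",
              object@background["DD"], object@background["DA"],
              object@background["AA"]))
  cat(sprintf("  leakage l=%g, alpha=%g, gamma=%g, gammaPIE=%g, delta=%.5g\n",
              object@leakage, object@alpha, object@gammaDet, object@gammaPIE,
              correctionDelta(object)))
})

setMethod("show", "ChainModel", function(object) {
  cat(sprintf("ChainModel (Gaussian chain): rms distance %g nm, R0 %g nm\n",
              object@rmsDistance, object@forsterRadius))
})

setMethod("show", "PopulationFit", function(object) {
  cat(sprintf("PopulationFit: %d component(s), n = %d bursts%s\n",
              length(object@means), object@n,
              if (object@converged) "" else " (NOT converged)"))
  for (i in seq_along(object@means)) {
    tag <- if (!is.na(object@donorOnlyComponent) &&
               i == object@donorOnlyComponent) " [donor-only]" else ""
    cat(sprintf("  mean = %.4f +/- %.4f (2 SE), sd = %.4f, weight = %.3f%s\n",
                object@means[i], 2 * object@se[i], object@sds[i],
                object@weights[i], tag))
  }
})

setMethod("show", "FcsFit", function(object) {
  cat(sprintf("FcsFit%s\n", if (object@converged) "" else " (NOT converged)"))
  cat(sprintf("  amplitude a = %.4g, diffusion time = %.4g ms\n",
              object@amplitude, object@diffusionTime * 1e3))
  cat(sprintf("  triplet: nT = %.4g, tauT = %.4g us; aspect ratio s = %.3g%s\n",
              object@tripletAmplitude, object@tripletTime * 1e6,
              object@aspectRatio, if (object@sFixed) " (fixed)" else ""))
})

setMethod("show", "CorrelationCurve", function(object) {
  cat(sprintf("CorrelationCurve %s x %s: %d lags, %.3g us to %.3g s\n",
              object@pair[1], object@pair[2], length(object@lag),
              min(object@lag) * 1e6, max(object@lag)))
})

setMethod("show", "IsothermFit", function(object) {
  cat(sprintf("IsothermFit: Kd = %.3g +/- %.3g nM (2 SD)%s%s\n",
              object@kd, object@kdError,
              if (object@tightBinding) " [tight-binding regime: too tight to compare accurately]" else "",
              if (object@converged) "" else " (NOT converged)"))
})

setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf("TitrationSeries (%s): %d points, cDNA = %g nM, cMITF %g-%g nM\n",
              object@kind, length(object@cMitf), object@cDna,
              min(object@cMitf), max(object@cMitf)))
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n")
  cat(sprintf("  burst search: dT = %g us, %d-%d photons\n",
              object@burstDT, object@minPhotons, object@maxPhotons))
  cat(sprintf("  aggregates: %g s bins, mean + %g SD\n",
              object@aggregateBin, object@aggregateK))
  cat(sprintf("  stoichiometry window [%g, %g], asymmetry threshold %g\n",
              object@stoichiometryWindow[1], object@stoichiometryWindow[2],
              object@asymmetryThreshold))
  show(object@corrections)
})

#' Bound fraction from a titration series
#'
#' Normalizes the raw readout to the bound fraction using the series'
#' endpoint values: theta = (x - x_free) / (x_bound - x_free).
#'
#' @param series a [TitrationSeries-class].
#' @return numeric vector of bound fractions.
#' @export
boundFraction <- function(series) {
  normalizedShift(series@readout, series@endpoints[1], series@endpoints[2])
}
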