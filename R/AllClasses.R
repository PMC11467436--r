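#' @import methods
#' @importFrom stats rexp rpois runif rnorm rbinom integrate optim nls
#'   coef vcov sd dnorm quantile var uniroot lm predict complete.cases
#' @importFrom utils read.table write.table head tail packageVersion
NULL

#' Detector-channel map and PIE gate definitions
#'
#' Maps small-integer detector ids to their optical role
#' (donor/acceptor emission, parallel/perpendicular polarization) and
#' defines the pulsed-interleaved-excitation (PIE) microtime gates: the
#' window after the donor-excitation pulse and the window after the
#' acceptor-excitation pulse. With 20 MHz interleaved alternation the
#' full PIE period is 50 ns and the two gates split it in half.
#'
#' @slot donorChannels integer(2), detector ids of the parallel and
#'   perpendicular donor-emission channels.
#' @slot acceptorChannels integer(2), ids of the acceptor-emission channels.
#' @slot donorGate numeric(2), donor-excitation microtime window in ns.
#' @slot acceptorGate numeric(2), acceptor-excitation microtime window in ns.
#' @slot piePeriod numeric(1), full excitation alternation period in ns.
#' @exportClass ChannelMap
setClass("ChannelMap",
  representation(
    donorChannels = "integer",
    acceptorChannels = "integer",
    donorGate = "numeric",
    acceptorGate = "numeric",
    piePeriod = "numeric"
  ),
  prototype(
    donorChannels = c(0L, 1L),
    acceptorChannels = c(2L, 3L),
    donorGate = c(0, 25),
    acceptorGate = c(25, 50),
    piePeriod = 50
  )
)

setValidity("ChannelMap", function(object) {
  msg <- character()
  if (length(object@donorChannels) != 2L || length(object@acceptorChannels) != 2L)
    msg <- c(msg, "donorChannels and acceptorChannels must each hold two detector ids (parallel, perpendicular)")
  if (anyDuplicated(c(object@donorChannels, object@acceptorChannels)))
    msg <- c(msg, "detector ids must be distinct across roles")
  if (length(object@piePeriod) != 1L || object@piePeriod <= 0)
    msg <- c(msg, "piePeriod must be a single positive number (ns)")
  for (g in list(object@donorGate, object@acceptorGate)) {
    if (length(g) != 2L || g[1] < 0 || g[2] <= g[1] || g[2] > object@piePeriod)
      msg <- c(msg, "each PIE gate must be an increasing window inside [0, piePeriod] ns")
  }
  if (max(object@donorGate[1], object@acceptorGate[1]) <
      min(object@donorGate[2], object@acceptorGate[2]))
    msg <- c(msg, "PIE gates must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Construct a ChannelMap
#'
#' @param donorChannels,acceptorChannels detector ids (parallel, perpendicular).
#' @param donorGate,acceptorGate PIE microtime windows in ns.
#' @param piePeriod excitation alternation period in ns (50 ns at 20 MHz).
#' @return A [ChannelMap-class] object.
#' @export
ChannelMap <- function(donorChannels = c(0L, 1L), acceptorChannels = c(2L, 3L),
                       donorGate = c(0, 25), acceptorGate = c(25, 50),
                       piePeriod = 50) {
  new("ChannelMap",
      donorChannels = as.integer(donorChannels),
      acceptorChannels = as.integer(acceptorChannels),
      donorGate = as.numeric(donorGate),
      acceptorGate = as.numeric(acceptorGate),
      piePeriod = as.numeric(piePeriod))
}

#' Time-tagged photon event stream
#'
#' The raw input of every analysis stage: one record per detected photon,
#' holding the macrotime (integer clock ticks since the start of the
#' acquisition), the microtime (integer TCSPC channels since the last
#' excitation pulse pair; encodes both the PIE gate and the fluorescence
#' decay) and the detector id. Resolutions convert ticks/channels to
#' seconds. Streams are strictly time-ordered by macrotime.
#'
#' @slot timestamps numeric, macrotime in integer ticks (stored as doubles
#'   so traces longer than 2^31 ticks are representable).
#' @slot nanotimes integer, microtime in TCSPC channels.
#' @slot detectors integer, detector id per photon.
#' @slot timestampResolution numeric(1), seconds per macrotime tick.
#' @slot nanotimeResolution numeric(1), seconds per microtime channel.
#' @slot channelMap a [ChannelMap-class].
#' @slot metadata list of provenance fields (seed, generator, version, ...).
#' @exportClass PhotonStream
setClass("PhotonStream",
  representation(
    timestamps = "numeric",
    nanotimes = "integer",
    detectors = "integer",
    timestampResolution = "numeric",
    nanotimeResolution = "numeric",
    channelMap = "ChannelMap",
    metadata = "list"
  ),
  prototype(
    timestamps = numeric(),
    nanotimes = integer(),
    detectors = integer(),
    timestampResolution = 12.5e-9,
    nanotimeResolution = 16e-12,
    metadata = list()
  )
)

setValidity("PhotonStream", function(object) {
  msg <- character()
  n <- length(object@timestamps)
  if (length(object@nanotimes) != n || length(object@detectors) != n)
    msg <- c(msg, "timestamps, nanotimes and detectors must have equal length")
  if (n > 1L && is.unsorted(object@timestamps))
    msg <- c(msg, sprintf("timestamps must be nondecreasing (first violation at index %d)",
                          which(diff(object@timestamps) < 0)[1] + 1L))
  if (object@timestampResolution <= 0 || object@nanotimeResolution <= 0)
    msg <- c(msg, "resolutions must be positive")
  nMax <- object@channelMap@piePeriod * 1e-9 / object@nanotimeResolution
  if (n && (min(object@nanotimes) < 0L || max(object@nanotimes) >= nMax))
    msg <- c(msg, "nanotimes must lie inside one PIE period")
  if (length(msg)) msg else TRUE
})

#' Construct a PhotonStream
#'
#' @param timestamps macrotime in integer ticks.
#' @param nanotimes microtime in integer TCSPC channels.
#' @param detectors integer detector ids.
#' @param timestampResolution seconds per tick (default 12.5 ns).
#' @param nanotimeResolution seconds per microtime channel (default 16 ps).
#' @param channelMap a [ChannelMap-class].
#' @param metadata list of provenance fields.
#' @return A [PhotonStream-class] object.
#' @export
PhotonStream <- function(timestamps = numeric(), nanotimes = integer(),
                         detectors = integer(),
                         timestampResolution = 12.5e-9,
                         nanotimeResolution = 16e-12,
                         channelMap = ChannelMap(), metadata = list()) {
  new("PhotonStream",
      timestamps = as.numeric(timestamps),
      nanotimes = as.integer(nanotimes),
      detectors = as.integer(detectors),
      timestampResolution = timestampResolution,
      nanotimeResolution = nanotimeResolution,
      channelMap = channelMap,
      metadata = metadata)
}

#' Correction factors for PIE burst counts
#'
#' Holds the quantities that turn raw gated photon counts into corrected
#' donor/acceptor counts: per-class background rates, spectral crosstalk
#' (leakage) of donor emission into the acceptor channel, the direct
#' acceptor excitation factor alpha, the relative detection-efficiency
#' ratio gamma, and the PIE excitation/detection balance gammaPIE. The
#' derived factor delta = gammaPIE * alpha / (1 - alpha) is always
#' recomputed from alpha and gammaPIE, never stored.
#'
#' @slot background named numeric: background count rates in Hz for the
#'   three excitation/detection classes `DD`, `DA`, `AA`.
#' @slot leakage numeric(1), donor-emission crosstalk fraction l.
#' @slot alpha numeric(1), direct acceptor excitation factor (default 0.042).
#' @slot gammaDet numeric(1), detection-efficiency ratio gamma.
#' @slot gammaPIE numeric(1), PIE color balance factor.
#' @exportClass CorrectionSet
setClass("CorrectionSet",
  representation(
    background = "numeric",
    leakage = "numeric",
    alpha = "numeric",
    gammaDet = "numeric",
    gammaPIE = "numeric"
  ),
  prototype(
    background = c(DD = 0, DA = 0, AA = 0),
    leakage = 0,
    alpha = 0.042,
    gammaDet = 1,
    gammaPIE = 1
  )
)

setValidity("CorrectionSet", function(object) {
  msg <- character()
  if (!all(c("DD", "DA", "AA") %in% names(object@background)))
    msg <- c(msg, "background must be named with classes DD, DA, AA")
  if (any(object@background < 0)) msg <- c(msg, "background rates must be >= 0")
  if (object@alpha < 0 || object@alpha >= 1) msg <- c(msg, "alpha must lie in [0, 1)")
  if (object@leakage < 0) msg <- c(msg, "leakage must be >= 0")
  if (object@gammaDet <= 0 || object@gammaPIE <= 0)
    msg <- c(msg, "gammaDet and gammaPIE must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a CorrectionSet
#'
#' @param background named numeric, Hz per counting class (`DD`, `DA`, `AA`).
#' @param leakage donor-into-acceptor crosstalk fraction l.
#' @param alpha direct acceptor excitation factor (default 0.042).
#' @param gammaDet detection-efficiency ratio gamma (default 1).
#' @param gammaPIE PIE color balance factor (default 1).
#' @return A [CorrectionSet-class] object.
#' @export
CorrectionSet <- function(background = c(DD = 0, DA = 0, AA = 0),
                          leakage = 0, alpha = 0.042,
                          gammaDet = 1, gammaPIE = 1) {
  bg <- c(DD = 0, DA = 0, AA = 0)
  bg[names(background)] <- background
  new("CorrectionSet", background = bg, leakage = leakage, alpha = alpha,
      gammaDet = gammaDet, gammaPIE = gammaPIE)
}

#' Derived direct-excitation factor delta
#'
#' delta = gammaPIE * alpha / (1 - alpha); recomputed on demand.
#'
#' @param corrections a [CorrectionSet-class].
#' @return numeric(1).
#' @export
correctionDelta <- function(corrections) {
  corrections@gammaPIE * corrections@alpha / (1 - corrections@alpha)
}

#' Gaussian-chain inter-dye distance model
#'
#' A 3D Gaussian chain: the inter-dye distance r has density
#' P(r) proportional to r^2 exp(-3 r^2 / (2 <r^2>)) on r > 0, the
#' standard end-to-end distribution of an ideal polymer. Paired with a
#' Foerster radius R0 it yields the transfer-efficiency distribution
#' E(r) = 1 / (1 + (r/R0)^6) used for fast-exchanging disordered chains.
#'
#' @slot rmsDistance numeric(1), root-mean-square inter-dye distance (nm).
#' @slot forsterRadius numeric(1), Foerster radius R0 (nm); default 6.0 nm,
#'   a configurable convention for a mid-red dye pair.
#' @exportClass ChainModel
setClass("ChainModel",
  representation(rmsDistance = "numeric", forsterRadius = "numeric"),
  prototype(rmsDistance = 6, forsterRadius = 6)
)

setValidity("ChainModel", function(object) {
  if (object@rmsDistance <= 0 || object@forsterRadius <= 0)
    "rmsDistance and forsterRadius must be positive (nm)" else TRUE
})

#' Construct a ChainModel
#'
#' @param rmsDistance root-mean-square inter-dye distance, nm.
#' @param forsterRadius Foerster radius R0, nm (default 6.0).
#' @return A [ChainModel-class] object.
#' @export
ChainModel <- function(rmsDistance, forsterRadius = 6.0) {
  new("ChainModel", rmsDistance = as.numeric(rmsDistance),
      forsterRadius = as.numeric(forsterRadius))
}

#' Analysis configuration
#'
#' Bundles the burst-search and filtering parameters with a
#' [CorrectionSet-class]. Defaults follow common practice for confocal
#' PIE measurements: delta-T threshold 100 us, 30-1000 photons per burst,
#' 2 s aggregate bins with a mean + 6 SD cut, stoichiometry window
#' [0.3, 0.7] around the 0.5 expected for a 1:1 FRET pair, asymmetry
#' confidence cutoff 1.5, direct-excitation alpha 0.042.
#'
#' @slot burstDT numeric(1), maximal inter-photon gap inside a burst (us).
#' @slot minPhotons,maxPhotons integer(1), burst size acceptance window.
#' @slot aggregateBin numeric(1), aggregate-removal bin width (s).
#' @slot aggregateK numeric(1), aggregate cut in SDs above the mean.
#' @slot stoichiometryWindow numeric(2), S window selecting FRET pairs.
#' @slot asymmetryThreshold numeric(1), confidence-level cutoff.
#' @slot histogramBinWidth numeric(1), display bin width for E histograms.
#' @slot irfOffset numeric(1), instrument-response microtime offset (ns).
#' @slot gFactor numeric(1), polarization G-factor for anisotropy.
#' @slot corrections a [CorrectionSet-class].
#' @slot seed integer(1), seed for the (only) stochastic stage, the
#'   mixture-fit initialization.
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
  representation(
    burstDT = "numeric",
    minPhotons = "integer",
    maxPhotons = "integer",
    aggregateBin = "numeric",
    aggregateK = "numeric",
    stoichiometryWindow = "numeric",
    asymmetryThreshold = "numeric",
    histogramBinWidth = "numeric",
    irfOffset = "numeric",
    gFactor = "numeric",
    corrections = "CorrectionSet",
    seed = "integer"
  ),
  prototype(
    burstDT = 100,
    minPhotons = 30L,
    maxPhotons = 1000L,
    aggregateBin = 2,
    aggregateK = 6,
    stoichiometryWindow = c(0.3, 0.7),
    asymmetryThreshold = 1.5,
    histogramBinWidth = 0.025,
    irfOffset = 0,
    gFactor = 1,
    seed = 1L
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  if (object@minPhotons >= object@maxPhotons)
    msg <- c(msg, "minPhotons must be smaller than maxPhotons")
  for (nm in c("burstDT", "aggregateBin", "aggregateK", "asymmetryThreshold",
               "histogramBinWidth"))
    if (slot(object, nm) <= 0) msg <- c(msg, paste(nm, "must be positive"))
  if (length(object@stoichiometryWindow) != 2L ||
      object@stoichiometryWindow[1] >= object@stoichiometryWindow[2])
    msg <- c(msg, "stoichiometryWindow must be an increasing pair")
  if (length(msg)) msg else TRUE
})

#' Construct an AnalysisConfig
#'
#' @param burstDT delta-T burst threshold, us (default 100).
#' @param minPhotons,maxPhotons burst size window (defaults 30, 1000).
#' @param aggregateBin aggregate-removal bin width, s (default 2).
#' @param aggregateK aggregate cut, SDs above the mean (default 6).
#' @param stoichiometryWindow S window for FRET-pair selection (default
#'   `c(0.3, 0.7)`).
#' @param asymmetryThreshold asymmetry confidence cutoff (default 1.5).
#' @param histogramBinWidth E-histogram display bin width (default 0.025).
#' @param irfOffset microtime offset subtracted before lifetimes, ns.
#' @param gFactor polarization G-factor (default 1).
#' @param corrections a [CorrectionSet-class] (default: alpha = 0.042,
#'   everything else off/identity).
#' @param seed integer seed for mixture-fit initialization.
#' @return An [AnalysisConfig-class] object.
#' @export
AnalysisConfig <- function(burstDT = 100, minPhotons = 30, maxPhotons = 1000,
                           aggregateBin = 2, aggregateK = 6,
                           stoichiometryWindow = c(0.3, 0.7),
                           asymmetryThreshold = 1.5,
                           histogramBinWidth = 0.025,
                           irfOffset = 0, gFactor = 1,
                           corrections = CorrectionSet(), seed = 1) {
  if (burstDT > 100)
    warning("burstDT above 100 us; burst search is usually run at 100 us or less")
  new("AnalysisConfig", burstDT = as.numeric(burstDT),
      minPhotons = as.integer(minPhotons), maxPhotons = as.integer(maxPhotons),
      aggregateBin = aggregateBin, aggregateK = aggregateK,
      stoichiometryWindow = as.numeric(stoichiometryWindow),
      asymmetryThreshold = asymmetryThreshold,
      histogramBinWidth = histogramBinWidth,
      irfOffset = irfOffset, gFactor = gFactor,
      corrections = corrections, seed = as.integer(seed))
}

#' Titration series for binding analysis
#'
#' One titration: total protein concentrations against a readout (FRET
#' shift, anisotropy shift or FCS diffusion-time shift) at fixed labeled
#' DNA concentration. Endpoint values map the raw readout linearly to
#' the bound fraction theta.
#'
#' @slot cMitf numeric, total protein concentration per point (nM).
#' @slot cDna numeric(1), total labeled-DNA concentration (nM).
#' @slot readout numeric, raw readout values.
#' @slot kind character(1), one of "fret", "anisotropy", "fcs".
#' @slot endpoints numeric(2), readout at fully free / fully bound.
#' @slot metadata list (seed, noise level, ground truth if simulated, ...).
#' @exportClass TitrationSeries
setClass("TitrationSeries",
  representation(
    cMitf = "numeric",
    cDna = "numeric",
    readout = "numeric",
    kind = "character",
    endpoints = "numeric",
    metadata = "list"
  )
)

setValidity("TitrationSeries", function(object) {
  msg <- character()
  if (length(object@readout) != length(object@cMitf))
    msg <- c(msg, "readout and cMitf must have equal length")
  if (any(object@cMitf < 0)) msg <- c(msg, "cMitf must be >= 0")
  if (length(object@cDna) != 1L || object@cDna <= 0)
    msg <- c(msg, "cDna must be a single positive concentration")
  if (!object@kind %in% c("fret", "anisotropy", "fcs"))
    msg <- c(msg, "kind must be one of fret, anisotropy, fcs")
  if (length(msg)) msg else TRUE
})

#' Construct a TitrationSeries
#'
#' @param cMitf total protein concentrations, nM.
#' @param cDna total labeled-DNA concentration, nM.
#' @param readout raw readout values (same length as `cMitf`).
#' @param kind readout kind: "fret", "anisotropy" or "fcs".
#' @param endpoints numeric(2): readout values at free and bound limits.
#' @param metadata provenance list.
#' @return A [TitrationSeries-class] object.
#' @export
TitrationSeries <- function(cMitf, cDna, readout, kind = "anisotropy",
                            endpoints = c(0, 1), metadata = list()) {
  new("TitrationSeries", cMitf = as.numeric(cMitf), cDna = as.numeric(cDna),
      readout = as.numeric(readout), kind = kind,
      endpoints = as.numeric(endpoints), metadata = metadata)
}

# ---- result containers ----

#' Gaussian population fit of a transfer-efficiency histogram
#'
#' @slot means,sds,weights numeric, per-component parameters; weights sum to 1.
#' @slot se numeric, standard error of each component mean.
#' @slot donorOnlyComponent integer(1), index of the pinned near-zero
#'   component, or NA if none.
#' @slot logLik numeric(1).
#' @slot n integer(1), number of bursts fitted.
#' @slot converged logical(1).
#' @exportClass PopulationFit
setClass("PopulationFit",
  representation(means = "numeric", sds = "numeric", weights = "numeric",
                 se = "numeric", donorOnlyComponent = "integer",
                 logLik = "numeric", n = "integer", converged = "logical"))

#' FCS diffusion + triplet model fit
#'
#' @slot amplitude,tripletAmplitude,tripletTime,diffusionTime,aspectRatio
#'   fitted parameters (times in seconds).
#' @slot se named numeric, standard errors.
#' @slot sFixed logical(1), whether the aspect ratio was held fixed.
#' @slot converged logical(1).
#' @slot fitted numeric, model values on the fitted lag grid.
#' @exportClass FcsFit
setClass("FcsFit",
  representation(amplitude = "numeric", tripletAmplitude = "numeric",
                 tripletTime = "numeric", diffusionTime = "numeric",
                 aspectRatio = "numeric", se = "numeric", sFixed = "logical",
                 converged = "logical", fitted = "numeric"))

#' Photon correlation curve
#'
#' @slot lag numeric, lag times (s), strictly increasing.
#' @slot G numeric, correlation values (baseline 1).
#' @slot se numeric, per-point standard error estimates (may be empty).
#' @slot pair character(2), the correlated channel roles.
#' @slot nPhotons numeric(2), photon counts used per channel.
#' @exportClass CorrelationCurve
setClass("CorrelationCurve",
  representation(lag = "numeric", G = "numeric", se = "numeric",
                 pair = "character", nPhotons = "numeric"))

setValidity("CorrelationCurve", function(object) {
  msg <- character()
  if (length(object@G) != length(object@lag))
    msg <- c(msg, "lag and G must have equal length")
  if (length(object@lag) > 1L && any(diff(object@lag) <= 0))
    msg <- c(msg, "lags must be strictly increasing")
  if (any(!is.finite(object@G))) msg <- c(msg, "G must be finite")
  if (length(msg)) msg else TRUE
})

#' Exact 2:1 binding-isotherm fit
#'
#' @slot kd numeric(1), dissociation constant (nM).
#' @slot kdError numeric(1), 2 SD fit error (nM).
#' @slot endpoints numeric(2), free/bound readout endpoints used.
#' @slot endpointsFitted logical(1), whether endpoints were co-fitted.
#' @slot residuals numeric.
#' @slot tightBinding logical(1), TRUE when the fitted Kd is below half
#'   the probe concentration, where the titration no longer constrains it.
#' @slot converged logical(1).
#' @exportClass IsothermFit
setClass("IsothermFit",
  representation(kd = "numeric", kdError = "numeric", endpoints = "numeric",
                 endpointsFitted = "logical", residuals = "numeric",
                 tightBinding = "logical", converged = "logical"))
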