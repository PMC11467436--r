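# Titration-series generator: bound fractions from the exact 2:1
# isotherm, mapped linearly between free and bound readout endpoints,
# with optional Gaussian noise on the bound fraction.

# default readout endpoints (free, bound) per readout kind:
# anisotropy rises on binding, FRET efficiency of the labeled probe
# drops as the dyes separate, FCS diffusion time rises with complex size
.defaultEndpoints <- function(kind) {
  switch(kind,
         anisotropy = c(0.08, 0.20),
         fret = c(0.65, 0.45),
         fcs = c(3.5e-4, 6.0e-4),
         stop("unknown readout kind: ", kind))
}

#' Simulate a binding titration
#'
#' Bound fractions follow [isothermTheta()] exactly; Gaussian noise of
#' standard deviation `noiseSd` is added on the bound-fraction scale and
#' the result mapped linearly between the free and bound readout
#' endpoints. With `noiseSd = 0` the stored readout is bitwise
#' reproducible from [isothermTheta()] and the endpoints.
#'
#' @param kd ground-truth dissociation constant, nM.
#' @param cDna labeled-DNA (probe) concentration, nM (0.5 by default, the
#'   standard probe concentration for these titrations).
#' @param concentrations total protein concentrations, nM, sorted
#'   ascending; default 12 log-spaced points over 0.01-100 nM.
#' @param readout readout kind: "anisotropy", "fret" or "fcs".
#' @param noiseSd Gaussian noise SD on the bound fraction.
#' @param endpoints numeric(2) free/bound readout values; defaults per kind.
#' @param seed integer seed.
#' @return A [TitrationSeries-class]; metadata records `kd`, `noiseSd`,
#'   `seed` and the noiseless bound fractions.
#' @examples
#' simulateTitration(kd = 1.9, noiseSd = 0.03, seed = 7)
#' @export
simulateTitration <- function(kd, cDna = 0.5,
                              concentrations = 10^seq(-2, 2, length.out = 12),
                              readout = c("anisotropy", "fret", "fcs"),
                              noiseSd = 0, endpoints = NULL, seed = 1) {
  readout <- match.arg(readout)
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (is.unsorted(concentrations)) stop("concentrations must be sorted")
  if (is.null(endpoints)) endpoints <- .defaultEndpoints(readout)
  set.seed(seed)
  theta <- isothermTheta(cDna, concentrations, kd)
  thetaNoisy <- if (noiseSd > 0) theta + rnorm(length(theta), sd = noiseSd)
                else theta
  values <- endpoints[1] + thetaNoisy * (endpoints[2] - endpoints[1])
  TitrationSeries(
    cMitf = concentrations, cDna = cDna, readout = values, kind = readout,
    endpoints = endpoints,
    metadata = list(kd = kd, noiseSd = noiseSd, seed = seed,
                    thetaTrue = theta,
                    version = as.character(packageVersion("fretBurst"))))
}
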