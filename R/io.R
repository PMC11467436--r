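# On-disk photon container and analysis configuration.
#
# Photon streams are stored as gzipped columnar text: `#`-prefixed
# header lines carrying the required metadata (resolutions, PIE gates,
# channel map, provenance), then three tab-separated integer columns
# `timestamp`, `nanotime`, `detector`. The round trip is lossless for
# the integer ticks/channels and all metadata fields.

.requiredHeader <- c("timestamp_resolution_s", "nanotime_resolution_s",
                     "pie_period_ns", "donor_gate_ns", "acceptor_gate_ns",
                     "donor_channels", "acceptor_channels")

#' Write a photon stream to a gzipped columnar text file
#'
#' @param stream a [PhotonStream-class].
#' @param path output path; written gzip-compressed regardless of
#'   extension (".psg.gz" by convention).
#' @return `path`, invisibly.
#' @export
writePhotonFile <- function(stream, path) {
  map <- channelMap(stream)
  con <- gzfile(path, "wt")
  on.exit(close(con))
  hdr <- c(
    "# fretBurst photon stream v1",
    sprintf("# timestamp_resolution_s: %.17g", timestampResolution(stream)),
    sprintf("# nanotime_resolution_s: %.17g", nanotimeResolution(stream)),
    sprintf("# pie_period_ns: %.17g", map@piePeriod),
    sprintf("# donor_gate_ns: %.17g %.17g", map@donorGate[1], map@donorGate[2]),
    sprintf("# acceptor_gate_ns: %.17g %.17g",
            map@acceptorGate[1], map@acceptorGate[2]),
    sprintf("# donor_channels: %d %d",
            map@donorChannels[1], map@donorChannels[2]),
    sprintf("# acceptor_channels: %d %d",
            map@acceptorChannels[1], map@acceptorChannels[2]))
  md <- streamMetadata(stream)
  for (key in c("seed", "generator", "duration", "version")) {
    if (!is.null(md[[key]]))
      hdr <- c(hdr, sprintf("# %s: %s", key, format(md[[key]], digits = 17)))
  }
  writeLines(hdr, con)
  writeLines("timestamp\tnanotime\tdetector", con)
  if (length(stream)) {
    writeLines(paste(format(photonTimestamps(stream), scientific = FALSE,
                            trim = TRUE),
                     photonNanotimes(stream), photonDetectors(stream),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a photon stream from a gzipped columnar text file
#'
#' Validates the schema: every required metadata field must be present
#' (a missing field raises an error naming it) and timestamps must be
#' nondecreasing (a violation raises an error naming the first
#' offending photon index).
#'
#' @param path file written by [writePhotonFile()].
#' @return A [PhotonStream-class].
#' @export
readPhotonFile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, 1L)
    if (!length(line)) stop("truncated photon file: no column header found")
    if (!startsWith(line, "#")) break
    hdr <- c(hdr, line)
  }
  kv <- list()
  for (h in hdr[-1]) {
    m <- regmatches(h, regexec("^#\\s*([a-z_]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- m[3]
  }
  for (field in .requiredHeader) {
    if (is.null(kv[[field]]))
      stop("photon file schema error: missing required metadata field '",
           field, "'")
  }
  num <- function(f) as.numeric(strsplit(trimws(kv[[f]]), "\\s+")[[1]])
  tab <- read.table(con, header = FALSE, sep = "\t",
                    col.names = c("timestamp", "nanotime", "detector"),
                    colClasses = c("numeric", "integer", "integer"))
  if (nrow(tab) > 1L) {
    bad <- which(diff(tab$timestamp) < 0)
    if (length(bad))
      stop(sprintf("photon file has unsorted timestamps: first violation at photon index %d",
                   bad[1] + 1L))
  }
  map <- ChannelMap(donorChannels = num("donor_channels"),
                    acceptorChannels = num("acceptor_channels"),
                    donorGate = num("donor_gate_ns"),
                    acceptorGate = num("acceptor_gate_ns"),
                    piePeriod = num("pie_period_ns"))
  md <- list()
  for (key in c("seed", "generator", "duration", "version")) {
    if (!is.null(kv[[key]]))
      md[[key]] <- if (key %in% c("seed", "duration"))
        as.numeric(kv[[key]]) else kv[[key]]
  }
  PhotonStream(timestamps = tab$timestamp,
               nanotimes = tab$nanotime,
               detectors = tab$detector,
               timestampResolution = num("timestamp_resolution_s"),
               nanotimeResolution = num("nanotime_resolution_s"),
               channelMap = map, metadata = md)
}

# flat YAML key -> AnalysisConfig / CorrectionSet field
.configKeys <- c("burst_dt_us", "min_photons", "max_photons",
                 "aggregate_bin_s", "aggregate_k", "stoichiometry_window",
                 "asymmetry_threshold", "histogram_bin_width",
                 "irf_offset_ns", "g_factor", "seed",
                 "background_dd_hz", "background_da_hz", "background_aa_hz",
                 "leakage", "alpha", "gamma", "gamma_pie")

#' Load an analysis configuration from YAML
#'
#' Unspecified fields take the package defaults (including the
#' direct-excitation factor alpha = 0.042); unknown keys are rejected to
#' catch typos. A `burst_dt_us` above 100 is accepted with a warning,
#' since the burst search is normally run at 100 us or less.
#'
#' @param path YAML file; an empty file yields the full default
#'   configuration.
#' @return An [AnalysisConfig-class].
#' @export
loadConfig <- function(path) {
  raw <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("no such file: ", path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .configKeys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  gv <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  corr <- CorrectionSet(
    background = c(DD = gv("background_dd_hz", 0),
                   DA = gv("background_da_hz", 0),
                   AA = gv("background_aa_hz", 0)),
    leakage = gv("leakage", 0),
    alpha = gv("alpha", 0.042),
    gammaDet = gv("gamma", 1),
    gammaPIE = gv("gamma_pie", 1))
  AnalysisConfig(
    burstDT = gv("burst_dt_us", 100),
    minPhotons = gv("min_photons", 30),
    maxPhotons = gv("max_photons", 1000),
    aggregateBin = gv("aggregate_bin_s", 2),
    aggregateK = gv("aggregate_k", 6),
    stoichiometryWindow = unlist(gv("stoichiometry_window", c(0.3, 0.7))),
    asymmetryThreshold = gv("asymmetry_threshold", 1.5),
    histogramBinWidth = gv("histogram_bin_width", 0.025),
    irfOffset = gv("irf_offset_ns", 0),
    gFactor = gv("g_factor", 1),
    corrections = corr,
    seed = gv("seed", 1))
}

# polynomial rolling hash over the deparsed configuration, for
# provenance headers (identification, not cryptography)
.configHash <- function(config) {
  txt <- paste(deparse(lapply(slotNames(config), function(s) slot(config, s))),
               collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Export a burst table as CSV with provenance header
#'
#' Writes `#`-prefixed lines carrying the package version, a hash of the
#' effective configuration and the seed, then the table with documented
#' headers (times in SI units).
#'
#' @param bursts data.frame from [burstPipeline()].
#' @param path output CSV path.
#' @param config the [AnalysisConfig-class] used.
#' @return `path`, invisibly.
#' @export
exportBurstTable <- function(bursts, path, config = AnalysisConfig()) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fretBurst %s", as.character(packageVersion("fretBurst"))),
    sprintf("# config_hash: %s", .configHash(config)),
    sprintf("# seed: %d", config@seed)), con)
  utils::write.csv(bursts, con, row.names = FALSE)
  invisible(path)
}
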