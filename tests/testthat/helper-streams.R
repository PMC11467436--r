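# Constructed photon streams for boundary and filter tests.

# stream from explicit arrival times (s); detectors default to the
# parallel donor channel, microtimes to mid donor gate
makeStream <- function(timesSec, detectors = 0L, microNs = 3,
                       map = ChannelMap()) {
  n <- length(timesSec)
  PhotonStream(
    timestamps = round(timesSec / 12.5e-9),
    nanotimes = rep_len(as.integer(microNs / (16e-12 * 1e9)), n),
    detectors = rep_len(as.integer(detectors), n),
    channelMap = map,
    metadata = list(duration = max(timesSec) + 1))
}

# photon clusters of given sizes with in-cluster gaps `gap` (s),
# separated by `sep` (s)
clusterTimes <- function(sizes, gap = 10e-6, sep = 1) {
  t0 <- 0
  out <- list()
  for (i in seq_along(sizes)) {
    out[[i]] <- t0 + seq_len(sizes[i]) * gap
    t0 <- out[[i]][sizes[i]] + sep
  }
  unlist(out)
}

# independent mass-action equilibrium solver: numeric root of
# Kd = P_free * D_free / PD for the bound probe fraction
oracleTheta <- function(cDna, cMitf, kd) {
  if (cMitf == 0) return(0)
  f <- function(pd) (cMitf - pd) * (cDna - pd) - kd * pd
  lo <- 0
  hi <- min(cDna, cMitf)
  pd <- uniroot(f, c(lo, hi), tol = 1e-15)$root
  pd / cDna
}
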