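# Photon correlation and diffusion + triplet model fitting.

test_that("noiseless model curves are refitted to four significant digits", {
  lag <- 10^seq(-6, 0, length.out = 120)
  G <- 1 + 0.5 * (1 + 0.2 * exp(-lag / 2e-6)) /
    ((1 + lag / 1e-3) * sqrt(1 + lag / (25 * 1e-3)))
  cv <- new("CorrelationCurve", lag = lag, G = G, se = numeric(0),
            pair = c("donor", "acceptor"), nPhotons = c(0, 0))
  f <- fitFcs(cv, s = 5)
  expect_equal(f@amplitude, 0.5, tolerance = 1e-4)
  expect_equal(f@tripletAmplitude, 0.2, tolerance = 1e-4)
  expect_equal(f@tripletTime, 2e-6, tolerance = 1e-4)
  expect_equal(f@diffusionTime, 1e-3, tolerance = 1e-4)
})

test_that("independent Poisson streams correlate to a flat baseline of 1", {
  set.seed(1)
  n <- 2e5
  td <- sort(runif(n, 0, 10)); ta <- sort(runif(n, 0, 10))
  ts <- c(round(td / 12.5e-9), round(ta / 12.5e-9))
  det <- c(rep(0L, n), rep(2L, n))
  nano <- as.integer(c(runif(n, 0, 1562), runif(n, 1563, 3124)))
  o <- order(ts)
  st <- PhotonStream(ts[o], nano[o], det[o], metadata = list(duration = 10))
  cc <- crossCorrelate(st, binWidth = 1e-5, minLag = 1e-5, maxLag = 0.5)
  expect_lt(abs(mean(cc@G) - 1), 0.005)
  expect_lt(max(abs(cc@G - 1)), 0.05)
})

test_that("multi-tau estimator matches a brute-force binned correlation", {
  st <- suppressWarnings(
    simulateDiffusionTrace(nMolecules = 8, duration = 3, boxSize = 3.5,
                           aspectRatio = 3, brightnessAtCenter = 120,
                           seed = 7))
  cc <- crossCorrelate(st, binWidth = 1e-5, minLag = 1e-5, maxLag = 0.02,
                       pointsPerOctave = 8L)
  # brute-force oracle on the same definition, independent code path
  tSec <- photonTimes(st)
  det <- photonDetectors(st)
  dur <- traceDuration(st)
  bw <- 1e-5
  nb <- ceiling(dur / bw)
  x <- tabulate(pmin(floor(tSec[det %in% c(0L, 1L)] / bw), nb - 1) + 1L, nb)
  y <- tabulate(pmin(floor(tSec[det %in% c(2L, 3L)] / bw), nb - 1) + 1L, nb)
  for (k in c(1L, 3L, 6L)) {
    num <- 0
    for (i in seq_len(nb - k)) num <- num + x[i] * y[i + k]
    g <- (num / (nb - k)) /
      (mean(x[seq_len(nb - k)]) * mean(y[(k + 1):nb]))
    got <- cc@G[which.min(abs(cc@lag - k * bw))]
    expect_equal(got, g, tolerance = 0.01)
  }
})

test_that("the correlation is symmetric under channel exchange", {
  st <- suppressWarnings(
    simulateDiffusionTrace(nMolecules = 8, duration = 3, boxSize = 3.5,
                           aspectRatio = 3, brightnessAtCenter = 120,
                           seed = 8))
  g1 <- crossCorrelate(st, pair = c("donor", "acceptor"), binWidth = 1e-5,
                       minLag = 1e-5, maxLag = 0.05)
  g2 <- crossCorrelate(st, pair = c("acceptor", "donor"), binWidth = 1e-5,
                       minLag = 1e-5, maxLag = 0.05)
  expect_identical(g1@lag, g2@lag)
  expect_lt(mean(abs(g1@G - g2@G)), 0.05 * mean(abs(g1@G - 1) + 1e-6) + 0.02)
})

test_that("lags beyond 10% of the trace duration are rejected", {
  st <- makeStream(seq(0, 1, by = 1e-4))
  expect_error(crossCorrelate(st, maxLag = 0.5), "10%")
})

test_that("curves narrower than 3 decades are refused by the fitter", {
  lag <- 10^seq(-4, -2, length.out = 30)
  cv <- new("CorrelationCurve", lag = lag, G = rep(1.1, 30), se = numeric(0),
            pair = c("donor", "acceptor"), nPhotons = c(0, 0))
  expect_error(fitFcs(cv), "3 decades")
})

test_that("Brownian traces yield the theoretical diffusion time within 20%", {
  # tauDiff = waist^2 / (4 D) = 1 ms
  st <- suppressWarnings(
    simulateDiffusionTrace(nMolecules = 20, boxSize = 4, aspectRatio = 3,
                           duration = 10, diffusionCoefficient = 22.5,
                           waist = 0.3, brightnessAtCenter = 120, seed = 4))
  cc <- crossCorrelate(st, binWidth = 5e-6, minLag = 5e-6, maxLag = 0.2)
  fit <- fitFcs(cc, fitTriplet = FALSE, s = 3)
  expect_lt(abs(fit@diffusionTime - 1e-3) / 1e-3, 0.2)
  # amplitude ~ 1 / (effective occupancy of the Gaussian volume)
  vEff <- pi^1.5 * 0.3^2 * (3 * 0.3)
  nEff <- 20 / 4^3 * vEff
  expect_lt(abs(fit@amplitude - 1 / nEff) / (1 / nEff), 0.25)
})

test_that("doubling the diffusion coefficient halves the fitted diffusion time", {
  fits <- lapply(c(22.5, 45), function(D) {
    st <- suppressWarnings(
      simulateDiffusionTrace(nMolecules = 14, boxSize = 3.5, aspectRatio = 3,
                             duration = 6, diffusionCoefficient = D,
                             waist = 0.3, brightnessAtCenter = 150, seed = 5))
    fitFcs(crossCorrelate(st, binWidth = 5e-6, minLag = 5e-6, maxLag = 0.2),
           fitTriplet = FALSE, s = 3)
  })
  ratio <- fits[[2]]@diffusionTime / fits[[1]]@diffusionTime
  expect_lt(abs(ratio - 0.5), 0.15)
})

test_that("a triplet-free trace fits a vanishing triplet amplitude", {
  st <- suppressWarnings(
    simulateDiffusionTrace(nMolecules = 14, boxSize = 3.5, aspectRatio = 3,
                           duration = 6, diffusionCoefficient = 22.5,
                           waist = 0.3, brightnessAtCenter = 150,
                           tripletFraction = 0, seed = 6))
  # fit above the propagation step: sub-step lags carry the boxcar
  # correlation of piecewise-constant intensities, which mimics a triplet
  fit <- fitFcs(crossCorrelate(st, binWidth = 1e-5, minLag = 2.5e-5,
                               maxLag = 0.2),
                fitTriplet = TRUE, s = 3)
  # the triplet amplitude must be consistent with zero ...
  expect_lt(fit@tripletAmplitude, 3 * fit@se[["nT"]] + 0.05)
  # ... and the dwell time flagged as unidentifiable
  expect_true(is.na(fit@tripletTime))
})

test_that("triplet blinking appears as a fast correlation component", {
  st <- suppressWarnings(
    simulateDiffusionTrace(nMolecules = 14, boxSize = 3.5, aspectRatio = 3,
                           duration = 6, diffusionCoefficient = 22.5,
                           waist = 0.3, brightnessAtCenter = 200,
                           tripletFraction = 0.25, tauT = 1e-4,
                           timeStep = 2e-5, seed = 9))
  fit <- fitFcs(crossCorrelate(st, binWidth = 2e-5, minLag = 2e-5,
                               maxLag = 0.2),
                fitTriplet = TRUE, s = 3)
  expect_gt(fit@tripletAmplitude, 0.1)
})

test_that("diffusion shift interpolates between free and bound endpoints", {
  expect_equal(as.numeric(diffusionShift(3.5e-4, 6e-4, 3.5e-4)), 0)
  expect_equal(as.numeric(diffusionShift(3.5e-4, 6e-4, 6e-4)), 1)
  expect_equal(as.numeric(diffusionShift(3.5e-4, 6e-4, 4.75e-4)), 0.5)
  out <- diffusionShift(3.5e-4, 6e-4, 7e-4)
  expect_equal(as.numeric(out), 1)
  expect_true(attr(out, "clipped"))
  expect_error(diffusionShift(1e-3, 1e-3, 1e-3), "degenerate")
})
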