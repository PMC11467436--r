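# Donor-lifetime vs efficiency: static and dynamic lines.

test_that("static line is 1 - E", {
  expect_identical(staticLine(0), 1)
  expect_identical(staticLine(1), 0)
  expect_equal(staticLine(0.66), 0.34)
  expect_error(staticLine(1.2))
})

test_that("chain moments match brute-force Monte-Carlo sampling", {
  for (ratio in c(0.6, 1, 1.7)) {
    ch <- ChainModel(rmsDistance = 6 * ratio, forsterRadius = 6)
    m <- chainMoments(ch)
    set.seed(round(100 * ratio))
    nMc <- 1e6
    r <- sqrt(ch@rmsDistance^2 / 3 * rchisq(nMc, df = 3))
    eMc <- 1 / (1 + (r / ch@forsterRadius)^6)
    seMean <- sd(eMc) / sqrt(nMc)
    expect_lt(abs(m[["meanE"]] - mean(eMc)), 3 * seMean)
    vMc <- var(eMc)
    seVar <- sd((eMc - mean(eMc))^2) / sqrt(nMc)
    expect_lt(abs(m[["varE"]] - vMc), 3 * seVar)
  }
})

test_that("efficiency variance respects the Bernoulli bound on [0,1]", {
  for (rms in c(2, 4, 6, 9, 14)) {
    m <- chainMoments(ChainModel(rms, 6))
    expect_lte(m[["varE"]], m[["meanE"]] * (1 - m[["meanE"]]) + 1e-12)
    expect_gte(m[["varE"]], 0)
  }
})

test_that("dynamic line lies on or above the static line and is convex above it", {
  sweep <- dynamicLine(seq(3, 14, by = 0.5), forsterRadius = 6)
  expect_true(all(sweep$rhoDynamic >= sweep$rhoStatic - 1e-12))
  expect_true(all(sweep$varE >= 0))
  # deviation from the diagonal peaks at intermediate efficiency
  dev <- sweep$rhoDynamic - sweep$rhoStatic
  peak <- which.max(dev)
  expect_gt(peak, 1)
  expect_lt(peak, nrow(sweep))
})

test_that("donor-only lifetime is recovered and shifts linearly with the IRF offset", {
  sim <- simulateBurstDataset(nBursts = 1500, trueE = 0.5, donorOnlyFraction = 1,
                              tauD = 3.5, seed = 71)
  tab <- suppressWarnings(burstPipeline(
    sim$stream, AnalysisConfig(corrections = sim$corrections)))
  tau <- donorOnlyLifetime(tab, sim$stream)
  # the 25 ns donor gate truncates the decay; expectation shifts by ~0.02 ns
  L <- 25
  meanTrunc <- 3.5 - L * exp(-L / 3.5) / (1 - exp(-L / 3.5))
  expect_lt(abs(tau - meanTrunc), 0.05)
  tauOff <- donorOnlyLifetime(tab, sim$stream, irfOffset = 1)
  expect_equal(tauOff, tau - 1)
})

test_that("a stream without donor-only bursts refuses the lifetime estimate", {
  sim <- simulateBurstDataset(nBursts = 200, trueE = 0.9, seed = 72)
  tab <- burstPipeline(sim$stream, AnalysisConfig(corrections = sim$corrections))
  tab$S <- 0.5  # force everything out of the donor-only class
  expect_error(donorOnlyLifetime(tab, sim$stream), "donor-only")
})

test_that("static simulations fall on the static line with slope -1", {
  # pool burst clouds across ground-truth efficiencies; within one
  # species shot noise decorrelates E and rho, the line appears across E
  pts <- list()
  for (trueE in c(0.15, 0.35, 0.55, 0.75)) {
    sim <- simulateBurstDataset(nBursts = 600, trueE = trueE,
                                donorOnlyFraction = 0.2,
                                seed = round(100 * trueE))
    tab <- burstPipeline(sim$stream,
                         AnalysisConfig(corrections = sim$corrections))
    tau <- donorOnlyLifetime(tab, sim$stream)
    cl <- classifyBursts(tab, sim$stream, tau)
    pts[[length(pts) + 1]] <- cl$bursts
  }
  cloud <- do.call(rbind, pts)
  fit <- lm(rho ~ E, data = cloud)
  ci <- confint(fit, level = 0.99)
  expect_gt(ci["E", 2], -1.05)
  expect_lt(ci["E", 1], -0.95)
  expect_gt(ci["(Intercept)", 2], 0.97)
  expect_lt(ci["(Intercept)", 1], 1.03)
  # and the mean signed deviation from the static line is ~0
  expect_lt(abs(mean(cloud$rho - (1 - cloud$E))), 0.01)
})

test_that("fast-exchange chains sit on the dynamic line", {
  for (ratio in c(0.75, 1, 1.5)) {
    ch <- ChainModel(rmsDistance = 6 * ratio, forsterRadius = 6)
    m <- chainMoments(ch)
    predicted <- m[["varE"]] / (1 - m[["meanE"]])
    sim <- simulateDynamicChainBursts(nBursts = 900, chain = ch,
                                      donorOnlyFraction = 0.2,
                                      seed = round(10 * ratio))
    tab <- burstPipeline(sim$stream,
                         AnalysisConfig(corrections = sim$corrections))
    tau <- donorOnlyLifetime(tab, sim$stream)
    cl <- classifyBursts(tab, sim$stream, tau)
    expect_lt(abs(cl$meanDeviation - predicted),
              0.02 + 3 * cl$seDeviation)
  }
})

test_that("a static/dynamic mixture shows a bimodal deviation cloud", {
  simS <- simulateBurstDataset(nBursts = 700, trueE = 0.6, seed = 81)
  ch <- ChainModel(6, 6)
  simC <- simulateDynamicChainBursts(nBursts = 700, chain = ch, seed = 82)
  m <- chainMoments(ch)
  devs <- c()
  for (sim in list(simS, simC)) {
    tab <- burstPipeline(sim$stream,
                         AnalysisConfig(corrections = sim$corrections))
    cl <- classifyBursts(tab, sim$stream, 3.48)
    devs <- c(devs, list(cl$bursts$deviation))
  }
  pooled <- unlist(devs)
  km <- kmeans(pooled, centers = c(0, 0.3))
  expect_lt(abs(min(km$centers)), 0.06)
  expect_gt(abs(diff(range(km$centers))),
            0.5 * m[["varE"]] / (1 - m[["meanE"]]))
})

test_that("classify-bursts guards its inputs", {
  sim <- simulateBurstDataset(nBursts = 200, trueE = 0.5, seed = 91)
  tab <- burstPipeline(sim$stream, AnalysisConfig(corrections = sim$corrections))
  expect_error(classifyBursts(tab, sim$stream, tauDonly = 0))
  cl <- classifyBursts(tab, sim$stream, 3.5, minDonorPhotons = 10)
  expect_true(all(cl$bursts$E <= 1.5 & cl$bursts$E >= -0.5))
  expect_identical(nrow(cl$bursts), cl$n)
})
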