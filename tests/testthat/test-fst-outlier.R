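# the island-model null is expensive at publication scale (50,000
# replicates); tests run scaled-down nulls (1,500-5,000 replicates) with
# correspondingly relaxed Monte-Carlo tolerances

test_that("island null configuration validates its invariants", {
  cfg <- islandNullConfig()
  expect_equal(cfg$nDemesTotal, 100)
  expect_equal(cfg$nDemesSampled, 11)
  expect_equal(cfg$sampleIndividualsPerDeme, 20)
  expect_equal(cfg$nReplicates, 50000)
  expect_equal(cfg$targetFst, 0.33)
  expect_error(islandNullConfig(targetFst = 0), "targetFst")
  expect_error(islandNullConfig(nDemesSampled = 200), "nDemesSampled")
})

test_that("migration calibration reaches the target mean FST", {
  cfg <- islandNullConfig(seed = 61)
  M <- calibrateMigration(cfg, pilotReps = 1500, tol = 0.01)
  expect_lt(abs(attr(M, "meanFst") - 0.33), 0.01)
  # verify on an independent draw (Monte-Carlo error at 1500 reps)
  f <- clineCoCo:::.meanIslandFst(cfg, as.numeric(M), 1500, seed = 999)
  expect_lt(abs(f - 0.33), 0.03)
  # deterministic given seed
  M2 <- calibrateMigration(cfg, pilotReps = 1500, tol = 0.01)
  expect_identical(as.numeric(M), as.numeric(M2))
})

test_that("panmixia and isolation limits bracket the null", {
  cfg <- islandNullConfig(seed = 62)
  set.seed(1)
  high <- clineCoCo:::simIslandLoci(100, 11, 40, M = 500, nReps = 300)
  fH <- vapply(high, function(m) if (ncol(m) < 2) NaN else wcFst(m), 0)
  expect_lt(mean(fH[is.finite(fH)]), 0.02)
  set.seed(2)
  low <- clineCoCo:::simIslandLoci(100, 11, 40, M = 0.005, nReps = 100,
                                   thetaRange = c(2, 10))
  fL <- vapply(low, function(m) if (ncol(m) < 2) NaN else wcFst(m), 0)
  expect_gt(mean(fL[is.finite(fL)]), 0.8)
})

test_that("null envelope is monotone, calibrated on held-out draws, and stable", {
  cfg <- islandNullConfig(nReplicates = 5000, seed = 63)
  M <- calibrateMigration(cfg, pilotReps = 1500)
  pairs <- simulateIslandNull(cfg, M)
  env <- buildNullEnvelope(pairs)
  q <- env@quantiles
  expect_true(all(q[, "q0.025"] <= q[, "q0.5"] + 1e-12))
  expect_true(all(q[, "q0.5"] <= q[, "q0.975"] + 1e-12))

  # held-out calibration: an independent null sample falls between the 95%
  # curves about 95% of the time
  cfg2 <- islandNullConfig(nReplicates = 2000, seed = 64)
  held <- simulateIslandNull(cfg2, M)
  # a held-out draw can fall just outside the envelope's He support
  cl <- suppressWarnings(classifyFstOutliers(held, env))
  inside <- !cl$outlierHigh95 & !cl$outlierLow95
  expect_equal(mean(inside), 0.95, tolerance = 0.03)

  # one-tail outlier rate on island-model data: 2.5% +- 1.5 points
  expect_lt(abs(mean(cl$outlierHigh95) - 0.025), 0.015)

  # scaled-down stability: two independent 5,000-replicate envelopes agree
  cfg3 <- islandNullConfig(nReplicates = 5000, seed = 65)
  env3 <- buildNullEnvelope(simulateIslandNull(cfg3, M))
  common <- range(c(env@binMid, env3@binMid))
  at <- seq(common[1] + 0.05, common[2] - 0.05, length.out = 15)
  for (lvl in c("q0.5", "q0.975")) {
    a <- approx(env@binMid, env@quantiles[, lvl], xout = at)$y
    b <- approx(env3@binMid, env3@quantiles[, lvl], xout = at)$y
    expect_lt(max(abs(a - b), na.rm = TRUE), 0.05)
  }
  expect_error(buildNullEnvelope(pairs[1:500, ]), ">= 1000")
})

test_that("outlier classification flags constructed selection signals", {
  cfg <- islandNullConfig(nReplicates = 4000, seed = 66)
  M <- calibrateMigration(cfg, pilotReps = 1500)
  env <- buildNullEnvelope(simulateIslandNull(cfg, M))

  # two site clusters fixed for alternative alleles: maximal FST for its He
  sites <- data.frame(id = sprintf("s%d", 1:10),
                      latitude = seq(30, 45, length.out = 10))
  split <- rbind(matrix(rep(c(40L, 0L), each = 5), 5),
                 matrix(rep(c(0L, 40L), each = 5), 5))
  dimnames(split) <- list(sites$id, c("1", "2"))
  # a locus sitting at the null median is not an outlier
  medianish <- t(sapply(seq(0.15, 0.6, length.out = 10), function(p)
    c(round(40 * p), 40 - round(40 * p))))
  dimnames(medianish) <- list(sites$id, c("1", "2"))
  ds <- ClineDataset(sites, c("split", "mid"), list(split, medianish))
  cl <- classifyFstOutliers(ds, env)
  expect_true(cl$outlierHigh95[cl$locus == "split"])
  expect_lt(cl$empiricalP[cl$locus == "split"], 0.05)
  expect_false(cl$outlierHigh95[cl$locus == "mid"])

  # planted high-FST locus among island-model loci is caught at 99%
  set.seed(9)
  null <- simulateIslandNull(islandNullConfig(nReplicates = 300, seed = 67), M)
  planted <- rbind(null, data.frame(He = 0.5, Fst = 0.95))
  cl2 <- classifyFstOutliers(planted, env)
  expect_true(cl2$outlierHigh99[nrow(cl2)])
})
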