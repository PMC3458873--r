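test_that("Co-Co coordinates log-transform absolute slopes", {
  fits <- data.frame(locus = c("a", "b", "c"),
                     midpoint = c(40, 39, 41),
                     slope = c(-0.2, 0.1, -0.1))
  pts <- cocoCoordinates(fits)
  expect_equal(pts$logAbsSlope[1], log(0.2))
  expect_equal(pts$logAbsSlope[2], pts$logAbsSlope[3])
  expect_error(cocoCoordinates(fits[0, ]), "no fits")
  fits$slope[2] <- 0
  expect_error(cocoCoordinates(fits), "nonzero")
})

test_that("log transform symmetrizes right-skewed slope distributions", {
  gen <- generateClineDataset(nSites = 18, nLoci = 80, fractionClinal = 1,
                              deltaP = c(0.3, 0.9), seed = 31)
  res <- screenDataset(gen$dataset, seed = 9, mantel = FALSE)
  sl <- abs(res$slope[res$isClinal])
  skew <- function(v) mean((v - mean(v))^3) / sd(v)^3
  expect_lt(abs(skew(log(sl))), abs(skew(sl)))
})

test_that("kernel density approximates a known bivariate normal", {
  set.seed(41)
  n <- 8000
  pts <- data.frame(midpoint = rnorm(n), logAbsSlope = rnorm(n))
  field <- estimateCocoDensity(pts, bandwidthMethod = "plugin",
                               gridSize = 128)
  at0 <- field@z[which.min(abs(field@x)), which.min(abs(field@y))]
  expect_equal(at0, 1 / (2 * pi), tolerance = 0.1)
  # exact estimand: a KDE with bandwidth H on N(0, I) estimates N(0, I + H)
  h2 <- field@H[1, 1]
  expect_equal(at0, 1 / (2 * pi * (1 + h2)), tolerance = 0.08)
  # grid mass is 1 (also enforced by the class validity)
  cell <- diff(field@x[1:2]) * diff(field@y[1:2])
  expect_equal(sum(field@z) * cell, 1, tolerance = 1e-3)

  # independent cross-check: MASS::kde2d with the matching fixed diagonal
  # bandwidth (kde2d's h is 4x the kernel sd)
  h <- sqrt(diag(field@H))
  ref <- MASS::kde2d(pts$midpoint, pts$logAbsSlope, h = 4 * h, n = 50,
                     lims = c(-1, 1, -1, 1))
  mine <- outer(ref$x, ref$y, function(x, y)
    clineCoCo:::.bilinear(field, x, y))
  expect_lt(max(abs(mine - ref$z)), 0.01)

  expect_error(estimateCocoDensity(pts[1:5, ]), ">= 10")
  same <- data.frame(midpoint = rep(1, 20), logAbsSlope = rep(2, 20))
  expect_error(estimateCocoDensity(same), "identical")
})

test_that("cross-validated bandwidths are sane on structured data", {
  set.seed(55)
  pts <- data.frame(midpoint = rnorm(150, 40, 1),
                    logAbsSlope = rnorm(150, -2, 0.5))
  field <- estimateCocoDensity(pts, bandwidthMethod = "cv", gridSize = 96)
  expect_true(field@method %in% c("cv", "plugin"))
  ev <- eigen(field@H, only.values = TRUE)$values
  expect_true(all(ev > 0))
  # doubling the grid changes HDR mass thresholds by very little
  field2 <- estimateCocoDensity(pts, bandwidthMethod = "cv", gridSize = 192)
  l1 <- hdrThresholds(field, 0.95)
  l2 <- hdrThresholds(field2, 0.95)
  expect_equal(unname(l1), unname(l2), tolerance = 0.005)
})

test_that("HDR thresholds are monotone, nested, and match Gaussian geometry", {
  set.seed(61)
  pts <- data.frame(midpoint = rnorm(4000), logAbsSlope = rnorm(4000))
  field <- estimateCocoDensity(pts, bandwidthMethod = "plugin",
                               gridSize = 128)
  lev <- hdrThresholds(field, c(0.75, 0.95, 0.99))
  expect_true(lev[1] > lev[2] && lev[2] > lev[3])
  # nesting as grid sets
  cell <- diff(field@x[1:2]) * diff(field@y[1:2])
  in75 <- field@z >= lev[1]; in95 <- field@z >= lev[2]; in99 <- field@z >= lev[3]
  expect_true(all(in95[in75]))
  expect_true(all(in99[in95]))
  # 95% HDR area: the analytic ellipse pi * qchisq(.95, 2), inflated by the
  # kernel convolution factor (1 + h^2); check both the raw 10% agreement
  # and the exact convolved value
  area95 <- sum(in95) * cell
  expect_equal(area95, pi * qchisq(0.95, 2), tolerance = 0.1)
  expect_equal(area95, pi * qchisq(0.95, 2) * (1 + field@H[1, 1]),
               tolerance = 0.05)
  # mass 1.0 falls back to the smallest positive density
  expect_equal(unname(hdrThresholds(field, 1.0)),
               min(field@z[field@z > 0]))
})

test_that("outlier flags are calibrated and catch planted outliers", {
  set.seed(71)
  frac <- replicate(30, {
    pts <- data.frame(midpoint = rnorm(150), logAbsSlope = rnorm(150))
    field <- estimateCocoDensity(pts, bandwidthMethod = "plugin",
                                 gridSize = 64)
    mean(flagCocoOutliers(pts, field, mass = 0.95)$outlier)
  })
  expect_lt(abs(mean(frac) - 0.05), 0.03)  # 5% +- 3 points

  # a locus with slope 10x the population median is flagged
  set.seed(72)
  pts <- data.frame(locus = c(sprintf("L%d", 1:60), "planted"),
                    midpoint = c(rnorm(60, 40, 0.5), 40),
                    logAbsSlope = c(rnorm(60, log(0.1), 0.2), log(1)))
  field <- estimateCocoDensity(pts, bandwidthMethod = "plugin", gridSize = 96)
  out <- flagCocoOutliers(pts, field)
  expect_true(out$outlier[out$locus == "planted"])

  # points outside the grid get density zero, flagged, with a warning
  far <- data.frame(locus = "far", midpoint = 1000, logAbsSlope = 0)
  expect_warning(res <- flagCocoOutliers(far, field), "outside")
  expect_true(res$outlier)
  expect_equal(res$density, 0)
})

test_that("Co-Co plot renders to file for several datasets", {
  for (s in 1:3) {
    set.seed(s)
    pts <- data.frame(locus = sprintf("L%d", 1:40),
                      midpoint = rnorm(40, 40), logAbsSlope = rnorm(40, -2))
    field <- estimateCocoDensity(pts, bandwidthMethod = "plugin",
                                 gridSize = 64)
    f <- tempfile(fileext = ".pdf")
    out <- plotCoco(pts, field, highlight = "L1", file = f)
    expect_true(file.exists(f) && file.size(f) > 0)
    expect_equal(nrow(out), 40)
  }
})
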