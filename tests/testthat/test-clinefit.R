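test_that("broken-stick prediction interpolates between its plateaus", {
  par <- c(38, 0.1, 42, 0.9)
  expect_equal(brokenStickPredict(par, 40), 0.5)
  expect_equal(brokenStickPredict(par, 30), 0.1)
  expect_equal(brokenStickPredict(par, 45), 0.9)
  # implied midpoint and slope
  expect_equal((38 + 42) / 2, 40)
  expect_equal((0.9 - 0.1) / (42 - 38), 0.2)
})

test_that("horizontal fit is the pooled-frequency MLE with the stated loglik", {
  fit <- fitHorizontal(c(30, 45), c(8, 2), c(10, 10))
  expect_equal(fit$p, 0.5)
  # oracle: loglik recomputed from independently summed binomial terms
  oracle <- dbinom(8, 10, 0.5, log = TRUE) + dbinom(2, 10, 0.5, log = TRUE) -
    (lchoose(10, 8) + lchoose(10, 2))  # package loglik drops the constant
  expect_equal(fit$loglik, oracle, tolerance = 1e-12)
  # degenerate: all sites fixed
  fx <- fitHorizontal(c(30, 45), c(10, 10), c(10, 10))
  expect_equal(fx$p, 1)
  expect_equal(fx$loglik, 20 * log(1 - 1e-6), tolerance = 1e-9)
})

test_that("broken-stick fit recovers noise-free generating parameters", {
  d <- makeBrokenStickCounts(params = c(38, 0.1, 42, 0.9))
  fit <- fitBrokenStick(d$lats, d$x, d$n)
  expect_true(fit$converged)
  expect_equal(unname(fit$params["latSouthBreak"]), 38, tolerance = 0.1)
  expect_equal(unname(fit$params["latNorthBreak"]), 42, tolerance = 0.1)
  expect_equal(unname(fit$params["pSouth"]), 0.1, tolerance = 0.01)
  expect_equal(unname(fit$params["pNorth"]), 0.9, tolerance = 0.01)
  expect_equal(fit$midpoint, 40, tolerance = 0.1)
  expect_equal(fit$slope, 0.2, tolerance = 0.02)
})

test_that("degenerate inputs are excluded with a reason, not an error", {
  fit <- fitBrokenStick(c(30, 40, 45), c(1, 5, 9), rep(10, 3))
  expect_false(fit$converged)
  expect_match(fit$reason, "degenerate")
  fit2 <- fitBrokenStick(rep(c(30, 40), c(3, 3)), rep(5, 6), rep(10, 6))
  expect_false(fit2$converged)
})

test_that("nesting invariant: broken-stick loglik never falls below horizontal", {
  set.seed(12)
  lats <- seq(30, 45, length.out = 12)
  for (i in 1:25) {
    p <- if (i %% 2) rep(runif(1, 0.1, 0.9), 12) else
      brokenStickPredict(c(37, runif(1, 0, 0.4), 42, runif(1, 0.6, 1)), lats)
    x <- rbinom(12, 40, p)
    fb <- fitBrokenStick(lats, x, rep(40, 12))
    fh <- fitHorizontal(lats, x, rep(40, 12))
    expect_gte(fb$loglik, fh$loglik)
  }
})

test_that("focal-allele reflection symmetry is exact", {
  set.seed(3)
  lats <- seq(30, 45, length.out = 15)
  for (i in 1:10) {
    p <- brokenStickPredict(c(37, 0.15, 42, 0.8), lats)
    x <- rbinom(15, 40, p)
    n <- rep(40, 15)
    if (2 * sum(x) == sum(n)) next  # canonical orientation undefined at exactly 0.5
    a <- fitBrokenStick(lats, x, n)
    b <- fitBrokenStick(lats, n - x, n)
    expect_identical(a$loglik, b$loglik)
    expect_identical(a$midpoint, b$midpoint)
    expect_identical(abs(a$slope), abs(b$slope))
    expect_identical(a$slope, -b$slope)
    ha <- fitHorizontal(lats, x, n); hb <- fitHorizontal(lats, n - x, n)
    expect_equal(lrtClinal(a, ha)$stat, lrtClinal(b, hb)$stat,
                 tolerance = 1e-9)
  }
})

test_that("parameter recovery on random synthetic clines is accurate", {
  set.seed(21)
  nRec <- 60
  midErr <- slopeRelErr <- numeric(nRec)
  lats <- seq(30, 45, length.out = 20)
  for (i in seq_len(nRec)) {
    mid <- runif(1, 36, 44)
    dp <- runif(1, 0.4, 0.9)
    w <- runif(1, 2, 5)
    par <- c(mid - w / 2, (1 - dp) / 2, mid + w / 2, (1 + dp) / 2)
    x <- rbinom(20, 40, brokenStickPredict(par, lats))
    fit <- fitBrokenStick(lats, x, rep(40, 20))
    midErr[i] <- abs(fit$midpoint - mid)
    slopeRelErr[i] <- abs(abs(fit$slope) - dp / w) / (dp / w)
  }
  expect_lt(median(midErr), 0.5)
  expect_lt(median(slopeRelErr), 0.2)
})

test_that("LRT clinality test has the nominal reference and calibration", {
  f0 <- list(loglik = -10); f1 <- list(loglik = -10)
  eq <- lrtClinal(f1, f0)
  expect_equal(eq$stat, 0); expect_equal(eq$p, 1)
  expect_equal(lrtClinal(list(loglik = -10 + 7.815 / 2), f0)$p, 0.05,
               tolerance = 1e-3)
  expect_error(lrtClinal(list(loglik = -11), f0), "optimizer")

  # strong cline: overwhelming evidence
  d <- makeBrokenStickCounts(params = c(38, 0.1, 42, 0.9),
                             lats = seq(30, 45, length.out = 20), n = 40)
  fb <- fitBrokenStick(d$lats, d$x, d$n)
  fh <- fitHorizontal(d$lats, d$x, d$n)
  expect_lt(lrtClinal(fb, fh)$p, 1e-6)

  # type-I error on flat loci within the documented band
  set.seed(31)
  lats <- seq(30, 45, length.out = 15)
  pv <- replicate(150, {
    x <- rbinom(15, 40, runif(1, 0.15, 0.85))
    lrtClinal(fitBrokenStick(lats, x, rep(40, 15)),
              fitHorizontal(lats, x, rep(40, 15)))$p
  })
  expect_gte(mean(pv < 0.05), 0.01)
  expect_lte(mean(pv < 0.05), 0.12)
})

test_that("logistic cross-check agrees with broken-stick on clean clines", {
  lats <- seq(30, 45, length.out = 20)
  p <- 0.1 + 0.8 * plogis(2 * (lats - 40))
  x <- round(p * 400)
  lg <- fitLogistic(lats, x, rep(400, 20))
  bs <- fitBrokenStick(lats, x, rep(400, 20))
  expect_true(lg$converged)
  expect_equal(lg$midpoint, bs$midpoint, tolerance = 0.5)

  # flat data: flagged failure or boundary, never an error
  set.seed(2)
  xf <- rbinom(20, 40, 0.4)
  lf <- fitLogistic(lats, xf, rep(40, 20))
  hfz <- fitHorizontal(lats, xf, rep(40, 20))
  # acceptable outcomes on flat data: flagged failure, boundary fit, or a
  # converged fit indistinguishable from the horizontal null
  expect_true(!isTRUE(lf$converged) || length(lf$flags) > 0 ||
                2 * (lf$loglik - hfz$loglik) < qchisq(0.95, 3))
  # nesting against horizontal holds for the logistic family too
  hf <- fitHorizontal(lats, xf, rep(40, 20))
  expect_gte(lf$loglik, hf$loglik - 1e-9)
})

test_that("gaussian least-squares option fits the same models", {
  d <- makeBrokenStickCounts()
  fg <- fitBrokenStick(d$lats, d$x, d$n, likelihood = "gaussian")
  expect_true(fg$converged)
  expect_equal(fg$midpoint, 40, tolerance = 0.2)
  hg <- fitHorizontal(d$lats, d$x, d$n, likelihood = "gaussian")
  expect_gte(fg$loglik, hg$loglik)
})
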