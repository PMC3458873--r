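## Twice-broken-stick cline models: two flat plateaus joined by one linear
## segment, fit by maximum likelihood to focal-allele counts along a
## transect, plus the horizontal (intercept-only) null and an optional
## 4-parameter logistic cross-check.

.PCLAMP <- 1e-6

#' Predict allele frequency under the twice-broken-stick model
#'
#' The model is flat at \code{pSouth} below the southern break, flat at
#' \code{pNorth} above the northern break, and linear in between.
#'
#' @param params numeric vector \code{c(latSouthBreak, pSouth,
#'   latNorthBreak, pNorth)} (or a list with those names).
#' @param lat latitude(s) at which to predict.
#' @return predicted frequency, vectorized over \code{lat}.
#' @examples
#' brokenStickPredict(c(38, 0.1, 42, 0.9), c(30, 40, 45))  # 0.1 0.5 0.9
#' @export
brokenStickPredict <- function(params, lat) {
  if (is.list(params))
    params <- c(params$latSouthBreak, params$pSouth,
                params$latNorthBreak, params$pNorth)
  b1 <- params[1]; pS <- params[2]; b2 <- params[3]; pN <- params[4]
  stopifnot(b1 < b2)
  frac <- pmin(pmax((lat - b1) / (b2 - b1), 0), 1)
  pS + frac * (pN - pS)
}

.binomLoglik <- function(x, n, p) {
  p <- pmin(pmax(p, .PCLAMP), 1 - .PCLAMP)
  sum(x * log(p) + (n - x) * log1p(-p))
}

.gaussLoglik <- function(x, n, p) {
  # profile-normal loglik on observed frequencies (least-squares option)
  r <- x / n - p
  N <- length(x)
  rss <- sum(r^2)
  -N / 2 * (log(2 * pi * max(rss, 1e-12) / N) + 1)
}

.clineLoglik <- function(x, n, p, likelihood) {
  if (likelihood == "binomial") .binomLoglik(x, n, p) else .gaussLoglik(x, n, p)
}

#' Fit the horizontal (intercept-only) cline null model
#'
#' Maximum-likelihood constant frequency under the binomial likelihood,
#' \eqn{\hat p = \sum x_i / \sum n_i}.
#'
#' @param lats site latitudes.
#' @param x focal-allele counts per site.
#' @param n sampled allele numbers per site (sites with n = 0 are dropped).
#' @param likelihood "binomial" (default) or "gaussian" (least squares).
#' @return list with \code{model}, \code{p}, \code{loglik}, \code{nSites}.
#' @export
fitHorizontal <- function(lats, x, n, likelihood = c("binomial", "gaussian")) {
  likelihood <- match.arg(likelihood)
  keep <- n > 0
  lats <- lats[keep]; x <- x[keep]; n <- n[keep]
  if (length(x) < 2) stop("need >= 2 assayed sites")
  p <- if (likelihood == "binomial") sum(x) / sum(n) else mean(x / n)
  list(model = "horizontal", p = p,
       loglik = .clineLoglik(x, n, rep(p, length(x)), likelihood),
       nSites = length(x), likelihood = likelihood)
}

## transform helpers: optimization runs on unconstrained parameters
.bsDecode <- function(par, L, U, wMin) {
  ctr <- L + (U - L) * stats::plogis(par[1])
  w <- wMin + (U - L - wMin) * stats::plogis(par[2])
  b1 <- max(ctr - w / 2, L)
  b2 <- min(ctr + w / 2, U)
  if (b2 - b1 < wMin) { b1 <- ctr - wMin / 2; b2 <- ctr + wMin / 2 }
  c(b1, stats::plogis(par[3]), b2, stats::plogis(par[4]))
}

#' Fit the twice-broken-stick cline model
#'
#' Maximizes the binomial log-likelihood of the three-segment model over its
#' four parameters (two break coordinates in latitude/frequency space) using
#' multi-start derivative-free optimization: all pairs of nine
#' sampled-latitude quantiles seed the break points, plateau frequencies are
#' initialized from the pooled frequencies outside each candidate break
#' pair, the best starts are refined with Nelder-Mead on logit/ordering
#' transforms that enforce \code{latSouthBreak < latNorthBreak}, and the
#' embedded horizontal fit is always included as a candidate so the
#' broken-stick likelihood can never fall below the horizontal one.
#'
#' Breaks may lie up to 1 degree beyond the sampled range so edge clines are
#' representable; break separation is bounded below at 0.01 degrees and fits
#' at that bound are flagged "step-like".  Data are internally reflected so
#' the pooled focal frequency is <= 0.5, which makes the fit exactly
#' symmetric under focal-allele complementation.
#'
#' @inheritParams fitHorizontal
#' @param nStarts number of grid starts to refine (default 3).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return list with \code{model}, \code{params} (named: latSouthBreak,
#'   pSouth, latNorthBreak, pNorth), \code{loglik}, \code{midpoint},
#'   \code{slope} (frequency change per degree, signed), \code{flags}
#'   (character: may contain "step-like"), \code{converged}.  Degenerate
#'   inputs (< 5 sites or < 3 distinct latitudes) return
#'   \code{converged = FALSE} with a \code{reason}.
#' @export
fitBrokenStick <- function(lats, x, n, likelihood = c("binomial", "gaussian"),
                           nStarts = 3, maxit = 300) {
  likelihood <- match.arg(likelihood)
  keep <- n > 0
  lats <- lats[keep]; x <- x[keep]; n <- n[keep]
  if (length(x) < 5 || length(unique(lats)) < 3) {
    return(list(model = "broken_stick", converged = FALSE,
                reason = "degenerate input: <5 sites or <3 distinct latitudes",
                loglik = NA_real_, midpoint = NA_real_, slope = NA_real_,
                params = NULL, flags = "failed"))
  }

  # canonical orientation: pooled frequency <= 0.5 (exact reflection symmetry)
  flipped <- sum(x) / sum(n) > 0.5
  if (flipped) x <- n - x

  L <- min(lats) - 1; U <- max(lats) + 1
  wMin <- 0.01
  obj <- function(par) {
    th <- .bsDecode(par, L, U, wMin)
    -.clineLoglik(x, n, brokenStickPredict(th, lats), likelihood)
  }

  # grid of candidate break pairs at latitude quantiles
  latQ <- unique(as.numeric(stats::quantile(lats, probs = seq(0.1, 0.9, length.out = 9))))
  pairs <- which(outer(latQ, latQ, "<"), arr.ind = TRUE)
  phat <- sum(x) / sum(n)
  gridPar <- matrix(NA_real_, nrow(pairs), 4)
  gridLL <- numeric(nrow(pairs))
  for (g in seq_len(nrow(pairs))) {
    b1 <- latQ[pairs[g, 1]]; b2 <- latQ[pairs[g, 2]]
    sel <- lats <= b1
    pS <- if (any(sel)) sum(x[sel]) / sum(n[sel]) else phat
    sel <- lats >= b2
    pN <- if (any(sel)) sum(x[sel]) / sum(n[sel]) else phat
    pS <- min(max(pS, 0.001), 0.999); pN <- min(max(pN, 0.001), 0.999)
    th <- c(b1, pS, b2, pN)
    gridPar[g, ] <- th
    gridLL[g] <- .clineLoglik(x, n, brokenStickPredict(th, lats), likelihood)
  }
  top <- order(gridLL, decreasing = TRUE)[seq_len(min(nStarts, nrow(pairs)))]

  encode <- function(th) {
    ctr <- (th[1] + th[3]) / 2; w <- th[3] - th[1]
    c(stats::qlogis(min(max((ctr - L) / (U - L), 1e-4), 1 - 1e-4)),
      stats::qlogis(min(max((w - wMin) / (U - L - wMin), 1e-4), 1 - 1e-4)),
      stats::qlogis(th[2]), stats::qlogis(th[4]))
  }

  best <- NULL
  bestLL <- -Inf
  for (g in top) {
    fit <- try(stats::optim(encode(gridPar[g, ]), obj, method = "Nelder-Mead",
                            control = list(maxit = maxit, reltol = 1e-9)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    th <- .bsDecode(fit$par, L, U, wMin)
    ll <- -fit$value
    sl <- abs((th[4] - th[2]) / (th[3] - th[1]))
    if (ll > bestLL + 1e-8 ||
        (abs(ll - bestLL) <= 1e-8 && !is.null(best) &&
         sl < abs((best[4] - best[2]) / (best[3] - best[1])))) {
      best <- th; bestLL <- ll
    }
  }

  # embedded horizontal candidate guarantees the nesting invariant
  hTh <- c(L + (U - L) / 4, phat, U - (U - L) / 4, phat)
  hLL <- .clineLoglik(x, n, brokenStickPredict(hTh, lats), likelihood)
  if (is.null(best) || hLL >= bestLL - 1e-8) {
    best <- hTh; bestLL <- hLL
  }

  if (flipped) best[c(2, 4)] <- 1 - best[c(2, 4)]
  flags <- character()
  if (best[3] - best[1] <= wMin + 1e-6) flags <- c(flags, "step-like")
  list(model = "broken_stick",
       params = c(latSouthBreak = best[1], pSouth = best[2],
                  latNorthBreak = best[3], pNorth = best[4]),
       loglik = bestLL,
       midpoint = (best[1] + best[3]) / 2,
       slope = (best[4] - best[2]) / (best[3] - best[1]),
       flags = flags, converged = TRUE, likelihood = likelihood)
}

#' Fit a four-parameter logistic cline (cross-check model)
#'
#' Sigmoid \eqn{p(lat) = p_S + (p_N - p_S)\,\mathrm{logit}^{-1}(\beta(lat - c))}
#' fit under the same binomial likelihood.  Used only to cross-validate
#' broken-stick fits on well-behaved clines; on flat or ill-defined data it
#' may fail to converge, in which case a flagged failure is returned rather
#' than an error.
#'
#' @inheritParams fitHorizontal
#' @return list like [fitBrokenStick()]'s, with \code{model = "logistic"},
#'   \code{midpoint} = the sigmoid center and \code{slope} = the frequency
#'   derivative at the center; \code{converged = FALSE} with flag "failed"
#'   or "boundary" when the fit is unreliable.
#' @export
fitLogistic <- function(lats, x, n, likelihood = c("binomial", "gaussian")) {
  likelihood <- match.arg(likelihood)
  keep <- n > 0
  lats <- lats[keep]; x <- x[keep]; n <- n[keep]
  if (length(x) < 5)
    return(list(model = "logistic", converged = FALSE, flags = "failed",
                loglik = NA_real_, midpoint = NA_real_, slope = NA_real_))
  L <- min(lats) - 1; U <- max(lats) + 1
  phat <- sum(x) / sum(n)
  obj <- function(par) {
    pS <- stats::plogis(par[1]); pN <- stats::plogis(par[2])
    ctr <- L + (U - L) * stats::plogis(par[3]); beta <- exp(par[4])
    p <- pS + (pN - pS) * stats::plogis(beta * (lats - ctr))
    -.clineLoglik(x, n, p, likelihood)
  }
  f <- x / n
  ord <- order(lats)
  pS0 <- mean(f[ord][seq_len(max(2, length(f) %/% 4))])
  pN0 <- mean(rev(f[ord])[seq_len(max(2, length(f) %/% 4))])
  starts <- list(
    c(stats::qlogis(min(max(pS0, .01), .99)), stats::qlogis(min(max(pN0, .01), .99)),
      0, log(1)),
    c(stats::qlogis(min(max(pS0, .01), .99)), stats::qlogis(min(max(pN0, .01), .99)),
      0, log(5)))
  best <- NULL; bestLL <- -Inf; bestPar <- NULL
  for (s in starts) {
    fit <- try(stats::optim(s, obj, method = "Nelder-Mead",
                            control = list(maxit = 500, reltol = 1e-9)),
               silent = TRUE)
    if (inherits(fit, "try-error") || !is.finite(fit$value)) next
    if (-fit$value > bestLL) { bestLL <- -fit$value; bestPar <- fit$par }
  }
  hLL <- .clineLoglik(x, n, rep(phat, length(x)), likelihood)
  if (is.null(bestPar) || bestLL < hLL) {
    # sigmoid degenerates to (or below) the flat fit: report the embedded
    # horizontal solution, flagged, so the nesting invariant still holds
    return(list(model = "logistic", converged = FALSE, flags = "failed",
                loglik = max(bestLL, hLL), midpoint = NA_real_,
                slope = NA_real_))
  }
  pS <- stats::plogis(bestPar[1]); pN <- stats::plogis(bestPar[2])
  ctr <- L + (U - L) * stats::plogis(bestPar[3]); beta <- exp(bestPar[4])
  flags <- character()
  if (beta > 50 || beta < 1e-3 || ctr < L + 0.01 * (U - L) ||
      ctr > U - 0.01 * (U - L)) flags <- "boundary"
  list(model = "logistic",
       params = c(pSouth = pS, pNorth = pN, center = ctr, steepness = beta),
       loglik = bestLL, midpoint = ctr,
       slope = (pN - pS) * beta / 4,  # derivative of the sigmoid at center
       flags = flags, converged = TRUE, likelihood = likelihood)
}

#' Likelihood-ratio test for clinality
#'
#' Compares the twice-broken-stick fit (4 parameters) against the horizontal
#' fit (1 parameter) on the same locus: \eqn{\Lambda = 2(\ell_{bs} -
#' \ell_{h})}, referred to a chi-square with 3 degrees of freedom.  The
#' break points are not regular parameters under the null, so the chi-square
#' reference is the nominal convention, not an exact distribution.
#'
#' @param fitBs result of [fitBrokenStick()].
#' @param fitH result of [fitHorizontal()] on the same data.
#' @return list with \code{stat}, \code{df} (= 3) and \code{p}.
#' @export
lrtClinal <- function(fitBs, fitH) {
  stat <- 2 * (fitBs$loglik - fitH$loglik)
  if (is.na(stat)) return(list(stat = NA_real_, df = 3, p = NA_real_))
  if (stat < -1e-6)
    stop("broken-stick loglik below horizontal: optimizer failure")
  stat <- max(stat, 0)
  list(stat = stat, df = 3, p = stats::pchisq(stat, df = 3, lower.tail = FALSE))
}
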