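## Synthetic-data generators with known ground truth.  These stand in for
## empirical allele-frequency compilations (which are scattered across
## decades of literature and not machine-readable) and give every pipeline
## stage a dataset whose true clinal structure is recorded.

#' Generate a synthetic transect dataset with known clinal structure
#'
#' A fraction of loci carry clines (logistic by default, or hard-stepped)
#' with midpoints and frequency contrasts drawn from the supplied
#' distributions; the remaining loci are flat at a uniform(0.05, 0.95)
#' frequency.  Observed counts are binomial draws at each site.  The default
#' latitude grid mimics a 30-45 degree coastal transect sampled more densely
#' near the 40 degree contact zone.
#'
#' @param nSites number of sites (default 20).
#' @param latRange transect extent in degrees N (default c(30, 45)).
#' @param nLoci number of loci (default 100).
#' @param fractionClinal fraction of loci that are truly clinal.
#' @param midpointRange uniform range of true cline midpoints (default
#'   c(38, 42)).
#' @param deltaP frequency contrast of clinal loci: a single value, or a
#'   range to draw uniformly from (default 0.8).
#' @param shape "logistic" (smooth, default) or "stepped".
#' @param width latitudinal width of the clinal transition (degrees,
#'   default 3).
#' @param nPerSite allele copies sampled per site (default 40).
#' @param seed integer seed.
#' @return list with \code{dataset} (a [ClineDataset-class], marker class
#'   "SNP") and \code{truth} (data.frame: locus, clinal, midpoint, deltaP,
#'   slope, pFlat).
#' @export
generateClineDataset <- function(nSites = 20, latRange = c(30, 45),
                                 nLoci = 100, fractionClinal = 0.5,
                                 midpointRange = c(38, 42), deltaP = 0.8,
                                 shape = c("logistic", "stepped"),
                                 width = 3, nPerSite = 40, seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(fractionClinal >= 0, fractionClinal <= 1)
  set.seed(seed)
  # denser sampling near the transect center, like empirical designs
  u <- stats::qbeta(seq(0.5 / nSites, 1 - 0.5 / nSites, length.out = nSites),
                    1.4, 1.4)
  lats <- latRange[1] + u * diff(latRange)
  sites <- data.frame(id = sprintf("site%02d", seq_len(nSites)),
                      latitude = lats, stringsAsFactors = FALSE)

  nClin <- round(nLoci * fractionClinal)
  clinal <- seq_len(nLoci) <= nClin
  mid <- stats::runif(nLoci, midpointRange[1], midpointRange[2])
  dp <- if (length(deltaP) == 2) stats::runif(nLoci, deltaP[1], deltaP[2])
        else rep(deltaP, nLoci)
  pFlat <- stats::runif(nLoci, 0.05, 0.95)
  dirUp <- sample(c(-1, 1), nLoci, replace = TRUE)

  counts <- vector("list", nLoci)
  truth <- data.frame(locus = sprintf("L%04d", seq_len(nLoci)),
                      clinal = clinal, midpoint = ifelse(clinal, mid, NA),
                      deltaP = ifelse(clinal, dp * dirUp, NA),
                      slope = NA_real_, pFlat = ifelse(clinal, NA, pFlat),
                      stringsAsFactors = FALSE)
  for (l in seq_len(nLoci)) {
    if (clinal[l]) {
      lo <- (1 - dp[l]) / 2
      if (shape == "logistic") {
        p <- lo + dp[l] * stats::plogis(4 / width * (lats - mid[l]))
        truth$slope[l] <- dirUp[l] * dp[l] / width  # sigmoid center slope
      } else {
        p <- ifelse(lats < mid[l] - width / 2, lo,
                    ifelse(lats > mid[l] + width / 2, lo + dp[l],
                           lo + dp[l] * (lats - mid[l] + width / 2) / width))
        truth$slope[l] <- dirUp[l] * dp[l] / width
      }
      if (dirUp[l] < 0) p <- 1 - p
    } else {
      p <- rep(pFlat[l], nSites)
    }
    x <- stats::rbinom(nSites, nPerSite, p)
    m <- cbind(x, nPerSite - x)
    dimnames(m) <- list(sites$id, c("1", "2"))
    counts[[l]] <- m
  }
  loci <- data.frame(id = truth$locus, markerClass = "SNP",
                     stringsAsFactors = FALSE)
  list(dataset = ClineDataset(sites, loci, counts,
                              provenance = "synthetic transect"),
       truth = truth)
}

#' Generate one multi-allelic locus with a designated clinal allele
#'
#' Allele 1 follows a logistic cline between its southern and northern
#' regional frequencies; the remaining k-1 alleles share the complement in
#' fixed proportions, so they are flat-complementary.  Used to exercise
#' focal-allele selection.
#'
#' @param k number of alleles (>= 3).
#' @param lats site latitudes.
#' @param pSouth,pNorth frequency of the designated allele at the transect
#'   ends.
#' @param midpoint,width cline location and latitudinal width.
#' @param n allele copies per site.
#' @param seed integer seed.
#' @return sites x k integer count matrix (allele ids "1".."k"; allele "1"
#'   is the true clinal allele).
#' @export
generateMultiallelicLocus <- function(k, lats, pSouth = 0.1, pNorth = 0.7,
                                      midpoint = 40, width = 3, n = 40,
                                      seed = 1L) {
  stopifnot(k >= 3)
  set.seed(seed)
  rest <- stats::runif(k - 1)
  rest <- rest / sum(rest)  # fixed proportions of the complement
  m <- matrix(0L, length(lats), k,
              dimnames = list(names(lats), as.character(seq_len(k))))
  for (i in seq_along(lats)) {
    p1 <- pSouth + (pNorth - pSouth) * stats::plogis(4 / width * (lats[i] - midpoint))
    probs <- c(p1, (1 - p1) * rest)
    if (abs(sum(probs) - 1) > 1e-9) stop("profiles must sum to 1")
    m[i, ] <- as.integer(stats::rmultinom(1, n, probs))
  }
  m
}
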