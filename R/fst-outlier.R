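## fdist-style FST outlier analysis: a finite-island coalescent null for
## (heterozygosity, FST) pairs, conditional quantile envelopes, and
## classification of empirical loci against them.

#' Configuration for the island-model FST null
#'
#' Defaults follow the standard desk setup for an fdist-style scan of a
#' dataset with a median of 11 assayed populations: 100 demes of which 11
#' are sampled with 20 diploid individuals each, 50,000 replicate coalescent
#' genealogies under infinite-alleles mutation, calibrated to a target mean
#' FST of 0.33.
#'
#' @param nDemesTotal total island-model demes.
#' @param nDemesSampled demes sampled per replicate.
#' @param sampleIndividualsPerDeme diploid individuals sampled per deme
#'   (40 gene copies by default).
#' @param nReplicates replicate loci for the envelope (scale down for
#'   exploratory runs; >= 1000 required by [buildNullEnvelope()]).
#' @param targetFst target mean FST for migration calibration.
#' @param thetaRange log-uniform range of total-population scaled mutation
#'   rates, spreading the null along the heterozygosity axis.
#' @param seed integer seed.
#' @return list of class "islandNullConfig".
#' @export
islandNullConfig <- function(nDemesTotal = 100, nDemesSampled = 11,
                             sampleIndividualsPerDeme = 20,
                             nReplicates = 50000, targetFst = 0.33,
                             thetaRange = c(0.01, 10), seed = 1L) {
  stopifnot(nDemesSampled <= nDemesTotal, nReplicates >= 1)
  if (!(targetFst > 0 && targetFst < 1))
    stop("targetFst must lie in (0, 1)")
  structure(list(nDemesTotal = nDemesTotal, nDemesSampled = nDemesSampled,
                 sampleIndividualsPerDeme = sampleIndividualsPerDeme,
                 nReplicates = nReplicates, targetFst = targetFst,
                 thetaRange = thetaRange, seed = as.integer(seed)),
            class = "islandNullConfig")
}

.meanIslandFst <- function(cfg, M, nReps, seed) {
  set.seed(seed)
  counts <- simIslandLoci(cfg$nDemesTotal, cfg$nDemesSampled,
                          2 * cfg$sampleIndividualsPerDeme, M, nReps,
                          cfg$thetaRange)
  f <- vapply(counts, function(m)
    if (ncol(m) < 2) NaN else wcFst(m), 0)
  mean(f[is.finite(f)])
}

#' Calibrate the island-model migration rate to a target mean FST
#'
#' Bisection on the scaled migration rate M = 4*Ne*m: mean simulated FST
#' over pilot replicates (common random numbers across candidate rates, so
#' the pilot mean is monotone in M) is driven to within \code{tol} of the
#' configured target.  The closed-form infinite-island relation
#' \eqn{F_{ST} = 1/(1 + M (d/(d-1))^2)} provides the starting bracket.
#'
#' @param cfg an [islandNullConfig()].
#' @param pilotReps replicates per bisection evaluation (default 2000).
#' @param tol absolute tolerance on the mean FST (default 0.01).
#' @param maxIter bisection iteration cap.
#' @return the calibrated M, with the achieved pilot mean FST as
#'   \code{attr(, "meanFst")}.
#' @export
calibrateMigration <- function(cfg, pilotReps = 2000, tol = 0.01,
                               maxIter = 50) {
  d <- cfg$nDemesTotal
  M0 <- (1 / cfg$targetFst - 1) / (d / (d - 1))^2
  lo <- M0 / 8; hi <- M0 * 8
  seed <- cfg$seed
  fLo <- .meanIslandFst(cfg, lo, pilotReps, seed)
  fHi <- .meanIslandFst(cfg, hi, pilotReps, seed)
  it <- 0
  while (fLo < cfg$targetFst && it < 8) {  # mean FST decreasing in M
    lo <- lo / 4; fLo <- .meanIslandFst(cfg, lo, pilotReps, seed); it <- it + 1
  }
  while (fHi > cfg$targetFst && it < 16) {
    hi <- hi * 4; fHi <- .meanIslandFst(cfg, hi, pilotReps, seed); it <- it + 1
  }
  if (fLo < cfg$targetFst || fHi > cfg$targetFst)
    stop("could not bracket the target FST")
  for (i in seq_len(maxIter)) {
    mid <- sqrt(lo * hi)
    fMid <- .meanIslandFst(cfg, mid, pilotReps, seed)
    if (abs(fMid - cfg$targetFst) < tol)
      return(structure(mid, meanFst = fMid))
    if (fMid > cfg$targetFst) lo <- mid else hi <- mid
  }
  stop("migration calibration did not converge in ", maxIter, " iterations")
}

#' Simulate the calibrated island-model null
#'
#' @param cfg an [islandNullConfig()].
#' @param M calibrated migration rate from [calibrateMigration()]; when
#'   missing, calibration is run first.
#' @param nReps number of replicates (defaults to \code{cfg$nReplicates}).
#' @return data.frame with one row per polymorphic replicate: \code{He}
#'   (total-sample expected heterozygosity) and \code{Fst} (Weir-Cockerham
#'   theta of the sampled counts).
#' @export
simulateIslandNull <- function(cfg, M = NULL, nReps = cfg$nReplicates) {
  if (is.null(M)) M <- calibrateMigration(cfg)
  set.seed(cfg$seed + 1L)
  counts <- simIslandLoci(cfg$nDemesTotal, cfg$nDemesSampled,
                          2 * cfg$sampleIndividualsPerDeme, as.numeric(M),
                          nReps, cfg$thetaRange)
  he <- vapply(counts, function(m) expectedHet(colSums(m) / sum(m)), 0)
  fst <- vapply(counts, function(m)
    if (ncol(m) < 2) NaN else wcFst(m), 0)
  ok <- is.finite(fst) & he > 0
  data.frame(He = he[ok], Fst = fst[ok])
}

#' Build the conditional FST-given-He null envelope
#'
#' Bins the null (He, FST) pairs into equal-count heterozygosity bins and
#' computes conditional FST quantiles per bin, smoothed along the He axis by
#' a 3-bin running median.
#'
#' @param pairs data.frame from [simulateIslandNull()] (>= 1000 rows).
#' @param bins number of equal-count He bins (default 25).
#' @param levels quantile levels (default 0.5%, 2.5%, median, 97.5%, 99.5%).
#' @param config optional configuration list stored with the envelope.
#' @return an [FstNullEnvelope-class].
#' @export
buildNullEnvelope <- function(pairs, bins = 25,
                              levels = c(0.005, 0.025, 0.5, 0.975, 0.995),
                              config = list()) {
  if (nrow(pairs) < 1000)
    stop("need >= 1000 null pairs for a stable envelope")
  edges <- unique(stats::quantile(pairs$He, probs = seq(0, 1, length.out = bins + 1)))
  if (length(edges) < 3) stop("degenerate He distribution")
  nb <- length(edges) - 1  # ties may merge bins
  bin <- pmin(pmax(findInterval(pairs$He, edges, rightmost.closed = TRUE), 1L), nb)
  q <- matrix(NA_real_, nb, length(levels),
              dimnames = list(NULL, sprintf("q%g", levels)))
  mid <- numeric(nb)
  for (b in seq_len(nb)) {
    sel <- bin == b
    q[b, ] <- stats::quantile(pairs$Fst[sel], probs = levels, names = FALSE)
    mid[b] <- stats::median(pairs$He[sel])
  }
  if (nb >= 3)
    for (j in seq_along(levels))
      q[, j] <- stats::runmed(q[, j], k = 3, endrule = "keep")
  q <- t(apply(q, 1, sort))  # enforce level monotonicity after smoothing
  colnames(q) <- sprintf("q%g", levels)
  new("FstNullEnvelope", binEdges = as.numeric(edges), binMid = mid,
      quantiles = q, pairs = cbind(pairs, bin = bin), config = config)
}

#' Classify empirical loci against the FST null envelope
#'
#' Each locus is placed in the He bin of its pooled-sample expected
#' heterozygosity; it is a high outlier when its FST exceeds the upper
#' envelope quantile there (97.5% for the 95% envelope, 99.5% for the 99%),
#' and a low outlier below the corresponding lower quantile.  The empirical
#' p-value is the fraction of null pairs in the locus's bin with FST at
#' least as large as observed.
#'
#' @param ds a [ClineDataset-class] (or a data.frame with He and Fst
#'   columns, one row per locus).
#' @param envelope an [FstNullEnvelope-class].
#' @return data.frame: locus, He, Fst, outlierHigh95, outlierHigh99,
#'   outlierLow95, empiricalP.
#' @export
classifyFstOutliers <- function(ds, envelope) {
  if (is(ds, "ClineDataset")) {
    loci <- ds@loci$id
    he <- vapply(seq_len(nLoci(ds)), function(j) {
      m <- ds@counts[[j]]
      expectedHet(colSums(m) / sum(m))
    }, 0)
    fst <- vapply(seq_len(nLoci(ds)), function(j) wcFst(ds@counts[[j]]), 0)
  } else {
    loci <- if (is.null(ds$locus)) as.character(seq_len(nrow(ds))) else ds$locus
    he <- ds$He; fst <- ds$Fst
  }
  edges <- envelope@binEdges
  nb <- nrow(envelope@quantiles)
  bin <- findInterval(he, edges, rightmost.closed = TRUE)
  outside <- bin < 1 | bin > nb
  if (any(outside, na.rm = TRUE))
    warning(sum(outside, na.rm = TRUE),
            " loci outside the envelope He support: nearest bin used")
  bin <- pmin(pmax(bin, 1L), nb)
  q <- envelope@quantiles
  np <- envelope@pairs
  emp <- vapply(seq_along(he), function(i) {
    if (!is.finite(fst[i])) return(NA_real_)
    sel <- np$bin == bin[i]
    mean(np$Fst[sel] >= fst[i])
  }, 0)
  data.frame(locus = loci, He = he, Fst = fst,
             outlierHigh95 = fst > q[bin, "q0.975"],
             outlierHigh99 = fst > q[bin, "q0.995"],
             outlierLow95 = fst < q[bin, "q0.025"],
             empiricalP = emp, stringsAsFactors = FALSE)
}

#' Plot the FST-outlier panel
#'
#' Scatter of per-locus (He, FST) over the null envelope: conditional median
#' dotted, 99% envelope solid; loci above the 95% envelope in red.
#'
#' @param classified data.frame from [classifyFstOutliers()].
#' @param envelope an [FstNullEnvelope-class].
#' @param file optional PDF path.
#' @return invisibly, \code{classified}.
#' @export
plotFstOutliers <- function(classified, envelope, file = NULL) {
  if (!is.null(file)) {
    grDevices::pdf(file, width = 6, height = 5)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(classified$He, classified$Fst,
                 col = ifelse(classified$outlierHigh95, "red", "grey50"),
                 pch = 16, xlab = "expected heterozygosity",
                 ylab = expression(F[ST]), main = "FST outlier scan")
  mid <- envelope@binMid
  q <- envelope@quantiles
  graphics::lines(mid, q[, "q0.5"], lty = 3)
  graphics::lines(mid, q[, "q0.005"], col = "black")
  graphics::lines(mid, q[, "q0.995"], col = "black")
  invisible(classified)
}
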