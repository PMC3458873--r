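#' Expected heterozygosity of an allele-frequency vector
#'
#' Gene diversity \eqn{H_e = 1 - \sum_a p_a^2}.
#'
#' @param freqs numeric vector of allele frequencies (sums to 1).
#' @return numeric in [0, 1].
#' @examples
#' expectedHet(c(0.5, 0.5))   # 0.5
#' expectedHet(rep(0.25, 4))  # 0.75
#' @export
expectedHet <- function(freqs) {
  if (abs(sum(freqs) - 1) > 1e-6)
    stop("frequencies must sum to 1")
  1 - sum(freqs^2)
}

#' Weir-Cockerham multi-allelic FST from allele counts
#'
#' The variance-components theta estimator applied to per-site allele counts
#' (gene copies treated as the sampling unit, i.e. the haploid form of the
#' estimator, appropriate for allele-frequency compilations analyzed under
#' HWE).  Per allele, with r assayed sites of sizes \eqn{n_i}, frequencies
#' \eqn{p_i}, weighted mean \eqn{\bar p} and among-site variance
#' \eqn{s^2 = \sum_i n_i (p_i - \bar p)^2 / ((r-1)\bar n)}:
#' \deqn{a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}
#'   \left(\bar p(1-\bar p) - \frac{r-1}{r} s^2\right)\right]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) -
#'   \frac{r-1}{r} s^2\right]}
#' and \eqn{\theta = \sum_a a / \sum_a (a + b)} over alleles.  The estimator
#' can be slightly negative; it equals 1 when sites are fixed for disjoint
#' alleles.
#'
#' @param counts sites x alleles count matrix; all-zero rows (unassayed
#'   sites) are dropped.
#' @return theta, or NaN when all sites are monomorphic for the same allele
#'   (no variance components defined).
#' @export
wcFst <- function(counts) {
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  r <- nrow(counts)
  if (r < 2) stop("need >= 2 assayed sites")
  n <- rowSums(counts)
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  p <- counts / n
  pbar <- colSums(counts) / sum(n)
  if (sum(pbar > 0) < 2) return(NaN)  # pooled sample monomorphic
  aSum <- 0
  abSum <- 0
  for (al in seq_along(pbar)) {
    s2 <- sum(n * (p[, al] - pbar[al])^2) / ((r - 1) * nbar)
    inner <- pbar[al] * (1 - pbar[al]) - (r - 1) / r * s2
    if (nbar > 1) {
      a <- (nbar / nc) * (s2 - inner / (nbar - 1))
      b <- (nbar / (nbar - 1)) * inner
    } else {
      a <- (nbar / nc) * s2
      b <- inner
    }
    aSum <- aSum + a
    abSum <- abSum + a + b
  }
  if (abSum == 0) return(NaN)
  aSum / abSum
}

#' Pairwise FST distance matrix for one locus
#'
#' Applies [wcFst()] to every pair of sites assayed for the locus; negative
#' estimates are clamped to 0 so the result can serve as a distance matrix
#' (e.g. for [mantelTest()]).
#'
#' @param ds a [ClineDataset-class].
#' @param locus locus id or index.
#' @return symmetric matrix (assayed sites only) with zero diagonal.
#' @export
pairwiseFst <- function(ds, locus) {
  m <- alleleCounts(ds, locus)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  r <- nrow(m)
  if (r < 3) stop("Mantel needs >= 3 assayed sites")
  out <- matrix(0, r, r, dimnames = list(rownames(m), rownames(m)))
  if (ncol(m) == 2) {
    # biallelic fast path: both alleles contribute identical variance
    # components, so theta reduces to the single-allele a/(a+b);
    # vectorized over all site pairs
    lt <- which(lower.tri(out))
    i <- row(out)[lt]; j <- col(out)[lt]
    n1 <- rowSums(m)[i]; n2 <- rowSums(m)[j]
    x1 <- m[i, 1]; x2 <- m[j, 1]
    S <- n1 + n2
    nbar <- S / 2
    nc <- S - (n1^2 + n2^2) / S
    pbar <- (x1 + x2) / S
    s2 <- (n1 * (x1 / n1 - pbar)^2 + n2 * (x2 / n2 - pbar)^2) / nbar
    inner <- pbar * (1 - pbar) - s2 / 2
    a <- (nbar / nc) * (s2 - inner / (nbar - 1))
    bb <- (nbar / (nbar - 1)) * inner
    f <- a / (a + bb)
    f[!is.finite(f)] <- 0
    f <- pmax(f, 0)
    out[lt] <- f
    out <- out + t(out)
    return(out)
  }
  for (i in seq_len(r - 1)) {
    for (j in (i + 1):r) {
      f <- wcFst(m[c(i, j), , drop = FALSE])
      f <- if (is.nan(f)) 0 else max(f, 0)
      out[i, j] <- out[j, i] <- f
    }
  }
  out
}

#' Geographic distance matrix from latitudes
#'
#' Absolute latitude difference in degrees: along an approximately
#' north-south coastal transect the geography is effectively
#' one-dimensional, so latitude separation is the natural distance.
#'
#' @param lats named numeric vector of latitudes.
#' @return symmetric distance matrix in degrees.
#' @export
latDistance <- function(lats) {
  out <- abs(outer(lats, lats, "-"))
  dimnames(out) <- list(names(lats), names(lats))
  out
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the lower triangles with a one-sided permutation
#' p-value: rows and columns of \code{B} are permuted jointly and
#' \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (nPerm + 1)}.
#'
#' @param A,B symmetric distance matrices over the same sites.
#' @param nPerm number of permutations (default 999; must be >= 99).
#' @param seed integer seed.
#' @return list with elements \code{r} and \code{p}.  A constant matrix
#'   (zero variance in a triangle) yields \code{r = NaN}, \code{p = 1}.
#' @export
mantelTest <- function(A, B, nPerm = 999, seed = NULL) {
  stopifnot(nrow(A) == ncol(A), all(dim(A) == dim(B)), nPerm >= 99)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(A)
  lt <- which(lower.tri(A))
  li <- row(A)[lt]
  lj <- col(A)[lt]
  a <- A[lt]
  b <- B[lt]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NaN, p = 1))
  rObs <- stats::cor(a, b)
  # joint row/column permutation maps the triangle onto the same multiset
  # of pair values, so the permuted mean and sd are those of b; only the
  # cross-product with the centered a changes
  ac <- a - mean(a)
  denom <- sqrt(sum(ac^2)) * sqrt(sum((b - mean(b))^2))
  hits <- 0L
  for (k in seq_len(nPerm)) {
    ix <- sample.int(n)
    rp <- sum(ac * B[cbind(ix[li], ix[lj])]) / denom
    if (rp >= rObs) hits <- hits + 1L
  }
  list(r = rObs, p = (1 + hits) / (nPerm + 1))
}
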