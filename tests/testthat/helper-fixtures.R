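# Shared fixture builders: every fixture is constructed in code, nothing on
# disk beyond what a test writes to tempdir().

# two-plateau dataset with exact counts
makeTinyDataset <- function() {
  sites <- data.frame(id = c("s1", "s2"), latitude = c(33, 43))
  cnt <- matrix(c(8L, 2L, 2L, 8L), 2,
                dimnames = list(c("s1", "s2"), c("1", "2")))
  ClineDataset(sites, "L1", list(cnt))
}

# noise-free broken-stick counts at many sites
makeBrokenStickCounts <- function(params = c(38, 0.1, 42, 0.9),
                                  lats = seq(30, 45, length.out = 20),
                                  n = 400) {
  p <- brokenStickPredict(params, lats)
  x <- round(p * n)
  list(lats = lats, x = x, n = rep(n, length(lats)))
}

# random dataset for round-trip properties
makeRandomDataset <- function(nSites = 6, nLoci = 4, seed = 1) {
  set.seed(seed)
  sites <- data.frame(id = sprintf("s%d", seq_len(nSites)),
                      latitude = sort(runif(nSites, 30, 45)))
  counts <- lapply(seq_len(nLoci), function(j) {
    k <- sample(2:4, 1)
    m <- matrix(rpois(nSites * k, 8), nSites, k,
                dimnames = list(sites$id, as.character(seq_len(k))))
    if (j == nLoci) m[1, ] <- 0L  # one unassayed site
    storage.mode(m) <- "integer"
    m
  })
  loci <- data.frame(id = sprintf("L%d", seq_len(nLoci)),
                     markerClass = sample(c("SNP", "allozyme"), nLoci,
                                          replace = TRUE))
  ClineDataset(sites, loci, counts)
}

# independently coded scalar Weir-Cockerham theta (textbook variance
# components, haploid/allele-count form) used as the oracle for wcFst
oracleWcFst <- function(counts) {
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  r <- nrow(counts)
  n <- rowSums(counts)
  nbar <- sum(n) / r
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  aTot <- 0; abTot <- 0
  for (al in seq_len(ncol(counts))) {
    p <- counts[, al] / n
    pbar <- sum(n * p) / sum(n)
    s2 <- 0
    for (i in seq_len(r)) s2 <- s2 + n[i] * (p[i] - pbar)^2
    s2 <- s2 / ((r - 1) * nbar)
    inner <- pbar * (1 - pbar) - (r - 1) / r * s2
    a <- (nbar / nc) * (s2 - inner / (nbar - 1))
    b <- (nbar / (nbar - 1)) * inner
    aTot <- aTot + a
    abTot <- abTot + a + b
  }
  aTot / abTot
}

# ratio-of-sums (pooled over loci) Weir-Cockerham theta: the multi-locus
# estimator whose expectation matches the coalescent-time FST
pooledWcFst <- function(countsList) {
  num <- den <- 0
  for (m in countsList) {
    if (ncol(m) < 2) next
    r <- nrow(m); n <- rowSums(m); nbar <- mean(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    p <- m / n; pbar <- colSums(m) / sum(n)
    for (al in seq_along(pbar)) {
      s2 <- sum(n * (p[, al] - pbar[al])^2) / ((r - 1) * nbar)
      inner <- pbar[al] * (1 - pbar[al]) - (r - 1) / r * s2
      a <- (nbar / nc) * (s2 - inner / (nbar - 1))
      b <- (nbar / (nbar - 1)) * inner
      num <- num + a; den <- den + a + b
    }
  }
  num / den
}
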