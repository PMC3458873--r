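#' Synthesize diploid genotypes under Hardy-Weinberg equilibrium
#'
#' For every assayed (site, locus) combination, draws \code{nIndividuals}
#' diploid genotypes by sampling two alleles independently from the site's
#' allele-frequency vector.  This reconstructs individual-level data from
#' published frequency tables so that frequency-only compilations can enter
#' genotype-based analyses (e.g. GenePop export for FST-outlier software).
#' Unassayed combinations are emitted as missing genotypes.
#'
#' @param ds a [ClineDataset-class].
#' @param nIndividuals diploid individuals per site; default 20.
#' @param seed integer seed for reproducibility.
#' @return a [GenotypeTable-class] with \code{nIndividuals} individuals per
#'   site (sites in dataset order).
#' @export
synthesizeGenotypes <- function(ds, nIndividuals = 20, seed = NULL) {
  stopifnot(nIndividuals >= 1)
  if (!is.null(seed)) set.seed(seed)
  nS <- nSites(ds)
  nL <- nLoci(ds)
  indivSite <- rep(ds@sites$id, each = nIndividuals)
  nInd <- length(indivSite)
  alleleIds <- lapply(ds@counts, colnames)
  genotypes <- vector("list", nL)
  for (j in seq_len(nL)) {
    m <- ds@counts[[j]]
    n <- rowSums(m)
    g <- matrix(0L, nInd, 2)
    for (i in seq_len(nS)) {
      if (n[i] == 0) next
      rows <- (i - 1L) * nIndividuals + seq_len(nIndividuals)
      p <- m[i, ] / n[i]
      g[rows, 1] <- sample.int(ncol(m), nIndividuals, replace = TRUE, prob = p)
      g[rows, 2] <- sample.int(ncol(m), nIndividuals, replace = TRUE, prob = p)
    }
    genotypes[[j]] <- g
  }
  new("GenotypeTable",
      individualSite = as.character(indivSite),
      loci = ds@loci[, "id", drop = FALSE],
      alleleIds = alleleIds,
      genotypes = genotypes)
}

#' Summarize a GenotypeTable back to per-site allele counts
#'
#' @param gt a [GenotypeTable-class].
#' @return list, per locus a sites x alleles integer count matrix (missing
#'   alleles excluded from the counts).
#' @export
genotypeAlleleCounts <- function(gt) {
  sites <- unique(gt@individualSite)
  lapply(seq_len(nrow(gt@loci)), function(j) {
    k <- length(gt@alleleIds[[j]])
    m <- matrix(0L, length(sites), k,
                dimnames = list(sites, gt@alleleIds[[j]]))
    g <- gt@genotypes[[j]]
    for (s in seq_along(sites)) {
      rows <- gt@individualSite == sites[s]
      a <- c(g[rows, 1], g[rows, 2])
      a <- a[a > 0]
      if (length(a)) {
        tab <- tabulate(a, nbins = k)
        m[s, ] <- tab
      }
    }
    m
  })
}
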