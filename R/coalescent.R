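## R-side wrappers around the compiled structured-coalescent engine.
## Time is in generations throughout; deme sizes are diploid Ne.

#' Simulate finite-island coalescent loci with infinite-alleles mutation
#'
#' One genealogy per replicate for \code{nSampled} demes x
#' \code{copiesPerDeme} gene copies under the d-island model, with
#' infinite-alleles mutations dropped on the branches.  The per-replicate
#' scaled mutation rate theta (= 4 * total Ne * mu) is drawn log-uniformly
#' from \code{thetaRange} so the null spans the heterozygosity axis.
#'
#' @param nDemes total demes d.
#' @param nSampled demes actually sampled.
#' @param copiesPerDeme gene copies sampled per sampled deme.
#' @param M scaled island migration rate 4*Ne*m per deme.
#' @param nReps replicates.
#' @param thetaRange range of total-population scaled mutation rates.
#' @return list of per-replicate allele count matrices (sampled demes x
#'   alleles).
#' @keywords internal
simIslandLoci <- function(nDemes, nSampled, copiesPerDeme, M, nReps,
                          thetaRange = c(0.01, 10)) {
  ne <- 1000  # arbitrary internal scale; only M and theta matter
  sampleSizes <- c(rep(copiesPerDeme, nSampled), rep(0L, nDemes - nSampled))
  theta <- exp(stats::runif(nReps, log(thetaRange[1]), log(thetaRange[2])))
  mu <- theta / (4 * ne * nDemes)
  res <- .simStructuredCoalescent(
    sampleSizes = as.integer(sampleSizes),
    epochEnds = Inf,
    neMat = matrix(ne, 1, nDemes),
    migType = 1L,
    migRate = M / (4 * ne),
    demeMap = matrix(seq_len(nDemes), 1, nDemes, byrow = FALSE),
    nReps = as.integer(nReps),
    mutModel = 2L,
    mu = mu)
  res$counts
}

#' Simulate the secondary-contact demography for one batch of loci
#'
#' Backwards in time: stepping-stone chain of \code{2 * demesPerSide} demes
#' (size \code{nePerDeme}) until \code{tExpand}; two isolated relicts (each
#' the pooled size of its side) until \code{tSplit}; a single ancestor (the
#' pooled total) before that.  Total Ne is identical in every epoch.  One
#' segregating site per locus is placed uniformly on each genealogy.
#'
#' @param demesPerSide demes in each half of the chain.
#' @param nePerDeme diploid deme size in the present epoch.
#' @param fourNm scaled stepping-stone exchange 4*Ne*m between neighbours.
#' @param tExpand,tSplit epoch boundaries in generations.
#' @param copiesPerDeme gene copies sampled per deme.
#' @param nLoci replicates (loci).
#' @return integer matrix nLoci x nDemes of derived-allele counts.
#' @keywords internal
simSecondaryContactLoci <- function(demesPerSide, nePerDeme, fourNm,
                                    tExpand, tSplit, copiesPerDeme, nLoci) {
  D <- 2L * demesPerSide
  relictNe <- demesPerSide * nePerDeme
  ancNe <- 2 * relictNe
  neMat <- rbind(rep(nePerDeme, D),
                 c(relictNe, relictNe, rep(0, D - 2)),
                 c(ancNe, rep(0, D - 1)))
  demeMap <- rbind(seq_len(D),
                   c(rep(1L, demesPerSide), rep(2L, demesPerSide)),
                   rep(1L, D))
  res <- .simStructuredCoalescent(
    sampleSizes = rep(as.integer(copiesPerDeme), D),
    epochEnds = c(tExpand, tSplit, Inf),
    neMat = neMat,
    migType = c(2L, 0L, 0L),
    migRate = c(fourNm / (4 * nePerDeme), 0, 0),
    demeMap = demeMap,
    nReps = as.integer(nLoci),
    mutModel = 1L,
    mu = 0)
  res$derived
}
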