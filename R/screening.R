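#' Screen one locus for clinality and Co-Co eligibility
#'
#' Runs the full per-locus pipeline: focal-allele selection, horizontal and
#' twice-broken-stick fits, the clinality LRT, and a Mantel test of per-locus
#' pairwise FST against latitudinal distance.  A locus is \emph{clinal} when
#' the LRT p-value is below \code{alpha}; it is \emph{Co-Co eligible} when it
#' is clinal \emph{and} shows significant isolation by distance (Mantel
#' p < \code{alpha}).
#'
#' @param ds a [ClineDataset-class].
#' @param locus locus id or index.
#' @param seed integer seed (controls the Mantel permutations).
#' @param alpha significance level for both criteria (default 0.05).
#' @param nPerm Mantel permutations (default 999).
#' @param mantel run the Mantel criterion (default TRUE; set FALSE for
#'   LRT-only screens where Co-Co eligibility is not needed).
#' @param northOf,southOf region thresholds for focal-allele selection.
#' @return one-row data.frame: locus, focalAllele, lrtStat, lrtP, mantelR,
#'   mantelP, midpoint, slope, isClinal, cocoEligible, flags.
#' @export
screenLocus <- function(ds, locus, seed = NULL, alpha = 0.05, nPerm = 999,
                        mantel = TRUE, northOf = 42, southOf = 34) {
  j <- .locusIndex(ds, locus)
  m <- ds@counts[[j]]
  lats <- ds@sites$latitude
  n <- rowSums(m)
  focal <- tryCatch(
    selectFocalAllele(ds, j, northOf = northOf, southOf = southOf),
    error = function(e) colnames(m)[1])
  x <- m[, focal]

  fh <- fitHorizontal(lats, x, n)
  fb <- fitBrokenStick(lats, x, n)
  if (!isTRUE(fb$converged)) {
    return(data.frame(locus = ds@loci$id[j], focalAllele = focal,
                      lrtStat = NA_real_, lrtP = NA_real_,
                      mantelR = NA_real_, mantelP = NA_real_,
                      midpoint = NA_real_, slope = NA_real_,
                      isClinal = FALSE, cocoEligible = FALSE,
                      flags = "fit-failed", stringsAsFactors = FALSE))
  }
  lrt <- lrtClinal(fb, fh)

  mr <- NA_real_; mp <- NA_real_
  if (mantel) {
    gm <- tryCatch(pairwiseFst(ds, j), error = function(e) NULL)
    if (!is.null(gm)) {
      lat2 <- latDistance(stats::setNames(lats, ds@sites$id))
      lat2 <- lat2[rownames(gm), rownames(gm)]
      mt <- mantelTest(gm, lat2, nPerm = nPerm, seed = seed)
      mr <- mt$r; mp <- mt$p
    }
  }
  isClinal <- isTRUE(lrt$p < alpha)
  data.frame(locus = ds@loci$id[j], focalAllele = focal,
             lrtStat = lrt$stat, lrtP = lrt$p,
             mantelR = mr, mantelP = mp,
             midpoint = fb$midpoint, slope = fb$slope,
             isClinal = isClinal,
             cocoEligible = isClinal && mantel && isTRUE(mp < alpha),
             flags = paste(fb$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Screen every locus of a dataset
#'
#' @inheritParams screenLocus
#' @param verbose print progress every 50 loci.
#' @return data.frame with one [screenLocus()] row per locus.
#' @export
screenDataset <- function(ds, seed = NULL, alpha = 0.05, nPerm = 999,
                          mantel = TRUE, northOf = 42, southOf = 34,
                          verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nLoci(ds))
  rows <- lapply(seq_len(nLoci(ds)), function(j) {
    if (verbose && j %% 50 == 0) message("screened ", j, "/", nLoci(ds))
    screenLocus(ds, j, seed = seeds[j], alpha = alpha, nPerm = nPerm,
                mantel = mantel, northOf = northOf, southOf = southOf)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Marker-class by clinality contingency table with Fisher's exact test
#'
#' Tabulates clinal vs non-clinal loci by marker class, collapses the table
#' to SNP vs non-SNP, and returns the two-sided Fisher exact p-value of the
#' resulting 2x2 table.
#'
#' @param results data.frame from [screenDataset()] (needs \code{isClinal}).
#' @param markerClasses character vector of marker classes, parallel to the
#'   rows of \code{results}; defaults to the \code{markerClass} column if
#'   present.
#' @return list with \code{table} (class x clinal/notClinal counts),
#'   \code{collapsed} (2x2 SNP vs non-SNP) and \code{fisherP}.
#' @export
clinalContingency <- function(results, markerClasses = results$markerClass) {
  if (is.null(markerClasses))
    stop("marker classes required (none found in results)")
  cls <- as.character(markerClasses)
  empty <- setdiff(unique(cls), cls[!is.na(results$isClinal)])
  if (length(empty))
    warning("classes with zero usable loci omitted: ",
            paste(empty, collapse = ", "))
  if (length(unique(cls)) < 2)
    stop("need >= 2 marker classes")
  tab <- table(class = cls,
               clinal = factor(ifelse(results$isClinal, "clinal", "notClinal"),
                               levels = c("clinal", "notClinal")))
  snp <- cls == "SNP"
  collapsed <- rbind(
    nonSNP = c(sum(results$isClinal[!snp]), sum(!results$isClinal[!snp])),
    SNP = c(sum(results$isClinal[snp]), sum(!results$isClinal[snp])))
  colnames(collapsed) <- c("clinal", "notClinal")
  p <- stats::fisher.test(collapsed)$p.value
  list(table = tab, collapsed = collapsed, fisherP = p)
}
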