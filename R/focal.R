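#' Assign sites to northern, central and southern regions
#'
#' Threshold assignment along the transect: north of 42 degrees N is
#' "north", south of 34 degrees N is "south", everything between is
#' "central".  The focal-allele choice contrasts the two range ends and
#' ignores the central (clinal) portion.
#'
#' @param ds a [ClineDataset-class], or a numeric vector of latitudes.
#' @param northOf latitude above which sites are northern (default 42).
#' @param southOf latitude below which sites are southern (default 34).
#' @return character vector ("north"/"central"/"south"), named by site id
#'   when available.
#' @export
assignRegions <- function(ds, northOf = 42, southOf = 34) {
  lats <- if (is(ds, "ClineDataset")) latitudes(ds) else ds
  out <- ifelse(lats > northOf, "north",
                ifelse(lats < southOf, "south", "central"))
  out
}

#' Select the focal allele of a locus
#'
#' For a multi-allelic locus, each allele is binarized (allele vs rest) and
#' its Weir-Cockerham theta computed across the northern plus southern sites
#' only; the allele with the largest such north-south differentiation is the
#' focal allele whose frequency is modeled against latitude downstream.  For
#' biallelic loci the two alleles are exact complements, so the first allele
#' in the locus's allele order is returned.  Ties are broken by allele order.
#'
#' @param ds a [ClineDataset-class].
#' @param locus locus id or index.
#' @param northOf,southOf region thresholds, see [assignRegions()].
#' @return the focal allele id (character).
#' @export
selectFocalAllele <- function(ds, locus, northOf = 42, southOf = 34) {
  m <- alleleCounts(ds, locus)
  reg <- assignRegions(ds, northOf, southOf)
  n <- rowSums(m)
  keep <- (reg != "central") & n > 0
  if (!any(reg[keep] == "north") || !any(reg[keep] == "south"))
    stop("locus has no assayed northern or no southern sites; ",
         "designate regions manually via northOf/southOf")
  sub <- m[keep, , drop = FALSE]
  if (ncol(m) == 2) return(colnames(m)[1])
  theta <- vapply(seq_len(ncol(sub)), function(a) {
    bin <- cbind(sub[, a], rowSums(sub) - sub[, a])
    f <- wcFst(bin)
    if (is.nan(f)) -Inf else f
  }, 0)
  colnames(m)[which.max(theta)]
}
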