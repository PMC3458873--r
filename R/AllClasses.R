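#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib clineCoCo, .registration = TRUE
NULL

#' ClineDataset: multi-locus, multi-population allele counts along a transect
#'
#' The universal container of the package: a set of population sites with
#' latitudes, a set of loci (each with an ordered allele list), and per
#' (site, locus) a vector of allele counts summing to the number of gene
#' copies sampled there.  A row sum of zero encodes "not assayed"; counts,
#' not frequencies, are the canonical storage.
#'
#' @slot sites data.frame with columns \code{id}, \code{latitude} and
#'   optionally \code{longitude}; one row per population site.
#' @slot loci data.frame with columns \code{id} and \code{markerClass}
#'   (one of \code{"mtDNA"}, \code{"allozyme"}, \code{"microsatellite"},
#'   \code{"SNP"}, \code{"simulated"}).
#' @slot counts list, one element per locus, each an integer matrix of
#'   dimension nSites x nAlleles with sites as rownames and allele ids as
#'   colnames.
#' @slot provenance free-text description of where the data came from.
#'
#' @seealso [ClineDataset()] for the constructor,
#'   [readFrequencyTable()] for file input.
#' @export
setClass("ClineDataset",
  representation(sites = "data.frame",
                 loci = "data.frame",
                 counts = "list",
                 provenance = "character"),
  prototype(provenance = ""))

validClineDataset <- function(object) {
  msg <- character()
  s <- object@sites
  l <- object@loci
  if (!all(c("id", "latitude") %in% names(s)))
    msg <- c(msg, "sites must have columns 'id' and 'latitude'")
  else {
    if (anyDuplicated(s$id)) msg <- c(msg, "site ids must be unique")
    if (!all(is.finite(s$latitude))) msg <- c(msg, "latitudes must be finite")
  }
  if (!all(c("id", "markerClass") %in% names(l)))
    msg <- c(msg, "loci must have columns 'id' and 'markerClass'")
  else if (anyDuplicated(l$id)) msg <- c(msg, "locus ids must be unique")
  if (length(object@counts) != nrow(l))
    msg <- c(msg, "counts must have one element per locus")
  for (j in seq_along(object@counts)) {
    m <- object@counts[[j]]
    if (!is.matrix(m) || nrow(m) != nrow(s)) {
      msg <- c(msg, sprintf("counts[[%d]] must be an nSites-row matrix", j))
      next
    }
    if (ncol(m) < 2)
      msg <- c(msg, sprintf("locus %d must have >= 2 alleles", j))
    if (any(m < 0) || any(m != round(m)))
      msg <- c(msg, sprintf("counts[[%d]] must be non-negative integers", j))
  }
  if (length(msg)) msg else TRUE
}
setValidity("ClineDataset", validClineDataset)

#' Construct a ClineDataset
#'
#' @param sites data.frame with columns \code{id}, \code{latitude} (decimal
#'   degrees N) and optionally \code{longitude}.
#' @param loci data.frame with columns \code{id} and \code{markerClass};
#'   a plain character vector of ids is also accepted (class "SNP" assumed).
#' @param counts list of nSites x k integer count matrices, one per locus.
#'   Row sums are the per-site sampled allele numbers; all-zero rows mean
#'   the site was not assayed for that locus.
#' @param provenance free-text provenance string.
#' @return A validated [ClineDataset-class] object.
#' @examples
#' sites <- data.frame(id = c("a", "b"), latitude = c(35, 43))
#' cnt <- matrix(c(8L, 2L, 2L, 8L), 2, dimnames = list(c("a", "b"), c("1", "2")))
#' ds <- ClineDataset(sites, "L1", list(cnt))
#' alleleFreqs(ds, "L1")
#' @export
ClineDataset <- function(sites, loci, counts, provenance = "") {
  sites <- as.data.frame(sites)
  if (is.character(loci))
    loci <- data.frame(id = loci, markerClass = "SNP",
                       stringsAsFactors = FALSE)
  loci <- as.data.frame(loci)
  if (is.null(loci$markerClass)) loci$markerClass <- "SNP"
  counts <- lapply(counts, function(m) {
    storage.mode(m) <- "integer"
    if (is.null(rownames(m))) rownames(m) <- as.character(sites$id)
    if (is.null(colnames(m))) colnames(m) <- as.character(seq_len(ncol(m)))
    m
  })
  names(counts) <- loci$id
  new("ClineDataset", sites = sites, loci = loci, counts = counts,
      provenance = provenance)
}

#' GenotypeTable: individual-level diploid genotypes
#'
#' Holds unordered diploid genotypes for a set of individuals nested in
#' sites, at a shared set of loci.  Genotypes are stored as allele indices
#' into each locus's allele list; 0 denotes a missing allele.
#'
#' @slot individualSite character vector, the site id of each individual
#'   (individuals are rows, stacked by site).
#' @slot loci data.frame with column \code{id}.
#' @slot alleleIds list of character vectors, the ordered allele ids per locus.
#' @slot genotypes list, per locus an nIndividuals x 2 integer matrix of
#'   allele indices (0 = missing).
#' @export
setClass("GenotypeTable",
  representation(individualSite = "character",
                 loci = "data.frame",
                 alleleIds = "list",
                 genotypes = "list"))

setValidity("GenotypeTable", function(object) {
  msg <- character()
  nInd <- length(object@individualSite)
  if (length(object@genotypes) != nrow(object@loci))
    msg <- c(msg, "one genotype matrix per locus required")
  for (j in seq_along(object@genotypes)) {
    g <- object@genotypes[[j]]
    if (!is.matrix(g) || nrow(g) != nInd || ncol(g) != 2) {
      msg <- c(msg, sprintf("genotypes[[%d]] must be nInd x 2", j))
      next
    }
    k <- length(object@alleleIds[[j]])
    if (any(g < 0) || any(g > k))
      msg <- c(msg, sprintf("genotypes[[%d]] contains allele index outside 0..k", j))
  }
  if (length(msg)) msg else TRUE
})

#' FstNullEnvelope: conditional FST-given-heterozygosity null envelope
#'
#' Quantile curves of the island-model coalescent null distribution of
#' Weir-Cockerham FST conditional on total-sample expected heterozygosity,
#' binned into equal-count heterozygosity bins and smoothed with a running
#' median.  Used by [classifyFstOutliers()].
#'
#' @slot binEdges numeric vector of heterozygosity bin edges (length bins+1).
#' @slot binMid numeric, midpoint heterozygosity per bin.
#' @slot quantiles matrix bins x levels of conditional FST quantiles, with
#'   colnames like "q0.025"; includes the conditional median as "q0.5".
#' @slot pairs data.frame of the null (He, Fst) draws with their bin index.
#' @slot config list describing the simulation configuration.
#' @export
setClass("FstNullEnvelope",
  representation(binEdges = "numeric",
                 binMid = "numeric",
                 quantiles = "matrix",
                 pairs = "data.frame",
                 config = "list"))

setValidity("FstNullEnvelope", function(object) {
  q <- object@quantiles
  if (length(object@binMid) != nrow(q))
    return("one quantile row per bin required")
  lev <- as.numeric(sub("^q", "", colnames(q)))
  ord <- order(lev)
  bad <- apply(q[, ord, drop = FALSE], 1L, is.unsorted, na.rm = TRUE)
  if (any(bad)) return("quantiles must be monotone within every bin")
  TRUE
})

#' CoCoDensity: 2-D kernel density over (midpoint, log|slope|) space
#'
#' @slot x,y grid coordinates (midpoint degrees; natural-log absolute slope).
#' @slot z density matrix (length(x) x length(y)); integrates to ~1.
#' @slot H 2x2 symmetric positive-definite bandwidth matrix.
#' @slot points the data the density was estimated from (locus, midpoint,
#'   logAbsSlope).
#' @slot method bandwidth selector actually used ("cv" or "plugin").
#' @export
setClass("CoCoDensity",
  representation(x = "numeric", y = "numeric", z = "matrix",
                 H = "matrix", points = "data.frame", method = "character"))

setValidity("CoCoDensity", function(object) {
  msg <- character()
  if (any(object@z < 0)) msg <- c(msg, "density must be non-negative")
  H <- object@H
  if (!isTRUE(all.equal(H, t(H))) || any(eigen(H, only.values = TRUE)$values <= 0))
    msg <- c(msg, "bandwidth matrix must be symmetric positive-definite")
  mass <- sum(object@z) * diff(object@x[1:2]) * diff(object@y[1:2])
  if (abs(mass - 1) > 1e-3)
    msg <- c(msg, sprintf("grid mass %.4f differs from 1 by more than 1e-3", mass))
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClineDataset", function(object) {
  cat("ClineDataset:", nrow(object@sites), "sites x",
      nrow(object@loci), "loci\n")
  cat("  latitude range:",
      sprintf("%.2f..%.2f", min(object@sites$latitude),
              max(object@sites$latitude)), "\n")
  cat("  marker classes:",
      paste(sprintf("%s (%d)", names(table(object@loci$markerClass)),
                    table(object@loci$markerClass)), collapse = ", "), "\n")
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable:", length(object@individualSite), "individuals in",
      length(unique(object@individualSite)), "sites x",
      nrow(object@loci), "loci\n")
})

setMethod("show", "FstNullEnvelope", function(object) {
  cat("FstNullEnvelope:", nrow(object@quantiles), "heterozygosity bins,",
      nrow(object@pairs), "null (He, FST) pairs\n")
  cat("  levels:", paste(colnames(object@quantiles), collapse = " "), "\n")
})

setMethod("show", "CoCoDensity", function(object) {
  cat("CoCoDensity:", nrow(object@points), "loci on a",
      length(object@x), "x", length(object@y), "grid (bandwidth:",
      object@method, ")\n")
})
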