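#' Accessors for ClineDataset objects
#'
#' @param x a [ClineDataset-class].
#' @param locus locus id (character) or index.
#' @name accessors
NULL

#' @describeIn accessors number of population sites.
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))
#' @describeIn accessors number of loci.
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @describeIn accessors site table (id, latitude, ...).
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))
#' @describeIn accessors locus table (id, markerClass).
#' @export
setGeneric("lociInfo", function(x) standardGeneric("lociInfo"))
#' @describeIn accessors site latitudes, named by site id.
#' @export
setGeneric("latitudes", function(x) standardGeneric("latitudes"))
#' @describeIn accessors allele count matrix for one locus (sites x alleles).
#' @export
setGeneric("alleleCounts", function(x, locus) standardGeneric("alleleCounts"))
#' @describeIn accessors allele frequency matrix for one locus; rows of
#'   unassayed sites are NA.
#' @export
setGeneric("alleleFreqs", function(x, locus) standardGeneric("alleleFreqs"))
#' @describeIn accessors per-site sampled allele numbers for one locus
#'   (0 = not assayed).
#' @export
setGeneric("sampleSizes", function(x, locus) standardGeneric("sampleSizes"))

setMethod("nSites", "ClineDataset", function(x) nrow(x@sites))
setMethod("nLoci", "ClineDataset", function(x) nrow(x@loci))
setMethod("siteInfo", "ClineDataset", function(x) x@sites)
setMethod("lociInfo", "ClineDataset", function(x) x@loci)
setMethod("latitudes", "ClineDataset", function(x)
  stats::setNames(x@sites$latitude, x@sites$id))

.locusIndex <- function(x, locus) {
  if (is.character(locus)) {
    j <- match(locus, x@loci$id)
    if (is.na(j)) stop("unknown locus: ", locus)
  } else {
    j <- as.integer(locus)
    if (j < 1L || j > nrow(x@loci)) stop("locus index out of range")
  }
  j
}

setMethod("alleleCounts", "ClineDataset", function(x, locus)
  x@counts[[.locusIndex(x, locus)]])

setMethod("alleleFreqs", "ClineDataset", function(x, locus) {
  m <- x@counts[[.locusIndex(x, locus)]]
  n <- rowSums(m)
  f <- m / ifelse(n > 0, n, NA_real_)
  f
})

setMethod("sampleSizes", "ClineDataset", function(x, locus)
  rowSums(x@counts[[.locusIndex(x, locus)]]))

#' Subset a ClineDataset by site and/or locus
#'
#' @param x a [ClineDataset-class].
#' @param i site selector (logical, integer or site ids).
#' @param j locus selector (logical, integer or locus ids).
#' @param ... ignored.
#' @param drop ignored.
#' @export
setMethod("[", "ClineDataset", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@sites))
  if (missing(j)) j <- seq_len(nrow(x@loci))
  if (is.character(i)) i <- match(i, x@sites$id)
  if (is.character(j)) j <- match(j, x@loci$id)
  sites <- x@sites[i, , drop = FALSE]
  loci <- x@loci[j, , drop = FALSE]
  counts <- lapply(x@counts[j], function(m) m[i, , drop = FALSE])
  new("ClineDataset", sites = sites, loci = loci, counts = counts,
      provenance = x@provenance)
})
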