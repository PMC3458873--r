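#' Convert a frequency vector to integer counts
#'
#' Rounds \code{freq * n} to integers with a largest-remainder correction so
#' the counts sum exactly to \code{n}.
#'
#' @param freq numeric vector of allele frequencies (must sum to 1).
#' @param n total allele number to distribute.
#' @return integer vector summing to \code{n}.
#' @keywords internal
countsFromFrequencies <- function(freq, n) {
  if (any(freq < 0) || any(freq > 1))
    stop("frequencies must lie in [0, 1]")
  if (abs(sum(freq) - 1) > 1e-6)
    stop("frequencies must sum to 1")
  raw <- freq * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    # hand the leftover copies to the largest fractional remainders
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  as.integer(cnt)
}

#' Read a long-format allele table into a ClineDataset
#'
#' Expects a comma-separated UTF-8 file with a header and the long-format
#' columns \code{site}, \code{latitude}, \code{locus}, \code{allele} and
#' either \code{count} or \code{frequency} (optionally with
#' \code{sample_size}).  Optional columns: \code{longitude},
#' \code{marker_class}.  Frequencies given without counts are converted to
#' counts using \code{assumedSampleSize} allele copies per site (published
#' allozyme and mtDNA compilations typically report frequencies only) with a
#' largest-remainder rounding so counts sum exactly to the sample size.
#'
#' @param path path to the CSV file.
#' @param assumedSampleSize allele copies assumed per (site, locus) when only
#'   frequencies are given; default 40 (20 diploid individuals).
#' @return a [ClineDataset-class].
#' @seealso [writeFrequencyTable()]
#' @export
readFrequencyTable <- function(path, assumedSampleSize = 40) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("site", "latitude", "locus", "allele")
  if (!all(req %in% names(tab)))
    stop("missing required columns: ",
         paste(setdiff(req, names(tab)), collapse = ", "))
  hasCount <- "count" %in% names(tab)
  hasFreq <- "frequency" %in% names(tab)
  if (!hasCount && !hasFreq)
    stop("need a 'count' or a 'frequency' column")
  if (hasFreq && !hasCount) {
    bad <- which(tab$frequency < 0 | tab$frequency > 1 | !is.finite(tab$frequency))
    if (length(bad))
      stop("frequency outside [0,1] at data line(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  if (hasCount) {
    bad <- which(!is.finite(tab$count) | tab$count < 0 | tab$count != round(tab$count))
    if (length(bad))
      stop("malformed count at data line(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }

  siteTab <- unique(tab[, intersect(c("site", "latitude", "longitude"), names(tab))])
  if (anyDuplicated(siteTab$site))
    stop("site listed with inconsistent coordinates: ",
         siteTab$site[duplicated(siteTab$site)][1])
  sites <- data.frame(id = as.character(siteTab$site),
                      latitude = siteTab$latitude,
                      stringsAsFactors = FALSE)
  if ("longitude" %in% names(siteTab)) sites$longitude <- siteTab$longitude

  lociIds <- unique(as.character(tab$locus))
  classes <- if ("marker_class" %in% names(tab)) {
    vapply(lociIds, function(l) as.character(tab$marker_class[tab$locus == l][1]), "")
  } else rep("SNP", length(lociIds))
  loci <- data.frame(id = lociIds, markerClass = classes,
                     stringsAsFactors = FALSE)

  counts <- lapply(lociIds, function(l) {
    sub <- tab[tab$locus == l, , drop = FALSE]
    alleles <- unique(as.character(sub$allele))
    m <- matrix(0L, nrow(sites), length(alleles),
                dimnames = list(sites$id, alleles))
    for (sid in unique(as.character(sub$site))) {
      rows <- sub[sub$site == sid, , drop = FALSE]
      a <- match(as.character(rows$allele), alleles)
      if (hasCount) {
        m[sid, a] <- as.integer(rows$count)
      } else {
        n <- if ("sample_size" %in% names(rows) && is.finite(rows$sample_size[1]))
          rows$sample_size[1] else assumedSampleSize
        f <- rows$frequency
        # alleles absent from the file at this site have frequency 0
        full <- numeric(length(alleles))
        full[a] <- f
        m[sid, ] <- countsFromFrequencies(full, n)
      }
    }
    m
  })
  ClineDataset(sites, loci, counts, provenance = path)
}

#' Write a ClineDataset as a long-format CSV
#'
#' Inverse of [readFrequencyTable()]: emits one row per (site, locus, allele)
#' with counts, skipping unassayed site-locus combinations.  The round trip
#' preserves counts exactly.
#'
#' @param ds a [ClineDataset-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeFrequencyTable <- function(ds, path) {
  rows <- list()
  for (j in seq_len(nLoci(ds))) {
    m <- ds@counts[[j]]
    n <- rowSums(m)
    for (i in which(n > 0)) {
      rows[[length(rows) + 1L]] <- data.frame(
        site = ds@sites$id[i],
        latitude = ds@sites$latitude[i],
        locus = ds@loci$id[j],
        marker_class = ds@loci$markerClass[j],
        allele = colnames(m),
        count = m[i, ],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop invariant and incompletely assayed loci
#'
#' Mirrors the usual pre-analysis filtering of SNP panels: loci invariant
#' across all assayed sites carry no geographic signal, and loci missing
#' from some sites break comparisons that assume a shared site set.
#'
#' @param ds a [ClineDataset-class].
#' @param requireVariant drop loci whose pooled sample is monomorphic.
#' @param requireAllSites drop loci not assayed at every site.
#' @return a filtered [ClineDataset-class]; dropped locus ids are attached
#'   as \code{attr(, "dropped")} and reported via message.
#' @export
filterLoci <- function(ds, requireVariant = TRUE, requireAllSites = FALSE) {
  keep <- rep(TRUE, nLoci(ds))
  for (j in seq_len(nLoci(ds))) {
    m <- ds@counts[[j]]
    n <- rowSums(m)
    if (requireVariant) {
      tot <- colSums(m)
      if (sum(tot > 0) < 2) keep[j] <- FALSE
    }
    if (requireAllSites && any(n == 0)) keep[j] <- FALSE
  }
  dropped <- ds@loci$id[!keep]
  if (length(dropped))
    message("filterLoci: dropped ", length(dropped), " loci")
  out <- ds[, which(keep)]
  attr(out, "dropped") <- dropped
  out
}
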