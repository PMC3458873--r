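#' Read a GenePop genotype file
#'
#' Accepts the standard GenePop dialect: a title line, locus names (one per
#' line or comma-separated), then \code{POP}-delimited samples with
#' individual lines \code{name , 0101 0202 ...} using 2- or 3-digit allele
#' codes (detected from the genotype field width).  Missing genotypes
#' (\code{0000}/\code{000000}) are honored.
#'
#' @param path path to the GenePop file.
#' @return a [GenotypeTable-class]; allele ids are the numeric allele codes
#'   as character strings, individuals belong to sites \code{pop1},
#'   \code{pop2}, ... in file order.
#' @export
readGenepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("truncated GenePop file")
  popIdx <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (!length(popIdx)) stop("no POP keyword found: not a GenePop file")

  header <- lines[2:(popIdx[1] - 1)]
  lociIds <- trimws(unlist(strsplit(header, ",")))
  lociIds <- lociIds[nzchar(lociIds)]
  nLoc <- length(lociIds)
  if (!nLoc) stop("no locus names before first POP")

  indivSite <- character()
  rawGeno <- list()  # per individual: character vector of genotype fields
  for (b in seq_along(popIdx)) {
    from <- popIdx[b] + 1L
    to <- if (b < length(popIdx)) popIdx[b + 1L] - 1L else length(lines)
    if (from > to) stop("truncated POP block ", b)
    for (ln in lines[from:to]) {
      parts <- strsplit(ln, ",")[[1]]
      if (length(parts) < 2) stop("malformed individual line: ", ln)
      fields <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
      if (length(fields) != nLoc)
        stop("individual has ", length(fields), " genotypes, expected ", nLoc)
      indivSite <- c(indivSite, paste0("pop", b))
      rawGeno[[length(rawGeno) + 1L]] <- fields
    }
  }
  nInd <- length(rawGeno)
  geno <- matrix("", nInd, nLoc)
  for (i in seq_len(nInd)) geno[i, ] <- rawGeno[[i]]

  alleleIds <- vector("list", nLoc)
  genotypes <- vector("list", nLoc)
  for (j in seq_len(nLoc)) {
    w <- unique(nchar(geno[, j]))
    if (!all(w %in% c(4L, 6L)) || length(w) != 1)
      stop("unknown allele-code width at locus ", lociIds[j])
    half <- w / 2
    a1 <- as.integer(substr(geno[, j], 1, half))
    a2 <- as.integer(substr(geno[, j], half + 1, w))
    codes <- sort(unique(c(a1[a1 > 0], a2[a2 > 0])))
    alleleIds[[j]] <- as.character(codes)
    g <- cbind(match(a1, codes), match(a2, codes))
    g[is.na(g)] <- 0L
    storage.mode(g) <- "integer"
    genotypes[[j]] <- g
  }
  new("GenotypeTable",
      individualSite = indivSite,
      loci = data.frame(id = lociIds, stringsAsFactors = FALSE),
      alleleIds = alleleIds,
      genotypes = genotypes)
}

#' Write a GenotypeTable in GenePop format
#'
#' Always writes 3-digit allele codes.  Allele ids that are themselves
#' numeric strings keep their numeric code (so a read/write round trip is
#' identical on codes); other allele ids are coded by their position in the
#' locus's allele list.
#'
#' @param gt a [GenotypeTable-class].
#' @param path output path.
#' @param title title line (first line of the file).
#' @return invisibly, the path.
#' @export
writeGenepop <- function(gt, path, title = "clineCoCo export") {
  nLoc <- nrow(gt@loci)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(gt@loci$id, con)
  codes <- lapply(seq_len(nLoc), function(j) {
    ids <- gt@alleleIds[[j]]
    num <- suppressWarnings(as.integer(ids))
    if (!anyNA(num) && all(num > 0) && all(num < 1000)) num
    else seq_along(ids)
  })
  sites <- unique(gt@individualSite)
  for (s in sites) {
    writeLines("POP", con)
    for (i in which(gt@individualSite == s)) {
      fields <- vapply(seq_len(nLoc), function(j) {
        g <- gt@genotypes[[j]][i, ]
        c1 <- if (g[1] > 0) codes[[j]][g[1]] else 0L
        c2 <- if (g[2] > 0) codes[[j]][g[2]] else 0L
        sprintf("%03d%03d", c1, c2)
      }, "")
      writeLines(paste0(s, "_", i, " , ", paste(fields, collapse = " ")), con)
    }
  }
  invisible(path)
}
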