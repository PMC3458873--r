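## Genomic Co-Co ("coincidence / concordance") analysis: each clinal locus
## becomes a point at (cline midpoint, log absolute slope); a 2-D kernel
## density over those points defines highest-density-region envelopes, and
## loci in the low-density tail are outliers whose cline location or shape
## departs from the genomic consensus.

#' Co-Co coordinates from cline fits
#'
#' Maps each clinal locus to (midpoint, natural log of |slope|).  Slopes are
#' strongly right-skewed across loci; the log transform approximately
#' symmetrizes them.
#'
#' @param fits data.frame with columns \code{locus}, \code{midpoint},
#'   \code{slope} (e.g. the eligible rows of [screenDataset()] output).
#' @return data.frame with columns locus, midpoint, logAbsSlope.
#' @export
cocoCoordinates <- function(fits) {
  if (nrow(fits) == 0) stop("no fits supplied")
  if (any(!is.finite(fits$slope)) || any(fits$slope == 0))
    stop("fits must have finite nonzero slopes (screen for clinality first)")
  data.frame(locus = fits$locus, midpoint = fits$midpoint,
             logAbsSlope = log(abs(fits$slope)), stringsAsFactors = FALSE)
}

.bivGaussH <- function(dx, dy, H) {
  # bivariate normal density at offsets (dx, dy) with covariance H
  det <- H[1, 1] * H[2, 2] - H[1, 2]^2
  qf <- (H[2, 2] * dx^2 - 2 * H[1, 2] * dx * dy + H[1, 1] * dy^2) / det
  exp(-qf / 2) / (2 * pi * sqrt(det))
}

.lscvObjective <- function(H, px, py) {
  n <- length(px)
  dx <- outer(px, px, "-"); dy <- outer(py, py, "-")
  t1 <- sum(.bivGaussH(dx, dy, 2 * H)) / n^2
  cross <- .bivGaussH(dx, dy, H)
  diag(cross) <- 0
  t1 - 2 * sum(cross) / (n * (n - 1))
}

.normalReferenceH <- function(px, py) {
  # normal-scale reference bandwidth (d = 2): H = n^{-1/3} * Sigma-hat
  n <- length(px)
  stats::cov(cbind(px, py)) * n^(-1 / 3)
}

#' Estimate the Co-Co 2-D kernel density
#'
#' Gaussian-kernel density over (midpoint, log|slope|) with a full 2x2
#' bandwidth matrix.  The default selector minimizes the least-squares
#' cross-validation criterion over (log sd_x, log sd_y, atanh rho) starting
#' from the normal-scale reference; if the CV search fails or degenerates,
#' the normal-scale reference ("plugin") bandwidth is used and recorded in
#' the \code{method} slot.  The density is evaluated on a rectangular grid
#' padded three marginal bandwidths beyond the data range.
#'
#' @param points data.frame from [cocoCoordinates()] (or any data.frame with
#'   \code{midpoint} and \code{logAbsSlope}).
#' @param bandwidthMethod "cv" (least-squares cross-validation, default) or
#'   "plugin" (normal-scale reference).
#' @param gridSize grid points per axis (default 256).
#' @return a [CoCoDensity-class].
#' @export
estimateCocoDensity <- function(points, bandwidthMethod = c("cv", "plugin"),
                                gridSize = 256) {
  bandwidthMethod <- match.arg(bandwidthMethod)
  px <- points$midpoint; py <- points$logAbsSlope
  if (length(px) < 10)
    stop("need >= 10 points for density estimation; ",
         "for tiny inputs use bandwidthMethod = 'plugin' on a larger set")
  if (stats::sd(px) == 0 && stats::sd(py) == 0)
    stop("all points identical: no density estimable")
  H0 <- .normalReferenceH(px, py)
  H <- H0
  used <- "plugin"
  if (bandwidthMethod == "cv") {
    par0 <- c(log(sqrt(H0[1, 1])), log(sqrt(H0[2, 2])),
              atanh(min(max(H0[1, 2] / sqrt(H0[1, 1] * H0[2, 2]), -0.95), 0.95)))
    decode <- function(par) {
      sx <- exp(par[1]); sy <- exp(par[2]); rho <- tanh(par[3])
      matrix(c(sx^2, rho * sx * sy, rho * sx * sy, sy^2), 2)
    }
    fit <- try(stats::optim(par0, function(par)
      .lscvObjective(decode(par), px, py),
      method = "Nelder-Mead", control = list(maxit = 300)), silent = TRUE)
    if (!inherits(fit, "try-error") && is.finite(fit$value)) {
      Hcv <- decode(fit$par)
      # guard against CV degeneracies (undersmoothing collapse)
      if (all(is.finite(Hcv)) && min(eigen(Hcv, only.values = TRUE)$values) >
          1e-6 * max(H0)) {
        H <- Hcv
        used <- "cv"
      }
    }
  }
  padX <- 3 * sqrt(H[1, 1]); padY <- 3 * sqrt(H[2, 2])
  gx <- seq(min(px) - padX, max(px) + padX, length.out = gridSize)
  gy <- seq(min(py) - padY, max(py) + padY, length.out = gridSize)
  z <- matrix(0, gridSize, gridSize)
  n <- length(px)
  # evaluate one grid row at a time: z[i, j] = sum_k phi(gx[i]-px[k], gy[j]-py[k])
  det <- H[1, 1] * H[2, 2] - H[1, 2]^2
  DY <- outer(gy, py, "-")           # gridSize x n, shared across rows
  DY2 <- DY * DY
  norm <- 2 * pi * sqrt(det) * n
  for (i in seq_len(gridSize)) {
    dx <- gx[i] - px
    qf <- (rep(H[2, 2], gridSize) %o% (dx * dx) -
             DY * rep(2 * H[1, 2] * dx, each = gridSize) +
             H[1, 1] * DY2) / det
    z[i, ] <- rowSums(exp(-qf / 2)) / norm
  }
  # renormalize the residual mass lost outside the grid (< 1e-3 by padding)
  mass <- sum(z) * diff(gx[1:2]) * diff(gy[1:2])
  z <- z / mass
  pts <- data.frame(locus = if (is.null(points$locus))
    as.character(seq_len(n)) else points$locus,
    midpoint = px, logAbsSlope = py, stringsAsFactors = FALSE)
  new("CoCoDensity", x = gx, y = gy, z = z, H = H, points = pts,
      method = used)
}

#' Highest-density-region thresholds
#'
#' For each target mass m, the density level lambda such that the grid cells
#' with density >= lambda carry total mass closest to m from above.
#'
#' @param field a [CoCoDensity-class].
#' @param masses coverage levels (default \code{c(0.75, 0.95, 0.99)}).
#' @return named numeric vector of density levels.
#' @export
hdrThresholds <- function(field, masses = c(0.75, 0.95, 0.99)) {
  cell <- diff(field@x[1:2]) * diff(field@y[1:2])
  dens <- sort(as.numeric(field@z), decreasing = TRUE)
  cum <- cumsum(dens) * cell
  lev <- vapply(masses, function(m) {
    i <- which(cum >= m)[1]
    if (is.na(i)) min(dens[dens > 0]) else dens[i]
  }, 0)
  names(lev) <- sprintf("m%g", masses)
  lev
}

.bilinear <- function(field, x, y) {
  gx <- field@x; gy <- field@y
  ix <- findInterval(x, gx)
  iy <- findInterval(y, gy)
  out <- numeric(length(x))
  inside <- ix >= 1 & ix < length(gx) & iy >= 1 & iy < length(gy)
  for (k in which(inside)) {
    x1 <- gx[ix[k]]; x2 <- gx[ix[k] + 1]
    y1 <- gy[iy[k]]; y2 <- gy[iy[k] + 1]
    wx <- (x[k] - x1) / (x2 - x1); wy <- (y[k] - y1) / (y2 - y1)
    z <- field@z
    out[k] <- (1 - wx) * (1 - wy) * z[ix[k], iy[k]] +
      wx * (1 - wy) * z[ix[k] + 1, iy[k]] +
      (1 - wx) * wy * z[ix[k], iy[k] + 1] +
      wx * wy * z[ix[k] + 1, iy[k] + 1]
  }
  if (any(!inside)) {
    warning(sum(!inside), " point(s) outside the density grid: density 0")
    out[!inside] <- 0
  }
  out
}

#' Flag Co-Co outlier loci
#'
#' A locus is an outlier at coverage \code{mass} when its (bilinearly
#' interpolated) density falls below the corresponding HDR threshold, i.e.
#' it lies outside the envelope containing that fraction of the genomic
#' cline cloud.  When the flagged points are the very points the density
#' was estimated from (the usual case), each point's own kernel is removed
#' before comparison (leave-one-out): without this correction an isolated
#' locus sits on its own density bump and escapes flagging, deflating the
#' outlier rate well below the nominal level.
#'
#' @param points data.frame from [cocoCoordinates()].
#' @param field a [CoCoDensity-class] (normally estimated from these points).
#' @param mass envelope coverage (default 0.95).
#' @param leaveOneOut remove each point's own kernel contribution before
#'   thresholding; by default applied automatically when \code{points}
#'   coincide with the field's fitting points.
#' @return data.frame: locus, midpoint, logAbsSlope, density, outlier.
#' @export
flagCocoOutliers <- function(points, field, mass = 0.95, leaveOneOut = NULL) {
  lev <- hdrThresholds(field, mass)
  d <- .bilinear(field, points$midpoint, points$logAbsSlope)
  if (is.null(points$locus))
    points$locus <- as.character(seq_len(nrow(points)))
  if (is.null(leaveOneOut)) {
    fp <- field@points
    leaveOneOut <- nrow(fp) == nrow(points) &&
      isTRUE(all.equal(fp$midpoint, points$midpoint)) &&
      isTRUE(all.equal(fp$logAbsSlope, points$logAbsSlope))
  }
  if (leaveOneOut) {
    n <- nrow(field@points)
    phi0 <- 1 / (2 * pi * sqrt(det(field@H)))
    d <- pmax((n * d - phi0) / (n - 1), 0)
  }
  data.frame(locus = points$locus, midpoint = points$midpoint,
             logAbsSlope = points$logAbsSlope, density = d,
             outlier = d < lev, stringsAsFactors = FALSE)
}

#' Plot a genomic Co-Co plot
#'
#' Scatter of loci in (midpoint, log|slope|) space with HDR contour
#' envelopes; outliers drawn in red, optionally named loci highlighted.
#'
#' @param points data.frame from [cocoCoordinates()].
#' @param field a [CoCoDensity-class].
#' @param masses envelope coverages to contour (default 0.75/0.95/0.99).
#' @param outlierMass coverage defining outliers (default 0.95).
#' @param highlight character vector of locus ids to label.
#' @param file optional path; when given, a PDF is written there.
#' @return invisibly, the outlier table from [flagCocoOutliers()].
#' @export
plotCoco <- function(points, field, masses = c(0.75, 0.95, 0.99),
                     outlierMass = 0.95, highlight = character(), file = NULL) {
  if (!is.null(file)) {
    grDevices::pdf(file, width = 6, height = 5)
    on.exit(grDevices::dev.off())
  }
  out <- flagCocoOutliers(points, field, mass = outlierMass)
  graphics::plot(points$midpoint, points$logAbsSlope,
                 col = ifelse(out$outlier, "red", "grey50"), pch = 16,
                 xlab = "cline midpoint (degrees latitude)",
                 ylab = "log |slope|",
                 main = "Genomic Co-Co plot")
  lev <- hdrThresholds(field, masses)
  graphics::contour(field@x, field@y, field@z, levels = lev,
                    labels = sprintf("%g%%", 100 * masses),
                    add = TRUE, col = "black")
  if (length(highlight)) {
    ix <- match(highlight, points$locus)
    ix <- ix[!is.na(ix)]
    graphics::points(points$midpoint[ix], points$logAbsSlope[ix],
                     col = "blue", pch = 1, cex = 1.6)
    graphics::text(points$midpoint[ix], points$logAbsSlope[ix],
                   labels = points$locus[ix], pos = 3, col = "blue", cex = 0.7)
  }
  invisible(out)
}
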