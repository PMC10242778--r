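# Registration-quality metrics.  TRE (target registration error) measures
# the per-landmark Euclidean distance between corresponding annotated
# points across channels; NCC (normalized cross-correlation) measures the
# pixel-wise similarity of rendered channel images.  A paired two-sided
# Wilcoxon signed-rank test assesses the before/after TRE improvement.

#' Read an annotation file
#'
#' Reads manually annotated landmark coordinates: a plain-text file with
#' one `x, y` pair (nm) per line, comma- or whitespace-separated
#' (ImageJ point-export compatible).  Lines starting with `#` and a
#' one-line non-numeric header are skipped.
#'
#' @param path path to the annotation file.
#' @param channel_id channel label (defaults to the file name).
#' @return An `annotation_set`: a data.frame with columns `x`, `y` and a
#'   `channel_id` attribute.  Point order defines the correspondence
#'   across channels.
#' @export
read_annotations <- function(path, channel_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parse_line <- function(l) {
    suppressWarnings(as.numeric(strsplit(l, "[,;[:space:]]+")[[1]]))
  }
  vals <- lapply(lines, parse_line)
  ok <- vapply(vals, function(v) length(v) >= 2 && all(is.finite(v[1:2])),
               logical(1))
  vals <- vals[ok]  # drops a non-numeric header line, if any
  if (!length(vals)) stop("no coordinate pairs found in ", path)
  if (is.null(channel_id))
    channel_id <- sub("\\.[^.]*$", "", basename(path))
  annotation_set(vapply(vals, `[`, numeric(1), 1),
                 vapply(vals, `[`, numeric(1), 2), channel_id)
}

#' @rdname read_annotations
#' @param x,y coordinates in nm, index-matched across channels.
#' @export
annotation_set <- function(x, y, channel_id = "ch") {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  structure(data.frame(x = as.numeric(x), y = as.numeric(y)),
            channel_id = as.character(channel_id),
            class = c("annotation_set", "data.frame"))
}

#' Snap annotations to the nearest localization
#'
#' Manual clicks land near, not on, the underlying localizations; snapping
#' replaces each annotated point by the coordinates of the closest
#' localization in the table (Euclidean distance, ties broken by the
#' lowest row index), removing the click-precision component from the TRE.
#'
#' @param annotations an `annotation_set`.
#' @param table a non-empty [loc_table].
#' @return An `annotation_set` of the same length with snapped
#'   coordinates.
#' @export
snap_annotations <- function(annotations, table) {
  stopifnot(inherits(table, "loc_table"))
  if (nrow(table) == 0L) stop("cannot snap to an empty localization table")
  snapped <- vapply(seq_len(nrow(annotations)), function(i) {
    d2 <- (table$x - annotations$x[i])^2 + (table$y - annotations$y[i])^2
    j <- which.min(d2)  # which.min takes the lowest index on ties
    c(table$x[j], table$y[j])
  }, numeric(2))
  annotation_set(snapped[1, ], snapped[2, ], attr(annotations, "channel_id"))
}

#' Target registration error between corresponding landmarks
#'
#' Computes the Euclidean distance between index-matched points of the
#' moving and reference channels, plus a mean +/- SD summary (sample SD,
#' divisor n-1).  Symmetric in its arguments and invariant under a common
#' rigid transform.
#'
#' @param moving,reference `annotation_set`s (or 2-column coordinate
#'   structures) with equal point counts and matching indices.
#' @return A list of class `tre_summary`: `distances` (nm, per pair),
#'   `mean`, `sd`, `n`.
#' @export
tre <- function(moving, reference) {
  m <- as.matrix(as.data.frame(moving)[, c("x", "y")])
  r <- as.matrix(as.data.frame(reference)[, c("x", "y")])
  if (nrow(m) != nrow(r))
    stop("annotation sets differ in length (", nrow(m), " vs ", nrow(r), ")")
  if (nrow(m) < 1L) stop("need at least one point pair")
  d <- unname(sqrt(rowSums((m - r)^2)))
  structure(list(distances = d, mean = mean(d),
                 sd = if (length(d) > 1) stats::sd(d) else NA_real_,
                 n = length(d)),
            class = "tre_summary")
}

#' @export
print.tre_summary <- function(x, ...) {
  cat(sprintf("TRE: %.1f +/- %.1f nm (mean +/- SD, n = %d)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}

#' Render localizations to a pixel image
#'
#' Deposits a unit-integral isotropic 2D Gaussian of width `sigma` for
#' each localization onto a pixel grid (the normalized-Gaussian rendering
#' convention); `sigma = 0` gives a plain 2D histogram.  Per-pixel values
#' are exact Gaussian integrals over the pixel area (separable erf
#' differences), truncated at 6 sigma; mass is clipped for localizations
#' within 6 sigma of the image boundary.
#'
#' @param table a [loc_table].
#' @param pixel_size pixel edge length in nm (e.g. 13 nm for a 10x
#'   magnification rendering of 130 nm camera pixels).
#' @param sigma Gaussian rendering width in nm (default 20, a typical
#'   localization uncertainty); 0 for histogram rendering.
#' @param bounds numeric vector `c(xmin, xmax, ymin, ymax)` in nm, or
#'   `NULL` to cover the data (padded by `3 * sigma`).
#' @return A `rendered_image`: list with `pixels` (matrix, rows = y,
#'   cols = x), `pixel_size` and `origin` (nm coordinates of the corner
#'   of pixel [1,1]).
#' @export
render <- function(table, pixel_size, sigma = 20, bounds = NULL) {
  stopifnot(inherits(table, "loc_table"), pixel_size > 0, sigma >= 0)
  if (is.null(bounds)) {
    if (nrow(table) == 0L) stop("cannot infer bounds from an empty table")
    pad <- 3 * sigma + pixel_size
    bounds <- c(min(table$x) - pad, max(table$x) + pad,
                min(table$y) - pad, max(table$y) + pad)
  }
  if (bounds[2] <= bounds[1] || bounds[4] <= bounds[3])
    stop("empty rendering bounds")
  nx <- max(1L, as.integer(ceiling((bounds[2] - bounds[1]) / pixel_size)))
  ny <- max(1L, as.integer(ceiling((bounds[4] - bounds[3]) / pixel_size)))
  img <- matrix(0, nrow = ny, ncol = nx)
  ox <- bounds[1]; oy <- bounds[3]
  if (sigma == 0) {
    ix <- floor((table$x - ox) / pixel_size) + 1L
    iy <- floor((table$y - oy) / pixel_size) + 1L
    ok <- ix >= 1L & ix <= nx & iy >= 1L & iy <= ny
    for (i in which(ok)) img[iy[i], ix[i]] <- img[iy[i], ix[i]] + 1
  } else {
    w <- ceiling(6 * sigma / pixel_size)  # 6-sigma truncation: < 1e-8 mass lost
    for (i in seq_len(nrow(table))) {
      cx <- (table$x[i] - ox) / pixel_size
      cy <- (table$y[i] - oy) / pixel_size
      jx <- max(1L, floor(cx) - w):min(nx, ceiling(cx) + w)
      jy <- max(1L, floor(cy) - w):min(ny, ceiling(cy) + w)
      if (!length(jx) || !length(jy)) next
      px <- diff(stats::pnorm((c(jx[1] - 1L, jx) * pixel_size) ,
                              mean = table$x[i] - ox, sd = sigma))
      py <- diff(stats::pnorm((c(jy[1] - 1L, jy) * pixel_size),
                              mean = table$y[i] - oy, sd = sigma))
      img[jy, jx] <- img[jy, jx] + py %o% px
    }
  }
  structure(list(pixels = img, pixel_size = pixel_size,
                 origin = c(x = ox, y = oy)),
            class = "rendered_image")
}

#' Normalized cross-correlation of two rendered images
#'
#' Pearson product-moment correlation of corresponding pixel intensities:
#' `sum((I1 - mean1) * (I2 - mean2)) / (N * M * sd1 * sd2)` with
#' population standard deviations.  Lies in [-1, 1]; invariant under
#' affine intensity rescaling `a * I + b` (a > 0) of either image.
#'
#' @param image1,image2 `rendered_image`s of identical dimensions and
#'   pixel size.
#' @return The correlation coefficient.
#' @export
ncc <- function(image1, image2) {
  p1 <- image1$pixels; p2 <- image2$pixels
  if (!all(dim(p1) == dim(p2)))
    stop("images differ in dimensions (", paste(dim(p1), collapse = "x"),
         " vs ", paste(dim(p2), collapse = "x"), ")")
  if (image1$pixel_size != image2$pixel_size)
    stop("images differ in pixel size")
  n <- length(p1)
  m1 <- mean(p1); m2 <- mean(p2)
  s1 <- sqrt(sum((p1 - m1)^2) / n)  # population SD
  s2 <- sqrt(sum((p2 - m2)^2) / n)
  if (s1 == 0 || s2 == 0)
    stop("zero-variance image: correlation undefined")
  sum((p1 - m1) * (p2 - m2)) / (n * s1 * s2)
}

#' Paired Wilcoxon signed-rank test on TRE distances
#'
#' Two-sided paired signed-rank test of the before vs. after registration
#' error distributions, at the conventional 0.05 significance level.
#'
#' @param before,after numeric vectors of per-landmark TRE distances (nm),
#'   equal lengths >= 5.
#' @return A list: `p_value`, `statistic`, `significant`
#'   (`p_value < alpha`), `alpha = 0.05`.
#' @export
paired_wilcoxon <- function(before, after) {
  if (length(before) != length(after))
    stop("before/after vectors differ in length")
  if (length(before) < 5L)
    stop("need at least 5 pairs for the signed-rank test")
  if (all(before == after)) {
    warning("all paired differences are zero; p = 1")
    return(list(p_value = 1, statistic = NA_real_, significant = FALSE,
                alpha = 0.05))
  }
  ht <- stats::wilcox.test(before, after, paired = TRUE,
                           alternative = "two.sided")
  list(p_value = ht$p.value, statistic = unname(ht$statistic),
       significant = ht$p.value < 0.05, alpha = 0.05)
}
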