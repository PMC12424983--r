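#' Statistical image of an XYT stack
#'
#' Per-pixel temporal mean plus a high temporal percentile of intensity.
#' Active pixels (carrying transients) score higher than inactive pixels of
#' equal mean, which is what makes this image segmentable into cells.
#'
#' @param movie a [ca_movie()].
#' @param upper_percentile temporal percentile added to the mean, in percent
#'   (default 99; must satisfy 50 < p <= 100). Percentiles use linear
#'   interpolation between order statistics (R quantile type 7).
#' @return numeric matrix with the movie's XY shape.
#' @export
statistical_image <- function(movie, upper_percentile = 99) {
  stopifnot(inherits(movie, "ca_movie"))
  if (upper_percentile <= 50 || upper_percentile > 100)
    stop("upper_percentile must satisfy 50 < p <= 100")
  d <- dim(movie$stack)
  if (d[1] < 2L) stop("statistical image requires >= 2 frames")
  flat <- matrix(movie$stack, d[1], d[2] * d[3])
  m <- colMeans(flat)
  q <- apply(flat, 2L, stats::quantile, probs = upper_percentile / 100,
             names = FALSE, type = 7)
  matrix(m + q, d[2], d[3])
}

#' Segment a statistical image into ROIs
#'
#' Otsu threshold on the (lightly smoothed) statistical image, distance
#' transform + watershed to split touching cells, 8-connected components,
#' then an area gate. Labels are renumbered 1..K in row-major centroid order
#' for determinism.
#'
#' @param stat_image numeric matrix from [statistical_image()].
#' @param min_area_px,max_area_px inclusive ROI area gate in pixels
#'   (defaults 30 and 2000, sized for cells in a 256x256 field).
#' @param threshold_method `"otsu"` (default) or a numeric threshold on the
#'   raw statistical-image scale.
#' @param smooth_px Gaussian pre-smoothing sigma in pixels (0 disables).
#' @param watershed_tolerance minimum depth between basins for a split
#'   (passed to the watershed; in distance-map pixel units).
#' @return object of class `roi_map`: `labels` matrix (0 = background) and
#'   `sizes` (per-ROI pixel counts). Empty foreground yields 0 ROIs.
#' @export
segment_rois <- function(stat_image, min_area_px = 30, max_area_px = 2000,
                         threshold_method = "otsu", smooth_px = 1,
                         watershed_tolerance = 1) {
  stopifnot(is.matrix(stat_image))
  if (!(min_area_px > 0 && min_area_px < max_area_px))
    stop("areas must satisfy 0 < min_area_px < max_area_px")
  img <- stat_image
  if (smooth_px > 0) {
    img <- apply(img, 2L, gauss_smooth, sigma = smooth_px)
    img <- t(apply(img, 1L, gauss_smooth, sigma = smooth_px))
  }
  rng <- range(img)
  if (rng[2] - rng[1] <= 1e-10 * max(abs(rng), 1)) {
    message("segment_rois: constant image, empty foreground")
    return(roi_map(matrix(0L, nrow(stat_image), ncol(stat_image))))
  }
  norm <- (img - rng[1]) / (rng[2] - rng[1])
  thr <- if (identical(threshold_method, "otsu")) {
    EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  } else {
    (as.numeric(threshold_method) - rng[1]) / (rng[2] - rng[1])
  }
  fg <- norm > thr
  if (!any(fg)) {
    message("segment_rois: empty foreground after thresholding")
    return(roi_map(matrix(0L, nrow(stat_image), ncol(stat_image))))
  }
  dm <- EBImage::distmap(EBImage::Image(fg * 1))
  ws <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(stat_image))
  sizes <- table(lab[lab > 0L])
  drop <- as.integer(names(sizes)[sizes < min_area_px | sizes > max_area_px])
  lab[lab %in% drop] <- 0L
  roi_map(relabel_row_major(lab))
}

#' Construct an ROI map
#'
#' @param labels integer label matrix; 0 is background, ROI k is labelled k.
#' @return object of class `roi_map` with per-ROI pixel counts in `sizes`.
#' @export
roi_map <- function(labels) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) && !identical(ids, seq_along(ids)))
    stop("ROI labels must be contiguous 1..K")
  sizes <- if (length(ids)) as.integer(table(factor(labels[labels > 0L], ids)))
           else integer(0)
  structure(list(labels = labels, sizes = sizes, n_roi = length(ids)),
            class = "roi_map")
}

#' @export
print.roi_map <- function(x, ...) {
  cat(sprintf("<roi_map> %d ROIs over %dx%d px\n",
              x$n_roi, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Extract one mean-intensity trace per ROI
#'
#' @param movie a [ca_movie()].
#' @param rois a [roi_map()] with the movie's XY shape.
#' @return a [trace_set()] with one column per ROI.
#' @export
extract_traces <- function(movie, rois) {
  stopifnot(inherits(movie, "ca_movie"), inherits(rois, "roi_map"))
  d <- dim(movie$stack)
  if (!identical(dim(rois$labels), d[2:3]))
    stop("ROI label image shape does not match movie XY shape")
  if (rois$n_roi == 0L) stop("no ROIs to extract")
  flat <- matrix(movie$stack, d[1], d[2] * d[3])
  lab <- as.vector(rois$labels)
  vals <- vapply(seq_len(rois$n_roi), function(k) {
    pix <- which(lab == k)
    if (length(pix) == 1L) flat[, pix] else rowMeans(flat[, pix, drop = FALSE])
  }, numeric(d[1]))
  trace_set(vals, movie$rate_hz)
}

#' Rebin a trace to a lower rate by non-overlapping block means
#'
#' The overall mean is preserved exactly when the rates divide.
#'
#' @param trace numeric vector.
#' @param rate_hz input sampling rate.
#' @param target_hz output rate; `rate_hz / target_hz` must be integer.
#' @return numeric vector of block means at `target_hz`.
#' @export
rebin_trace <- function(trace, rate_hz, target_hz) {
  ratio <- rate_hz / target_hz
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1)
    stop("rate_hz must be an integer multiple of target_hz")
  ratio <- as.integer(round(ratio))
  n <- (length(trace) %/% ratio) * ratio
  if (n < length(trace))
    stop("trace length must be divisible by the rebin factor")
  colMeans(matrix(trace, ratio))
}
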