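#' Lay out circular cells in a movie frame
#'
#' @param centers two-column matrix or data frame of (row, col) centres in px.
#' @param radius_px disk radius per cell (recycled).
#' @return data frame with columns `row`, `col`, `radius`.
#' @export
cell_layout <- function(centers, radius_px) {
  centers <- as.data.frame(centers)
  names(centers)[1:2] <- c("row", "col")
  centers$radius <- rep_len(radius_px, nrow(centers))
  centers
}

#' Simulate an islet movie (XYT stack) with known ROI membership
#'
#' Cells are non-overlapping disks whose pixels all carry the cell's clean
#' trace (from [simulate_traces()] with zero trace-level noise) plus
#' independent per-pixel Gaussian noise; background pixels carry
#' `bg_level` plus noise. Negative intensities are clipped at zero.
#'
#' @param spec a [trace_population_spec()]; `spec$n_cells` must equal the
#'   number of layout rows.
#' @param layout a [cell_layout()] data frame of disk centres and radii (px).
#' @param dim_px frame size `c(rows, cols)` (default `c(256, 256)`, the
#'   acquisition format this emulates).
#' @param bg_level background intensity.
#' @param pixel_noise_sd per-pixel Gaussian noise standard deviation.
#' @return list with `movie` (class `ca_movie`: `stack[frame, row, col]`,
#'   `rate_hz`), `labels` (true ROI label image), and `truth` (planted-event
#'   ground truth plus the clean per-cell traces).
#' @export
simulate_movie <- function(spec, layout, dim_px = c(256, 256),
                           bg_level = 20, pixel_noise_sd = 10) {
  stopifnot(inherits(spec, "trace_population_spec"))
  layout <- as.data.frame(layout)
  if (nrow(layout) != spec$n_cells)
    stop_field("layout", "number of cells must equal spec$n_cells")
  nr <- dim_px[1]; nc <- dim_px[2]
  # disks must be inside the frame and pairwise disjoint
  if (any(layout$row - layout$radius < 1 | layout$row + layout$radius > nr |
          layout$col - layout$radius < 1 | layout$col + layout$radius > nc))
    stop("cell layout: disks must lie inside the frame")
  if (nrow(layout) > 1L) {
    d <- as.matrix(stats::dist(layout[, c("row", "col")]))
    rs <- outer(layout$radius, layout$radius, "+")
    diag(d) <- Inf
    if (any(d <= rs)) stop("cell layout: overlapping cells")
  }

  labels <- matrix(0L, nr, nc)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (k in seq_len(nrow(layout))) {
    inside <- (rr - layout$row[k])^2 + (cc - layout$col[k])^2 <= layout$radius[k]^2
    labels[inside] <- k
  }

  clean_spec <- spec
  clean_spec$noise_sd <- 0
  clean_spec$amplitude_rel <- spec$amplitude_snr * spec$noise_sd / spec$baseline
  sim <- simulate_traces(clean_spec)
  clean <- sim$traces$values      # n_t x K, includes baseline and bleaching
  n_t <- nrow(clean)

  stack <- with_seed(spec$seed + 1L, {
    flat <- matrix(stats::rnorm(n_t * nr * nc, 0, pixel_noise_sd), n_t, nr * nc)
    flat <- flat + bg_level
    for (k in seq_len(spec$n_cells)) {
      pix <- which(labels == k)
      flat[, pix] <- flat[, pix] - bg_level + clean[, k]
    }
    flat[flat < 0] <- 0
    array(flat, dim = c(n_t, nr, nc))
  })
  movie <- ca_movie(stack, spec$rate_hz)
  sim$truth$clean_traces <- clean
  list(movie = movie, labels = labels, truth = sim$truth)
}

#' Construct a Ca2+ movie object
#'
#' @param stack numeric array `[frame, row, col]` of non-negative intensities.
#' @param rate_hz frame rate (frames/second).
#' @param px_um optional pixel size in microns.
#' @return object of class `ca_movie`.
#' @export
ca_movie <- function(stack, rate_hz, px_um = NULL) {
  if (length(dim(stack)) != 3L) stop("stack must be a 3-D array [frame, row, col]")
  if (dim(stack)[1] < 2L) stop("movie must have >= 2 frames")
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be > 0")
  if (any(!is.finite(stack)) || any(stack < 0))
    stop("intensities must be finite and >= 0")
  structure(list(stack = stack, rate_hz = rate_hz, px_um = px_um),
            class = "ca_movie")
}

#' @export
print.ca_movie <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("<ca_movie> %d frames of %dx%d px @ %g Hz\n",
              d[1], d[2], d[3], x$rate_hz))
  invisible(x)
}
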