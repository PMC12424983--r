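# File-format helpers: multi-page TIFF movies and label images, CSV traces
# and event tables, JSON provenance.

#' Read a movie from a multi-page TIFF
#'
#' @param path TIFF file with one page per frame.
#' @param rate_hz frame rate of the recording (not stored in plain TIFF).
#' @param scale multiply stored values by this factor (TIFF readers return
#'   intensities normalized to \[0, 1\]; the writer's scale restores the
#'   original range).
#' @return a [ca_movie()].
#' @export
read_movie <- function(path, rate_hz, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  stack <- array(0, c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) stack[i, , ] <- pages[[i]] * scale
  ca_movie(stack, rate_hz)
}

#' Write a movie as an unsigned 16-bit multi-page TIFF
#'
#' Intensities are scaled by `1 / scale` into \[0, 1\] before writing;
#' pass the same `scale` to [read_movie()] to restore them.
#'
#' @param movie a [ca_movie()].
#' @param path output path.
#' @param scale intensity corresponding to full scale (default: the movie
#'   maximum).
#' @return invisibly, the scale used.
#' @export
write_movie <- function(movie, path, scale = NULL) {
  stopifnot(inherits(movie, "ca_movie"))
  scale <- scale %||% max(movie$stack)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(dim(movie$stack)[1]), function(i)
    pmin(movie$stack[i, , ] / scale, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(scale)
}

#' Write/read a trace set as CSV (columns roi_id, time_s, value)
#' @param traces a [trace_set()].
#' @param path output path.
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  n <- nrow(traces$values)
  df <- data.frame(
    roi_id = rep(traces$roi_ids, each = n),
    time_s = rep((seq_len(n) - 1L) / traces$rate_hz, ncol(traces$values)),
    value = as.vector(traces$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @param rate_hz sampling rate of the stored traces.
#' @export
read_traces <- function(path, rate_hz) {
  df <- utils::read.csv(path)
  ids <- sort(unique(df$roi_id))
  vals <- vapply(ids, function(k) df$value[df$roi_id == k],
                 numeric(sum(df$roi_id == ids[1])))
  trace_set(vals, rate_hz, roi_ids = ids)
}

#' Write an event table with a JSON provenance sidecar
#'
#' @param events event table (data frame).
#' @param path CSV output path; parameters are written to
#'   `<path>.params.json` when `params` is non-NULL.
#' @param params named list of detection parameters.
#' @export
write_events <- function(events, path, params = NULL) {
  utils::write.csv(events, path, row.names = FALSE)
  if (!is.null(params))
    jsonlite::write_json(params, paste0(path, ".params.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write an ROI map as a 16-bit TIFF label image plus a CSV summary
#'
#' @param rois a [roi_map()].
#' @param tiff_path,csv_path output paths (either may be `NULL`).
#' @export
write_roi_map <- function(rois, tiff_path = NULL, csv_path = NULL) {
  stopifnot(inherits(rois, "roi_map"))
  if (!is.null(tiff_path))
    tiff::writeTIFF(rois$labels / 65535, tiff_path, bits.per.sample = 16L)
  if (!is.null(csv_path)) {
    if (rois$n_roi) {
      nr <- nrow(rois$labels)
      idx <- which(rois$labels > 0L)
      l <- rois$labels[idx]
      df <- data.frame(roi_id = seq_len(rois$n_roi),
                       n_px = rois$sizes,
                       center_row = as.numeric(tapply((idx - 1L) %% nr + 1L, l, mean)),
                       center_col = as.numeric(tapply((idx - 1L) %/% nr + 1L, l, mean)))
    } else {
      df <- data.frame(roi_id = integer(), n_px = integer(),
                       center_row = numeric(), center_col = numeric())
    }
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(c(tiff_path, csv_path))
}
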