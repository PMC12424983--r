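#' Photobleaching correction (F/F0)
#'
#' Divides a raw fluorescence trace by a fitted slowly varying baseline so a
#' transient-free trace sits at 1.0. The default baseline model is a
#' constant-plus-exponential decay fitted to a running low quantile of the
#' trace (robust to the transients themselves); `"quantile"` uses the
#' smoothed running quantile directly, for baselines that are not
#' exponential. After division the output is rescaled so its median is
#' exactly 1, removing the small offset between the low-quantile envelope
#' and the true baseline.
#'
#' @param trace numeric raw trace.
#' @param rate_hz sampling rate (frames/second).
#' @param method `"exponential"` (default) or `"quantile"`.
#' @param window_s running-quantile window in seconds (default 30, long
#'   relative to single transients, short relative to bleaching).
#' @param q low quantile used for the baseline envelope (default 0.1).
#' @return object of class `normalized_trace`: `values` (F/F0), `rate_hz`,
#'   `baseline` (the fitted F0 curve), `method`.
#' @export
debleach <- function(trace, rate_hz, method = c("exponential", "quantile"),
                     window_s = 30, q = 0.1) {
  method <- match.arg(method)
  n <- length(trace)
  if (n < 10 * rate_hz) stop("trace must be at least 10 s long")
  t <- (seq_len(n) - 1L) / rate_hz
  w <- max(3L, as.integer(round(window_s * rate_hz)))
  # running low-quantile envelope on a coarse grid, then interpolated
  centers <- unique(c(seq(1L, n, by = max(1L, w %/% 2L)), n))
  env <- vapply(centers, function(i) {
    lo <- max(1L, i - w %/% 2L); hi <- min(n, i + w %/% 2L)
    stats::quantile(trace[lo:hi], q, names = FALSE)
  }, numeric(1))
  b <- stats::approx(t[centers], env, xout = t, rule = 2)$y

  if (diff(range(b)) <= 1e-12 * max(abs(b), 1)) {
    # flat envelope: constant baseline, output is exactly trace/median
    f0 <- rep(mean(b), n)
    out <- trace / f0
    med <- stats::median(out)
    if (any(f0 <= 0) || med <= 0) stop("baseline fit is non-positive; cannot form F/F0")
    return(structure(list(values = out / med, rate_hz = rate_hz,
                          baseline = f0 * med, method = method),
                     class = "normalized_trace"))
  }
  if (method == "exponential") {
    fit <- tryCatch({
      st <- list(a = max(b[1] - b[length(b)], 1e-8 * max(abs(b), 1)),
                 tau = max(t) / 2, c = b[length(b)])
      m <- minpack.lm::nlsLM(bv ~ a * exp(-tv / tau) + c,
                             data = list(bv = b, tv = t), start = st,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
      stats::predict(m)
    }, error = function(e) NULL)
    f0 <- if (is.null(fit)) rep(mean(b), n) else fit
  } else {
    f0 <- gauss_smooth(b, sigma = w / 4)
  }
  if (any(f0 <= 0)) stop("baseline fit is non-positive; cannot form F/F0")
  out <- trace / f0
  med <- stats::median(out)
  if (med <= 0) stop("baseline fit is non-positive; cannot form F/F0")
  out <- out / med
  structure(list(values = out, rate_hz = rate_hz, baseline = f0 * med,
                 method = method),
            class = "normalized_trace")
}

#' @export
print.normalized_trace <- function(x, ...) {
  cat(sprintf("<normalized_trace> %d frames @ %g Hz (%s baseline)\n",
              length(x$values), x$rate_hz, x$method))
  invisible(x)
}

# measure FWHM of one detection on the de-bleached trace;
# returns NULL if no positive excursion is measurable.
# Crossings are located on a lightly smoothed copy `xs` (so a single noise
# dip near the half level cannot truncate the walk) and the smoothing's
# quadratic widening is removed afterwards.
measure_fwhm <- function(x, xs, t, run, scale_samples, smooth_sigma) {
  peak <- run[which.max(xs[run])]
  n <- length(xs)
  dt <- t[2] - t[1]
  # two passes: the first uses a window proportional to the detection scale,
  # the second rescales window and exclusion zone to the measured width so
  # wide events detected at small scales do not contaminate their own
  # baseline estimate
  half_w <- as.integer(round(3 * scale_samples))
  excl <- run
  t_left <- t_right <- NULL
  for (pass in 1:2) {
    lo <- max(1L, peak - half_w); hi <- min(n, peak + half_w)
    base_idx <- setdiff(lo:hi, excl)
    # low quantile rather than median: robust against neighbouring events
    # inside the window when trains are dense
    base <- if (length(base_idx)) stats::quantile(xs[base_idx], 0.25, names = FALSE)
            else stats::quantile(xs, 0.25, names = FALSE)
    height <- xs[peak] - base
    if (height <= 0) return(NULL)
    half <- base + height / 2
    # crossings with linear interpolation for sub-frame precision
    i <- peak
    while (i > 1L && xs[i - 1L] > half) i <- i - 1L
    t_left <- if (i == 1L) t[1] else {
      t[i - 1L] + dt * (half - xs[i - 1L]) / (xs[i] - xs[i - 1L])
    }
    i <- peak
    while (i < n && xs[i + 1L] > half) i <- i + 1L
    t_right <- if (i == n) t[n] else {
      t[i] + dt * (xs[i] - half) / (xs[i] - xs[i + 1L])
    }
    if (!is.finite(t_left) || !is.finite(t_right) || t_right <= t_left)
      return(NULL)
    w_samp <- (t_right - t_left) / dt
    half_w <- as.integer(round(max(3 * scale_samples, 3 * w_samp)))
    excl <- max(1L, as.integer(round(peak - 1.5 * w_samp))):
            min(n, as.integer(round(peak + 1.5 * w_samp)))
  }
  # smoothing a pulse widens its FWHM approximately in quadrature; a
  # measured width at or below the blur itself is unresolvable at this
  # scale (a genuine event that narrow fires at a finer scale instead)
  blur <- 2 * sqrt(2 * log(2)) * smooth_sigma * dt
  fw2 <- (t_right - t_left)^2 - blur^2
  if (fw2 <= 0) return(NULL)
  fw <- sqrt(fw2)
  mid <- (t_left + t_right) / 2
  list(t_left = mid - fw / 2, t_right = mid + fw / 2, peak = peak)
}

#' Detect oscillatory Ca2+ events across multiple timescales
#'
#' Each dyadic timescale is isolated with a band-pass filter (difference of
#' Gaussian smoothings at sigma = scale/2.355 and 2*scale/2.355), the
#' filtered trace is standardized against a robust noise floor, and
#' excursions with z-score above `z_thresh` are marked. The noise floor is
#' the white-noise level estimated from the trace's first difference
#' (transients are slow relative to the frame interval, so the difference
#' is noise-dominated even on dense trains) propagated through the
#' band-pass gain, then refined by one reweighted-MAD step that captures
#' signal-induced filter ripple. Detections are merged across scales finest
#' scale first: a coarser detection is kept only where no finer detection's
#' FWHM interval overlaps it, so a coarse blob spanning two resolved fast
#' events cannot swallow them. Halfwidth (FWHM) is measured on the
#' de-bleached trace around the peak against a local low-quantile baseline
#' (window rescaled to the measured width in a second pass), with
#' half-maximum crossings located by linear interpolation on a lightly
#' smoothed copy and the smoothing blur removed in quadrature; the midtime
#' is the midpoint of the FWHM interval.
#'
#' @param norm_trace a [debleach()] result, or a numeric trace assumed to be
#'   already normalized (then `rate_hz` must be given).
#' @param rate_hz sampling rate; taken from `norm_trace` when it is a
#'   `normalized_trace`.
#' @param scales_s detection timescales in seconds (default dyadic 1..256).
#' @param z_thresh detection threshold on the z-score (default 4, strict).
#' @param roi_id ROI identifier stamped on the events.
#' @return data frame of events with columns `roi_id`, `onset_s`,
#'   `midtime_s`, `halfwidth_s`, `peak_z`, `scale_s`, sorted by midtime.
#' @export
detect_events <- function(norm_trace, rate_hz = NULL, scales_s = 2^(0:8),
                          z_thresh = 4, roi_id = 1L) {
  if (inherits(norm_trace, "normalized_trace")) {
    x <- norm_trace$values
    rate_hz <- norm_trace$rate_hz
  } else {
    x <- as.numeric(norm_trace)
    if (is.null(rate_hz)) stop("rate_hz required for a plain numeric trace")
  }
  n <- length(x)
  t <- (seq_len(n) - 1L) / rate_hz
  if (rate_hz * min(scales_s) < 4)
    stop("smallest scale must span at least 4 samples at this rate")
  empty <- data.frame(roi_id = integer(), onset_s = numeric(),
                      midtime_s = numeric(), halfwidth_s = numeric(),
                      peak_z = numeric(), scale_s = numeric())
  usable <- scales_s[2 * scales_s * rate_hz <= n]
  if (length(usable) < length(scales_s))
    warning(sprintf("trace shorter than scales {%s} s; skipped",
                    paste(setdiff(scales_s, usable), collapse = ", ")))
  # white-noise level from the first difference (transients are slow at the
  # frame rate, so the difference is essentially pure noise even when the
  # trace is dense with events), propagated through each band-pass gain
  sd0 <- stats::mad(diff(x)) / sqrt(2)
  band_gain <- function(s1, s2) {
    r <- as.integer(ceiling(4 * s2))
    kern <- function(sg) {
      if (sg <= 0.25) { k <- numeric(2L * r + 1L); k[r + 1L] <- 1; k }
      else { k <- stats::dnorm(seq.int(-r, r), sd = sg); k / sum(k) }
    }
    sqrt(sum((kern(s1) - kern(s2))^2))
  }
  dets <- list()
  for (s in usable) {
    s1 <- s / 2.355 * rate_hz
    s2 <- 2 * s / 2.355 * rate_hz
    band <- gauss_smooth(x, s1) - gauss_smooth(x, s2)
    noise0 <- sd0 * band_gain(s1, s2)
    if (noise0 <= 0) noise0 <- stats::mad(band)  # noise-free synthetic input
    if (noise0 <= 0) next
    # one reweighting step: exclude clear events, then let the MAD of the
    # remainder capture signal-induced filter ripple the white-noise
    # propagation misses (dense trains), without event inflation
    z0 <- (band - stats::median(band)) / noise0
    quiet <- abs(z0) <= 3
    # the absolute floor keeps numerical residue of the FFT convolution on
    # (near-)noiseless traces from masquerading as a noise level
    floor_eps <- 1e-12 * max(abs(x), .Machine$double.eps)
    noise <- max(noise0, stats::mad(band[quiet]), floor_eps)
    z <- (band - stats::median(band[quiet])) / noise
    above <- z > z_thresh
    if (!any(above)) next
    sig_meas <- max(1, s * rate_hz / 8)
    xs <- gauss_smooth(x, sig_meas)
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      run <- starts[j]:ends[j]
      fw <- measure_fwhm(x, xs, t, run, s * rate_hz, sig_meas)
      if (is.null(fw)) next
      dets[[length(dets) + 1L]] <- data.frame(
        t_left = fw$t_left, t_right = fw$t_right,
        peak_z = max(z[run]), scale_s = s)
    }
  }
  if (!length(dets)) return(empty)
  d <- do.call(rbind, dets)
  # cross-scale merge, finest scale first: a coarser detection is kept only
  # if its FWHM interval does not overlap an already-accepted one, so a
  # coarse blob spanning two resolved fast events cannot swallow them;
  # within a scale, stronger detections take precedence
  d <- d[order(d$scale_s, -d$peak_z), , drop = FALSE]
  acc <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    j <- which(acc)
    if (!length(j) || all(d$t_left[i] >= d$t_right[j] | d$t_right[i] <= d$t_left[j]))
      acc[i] <- TRUE
  }
  d <- d[acc, , drop = FALSE]
  out <- data.frame(roi_id = as.integer(roi_id),
                    onset_s = d$t_left,
                    midtime_s = (d$t_left + d$t_right) / 2,
                    halfwidth_s = d$t_right - d$t_left,
                    peak_z = d$peak_z,
                    scale_s = d$scale_s)
  out <- out[order(out$midtime_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect events for every ROI of a trace set
#'
#' De-bleaches each trace and runs [detect_events()], returning one pooled
#' event table.
#'
#' @param traces a [trace_set()].
#' @param scales_s,z_thresh see [detect_events()].
#' @param debleach_method passed to [debleach()].
#' @return event table (data frame) over all ROIs.
#' @export
detect_events_set <- function(traces, scales_s = 2^(0:8), z_thresh = 4,
                              debleach_method = "exponential") {
  stopifnot(inherits(traces, "trace_set"))
  evs <- lapply(seq_along(traces$roi_ids), function(k) {
    nt <- debleach(traces$values[, k], traces$rate_hz, method = debleach_method)
    detect_events(nt, scales_s = scales_s, z_thresh = z_thresh,
                  roi_id = traces$roi_ids[k])
  })
  out <- do.call(rbind, evs)
  rownames(out) <- NULL
  out
}

#' Inter-event intervals from one ROI's events
#'
#' Time differences between midtimes of consecutive events.
#'
#' @param events event data frame for a single ROI (sorted or not; sorted by
#'   midtime internally).
#' @return numeric vector of intervals in seconds (empty for < 2 events).
#' @export
inter_event_intervals <- function(events) {
  if (is.data.frame(events)) {
    if (length(unique(events$roi_id)) > 1L)
      stop("inter_event_intervals expects events of a single ROI")
    mids <- sort(events$midtime_s)
  } else mids <- sort(as.numeric(events))
  if (length(mids) < 2L) return(numeric(0))
  diff(mids)
}

#' Discard low-activity ROIs
#'
#' ROIs with fewer than `min_events` detected events over the whole
#' recording are removed entirely. Applied before any halfwidth band
#' filtering, so the activity count reflects all detected oscillations.
#'
#' @param events event table.
#' @param min_events minimum number of events to keep an ROI (default 5;
#'   an ROI with exactly 5 events is kept).
#' @return filtered event table.
#' @export
filter_rois <- function(events, min_events = 5) {
  if (!nrow(events)) return(events)
  counts <- table(events$roi_id)
  keep <- as.integer(names(counts)[counts >= min_events])
  out <- events[events$roi_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep events in a halfwidth band
#'
#' Retains the dominant fast component: events with
#' `lo_s <= halfwidth_s <= hi_s` (inclusive at both ends).
#'
#' @param events event table.
#' @param lo_s,hi_s band edges in seconds (defaults 1 and 10).
#' @return filtered event table.
#' @export
band_filter_events <- function(events, lo_s = 1, hi_s = 10) {
  if (lo_s >= hi_s) stop("band edges must satisfy lo_s < hi_s")
  if (!nrow(events)) return(events)
  out <- events[events$halfwidth_s >= lo_s & events$halfwidth_s <= hi_s, ,
                drop = FALSE]
  rownames(out) <- NULL
  out
}
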