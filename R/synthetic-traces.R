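#' Specification of a synthetic oscillatory trace population
#'
#' Describes a population of beta-cell-like cytosolic Ca2+ traces: a renewal
#' process of transient events per cell (log-normal inter-event intervals,
#' log-normal FWHM halfwidths), multiplicative photobleaching, additive
#' Gaussian noise, and optional cell-cell coupling through a shared "islet
#' clock" that triggers co-firing in coupled cells.
#'
#' Event halfwidths and inter-event intervals are parameterised by their
#' *median* (seconds) and a log-normal dispersion (`sdlog`), matching the
#' heavy-tailed, strictly positive kinetics distributions observed in islet
#' recordings (condition medians of roughly 2.5-5.5 s halfwidth and
#' 12-44 s inter-event interval).
#'
#' @param n_cells number of cells (>= 1).
#' @param duration_s recording duration in seconds (> 0).
#' @param rate_hz sampling rate in frames/second (default 20, the acquisition
#'   rate of the imaging protocol this emulates).
#' @param halfwidth_dist numeric length-2: median FWHM (s) and log-normal
#'   dispersion (sdlog) of event halfwidths.
#' @param iei_dist numeric length-2: median inter-event interval (s) and
#'   log-normal dispersion.
#' @param amplitude_snr transient peak height in units of the noise standard
#'   deviation `noise_sd`.
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units).
#' @param baseline resting fluorescence level (intensity units).
#' @param bleach_tau_s exponential photobleaching time constant in seconds;
#'   `Inf` disables bleaching.
#' @param coupling list with elements `adjacency` (K x K logical/0-1 symmetric
#'   matrix, no self-edges, or `NULL` for no coupling) and `p_shared`
#'   (shared-event probability in \[0, 1\]). Cells in the same connected
#'   component of `adjacency` share an event clock.
#' @param kernel transient shape: `"gaussian"` (symmetric, closed-form FWHM;
#'   default) or `"biexp"` (asymmetric rise/decay with matched FWHM).
#' @param seed integer RNG seed; identical spec + seed gives identical output.
#' @return object of class `trace_population_spec`.
#' @export
trace_population_spec <- function(n_cells,
                                  duration_s,
                                  rate_hz = 20,
                                  halfwidth_dist = c(4.0, 0.3),
                                  iei_dist = c(30, 0.4),
                                  amplitude_snr = 8,
                                  noise_sd = 1,
                                  baseline = 100,
                                  bleach_tau_s = Inf,
                                  coupling = list(adjacency = NULL, p_shared = 0),
                                  kernel = c("gaussian", "biexp"),
                                  seed = 1L) {
  kernel <- match.arg(kernel)
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 1)
    stop_field("n_cells", "must be a single number >= 1")
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop_field("duration_s", "must be > 0")
  if (!is.numeric(rate_hz) || rate_hz <= 0)
    stop_field("rate_hz", "must be > 0")
  if (length(halfwidth_dist) != 2L || halfwidth_dist[1] <= 0 || halfwidth_dist[2] < 0)
    stop_field("halfwidth_dist", "must be (median_s > 0, dispersion >= 0)")
  if (length(iei_dist) != 2L || iei_dist[1] <= 0 || iei_dist[2] < 0)
    stop_field("iei_dist", "must be (median_s > 0, dispersion >= 0)")
  if (!is.numeric(amplitude_snr) || amplitude_snr < 0)
    stop_field("amplitude_snr", "must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_field("noise_sd", "must be >= 0")
  if (!is.numeric(baseline) || baseline <= 0)
    stop_field("baseline", "must be > 0")
  if (!is.numeric(bleach_tau_s) || bleach_tau_s <= 0)
    stop_field("bleach_tau_s", "must be > 0 (Inf for none)")
  p <- coupling$p_shared %||% 0
  if (!is.numeric(p) || p < 0 || p > 1)
    stop_field("coupling$p_shared", "must be in [0, 1]")
  adj <- coupling$adjacency
  if (!is.null(adj)) {
    adj <- matrix(as.logical(adj), nrow(adj), ncol(adj))
    if (nrow(adj) != n_cells || ncol(adj) != n_cells)
      stop_field("coupling$adjacency", "must be n_cells x n_cells")
    if (!isTRUE(all(adj == t(adj))))
      stop_field("coupling$adjacency", "must be symmetric")
    if (any(diag(adj)))
      stop_field("coupling$adjacency", "must have no self-edges")
  }
  structure(list(
    n_cells = as.integer(n_cells), duration_s = duration_s, rate_hz = rate_hz,
    halfwidth_dist = as.numeric(halfwidth_dist), iei_dist = as.numeric(iei_dist),
    amplitude_snr = amplitude_snr, noise_sd = noise_sd, baseline = baseline,
    bleach_tau_s = bleach_tau_s,
    coupling = list(adjacency = adj, p_shared = p),
    kernel = kernel, seed = as.integer(seed)
  ), class = "trace_population_spec")
}

# renewal event train on (0, duration]: log-normal IEIs, uniform phase offset
renewal_train <- function(duration_s, median_s, sdlog) {
  meanlog <- log(median_s)
  times <- numeric(0)
  t0 <- stats::runif(1, 0, median_s)
  tcur <- t0
  repeat {
    k <- max(8L, ceiling((duration_s - tcur) / median_s * 2) + 8L)
    draws <- stats::rlnorm(k, meanlog, sdlog)
    times <- c(times, tcur + cumsum(c(0, draws)))
    tcur <- times[length(times)]
    if (tcur > duration_s) break
  }
  times[times <= duration_s]
}

# transient kernel with unit peak and exact FWHM
transient_shape <- function(t, mid, fwhm, kernel) {
  if (kernel == "gaussian") {
    exp(-4 * log(2) * (t - mid)^2 / fwhm^2)
  } else {
    # bi-exponential rise/decay; decay constant solved so the FWHM matches
    tau_r <- fwhm / 8
    f <- function(td) {
      tp <- log(td / tau_r) * td * tau_r / (td - tau_r)
      h <- function(x) (exp(-x / td) - exp(-x / tau_r))
      pk <- h(tp)
      lo <- stats::uniroot(function(x) h(x) - pk / 2, c(0, tp))$root
      hi <- stats::uniroot(function(x) h(x) - pk / 2, c(tp, tp + 60 * td))$root
      (hi - lo) - fwhm
    }
    td <- stats::uniroot(f, c(tau_r * 1.05, fwhm * 20))$root
    tp <- log(td / tau_r) * td * tau_r / (td - tau_r)
    x <- t - (mid - tp)  # centre the peak near mid
    pk <- exp(-tp / td) - exp(-tp / tau_r)
    out <- numeric(length(t))
    pos <- x > 0
    out[pos] <- (exp(-x[pos] / td) - exp(-x[pos] / tau_r)) / pk
    out
  }
}

#' Simulate a coupled population of oscillatory Ca2+ traces
#'
#' Each trace is `baseline * bleach(t) * (1 + sum of transients) + noise`.
#' Coupled cells (same connected component of the coupling adjacency) adopt
#' events of a shared renewal "islet clock" with probability `p_shared`
#' (with shared kinetics, so co-fired events are identical in time and
#' shape), and keep their own independent events with probability
#' `1 - p_shared`.
#'
#' @param spec a [trace_population_spec()].
#' @return list with elements `traces` (a `trace_set`: matrix of `n_t` rows x
#'   `n_cells` columns plus `rate_hz`) and `truth` (ground truth: data frame
#'   of planted events with `cell_id`, `onset_s`, `midtime_s`, `fwhm_s`,
#'   `amplitude` in noise-sigma units; `adjacency`; `bleach` curve matrix).
#' @export
simulate_traces <- function(spec) {
  stopifnot(inherits(spec, "trace_population_spec"))
  with_seed(spec$seed, {
    n_t <- round(spec$duration_s * spec$rate_hz)
    t <- (seq_len(n_t) - 1L) / spec$rate_hz
    K <- spec$n_cells
    # relative transient amplitude; an explicit override lets callers keep
    # the planted amplitude while silencing trace-level noise (movie path)
    a_rel <- spec$amplitude_rel %||%
      (spec$amplitude_snr * spec$noise_sd / spec$baseline)

    # connected components of the coupling adjacency define shared clocks
    comp <- seq_len(K)
    p <- spec$coupling$p_shared
    if (!is.null(spec$coupling$adjacency) && p > 0) {
      g <- igraph::graph_from_adjacency_matrix(spec$coupling$adjacency,
                                               mode = "undirected")
      comp <- igraph::components(g)$membership
    }
    clocks <- list()
    for (cid in unique(comp)) {
      members <- which(comp == cid)
      if (length(members) > 1L && p > 0) {
        tt <- renewal_train(spec$duration_s, spec$iei_dist[1], spec$iei_dist[2])
        # all-or-none co-firing: a clock event fires in every member of the
        # component with probability p (with shared kinetics), so coupled
        # pairs co-fire with exactly the stated shared-event probability
        clocks[[as.character(cid)]] <- data.frame(
          midtime_s = tt,
          fwhm_s = stats::rlnorm(length(tt), log(spec$halfwidth_dist[1]),
                                 spec$halfwidth_dist[2]),
          co_fire = stats::runif(length(tt)) < p
        )
      }
    }

    ev_list <- vector("list", K)
    for (k in seq_len(K)) {
      own <- renewal_train(spec$duration_s, spec$iei_dist[1], spec$iei_dist[2])
      own_f <- stats::rlnorm(length(own), log(spec$halfwidth_dist[1]),
                             spec$halfwidth_dist[2])
      keep_own <- stats::runif(length(own)) < (1 - p)
      ev <- data.frame(midtime_s = own[keep_own], fwhm_s = own_f[keep_own])
      ck <- clocks[[as.character(comp[k])]]
      if (!is.null(ck) && nrow(ck)) {
        ev <- rbind(ev, ck[ck$co_fire, c("midtime_s", "fwhm_s"), drop = FALSE])
      }
      ev <- ev[order(ev$midtime_s), , drop = FALSE]
      ev$cell_id <- k
      ev_list[[k]] <- ev
    }
    events <- do.call(rbind, ev_list)
    events$amplitude <- spec$amplitude_snr
    events$onset_s <- events$midtime_s - events$fwhm_s / 2
    rownames(events) <- NULL
    events <- events[, c("cell_id", "onset_s", "midtime_s", "fwhm_s", "amplitude")]

    bleach <- if (is.finite(spec$bleach_tau_s)) exp(-t / spec$bleach_tau_s) else rep(1, n_t)
    values <- matrix(0, n_t, K)
    for (k in seq_len(K)) {
      sig <- numeric(n_t)
      ev <- events[events$cell_id == k, , drop = FALSE]
      for (i in seq_len(nrow(ev))) {
        f <- ev$fwhm_s[i]; m <- ev$midtime_s[i]
        span <- t >= m - 4 * f & t <= m + 4 * f
        sig[span] <- sig[span] + a_rel * transient_shape(t[span], m, f, spec$kernel)
      }
      values[, k] <- spec$baseline * bleach * (1 + sig) +
        stats::rnorm(n_t, 0, spec$noise_sd)
    }
    traces <- trace_set(values, spec$rate_hz)
    truth <- list(events = events,
                  adjacency = spec$coupling$adjacency,
                  bleach = matrix(bleach, n_t, K),
                  baseline = spec$baseline)
    list(traces = traces, truth = truth)
  })
}

#' Construct a trace set
#'
#' @param values numeric matrix, one column per ROI/cell, one row per frame.
#' @param rate_hz sampling rate (frames/second).
#' @param roi_ids optional integer ROI identifiers (default `1:K`).
#' @return object of class `trace_set`.
#' @export
trace_set <- function(values, rate_hz, roi_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be > 0")
  roi_ids <- roi_ids %||% seq_len(ncol(values))
  if (length(roi_ids) != ncol(values)) stop("roi_ids length must match columns")
  colnames(values) <- roi_ids
  structure(list(values = values, rate_hz = rate_hz,
                 roi_ids = as.integer(roi_ids)),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d ROIs x %d frames @ %g Hz (%.1f s)\n",
              ncol(x$values), nrow(x$values), x$rate_hz,
              nrow(x$values) / x$rate_hz))
  invisible(x)
}
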