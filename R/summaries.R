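#' Construct a protocol timeline
#'
#' Ordered treatment intervals over recording time. Intervals are half-open
#' `[start_s, end_s)`, must not overlap, and carry a condition label such as
#' `"6 mM glucose"` or `"8 mM + 1 nM Epi"`.
#'
#' @param start_s,end_s numeric interval bounds in seconds (`start_s < end_s`).
#' @param condition character condition labels, unique per interval.
#' @return data frame of class `protocol_timeline`, ordered by `start_s`.
#' @export
protocol_timeline <- function(start_s, end_s, condition) {
  stopifnot(length(start_s) == length(end_s),
            length(start_s) == length(condition))
  if (any(start_s >= end_s)) stop("each interval needs start_s < end_s")
  tl <- data.frame(start_s = start_s, end_s = end_s,
                   condition = as.character(condition))
  tl <- tl[order(tl$start_s), ]
  if (nrow(tl) > 1L && any(tl$start_s[-1L] < tl$end_s[-nrow(tl)]))
    stop("timeline intervals must not overlap")
  if (anyDuplicated(tl$condition)) stop("condition labels must be unique")
  rownames(tl) <- NULL
  class(tl) <- c("protocol_timeline", "data.frame")
  tl
}

#' Read a protocol timeline from JSON
#'
#' Expects a JSON array of objects with `start_s`, `end_s`, `condition`.
#' @param path file path.
#' @return a [protocol_timeline()].
#' @export
read_timeline <- function(path) {
  x <- jsonlite::fromJSON(path)
  protocol_timeline(x$start_s, x$end_s, x$condition)
}

#' Label events with their protocol condition
#'
#' Each event is assigned the condition of the half-open interval
#' `[start_s, end_s)` containing its midtime; events falling in gaps or
#' beyond the timeline are labelled `"unassigned"`.
#'
#' @param events event table with a `midtime_s` column.
#' @param timeline a [protocol_timeline()].
#' @return the event table with an added `condition` column.
#' @export
assign_condition <- function(events, timeline) {
  stopifnot(inherits(timeline, "protocol_timeline"))
  cond <- rep("unassigned", nrow(events))
  for (i in seq_len(nrow(timeline))) {
    hit <- events$midtime_s >= timeline$start_s[i] &
           events$midtime_s < timeline$end_s[i]
    cond[hit] <- timeline$condition[i]
  }
  events$condition <- cond
  events
}

#' Gaussian kernel density estimate with a bandwidth factor
#'
#' Bandwidth is `factor * sd(values)` (the scalar bandwidth-factor
#' convention, where the factor replaces the rule-of-thumb multiplier).
#' The curve is renormalized so its trapezoidal integral over the grid is 1.
#'
#' @param values numeric observations (n >= 2, non-zero variance).
#' @param factor bandwidth factor (default 0.2).
#' @param grid evaluation grid; defaults to 512 points spanning the data
#'   range padded by 3 bandwidths.
#' @return object of class `kde_curve`: `grid`, `density`, `bandwidth`,
#'   `factor`, `n`.
#' @export
kde <- function(values, factor = 0.2, grid = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("kde requires at least 2 observations")
  s <- stats::sd(values)
  if (s <= 0) stop("kde requires non-zero variance")
  h <- factor * s
  if (is.null(grid))
    grid <- seq(min(values) - 3 * h, max(values) + 3 * h, length.out = 512L)
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, values, h)), numeric(1))
  area <- trapz(grid, dens)
  structure(list(grid = grid, density = dens / area, bandwidth = h,
                 factor = factor, n = length(values)),
            class = "kde_curve")
}

#' Pointwise difference of two KDE curves on a shared grid
#'
#' @param curve_a,curve_b [kde()] results on identical grids.
#' @return object of class `kde_curve_diff`: `grid`, `density` (a - b).
#' @export
kde_difference <- function(curve_a, curve_b) {
  stopifnot(inherits(curve_a, "kde_curve"), inherits(curve_b, "kde_curve"))
  if (length(curve_a$grid) != length(curve_b$grid) ||
      any(abs(curve_a$grid - curve_b$grid) > 1e-12))
    stop("KDE curves must share an identical grid")
  structure(list(grid = curve_a$grid,
                 density = curve_a$density - curve_b$density),
            class = "kde_curve_diff")
}

#' Per-condition medians of event kinetics
#'
#' Pools events per condition and reports the median halfwidth and median
#' inter-event interval plus counts. Inter-event intervals are computed
#' within each ROI between consecutive events and assigned to the condition
#' of the *earlier* event's midtime; intervals whose two events lie in
#' different conditions are discarded (they straddle a solution change).
#' Even-sized medians use the mean of the central pair.
#'
#' @param events labelled event table from [assign_condition()].
#' @param per_roi if `TRUE`, medians of per-ROI medians instead of pooling
#'   observations across ROIs (default `FALSE`: pooled).
#' @return data frame with `condition`, `median_halfwidth_s`,
#'   `median_iei_s`, `n_events`, `n_iei`.
#' @export
condition_medians <- function(events, per_roi = FALSE) {
  stopifnot("condition" %in% names(events))
  conds <- unique(events$condition)
  iei_df <- do.call(rbind, lapply(split(events, events$roi_id), function(ev) {
    ev <- ev[order(ev$midtime_s), , drop = FALSE]
    if (nrow(ev) < 2L) return(NULL)
    data.frame(roi_id = ev$roi_id[-nrow(ev)],
               iei_s = diff(ev$midtime_s),
               condition = ev$condition[-nrow(ev)],
               same = ev$condition[-nrow(ev)] == ev$condition[-1L])
  }))
  if (!is.null(iei_df)) iei_df <- iei_df[iei_df$same, , drop = FALSE]
  out <- do.call(rbind, lapply(conds, function(cn) {
    hw <- events$halfwidth_s[events$condition == cn]
    hw_roi <- events$roi_id[events$condition == cn]
    ii <- if (is.null(iei_df)) numeric(0) else iei_df$iei_s[iei_df$condition == cn]
    ii_roi <- if (is.null(iei_df)) integer(0) else iei_df$roi_id[iei_df$condition == cn]
    med <- function(v, g) {
      if (!length(v)) return(NA_real_)
      if (per_roi) stats::median(vapply(split(v, g), stats::median, numeric(1)))
      else stats::median(v)
    }
    data.frame(condition = cn,
               median_halfwidth_s = med(hw, hw_roi),
               median_iei_s = med(ii, ii_roi),
               n_events = length(hw), n_iei = length(ii))
  }))
  rownames(out) <- NULL
  out
}

# exact two-sided Mann-Whitney p by enumeration of all group labelings,
# average ranks for ties; used for small samples
mwu_exact <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2L, function(ix) sum(rk[ix]) - na * (na + 1) / 2)
  eps <- 1e-9
  p <- 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps))
  list(u = u_obs, p = min(1, p))
}

#' Two-sample comparison (Mann-Whitney U, Student's t, or Kolmogorov-Smirnov)
#'
#' The Mann-Whitney U test uses exact enumeration over all group labelings
#' (with average ranks for ties) when `choose(n_a + n_b, n_a) <= 50000`, and
#' the normal approximation with continuity correction otherwise. The t test
#' is Student's (pooled variance); the KS test is the two-sample test with
#' asymptotic p-value. All tests are two-sided.
#'
#' @param sample_a,sample_b numeric samples.
#' @param test one of `"mwu"`, `"t"`, `"ks"`.
#' @return object of class `group_comparison`: `test`, `statistic` (U, t or
#'   D), `p_value`, `n_a`, `n_b`.
#' @export
compare_groups <- function(sample_a, sample_b, test = c("mwu", "t", "ks")) {
  test <- match.arg(test)
  na <- length(sample_a); nb <- length(sample_b)
  if (na < 1L || nb < 1L) stop("both samples must be non-empty")
  res <- switch(test,
    mwu = {
      if (choose(na + nb, na) <= 5e4) {
        r <- mwu_exact(sample_a, sample_b)
        list(statistic = r$u, p_value = r$p)
      } else {
        w <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                                 exact = FALSE, correct = TRUE))
        list(statistic = unname(w$statistic), p_value = w$p.value)
      }
    },
    t = {
      if (na < 3L || nb < 3L) stop("t test requires n >= 3 per group")
      tt <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
      list(statistic = unname(tt$statistic), p_value = tt$p.value)
    },
    ks = {
      k <- suppressWarnings(stats::ks.test(sample_a, sample_b,
                                           exact = FALSE))
      list(statistic = unname(k$statistic), p_value = k$p.value)
    })
  structure(list(test = test, statistic = res$statistic,
                 p_value = res$p_value, n_a = na, n_b = nb),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4g, p = %.4g (n = %d vs %d)\n",
              toupper(x$test), x$statistic, x$p_value, x$n_a, x$n_b))
  invisible(x)
}
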