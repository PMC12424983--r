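#' Pairwise zero-lag correlation matrix of ROI traces
#'
#' Zero-lag Pearson correlation of (optionally de-bleached) traces,
#' restricted to a time window, e.g. one protocol condition. The threshold
#' note "0.7 explains ~50% (R^2 > 0.49)" only makes sense for a correlation
#' coefficient, hence zero-lag Pearson rather than a lagged
#' cross-correlogram; `max_lag_s` enables a max-over-lags variant.
#'
#' @param traces a [trace_set()] with >= 2 ROIs.
#' @param window optional `c(start_s, end_s)`; default is the whole trace.
#'   Must span at least 30 s.
#' @param debleach de-bleach traces before correlating (default `TRUE`).
#' @param max_lag_s if > 0, entry (i, j) is the maximum correlation over
#'   integer-frame lags within `+/- max_lag_s` (default 0 = zero lag only).
#' @return object of class `correlation_matrix`: `values` (K x K, unit
#'   diagonal), `window`. Zero-variance traces get zero rows/columns with a
#'   warning.
#' @export
correlation_matrix <- function(traces, window = NULL, debleach = TRUE,
                               max_lag_s = 0) {
  stopifnot(inherits(traces, "trace_set"))
  K <- ncol(traces$values)
  if (K < 2L) stop("need at least 2 ROIs")
  n <- nrow(traces$values)
  t <- (seq_len(n) - 1L) / traces$rate_hz
  window <- window %||% c(0, n / traces$rate_hz)
  sel <- t >= window[1] & t < window[2]
  if (sum(sel) < 30 * traces$rate_hz)
    stop("window must span at least 30 s of samples")
  v <- traces$values[sel, , drop = FALSE]
  if (debleach)
    v <- vapply(seq_len(K), function(k)
      debleach(v[, k], traces$rate_hz)$values, numeric(nrow(v)))
  sds <- apply(v, 2L, stats::sd)
  flat <- which(sds == 0)
  if (length(flat))
    warning(sprintf("zero-variance trace(s) in window: %s; correlations set to 0",
                    paste(traces$roi_ids[flat], collapse = ", ")))
  if (max_lag_s > 0) {
    L <- as.integer(round(max_lag_s * traces$rate_hz))
    cm <- diag(1, K)
    for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
      best <- -1
      for (l in -L:L) {
        a <- v[max(1, 1 + l):min(nrow(v), nrow(v) + l), i]
        b <- v[max(1, 1 - l):min(nrow(v), nrow(v) - l), j]
        if (stats::sd(a) > 0 && stats::sd(b) > 0)
          best <- max(best, stats::cor(a, b))
      }
      cm[i, j] <- cm[j, i] <- best
    }
  } else {
    cm <- suppressWarnings(stats::cor(v))
  }
  cm[!is.finite(cm)] <- 0
  if (length(flat)) { cm[flat, ] <- 0; cm[, flat] <- 0 }
  diag(cm) <- 1
  dimnames(cm) <- list(traces$roi_ids, traces$roi_ids)
  structure(list(values = cm, window = window),
            class = "correlation_matrix")
}

#' Build an unweighted, undirected functional network
#'
#' Nodes are ROIs; an edge connects i and j (i != j) when their correlation
#' is at least the threshold (inclusive `>=`).
#'
#' @param corr a [correlation_matrix()] or a plain symmetric matrix.
#' @param threshold correlation threshold (default 0.7).
#' @return object of class `functional_network`: `nodes`, `adjacency`
#'   (logical), `edges` (two-column matrix), `threshold`.
#' @export
build_network <- function(corr, threshold = 0.7) {
  cm <- if (inherits(corr, "correlation_matrix")) corr$values else as.matrix(corr)
  K <- nrow(cm)
  adj <- cm >= threshold
  diag(adj) <- FALSE
  adj <- adj | t(adj)  # guard symmetry for near-threshold asymmetries
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  nodes <- rownames(cm) %||% as.character(seq_len(K))
  structure(list(nodes = nodes, adjacency = adj,
                 edges = cbind(from = idx[, 1], to = idx[, 2]),
                 threshold = threshold),
            class = "functional_network")
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("<functional_network> %d nodes, %d edges (threshold %g)\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Summary metrics of a functional network
#'
#' Mean node degree `2|E|/K`, average local clustering coefficient (0 for
#' nodes of degree < 2), and global efficiency (mean over distinct node
#' pairs of the inverse shortest-path length; disconnected pairs
#' contribute 0).
#'
#' @param net a [build_network()] result.
#' @return list with `mean_node_degree`, `average_clustering`,
#'   `mean_efficiency`.
#' @export
network_metrics <- function(net) {
  stopifnot(inherits(net, "functional_network"))
  K <- length(net$nodes)
  if (K < 1L) stop("network has no nodes")
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
  mean_degree <- mean(igraph::degree(g))
  clust <- if (igraph::ecount(g) == 0L) 0 else
    mean(igraph::transitivity(g, type = "local", isolates = "zero"))
  eff <- if (K < 2L) 0 else igraph::global_efficiency(g)
  if (!is.finite(eff)) eff <- 0
  list(mean_node_degree = mean_degree,
       average_clustering = clust,
       mean_efficiency = eff)
}

#' Write a functional network to GraphML and an edge-list CSV
#'
#' @param net a [build_network()] result.
#' @param graphml_path,edges_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_network <- function(net, graphml_path = NULL, edges_path = NULL) {
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
  igraph::V(g)$name <- as.character(net$nodes)
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(edges_path))
    utils::write.csv(data.frame(from = net$nodes[net$edges[, 1]],
                                to = net$nodes[net$edges[, 2]]),
                     edges_path, row.names = FALSE)
  invisible(c(graphml_path, edges_path))
}
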