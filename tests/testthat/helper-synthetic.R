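# Shared helpers: event matching against planted ground truth, a brute-force
# graph-metric oracle, and small canned layouts.

# match detected events to planted events by midtime proximity;
# returns recall and the FWHM absolute errors of the matched pairs
match_events <- function(detected, truth) {
  hits <- 0L
  errs <- numeric(0)
  for (i in seq_len(nrow(truth))) {
    if (!nrow(detected)) break
    j <- which.min(abs(detected$midtime_s - truth$midtime_s[i]))
    if (abs(detected$midtime_s[j] - truth$midtime_s[i]) < truth$fwhm_s[i]) {
      hits <- hits + 1L
      errs <- c(errs, abs(detected$halfwidth_s[j] - truth$fwhm_s[i]))
    }
  }
  list(recall = hits / max(1L, nrow(truth)), fwhm_abs_err = errs)
}

# brute-force network metrics: direct degree sum, triangle counting per
# node, and all-pairs BFS for shortest paths
graph_metrics_oracle <- function(adj) {
  K <- nrow(adj)
  deg <- rowSums(adj)
  clust <- vapply(seq_len(K), function(v) {
    nb <- which(adj[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0L
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (adj[nb[a], nb[b]]) tri <- tri + 1L
    2 * tri / (k * (k - 1))
  }, numeric(1))
  eff <- 0
  if (K >= 2) {
    tot <- 0
    for (s in seq_len(K)) {
      dist <- rep(Inf, K); dist[s] <- 0
      frontier <- s
      while (length(frontier)) {
        nxt <- integer(0)
        for (v in frontier) {
          for (w in which(adj[v, ])) if (dist[w] == Inf) {
            dist[w] <- dist[v] + 1; nxt <- c(nxt, w)
          }
        }
        frontier <- nxt
      }
      tot <- tot + sum(1 / dist[-s][is.finite(dist[-s])])
    }
    eff <- tot / (K * (K - 1))
  }
  list(mean_node_degree = mean(deg),
       average_clustering = mean(clust),
       mean_efficiency = eff)
}

random_adjacency <- function(K, p, seed) {
  set.seed(seed)
  adj <- matrix(FALSE, K, K)
  adj[upper.tri(adj)] <- runif(K * (K - 1) / 2) < p
  adj | t(adj)
}

# standard six-cell disk layout inside a 48 x 48 frame
six_cell_layout <- function() {
  cell_layout(expand.grid(row = c(12, 36), col = c(8, 24, 40))[, c(1, 2)],
              radius_px = 5)
}

full_coupling <- function(K) {
  a <- matrix(TRUE, K, K); diag(a) <- FALSE; a
}
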