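# Internal helpers shared across modules.

#' Evaluate code with a temporarily fixed RNG state
#'
#' Restores the caller's `.Random.seed` afterwards so generators are
#' reproducible without perturbing the session RNG stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Gaussian smoothing of a 1-D signal (reflect padding, FFT convolution)
#' @param x numeric vector
#' @param sigma kernel standard deviation in samples
#' @noRd
gauss_smooth <- function(x, sigma) {
  n <- length(x)
  if (sigma <= 0.25 || n < 3L) return(x)
  r <- min(n - 1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma)
  k <- k / sum(k)
  xp <- c(rev(x[seq_len(r)]), x, rev(x[seq.int(n - r + 1L, n)]))
  full <- stats::convolve(xp, rev(k), type = "open")
  full[seq.int(2L * r + 1L, 2L * r + n)]
}

#' Trapezoidal integral
#' @noRd
trapz <- function(x, y) {
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

#' Connected-component labelling of a logical matrix
#'
#' Breadth-first flood fill; `connectivity` 4 or 8. Labels are assigned in
#' column-major scan order of the first pixel encountered.
#' @noRd
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  remaining <- mask
  if (connectivity == 8L) {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  cur <- 0L
  fg <- which(remaining)
  for (seed in fg) {
    if (!remaining[seed]) next
    cur <- cur + 1L
    lab[seed] <- cur
    remaining[seed] <- FALSE
    frontier <- seed
    while (length(frontier)) {
      r0 <- (frontier - 1L) %% nr + 1L
      c0 <- (frontier - 1L) %/% nr + 1L
      nb <- integer(0)
      for (j in seq_along(dr)) {
        r2 <- r0 + dr[j]; c2 <- c0 + dc[j]
        ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
        if (any(ok)) nb <- c(nb, (c2[ok] - 1L) * nr + r2[ok])
      }
      nb <- unique(nb[remaining[nb]])
      if (length(nb)) {
        lab[nb] <- cur
        remaining[nb] <- FALSE
      }
      frontier <- nb
    }
  }
  lab
}

#' Perimeter pixels of a binary mask (pixel with >= 1 of its 4-neighbours
#' outside the mask, image border counts as outside)
#' @noRd
perimeter_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  up    <- pad[1:nr, 2:(nc + 1L)]
  down  <- pad[3:(nr + 2L), 2:(nc + 1L)]
  left  <- pad[2:(nr + 1L), 1:nc]
  right <- pad[2:(nr + 1L), 3:(nc + 2L)]
  core & !(up & down & left & right)
}

#' Relabel a label matrix so labels run 1..K in row-major centroid order
#' @noRd
relabel_row_major <- function(lab) {
  ids <- sort(unique(lab[lab > 0L]))
  if (!length(ids)) return(lab)
  nr <- nrow(lab)
  idx <- which(lab > 0L)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  l <- lab[idx]
  cr <- tapply(rr, l, mean)
  ccol <- tapply(cc, l, mean)
  ord <- order(cr, ccol)
  map <- integer(max(ids))
  map[as.integer(names(cr))[ord]] <- seq_along(ord)
  out <- lab
  out[idx] <- map[l]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, why) {
  stop(sprintf("invalid field '%s': %s", field, why), call. = FALSE)
}
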