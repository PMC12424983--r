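#' Specification of a synthetic mitochondria/ER mask layout
#'
#' Mitochondria are axis-aligned rectangles; each ER rectangle is attached to
#' one mitochondrion on its left or right side at a known pixel gap and
#' facing length, so contact geometry (perimeter, contact run length,
#' coupled/uncoupled state under the 10 nm proximity / >=10 nm length / >5%
#' perimeter rules) is known analytically.
#'
#' @param canvas_px canvas size `c(rows, cols)` in pixels.
#' @param nm_per_px physical pixel size in nm (default 5, the SEM resolution
#'   this emulates).
#' @param mito data frame with one row per mitochondrion: `row`, `col`
#'   (top-left corner), `height`, `width` in px (each >= 2).
#' @param er data frame with one row per ER rectangle: `mito_id` (index into
#'   `mito`), `side` (`"left"` or `"right"`), `gap_px` (empty columns between
#'   the organelles, >= 1), `offset_rows` (start row offset of the ER within
#'   the mitochondrion's row span, >= 0), `len_rows` (facing length in rows),
#'   `width` (ER width in px). May have zero rows (no ER).
#' @param seed integer seed (recorded for provenance; the layout itself is
#'   deterministic).
#' @return object of class `mask_layout_spec`.
#' @seealso [random_mask_layout()] to draw a randomized layout.
#' @export
mask_layout_spec <- function(canvas_px, nm_per_px = 5, mito, er = NULL, seed = 1L) {
  if (!is.numeric(nm_per_px) || nm_per_px <= 0)
    stop_field("nm_per_px", "must be > 0")
  mito <- as.data.frame(mito)
  if (!nrow(mito)) stop_field("mito", "need at least one mitochondrion")
  if (any(mito$height < 2) || any(mito$width < 2))
    stop_field("mito", "rectangles must be at least 2x2 px")
  if (is.null(er)) er <- data.frame(mito_id = integer(), side = character(),
                                    gap_px = integer(), offset_rows = integer(),
                                    len_rows = integer(), width = integer())
  er <- as.data.frame(er)
  if (nrow(er)) {
    if (any(er$gap_px < 1)) stop_field("er$gap_px", "must be >= 1 (disjoint masks)")
    if (any(!er$side %in% c("left", "right"))) stop_field("er$side", "left or right")
    if (any(er$mito_id < 1 | er$mito_id > nrow(mito)))
      stop_field("er$mito_id", "out of range")
    h <- mito$height[er$mito_id]
    if (any(er$offset_rows < 0 | er$offset_rows + er$len_rows > h))
      stop_field("er", "facing span must lie within the mitochondrion rows")
    if (any(er$len_rows < 1) || any(er$width < 1))
      stop_field("er", "len_rows and width must be >= 1")
  }
  structure(list(canvas_px = as.integer(canvas_px), nm_per_px = nm_per_px,
                 mito = mito, er = er, seed = as.integer(seed)),
            class = "mask_layout_spec")
}

#' Draw a randomized organelle mask layout
#'
#' Mitochondria are placed on a grid of well-separated slots; ER rectangles
#' are attached at random gaps (1-3 px) and facing lengths, producing a mix
#' of qualifying contacts, sub-threshold (too-distant or too-short) contacts,
#' and ER-free mitochondria.
#'
#' @param n_mito number of mitochondria.
#' @param nm_per_px pixel size in nm.
#' @param seed integer RNG seed.
#' @return a [mask_layout_spec()].
#' @export
random_mask_layout <- function(n_mito = 9, nm_per_px = 5, seed = 1L) {
  with_seed(seed, {
    g <- ceiling(sqrt(n_mito))
    slot <- 28L
    canvas <- c(g * slot + 4L, g * slot + 4L)
    mito <- data.frame(row = integer(), col = integer(),
                       height = integer(), width = integer())
    er <- data.frame(mito_id = integer(), side = character(),
                     gap_px = integer(), offset_rows = integer(),
                     len_rows = integer(), width = integer())
    for (i in seq_len(n_mito)) {
      sr <- ((i - 1L) %/% g) * slot + 4L
      sc <- ((i - 1L) %% g) * slot + 8L
      h <- sample(4:9, 1L); w <- sample(4:8, 1L)
      mito <- rbind(mito, data.frame(row = sr + sample(0:2, 1L),
                                     col = sc + sample(0:2, 1L),
                                     height = h, width = w))
      for (side in c("right", "left")) {
        p_attach <- if (side == "right") 0.8 else 0.25
        if (stats::runif(1) < p_attach) {
          len <- sample(seq_len(h), 1L)
          er <- rbind(er, data.frame(
            mito_id = i, side = side,
            gap_px = sample(1:3, 1L, prob = c(0.5, 0.25, 0.25)),
            offset_rows = sample(0:(h - len), 1L),
            len_rows = len, width = sample(2:4, 1L)))
        }
      }
    }
    mask_layout_spec(canvas, nm_per_px, mito, er, seed = seed)
  })
}

#' Render an organelle mask layout and compute its analytic contact truth
#'
#' The ground-truth table applies the membrane-contact rules in closed form
#' from the layout geometry (centre-to-centre proximity `<= max_gap_nm`,
#' contact-site length `>= min_len_nm`, coupled when qualifying contact
#' pixels exceed `coupled_fraction` of the perimeter), independently of the
#' pixel-scanning measurement pipeline.
#'
#' @param spec a [mask_layout_spec()].
#' @param max_gap_nm proximity criterion in nm (default 10, inclusive).
#' @param min_len_nm minimum contact-site length in nm (default 10).
#' @param coupled_fraction perimeter fraction above which a mitochondrion is
#'   ER-coupled (default 0.05, strict inequality).
#' @return list with `mito_mask`, `er_mask` (logical matrices), `nm_per_px`,
#'   and `truth`: per-mitochondrion data frame (`mito_id`, `center_row`,
#'   `center_col`, `perimeter_px`, `contact_px`, `contact_fraction`,
#'   `n_sites`, `coupled`) sorted in row-major centroid order.
#' @export
simulate_organelle_masks <- function(spec, max_gap_nm = 10, min_len_nm = 10,
                                     coupled_fraction = 0.05) {
  stopifnot(inherits(spec, "mask_layout_spec"))
  nr <- spec$canvas_px[1]; nc <- spec$canvas_px[2]
  mito_mask <- matrix(FALSE, nr, nc)
  er_mask <- matrix(FALSE, nr, nc)
  paint <- function(mask, r0, c0, h, w, other) {
    if (r0 < 1 || c0 < 1 || r0 + h - 1 > nr || c0 + w - 1 > nc)
      stop("layout exceeds canvas")
    rows <- r0:(r0 + h - 1); cols <- c0:(c0 + w - 1)
    if (any(mask[rows, cols]) || any(other[rows, cols]))
      stop("overlapping organelles in layout")
    mask[rows, cols] <- TRUE
    mask
  }
  m <- spec$mito
  for (i in seq_len(nrow(m)))
    mito_mask <- paint(mito_mask, m$row[i], m$col[i], m$height[i], m$width[i], er_mask)
  e <- spec$er
  for (j in seq_len(nrow(e))) {
    i <- e$mito_id[j]
    r0 <- m$row[i] + e$offset_rows[j]
    c0 <- if (e$side[j] == "right") m$col[i] + m$width[i] + e$gap_px[j]
          else m$col[i] - e$gap_px[j] - e$width[j]
    er_mask <- paint(er_mask, r0, c0, e$len_rows[j], e$width[j], mito_mask)
  }

  # analytic truth: facing-side runs at centre distance (gap+1) px
  nm <- spec$nm_per_px
  perim <- 2L * (m$height + m$width) - 4L
  contact_px <- integer(nrow(m))
  n_sites <- integer(nrow(m))
  for (j in seq_len(nrow(e))) {
    i <- e$mito_id[j]
    dist_nm <- (e$gap_px[j] + 1) * nm
    len_nm <- e$len_rows[j] * nm
    if (dist_nm <= max_gap_nm && len_nm >= min_len_nm) {
      contact_px[i] <- contact_px[i] + e$len_rows[j]
      n_sites[i] <- n_sites[i] + 1L
    }
  }
  truth <- data.frame(
    mito_id = seq_len(nrow(m)),
    center_row = m$row + (m$height - 1) / 2,
    center_col = m$col + (m$width - 1) / 2,
    perimeter_px = perim,
    contact_px = contact_px,
    contact_fraction = contact_px / perim,
    n_sites = n_sites
  )
  truth$coupled <- truth$contact_fraction > coupled_fraction
  truth <- truth[order(truth$center_row, truth$center_col), ]
  truth$mito_id <- seq_len(nrow(truth))
  rownames(truth) <- NULL
  list(mito_mask = mito_mask, er_mask = er_mask,
       nm_per_px = nm, truth = truth)
}
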