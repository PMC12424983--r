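#' Mitochondria/ER mask pair
#'
#' @param mito,er logical (or 0/1) matrices of identical shape; the two
#'   masks must be disjoint.
#' @param nm_per_px physical pixel size in nm (default 5).
#' @return object of class `mask_pair`.
#' @export
mask_pair <- function(mito, er, nm_per_px = 5) {
  mito <- matrix(as.logical(mito), nrow(mito), ncol(mito))
  er <- matrix(as.logical(er), nrow(er), ncol(er))
  if (!identical(dim(mito), dim(er))) stop("masks must have identical shapes")
  if (any(mito & er)) stop("mitochondria and ER masks must be disjoint")
  if (nm_per_px <= 0) stop_field("nm_per_px", "must be > 0")
  structure(list(mito = mito, er = er, nm_per_px = nm_per_px),
            class = "mask_pair")
}

# Euclidean distance (in px, centre-to-centre) from every pixel to the
# nearest ER pixel; Inf when the ER mask is empty
distance_to_er <- function(er) {
  if (!any(er)) return(matrix(Inf, nrow(er), ncol(er)))
  dm <- EBImage::distmap(EBImage::Image((!er) * 1), metric = "euclidean")
  matrix(as.numeric(EBImage::imageData(dm)), nrow(er))
}

#' Find mitochondria-ER contact sites
#'
#' A mitochondrion perimeter pixel (a mask pixel with at least one
#' 4-neighbour outside the mask) is "in contact" when any ER pixel lies
#' within `max_gap_nm` of it (Euclidean, centre-to-centre, inclusive).
#' Contact sites are 8-connected runs of in-contact perimeter pixels whose
#' length (pixel count x pixel size) is at least `min_len_nm`.
#'
#' @param pair a [mask_pair()].
#' @param max_gap_nm proximity criterion in nm (default 10, i.e. 2 px at
#'   5 nm resolution).
#' @param min_len_nm minimum site length in nm (default 10).
#' @return list with `sites` (data frame: `site_id`, `mito_id`, `n_px`,
#'   `length_nm`) and `pixels` (data frame of qualifying-site pixels:
#'   `site_id`, `mito_id`, `row`, `col`). Mitochondria are labelled by
#'   8-connected components in row-major centroid order.
#' @export
find_contact_sites <- function(pair, max_gap_nm = 10, min_len_nm = 10) {
  stopifnot(inherits(pair, "mask_pair"))
  empty <- list(sites = data.frame(site_id = integer(), mito_id = integer(),
                                   n_px = integer(), length_nm = numeric()),
                pixels = data.frame(site_id = integer(), mito_id = integer(),
                                    row = integer(), col = integer()))
  if (!any(pair$mito)) return(empty)
  mlab <- relabel_row_major(label_components(pair$mito, 8L))
  perim <- perimeter_mask(pair$mito)
  dist_px <- distance_to_er(pair$er)
  in_contact <- perim & (dist_px * pair$nm_per_px <= max_gap_nm)
  if (!any(in_contact)) return(empty)
  runs <- label_components(in_contact, 8L)
  nr <- nrow(runs)
  sites <- list(); pixels <- list(); sid <- 0L
  for (r in sort(unique(runs[runs > 0L]))) {
    idx <- which(runs == r)
    len_nm <- length(idx) * pair$nm_per_px
    if (len_nm < min_len_nm) next
    sid <- sid + 1L
    mid <- mlab[idx[1]]
    sites[[sid]] <- data.frame(site_id = sid, mito_id = mid,
                               n_px = length(idx), length_nm = len_nm)
    pixels[[sid]] <- data.frame(site_id = sid, mito_id = mid,
                                row = (idx - 1L) %% nr + 1L,
                                col = (idx - 1L) %/% nr + 1L)
  }
  if (!sid) return(empty)
  list(sites = do.call(rbind, sites), pixels = do.call(rbind, pixels))
}

#' Classify mitochondria as ER-coupled or uncoupled
#'
#' A mitochondrion is ER-coupled when more than `coupled_fraction` of its
#' perimeter pixels (strictly) belong to qualifying contact sites.
#'
#' @param pair a [mask_pair()].
#' @param sites result of [find_contact_sites()] on the same pair; computed
#'   if missing.
#' @param coupled_fraction perimeter fraction threshold (default 0.05).
#' @param max_gap_nm,min_len_nm passed to [find_contact_sites()] when
#'   `sites` is missing.
#' @return data frame of class `contact_report`: per mitochondrion `mito_id`,
#'   `center_row`, `center_col`, `perimeter_px`, `contact_px`,
#'   `contact_fraction`, `n_sites`, `coupled`; the population coupled
#'   fraction is in `attr(, "fraction_coupled")`.
#' @export
classify_mitochondria <- function(pair, sites = NULL, coupled_fraction = 0.05,
                                  max_gap_nm = 10, min_len_nm = 10) {
  stopifnot(inherits(pair, "mask_pair"))
  if (is.null(sites)) sites <- find_contact_sites(pair, max_gap_nm, min_len_nm)
  mlab <- relabel_row_major(label_components(pair$mito, 8L))
  K <- max(mlab)
  if (K == 0L) {
    rep0 <- data.frame(mito_id = integer(), center_row = numeric(),
                       center_col = numeric(), perimeter_px = integer(),
                       contact_px = integer(), contact_fraction = numeric(),
                       n_sites = integer(), coupled = logical())
    attr(rep0, "fraction_coupled") <- NA_real_
    class(rep0) <- c("contact_report", "data.frame")
    return(rep0)
  }
  perim <- perimeter_mask(pair$mito)
  nr <- nrow(mlab)
  pidx <- which(perim)
  plab <- mlab[pidx]
  perimeter_px <- as.integer(table(factor(plab, seq_len(K))))
  contact_px <- integer(K)
  n_sites <- integer(K)
  if (nrow(sites$sites)) {
    agg <- tapply(sites$sites$n_px, factor(sites$sites$mito_id, seq_len(K)), sum)
    contact_px <- as.integer(ifelse(is.na(agg), 0L, agg))
    cnt <- table(factor(sites$sites$mito_id, seq_len(K)))
    n_sites <- as.integer(cnt)
  }
  idxs <- which(mlab > 0L)
  cr <- tapply((idxs - 1L) %% nr + 1L, mlab[idxs], mean)
  cc <- tapply((idxs - 1L) %/% nr + 1L, mlab[idxs], mean)
  rep <- data.frame(mito_id = seq_len(K),
                    center_row = as.numeric(cr), center_col = as.numeric(cc),
                    perimeter_px = perimeter_px, contact_px = contact_px,
                    contact_fraction = contact_px / perimeter_px,
                    n_sites = n_sites)
  rep$coupled <- rep$contact_fraction > coupled_fraction
  attr(rep, "fraction_coupled") <- mean(rep$coupled)
  class(rep) <- c("contact_report", "data.frame")
  rep
}

#' Nearest mitochondria-to-ER distance profile
#'
#' For each mitochondrion, the minimum over its perimeter pixels of the
#' Euclidean distance to the nearest ER pixel, in nm, binned into a
#' histogram. With an empty ER mask all distances are infinite and reported
#' as censored.
#'
#' @param pair a [mask_pair()] with a non-empty mitochondria mask.
#' @param bins_nm histogram break points in nm (default
#'   `c(0, 10, 20, 50, Inf)`).
#' @return list with `distances_nm` (per-mitochondrion minima, row-major
#'   centroid order), `counts` (per bin), `breaks_nm`, `n_censored`.
#' @export
nearest_distance_profile <- function(pair, bins_nm = c(0, 10, 20, 50, Inf)) {
  stopifnot(inherits(pair, "mask_pair"))
  if (!any(pair$mito)) stop("mitochondria mask is empty")
  mlab <- relabel_row_major(label_components(pair$mito, 8L))
  perim <- perimeter_mask(pair$mito)
  dist_nm <- distance_to_er(pair$er) * pair$nm_per_px
  pidx <- which(perim)
  d <- tapply(dist_nm[pidx], mlab[pidx], min)
  d <- as.numeric(d[order(as.integer(names(d)))])
  finite <- d[is.finite(d)]
  counts <- if (length(finite))
    as.integer(table(cut(finite, bins_nm, right = FALSE))) else
    integer(length(bins_nm) - 1L)
  list(distances_nm = d, counts = counts, breaks_nm = bins_nm,
       n_censored = sum(!is.finite(d)))
}
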