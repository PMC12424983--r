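two_squares <- function(gap_px) {
  m <- matrix(FALSE, 20, 20); e <- m
  m[5:8, 5:8] <- TRUE
  e[5:8, (9 + gap_px):(12 + gap_px)] <- TRUE
  mask_pair(m, e, nm_per_px = 5)
}

test_that("contact sites follow the 10 nm proximity and 10 nm length rules", {
  s1 <- find_contact_sites(two_squares(1))
  expect_equal(nrow(s1$sites), 1L)
  expect_equal(s1$sites$n_px, 4L)
  expect_equal(s1$sites$length_nm, 20)

  expect_equal(nrow(find_contact_sites(two_squares(3))$sites), 0L)

  # a single in-contact perimeter pixel (5 nm) is below the 10 nm site length
  m <- matrix(FALSE, 20, 20); e <- m
  m[5:8, 5:8] <- TRUE; e[6, 10] <- TRUE
  expect_equal(nrow(find_contact_sites(mask_pair(m, e, 5))$sites), 0L)

  expect_error(mask_pair(matrix(TRUE, 2, 2), matrix(TRUE, 2, 2)), "disjoint")
  expect_equal(nrow(find_contact_sites(
    mask_pair(matrix(FALSE, 5, 5), matrix(FALSE, 5, 5)))$sites), 0L)
})

test_that("coupling classification uses a strict 5% perimeter boundary", {
  r1 <- classify_mitochondria(two_squares(1))
  expect_equal(r1$perimeter_px, 12L)
  expect_equal(r1$contact_px, 4L)
  expect_equal(r1$contact_fraction, 1 / 3)
  expect_true(r1$coupled)

  # 21x21 square: perimeter 80 px; a 4-px site is exactly 5% -> NOT coupled
  m <- matrix(FALSE, 40, 40); e <- m
  m[5:25, 5:25] <- TRUE
  e[10:13, 27:29] <- TRUE              # gap 1 px, facing length 4 px
  r2 <- classify_mitochondria(mask_pair(m, e, 5))
  expect_equal(r2$perimeter_px, 80L)
  expect_equal(r2$contact_fraction, 0.05)
  expect_false(r2$coupled)
  # one more pixel of contact tips it over
  e[10:14, 27:29] <- TRUE
  r3 <- classify_mitochondria(mask_pair(m, e, 5))
  expect_equal(r3$contact_fraction, 5 / 80)
  expect_true(r3$coupled)

  # no ER: all fractions zero, population coupled fraction zero
  r0 <- classify_mitochondria(mask_pair(m, matrix(FALSE, 40, 40), 5))
  expect_equal(r0$contact_fraction, 0)
  expect_equal(attr(r0, "fraction_coupled"), 0)
})

test_that("contact quantification is invariant to rotation and mirroring", {
  gt <- simulate_organelle_masks(random_mask_layout(6, seed = 2))
  base <- classify_mitochondria(mask_pair(gt$mito_mask, gt$er_mask, 5))
  summ <- function(r) list(sum(r$contact_px), sort(r$contact_fraction),
                           sum(r$coupled))
  for (tf in list(function(m) t(m),
                  function(m) m[nrow(m):1, ],
                  function(m) m[, ncol(m):1])) {
    r <- classify_mitochondria(mask_pair(tf(gt$mito_mask), tf(gt$er_mask), 5))
    expect_equal(summ(r), summ(base))
  }
})

test_that("contact fraction is monotone in the proximity criterion", {
  gt <- simulate_organelle_masks(random_mask_layout(8, seed = 4))
  pr <- mask_pair(gt$mito_mask, gt$er_mask, 5)
  prev <- rep(-1, nrow(gt$truth))
  for (gap in c(5, 10, 15, 25)) {
    r <- classify_mitochondria(pr, max_gap_nm = gap)
    expect_true(all(r$contact_fraction >= prev))
    prev <- r$contact_fraction
  }
})

test_that("classification matches the generator's analytic truth on random layouts", {
  for (seed in 1:10) {
    gt <- simulate_organelle_masks(random_mask_layout(9, seed = seed))
    r <- classify_mitochondria(mask_pair(gt$mito_mask, gt$er_mask, gt$nm_per_px))
    o <- order(r$center_row, r$center_col)
    expect_equal(r$contact_px[o], gt$truth$contact_px)
    expect_equal(r$coupled[o], gt$truth$coupled)
    expect_equal(attr(r, "fraction_coupled"), mean(r$coupled))
  }
})

test_that("nearest-distance profiles bin per-mitochondrion minima in nm", {
  # three mitochondria at centre distances 5, 25 and 60 nm from nearest ER
  m <- matrix(FALSE, 60, 90); e <- m
  m[5:8, 5:8] <- TRUE;   e[5:8, 9:10] <- TRUE     # adjacent -> 1 px = 5 nm
  m[25:28, 5:8] <- TRUE; e[25:28, 13:14] <- TRUE  # 5 px -> 25 nm
  m[45:48, 5:8] <- TRUE; e[45:48, 20:21] <- TRUE  # 12 px -> 60 nm
  p <- nearest_distance_profile(mask_pair(m, e, 5),
                                bins_nm = c(0, 10, 20, 50, Inf))
  expect_equal(sort(p$distances_nm), c(5, 25, 60))
  expect_equal(p$counts, c(1L, 0L, 1L, 1L))

  # single ER pixel at a (3, 4) pixel offset: 5 px = 25 nm (3-4-5 triangle)
  m2 <- matrix(FALSE, 20, 20); e2 <- m2
  m2[5:6, 5:6] <- TRUE; e2[9, 10] <- TRUE
  expect_equal(nearest_distance_profile(mask_pair(m2, e2, 5))$distances_nm, 25)

  # empty ER mask: censored
  p0 <- nearest_distance_profile(mask_pair(m2, matrix(FALSE, 20, 20), 5))
  expect_equal(p0$n_censored, 1L)
  expect_true(all(!is.finite(p0$distances_nm)))
})

test_that("ER surface-to-volume follows face counting exactly and the smooth option approaches 3/r", {
  a <- array(FALSE, c(3, 3, 3)); a[2, 2, 2] <- TRUE
  r1 <- er_surface_to_volume(a, 10)
  expect_equal(r1$surface_nm2, 600)
  expect_equal(r1$volume_nm3, 1000)
  expect_equal(r1$sa_to_v, 0.6)

  b <- array(FALSE, c(4, 3, 3)); b[2:3, 2, 2] <- TRUE
  r2 <- er_surface_to_volume(b, 10)
  expect_equal(r2$surface_nm2, 1000)
  expect_equal(r2$sa_to_v, 0.5)

  # two separate objects are reported separately
  c3 <- array(FALSE, c(7, 3, 3)); c3[2, 2, 2] <- TRUE; c3[6, 2, 2] <- TRUE
  expect_equal(nrow(er_surface_to_volume(c3, 10)), 2L)
  expect_equal(nrow(er_surface_to_volume(array(FALSE, c(3, 3, 3)), 10)), 0L)

  n <- 35; ctr <- 18; r <- 15
  g <- expand.grid(1:n, 1:n, 1:n)
  ball <- array((g[, 1] - ctr)^2 + (g[, 2] - ctr)^2 + (g[, 3] - ctr)^2 <= r^2,
                c(n, n, n))
  sv <- er_surface_to_volume(ball, 1, method = "smoothed")
  expect_lt(abs(sv$sa_to_v - 3 / r) / (3 / r), 0.1)
})
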