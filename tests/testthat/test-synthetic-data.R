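test_that("trace generator is deterministic and validates its fields", {
  sp <- trace_population_spec(3, 60, seed = 7)
  s1 <- simulate_traces(sp)
  s2 <- simulate_traces(sp)
  expect_identical(s1$traces$values, s2$traces$values)
  expect_identical(s1$truth$events, s2$truth$events)

  expect_error(trace_population_spec(0, 60), "n_cells")
  expect_error(trace_population_spec(2, -1), "duration_s")
  expect_error(trace_population_spec(2, 60, rate_hz = 0), "rate_hz")
  expect_error(trace_population_spec(2, 60,
    coupling = list(adjacency = NULL, p_shared = 1.5)), "p_shared")
  adj_bad <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_error(trace_population_spec(2, 60,
    coupling = list(adjacency = adj_bad, p_shared = 1)), "adjacency")
})

test_that("zero-amplitude spec yields bleached baseline plus noise, with planted times kept", {
  sp <- trace_population_spec(1, 120, amplitude_snr = 0, noise_sd = 0.5,
                              bleach_tau_s = 300, seed = 3)
  sim <- simulate_traces(sp)
  expect_gt(nrow(sim$truth$events), 0)
  expect_true(all(sim$truth$events$amplitude == 0))
  expected <- sp$baseline * sim$truth$bleach[, 1]
  expect_lt(max(abs(sim$traces$values[, 1] - expected)), 5 * 0.5)
  expect_lt(abs(sd(sim$traces$values[, 1] - expected) - 0.5), 0.05)
})

test_that("fully coupled noiseless pair is near-perfectly correlated", {
  sp <- trace_population_spec(2, 300, amplitude_snr = 8000, noise_sd = 0.001,
                              coupling = list(adjacency = full_coupling(2),
                                              p_shared = 1), seed = 5)
  sim <- simulate_traces(sp)
  expect_gt(cor(sim$traces$values[, 1], sim$traces$values[, 2]), 0.99)
})

test_that("planted kinetics reproduce the requested medians at large n", {
  sp <- trace_population_spec(5, 1200, halfwidth_dist = c(3.0, 0.3),
                              iei_dist = c(12, 0.4), seed = 11)
  tru <- simulate_traces(sp)$truth$events
  expect_gte(nrow(tru), 400)
  ieis <- unlist(lapply(split(tru, tru$cell_id),
                        function(e) diff(sort(e$midtime_s))))
  expect_lt(abs(median(tru$fwhm_s) - 3.0) / 3.0, 0.05)
  expect_lt(abs(median(ieis) - 12) / 12, 0.05)
  # planted midtimes strictly increasing per cell
  for (e in split(tru, tru$cell_id))
    expect_true(all(diff(e$midtime_s) > 0))
})

test_that("pairwise correlation is non-decreasing in the shared-event probability", {
  corr_mean <- function(p) {
    sp <- trace_population_spec(6, 300, iei_dist = c(15, 0.4),
                                amplitude_snr = 8,
                                coupling = list(adjacency = full_coupling(6),
                                                p_shared = p), seed = 7)
    cm <- correlation_matrix(simulate_traces(sp)$traces)$values
    mean(cm[upper.tri(cm)])
  }
  r <- vapply(c(0, 0.5, 1), corr_mean, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("movie generator plants cells as labelled disks and is reproducible", {
  sp <- trace_population_spec(2, 30, amplitude_snr = 8, seed = 2)
  lay <- cell_layout(data.frame(row = c(15, 35), col = c(15, 35)), 6)
  mv <- simulate_movie(sp, lay, dim_px = c(50, 50),
                       bg_level = 0, pixel_noise_sd = 0)
  # background exactly 0, so the temporal mean has exactly 2 bright blobs
  avg <- apply(mv$movie$stack, c(2, 3), mean)
  lab <- isletca:::label_components(avg > 0, 8L)
  expect_equal(max(lab), 2L)
  expect_equal(sort(unique(as.vector(mv$labels))), c(0L, 1L, 2L))

  mv2 <- simulate_movie(sp, lay, dim_px = c(50, 50),
                        bg_level = 0, pixel_noise_sd = 0)
  expect_identical(mv$movie$stack, mv2$movie$stack)

  # extracted trace from the true labels matches the planted clean trace
  sp_noisy <- trace_population_spec(1, 30, amplitude_snr = 8, seed = 4)
  lay1 <- cell_layout(data.frame(row = 25, col = 25), 7)
  mvn <- simulate_movie(sp_noisy, lay1, dim_px = c(50, 50),
                        bg_level = 10, pixel_noise_sd = 5)
  tr <- extract_traces(mvn$movie, roi_map(mvn$labels))
  n_pix <- sum(mvn$labels == 1)
  tol <- 6 * 5 / sqrt(n_pix)   # pointwise, 6 sigma of the pixel-averaged noise
  expect_lt(max(abs(tr$values[, 1] - mvn$truth$clean_traces[, 1])), tol)
})

test_that("overlapping or out-of-frame cell layouts are rejected", {
  sp <- trace_population_spec(2, 20, seed = 1)
  expect_error(simulate_movie(sp,
    cell_layout(data.frame(row = c(20, 25), col = c(20, 25)), 6),
    dim_px = c(50, 50)), "overlap")
  expect_error(simulate_movie(sp,
    cell_layout(data.frame(row = c(3, 40), col = c(3, 40)), 6),
    dim_px = c(50, 50)), "inside")
})

test_that("dose-response generator follows the 4PL closed form", {
  tab <- simulate_dose_response(2, 10, 5, 1.3, concentrations = 5, noise_sd = 0)
  expect_equal(tab$response, 6)    # midpoint at conc == ec50
  lowc <- simulate_dose_response(2, 10, 5, 1,
                                 concentrations = 5e-6, noise_sd = 0)
  expect_lt(abs(lowc$response - 2), 1e-4 * 8)
  t1 <- simulate_dose_response(0, 1, 1, 1, c(0.1, 1, 10), noise_sd = 0.3, seed = 9)
  t2 <- simulate_dose_response(0, 1, 1, 1, c(0.1, 1, 10), noise_sd = 0.3, seed = 9)
  expect_identical(t1, t2)
  expect_error(simulate_dose_response(0, 1, 1, 1, c(-1, 2)), "concentrations")
})

test_that("mask layouts render hand-checkable contact geometry", {
  # two 4x4 squares, 1-px gap at 5 nm/px: one 20-nm contact site
  spec1 <- mask_layout_spec(c(20, 20), 5,
                            mito = data.frame(row = 5, col = 5, height = 4, width = 4),
                            er = data.frame(mito_id = 1, side = "right", gap_px = 1,
                                            offset_rows = 0, len_rows = 4, width = 4))
  out1 <- simulate_organelle_masks(spec1)
  expect_equal(out1$truth$n_sites, 1L)
  expect_equal(out1$truth$contact_px, 4L)
  expect_true(out1$truth$coupled)

  # 3-px gap (15 nm centre distance 20 nm): no contact
  spec3 <- mask_layout_spec(c(20, 20), 5,
                            mito = data.frame(row = 5, col = 5, height = 4, width = 4),
                            er = data.frame(mito_id = 1, side = "right", gap_px = 3,
                                            offset_rows = 0, len_rows = 4, width = 4))
  out3 <- simulate_organelle_masks(spec3)
  expect_equal(out3$truth$n_sites, 0L)
  expect_false(out3$truth$coupled)

  # no ER at all: uncoupled
  spec0 <- mask_layout_spec(c(20, 20), 5,
                            mito = data.frame(row = 5, col = 5, height = 4, width = 4))
  out0 <- simulate_organelle_masks(spec0)
  expect_false(any(out0$truth$coupled))
  expect_false(any(out0$er_mask))

  # determinism of randomized layouts
  expect_identical(simulate_organelle_masks(random_mask_layout(6, seed = 3)),
                   simulate_organelle_masks(random_mask_layout(6, seed = 3)))
})
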