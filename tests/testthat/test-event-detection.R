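test_that("de-bleaching recovers a flat F/F0 baseline", {
  # constant trace: all values exactly 1
  nb <- debleach(rep(5, 400), 20)
  expect_equal(nb$values, rep(1, 400))

  # pure exponential decay, tau = 300 s: residual < 1%
  t <- (0:11999) / 20
  nb2 <- debleach(100 * exp(-t / 300), 20)
  expect_lt(max(abs(nb2$values - 1)), 0.01)

  # transient relative amplitude preserved within 5% on a decaying baseline
  pulse <- 0.1 * exp(-4 * log(2) * (t - 300)^2 / 3^2)
  raw <- 100 * exp(-t / 300) * (1 + pulse)
  nb3 <- debleach(raw, 20)
  expect_lt(abs(max(nb3$values) - 1.1) / 0.1, 0.05)

  expect_error(debleach(rep(1, 30), 20), "10 s")
})

test_that("detector finds a planted pulse with accurate halfwidth and stays silent on flat input", {
  t <- (0:11999) / 20
  expect_equal(nrow(detect_events(rep(1, 12000), 20)), 0L)

  set.seed(2)
  x <- 1 + 0.1 * exp(-4 * log(2) * (t - 300)^2 / 3^2) + rnorm(12000, 0, 0.01)
  ev <- detect_events(x, 20)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$halfwidth_s - 3.0), 0.15)
  expect_lt(abs(ev$midtime_s - 300), 0.5)
  expect_gt(ev$peak_z, 4)
})

test_that("raising the z threshold never increases the detection count", {
  set.seed(3)
  sp <- trace_population_spec(1, 300, amplitude_snr = 6, iei_dist = c(20, 0.4),
                              seed = 3)
  nb <- debleach(simulate_traces(sp)$traces$values[, 1], 20)
  n <- vapply(c(3, 4, 5, 6), function(z)
    nrow(detect_events(nb, z_thresh = z)), integer(1))
  expect_true(all(diff(n) <= 0))
})

test_that("shifting a trace shifts all midtimes by exactly the shift", {
  t <- (0:11999) / 20
  mk <- function(center) 1 + 0.1 * exp(-4 * log(2) * (t - center)^2 / 3^2)
  e1 <- detect_events(mk(200), 20)
  e2 <- detect_events(mk(200 + 37 / 20), 20)   # 37-frame shift
  expect_equal(e2$midtime_s - e1$midtime_s, 37 / 20, tolerance = 1e-6)
  expect_equal(e2$halfwidth_s, e1$halfwidth_s, tolerance = 1e-6)
})

test_that("detection recall and FWHM accuracy hold on planted renewal trains", {
  for (seed in 1:3) {
    sp <- trace_population_spec(1, 600, halfwidth_dist = c(3.5, 0.25),
                                iei_dist = c(25, 0.3), amplitude_snr = 8,
                                noise_sd = 1, seed = seed)
    sim <- simulate_traces(sp)
    ev <- detect_events(debleach(sim$traces$values[, 1], 20))
    m <- match_events(ev, sim$truth$events)
    expect_gte(m$recall, 0.95)
    expect_lte(mean(m$fwhm_abs_err), 0.2)
  }
})

test_that("inter-event intervals are midtime differences", {
  ev <- data.frame(roi_id = 1, midtime_s = c(10, 30, 70))
  expect_equal(inter_event_intervals(ev), c(20, 40))
  expect_equal(inter_event_intervals(ev[1, ]), numeric(0))
  ev2 <- rbind(ev, data.frame(roi_id = 2, midtime_s = 5))
  expect_error(inter_event_intervals(ev2), "single ROI")
})

test_that("ROI activity filter uses a >= 5 boundary and the band filter is inclusive", {
  mk <- function(roi, n, hw = 3) data.frame(
    roi_id = roi, onset_s = seq_len(n), midtime_s = seq_len(n) * 10,
    halfwidth_s = hw, peak_z = 5, scale_s = 2)
  tab <- rbind(mk(1, 4), mk(2, 5))
  kept <- filter_rois(tab, min_events = 5)
  expect_equal(unique(kept$roi_id), 2L)   # 4 events discarded, 5 kept
  expect_equal(nrow(filter_rois(tab[0, ])), 0L)

  tab2 <- data.frame(roi_id = 1, onset_s = 1:5, midtime_s = 1:5 * 10,
                     halfwidth_s = c(0.5, 0.99, 3, 10.0, 12),
                     peak_z = 5, scale_s = 2)
  expect_equal(band_filter_events(tab2)$halfwidth_s, c(3, 10.0))
  expect_equal(band_filter_events(tab2, 0.1, 20), tab2)
  expect_error(band_filter_events(tab2, 5, 2), "lo_s < hi_s")
})

test_that("activity filter runs on pre-band counts (implemented filter order)", {
  # ROI 1 has 5 events total but only 2 inside the 1-10 s band: the
  # activity filter (applied first, on total counts) keeps it, the band
  # filter then reduces it to 2 events; reversing the order would drop it
  tab <- data.frame(roi_id = 1, onset_s = 1:5, midtime_s = 1:5 * 30,
                    halfwidth_s = c(0.5, 0.7, 2, 3, 15), peak_z = 5, scale_s = 2)
  out <- band_filter_events(filter_rois(tab, 5))
  expect_equal(nrow(out), 2L)
  reversed <- filter_rois(band_filter_events(tab), 5)
  expect_equal(nrow(reversed), 0L)
})
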