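test_that("condition assignment uses half-open intervals and labels gaps", {
  tl <- protocol_timeline(c(0, 100), c(100, 200), c("6 mM", "8 mM"))
  ev <- data.frame(roi_id = 1, midtime_s = c(50, 100, 150, 250))
  lab <- assign_condition(ev, tl)
  expect_equal(lab$condition, c("6 mM", "8 mM", "8 mM", "unassigned"))
  # every event gets exactly one label
  expect_equal(sum(!is.na(lab$condition)), nrow(ev))

  expect_error(protocol_timeline(c(0, 50), c(100, 150), c("a", "b")), "overlap")
  expect_error(protocol_timeline(0, 0, "a"), "start_s < end_s")
  expect_error(protocol_timeline(c(0, 100), c(100, 200), c("a", "a")), "unique")
})

test_that("KDE uses the bandwidth-factor convention and normalizes on its grid", {
  k <- kde(c(-2, 2), factor = 0.2, grid = seq(-5, 5, length.out = 401))
  expect_equal(k$bandwidth, 0.2 * sd(c(-2, 2)))
  expect_lt(max(abs(k$density - rev(k$density))), 1e-12)  # symmetry about 0

  set.seed(5)
  x <- rnorm(1e4, 5, 1)
  k2 <- kde(x, factor = 0.2)
  integral <- sum(diff(k2$grid) * (k2$density[-1] + k2$density[-length(k2$density)]) / 2)
  expect_lt(abs(integral - 1), 1e-3)
  expect_lt(abs(k2$grid[which.max(k2$density)] - 5), 0.1)

  expect_error(kde(1), "2 observations")
  expect_error(kde(c(3, 3, 3)), "variance")
})

test_that("KDE differences are signed, integrate to zero, and demand a shared grid", {
  g <- seq(-2, 12, length.out = 501)
  set.seed(6)
  a <- kde(rnorm(2000, 6, 1), grid = g)
  b <- kde(rnorm(2000, 4, 1), grid = g)
  expect_equal(kde_difference(a, a)$density, rep(0, length(g)))
  d <- kde_difference(a, b)
  expect_gt(mean(d$density[g > 6]), 0)      # positive lobe at high values
  expect_lt(mean(d$density[g < 4]), 0)
  integral <- sum(diff(g) * (d$density[-1] + d$density[-501]) / 2)
  expect_lt(abs(integral), 2e-3)
  c2 <- kde(rnorm(100), grid = seq(-4, 4, length.out = 101))
  expect_error(kde_difference(a, c2), "grid")
})

test_that("condition medians pool correctly and drop boundary-straddling intervals", {
  ev <- data.frame(roi_id = 1, midtime_s = c(10, 20, 30),
                   halfwidth_s = c(1, 2, 3), condition = "A")
  m <- condition_medians(ev)
  expect_equal(m$median_halfwidth_s, 2)
  ev4 <- rbind(ev, data.frame(roi_id = 1, midtime_s = 40, halfwidth_s = 4,
                              condition = "A"))
  expect_equal(condition_medians(ev4)$median_halfwidth_s, 2.5)

  # an interval whose two events lie in different conditions is discarded
  ev2 <- data.frame(roi_id = 1, midtime_s = c(10, 20, 110, 120),
                    halfwidth_s = 2,
                    condition = c("A", "A", "B", "B"))
  m2 <- condition_medians(ev2)
  expect_equal(m2$n_iei[m2$condition == "A"], 1L)   # 10-20 only, not 20-110
  expect_equal(m2$n_iei[m2$condition == "B"], 1L)
  expect_equal(m2$median_iei_s, c(10, 10))
})

test_that("synthetic fast/sparse phenotypes keep their planted median ordering", {
  med <- function(hw, iei, seed) {
    sp <- trace_population_spec(4, 600, halfwidth_dist = c(hw, 0.25),
                                iei_dist = c(iei, 0.35), amplitude_snr = 8,
                                seed = seed)
    sim <- simulate_traces(sp)
    ev <- detect_events_set(sim$traces)
    ev$condition <- "all"
    condition_medians(ev)
  }
  for (seed in 1:3) {
    al <- med(4.0, 30, seed)
    cr <- med(2.8, 12, seed + 50)
    expect_lt(cr$median_halfwidth_s, al$median_halfwidth_s)
    expect_lt(cr$median_iei_s, al$median_iei_s)
    expect_lt(abs(al$median_halfwidth_s - 4.0) / 4.0, 0.1)
    expect_lt(abs(cr$median_halfwidth_s - 2.8) / 2.8, 0.1)
  }
})

test_that("Mann-Whitney U matches exact enumeration, including ties", {
  r1 <- compare_groups(1:3, 4:6, "mwu")
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p_value, 0.1)      # 2/20 labelings as extreme

  r2 <- compare_groups(1:3, 1:3, "mwu")
  expect_equal(r2$statistic, 4.5)    # average-rank U with full ties
  expect_equal(r2$p_value, 1)

  # cross-check against the exact distribution for tie-free samples
  set.seed(8)
  for (i in 1:5) {
    a <- sample(100, sample(3:6, 1))
    b <- sample(200:300, sample(3:6, 1))
    ours <- compare_groups(a, b, "mwu")
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("KS and t tests report the expected statistics and errors", {
  k <- compare_groups(c(1, 2, 3), c(1, 2, 3), "ks")
  expect_equal(k$statistic, 0)
  expect_equal(k$p_value, 1)
  set.seed(10)
  tt <- compare_groups(rnorm(20), rnorm(20, 2), "t")
  expect_lt(tt$p_value, 0.01)
  expect_error(compare_groups(1:2, 1:5, "t"), "n >= 3")
  expect_error(compare_groups(1:3, 1:3, "median"), "arg")
})
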