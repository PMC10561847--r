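test_that("the circle map sends start, center and end to -pi, 0, pi", {
  expect_equal(window_phase(2.0, 1.5, 2.5, 2.0), 0)
  expect_equal(window_phase(1.5, 1.5, 2.5, 2.0), -pi)
  expect_equal(window_phase(2.25, 1.5, 2.5, 2.0), pi / 2)
  # asymmetric window: center still maps to 0, segments stay linear
  expect_equal(window_phase(1.9, 1.5, 3.0, 2.0), -pi * 0.2, tolerance = 1e-12)
  expect_equal(window_phase(2.5, 1.5, 3.0, 2.0), pi * 0.5, tolerance = 1e-12)
  expect_error(window_phase(3.0, 1.5, 2.5, 2.0), "outside")
})

test_that("Rayleigh test matches hand values and its Monte-Carlo null", {
  # maximal concentration
  r1 <- rayleigh_test(rep(0.3, 50))
  expect_equal(r1$z, 50, tolerance = 1e-9)
  expect_lt(r1$p, 1e-6)

  # perfect four-point uniformity
  r0 <- rayleigh_test(c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(r0$z, 0, tolerance = 1e-12)
  expect_gt(r0$p, 0.99)

  expect_error(rayleigh_test(c(0, 1, 2)), "at least 4")

  # small-sample approximation agrees with a 100k Monte-Carlo null
  set.seed(31)
  ang <- rnorm(10, 0, 0.75) %% (2 * pi)  # concentrated n = 10 sample
  rt <- rayleigh_test(ang)
  p_mc <- mc_rayleigh_p(rt$r_bar, 10)
  expect_lt(abs(rt$p - p_mc), 0.01)

  # monotone: p decreases as concentration rises at fixed n
  ps <- vapply(c(2, 1, 0.5, 0.25), function(s) {
    set.seed(5)
    rayleigh_test(rnorm(20, 0, s))$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("Rayleigh p-values are uniform under the null", {
  set.seed(77)
  ps <- vapply(1:1000, function(i)
    rayleigh_test(runif(10, 0, 2 * pi))$p, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("Watson-Wheeler test separates distinct distributions and holds its null", {
  # two tight clusters at 0 and pi are detected
  set.seed(9)
  a <- rnorm(20, 0, 0.1)
  b <- rnorm(20, pi, 0.1)
  ww <- watson_wheeler_test(a, b)
  expect_lt(ww$p, 0.001)
  # permutation route agrees that the difference is extreme
  set.seed(10)
  wwp <- watson_wheeler_test(a, b, method = "permutation", n_perm = 1000)
  expect_lt(wwp$p, 0.005)

  expect_error(watson_wheeler_test(rnorm(5), rnorm(20)), "10 angles")

  # null: random split of one distribution gives uniform p
  set.seed(42)
  ps <- vapply(1:1000, function(i) {
    pool <- rnorm(40, 1, 0.8) %% (2 * pi)
    idx <- sample(40, 20)
    watson_wheeler_test(pool[idx], pool[-idx])$w
  }, numeric(1))
  ps <- pchisq(ps, 2, lower.tail = FALSE)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("condition phasors pool trials and rotate onto the stimulus angle", {
  tr <- locked_trace(period = 1, duration = 10.2)
  centers <- as.numeric(extract_beat_centers(tr, mean_period = 1))
  grid <- build_beat_windows(centers, 1)

  cfg <- sim_config(base_tempo = 60, duration_beats = 10, seed = 1)
  seqs <- list(stim = structure(
    list(onsets = data.frame(oscillator_id = 1L, onset_time_s = centers),
         trace = tr, config = cfg, condition_label = "strong",
         stimulus_id = "stim", mean_r = 0.99, duration = 10.2),
    class = "stimulus_sequence"))
  grids <- list(stim = grid)

  # taps exactly at centers: r = 1, phi = 0 after rotation
  trials <- list(tap_trial("p1", "stim", centers, 1, "strong"))
  ph <- condition_phasors(trials, seqs, grids)
  tap_row <- ph[ph$who == "tap", ]
  expect_equal(tap_row$r, 1, tolerance = 1e-9)
  expect_equal(tap_row$phi_rad, 0, tolerance = 1e-9)

  # taps spread uniformly over windows: r near 0
  set.seed(3)
  u <- sort(runif(400, min(grid$windows$window_start_s),
                  max(grid$windows$window_end_s) - 1e-9))
  trials_u <- list(tap_trial("p2", "stim", u, 1, "strong"))
  ph_u <- condition_phasors(trials_u, seqs, grids)
  expect_lt(ph_u$r[ph_u$who == "tap"], 0.15)

  # pooled phasor equals the scalar-loop oracle
  phases <- grid_phases(u, grid)
  oracle <- loop_phasor(phases)
  op <- order_parameters(phases)
  expect_equal(op$r, oracle$r, tolerance = 1e-12)
  expect_equal(op$phi, oracle$phi, tolerance = 1e-12)
})
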