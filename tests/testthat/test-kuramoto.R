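test_that("ensemble initialization draws the configured frequency distribution", {
  cfg <- sim_config(base_tempo = 60, n_oscillators = 1, freq_sd_fraction = 0,
                    seed = 1)
  st <- init_ensemble(cfg)
  expect_equal(st$omegas, 2 * pi, tolerance = 1e-12)

  cfg0 <- sim_config(base_tempo = 120, n_oscillators = 25,
                     freq_sd_fraction = 0, seed = 3)
  st0 <- init_ensemble(cfg0)
  expect_equal(st0$omegas, rep(4 * pi, 25), tolerance = 1e-12)
  expect_true(all(st0$phases >= 0 & st0$phases < 2 * pi))

  # seeded determinism
  a <- init_ensemble(sim_config(seed = 99))
  b <- init_ensemble(sim_config(seed = 99))
  expect_identical(a$phases, b$phases)
  expect_identical(a$omegas, b$omegas)

  expect_error(sim_config(base_tempo = 0), "positive")
  expect_error(sim_config(n_oscillators = 0), "positive")
})

test_that("order parameters match hand and loop-oracle computations", {
  # identical phases: full coherence at that angle
  op <- order_parameters(rep(0.7, 40))
  expect_equal(op$r, 1, tolerance = 1e-12)
  expect_equal(op$phi, 0.7, tolerance = 1e-12)

  # antipodal cancellation: R = 0, angle indeterminate
  op0 <- order_parameters(c(0, pi))
  expect_equal(op0$r, 0, tolerance = 1e-12)
  expect_true(op0$indeterminate)

  # hand-computed complex sum of two unit vectors
  op2 <- order_parameters(c(0, pi / 2))
  expect_equal(op2$r, cos(pi / 4), tolerance = 1e-9)
  expect_equal(op2$phi, pi / 4, tolerance = 1e-9)

  # vectorized result equals a scalar loop summation on random phase sets
  set.seed(11)
  for (i in 1:20) {
    ang <- runif(sample(2:100, 1), 0, 2 * pi)
    op <- order_parameters(ang)
    oracle <- loop_phasor(ang)
    expect_equal(op$r, oracle$r, tolerance = 1e-12)
    if (!op$indeterminate)
      expect_equal(op$phi, oracle$phi, tolerance = 1e-12)
  }

  expect_error(order_parameters(numeric(0)), "non-empty")
})

test_that("Euler step advances phases correctly in limiting cases", {
  cfg <- sim_config(n_oscillators = 3, base_tempo = 60,
                    freq_sd_fraction = 0.05, k_init = 0, seed = 5)
  st <- init_ensemble(cfg)
  st2 <- euler_step(st, cfg)
  # k = 0: each phase advances exactly omega_i * dt (mod 2 pi)
  expect_equal(st2$phases, (st$phases + st$omegas * cfg$dt) %% (2 * pi),
               tolerance = 1e-12)

  # two oscillators, equal omega, k > 0: phases attract
  cfg2 <- sim_config(n_oscillators = 2, base_tempo = 60,
                     freq_sd_fraction = 0, k_init = 2, seed = 1)
  st <- init_ensemble(cfg2)
  st$phases <- c(0, 0.5)
  st2 <- euler_step(st, cfg2)
  d <- abs(st2$phases[2] - st2$phases[1])
  expect_lt(min(d, 2 * pi - d), 0.5)

  # single oscillator: coupling term vanishes (R = 1, phi = own phase)
  cfg1 <- sim_config(n_oscillators = 1, base_tempo = 60,
                     freq_sd_fraction = 0, k_init = 50, seed = 1)
  st <- init_ensemble(cfg1)
  st2 <- euler_step(st, cfg1)
  expect_equal(st2$phases, (st$phases + st$omegas * cfg1$dt) %% (2 * pi),
               tolerance = 1e-12)
})

test_that("wrap detection fires only on wrapped-phase decrease", {
  expect_true(detect_wrap(6.2, 0.1))
  expect_false(detect_wrap(1.0, 1.1))
  expect_false(detect_wrap(0.0, 0.0))
  expect_identical(detect_wrap(c(6.2, 1.0), c(0.1, 1.1)), c(TRUE, FALSE))
})

test_that("feedback controller steps k toward the target and clamps at 0", {
  expect_equal(feedback_update_k(1.0, 0.5, 0.9, 0.01), 1.01)
  expect_equal(feedback_update_k(0.005, 0.99, 0.9, 0.01), 0)
  expect_equal(feedback_update_k(0.7, 0.9, 0.9, 0.01), 0.7)
  expect_error(feedback_update_k(1, 0.5, 0.9, -0.01), "non-negative")
})

test_that("simulated sequences have the right duration, bounds and determinism", {
  cfg <- sim_config(coupling_mode = "none", base_tempo = 72,
                    duration_beats = 22, seed = 8)
  sq <- simulate_sequence(cfg)
  expect_equal(sq$duration, 22 * 60 / 72, tolerance = 1e-12)
  expect_true(all(sq$onsets$onset_time_s >= 0 &
                  sq$onsets$onset_time_s <= sq$duration))
  expect_false(is.unsorted(sq$onsets$onset_time_s))
  expect_true(all(sq$trace$r >= 0 & sq$trace$r <= 1))
  expect_equal(diff(sq$trace$time_s), rep(cfg$dt, nrow(sq$trace) - 1),
               tolerance = 1e-9)

  # identical config + seed: bit-identical onset lists
  sq2 <- simulate_sequence(cfg)
  expect_identical(sq$onsets, sq2$onsets)
})

test_that("coherence stays in [0, 1] and uncoupled ensembles stay incoherent", {
  for (mode in c("none", "feedback")) {
    sq <- simulate_sequence(sim_config(coupling_mode = mode, r_target = 0.97,
                                       k_init = 2.5, base_tempo = 92,
                                       duration_beats = 8, seed = 21))
    expect_true(all(sq$trace$r >= 0 & sq$trace$r <= 1))
  }
  # k = 0, N = 40: seed-averaged time-mean R well below the coupled regime
  rs <- vapply(1:8, function(s)
    simulate_sequence(sim_config(coupling_mode = "none", base_tempo = 92,
                                 seed = s))$mean_r, numeric(1))
  expect_lt(mean(rs), 0.2)
})

test_that("feedback locking tightens onset dispersion within beats", {
  # with target coherence 1 the post-transient onset spread per beat must
  # shrink far below the uncoupled case
  beat_sd <- function(sq) {
    grid <- segment_sequence(sq)
    asg <- assign_to_windows(sq$onsets$onset_time_s, grid)
    asg <- asg[!asg$excluded & asg$window > 4, ]
    mean(tapply(asg$offset_s, asg$window, stats::sd), na.rm = TRUE)
  }
  locked <- simulate_sequence(sim_config(coupling_mode = "feedback",
                                         r_target = 1, k_init = 2.5,
                                         base_tempo = 92, seed = 31),
                              condition_label = "strong")
  free <- simulate_sequence(sim_config(coupling_mode = "none",
                                       base_tempo = 92, seed = 31))
  expect_lt(beat_sd(locked), 0.5 * beat_sd(free))
})

test_that("batch generation yields one reproducible sequence per design cell", {
  d1 <- exp1_design()
  d2 <- exp2_design()
  expect_equal(nrow(d1), 30)
  expect_equal(nrow(d2), 40)

  small <- d2[d2$tempo_bpm == 92 & d2$version == 1, ]
  seqs <- batch_generate(small, seed = 4)
  expect_length(seqs, 4)
  expect_setequal(vapply(seqs, function(s) s$condition_label, character(1)),
                  c("strong", "medium", "weak", "none"))
  seqs2 <- batch_generate(small, seed = 4)
  expect_identical(seqs[[1]]$onsets, seqs2[[1]]$onsets)

  expect_error(batch_generate(small[integer(0), ], seed = 1), "non-empty")
  expect_error(batch_generate(rbind(small, small), seed = 1), "duplicate")
})
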