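# Shared fixtures and independent oracles for the test suite.

# Analytic coherence trace of a fully locked ensemble: psi advances at
# exactly 2*pi/period, wrapped to [-pi, pi), R constant.
locked_trace <- function(period, duration, dt = 0.016, psi0 = 0.3, r = 0.99) {
  times <- seq(dt, duration, by = dt)
  psi <- (psi0 + 2 * pi * times / period + pi) %% (2 * pi) - pi
  data.frame(time_s = times, r = r, psi_rad = psi)
}

# scalar-loop oracle for the mean phasor of a set of angles
loop_phasor <- function(angles) {
  re <- 0
  im <- 0
  for (a in angles) {
    re <- re + cos(a)
    im <- im + sin(a)
  }
  list(r = sqrt(re^2 + im^2) / length(angles),
       phi = atan2(im, re))
}

# brute-force double-loop oracle for the phase-portrait RMS dispersion
brute_dispersion <- function(itis) {
  n <- length(itis) - 1
  pts <- matrix(NA_real_, n, 2)
  for (j in seq_len(n)) pts[j, ] <- c(itis[j], itis[j + 1])
  cx <- sum(pts[, 1]) / n
  cy <- sum(pts[, 2]) / n
  acc <- 0
  for (j in seq_len(n)) acc <- acc + (pts[j, 1] - cx)^2 + (pts[j, 2] - cy)^2
  sqrt(acc / n)
}

# Monte-Carlo null p-value for the Rayleigh test: fraction of uniform
# samples of size n whose mean resultant length reaches r_bar_obs.
mc_rayleigh_p <- function(r_bar_obs, n, nsim = 100000L) {
  ang <- matrix(stats::runif(nsim * n, 0, 2 * pi), nsim, n)
  r_bar <- sqrt(rowMeans(cos(ang))^2 + rowMeans(sin(ang))^2)
  mean(r_bar >= r_bar_obs)
}

# One full default-cohort pipeline run, computed once per test session.
.fixture_env <- new.env(parent = emptyenv())
cohort_fixture <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  seqs <- batch_generate(exp2_design(), seed = 42)
  grids <- lapply(seqs, segment_sequence)
  cohort <- simulate_cohort(seqs, grids, seed = 42)
  points <- build_trial_points(cohort$trials, seqs)
  model <- suppressWarnings(fit_clusters(points, seed = 42))
  groups <- assign_groups(model$assignment)
  .fixture_env$fx <- list(sequences = seqs, grids = grids,
                          trials = cohort$trials, truth = cohort$truth,
                          modes = cohort$modes, points = points,
                          model = model, groups = groups)
  .fixture_env$fx
}
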