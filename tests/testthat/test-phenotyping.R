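make_points <- function(n_per, centers_r, centers_niti, sd = 0.02,
                        seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_along(centers_r), function(i) {
    data.frame(participant_id = sprintf("p%d", i),
               stimulus_id = sprintf("s%d", seq_len(n_per)),
               condition = "none", tempo_bpm = 92,
               mean_r = 10^centers_r[i],
               log10_r = rnorm(n_per, centers_r[i], sd),
               mean_niti = rnorm(n_per, centers_niti[i], sd),
               mean_iti = rnorm(n_per, centers_niti[i] * 0.65, sd))
  }))
}

test_that("trial points exclude underlength trials and carry stimulus coherence", {
  sq <- simulate_sequence(sim_config(coupling_mode = "none", base_tempo = 92,
                                     duration_beats = 6, seed = 2),
                          condition_label = "none")
  trials <- list(tap_trial("a", "x", c(0.5, 1.1, 1.8), 60 / 92, "none"),
                 tap_trial("b", "x", 1.0, 60 / 92, "none"))
  expect_warning(pts <- build_trial_points(trials, list(x = sq)),
                 "excluded")
  expect_equal(nrow(pts), 1)
  expect_equal(pts$mean_r, sq$mean_r)
  expect_equal(pts$log10_r, log10(sq$mean_r))
})

test_that("k-means recovers well-separated blobs deterministically", {
  pts <- make_points(40, centers_r = c(-0.02, -0.5, -0.9, -0.6, -0.7),
                     centers_niti = c(1.0, 1.0, 0.35, 2.0, 3.0))
  m <- fit_clusters(pts, seed = 5)
  expect_equal(sort(unique(m$assignment$label)), 1:5)
  # each blob is pure: participant ids were assigned per blob
  purity <- tapply(m$assignment$label, m$assignment$participant_id,
                   function(l) max(table(l)) / length(l))
  expect_true(all(purity == 1))

  m2 <- fit_clusters(pts, seed = 5)
  expect_identical(m$assignment$cluster, m2$assignment$cluster)

  expect_error(fit_clusters(pts[c(1, 41, 81), ]), "distinct points")
})

test_that("centroid labeling follows the published cluster semantics", {
  ctr <- data.frame(log10_r = c(-0.02, -0.6, -0.8, -0.6, -0.7),
                    mean_niti = c(1.0, 1.0, 0.3, 2.0, 3.0))
  expect_equal(label_clusters(ctr), c(1L, 2L, 3L, 4L, 5L))
  # labeling depends only on centroid geometry, not on row order
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(label_clusters(ctr[perm, ]), c(1L, 2L, 3L, 4L, 5L)[perm])

  expect_equal(label_clusters(data.frame(log10_r = -0.5, mean_niti = 0.5)),
               3L)
  # gap case 1.5 falls outside every band: nearest rule with warning
  expect_warning(l <- label_clusters(data.frame(log10_r = -0.5,
                                                mean_niti = 1.5)),
                 "outside")
  expect_equal(l, 2L)
})

test_that("group assignment applies the occupancy rules with Fast/Hybrid precedence", {
  mk <- function(pid, labels_by_cond) {
    do.call(rbind, lapply(names(labels_by_cond), function(cc)
      data.frame(participant_id = pid, condition = cc,
                 label = labels_by_cond[[cc]])))
  }
  # all trials in clusters 1-2 -> Regular
  reg <- mk("r", list(strong = rep(1L, 10), medium = rep(2L, 10),
                      weak = rep(2L, 10), none = rep(2L, 10)))
  # cluster 3 everywhere except strong -> Fast
  fast <- mk("f", list(strong = rep(1L, 10),
                       medium = c(rep(3L, 9), 1L),
                       weak = rep(3L, 10), none = rep(3L, 10)))
  # cluster 3 dominant only in the none condition -> Hybrid
  hyb <- mk("h", list(strong = rep(1L, 10), medium = rep(2L, 10),
                      weak = rep(2L, 10),
                      none = c(rep(3L, 8), 2L, 2L)))
  g <- assign_groups(rbind(reg, fast, hyb))
  expect_equal(g$group[match(c("r", "f", "h"), g$participant_id)],
               c("Regular", "Fast", "Hybrid"))
  # the Hybrid participant has a clusters-1-2 majority overall, so the
  # Regular rule alone would have claimed it
  expect_gt(g$prop_12[g$participant_id == "h"], 0.5)
})

test_that("RMS dispersion matches hand computation and the brute-force oracle", {
  expect_equal(dispersion_metric(rep(0.3, 6))$rms_dispersion, 0)
  expect_equal(dispersion_metric(rep(0.3, 6))$label, "dense")

  # alternating 0.2/0.6 (odd length, so the portrait has five points on
  # each side): centroid (0.4, 0.4), rms = sqrt(0.08)
  alt <- rep(c(0.2, 0.6), length.out = 11)
  dm <- dispersion_metric(alt)
  expect_equal(dm$centroid, c(0.4, 0.4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(dm$rms_dispersion, sqrt(0.08), tolerance = 1e-12)
  expect_equal(dm$label, "sparse")

  # boundary: dispersion exactly equal to the threshold is sparse
  dm_thr <- dispersion_metric(alt, threshold = sqrt(0.08))
  expect_equal(dm_thr$label, "sparse")

  expect_error(dispersion_metric(c(0.2, 0.3)), "at least 3")

  set.seed(17)
  for (i in 1:10) {
    itis <- runif(sample(3:30, 1), 0.1, 0.9)
    expect_equal(dispersion_metric(itis)$rms_dispersion,
                 brute_dispersion(itis), tolerance = 1e-12)
  }
})

test_that("the factorial ITI regression recovers planted coefficients", {
  set.seed(21)
  n <- 300
  d <- data.frame(r = runif(n, 0.05, 0.5),
                  tempo = sample(c(72, 81, 92, 105, 119), n, TRUE),
                  group = sample(c("Regular", "Hybrid", "Fast"), n, TRUE))
  beta <- c(`(Intercept)` = 0.5, r = 0.2, tempo = -0.002,
            groupHybrid = -0.08, groupFast = -0.25)
  X <- model.matrix(~ r + tempo + group,
                    transform(d, group = factor(group,
                      levels = c("Regular", "Hybrid", "Fast"))))
  d$mean_iti <- drop(X %*% beta) + rnorm(n, 0, 0.02)
  fit <- fit_iti_regression(d)
  est <- fit$coefficients
  for (nm in names(beta)) {
    expect_lt(abs(est[nm, "Estimate"] - beta[nm]), 2 * est[nm, "Std. Error"])
  }
  expect_gt(fit$r_squared, 0.5)

  expect_error(fit_iti_regression(transform(d, group = "Fast")),
               "at least 2")
  expect_warning(fit_iti_regression(transform(d, tempo = 92)), "constant")
})
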