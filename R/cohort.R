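#' Synthetic tapper profile
#'
#' Parameterizes a statistical emulator of one tapping phenotype. Defaults
#' are read off the published group summaries: per-condition frequent-mode
#' probabilities mirror the cluster-occupancy table, per-condition beat
#' noise follows the fitted adaptation curves `A * exp(B * t)` (nITI SD per
#' tap section), dense-mode intervals use the group mean dense raw ITIs
#' (590/480/211 ms) and sparse-mode intervals scale with the beat period
#' (reproducing the tempo scaling of sparse tapping).
#'
#' @param phenotype `"Regular"`, `"Hybrid"` or `"Fast"`.
#' @param beat_noise_A,beat_noise_B Named per-condition vectors (strong,
#'   medium, weak, none): initial nITI SD and per-section decay of the
#'   beat-tapping noise.
#' @param anticipation_ms Mean tap anticipation relative to the beat center
#'   in milliseconds (default -30 ms, a generic negative asynchrony).
#' @param dense_iti_ms Mean dense-mode inter-tap interval in ms.
#' @param sparse_scale Sparse-mode mean interval as a fraction of the beat
#'   period.
#' @param switch_probs Named per-condition probabilities of producing a
#'   frequent-tapping (cluster-3-like) trial.
#' @param double_probs,triple_probs Named per-condition probabilities of
#'   tapping every second beat (nITI around 2) or every third beat (nITI
#'   around 3) -- the rare cluster-4/5 behaviours.
#' @param dense_prob Probability that a frequent-tapping trial is dense
#'   rather than sparse.
#' @param freq_cap Ceiling on frequent-mode intervals as a fraction of the
#'   beat period. Frequent tapping is tapping below the beat rate; for the
#'   Hybrid and Fast phenotypes the cap (0.65) keeps their frequent trials
#'   below the beat even at fast tempi, while the Regular phenotype's rare
#'   frequent tapping sits near its beat rate (no cap), as its long dense
#'   and sparse intervals imply.
#' @return A `tapper_profile` list.
#' @export
tapper_profile <- function(phenotype = c("Regular", "Hybrid", "Fast"),
                           beat_noise_A = NULL, beat_noise_B = NULL,
                           anticipation_ms = -30,
                           dense_iti_ms = NULL, sparse_scale = NULL,
                           switch_probs = NULL,
                           double_probs = NULL, triple_probs = NULL,
                           dense_prob = NULL, freq_cap = NULL) {
  phenotype <- match.arg(phenotype)
  conds <- c("strong", "medium", "weak", "none")
  def <- switch(phenotype,
    Regular = list(
      A = c(strong = 0.27, medium = 0.51, weak = 0.68, none = 1.00),
      B = c(strong = -0.18, medium = -0.25, weak = -0.26, none = -0.22),
      dense_iti_ms = 590, sparse_scale = 0.91,
      switch = c(strong = 0, medium = 0, weak = 0.019, none = 0.294),
      double = c(strong = 0, medium = 0.044, weak = 0.075, none = 0.10),
      triple = c(strong = 0, medium = 0, weak = 0, none = 0.0125),
      dense_prob = 0.51, freq_cap = Inf),
    Hybrid = list(
      A = c(strong = 0.14, medium = 0.25, weak = 0.23, none = 0.42),
      B = c(strong = -0.13, medium = -0.13, weak = -0.09, none = -0.16),
      dense_iti_ms = 480, sparse_scale = 0.69,
      switch = c(strong = 0, medium = 0.06, weak = 0.048, none = 0.78),
      double = c(strong = 0, medium = 0, weak = 0, none = 0),
      triple = c(strong = 0, medium = 0, weak = 0, none = 0),
      dense_prob = 0.48, freq_cap = 0.65),
    Fast = list(
      A = c(strong = 0.19, medium = 0.19, weak = 0.21, none = 0.25),
      B = c(strong = -0.11, medium = 0.04, weak = 0.00, none = -0.13),
      dense_iti_ms = 211, sparse_scale = 0.46,
      switch = c(strong = 0, medium = 0.856, weak = 0.944, none = 0.989),
      double = c(strong = 0, medium = 0, weak = 0, none = 0),
      triple = c(strong = 0, medium = 0, weak = 0, none = 0),
      dense_prob = 0.55, freq_cap = 0.65))
  pick <- function(user, fallback) {
    if (is.null(user)) return(fallback[conds])
    stopifnot(all(conds %in% names(user)))
    user[conds]
  }
  prof <- structure(
    list(phenotype = phenotype,
         beat_noise_A = pick(beat_noise_A, def$A),
         beat_noise_B = pick(beat_noise_B, def$B),
         anticipation_ms = anticipation_ms,
         dense_iti_ms = if (is.null(dense_iti_ms)) def$dense_iti_ms
                        else dense_iti_ms,
         sparse_scale = if (is.null(sparse_scale)) def$sparse_scale
                        else sparse_scale,
         switch_probs = pick(switch_probs, def$switch),
         double_probs = pick(double_probs, def$double),
         triple_probs = pick(triple_probs, def$triple),
         dense_prob = if (is.null(dense_prob)) def$dense_prob
                      else dense_prob,
         freq_cap = if (is.null(freq_cap)) def$freq_cap else freq_cap),
    class = "tapper_profile")
  probs <- c(prof$switch_probs, prof$double_probs, prof$triple_probs,
             prof$dense_prob)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (!is.finite(prof$dense_iti_ms) || prof$dense_iti_ms <= 0)
    stop("`dense_iti_ms` must be positive")
  prof
}

#' Simulate one tap trial of a synthetic tapper
#'
#' Draws a tapping mode for the trial from the profile's per-condition
#' probabilities, then emits tap times accordingly:
#' \itemize{
#'   \item \emph{beat} mode: one tap per beat window at
#'     `center + anticipation + noise`, the Gaussian noise SD following the
#'     profile's adaptation curve `A * exp(B * section)` (in nITI units,
#'     divided by `sqrt(2)` so that the SD of the resulting normalized
#'     intervals matches the curve);
#'   \item \emph{frequent} mode, dense: intervals Gaussian around
#'     `dense_iti_ms` with 5 percent CV, tempo-independent;
#'   \item \emph{frequent} mode, sparse: intervals Gaussian around
#'     `sparse_scale * base_period` with 25 percent CV;
#'   \item \emph{double} / \emph{triple} modes: a tap every second / third
#'     beat center (rare slow behaviours).
#' }
#'
#' @param profile A [tapper_profile()].
#' @param sequence The `stimulus_sequence` being tapped to.
#' @param grid The `beat_grid` derived from that sequence.
#' @param participant_id Identifier stored in the trial.
#' @param seed Optional seed for reproducibility.
#' @return A [tap_trial()] with attribute `mode` (the drawn mode).
#' @export
simulate_tapper <- function(profile, sequence, grid,
                            participant_id = "synthetic", seed = NULL) {
  stopifnot(inherits(profile, "tapper_profile"),
            inherits(sequence, "stimulus_sequence"),
            inherits(grid, "beat_grid"))
  if (!is.null(seed)) set.seed(seed)
  cond <- sequence$condition_label
  base_period <- 60 / sequence$config$base_tempo
  duration <- sequence$duration
  u <- stats::runif(1)
  p_freq <- profile$switch_probs[[cond]]
  p_dbl <- profile$double_probs[[cond]]
  p_trp <- profile$triple_probs[[cond]]
  mode <- if (u < p_freq) {
    if (stats::runif(1) < profile$dense_prob) "dense" else "sparse"
  } else if (u < p_freq + p_dbl) "double"
  else if (u < p_freq + p_dbl + p_trp) "triple"
  else "beat"

  centers <- grid$centers
  anticipation <- profile$anticipation_ms / 1000
  taps <- switch(mode,
    beat = {
      sections <- pmin(ceiling(seq_along(centers) / 3), 7L)
      sd_niti <- profile$beat_noise_A[[cond]] *
        exp(profile$beat_noise_B[[cond]] * sections)
      centers + anticipation +
        stats::rnorm(length(centers), 0, sd_niti * base_period / sqrt(2))
    },
    double = centers[seq(1, length(centers), by = 2)] + anticipation +
      stats::rnorm(ceiling(length(centers) / 2), 0, 0.05 * base_period),
    triple = centers[seq(1, length(centers), by = 3)] + anticipation +
      stats::rnorm(ceiling(length(centers) / 3), 0, 0.05 * base_period),
    dense = frequent_train(duration,
                           min(profile$dense_iti_ms / 1000,
                               profile$freq_cap * base_period),
                           cv = 0.05),
    sparse = frequent_train(duration,
                            min(profile$sparse_scale, profile$freq_cap) *
                              base_period,
                            cv = 0.25))
  taps <- taps[taps >= 0 & taps <= duration]
  trial <- tap_trial(participant_id, sequence$stimulus_id, taps,
                     base_period, condition_label = cond)
  attr(trial, "mode") <- mode
  trial
}

# tap train with iid Gaussian intervals, floored at 80 ms
frequent_train <- function(duration, mean_iti, cv) {
  n_max <- ceiling(duration / max(mean_iti * (1 - 3 * cv), 0.08)) + 2L
  itis <- pmax(stats::rnorm(n_max, mean_iti, cv * mean_iti), 0.08)
  taps <- cumsum(c(stats::runif(1, 0, mean_iti), itis))
  taps[taps <= duration]
}

#' Simulate a full synthetic cohort over a stimulus design
#'
#' One trial per tapper per stimulus sequence, with per-trial seeds derived
#' from the master seed. Default group sizes follow the published cohort:
#' 17 Regular, 24 Hybrid, 9 Fast.
#'
#' @param sequences Named list of `stimulus_sequence`s (e.g. from
#'   [batch_generate()]).
#' @param grids Named list of `beat_grid`s parallel to `sequences`
#'   (computed via [segment_sequence()] if omitted).
#' @param n_regular,n_hybrid,n_fast Group sizes (at least one tapper in
#'   total).
#' @param seed Master seed.
#' @param profiles Optional named list of [tapper_profile()] overrides per
#'   phenotype.
#' @return List with `trials` (list of `tap_trial`s), `truth` (data frame
#'   `participant_id`, `phenotype`) and `modes` (data frame of the drawn
#'   per-trial modes).
#' @export
simulate_cohort <- function(sequences, grids = NULL,
                            n_regular = 17L, n_hybrid = 24L, n_fast = 9L,
                            seed = 1L, profiles = NULL) {
  if (n_regular < 0 || n_hybrid < 0 || n_fast < 0)
    stop("group sizes must be non-negative")
  if (n_regular + n_hybrid + n_fast < 1L)
    stop("need at least one tapper")
  if (is.null(grids))
    grids <- lapply(sequences, segment_sequence)
  phenos <- rep(c("Regular", "Hybrid", "Fast"),
                c(n_regular, n_hybrid, n_fast))
  ids <- sprintf("P%02d", seq_along(phenos))
  if (is.null(profiles))
    profiles <- list(Regular = tapper_profile("Regular"),
                     Hybrid = tapper_profile("Hybrid"),
                     Fast = tapper_profile("Fast"))
  n_trials <- length(phenos) * length(sequences)
  seeds <- derive_seeds(seed, n_trials, salt = 7L)
  trials <- vector("list", n_trials)
  modes <- character(n_trials)
  trial_i <- 0L
  for (p in seq_along(phenos)) {
    prof <- profiles[[phenos[p]]]
    for (id in names(sequences)) {
      trial_i <- trial_i + 1L
      trials[[trial_i]] <- simulate_tapper(prof, sequences[[id]],
                                           grids[[id]],
                                           participant_id = ids[p],
                                           seed = seeds[trial_i])
      modes[trial_i] <- attr(trials[[trial_i]], "mode")
    }
  }
  list(trials = trials,
       truth = data.frame(participant_id = ids, phenotype = phenos),
       modes = data.frame(
         participant_id = rep(ids, each = length(sequences)),
         stimulus_id = rep(names(sequences), length(phenos)),
         mode = modes))
}
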