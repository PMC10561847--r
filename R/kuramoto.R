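#' Initialize the oscillator ensemble
#'
#' Draws intrinsic angular frequencies from a Gaussian distribution with
#' mean `2 * pi * base_tempo / 60` rad/s and standard deviation
#' `freq_sd_fraction` times that mean, and initial phases uniformly on
#' `[0, 2 * pi)`.
#'
#' @param config A [sim_config()].
#' @return An `ensemble_state` list with elements `phases`, `omegas`, `k`
#'   (current coupling coefficient) and `t` (elapsed time, seconds).
#' @examples
#' st <- init_ensemble(sim_config(base_tempo = 60, n_oscillators = 1,
#'                                freq_sd_fraction = 0, seed = 1))
#' st$omegas  # 2 * pi rad/s
#' @export
init_ensemble <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  omega_mean <- 2 * pi * config$base_tempo / 60
  n <- config$n_oscillators
  omegas <- if (config$freq_sd_fraction > 0) {
    stats::rnorm(n, mean = omega_mean, sd = config$freq_sd_fraction * omega_mean)
  } else {
    rep(omega_mean, n)
  }
  phases <- stats::runif(n, 0, 2 * pi)
  structure(list(phases = phases, omegas = omegas,
                 k = config$k_init, t = 0),
            class = "ensemble_state")
}

#' Complex order parameters of a set of phases
#'
#' Computes the mean-field phasor `R * exp(1i * phi)` of the unit vectors
#' at the given phase angles: `R` is the phase-coherence magnitude in
#' `[0, 1]` and `phi` the mean angle in `[-pi, pi)`. When `R` is numerically
#' zero the mean angle is undefined and flagged via `indeterminate`.
#'
#' @param phases Numeric vector of phase angles in radians (any range).
#' @return A `phasor_summary` list with `r`, `phi`, `n` and `indeterminate`.
#' @examples
#' order_parameters(c(0, pi / 2))  # r = cos(pi/4), phi = pi/4
#' @export
order_parameters <- function(phases) {
  if (length(phases) == 0L || !is.numeric(phases))
    stop("`phases` must be a non-empty numeric vector")
  z <- mean(complex(modulus = 1, argument = phases))
  r <- min(Mod(z), 1)
  indeterminate <- r < 1e-12
  structure(list(r = r,
                 phi = if (indeterminate) NA_real_ else Arg(z),
                 n = length(phases),
                 indeterminate = indeterminate),
            class = "phasor_summary")
}

#' @export
print.phasor_summary <- function(x, ...) {
  cat("<phasor> R = ", format(x$r, digits = 4),
      ", phi = ", format(x$phi, digits = 4),
      " rad, n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' One forward-Euler step of the mean-field Kuramoto dynamics
#'
#' Advances every phase by `dt * (omega_i + k * R * sin(phi - phi_i))`,
#' using the order parameters of the current state (attractive mean-field
#' coupling), then wraps to `[0, 2 * pi)`. Elapsed time advances by `dt`.
#'
#' @param state An `ensemble_state`.
#' @param config The [sim_config()] providing `dt`.
#' @return The advanced `ensemble_state`.
#' @export
euler_step <- function(state, config) {
  stopifnot(inherits(state, "ensemble_state"), inherits(config, "sim_config"))
  op <- order_parameters(state$phases)
  coupling <- if (op$indeterminate) 0 else
    state$k * op$r * sin(op$phi - state$phases)
  phases <- (state$phases + config$dt * (state$omegas + coupling)) %% (2 * pi)
  state$phases <- phases
  state$t <- state$t + config$dt
  state
}

#' Detect a completed cycle from wrapped phases
#'
#' An oscillator completes a cycle between two integration steps when its
#' wrapped phase decreases (the phase passed 2 * pi and re-entered near 0).
#'
#' @param prev_phase,curr_phase Wrapped phases in `[0, 2 * pi)`; vectors are
#'   compared element-wise.
#' @return Logical: `TRUE` where a cycle completed.
#' @examples
#' detect_wrap(6.2, 0.1)  # TRUE
#' detect_wrap(1.0, 1.1)  # FALSE
#' @export
detect_wrap <- function(prev_phase, curr_phase) {
  curr_phase < prev_phase
}

#' Bang-bang feedback update of the coupling coefficient
#'
#' Steps the coupling coefficient by a constant amount toward the target
#' coherence: incremented when the smoothed coherence is below target,
#' decremented when above, unchanged at equality; never below 0.
#'
#' @param k Current coupling coefficient (non-negative).
#' @param r_smoothed Exponentially smoothed coherence magnitude.
#' @param r_target Target coherence magnitude.
#' @param k_step Constant step size (non-negative).
#' @return The updated coupling coefficient.
#' @examples
#' feedback_update_k(1.0, 0.5, 0.9, 0.01)  # 1.01
#' @export
feedback_update_k <- function(k, r_smoothed, r_target, k_step) {
  if (!is.finite(k) || k < 0) stop("`k` must be finite and non-negative")
  if (!is.finite(k_step) || k_step < 0) stop("`k_step` must be non-negative")
  if (!is.finite(r_smoothed) || !is.finite(r_target))
    stop("coherence values must be finite")
  if (r_smoothed < r_target) k <- k + k_step
  else if (r_smoothed > r_target) k <- k - k_step
  max(k, 0)
}

#' Simulate one stimulus sequence
#'
#' Runs the forward-Euler loop for `duration_beats * 60 / base_tempo`
#' seconds, recording an onset event each time an oscillator completes a
#' cycle and the order parameters `R`, `psi` at every step. In feedback
#' mode the coupling coefficient is stepped each iteration toward
#' `r_target` based on an exponentially smoothed `R`.
#'
#' Onset times are quantized to the integration grid (multiples of `dt`),
#' matching the generator's temporal precision.
#'
#' @param config A [sim_config()].
#' @param condition_label Optional condition tag (`"strong"`, `"medium"`,
#'   `"weak"`, `"none"`); defaults to `"none"` for uncoupled configs and
#'   `"strong"` otherwise.
#' @param stimulus_id Optional identifier stored with the sequence.
#' @return A `stimulus_sequence` list with:
#'   \describe{
#'     \item{onsets}{data frame `oscillator_id`, `onset_time_s`, time-sorted.}
#'     \item{trace}{data frame `time_s`, `r`, `psi_rad` (one row per step).}
#'     \item{k_trace}{coupling coefficient per step.}
#'     \item{config}{the input configuration.}
#'     \item{condition_label, stimulus_id}{metadata.}
#'     \item{mean_r}{time-average of `R` over the whole sequence.}
#'     \item{duration}{sequence duration in seconds.}
#'   }
#' @examples
#' seq1 <- simulate_sequence(sim_config(coupling_mode = "none", seed = 1,
#'                                      duration_beats = 4))
#' head(seq1$onsets)
#' @export
simulate_sequence <- function(config, condition_label = NULL,
                              stimulus_id = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(condition_label))
    condition_label <- if (config$coupling_mode == "none") "none" else "strong"
  duration <- config$duration_beats * 60 / config$base_tempo
  n_steps <- ceiling(duration / config$dt)
  state <- init_ensemble(config)

  times <- numeric(n_steps)
  r_values <- numeric(n_steps)
  psi_values <- numeric(n_steps)
  k_values <- numeric(n_steps)
  onset_id <- vector("list", n_steps)
  r_ema <- NA_real_

  for (step in seq_len(n_steps)) {
    prev <- state$phases
    op <- order_parameters(prev)
    if (config$coupling_mode == "feedback") {
      r_ema <- if (is.na(r_ema)) op$r else
        (1 - config$r_smooth) * r_ema + config$r_smooth * op$r
      state$k <- feedback_update_k(state$k, r_ema, config$r_target,
                                   config$k_step)
    }
    state <- euler_step(state, config)
    wrapped <- detect_wrap(prev, state$phases)
    if (any(wrapped)) onset_id[[step]] <- which(wrapped)
    times[step] <- state$t
    r_values[step] <- op$r
    psi_values[step] <- if (op$indeterminate) 0 else op$phi
    k_values[step] <- state$k
  }

  counts <- lengths(onset_id)
  onsets <- data.frame(
    oscillator_id = unlist(onset_id, use.names = FALSE),
    onset_time_s = rep(times, counts))
  if (nrow(onsets) > 0)
    onsets <- onsets[order(onsets$onset_time_s, onsets$oscillator_id), ,
                     drop = FALSE]
  rownames(onsets) <- NULL

  structure(
    list(onsets = onsets,
         trace = data.frame(time_s = times, r = r_values,
                            psi_rad = psi_values),
         k_trace = k_values,
         config = config,
         condition_label = condition_label,
         stimulus_id = stimulus_id,
         mean_r = mean(r_values),
         duration = duration),
    class = "stimulus_sequence")
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat("<stimulus_sequence> ", if (is.null(x$stimulus_id)) "(unnamed)" else
        x$stimulus_id,
      ": ", x$condition_label, ", ", x$config$base_tempo, " BPM, ",
      nrow(x$onsets), " onsets over ", format(x$duration, digits = 4),
      " s, mean |R| = ", format(x$mean_r, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Generate every sequence of a factorial stimulus design
#'
#' Runs [simulate_sequence()] once per design row with a distinct seed
#' derived from `seed` so the whole batch is reproducible from one integer.
#'
#' @param design A design data frame as returned by [exp1_design()] or
#'   [exp2_design()].
#' @param seed Master seed for the batch.
#' @param n_oscillators,freq_sd_fraction,dt Passed to every [sim_config()].
#' @return A named list of `stimulus_sequence` objects (names are
#'   `stimulus_id`s).
#' @examples
#' \donttest{
#' seqs <- batch_generate(exp2_design(), seed = 1)
#' length(seqs)  # 40
#' }
#' @export
batch_generate <- function(design, seed, n_oscillators = 40L,
                           freq_sd_fraction = 0.03, dt = 0.016) {
  if (!is.data.frame(design) || nrow(design) == 0L)
    stop("`design` must be a non-empty data frame")
  needed <- c("stimulus_id", "condition", "tempo_bpm", "coupling_mode",
              "k_init", "duration_beats")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols))
    stop("design is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(design$stimulus_id))
    stop("duplicate design cells (stimulus_id values must be unique)")
  seeds <- derive_seeds(seed, nrow(design))
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    cfg <- sim_config(
      n_oscillators = n_oscillators,
      base_tempo = row$tempo_bpm,
      freq_sd_fraction = freq_sd_fraction,
      coupling_mode = row$coupling_mode,
      k_init = row$k_init,
      r_target = if (is.na(row$r_target)) 1 else row$r_target,
      dt = dt,
      duration_beats = row$duration_beats,
      seed = seeds[i])
    out[[i]] <- simulate_sequence(cfg, condition_label = row$condition,
                                  stimulus_id = row$stimulus_id)
  }
  names(out) <- design$stimulus_id
  out
}

# Deterministic stream of sub-seeds below 2^31, spread out from one master
# seed so consecutive batches do not collide.
derive_seeds <- function(seed, n, salt = 0L) {
  (as.double(seed) * 7919 + salt * 104729 + 1000 * seq_len(n)) %% 2147483629
}
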