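#' Inter-tap intervals
#'
#' First differences of a strictly increasing tap-time series; empty if
#' there are fewer than two taps.
#'
#' @param tap_times Tap times in seconds, strictly increasing.
#' @return Numeric vector of intervals in seconds.
#' @examples
#' compute_itis(c(0, 0.5, 1.0))  # 0.5 0.5
#' @export
compute_itis <- function(tap_times) {
  if (length(tap_times) < 2L) return(numeric(0))
  if (is.unsorted(tap_times, strictly = TRUE))
    stop("`tap_times` must be strictly increasing")
  diff(tap_times)
}

#' Normalize inter-tap intervals by the stimulus mean period
#'
#' Divides each interval by the design beat period (`60 / base_tempo`), so
#' that tapping aligned with every beat has mean normalized ITI (nITI) 1,
#' comparable across tempo conditions.
#'
#' @param itis Intervals in seconds.
#' @param base_period Stimulus mean beat period in seconds (> 0).
#' @return Dimensionless intervals.
#' @export
normalize_itis <- function(itis, base_period) {
  if (!is.finite(base_period) || base_period <= 0)
    stop("`base_period` must be positive")
  itis / base_period
}

#' Build a tap trial with derived interval metrics
#'
#' @param participant_id,stimulus_id Identifiers.
#' @param tap_times Strictly increasing tap times in seconds (duplicates
#'   are removed).
#' @param base_period Stimulus mean beat period in seconds.
#' @param condition_label Optional coupling-condition tag.
#' @return A `tap_trial` list with `tap_times`, `itis`, `nitis` and
#'   metadata.
#' @export
tap_trial <- function(participant_id, stimulus_id, tap_times, base_period,
                      condition_label = NA_character_) {
  tap_times <- sort(unique(as.numeric(tap_times)))
  itis <- compute_itis(tap_times)
  structure(
    list(participant_id = as.character(participant_id),
         stimulus_id = as.character(stimulus_id),
         tap_times = tap_times,
         itis = itis,
         nitis = if (length(itis)) normalize_itis(itis, base_period)
                 else numeric(0),
         base_period = base_period,
         condition_label = condition_label),
    class = "tap_trial")
}

#' @export
print.tap_trial <- function(x, ...) {
  cat("<tap_trial> ", x$participant_id, " x ", x$stimulus_id, ": ",
      length(x$tap_times), " taps, mean nITI = ",
      if (length(x$nitis)) format(mean(x$nitis), digits = 3) else "NA",
      "\n", sep = "")
  invisible(x)
}

#' Tap-section summaries of normalized ITIs
#'
#' Splits the first `n_sections * section_size` intervals into consecutive
#' non-overlapping sections of `section_size` intervals each and reports
#' per-section mean and SD. Sections with fewer than `section_size`
#' available intervals are marked incomplete (and should be excluded from
#' curve fits).
#'
#' @param nitis Normalized intervals.
#' @param section_size Intervals per section (default 3).
#' @param n_sections Number of sections: 3 for the short constant-coupling
#'   design, 7 for the 22-beat feedback design.
#' @return Data frame `section`, `mean_niti`, `sd_niti`, `n`, `complete`.
#' @export
section_stats <- function(nitis, section_size = 3L, n_sections = 7L) {
  section_size <- as.integer(section_size)
  n_sections <- as.integer(n_sections)
  if (is.na(section_size) || section_size < 2L)
    stop("`section_size` must be >= 2")
  if (is.na(n_sections) || n_sections < 1L)
    stop("`n_sections` must be >= 1")
  out <- data.frame(section = seq_len(n_sections),
                    mean_niti = NA_real_, sd_niti = NA_real_,
                    n = 0L, complete = FALSE)
  for (s in seq_len(n_sections)) {
    idx <- ((s - 1L) * section_size + 1L):(s * section_size)
    vals <- nitis[idx[idx <= length(nitis)]]
    out$n[s] <- length(vals)
    if (length(vals)) {
      out$mean_niti[s] <- mean(vals)
      out$sd_niti[s] <- stats::sd(vals)
    }
    out$complete[s] <- length(vals) == section_size
  }
  out
}

#' Fit an exponential to a per-section SD trajectory
#'
#' Fits `y(t) = A * exp(B * t)` to section SD values at `t = 1..S` by
#' least squares on the log scale (degree-1 polynomial on `(t, log y)`);
#' `A` is `exp(intercept)` and `B` the slope. `r_squared` and the
#' coefficient p-values come from the log-scale linear fit. Non-positive
#' values are floored at `1e-6` with a warning.
#'
#' @param sd_by_section Per-section SD values (sections `1..S` in order).
#' @return An `exp_fit` list with `A`, `B`, `r_squared`, `p_A`, `p_B`.
#' @examples
#' fit_exponential(0.5 * exp(-0.25 * (1:7)))  # recovers A = 0.5, B = -0.25
#' @export
fit_exponential <- function(sd_by_section) {
  y <- as.numeric(sd_by_section)
  y <- y[!is.na(y)]
  if (length(y) < 3L) stop("need at least 3 section values")
  if (any(y <= 0)) {
    warning("non-positive SD values floored at 1e-6 before log fit")
    y <- pmax(y, 1e-6)
  }
  t <- seq_along(y)
  if (max(y) - min(y) < 1e-12) {
    return(structure(list(A = y[1], B = 0, r_squared = NA_real_,
                          p_A = NA_real_, p_B = NA_real_),
                     class = "exp_fit"))
  }
  fit <- stats::lm(log(y) ~ t)
  sm <- summary(fit)
  structure(
    list(A = unname(exp(stats::coef(fit)[1])),
         B = unname(stats::coef(fit)[2]),
         r_squared = sm$r.squared,
         p_A = sm$coefficients[1, 4],
         p_B = sm$coefficients[2, 4]),
    class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("<exp_fit> y(t) = ", format(x$A, digits = 3), " * exp(",
      format(x$B, digits = 3), " * t), R^2 = ",
      format(x$r_squared, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Screen a participant by practice-trial compliance
#'
#' A participant passes only if every strong-coupling practice trial
#' contains strictly more than 80 percent of the expected tap count (one
#' tap per beat window) and every other practice trial contains at least
#' two taps.
#'
#' @param practice_trials List of `tap_trial`s; strong trials are those
#'   with `condition_label == "strong"`.
#' @param expected_counts Named or positional expected tap counts for the
#'   strong trials (typically the number of beat windows).
#' @return List with `pass` (logical) and `reason` (character).
#' @export
screen_participant <- function(practice_trials, expected_counts) {
  if (length(practice_trials) == 0L)
    return(list(pass = FALSE, reason = "no practice trials"))
  is_strong <- vapply(practice_trials,
                      function(tr) identical(tr$condition_label, "strong"),
                      logical(1))
  strong <- practice_trials[is_strong]
  if (length(strong) && (length(expected_counts) < length(strong) ||
                         any(expected_counts[seq_along(strong)] <= 0)))
    stop("`expected_counts` must provide a positive count per strong trial")
  for (i in seq_along(strong)) {
    n_taps <- length(strong[[i]]$tap_times)
    if (n_taps <= 0.8 * expected_counts[i])
      return(list(pass = FALSE,
                  reason = sprintf(
                    "strong practice trial %s: %d taps <= 80%% of %d",
                    strong[[i]]$stimulus_id, n_taps, expected_counts[i])))
  }
  for (tr in practice_trials[!is_strong]) {
    if (length(tr$tap_times) < 2L)
      return(list(pass = FALSE,
                  reason = sprintf("practice trial %s: fewer than 2 taps",
                                   tr$stimulus_id)))
  }
  list(pass = TRUE, reason = "ok")
}
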