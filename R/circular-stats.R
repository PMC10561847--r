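#' Map an event time to a within-beat phase angle
#'
#' Piecewise-linear circle map over one beat window: the window start maps
#' to `-pi`, the beat center to 0 and the window end to `+pi`, with two
#' separate linear segments so that asymmetric windows keep the center at
#' phase 0. Negative phases mean the event leads the beat center, positive
#' phases that it lags.
#'
#' @param event_time Event time in seconds (vectorized).
#' @param window_start,window_end Window bounds (half-open
#'   `[start, end)`).
#' @param center Beat center inside the window.
#' @return Phase angle(s) in radians in `[-pi, pi)`.
#' @export
window_phase <- function(event_time, window_start, window_end, center) {
  if (any(event_time < window_start | event_time >= window_end))
    stop("event outside its window")
  if (center <= window_start || center >= window_end)
    stop("center must lie strictly inside the window")
  ifelse(event_time <= center,
         -pi + (event_time - window_start) / (center - window_start) * pi,
         (event_time - center) / (window_end - center) * pi)
}

#' Within-beat phases of events against a beat grid
#'
#' Assigns events to windows and applies [window_phase()] per window;
#' events outside the grid span are dropped.
#'
#' @param event_times Event times in seconds.
#' @param grid A `beat_grid`.
#' @return Numeric vector of phases in radians.
#' @export
grid_phases <- function(event_times, grid) {
  asg <- assign_to_windows(event_times, grid)
  asg <- asg[!asg$excluded, , drop = FALSE]
  if (nrow(asg) == 0L) return(numeric(0))
  w <- grid$windows
  vapply(seq_len(nrow(asg)), function(i) {
    j <- asg$window[i]
    window_phase(asg$event_time_s[i], w$window_start_s[j],
                 w$window_end_s[j], w$center_s[j])
  }, numeric(1))
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether a sample of angles departs from uniformity on the circle.
#' The statistic is `z = n * Rbar^2` where `Rbar` is the mean resultant
#' length; the p-value uses the standard small-sample-corrected
#' approximation.
#'
#' @param angles Angles in radians, at least 4.
#' @return List with `z`, `p`, `r_bar`, `n`.
#' @examples
#' rayleigh_test(rep(0.3, 50))$p  # tiny: maximal concentration
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 4L) stop("Rayleigh test needs at least 4 angles")
  r_bar <- Mod(mean(complex(modulus = 1, argument = angles)))
  z <- n * r_bar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * r_bar)^2)) - (1 + 2 * n))
  list(z = z, p = min(max(p, .Machine$double.xmin), 1), r_bar = r_bar, n = n)
}

#' Watson-Wheeler two-sample test for circular distributions
#'
#' Nonparametric comparison of two samples of angles using uniform scores:
#' pooled angles receive circular ranks (ties get average ranks), each rank
#' is mapped to a uniform score `2 * pi * rank / N`, and the statistic
#' `W = 2 * sum_j (C_j^2 + S_j^2) / n_j` is referred to a chi-square
#' distribution with 2 degrees of freedom. Requires at least 10 angles per
#' sample for the chi-square approximation; for smaller samples use
#' `method = "permutation"`.
#'
#' @param angles_a,angles_b Angle samples in radians.
#' @param method `"asymptotic"` (chi-square, default) or `"permutation"`.
#' @param n_perm Number of permutations when `method = "permutation"`.
#' @return List with `w`, `p`, `n_a`, `n_b`, `method`.
#' @export
watson_wheeler_test <- function(angles_a, angles_b,
                                method = c("asymptotic", "permutation"),
                                n_perm = 2000L) {
  method <- match.arg(method)
  n_a <- length(angles_a)
  n_b <- length(angles_b)
  if (method == "asymptotic" && (n_a < 10L || n_b < 10L))
    stop("Watson-Wheeler chi-square approximation needs >= 10 angles per ",
         "sample; use method = \"permutation\" for smaller samples")
  if (n_a < 2L || n_b < 2L) stop("each sample needs at least 2 angles")
  w_obs <- ww_statistic(angles_a, angles_b)
  if (method == "asymptotic") {
    p <- stats::pchisq(w_obs, df = 2, lower.tail = FALSE)
  } else {
    pooled <- c(angles_a, angles_b)
    n <- n_a + n_b
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n, n_a)
      if (ww_statistic(pooled[idx], pooled[-idx]) >= w_obs)
        exceed <- exceed + 1L
    }
    p <- (exceed + 1) / (n_perm + 1)
  }
  list(w = w_obs, p = p, n_a = n_a, n_b = n_b, method = method)
}

# uniform-scores statistic shared by both p-value routes
ww_statistic <- function(angles_a, angles_b) {
  n_a <- length(angles_a)
  pooled <- c(angles_a, angles_b) %% (2 * pi)
  ranks <- rank(pooled, ties.method = "average")
  scores <- 2 * pi * ranks / length(pooled)
  grp <- rep(c(TRUE, FALSE), c(n_a, length(angles_b)))
  w <- 0
  for (g in c(TRUE, FALSE)) {
    s <- scores[grp == g]
    w <- w + (sum(cos(s))^2 + sum(sin(s))^2) / length(s)
  }
  2 * w
}

#' Pooled tap and onset phasors per coupling condition
#'
#' Pools within-beat phases of participant taps and of stimulus onsets
#' across all trials of each coupling condition, and summarizes each pool
#' as a mean phasor. Tap angles are reported after rotating each
#' condition so that the stimulus-onset mean angle sits at 0 (the onset
#' phasor is the reference direction).
#'
#' @param trials List of `tap_trial`s.
#' @param sequences Named list of `stimulus_sequence`s covering every
#'   `stimulus_id` in `trials`.
#' @param grids Named list of `beat_grid`s parallel to `sequences`.
#' @return Data frame with one row per condition and role (`tap` /
#'   `onset`): `condition`, `who`, `r`, `phi_rad`, `n`, `rayleigh_z`,
#'   `rayleigh_p`. Conditions without events are flagged with `n = 0`.
#' @export
condition_phasors <- function(trials, sequences, grids) {
  stopifnot(length(sequences) == length(grids))
  conds <- unique(vapply(sequences, function(s) s$condition_label,
                         character(1)))
  tap_pool <- stats::setNames(vector("list", length(conds)), conds)
  onset_pool <- tap_pool
  for (id in names(sequences)) {
    cond <- sequences[[id]]$condition_label
    onset_pool[[cond]] <- c(onset_pool[[cond]],
                            grid_phases(sequences[[id]]$onsets$onset_time_s,
                                        grids[[id]]))
  }
  for (tr in trials) {
    id <- tr$stimulus_id
    if (!id %in% names(sequences))
      stop("no stimulus sequence for trial stimulus ", id)
    cond <- sequences[[id]]$condition_label
    tap_pool[[cond]] <- c(tap_pool[[cond]],
                          grid_phases(tr$tap_times, grids[[id]]))
  }
  rows <- list()
  for (cond in conds) {
    onset_op <- if (length(onset_pool[[cond]]))
      order_parameters(onset_pool[[cond]]) else NULL
    ref <- if (!is.null(onset_op) && !onset_op$indeterminate) onset_op$phi
           else 0
    for (who in c("tap", "onset")) {
      pool <- if (who == "tap") tap_pool[[cond]] else onset_pool[[cond]]
      if (length(pool) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          condition = cond, who = who, r = NA_real_, phi_rad = NA_real_,
          n = 0L, rayleigh_z = NA_real_, rayleigh_p = NA_real_)
        next
      }
      op <- order_parameters(pool)
      ray <- if (length(pool) >= 4L) rayleigh_test(pool) else
        list(z = NA_real_, p = NA_real_)
      phi <- if (op$indeterminate) NA_real_ else
        ((op$phi - ref + pi) %% (2 * pi)) - pi
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond, who = who, r = op$r, phi_rad = phi,
        n = op$n, rayleigh_z = ray$z, rayleigh_p = ray$p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
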