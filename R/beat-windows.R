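#' Extract referent beat centers from a coherence trace
#'
#' Beat centers are the cycle completions of the ensemble mean angle psi:
#' the trace's wrapped psi series is unwrapped (step differences mapped to
#' `(-pi, pi]`) and each upward crossing of a multiple of `2 * pi` marks a
#' center, with the crossing time interpolated linearly between steps.
#'
#' For weakly or un-coupled stimuli the mean-angle trajectory is noisy and
#' crossings can be far apart; any inter-center gap of at least twice the
#' mean oscillator period is handled according to `gap_mode`: `"fill"`
#' (default) inserts synthetic centers spaced `mean_period` apart until the
#' remaining gap is below `2 * mean_period`; `"drop"` leaves the gap.
#'
#' @param trace Data frame with columns `time_s` and `psi_rad` (a
#'   `stimulus_sequence$trace` works directly).
#' @param mean_period Mean oscillator period in seconds (usually
#'   `60 / base_tempo`).
#' @param gap_mode `"fill"` or `"drop"`.
#' @return Numeric vector of strictly increasing center times (seconds),
#'   with attribute `synthetic` flagging inserted centers.
#' @export
extract_beat_centers <- function(trace, mean_period,
                                 gap_mode = c("fill", "drop")) {
  gap_mode <- match.arg(gap_mode)
  if (!is.data.frame(trace) || nrow(trace) == 0L)
    stop("`trace` must be a non-empty data frame")
  if (!all(c("time_s", "psi_rad") %in% names(trace)))
    stop("`trace` needs columns `time_s` and `psi_rad`")
  if (!is.finite(mean_period) || mean_period <= 0)
    stop("`mean_period` must be positive")
  times <- trace$time_s
  if (max(times) - min(times) < mean_period)
    stop("trace is shorter than one mean period")

  # unwrap: map step differences into (-pi, pi] and accumulate
  psi <- trace$psi_rad
  d <- diff(psi)
  d <- d - 2 * pi * round(d / (2 * pi))
  unwrapped <- cumsum(c(psi[1], d))

  # upward crossings of 2*pi levels; linear interpolation within the step
  levels_lo <- ceiling(unwrapped[-length(unwrapped)] / (2 * pi))
  levels_hi <- floor(unwrapped[-1] / (2 * pi))
  centers <- numeric(0)
  crossing_steps <- which(levels_hi >= levels_lo &
                          unwrapped[-1] > unwrapped[-length(unwrapped)])
  crossed <- numeric(0)
  for (s in crossing_steps) {
    for (lev in levels_lo[s]:levels_hi[s]) {
      target <- 2 * pi * lev
      if (length(crossed) && any(abs(crossed - target) < 1e-9)) next
      frac <- (target - unwrapped[s]) / (unwrapped[s + 1] - unwrapped[s])
      centers <- c(centers, times[s] + frac * (times[s + 1] - times[s]))
      crossed <- c(crossed, target)
    }
  }
  centers <- sort(centers)
  synthetic <- rep(FALSE, length(centers))

  if (gap_mode == "fill" && length(centers) >= 2L) {
    out_c <- centers[1]
    out_s <- FALSE
    for (i in seq_along(centers)[-1]) {
      gap <- centers[i] - out_c[length(out_c)]
      while (gap >= 2 * mean_period) {
        out_c <- c(out_c, out_c[length(out_c)] + mean_period)
        out_s <- c(out_s, TRUE)
        gap <- centers[i] - out_c[length(out_c)]
      }
      out_c <- c(out_c, centers[i])
      out_s <- c(out_s, FALSE)
    }
    centers <- out_c
    synthetic <- out_s
  }
  if (length(centers) == 0L)
    stop("no beat centers found in trace")
  attr(centers, "synthetic") <- synthetic
  centers
}

#' Build beat windows around beat centers
#'
#' Interior window boundaries sit at the midpoints between consecutive
#' centers; the first window starts half a mean period before the first
#' center (floored at 0) and the last ends half a mean period after the
#' last center. Windows are half-open `[start, end)`.
#'
#' @param centers Strictly increasing center times in seconds.
#' @param mean_period Mean beat period in seconds.
#' @return A `beat_grid` list with `centers`, `windows` (data frame
#'   `center_s`, `window_start_s`, `window_end_s`) and `mean_period`.
#' @examples
#' build_beat_windows(c(1, 2, 3), 1)
#' @export
build_beat_windows <- function(centers, mean_period) {
  centers <- as.numeric(centers)
  if (length(centers) < 1L) stop("need at least one center")
  if (is.unsorted(centers, strictly = TRUE))
    stop("`centers` must be strictly increasing")
  if (!is.finite(mean_period) || mean_period <= 0)
    stop("`mean_period` must be positive")
  starts <- c(max(centers[1] - mean_period / 2, 0),
              (centers[-length(centers)] + centers[-1]) / 2)
  ends <- c((centers[-length(centers)] + centers[-1]) / 2,
            centers[length(centers)] + mean_period / 2)
  structure(
    list(centers = centers,
         windows = data.frame(center_s = centers, window_start_s = starts,
                              window_end_s = ends),
         mean_period = mean_period),
    class = "beat_grid")
}

#' @export
print.beat_grid <- function(x, ...) {
  cat("<beat_grid> ", length(x$centers), " beat centers spanning [",
      format(x$windows$window_start_s[1], digits = 4), ", ",
      format(x$windows$window_end_s[nrow(x$windows)], digits = 4),
      ") s, mean period ", format(x$mean_period, digits = 4), " s\n",
      sep = "")
  invisible(x)
}

#' Segment a stimulus sequence into a beat grid
#'
#' Convenience wrapper: extracts beat centers from the sequence's coherence
#' trace (mean period taken as `60 / base_tempo`) and builds the windows.
#'
#' @param sequence A `stimulus_sequence`.
#' @param gap_mode Passed to [extract_beat_centers()].
#' @return A `beat_grid`.
#' @export
segment_sequence <- function(sequence, gap_mode = "fill") {
  stopifnot(inherits(sequence, "stimulus_sequence"))
  mean_period <- 60 / sequence$config$base_tempo
  centers <- extract_beat_centers(sequence$trace, mean_period,
                                  gap_mode = gap_mode)
  grid <- build_beat_windows(as.numeric(centers), mean_period)
  attr(grid, "synthetic") <- attr(centers, "synthetic")
  grid
}

#' Assign event times to beat windows
#'
#' Maps each event to the half-open window `[start, end)` containing it;
#' an event exactly on a boundary belongs to the later window. Events
#' outside the grid's span are flagged excluded (window index `NA`).
#'
#' @param event_times Numeric vector of event times in seconds.
#' @param grid A `beat_grid`.
#' @return Data frame with `event_time_s`, `window` (index or `NA`),
#'   `offset_s` (time minus that window's center) and `excluded`.
#' @export
assign_to_windows <- function(event_times, grid) {
  stopifnot(inherits(grid, "beat_grid"))
  w <- grid$windows
  boundaries <- c(w$window_start_s, w$window_end_s[nrow(w)])
  idx <- findInterval(event_times, boundaries, left.open = FALSE,
                      rightmost.closed = FALSE)
  excluded <- idx < 1L | idx > nrow(w) |
    event_times >= w$window_end_s[nrow(w)]
  idx[excluded] <- NA_integer_
  data.frame(event_time_s = event_times,
             window = idx,
             offset_s = event_times - w$center_s[idx],
             excluded = excluded)
}
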