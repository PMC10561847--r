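#' Render a stimulus sequence to a click-train audio buffer
#'
#' Superimposes one short percussive click (an exponentially decaying sine
#' burst) per onset at the nearest sample, sums overlapping clicks and
#' peak-normalizes the mix.
#'
#' @param sequence A `stimulus_sequence`.
#' @param sample_rate Samples per second, at least 8000 (default 44100).
#' @param click_freq Click carrier frequency in Hz.
#' @param click_decay Exponential amplitude decay rate of the click (1/s).
#' @return Numeric vector of samples in `[-1, 1]` with attributes
#'   `sample_rate` and `duration`.
#' @export
render_clicks <- function(sequence, sample_rate = 44100,
                          click_freq = 1800, click_decay = 80) {
  stopifnot(inherits(sequence, "stimulus_sequence"))
  if (!is.finite(sample_rate) || sample_rate < 8000)
    stop("`sample_rate` must be >= 8000 Hz")
  n_samples <- ceiling(sequence$duration * sample_rate)
  buf <- numeric(n_samples)
  click_len <- ceiling(0.05 * sample_rate)
  tt <- seq(0, by = 1 / sample_rate, length.out = click_len)
  click <- sin(2 * pi * click_freq * tt) * exp(-click_decay * tt)
  for (onset in sequence$onsets$onset_time_s) {
    start <- round(onset * sample_rate) + 1
    if (start > n_samples) next
    idx <- start:min(start + click_len - 1, n_samples)
    buf[idx] <- buf[idx] + click[seq_along(idx)]
  }
  peak <- max(abs(buf))
  if (peak > 0) buf <- buf / peak
  attr(buf, "sample_rate") <- sample_rate
  attr(buf, "duration") <- sequence$duration
  buf
}

#' Write an audio buffer as a mono 16-bit PCM WAV file
#'
#' @param buffer Numeric samples in `[-1, 1]` (values outside are clipped),
#'   e.g. from [render_clicks()].
#' @param path Output file path.
#' @param sample_rate Samples per second; defaults to the buffer's
#'   `sample_rate` attribute.
#' @return `path`, invisibly.
#' @export
write_wav <- function(buffer, path, sample_rate = attr(buffer, "sample_rate")) {
  if (is.null(sample_rate)) sample_rate <- 44100L
  sample_rate <- as.integer(sample_rate)
  pcm <- as.integer(round(pmax(pmin(buffer, 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")         # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")          # PCM
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(sample_rate, con, size = 4, endian = "little")
  writeBin(sample_rate * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")          # block align
  writeBin(16L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
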