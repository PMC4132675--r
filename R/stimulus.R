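#' Tone-cloud specification
#'
#' Parameters of the time-frequency grid from which tone clouds are drawn.
#' A cloud segment divides the time-frequency plane into non-overlapping
#' frequency channels (a fixed number per octave) and fixed-length time
#' windows; each grid cell receives exactly one pure-tone pip with random
#' onset within its window and random (log-uniform) frequency within its
#' channel. Matching counts per channel and window give all clouds the same
#' long-term spectrum and temporal envelope on average.
#'
#' @param f_min,f_max Frequency range covered by the channels (Hz).
#' @param channels_per_octave Number of frequency channels per octave.
#' @param window_s Duration of one time window (s).
#' @param pip_duration_s Duration of each tone pip (s). Pips keep this fixed
#'   duration even when their random onset makes them overrun the window;
#'   they are truncated only at the segment boundary so that repeated
#'   segments stay sample-identical.
#' @param segment_s Duration of one cloud segment (s); must be an integer
#'   multiple of `window_s`.
#' @param n_segments Number of contiguous segments per stimulus.
#' @param sample_rate Audio sample rate (samples/s).
#' @param ramp_s Raised-cosine onset/offset ramp applied to each pip (s).
#' @param rms Target root-mean-square level of the rendered stimulus
#'   (linear units; the whole waveform is rescaled after synthesis).
#'
#' @return An object of class `tone_cloud_spec`.
#' @export
tone_cloud_spec <- function(f_min = 100, f_max = 10000, channels_per_octave = 2,
                            window_s = 0.05, pip_duration_s = 0.05,
                            segment_s = 0.5, n_segments = 3,
                            sample_rate = 44100, ramp_s = 0.005, rms = 0.1) {
  if (!is.numeric(f_min) || !is.numeric(f_max) || f_min <= 0 || f_max <= f_min)
    stop("invalid spec: need 0 < f_min < f_max", call. = FALSE)
  if (channels_per_octave < 1) stop("invalid spec: channels_per_octave >= 1", call. = FALSE)
  n_windows <- segment_s / window_s
  if (abs(n_windows - round(n_windows)) > 1e-9)
    stop("invalid spec: segment_s must be an integer multiple of window_s", call. = FALSE)
  if (n_segments < 1) stop("invalid spec: n_segments >= 1", call. = FALSE)
  if (pip_duration_s > segment_s)
    stop("invalid spec: pip_duration_s must not exceed segment_s", call. = FALSE)
  structure(list(f_min = f_min, f_max = f_max,
                 channels_per_octave = channels_per_octave,
                 window_s = window_s, pip_duration_s = pip_duration_s,
                 segment_s = segment_s, n_segments = n_segments,
                 sample_rate = sample_rate, ramp_s = ramp_s, rms = rms),
            class = "tone_cloud_spec")
}

#' Frequency channels tiling a range
#'
#' Divides `[f_min, f_max]` into contiguous bands of width
#' `1/channels_per_octave` octave starting at `f_min`; the last band is
#' truncated at `f_max` so the union covers the range exactly.
#'
#' @param f_min,f_max Frequency bounds (Hz), `0 < f_min < f_max`.
#' @param channels_per_octave Channels per octave.
#' @return A data frame with columns `index`, `low_hz`, `high_hz`.
#' @export
make_frequency_channels <- function(f_min, f_max, channels_per_octave) {
  if (!is.numeric(f_min) || !is.numeric(f_max) || f_min <= 0 || f_max <= f_min)
    stop("invalid spec: need 0 < f_min < f_max", call. = FALSE)
  if (channels_per_octave < 1) stop("invalid spec: channels_per_octave >= 1", call. = FALSE)
  n <- ceiling(channels_per_octave * log2(f_max / f_min) - 1e-9)
  lo <- f_min * 2^((seq_len(n) - 1) / channels_per_octave)
  hi <- pmin(f_min * 2^(seq_len(n) / channels_per_octave), f_max)
  data.frame(index = seq_len(n), low_hz = lo, high_hz = hi)
}

# Draw the pip table for one segment: one pip per (channel, window) cell.
draw_pip_table <- function(spec) {
  ch <- make_frequency_channels(spec$f_min, spec$f_max, spec$channels_per_octave)
  n_windows <- round(spec$segment_s / spec$window_s)
  grid <- expand.grid(channel_index = ch$index, window_index = seq_len(n_windows))
  lo <- ch$low_hz[grid$channel_index]
  hi <- ch$high_hz[grid$channel_index]
  n <- nrow(grid)
  data.frame(
    channel_index = grid$channel_index,
    window_index = grid$window_index,
    onset_s = (grid$window_index - 1) * spec$window_s + runif(n) * spec$window_s,
    frequency_hz = exp(runif(n, log(lo), log(hi))),
    duration_s = spec$pip_duration_s,
    amplitude = 1
  )
}

# Render a pip table to one segment waveform of exactly segment_s seconds.
# Pips keep their nominal duration but are truncated at the segment end.
render_segment <- function(pips, spec) {
  sr <- spec$sample_rate
  n_samp <- round(spec$segment_s * sr)
  wave <- numeric(n_samp)
  n_pip_samp <- round(spec$pip_duration_s * sr)
  t_pip <- (seq_len(n_pip_samp) - 1) / sr
  env <- rep(1, n_pip_samp)
  n_ramp <- round(spec$ramp_s * sr)
  if (n_ramp > 0) {
    r <- 0.5 * (1 - cos(pi * (seq_len(n_ramp) - 0.5) / n_ramp))
    env[seq_len(n_ramp)] <- r
    env[n_pip_samp + 1 - seq_len(n_ramp)] <- r
  }
  for (i in seq_len(nrow(pips))) {
    start <- round(pips$onset_s[i] * sr) + 1
    idx <- start:min(start + n_pip_samp - 1, n_samp)
    k <- seq_along(idx)
    wave[idx] <- wave[idx] +
      pips$amplitude[i] * env[k] * sin(2 * pi * pips$frequency_hz[i] * t_pip[k])
  }
  wave
}

#' Synthesise one tone-cloud segment
#'
#' Draws one pip per time-frequency grid cell (onset uniform within the
#' cell's window, frequency log-uniform within its channel) and renders the
#' summed waveform with raised-cosine ramps per pip. Uses the R random
#' number generator; call [set.seed()] beforehand for reproducibility.
#'
#' @param spec A [tone_cloud_spec()].
#' @return A list with `pips` (data frame, one row per grid cell) and
#'   `waveform` (numeric vector of `segment_s * sample_rate` samples).
#' @export
synthesize_segment <- function(spec) {
  stopifnot(inherits(spec, "tone_cloud_spec"))
  pips <- draw_pip_table(spec)
  list(pips = pips, waveform = render_segment(pips, spec))
}

#' Synthesise a full tone-cloud stimulus
#'
#' Builds a stimulus of `n_segments` contiguous segments:
#' * `"RTC"` (repeated tone cloud): one fresh segment repeated;
#' * `"NTC"` (non-repeated): independent fresh segments;
#' * `"RefTC"` (reference repeated tone cloud): a stored exemplar segment
#'   repeated -- the same exemplar recurs across trials, which is the only
#'   difference between RefTC and RTC.
#'
#' The final waveform is RMS-normalised to `spec$rms`.
#'
#' @param category `"RefTC"`, `"RTC"` or `"NTC"`.
#' @param spec A [tone_cloud_spec()].
#' @param ref_exemplar For `"RefTC"`, a stored exemplar as returned by
#'   [make_ref_exemplar()] (its pip table is reused verbatim).
#' @param exemplar_id Optional identifier recorded on RefTC stimuli.
#' @return An object of class `tone_cloud_stimulus` with fields `category`,
#'   `exemplar_id`, `segments` (list of pip tables), `waveform` and `spec`.
#' @export
synthesize_stimulus <- function(category = c("RTC", "NTC", "RefTC"), spec,
                                ref_exemplar = NULL, exemplar_id = NULL) {
  category <- match.arg(category)
  stopifnot(inherits(spec, "tone_cloud_spec"))
  if (category == "RefTC") {
    if (is.null(ref_exemplar))
      stop("missing exemplar: RefTC requires a stored ref_exemplar", call. = FALSE)
    pips <- ref_exemplar$pips
    if (is.null(exemplar_id)) exemplar_id <- ref_exemplar$exemplar_id
    segments <- rep(list(pips), spec$n_segments)
  } else if (category == "RTC") {
    pips <- draw_pip_table(spec)
    segments <- rep(list(pips), spec$n_segments)
  } else {
    segments <- replicate(spec$n_segments, draw_pip_table(spec), simplify = FALSE)
  }
  waves <- lapply(segments, render_segment, spec = spec)
  waveform <- unlist(waves, use.names = FALSE)
  r <- sqrt(mean(waveform^2))
  if (r > 0) waveform <- waveform * (spec$rms / r)
  structure(list(category = category, exemplar_id = exemplar_id,
                 segments = segments, waveform = waveform, spec = spec),
            class = "tone_cloud_stimulus")
}

#' Create and store a reference exemplar
#'
#' Draws one segment's pip table to serve as a fixed RefTC exemplar that can
#' be replayed identically across trials.
#'
#' @param spec A [tone_cloud_spec()].
#' @param exemplar_id Identifier (1-3 in the standard design).
#' @return A list with `exemplar_id` and `pips`.
#' @export
make_ref_exemplar <- function(spec, exemplar_id = 1L) {
  stopifnot(inherits(spec, "tone_cloud_spec"))
  list(exemplar_id = as.integer(exemplar_id), pips = draw_pip_table(spec))
}

#' @export
print.tone_cloud_stimulus <- function(x, ...) {
  cat(sprintf("<tone_cloud_stimulus> %s%s: %d segments x %.2f s, %d pips/segment, %d samples\n",
              x$category,
              if (!is.null(x$exemplar_id)) paste0("-", x$exemplar_id) else "",
              length(x$segments), x$spec$segment_s, nrow(x$segments[[1]]),
              length(x$waveform)))
  invisible(x)
}
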