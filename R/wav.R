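#' Write a waveform to a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer (mono, 16-bit PCM). Samples are clipped to
#' \[-1, 1\] and scaled to the signed 16-bit range.
#'
#' @param waveform Numeric vector of samples in \[-1, 1\].
#' @param path Output file path.
#' @param sample_rate Sample rate (samples/s).
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, path, sample_rate = 44100) {
  samples <- as.integer(round(pmax(-1, pmin(1, waveform)) * 32767))
  n <- length(samples)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")           # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(samples, con, size = 2, endian = "little")
  invisible(path)
}

#' Write a stimulus to WAV plus JSON sidecar
#'
#' Renders the stimulus waveform to a 16-bit PCM WAV file and writes a JSON
#' sidecar holding the spec, category, exemplar id and the full pip tables,
#' from which the stimulus can be reconstructed exactly.
#'
#' @param stimulus A `tone_cloud_stimulus`.
#' @param path Output WAV path; the sidecar replaces the extension with
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_stimulus <- function(stimulus, path) {
  stopifnot(inherits(stimulus, "tone_cloud_stimulus"))
  write_wav(stimulus$waveform, path, stimulus$spec$sample_rate)
  sidecar <- sub("\\.[^.]*$", ".json", path)
  meta <- list(category = stimulus$category,
               exemplar_id = stimulus$exemplar_id,
               spec = unclass(stimulus$spec),
               segments = stimulus$segments)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
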