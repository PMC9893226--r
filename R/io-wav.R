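# Minimal RIFF/WAVE reader and writer (mono or multichannel PCM16 and
# float32), sufficient for the vocoder CLI round trip. No audio package is
# available in the analysis environment.

#' Write a waveform to a WAV file
#'
#' @param samples numeric vector in \[-1, 1\] (values are clipped), or a matrix
#'   with one column per channel.
#' @param path output path.
#' @param sample_rate sampling rate in Hz.
#' @param bits 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate, bits = 16) {
  if (!bits %in% c(16, 32)) stop("bits must be 16 or 32", call. = FALSE)
  m <- if (is.matrix(samples)) samples else matrix(samples, ncol = 1)
  n_chan <- ncol(m)
  n <- nrow(m)
  interleaved <- as.numeric(t(m))
  bytes_per <- bits / 8
  data_len <- n * n_chan * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_len), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (bits == 16) 1L else 3L, con, size = 2, endian = "little")
  writeBin(as.integer(n_chan), con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * n_chan * bytes_per), con,
           size = 4, endian = "little")
  writeBin(as.integer(n_chan * bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  clipped <- pmin(pmax(interleaved, -1), 1)
  if (bits == 16) {
    writeBin(as.integer(round(clipped * 32767)), con, size = 2,
             endian = "little")
  } else {
    writeBin(clipped, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file written by [write_wav()]
#'
#' Handles uncompressed little-endian PCM16 and float32 RIFF/WAVE files.
#'
#' @param path file path.
#' @return list with `samples` (numeric vector, or matrix if multichannel)
#'   and `sample_rate`.
#' @export
read_wav <- function(path) {
  bytes <- readBin(path, "raw", file.size(path))
  if (rawToChar(bytes[1:4]) != "RIFF" || rawToChar(bytes[9:12]) != "WAVE") {
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  }
  pos <- 13L
  fmt <- NULL
  data_raw <- NULL
  while (pos + 8 <= length(bytes)) {
    chunk_id <- rawToChar(bytes[pos:(pos + 3)])
    chunk_len <- readBin(bytes[(pos + 4):(pos + 7)], "integer", 1, size = 4,
                         endian = "little")
    body <- bytes[(pos + 8):(pos + 7 + chunk_len)]
    if (chunk_id == "fmt ") fmt <- body
    if (chunk_id == "data") data_raw <- body
    pos <- pos + 8L + chunk_len + (chunk_len %% 2L)
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("missing fmt or data chunk in ", path, call. = FALSE)
  }
  audio_format <- readBin(fmt[1:2], "integer", 1, size = 2, endian = "little")
  n_chan <- readBin(fmt[3:4], "integer", 1, size = 2, endian = "little")
  sample_rate <- readBin(fmt[5:8], "integer", 1, size = 4, endian = "little")
  bits <- readBin(fmt[15:16], "integer", 1, size = 2, endian = "little")
  if (audio_format == 1L && bits == 16L) {
    vals <- readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                    signed = TRUE, endian = "little") / 32767
  } else if (audio_format == 3L && bits == 32L) {
    vals <- readBin(data_raw, "numeric", length(data_raw) / 4, size = 4,
                    endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", audio_format, ", ", bits,
         " bits)", call. = FALSE)
  }
  samples <- if (n_chan > 1) {
    matrix(vals, ncol = n_chan, byrow = TRUE)
  } else {
    vals
  }
  list(samples = samples, sample_rate = sample_rate)
}
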