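#' Vocoder specification
#'
#' Parameters of the noise vocoder: the analysis range 50-8000 Hz is divided
#' into `n_channels` logarithmically spaced bands; each band's amplitude
#' envelope (half-wave rectified, low-pass filtered at 30 Hz) modulates
#' band-limited white noise, and the channels are summed.
#'
#' @param n_channels number of channels (>= 1).
#' @param f_lo,f_hi band edges of the full analysis range, Hz.
#' @param envelope_cutoff envelope low-pass cutoff, Hz (default 30).
#' @param sample_rate sampling rate, Hz; must satisfy `sample_rate >= 2 * f_hi`.
#' @return an object of class `vocoder_spec`.
#' @examples
#' spec <- vocoder_spec(8, sample_rate = 22050)
#' channel_edges(spec)
#' @export
vocoder_spec <- function(n_channels, f_lo = 50, f_hi = 8000,
                         envelope_cutoff = 30, sample_rate = 22050) {
  stop_if_not_scalar_finite(n_channels, "n_channels")
  if (n_channels < 1 || n_channels != round(n_channels)) {
    stop("n_channels must be a positive integer", call. = FALSE)
  }
  if (!(f_lo > 0 && f_lo < f_hi)) stop("need 0 < f_lo < f_hi", call. = FALSE)
  if (f_hi > sample_rate / 2) {
    stop("f_hi exceeds the Nyquist frequency", call. = FALSE)
  }
  if (envelope_cutoff <= 0) stop("envelope_cutoff must be > 0", call. = FALSE)
  structure(list(n_channels = as.integer(n_channels), f_lo = f_lo,
                 f_hi = f_hi, envelope_cutoff = envelope_cutoff,
                 sample_rate = sample_rate),
            class = "vocoder_spec")
}

#' Logarithmically spaced channel edges
#'
#' Returns the `n_channels + 1` band boundaries forming a geometric
#' progression from `f_lo` to `f_hi`.
#'
#' @param spec a [vocoder_spec()].
#' @return numeric vector of strictly increasing edge frequencies (Hz).
#' @export
channel_edges <- function(spec) {
  stopifnot(inherits(spec, "vocoder_spec"))
  spec$f_lo * (spec$f_hi / spec$f_lo)^(0:spec$n_channels / spec$n_channels)
}

# Zero-phase filtering with the squared magnitude response of an
# order-`order` Butterworth filter, applied in the frequency domain. The
# squared response corresponds to one forward and one backward pass of the
# analogue prototype, so the result is phase-neutral by construction.
fft_butterworth <- function(x, sample_rate, type = c("low", "band"),
                            f1, f2 = NULL, order = 4) {
  type <- match.arg(type)
  n <- length(x)
  if (n == 0L) return(x)
  freqs <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1) * sample_rate / n
  af <- abs(freqs)
  if (type == "low") {
    h2 <- 1 / (1 + (af / f1)^(2 * order))
  } else {
    bw <- f2 - f1
    psi <- ifelse(af > 0, abs((af^2 - f1 * f2) / (af * bw)), Inf)
    h2 <- 1 / (1 + psi^(2 * order))
  }
  Re(stats::fft(stats::fft(x) * h2, inverse = TRUE)) / n
}

#' Extract a channel amplitude envelope
#'
#' Half-wave rectifies the band-limited signal and low-pass filters the
#' result at `cutoff` Hz (zero-phase Butterworth response); residual negative
#' filter ringing is clipped at zero, so the envelope is nonnegative.
#'
#' @param band_signal numeric waveform (already band-limited).
#' @param cutoff envelope low-pass cutoff in Hz (< Nyquist).
#' @param sample_rate sampling rate, Hz.
#' @return nonnegative envelope, same length as the input.
#' @export
extract_envelope <- function(band_signal, cutoff, sample_rate) {
  if (!all(is.finite(band_signal))) {
    stop("band_signal must be finite", call. = FALSE)
  }
  if (cutoff >= sample_rate / 2) {
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  rectified <- pmax(band_signal, 0)
  env <- fft_butterworth(rectified, sample_rate, "low", f1 = cutoff)
  pmax(env, 0)
}

#' Noise-vocode a waveform
#'
#' For each of the `n_channels` logarithmic bands: band-pass filter the
#' input, extract its 30 Hz amplitude envelope, impose that envelope on
#' band-pass filtered white noise, and scale the modulated carrier to the
#' band's RMS. Channels are summed and the output is rescaled to the input
#' RMS. The noise carrier is seeded, so the output is reproducible.
#'
#' @param signal numeric waveform.
#' @param spec a [vocoder_spec()] with matching `sample_rate`.
#' @param seed RNG seed for the noise carriers.
#' @return vocoded waveform, same length as `signal`.
#' @examples
#' x <- generate_toy_audio(0.25, 16000)
#' y <- vocode(x, vocoder_spec(4, sample_rate = 16000), seed = 1)
#' @export
vocode <- function(signal, spec, seed = 1) {
  stopifnot(inherits(spec, "vocoder_spec"))
  if (length(signal) == 0L) stop("signal is empty", call. = FALSE)
  if (!all(is.finite(signal))) stop("signal must be finite", call. = FALSE)
  edges <- channel_edges(spec)
  fs <- spec$sample_rate
  n <- length(signal)
  rms <- function(x) sqrt(mean(x^2))
  out <- numeric(n)
  with_seed(substream_seed(seed, "vocoder"), {
    for (ch in seq_len(spec$n_channels)) {
      band <- fft_butterworth(signal, fs, "band",
                              f1 = edges[ch], f2 = edges[ch + 1])
      env <- extract_envelope(band, spec$envelope_cutoff, fs)
      carrier <- fft_butterworth(stats::rnorm(n), fs, "band",
                                 f1 = edges[ch], f2 = edges[ch + 1])
      mod <- carrier * env
      band_rms <- rms(band)
      mod_rms <- rms(mod)
      if (band_rms > 0 && mod_rms > 0) {
        out <- out + mod * (band_rms / mod_rms)
      }
    }
  })
  in_rms <- rms(signal)
  out_rms <- rms(out)
  if (in_rms > 0 && out_rms > 0) out <- out * (in_rms / out_rms)
  out
}
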