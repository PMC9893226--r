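# Toy audio and toy imaging volumes for exercising the vocoder and lesion
# modules without real recordings or scans.

#' Generate a deterministic toy test signal
#'
#' A harmonic complex (fundamental 60 Hz, harmonics spanning 50-8000 Hz)
#' with a global amplitude modulation at `mod_freq` plus slower per-harmonic
#' modulators that differ across frequency, and a small seeded noise floor.
#' The signal has spectral energy across the whole vocoder analysis range, a
#' known dominant envelope modulation frequency, and band-specific envelope
#' detail — which together make vocoder behaviour checkable with FFT and
#' envelope-correlation oracles.
#'
#' @param duration_s duration in seconds (> 0).
#' @param sample_rate sampling rate in Hz; must be at least 16000 so the
#'   8000 Hz band edge is representable.
#' @param seed RNG seed for the noise floor.
#' @param mod_freq global amplitude-modulation frequency in Hz (default 4).
#' @return numeric waveform of length `round(duration_s * sample_rate)`.
#' @examples
#' x <- generate_toy_audio(0.5, 16000, seed = 1)
#' @export
generate_toy_audio <- function(duration_s, sample_rate, seed = 1,
                               mod_freq = 4) {
  stop_if_not_scalar_finite(duration_s, "duration_s")
  stop_if_not_scalar_finite(sample_rate, "sample_rate")
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (sample_rate < 16000) {
    stop("sample_rate must be >= 16000 Hz (Nyquist below top band edge)",
         call. = FALSE)
  }
  n <- round(duration_s * sample_rate)
  t <- seq_len(n) / sample_rate
  f0 <- 60
  harmonics <- seq(f0, 8000, by = f0)
  x <- numeric(n)
  for (k in seq_along(harmonics)) {
    # per-harmonic modulator rates spread over 1-9 Hz so different vocoder
    # channels carry distinguishable envelopes; 1/sqrt(k) amplitude rolloff
    # keeps high-frequency energy substantial
    rk <- 1 + (k * 7L) %% 9L
    modk <- 1 + 0.5 * sin(2 * pi * rk * t + k)
    x <- x + modk * sin(2 * pi * harmonics[k] * t + k^2) / sqrt(k)
  }
  x <- x * (1 + 0.9 * sin(2 * pi * mod_freq * t)) / 2
  noise <- with_seed(seed, stats::rnorm(n, 0, 0.01))
  x <- x + noise
  x / max(abs(x))
}

#' Generate toy probabilistic network maps and lesion masks
#'
#' Builds two smooth probabilistic "activation overlap" maps (language-like:
#' one lateralised blob; MD-like: two symmetric blobs) and one spherical
#' binary lesion mask per participant, all on an identical grid with an
#' identical diagonal affine. Lesion radii increase across participants so
#' overlap volumes are graded.
#'
#' @param grid_shape integer triple, voxels per axis.
#' @param voxel_size_mm numeric triple, voxel edge lengths in mm.
#' @param seed RNG seed for lesion centre jitter.
#' @param n_participants number of lesion masks to generate.
#' @return list with elements `prob_map_lang`, `prob_map_md` (probability
#'   [volume_grid()]s) and `lesion_masks` (named list of binary grids).
#' @export
generate_toy_volumes <- function(grid_shape = c(24L, 24L, 24L),
                                 voxel_size_mm = c(2, 2, 2),
                                 seed = 1, n_participants = 19) {
  if (length(grid_shape) != 3L || any(grid_shape < 2) ||
      any(grid_shape != round(grid_shape))) {
    stop("grid_shape must be three integers >= 2", call. = FALSE)
  }
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stop("voxel_size_mm must be three positive numbers", call. = FALSE)
  }
  affine <- diag(c(voxel_size_mm, 1))
  ax <- lapply(grid_shape, function(n) seq_len(n) - (n + 1) / 2)
  blob <- function(centre, width) {
    d2 <- outer(outer((ax[[1]] - centre[1])^2, (ax[[2]] - centre[2])^2, "+"),
                (ax[[3]] - centre[3])^2, "+")
    exp(-d2 / (2 * width^2))
  }
  half <- grid_shape[1] / 4
  prob_lang <- pmin(blob(c(-half, 1, 0), grid_shape[1] / 6), 1)
  prob_md <- pmin(blob(c(-half, -2, 2), grid_shape[1] / 8) +
                    blob(c(half, -2, 2), grid_shape[1] / 8), 1)
  centres <- with_seed(substream_seed(seed, "volumes"), {
    matrix(stats::runif(3 * n_participants, -grid_shape[1] / 4,
                        grid_shape[1] / 4), ncol = 3)
  })
  radii <- seq(1.5, grid_shape[1] / 3, length.out = max(n_participants, 1))
  masks <- lapply(seq_len(n_participants), function(i) {
    d2 <- outer(outer((ax[[1]] - centres[i, 1])^2,
                      (ax[[2]] - centres[i, 2])^2, "+"),
                (ax[[3]] - centres[i, 3])^2, "+")
    volume_grid((d2 <= radii[i]^2) * 1, voxel_size_mm, affine,
                kind = "binary")
  })
  names(masks) <- sprintf("p%02d", seq_len(n_participants))
  list(
    prob_map_lang = volume_grid(prob_lang, voxel_size_mm, affine,
                                kind = "probability"),
    prob_map_md = volume_grid(prob_md, voxel_size_mm, affine,
                              kind = "probability"),
    lesion_masks = masks
  )
}
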