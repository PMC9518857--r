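#' Mel-scale parameters
#'
#' The perceptual mel scale used throughout is
#' `Mel(f) = C * log10(1 + f / f0)` with corner frequency `f0` (700 Hz by
#' convention, acceptable range 600-1000 Hz) and the constant `C` chosen so
#' that 1000 Hz maps to exactly 1000 mels: `C = 1000 / log10(1 + 1000/f0)`.
#' `C` is kept unrounded internally; at `f0 = 700` it rounds to the familiar
#' 2595.
#'
#' @param corner_frequency_hz Corner frequency `f0` in Hz, in `[600, 1000]`.
#' @return A list with `corner_frequency_hz` and the unrounded `constant`.
#' @export
mel_scale_params <- function(corner_frequency_hz = 700) {
  if (corner_frequency_hz < 600 || corner_frequency_hz > 1000) {
    stop("mel_scale_params: corner frequency must lie in [600, 1000] Hz")
  }
  list(corner_frequency_hz = corner_frequency_hz,
       constant = mel_constant(corner_frequency_hz))
}

#' Mel-scale constant C
#'
#' `C = 1000 / log10(1 + 1000 / f0)`, unrounded, so that 1000 Hz always maps
#' to 1000 mels. For `f0 = 700` this is 2595.0091... (2595 when rounded).
#'
#' @param corner_frequency_hz Corner frequency `f0` in Hz, > 0.
#' @return The dimensionless constant.
#' @export
mel_constant <- function(corner_frequency_hz) {
  if (!is.numeric(corner_frequency_hz) || corner_frequency_hz <= 0) {
    stop("mel_constant: corner frequency must be positive")
  }
  1000 / log10(1 + 1000 / corner_frequency_hz)
}

#' Hz to mel conversion
#'
#' @param f Frequency in Hz, >= 0 (vectorised).
#' @param params A [mel_scale_params] list.
#' @return Frequency on the mel scale.
#' @export
hz_to_mel <- function(f, params = mel_scale_params()) {
  if (any(f < 0)) stop("hz_to_mel: negative frequency")
  params$constant * log10(1 + f / params$corner_frequency_hz)
}

#' Mel to Hz conversion (inverse of [hz_to_mel])
#' @param m Mels, >= 0 (vectorised).
#' @param params A [mel_scale_params] list.
#' @return Frequency in Hz.
#' @export
mel_to_hz <- function(m, params = mel_scale_params()) {
  params$corner_frequency_hz * (10^(m / params$constant) - 1)
}

#' MFCC extraction dialect
#'
#' Bundles every tunable of the four-stage MFCC pipeline so the exact recipe
#' travels with the extracted features (and so an external oracle can be
#' configured identically). Defaults follow the common speech-analysis
#' dialect: 13 coefficients, 2048-point FFT window, hop 512, periodic Hann
#' window, 128 triangular mel filters from 0 Hz to Nyquist, common (base-10)
#' log energies floored at a relative epsilon, orthonormal type-II DCT, and
#' pre-emphasis 0.97.
#'
#' @param sample_rate Sampling rate in Hz; `NULL` means "taken from the clip".
#' @param n_mfcc Number of cepstral coefficients retained.
#' @param n_fft FFT size; also the analysis frame length.
#' @param hop_length Hop between successive frames, in samples.
#' @param preemphasis Pre-emphasis coefficient alpha in `[0, 1)`.
#' @param n_mels Number of mel filters.
#' @param fmin,fmax Filter-bank band edges in Hz; `fmax = NULL` means Nyquist.
#' @param corner_frequency_hz Mel-scale corner frequency `f0`.
#' @param floor_rel Relative stability epsilon for the log: energies are
#'   floored at `floor_rel * max(energy)`.
#' @return A list of class `mfcc_dialect`.
#' @export
mfcc_dialect <- function(sample_rate = NULL, n_mfcc = 13L, n_fft = 2048L,
                         hop_length = 512L, preemphasis = 0.97,
                         n_mels = 128L, fmin = 0, fmax = NULL,
                         corner_frequency_hz = 700, floor_rel = 1e-10) {
  structure(
    list(sample_rate = sample_rate, n_mfcc = as.integer(n_mfcc),
         n_fft = as.integer(n_fft), hop_length = as.integer(hop_length),
         preemphasis = preemphasis, n_mels = as.integer(n_mels),
         fmin = fmin, fmax = fmax,
         corner_frequency_hz = corner_frequency_hz, floor_rel = floor_rel,
         window = "hann_periodic", log_base = 10, dct = "ortho-II"),
    class = "mfcc_dialect"
  )
}

#' Pre-emphasis high-pass filter
#'
#' `y[t] = x[t] - alpha * x[t-1]`, `y[1] = x[1]`; sharpens the spectral
#' envelope against the natural -6 dB/octave tilt of voiced speech.
#'
#' @param clip An [audio_clip].
#' @param alpha Coefficient in `[0, 1)`.
#' @return A filtered [audio_clip] of identical length and rate.
#' @export
pre_emphasize <- function(clip, alpha = 0.97) {
  stopifnot(inherits(clip, "audio_clip"))
  if (alpha < 0 || alpha >= 1) stop("pre_emphasize: alpha must be in [0, 1)")
  x <- clip$samples
  y <- c(x[1L], x[-1L] - alpha * x[-length(x)])
  out <- clip
  out$samples <- y
  out
}

#' Slice a signal into overlapping analysis frames
#'
#' Frames advance by `hop_length`; signals shorter than one frame yield a
#' single zero-padded frame, otherwise the tail is zero-padded so the final
#' partial frame is kept: `n_frames = 1 + ceiling((L - frame_length) / hop)`.
#'
#' @param clip An [audio_clip].
#' @param frame_length Frame length in samples.
#' @param hop_length Hop in samples, `1 <= hop_length <= frame_length`.
#' @return A list of class `frame_stack` with a `n_frames x frame_length`
#'   matrix `frames` plus the two lengths.
#' @export
frame_signal <- function(clip, frame_length = 2048L, hop_length = 512L) {
  stopifnot(inherits(clip, "audio_clip"))
  frame_length <- as.integer(frame_length)
  hop_length <- as.integer(hop_length)
  if (frame_length < 1L) stop("frame_signal: frame_length must be >= 1")
  if (hop_length < 1L || hop_length > frame_length) {
    stop("frame_signal: need 1 <= hop_length <= frame_length")
  }
  x <- clip$samples
  L <- length(x)
  if (L == 0L) stop("frame_signal: empty signal")
  n_frames <- if (L <= frame_length) 1L
              else 1L + as.integer(ceiling((L - frame_length) / hop_length))
  need <- frame_length + (n_frames - 1L) * hop_length
  if (need > L) x <- c(x, numeric(need - L))
  idx <- outer(seq_len(frame_length), (seq_len(n_frames) - 1L) * hop_length, "+")
  structure(
    list(frames = t(matrix(x[idx], nrow = frame_length)),
         frame_length = frame_length, hop_length = hop_length),
    class = "frame_stack"
  )
}

#' Periodic Hann window
#' @param n Window length.
#' @return Numeric vector `0.5 - 0.5 * cos(2*pi*k/n)`, `k = 0..n-1`.
#' @export
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)

#' Apply a periodic Hann window to every frame
#'
#' Tapers frame edges to suppress spectral leakage from the implicit
#' rectangular cut; the periodic (DFT-even) form is used.
#'
#' @param frames A `frame_stack` from [frame_signal].
#' @return The windowed `frame_stack`.
#' @export
apply_hann <- function(frames) {
  stopifnot(inherits(frames, "frame_stack"))
  w <- hann_window(frames$frame_length)
  frames$frames <- sweep(frames$frames, 2L, w, "*")
  frames
}

#' Per-frame power spectrum
#'
#' Squared magnitude of the `n_fft`-point DFT of every frame, keeping the
#' `n_fft/2 + 1` non-negative-frequency bins.
#'
#' @param frames A `frame_stack`.
#' @param n_fft FFT size, `>= frame_length`.
#' @return A `n_frames x (n_fft/2 + 1)` matrix of non-negative power values.
#' @export
power_spectrum <- function(frames, n_fft = frames$frame_length) {
  stopifnot(inherits(frames, "frame_stack"))
  n_fft <- as.integer(n_fft)
  if (n_fft < frames$frame_length) {
    stop("power_spectrum: n_fft must be >= frame_length")
  }
  x <- t(frames$frames)
  if (n_fft > nrow(x)) {
    x <- rbind(x, matrix(0, n_fft - nrow(x), ncol(x)))
  }
  sp <- stats::mvfft(x)[seq_len(n_fft %/% 2L + 1L), , drop = FALSE]
  t(Mod(sp)^2)
}

#' Build a triangular mel filter bank
#'
#' `n_mels` triangular filters whose centres are equally spaced on the mel
#' axis between `hz_to_mel(fmin)` and `hz_to_mel(fmax)`; adjacent filters
#' share edges (filter k's high edge is filter k+1's centre). Triangles are
#' constructed on the continuous Hz axis and evaluated at the FFT-bin centre
#' frequencies, with no area normalisation.
#'
#' @param n_mels Number of filters.
#' @param n_fft FFT size (fixes the bin grid).
#' @param sample_rate Sampling rate in Hz.
#' @param params A [mel_scale_params] list.
#' @param fmin,fmax Band edges in Hz, `fmax <= sample_rate / 2`.
#' @return A list of class `mel_filterbank` with `weights`
#'   (`n_mels x (n_fft/2+1)`) and `band_edges_hz` (`n_mels x 3`,
#'   columns low/centre/high).
#' @export
build_mel_filterbank <- function(n_mels, n_fft, sample_rate,
                                 params = mel_scale_params(),
                                 fmin = 0, fmax = sample_rate / 2) {
  if (n_mels < 1L) stop("build_mel_filterbank: n_mels must be >= 1")
  if (fmin >= fmax) stop("build_mel_filterbank: fmin must be < fmax")
  if (fmax > sample_rate / 2 + 1e-9) {
    stop("build_mel_filterbank: fmax exceeds Nyquist")
  }
  n_bins <- n_fft %/% 2L + 1L
  bin_hz <- (seq_len(n_bins) - 1L) * sample_rate / n_fft
  mel_pts <- seq(hz_to_mel(fmin, params), hz_to_mel(fmax, params),
                 length.out = n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts, params)
  w <- matrix(0, n_mels, n_bins)
  for (k in seq_len(n_mels)) {
    lo <- hz_pts[k]; ce <- hz_pts[k + 1L]; hi <- hz_pts[k + 2L]
    up <- (bin_hz - lo) / (ce - lo)
    down <- (hi - bin_hz) / (hi - ce)
    w[k, ] <- pmax(0, pmin(up, down))
  }
  if (any(rowSums(w) == 0)) {
    stop("build_mel_filterbank: n_mels too large for the FFT bin resolution")
  }
  structure(
    list(weights = w,
         band_edges_hz = cbind(low = hz_pts[seq_len(n_mels)],
                               centre = hz_pts[seq_len(n_mels) + 1L],
                               high = hz_pts[seq_len(n_mels) + 2L])),
    class = "mel_filterbank"
  )
}

#' Log mel-band energies
#'
#' Applies the filter bank to each power spectrum and takes the common
#' (base-10) logarithm, flooring energies at `floor_rel` times the maximum
#' filter-bank energy for numerical stability (silence thus maps to a
#' constant floor value, not `-Inf`).
#'
#' @param spectra `n_frames x n_bins` power-spectrum matrix.
#' @param bank A `mel_filterbank`.
#' @param floor_rel Relative stability epsilon.
#' @return `n_frames x n_mels` matrix of log10 energies.
#' @export
log_mel_energies <- function(spectra, bank, floor_rel = 1e-10) {
  stopifnot(inherits(bank, "mel_filterbank"))
  if (ncol(spectra) != ncol(bank$weights)) {
    stop("log_mel_energies: spectral bin count does not match filter bank")
  }
  e <- spectra %*% t(bank$weights)
  mx <- max(e)
  eps <- if (mx > 0) mx * floor_rel else .Machine$double.xmin
  log10(pmax(e, eps))
}

#' Cepstral coefficients by type-II DCT
#'
#' Per frame, the first `n_coefficients` coefficients of the orthonormal
#' type-II discrete cosine transform of the log mel energies, lowest index
#' first ("in order of significance").
#'
#' @param log_energies `n_frames x n_mels` matrix.
#' @param n_coefficients Number of coefficients kept, `<= n_mels`.
#' @param source_id Identifier carried on the result.
#' @return A `mfcc_matrix`: list with `coefficients`
#'   (`n_frames x n_coefficients`), `n_coefficients`, `source_id`.
#' @export
dct_cepstra <- function(log_energies, n_coefficients = 13L,
                        source_id = NA_character_) {
  n_mels <- ncol(log_energies)
  if (n_coefficients > n_mels) {
    stop("dct_cepstra: n_coefficients must be <= number of mel bands")
  }
  D <- dct_matrix(n_mels)[seq_len(n_coefficients), , drop = FALSE]
  structure(
    list(coefficients = log_energies %*% t(D),
         n_coefficients = as.integer(n_coefficients),
         source_id = as.character(source_id)),
    class = "mfcc_matrix"
  )
}

#' Orthonormal type-II DCT matrix
#' @param n Transform size.
#' @return `n x n` matrix `D` such that `D %*% x` is the orthonormal DCT-II
#'   of `x` and `t(D)` is its inverse.
#' @export
dct_matrix <- function(n) {
  k <- seq_len(n) - 1L
  m <- seq_len(n) - 1L
  D <- sqrt(2 / n) * cos(pi * outer(k, 2 * m + 1) / (2 * n))
  D[1L, ] <- D[1L, ] / sqrt(2)
  D
}

#' Extract MFCC features from a clip
#'
#' The full four-stage pipeline: pre-emphasis, framing + periodic Hann
#' windowing, FFT power spectrum, mel filter bank with log compression, and
#' type-II DCT. Equivalent by construction to calling the stage functions in
#' sequence (no hidden state).
#'
#' @param clip An [audio_clip].
#' @param dialect An [mfcc_dialect]; `sample_rate = NULL` uses the clip rate.
#' @return A `mfcc_matrix` whose row count equals [frame_signal]'s frame
#'   count.
#' @export
extract_mfcc <- function(clip, dialect = mfcc_dialect()) {
  stopifnot(inherits(clip, "audio_clip"), inherits(dialect, "mfcc_dialect"))
  sr <- if (is.null(dialect$sample_rate)) clip$sample_rate else dialect$sample_rate
  fmax <- if (is.null(dialect$fmax)) sr / 2 else dialect$fmax
  params <- mel_scale_params(dialect$corner_frequency_hz)
  emph <- pre_emphasize(clip, dialect$preemphasis)
  frames <- apply_hann(frame_signal(emph, dialect$n_fft, dialect$hop_length))
  spectra <- power_spectrum(frames, dialect$n_fft)
  bank <- build_mel_filterbank(dialect$n_mels, dialect$n_fft, sr, params,
                               dialect$fmin, fmax)
  loge <- log_mel_energies(spectra, bank, dialect$floor_rel)
  dct_cepstra(loge, dialect$n_mfcc, clip$source_id)
}
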