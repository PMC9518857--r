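test_that("mel constant and mel mapping reproduce the perceptual anchors", {
  # C at the conventional 700 Hz corner rounds to 2595
  expect_identical(round(mel_constant(700)), 2595)
  # 1000 Hz maps to exactly 1000 mels for any corner frequency
  for (f0 in c(600, 700, 850, 1000)) {
    expect_equal(hz_to_mel(1000, mel_scale_params(f0)), 1000,
                 tolerance = 1e-12)
  }
  expect_equal(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700), mel_constant(700) * log10(2),
               tolerance = 1e-12)
  expect_equal(mel_constant(1000), 1000 / log10(2), tolerance = 1e-12)
  expect_error(hz_to_mel(-5), "negative")
  expect_error(mel_constant(0), "positive")
  expect_error(mel_scale_params(500), "\\[600, 1000\\]")
})

test_that("hz_to_mel is strictly increasing and inverts through mel_to_hz", {
  f <- seq(0, 22050, length.out = 500)
  for (f0 in c(600, 700, 1000)) {
    p <- mel_scale_params(f0)
    m <- hz_to_mel(f, p)
    expect_true(all(diff(m) > 0))
    expect_equal(mel_to_hz(m, p), f, tolerance = 1e-8)
  }
})

test_that("pre-emphasis implements the first-difference recurrence", {
  clip <- sine_clip(100, duration_s = 0.01, sr = 8000)
  expect_identical(pre_emphasize(clip, 0)$samples, clip$samples)
  const <- audio_clip(rep(0.4, 50), 8000)
  out <- pre_emphasize(const, 0.97)$samples
  expect_equal(out[1], 0.4)
  expect_equal(out[-1], rep(0.03 * 0.4, 49), tolerance = 1e-12)
  alt <- audio_clip(rep(c(0.5, -0.5), 25), 8000)    # alternating +-
  out2 <- pre_emphasize(alt, 0.97)$samples
  expect_equal(abs(out2[-1]), rep(0.5 * 1.97, 49), tolerance = 1e-12)
  expect_error(pre_emphasize(clip, 1), "alpha")
  expect_error(pre_emphasize(clip, -0.1), "alpha")
})

test_that("framing counts, padding and overlap follow the contract", {
  mk <- function(L) audio_clip(seq_len(L) / L, 44100)
  expect_identical(nrow(frame_signal(mk(2048), 2048, 512)$frames), 1L)
  expect_identical(nrow(frame_signal(mk(4096), 2048, 512)$frames), 5L)
  # short signal: one zero-padded frame
  fs <- frame_signal(mk(1000), 2048, 512)
  expect_identical(nrow(fs$frames), 1L)
  expect_identical(fs$frames[1, 1001:2048], rep(0, 1048))
  # overlap: frame 2 starts hop samples into frame 1
  fs2 <- frame_signal(mk(4096), 2048, 512)
  expect_identical(fs2$frames[2, 1:(2048 - 512)], fs2$frames[1, 513:2048])
  expect_error(frame_signal(mk(100), 512, 600), "hop_length")
})

test_that("periodic hann window has the expected analytic properties", {
  n <- 256L
  w <- hann_window(n)
  expect_equal(w[1], 0)
  expect_equal(sum(w), n / 2, tolerance = 1e-9)       # sum of periodic Hann
  ones <- structure(list(frames = matrix(1, 3, n), frame_length = n,
                         hop_length = n), class = "frame_stack")
  windowed <- apply_hann(ones)
  expect_equal(rowSums(windowed$frames), rep(n / 2, 3), tolerance = 1e-9)
  zero <- ones
  zero$frames[] <- 0
  expect_identical(apply_hann(zero)$frames, zero$frames)
})

test_that("power spectrum concentrates on-grid tones and obeys Parseval", {
  n <- 256L
  k <- 12L
  frames <- structure(
    list(frames = rbind(cos(2 * pi * k * (0:(n - 1)) / n), numeric(n)),
         frame_length = n, hop_length = n),
    class = "frame_stack"
  )
  ps <- power_spectrum(frames, n)
  expect_identical(ncol(ps), n %/% 2L + 1L)
  expect_true(all(ps >= 0))
  expect_identical(ps[2, ], rep(0, n / 2 + 1))        # zero frame
  peak <- ps[1, k + 1L]
  expect_lt(max(ps[1, -(k + 1L)]) / peak, 1e-9)       # energy at bin k only
  # Parseval: sum |x|^2 = (1/n) * two-sided spectral sum
  set.seed(3)
  x <- stats::rnorm(n)
  fr <- structure(list(frames = matrix(x, 1), frame_length = n,
                       hop_length = n), class = "frame_stack")
  p1 <- power_spectrum(fr, n)[1, ]
  two_sided <- p1[1] + p1[n / 2 + 1] + 2 * sum(p1[2:(n / 2)])
  expect_equal(sum(x^2), two_sided / n, tolerance = 1e-9)
  expect_error(power_spectrum(fr, 128), "n_fft")
})

test_that("mel filter bank centres are equal-spaced in mels and cover the band", {
  sr <- 44100
  bank <- build_mel_filterbank(128, 2048, sr)
  centres_mel <- hz_to_mel(bank$band_edges_hz[, "centre"])
  d <- diff(centres_mel)
  expect_lt(max(abs(d - d[1])) / d[1], 1e-9)
  expect_true(all(bank$weights >= 0))
  # adjacent filters share edges
  expect_equal(bank$band_edges_hz[-1, "low"],
               unname(bank$band_edges_hz[-128, "centre"]), tolerance = 1e-9)
  # every bin between first and last centre has coverage
  bin_hz <- (0:1024) * sr / 2048
  inside <- bin_hz > bank$band_edges_hz[1, "centre"] &
    bin_hz < bank$band_edges_hz[128, "centre"]
  expect_true(all(colSums(bank$weights)[inside] > 0))
  # single filter spans the whole band
  b1 <- build_mel_filterbank(1, 256, 8000)
  expect_identical(nrow(b1$weights), 1L)
  expect_error(build_mel_filterbank(4, 256, 8000, fmin = 4000, fmax = 1000),
               "fmin")
  expect_error(build_mel_filterbank(2000, 256, 8000), "resolution")
})

test_that("log mel energies floor silence and respect scaling/monotonicity", {
  bank <- build_mel_filterbank(8, 64, 8000)
  z <- matrix(0, 3, 33)
  lz <- log_mel_energies(z, bank)
  expect_true(all(lz == lz[1, 1]))                     # constant floor
  set.seed(4)
  s <- matrix(stats::rexp(5 * 33), 5, 33)
  e1 <- log_mel_energies(s, bank)
  e10 <- log_mel_energies(10 * s, bank)
  expect_equal(e10, e1 + 1, tolerance = 1e-9)          # log10 homomorphism
  bigger <- log_mel_energies(s + 1, bank)
  expect_true(all(bigger >= e1))
  expect_error(log_mel_energies(matrix(0, 2, 10), bank), "bin count")
})

test_that("dct cepstra are the orthonormal type-II transform", {
  # constant vector -> only coefficient 0 non-zero
  cm <- dct_cepstra(matrix(3.7, 2, 16), 16)$coefficients
  expect_equal(cm[, 1], rep(3.7 * 4, 2), tolerance = 1e-12)  # sqrt(16)*mean
  expect_equal(cm[, -1], matrix(0, 2, 15), tolerance = 1e-12)
  # full-length DCT inverts through its transpose
  set.seed(5)
  x <- matrix(stats::rnorm(4 * 32), 4, 32)
  D <- dct_matrix(32)
  expect_equal(x %*% t(D) %*% D, x, tolerance = 1e-9)
  # 13 of 128 mel bands
  le <- matrix(stats::rnorm(6 * 128), 6, 128)
  expect_identical(dim(dct_cepstra(le, 13)$coefficients), c(6L, 13L))
  expect_error(dct_cepstra(le, 200), "n_coefficients")
})

test_that("extract_mfcc equals the stage-by-stage composition", {
  clip <- random_clip(11, duration_s = 0.5)
  d <- mfcc_dialect()
  direct <- extract_mfcc(clip, d)$coefficients
  emph <- pre_emphasize(clip, d$preemphasis)
  fr <- apply_hann(frame_signal(emph, d$n_fft, d$hop_length))
  sp <- power_spectrum(fr, d$n_fft)
  bank <- build_mel_filterbank(d$n_mels, d$n_fft, clip$sample_rate,
                               mel_scale_params(d$corner_frequency_hz),
                               d$fmin, clip$sample_rate / 2)
  staged <- dct_cepstra(log_mel_energies(sp, bank, d$floor_rel),
                        d$n_mfcc)$coefficients
  expect_equal(direct, staged, tolerance = 1e-12)
})

test_that("extract_mfcc framing arithmetic and silence degeneracy", {
  clip <- sine_clip(440, duration_s = 2)
  m <- extract_mfcc(clip)
  expect_identical(dim(m$coefficients), c(170L, 13L))  # 1+ceil(86152/512)
  silent <- audio_clip(numeric(44100), 44100, "quiet")
  ms <- extract_mfcc(silent)$coefficients
  expect_true(all(abs(sweep(ms, 2, ms[1, ])) < 1e-9))  # identical rows
})

test_that("delaying by one hop shifts mfcc rows by one", {
  clip <- random_clip(12, duration_s = 0.5)
  d <- mfcc_dialect()
  delayed <- audio_clip(c(numeric(d$hop_length), clip$samples),
                        clip$sample_rate, clip$source_id)
  a <- extract_mfcc(clip, d)$coefficients
  b <- extract_mfcc(delayed, d)$coefficients
  n <- nrow(a)
  # interior rows: row t of the original appears as row t+1 of the delayed
  expect_equal(b[3:(n - 1), ], a[2:(n - 2), ], tolerance = 1e-6)
})
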