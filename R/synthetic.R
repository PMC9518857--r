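#' Class profile for synthetic speech
#'
#' Describes the candidate speech biomarkers the synthetic classes encode:
#' speech rate (syllables/second), silent-pause occurrence rate and mean
#' length, a multiplicative shift of the formant centre frequencies, and
#' relative pitch-period jitter. The defaults describe the control class.
#'
#' @param syllable_rate Syllables per second.
#' @param pause_rate Silent pauses per minute.
#' @param pause_length_mean Mean pause duration in seconds.
#' @param formant_shift Multiplicative factor on formant centre frequencies.
#' @param jitter_sd Relative standard deviation of the pitch period.
#' @return A list of class `class_profile`.
#' @export
class_profile <- function(syllable_rate = 4.5, pause_rate = 6,
                          pause_length_mean = 0.35, formant_shift = 1.0,
                          jitter_sd = 0.01) {
  stopifnot(syllable_rate > 0, pause_rate >= 0, pause_length_mean >= 0,
            formant_shift > 0, jitter_sd >= 0)
  structure(list(syllable_rate = syllable_rate, pause_rate = pause_rate,
                 pause_length_mean = pause_length_mean,
                 formant_shift = formant_shift, jitter_sd = jitter_sd),
            class = "class_profile")
}

#' Default positive-class (mTBI-like) profile at full effect
#'
#' Slower, pause-heavier speech with slightly lowered formants and more
#' jitter — the directions reported for impaired speech; the magnitudes are
#' fixture choices for exercising the pipeline, not clinical claims.
#' @return A `class_profile`.
#' @export
impaired_profile <- function() {
  class_profile(syllable_rate = 3.2, pause_rate = 14,
                pause_length_mean = 0.8, formant_shift = 0.94,
                jitter_sd = 0.05)
}

#' Interpolate between two class profiles
#'
#' Linear interpolation field-by-field; `effect_size = 0` returns `from`
#' exactly (identical class distributions), `effect_size = 1` returns `to`.
#'
#' @param from,to `class_profile`s.
#' @param effect_size Scalar in `[0, 1]`.
#' @return A `class_profile`.
#' @export
interpolate_profile <- function(from, to, effect_size) {
  stopifnot(effect_size >= 0, effect_size <= 1)
  vals <- Map(function(a, b) (1 - effect_size) * a + effect_size * b,
              unclass(from), unclass(to))
  do.call(class_profile, vals)
}

#' Cohort specification for the synthetic generator
#'
#' @param n_participants Number of participants, >= 2.
#' @param prevalence Fraction of positive (mTBI) participants.
#' @param effect_size Scalar in `[0, 1]` interpolating the positive-class
#'   profile from the control profile.
#' @param clip_duration_s Duration of each participant's clip, seconds.
#' @param sample_rate Recording rate in Hz (44100 by convention).
#' @param seed RNG seed for the whole cohort.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 46L, prevalence = 7 / 46,
                        effect_size = 1, clip_duration_s = 10,
                        sample_rate = 44100, seed = 1L) {
  stopifnot(n_participants >= 2L, prevalence >= 0, prevalence <= 1,
            effect_size >= 0, effect_size <= 1, clip_duration_s > 0)
  structure(list(n_participants = as.integer(n_participants),
                 prevalence = prevalence, effect_size = effect_size,
                 clip_duration_s = clip_duration_s,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Second-order resonator cascade: formant filter of the source-filter model.
.resonate <- function(x, formants_hz, bandwidths_hz, sample_rate) {
  for (j in seq_along(formants_hz)) {
    f <- min(formants_hz[j], 0.45 * sample_rate)
    r <- exp(-pi * bandwidths_hz[j] / sample_rate)
    theta <- 2 * pi * f / sample_rate
    x <- stats::filter(x, c(2 * r * cos(theta), -r^2), method = "recursive")
  }
  as.numeric(x)
}

# Canonical vowel formant targets (Hz): /a/, /i/, /u/.
.vowel_formants <- list(a = c(730, 1090, 2440),
                        i = c(270, 2290, 3010),
                        u = c(300, 870, 2240))

#' Synthesise one speech-like utterance
#'
#' Source-filter synthesis: a jittered glottal pulse train excites a cascade
#' of three second-order resonators tuned to vowel formant targets (scaled
#' by the profile's `formant_shift` and the speaker's vocal-tract factor).
#' Syllables of mean length `1/syllable_rate` carry a raised-cosine
#' amplitude envelope over a 0.15 floor (coarticulation: no silence without
#' an explicit pause) and abut directly. Silent pauses of gamma(shape 4)
#' length around `pause_length_mean` are inserted quasi-periodically at
#' syllable boundaries, the gap between pauses drawn around the mean
#' implied by the profile's pauses-per-minute. Deterministic given `seed`.
#'
#' @param profile A [class_profile].
#' @param duration_s Target duration in seconds, > 0.
#' @param sample_rate Sampling rate in Hz.
#' @param seed RNG seed.
#' @param f0_hz Speaker fundamental frequency in Hz.
#' @param vocal_tract_factor Speaker-specific multiplicative factor on all
#'   formants (1 = canonical tract).
#' @param source_id Identifier for the returned clip.
#' @return An [audio_clip] of approximately `duration_s` seconds (trimmed or
#'   zero-padded to exactly `round(duration_s * sample_rate)` samples).
#' @export
generate_utterance <- function(profile, duration_s, sample_rate = 44100,
                               seed = 1L, f0_hz = 120,
                               vocal_tract_factor = 1,
                               source_id = "synthetic") {
  stopifnot(inherits(profile, "class_profile"), duration_s > 0)
  n_target <- round(duration_s * sample_rate)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  # quasi-periodic pause scheduling: speakers pause at roughly regular
  # phrase boundaries, so the gap between pauses (in syllables) is drawn
  # around the mean implied by the profile's pauses-per-minute
  syll_per_pause <- if (profile$pause_rate > 0) {
    profile$syllable_rate * 60 / profile$pause_rate
  } else Inf
  next_gap <- function() {
    if (!is.finite(syll_per_pause)) return(Inf)
    max(1, round(syll_per_pause * exp(stats::rnorm(1, 0, 0.2))))
  }
  until_pause <- next_gap()
  bandwidths <- c(60, 90, 120)
  vowels <- names(.vowel_formants)
  pieces <- list()
  total <- 0L
  while (total < n_target) {
    syl_dur <- (1 / profile$syllable_rate) * exp(stats::rnorm(1, 0, 0.15))
    n_syl <- max(32L, round(syl_dur * sample_rate))
    # jittered glottal pulse train
    exc <- numeric(n_syl)
    pos <- 1
    period0 <- sample_rate / f0_hz
    while (pos <= n_syl) {
      exc[ceiling(pos)] <- 1
      pos <- pos + period0 * (1 + stats::rnorm(1, 0, profile$jitter_sd))
    }
    fm <- .vowel_formants[[sample(vowels, 1L)]] *
      profile$formant_shift * vocal_tract_factor
    syl <- .resonate(exc, fm, bandwidths, sample_rate)
    # raised-cosine syllable envelope over an amplitude floor: adjacent
    # syllables coarticulate, so voicing never drops to silence without an
    # explicit pause
    env <- 0.15 + 0.85 *
      (0.5 - 0.5 * cos(2 * pi * (seq_len(n_syl) - 1L) / (n_syl - 1L)))
    pieces[[length(pieces) + 1L]] <- syl * env
    total <- total + n_syl
    until_pause <- until_pause - 1
    if (is.finite(until_pause) && until_pause <= 0) {
      # gamma(shape 4) pause lengths: right-skewed but not memoryless
      n_pause <- round(stats::rgamma(1, shape = 4,
                                     scale = profile$pause_length_mean / 4) *
                         sample_rate)
      if (n_pause > 0) {
        pieces[[length(pieces) + 1L]] <- numeric(n_pause)
        total <- total + n_pause
      }
      until_pause <- next_gap()
    }
  }
  x <- unlist(pieces, use.names = FALSE)[seq_len(n_target)]
  peak <- max(abs(x))
  if (peak > 0) x <- 0.5 * x / peak
  x <- x + stats::rnorm(n_target, 0, 1e-4)   # -54 dB recording noise floor
  x <- pmin(1, pmax(-1, x))
  audio_clip(x, sample_rate, source_id)
}

#' Generate a labelled synthetic cohort
#'
#' Draws `round(prevalence * n)` positive participants; each participant gets
#' one WAV clip synthesised under their class profile with a per-participant
#' vocal-tract baseline and fundamental frequency, so speakers differ within
#' class. Positive-class profiles are `interpolate_profile(control,
#' positive, effect_size)`. Deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec].
#' @param dir Output directory for WAVs and `manifest.csv`.
#' @param control Control-class profile.
#' @param positive Positive-class profile at `effect_size = 1`.
#' @return The manifest data.frame (`participant_id`, `label`, `clip_path`
#'   relative to `dir`), invisibly written to `dir/manifest.csv`.
#' @export
generate_cohort <- function(spec, dir, control = class_profile(),
                            positive = impaired_profile()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  n_pos <- round(spec$prevalence * n)
  if (n_pos == 0L || n_pos == n) {
    stop("generate_cohort: prevalence produces an empty class")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pos_profile <- interpolate_profile(control, positive, spec$effect_size)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(spec$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))

  labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  clip_seeds <- sample.int(.Machine$integer.max - 1L, n)
  vt <- stats::rnorm(n, 1, 0.03)
  f0 <- stats::rnorm(n, 120, 12)
  ids <- sprintf("P%03d", seq_len(n))
  paths <- paste0(ids, ".wav")
  for (i in seq_len(n)) {
    prof <- if (labels[i] == 1L) pos_profile else control
    clip <- generate_utterance(prof, spec$clip_duration_s, spec$sample_rate,
                               seed = clip_seeds[i], f0_hz = max(70, f0[i]),
                               vocal_tract_factor = max(0.7, vt[i]),
                               source_id = ids[i])
    write_wav(clip, file.path(dir, paths[i]))
  }
  manifest <- data.frame(participant_id = ids, label = labels,
                         clip_path = paths, stringsAsFactors = FALSE)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}
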