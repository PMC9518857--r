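# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures on disk.

# a clean sine clip
sine_clip <- function(freq = 440, duration_s = 1, sr = 44100, amp = 0.8,
                      id = "sine") {
  t <- seq_len(round(duration_s * sr)) - 1L
  audio_clip(amp * sin(2 * pi * freq * t / sr), sr, id)
}

# seeded noise-plus-tones clip, used for oracle comparisons
random_clip <- function(seed, duration_s = 1, sr = 44100, id = NULL) {
  set.seed(seed)
  n <- round(duration_s * sr)
  t <- (seq_len(n) - 1L) / sr
  x <- 0.25 * sin(2 * pi * stats::runif(1, 100, 2000) * t) +
    0.15 * sin(2 * pi * stats::runif(1, 2000, 8000) * t) +
    0.1 * stats::rnorm(n)
  audio_clip(pmax(-1, pmin(1, x)), sr,
             if (is.null(id)) paste0("rnd", seed) else id)
}

# random labelled manifest (no audio behind it) for split tests
random_manifest <- function(n, n_pos, seed) {
  set.seed(seed)
  data.frame(participant_id = sprintf("S%03d", seq_len(n)),
             label = sample(c(rep(1L, n_pos), rep(0L, n - n_pos))),
             clip_path = "none.wav", stringsAsFactors = FALSE)
}

# independent AUROC oracle: Mann-Whitney / rank-sum with midranks
rank_sum_auroc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# run the numpy/scipy reference MFCC on a list of clips, returning the
# list of coefficient matrices (see inst/oracle/mfcc_oracle.py)
oracle_mfcc <- function(clips, dialect) {
  td <- tempfile("oracle")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  script <- system.file("oracle", "mfcc_oracle.py", package = "speechscreen")
  job <- list(
    dialect = unclass(dialect),
    clips = lapply(seq_along(clips), function(i) {
      sf <- file.path(td, sprintf("s%d.f64", i))
      writeBin(clips[[i]]$samples, sf, size = 8, endian = "little")
      list(samples = sf, sample_rate = clips[[i]]$sample_rate,
           out = file.path(td, sprintf("o%d.f64", i)))
    })
  )
  jp <- file.path(td, "job.json")
  jsonlite::write_json(job, jp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  status <- system2("python", c(script, jp), stdout = TRUE, stderr = TRUE)
  lapply(seq_along(clips), function(i) {
    f <- job$clips[[i]]$out
    if (!file.exists(f)) {
      stop("mfcc oracle did not produce output: ",
           paste(status, collapse = "\n"))
    }
    v <- readBin(f, "double", n = file.size(f) / 8, endian = "little")
    matrix(v, ncol = dialect$n_mfcc, byrow = TRUE)
  })
}

# tiny synthetic dataset + split for fast training tests
tiny_cohort <- function(seed, n = 10L, effect = 1, duration_s = 2,
                        fps = 40L) {
  dirc <- file.path(tempdir(),
                    sprintf("tiny_%d_%g_%d_%g", seed, effect, n, duration_s))
  if (!dir.exists(dirc)) {
    cs <- cohort_spec(n_participants = n, prevalence = 0.3,
                      effect_size = effect, clip_duration_s = duration_s,
                      seed = seed)
    generate_cohort(cs, dirc)
  }
  man <- read_manifest(file.path(dirc, "manifest.csv"))
  man$clip_path <- file.path(dirc, man$clip_path)
  ds <- extract_dataset(man, mfcc_dialect(), fps)
  list(manifest = man, dataset = ds,
       split = split_participants(man, seed = seed + 1L))
}

# the scaled-down end-to-end experiment of the acceptance suite:
# 40 participants, prevalence 0.25, 3 s clips, unit scale 1/8, <= 30 epochs
scaled_experiment <- function(seed, effect_size) {
  dirc <- file.path(tempdir(), sprintf("scaled_%d_%g", seed, effect_size))
  cs <- cohort_spec(n_participants = 40L, prevalence = 0.25,
                    effect_size = effect_size, clip_duration_s = 3,
                    seed = seed)
  man <- generate_cohort(cs, dirc)
  man$clip_path <- file.path(dirc, man$clip_path)
  fps <- 50L
  ds <- extract_dataset(man, mfcc_dialect(), fps)
  sp <- split_participants(man, seed = seed + 1L)
  spec <- model_spec(input_shape = c(fps, 13L), unit_scale = 1 / 8)
  cfg <- training_config(learning_rate = 0.05, batch_size = 16L,
                         max_epochs = 30L, momentum = 0.9,
                         early_stop_patience = 10L)
  fit <- train_model(build_model(spec, seed = seed + 2L), ds, sp, cfg,
                     seed = seed + 3L)
  rep <- evaluate_model(fit$model, ds, sp)
  unlink(dirc, recursive = TRUE)
  list(history = fit$history, report = rep, auroc = rep$auroc)
}
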