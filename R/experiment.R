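#' Default experiment configuration
#'
#' A nested list mirroring the JSON config file sections: `cohort`
#' (synthetic generation; `NULL` to use real audio via `manifest`),
#' `manifest`/`audio_dir` (real data), `extraction`, `space` (PSO candidate
#' sets; `NULL` disables the search), `model`, `training`, `evaluation`,
#' `seed`.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    cohort = list(n_participants = 46L, prevalence = 7 / 46,
                  effect_size = 1, clip_duration_s = 10,
                  sample_rate = 44100),
    manifest = NULL,
    audio_dir = NULL,
    extraction = list(n_mfcc = 13L, n_fft = 2048L, hop_length = 512L,
                      frames_per_segment = 100L),
    space = NULL,
    model = list(unit_scale = 1),
    training = list(learning_rate = 1e-4, batch_size = 128L,
                    max_epochs = 89L, momentum = 0.9,
                    early_stop_patience = 10L),
    evaluation = list(granularity = "segment", threshold = 0.5),
    pso = list(n_particles = 15L, max_iterations = 30L, patience = 10L,
               epochs = 10L),
    seed = 1L
  )
}

#' Read an experiment configuration file (JSON)
#'
#' Missing sections fall back to [default_config]; unknown keys are errors
#' at the point of use.
#'
#' @param path JSON file path.
#' @return Config list.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  utils::modifyList(default_config(), user)
}

#' Run the full screening experiment
#'
#' Pipeline: (optional) synthetic cohort generation, MFCC extraction and
#' segmentation to the JSON feature file, participant-level split,
#' (optional) PSO hyperparameter search, training with early stopping, and
#' held-out evaluation. All artifacts land in `out_dir`: `features.json`,
#' `split.csv`, `history.csv`, `pso_trace.csv` (when searching),
#' `metrics.csv`, `roc.csv`, and the resolved `config.json`. Fully
#' reproducible from `seed`.
#'
#' @param config Config list (see [default_config] / [read_config]).
#' @param out_dir Run directory, created if missing.
#' @param seed Overrides `config$seed` when non-`NULL`.
#' @return List with `manifest`, `dataset`, `split`, `model`, `history`,
#'   `report`, and `best_assignment` (when PSO ran).
#' @export
run_experiment <- function(config = default_config(), out_dir = tempfile(),
                           seed = NULL) {
  config <- utils::modifyList(default_config(), config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  seed0 <- as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("run_experiment: stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }

  manifest <- stage("cohort", {
    if (!is.null(config$manifest)) {
      m <- read_manifest(config$manifest)
      if (!is.null(config$audio_dir)) {
        m$clip_path <- file.path(config$audio_dir, m$clip_path)
      }
      m
    } else {
      cs <- do.call(cohort_spec, c(config$cohort, list(seed = seed0)))
      audio_dir <- file.path(out_dir, "audio")
      m <- generate_cohort(cs, audio_dir)
      m$clip_path <- file.path(audio_dir, m$clip_path)
      m
    }
  })

  ext <- config$extraction
  dialect <- do.call(mfcc_dialect,
                     ext[names(ext) %in% names(formals(mfcc_dialect))])
  fps <- if (is.null(ext$frames_per_segment)) 100L
         else as.integer(ext$frames_per_segment)
  dataset <- stage("extract", extract_dataset(manifest, dialect, fps))
  write_feature_json(dataset, file.path(out_dir, "features.json"))

  split <- stage("split", split_participants(manifest, seed = seed0 + 1L))
  utils::write.csv(as.data.frame(split), file.path(out_dir, "split.csv"),
                   row.names = FALSE)

  tr <- config$training
  cfg <- do.call(training_config,
                 tr[names(tr) %in% names(formals(training_config))])
  spec_args <- config$model
  spec_args$input_shape <- c(fps, dialect$n_mfcc)
  spec <- do.call(model_spec,
                  spec_args[names(spec_args) %in%
                              names(formals(model_spec))])

  best_assignment <- NULL
  if (!is.null(config$space) && length(config$space)) {
    pso_res <- stage("optimize", {
      space <- hparam_space(config$space)
      pso_optimize(
        space,
        fitness = function(a) {
          pso_fitness(a, dataset, split, base_spec = spec,
                      seed = seed0 + 2L,
                      epochs = min(config$pso$epochs, cfg$max_epochs),
                      base_cfg = cfg)
        },
        n_particles = config$pso$n_particles,
        max_iterations = config$pso$max_iterations,
        patience = config$pso$patience,
        seed = seed0 + 3L
      )
    })
    best_assignment <- pso_res$best
    write_pso_trace(pso_res$trace, file.path(out_dir, "pso_trace.csv"))
    cfg_over <- best_assignment[names(best_assignment) %in%
                                  names(formals(training_config))]
    if (length(cfg_over)) {
      cfg <- do.call(training_config, utils::modifyList(
        unclass(cfg)[names(unclass(cfg)) %in%
                       names(formals(training_config))], cfg_over))
    }
    spec_over <- best_assignment[names(best_assignment) %in%
                                   names(formals(model_spec))]
    if (length(spec_over)) {
      spec <- do.call(model_spec, utils::modifyList(
        unclass(spec)[names(unclass(spec)) %in% names(formals(model_spec))],
        spec_over))
    }
  }

  fit <- stage("train", {
    model <- build_model(spec, seed = seed0 + 4L)
    train_model(model, dataset, split, cfg, seed = seed0 + 5L)
  })
  utils::write.csv(
    cbind(fit$history,
          best_epoch = attr(fit$history, "best_epoch"),
          stopped_epoch = attr(fit$history, "stopped_epoch")),
    file.path(out_dir, "history.csv"), row.names = FALSE)

  report <- stage("evaluate", {
    evaluate_model(fit$model, dataset, split,
                   granularity = config$evaluation$granularity,
                   threshold = config$evaluation$threshold)
  })
  write_report(report, out_dir)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  list(manifest = manifest, dataset = dataset, split = split,
       model = fit$model, history = fit$history, report = report,
       best_assignment = best_assignment, out_dir = out_dir)
}
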