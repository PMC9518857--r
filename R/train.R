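#' Participant-level train/validation/test split
#'
#' Partitions participants (never individual segments) into train,
#' validation and test sets at the nearest-integer fractions: validation and
#' test sizes are `round(fraction * n)` and train takes the remainder
#' (46 participants at 60/20/20 gives 28/9/9). Allocation is stratified by
#' class with a largest-remainder quota per class, constrained to the
#' overall partition sizes; each partition receives at least one participant
#' of each class when the class is large enough. Deterministic given `seed`.
#'
#' @param manifest Participant manifest data.frame (see [read_manifest]);
#'   only `participant_id` and `label` are used.
#' @param fractions Length-3 numeric `(train, validation, test)` summing
#'   to 1.
#' @param seed RNG seed.
#' @return A data.frame of class `split_assignment` with columns
#'   `participant_id`, `label`, `partition` (factor train/validation/test).
#' @export
split_participants <- function(manifest, fractions = c(0.6, 0.2, 0.2),
                               seed = 1L) {
  if (!"clip_path" %in% names(manifest)) manifest$clip_path <- ""
  manifest <- validate_manifest(manifest)
  if (nrow(manifest) < 5L) stop("split_participants: need >= 5 participants")
  if (length(unique(manifest$label)) < 2L) {
    stop("split_participants: both classes must be present")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("split_participants: fractions must sum to 1")
  }
  n <- nrow(manifest)
  n_val <- round(fractions[2L] * n)
  n_test <- round(fractions[3L] * n)

  classes <- sort(unique(manifest$label))
  class_n <- vapply(classes, function(k) sum(manifest$label == k), integer(1))

  # largest-remainder quota of a partition of size m across classes
  quota <- function(m) {
    q <- class_n * m / n
    base <- floor(q)
    rem <- m - sum(base)
    if (rem > 0) {
      extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1L
    }
    base
  }
  set.seed(seed)
  part <- setNames(rep("train", n), manifest$participant_id)
  if (any(class_n < 3L)) {
    # a class this small cannot be stratified across three partitions;
    # fall back to a plain random split at the same overall sizes
    warning("split_participants: a class has fewer than 3 participants; ",
            "falling back to an unstratified split")
    ids <- sample(manifest$participant_id)
    part[ids[seq_len(n_val)]] <- "validation"
    part[ids[n_val + seq_len(n_test)]] <- "test"
  } else {
    # keep >=1 of each class per partition while preserving the overall
    # partition size: forcing a zero quota up steals one from the class
    # with the largest quota
    force_min_one <- function(q) {
      for (k in seq_along(q)) {
        if (q[k] == 0L) {
          donor <- which.max(ifelse(seq_along(q) == k, -Inf, q))
          if (q[donor] > 1L) {      # infeasible otherwise; leave at 0
            q[donor] <- q[donor] - 1L
            q[k] <- 1L
          }
        }
      }
      q
    }
    q_val <- force_min_one(quota(n_val))
    q_test <- force_min_one(quota(n_test))
    for (k in seq_along(classes)) {
      if (q_val[k] + q_test[k] >= class_n[k]) {
        stop("split_participants: class ", classes[k],
             " too small for the requested fractions")
      }
    }
    for (k in seq_along(classes)) {
      ids <- sample(manifest$participant_id[manifest$label == classes[k]])
      take <- 0L
      if (q_val[k] > 0L) {
        part[ids[seq_len(q_val[k])]] <- "validation"
        take <- q_val[k]
      }
      if (q_test[k] > 0L) {
        part[ids[take + seq_len(q_test[k])]] <- "test"
      }
    }
  }
  out <- data.frame(participant_id = manifest$participant_id,
                    label = manifest$label,
                    partition = factor(part[manifest$participant_id],
                                       levels = c("train", "validation",
                                                  "test")),
                    stringsAsFactors = FALSE)
  attr(out, "fractions") <- fractions
  attr(out, "seed") <- seed
  class(out) <- c("split_assignment", "data.frame")
  out
}

#' Training configuration
#'
#' Defaults are the tuned full-scale hyperparameters: SGD with momentum 0.9
#' at learning rate 1e-4, batch size 128, up to 89 epochs, early stopping on
#' validation loss with patience 10 and best-weight restoration.
#'
#' @param learning_rate SGD learning rate, > 0 (0 allowed for diagnostics).
#' @param batch_size Mini-batch size; clamped to the training-set size.
#' @param max_epochs Epoch budget, >= 1.
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param early_stop_patience Epochs without validation improvement
#'   tolerated before stopping (0 stops at the first non-improving epoch).
#' @param standardize Z-score features per coefficient with
#'   training-partition statistics?
#' @param clip_grad_norm Global gradient-norm clip (`Inf` disables).
#' @return A list of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, batch_size = 128L,
                            max_epochs = 89L, momentum = 0.9,
                            early_stop_patience = 10L, standardize = TRUE,
                            clip_grad_norm = 5) {
  stopifnot(learning_rate >= 0, batch_size >= 1L, max_epochs >= 1L,
            momentum >= 0, momentum < 1, early_stop_patience >= 0L)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), momentum = momentum,
                 early_stop_patience = as.integer(early_stop_patience),
                 early_stop_metric = "validation_loss",
                 standardize = standardize,
                 clip_grad_norm = clip_grad_norm),
            class = "training_config")
}

# mean cross-entropy of a model on a stacked cube, dropout off
.eval_loss <- function(params, x, y, n_dense1) {
  out <- nn_predict_cpp(params, x, matrix(1, dim(x)[1L], n_dense1), FALSE)
  p <- out$probs[cbind(seq_along(y), y + 1L)]
  -mean(log(pmax(p, 1e-300)))
}

#' Train a Bi-LSTM-A model
#'
#' Stochastic gradient descent with momentum on shuffled mini-batches of
#' training-partition segments; after every epoch the validation loss is
#' recorded, and training stops when `early_stop_patience` epochs pass
#' without improvement or the epoch budget is exhausted. The returned model
#' carries the weights of the best validation epoch. Segments of test
#' participants are never touched (leakage guard asserted).
#'
#' @param model A `bilstm_a` from [build_model].
#' @param data A `feature_dataset`.
#' @param split A `split_assignment` covering the dataset's participants.
#' @param cfg A [training_config].
#' @param seed RNG seed for shuffling and dropout masks.
#' @return List with `model` (best weights, normalisation stats attached)
#'   and `history` (class `training_history`: data.frame of per-epoch train
#'   and validation loss plus `best_epoch`, `stopped_epoch` attributes).
#' @export
train_model <- function(model, data, split, cfg = training_config(),
                        seed = 1L) {
  stopifnot(inherits(model, "bilstm_a"), inherits(data, "feature_dataset"),
            inherits(split, "split_assignment"),
            inherits(cfg, "training_config"))
  arr <- dataset_arrays(data)
  part <- setNames(as.character(split$partition), split$participant_id)
  unknown <- setdiff(arr$participant_id, names(part))
  if (length(unknown)) {
    stop("train_model: segments from participants missing in split: ",
         paste(unique(unknown), collapse = ", "))
  }
  seg_part <- part[arr$participant_id]
  idx_train <- which(seg_part == "train")
  idx_val <- which(seg_part == "validation")
  if (!length(idx_train)) stop("train_model: empty training partition")
  if (!length(idx_val)) stop("train_model: empty validation partition")
  # leakage guard: train/val indices must not touch test participants
  stopifnot(!any(arr$participant_id[c(idx_train, idx_val)] %in%
                   split$participant_id[split$partition == "test"]))

  if (cfg$standardize) {
    tr <- arr$x[idx_train, , , drop = FALSE]
    model$feature_mean <- apply(tr, 3L, mean)
    sds <- apply(tr, 3L, stats::sd)
    model$feature_sd <- ifelse(sds > 0, sds, 1)
  } else {
    model$feature_mean <- NULL
    model$feature_sd <- NULL
  }
  x_train <- .batch_cube(model, arr$x[idx_train, , , drop = FALSE])
  y_train <- arr$y[idx_train]
  x_val <- .batch_cube(model, arr$x[idx_val, , , drop = FALSE])
  y_val <- arr$y[idx_val]

  n_train <- length(y_train)
  bs <- min(cfg$batch_size, n_train)
  nd1 <- model$spec$dense1_units
  params <- model$params
  vel <- lapply(params, function(p) p * 0)
  best <- list(epoch = 0L, val = Inf, params = params)
  hist_train <- numeric(0)
  hist_val <- numeric(0)
  set.seed(seed)
  stall <- 0L
  epoch <- 0L
  while (epoch < cfg$max_epochs) {
    epoch <- epoch + 1L
    ord <- sample.int(n_train)
    batch_losses <- numeric(0)
    for (b0 in seq(1L, n_train, by = bs)) {
      bi <- ord[b0:min(b0 + bs - 1L, n_train)]
      mask <- draw_dropout_mask(length(bi), nd1, model$spec$dropout_rate)
      res <- nn_loss_grad(params, x_train[bi, , , drop = FALSE],
                          as.integer(y_train[bi]), mask,
                          model$spec$dropout_rate > 0)
      if (!is.finite(res$loss)) {
        stop("train_model: non-finite training loss at epoch ", epoch,
             " (batch starting ", b0, "); learning rate ",
             cfg$learning_rate, " likely too large")
      }
      batch_losses <- c(batch_losses, res$loss)
      g <- res$grads
      if (is.finite(cfg$clip_grad_norm)) {
        gnorm <- sqrt(sum(vapply(g, function(m) sum(m^2), numeric(1))))
        if (gnorm > cfg$clip_grad_norm) {
          g <- lapply(g, function(m) m * (cfg$clip_grad_norm / gnorm))
        }
      }
      for (nm in names(params)) {
        vel[[nm]] <- cfg$momentum * vel[[nm]] - cfg$learning_rate * g[[nm]]
        params[[nm]] <- params[[nm]] + vel[[nm]]
      }
    }
    hist_train <- c(hist_train, mean(batch_losses))
    vloss <- .eval_loss(params, x_val, y_val, nd1)
    if (!is.finite(vloss)) {
      stop("train_model: non-finite validation loss at epoch ", epoch)
    }
    hist_val <- c(hist_val, vloss)
    if (vloss < best$val) {
      best <- list(epoch = epoch, val = vloss, params = params)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall > cfg$early_stop_patience) break
    }
  }
  model$params <- best$params
  history <- structure(
    data.frame(epoch = seq_along(hist_train), train_loss = hist_train,
               val_loss = hist_val),
    best_epoch = best$epoch, stopped_epoch = epoch,
    class = c("training_history", "data.frame")
  )
  list(model = model, history = history)
}

#' PSO fitness of a hyperparameter assignment
#'
#' Builds the model with any unit overrides, trains under a reduced epoch
#' budget, and returns the best validation loss (the minimised fitness).
#' A failed or non-finite training run returns `+Inf` so the swarm survives
#' bad regions. Deterministic given `seed`.
#'
#' @param assignment Named list from [decode_position]; recognised names:
#'   `learning_rate`, `batch_size`, `momentum`, `bilstm_units`,
#'   `lstm_units`, `attention_units`, `dense1_units`, `dense2_units`,
#'   `dropout_rate`.
#' @param data A `feature_dataset`.
#' @param split A `split_assignment`.
#' @param base_spec The [model_spec] to override.
#' @param seed RNG seed.
#' @param epochs Reduced training budget for fitness evaluation.
#' @param base_cfg [training_config] supplying non-searched settings.
#' @return Scalar fitness (best validation loss), `+Inf` on failure.
#' @export
pso_fitness <- function(assignment, data, split, base_spec = model_spec(),
                        seed = 1L, epochs = 10L,
                        base_cfg = training_config()) {
  spec_args <- assignment[names(assignment) %in%
                            c("bilstm_units", "lstm_units",
                              "attention_units", "dense1_units",
                              "dense2_units", "dropout_rate")]
  cfg_args <- assignment[names(assignment) %in%
                           c("learning_rate", "batch_size", "momentum")]
  tryCatch({
    spec <- do.call(model_spec, utils::modifyList(
      unclass(base_spec)[names(unclass(base_spec)) %in%
                           names(formals(model_spec))],
      spec_args))
    cfg <- do.call(training_config, utils::modifyList(
      unclass(base_cfg)[names(unclass(base_cfg)) %in%
                          names(formals(training_config))],
      c(cfg_args, list(max_epochs = epochs))))
    model <- build_model(spec, seed = seed)
    fit <- train_model(model, data, split, cfg, seed = seed)
    v <- min(fit$history$val_loss)
    if (!is.finite(v)) Inf else v
  }, error = function(e) Inf)
}
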