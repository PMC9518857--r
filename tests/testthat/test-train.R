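test_that("46 participants split 28/9/9 with class stratification", {
  man <- random_manifest(46, 7, seed = 41)
  sp <- split_participants(man, seed = 42)
  expect_identical(as.integer(table(sp$partition)), c(28L, 9L, 9L))
  tab <- table(sp$partition, sp$label)
  expect_true(all(tab[, "1"] >= 1))           # every partition sees mTBI
  expect_identical(sum(tab[, "1"]), 7L)
  # deterministic
  expect_identical(split_participants(man, seed = 42), sp)
  expect_false(identical(split_participants(man, seed = 43)$partition,
                         sp$partition))
})

test_that("splits partition cleanly at nearest-integer sizes for any cohort", {
  set.seed(44)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    n_pos <- sample(3:(n - 3), 1)
    man <- random_manifest(n, n_pos, seed = 4000 + i)
    sp <- split_participants(man, seed = i)
    expect_setequal(sp$participant_id, man$participant_id)
    expect_identical(anyDuplicated(sp$participant_id), 0L)
    sizes <- as.integer(table(sp$partition))
    expect_identical(sizes[2], as.integer(round(0.2 * n)))
    expect_identical(sizes[3], as.integer(round(0.2 * n)))
    expect_identical(sum(sizes), n)
  }
})

test_that("tiny classes fall back to an unstratified split with a warning", {
  man <- random_manifest(12, 2, seed = 45)
  expect_warning(sp <- split_participants(man, seed = 46), "unstratified")
  expect_identical(as.integer(table(sp$partition)), c(8L, 2L, 2L))
  expect_error(split_participants(random_manifest(4, 2, seed = 1)),
               ">= 5 participants")
  all_neg <- random_manifest(10, 5, seed = 1)
  all_neg$label <- 0L
  expect_error(split_participants(all_neg), "both classes")
})

test_that("zero learning rate leaves the loss untouched", {
  tc <- tiny_cohort(seed = 51)
  spec <- model_spec(input_shape = c(40L, 13L), unit_scale = 1 / 16,
                     dropout_rate = 0)
  cfg <- training_config(learning_rate = 0, batch_size = 64L,
                         max_epochs = 4L, early_stop_patience = 10L)
  fit <- train_model(build_model(spec, seed = 52), tc$dataset, tc$split,
                     cfg, seed = 53)
  expect_lt(diff(range(fit$history$train_loss)), 1e-7)
  expect_lt(diff(range(fit$history$val_loss)), 1e-7)
})

test_that("training on a strong cohort reduces the loss", {
  tc <- tiny_cohort(seed = 54)
  spec <- model_spec(input_shape = c(40L, 13L), unit_scale = 1 / 8)
  cfg <- training_config(learning_rate = 0.05, batch_size = 16L,
                         max_epochs = 10L, early_stop_patience = 10L)
  fit <- train_model(build_model(spec, seed = 55), tc$dataset, tc$split,
                     cfg, seed = 56)
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  # the returned weights are the validation optimum
  expect_identical(attr(h, "best_epoch"), which.min(h$val_loss))
})

test_that("early stopping with zero patience halts at the first stall", {
  tc <- tiny_cohort(seed = 57)
  spec <- model_spec(input_shape = c(40L, 13L), unit_scale = 1 / 16)
  cfg <- training_config(learning_rate = 0.05, batch_size = 16L,
                         max_epochs = 30L, early_stop_patience = 0L)
  fit <- train_model(build_model(spec, seed = 58), tc$dataset, tc$split,
                     cfg, seed = 59)
  h <- fit$history
  stopped <- attr(h, "stopped_epoch")
  if (stopped < 30L) {
    # the stopping epoch is the first whose validation loss fails to improve
    firsts <- which(h$val_loss >= cummin(c(Inf, utils::head(h$val_loss, -1))))
    expect_identical(stopped, min(firsts))
  }
})

test_that("the split leakage guard catches unknown and test participants", {
  tc <- tiny_cohort(seed = 61)
  spec <- model_spec(input_shape = c(40L, 13L), unit_scale = 1 / 16)
  cfg <- training_config(learning_rate = 0.01, batch_size = 32L,
                         max_epochs = 1L)
  incomplete <- tc$split[tc$split$participant_id !=
                           tc$split$participant_id[1], ]
  class(incomplete) <- class(tc$split)
  expect_error(
    train_model(build_model(spec, seed = 62), tc$dataset, incomplete, cfg),
    "missing in split"
  )
})

test_that("pso_fitness is deterministic and returns Inf sentinels", {
  tc <- tiny_cohort(seed = 63)
  spec <- model_spec(input_shape = c(40L, 13L), unit_scale = 1 / 16)
  cfg <- training_config(learning_rate = 0.02, batch_size = 32L,
                         max_epochs = 3L)
  asg <- list(learning_rate = 0.02, batch_size = 16, momentum = 0.9)
  f1 <- pso_fitness(asg, tc$dataset, tc$split, spec, seed = 64, epochs = 3,
                    base_cfg = cfg)
  f2 <- pso_fitness(asg, tc$dataset, tc$split, spec, seed = 64, epochs = 3,
                    base_cfg = cfg)
  expect_identical(f1, f2)
  expect_true(is.finite(f1))
  # an invalid assignment cannot crash the swarm
  bad <- list(learning_rate = -1, batch_size = 16, momentum = 0.9)
  expect_identical(pso_fitness(bad, tc$dataset, tc$split, spec, seed = 64,
                               epochs = 2, base_cfg = cfg), Inf)
  # non-finite training loss propagates as the Inf sentinel, not an error
  corrupt <- tc$dataset
  corrupt$segments[[1]]$features[1, 1] <- NaN
  expect_identical(pso_fitness(asg, corrupt, tc$split, spec, seed = 64,
                               epochs = 2, base_cfg = cfg), Inf)
})

test_that("a zero learning rate never beats the tuned configuration", {
  tc <- tiny_cohort(seed = 65, n = 14L, duration_s = 3, fps = 50L)
  spec <- model_spec(input_shape = c(50L, 13L), unit_scale = 1 / 8)
  cfg <- training_config(learning_rate = 0.05, batch_size = 16L,
                         max_epochs = 12L)
  f_frozen <- pso_fitness(list(learning_rate = 0, batch_size = 16,
                               momentum = 0.9),
                          tc$dataset, tc$split, spec, seed = 67,
                          epochs = 12, base_cfg = cfg)
  f_tuned <- pso_fitness(list(learning_rate = 0.05, batch_size = 16,
                              momentum = 0.9),
                         tc$dataset, tc$split, spec, seed = 67,
                         epochs = 12, base_cfg = cfg)
  expect_gte(f_frozen, f_tuned)
})

test_that("run_experiment produces a complete, reproducible run directory", {
  cfg <- list(
    cohort = list(n_participants = 10L, prevalence = 0.3, effect_size = 1,
                  clip_duration_s = 2, sample_rate = 44100),
    extraction = list(frames_per_segment = 40L),
    model = list(unit_scale = 1 / 16),
    training = list(learning_rate = 0.05, batch_size = 16L, max_epochs = 3L,
                    momentum = 0.9, early_stop_patience = 10L),
    seed = 71L
  )
  d1 <- tempfile("run")
  r1 <- run_experiment(cfg, d1)
  expect_true(all(file.exists(file.path(
    d1, c("features.json", "split.csv", "history.csv", "metrics.csv",
          "roc.csv", "config.json")))))
  expect_s3_class(r1$report, "evaluation_report")
  d2 <- tempfile("run")
  r2 <- run_experiment(cfg, d2)
  expect_identical(r2$report$auroc, r1$report$auroc)
  expect_identical(r2$history$val_loss, r1$history$val_loss)
  m1 <- utils::read.csv(file.path(d1, "metrics.csv"))
  m2 <- utils::read.csv(file.path(d2, "metrics.csv"))
  expect_identical(m1, m2)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("run_experiment with a candidate space writes a pso trace", {
  cfg <- list(
    cohort = list(n_participants = 10L, prevalence = 0.3, effect_size = 1,
                  clip_duration_s = 2, sample_rate = 44100),
    extraction = list(frames_per_segment = 40L),
    model = list(unit_scale = 1 / 16),
    training = list(learning_rate = 0.05, batch_size = 16L, max_epochs = 2L,
                    momentum = 0.9),
    space = list(learning_rate = c(0.01, 0.05), batch_size = c(8, 16)),
    pso = list(n_particles = 3L, max_iterations = 2L, patience = 5L,
               epochs = 2L),
    seed = 72L
  )
  d <- tempfile("run")
  r <- run_experiment(cfg, d)
  expect_true(file.exists(file.path(d, "pso_trace.csv")))
  expect_true(all(c("learning_rate", "batch_size") %in%
                    names(r$best_assignment)))
  expect_true(r$best_assignment$learning_rate %in% c(0.01, 0.05))
  unlink(d, recursive = TRUE)
})
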