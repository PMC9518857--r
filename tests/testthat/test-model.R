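tiny_spec <- function(dropout = 0) {
  model_spec(input_shape = c(6L, 4L), bilstm_units = 6L, lstm_units = 4L,
             attention_units = 5L, dense1_units = 5L, dense2_units = 4L,
             dropout_rate = dropout)
}

rand_batch <- function(n, spec, seed) {
  set.seed(seed)
  array(stats::rnorm(n * spec$input_shape[1] * spec$input_shape[2]),
        c(n, spec$input_shape[1], spec$input_shape[2]))
}

test_that("forward outputs live on the probability simplex, deterministically", {
  spec <- tiny_spec()
  m <- build_model(spec, seed = 1)
  x <- rand_batch(4, spec, 11)
  out <- forward(m, x)
  expect_identical(dim(out$probs), c(4L, 2L))
  expect_equal(rowSums(out$probs), rep(1, 4), tolerance = 1e-6)
  expect_true(all(out$probs >= 0))
  expect_true(all(is.finite(out$probs)))
  # identical seed -> identical model -> identical outputs
  m2 <- build_model(spec, seed = 1)
  expect_identical(forward(m2, x)$probs, out$probs)
  # inference is repeatable
  expect_identical(forward(m, x)$probs, out$probs)
  # attention weights are a distribution over timesteps
  expect_equal(rowSums(out$attention), rep(1, 4), tolerance = 1e-6)
  expect_true(all(out$attention >= 0))
})

test_that("training-mode dropout is stochastic but seed-reproducible", {
  spec <- tiny_spec(dropout = 0.6)
  m <- build_model(spec, seed = 2)
  x <- rand_batch(3, spec, 12)
  set.seed(99)
  a <- forward(m, x, training = TRUE)
  set.seed(99)
  b <- forward(m, x, training = TRUE)
  expect_identical(a$probs, b$probs)
  clean <- forward(m, x)
  expect_false(identical(a$probs, clean$probs))
})

test_that("batch permutation permutes outputs identically", {
  spec <- tiny_spec()
  m <- build_model(spec, seed = 3)
  x <- rand_batch(6, spec, 13)
  perm <- c(4, 1, 6, 2, 5, 3)
  p1 <- forward(m, x)$probs
  p2 <- forward(m, x[perm, , ])$probs
  expect_equal(p2, p1[perm, ], tolerance = 1e-12)
})

test_that("shape mismatches are rejected", {
  m <- build_model(tiny_spec(), seed = 4)
  expect_error(forward(m, array(0, c(2, 5, 4))), "does not match")
  expect_error(forward(m, array(0, c(2, 6, 3))), "does not match")
})

test_that("count_parameters matches independent layer-by-layer arithmetic", {
  spec <- model_spec()   # full-scale default
  # hand arithmetic with H1 = 256 per direction (total reading of 512)
  lstm <- function(din, h) 4 * (h * (din + h) + h)
  expected <- 2 * lstm(13, 256) + lstm(512, 256) +
    (256 * 512 + 512 + 512) +                   # attention W, b, v
    (256 * 128 + 128) + (128 * 64 + 64) + (64 * 2 + 2)
  expect_identical(count_parameters(spec), expected)
  # the final dense layer contributes 64*2+2 = 130
  spec_noout <- model_spec(n_classes = 4L)
  expect_identical(count_parameters(spec_noout) - count_parameters(spec),
                   (64 * 4 + 4) - 130)
  # sanity band around the reported lightweight model
  expect_gte(count_parameters(spec), 0.8e6)
  expect_lte(count_parameters(spec), 3.0e6)
  # per-direction reading is far larger
  expect_gt(count_parameters(model_spec(bidirectional_reading =
                                          "per_direction")), 3e6)
  # monotone in width
  expect_gt(count_parameters(model_spec(dense1_units = 256L)),
            count_parameters(spec))
})

test_that("attention_pool matches its contract and the compiled kernel", {
  set.seed(14)
  d <- 5L; A <- 4L
  pars <- list(W = matrix(stats::rnorm(d * A), d, A),
               b = stats::rnorm(A), v = stats::rnorm(A))
  # singleton sequence: weight 1, context = the step
  h1 <- matrix(stats::rnorm(d), 1, d)
  r1 <- attention_pool(h1, pars)
  expect_equal(r1$weights, 1)
  expect_equal(r1$context, as.numeric(h1))
  # identical timesteps: context equals the common vector
  h <- matrix(rep(stats::rnorm(d), each = 7), 7, d)
  r2 <- attention_pool(h, pars)
  expect_equal(r2$context, as.numeric(h[1, ]), tolerance = 1e-12)
  # weights are a distribution; compiled and R versions agree
  for (i in 1:5) {
    hs <- matrix(stats::rnorm(6 * d), 6, d)
    rr <- attention_pool(hs, pars)
    expect_equal(sum(rr$weights), 1, tolerance = 1e-12)
    expect_true(all(rr$weights >= 0))
    cc <- speechscreen:::cpp_attention(hs, pars$W, pars$b, pars$v)
    expect_equal(as.numeric(cc$context), rr$context, tolerance = 1e-12)
    expect_equal(as.numeric(cc$weights), rr$weights, tolerance = 1e-12)
  }
  expect_error(attention_pool(matrix(0, 0, d), pars), "empty")
})

test_that("analytic gradients match central differences", {
  spec <- tiny_spec(dropout = 0.5)
  m <- build_model(spec, seed = 42)
  # nudge biases off zero so no ReLU pre-activation sits exactly on the kink
  set.seed(15)
  for (nm in c("bd1", "bd2", "bo", "ba")) {
    m$params[[nm]] <- m$params[[nm]] + stats::rnorm(length(m$params[[nm]]),
                                                    0, 0.05)
  }
  x <- rand_batch(3, spec, 16)
  xc <- aperm(x, c(1, 3, 2))
  y <- c(0L, 1L, 1L)
  for (use_dropout in c(FALSE, TRUE)) {
    mask <- if (use_dropout) draw_dropout_mask(3, spec$dense1_units, 0.5)
            else matrix(1, 3, spec$dense1_units)
    res <- speechscreen:::nn_loss_grad(m$params, xc, y, mask, use_dropout)
    num_grad <- function(nm, i) {
      e <- 1e-6
      p1 <- m$params; p2 <- m$params
      p1[[nm]][i] <- p1[[nm]][i] + e
      p2[[nm]][i] <- p2[[nm]][i] - e
      (speechscreen:::nn_loss_grad(p1, xc, y, mask, use_dropout)$loss -
         speechscreen:::nn_loss_grad(p2, xc, y, mask, use_dropout)$loss) /
        (2 * e)
    }
    set.seed(17)
    for (nm in names(res$grads)) {
      g <- res$grads[[nm]]
      for (i in sample(length(g), min(4, length(g)))) {
        n <- num_grad(nm, i)
        expect_lt(abs(g[i] - n) / max(1e-6, abs(g[i]) + abs(n)), 1e-4)
      }
    }
  }
})

test_that("unit_scale produces a valid smaller architecture", {
  s <- model_spec(unit_scale = 1 / 8)
  expect_identical(s$bilstm_units, 64L)
  expect_identical(s$lstm_units, 32L)
  expect_identical(s$dense1_units, 16L)
  m <- build_model(s, seed = 5)
  out <- forward(m, rand_batch(2, s, 18))
  expect_equal(rowSums(out$probs), c(1, 1), tolerance = 1e-6)
  expect_lt(count_parameters(s), count_parameters(model_spec()))
})

test_that("invalid specs are rejected", {
  expect_error(model_spec(dropout_rate = 1), "dropout_rate")
  expect_error(model_spec(dropout_rate = -0.2), "dropout_rate")
})
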