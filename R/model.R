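#' Bi-LSTM-A architecture specification
#'
#' The seven-layer architecture: bidirectional LSTM (sequence output),
#' LSTM (sequence output), additive temporal attention pooling to a single
#' context vector, dense + ReLU, dropout, dense + ReLU, dense softmax over
#' two classes.
#'
#' `bilstm_units` is by default read as the TOTAL concatenated output width
#' of the bidirectional layer (512 = 256 units per direction); the
#' alternative per-direction reading is selectable with
#' `bidirectional_reading = "per_direction"`. The total reading puts the
#' default parameter count near 1.5 million, consistent with a lightweight
#' on-device model; the per-direction reading exceeds 3 million.
#'
#' `unit_scale` divides the recurrent/attention/dense widths for desk-scale
#' experiments (e.g. `1/8`), keeping the architecture shape intact.
#'
#' @param input_shape `(frames_per_segment, n_coefficients)`.
#' @param bilstm_units Bidirectional layer width (see above), default 512.
#' @param lstm_units Second recurrent layer units, default 256.
#' @param attention_units Hidden width of the additive attention scorer,
#'   default 512.
#' @param dense1_units,dense2_units Dense layer widths, defaults 128 and 64.
#' @param dropout_rate Dropout fraction after the first dense layer,
#'   default 0.6.
#' @param n_classes Output classes, default 2.
#' @param bidirectional_reading `"total"` or `"per_direction"`.
#' @param unit_scale Multiplicative scale on all widths, default 1.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(input_shape = c(100L, 13L), bilstm_units = 512L,
                       lstm_units = 256L, attention_units = 512L,
                       dense1_units = 128L, dropout_rate = 0.6,
                       dense2_units = 64L, n_classes = 2L,
                       bidirectional_reading = c("total", "per_direction"),
                       unit_scale = 1) {
  bidirectional_reading <- match.arg(bidirectional_reading)
  sc <- function(u) max(2L, as.integer(round(u * unit_scale)))
  bilstm_units <- sc(bilstm_units)
  if (bilstm_units %% 2L == 1L) bilstm_units <- bilstm_units + 1L
  spec <- list(
    input_shape = as.integer(input_shape),
    bilstm_units = bilstm_units,
    lstm_units = sc(lstm_units),
    attention_units = sc(attention_units),
    dense1_units = sc(dense1_units),
    dropout_rate = dropout_rate,
    dense2_units = sc(dense2_units),
    n_classes = as.integer(n_classes),
    bidirectional_reading = bidirectional_reading
  )
  if (any(unlist(spec[c("bilstm_units", "lstm_units", "attention_units",
                        "dense1_units", "dense2_units", "n_classes")]) < 1L)) {
    stop("model_spec: all unit counts must be >= 1")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("model_spec: dropout_rate must be in [0, 1)")
  }
  structure(spec, class = "model_spec")
}

# units per direction of the bidirectional layer
.h1_units <- function(spec) {
  if (spec$bidirectional_reading == "total") spec$bilstm_units %/% 2L
  else spec$bilstm_units
}

#' Exact trainable-parameter count
#'
#' Closed forms: LSTM direction `4 * (H * (d_in + H) + H)`; dense
#' `d_in * u + u`; additive attention `d * a + a + a` (scorer matrix, scorer
#' bias, scoring vector).
#'
#' @param spec A [model_spec].
#' @return Integer parameter total.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  d <- spec$input_shape[2L]
  h1 <- .h1_units(spec)
  h2 <- spec$lstm_units
  lstm_p <- function(din, h) 4 * (h * (din + h) + h)
  dense_p <- function(din, u) din * u + u
  2 * lstm_p(d, h1) +                 # two directions
    lstm_p(2 * h1, h2) +
    (h2 * spec$attention_units + spec$attention_units +
       spec$attention_units) +
    dense_p(h2, spec$dense1_units) +
    dense_p(spec$dense1_units, spec$dense2_units) +
    dense_p(spec$dense2_units, spec$n_classes)
}

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Build a Bi-LSTM-A model
#'
#' Initialises all weights (Glorot-uniform matrices, zero biases with the
#' LSTM forget-gate biases set to 1) deterministically from `seed`.
#'
#' @param spec A [model_spec].
#' @param seed RNG seed for initialisation.
#' @return An object of class `bilstm_a` holding `spec`, the parameter list,
#'   `rng_seed`, and (after training) feature normalisation statistics.
#' @export
build_model <- function(spec = model_spec(), seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(seed)
  d <- spec$input_shape[2L]
  h1 <- .h1_units(spec)
  h2 <- spec$lstm_units
  a <- spec$attention_units
  lstm_init <- function(din, h) {
    b <- numeric(4L * h)
    b[(h + 1L):(2L * h)] <- 1          # forget-gate bias
    list(W = .glorot(din, 4L * h), U = .glorot(h, 4L * h), b = b)
  }
  lf <- lstm_init(d, h1)
  lb <- lstm_init(d, h1)
  l2 <- lstm_init(2L * h1, h2)
  params <- list(
    Wf = lf$W, Uf = lf$U, bf = lf$b,
    Wb = lb$W, Ub = lb$U, bb = lb$b,
    W2 = l2$W, U2 = l2$U, b2 = l2$b,
    Wa = .glorot(h2, a), ba = numeric(a), va = as.numeric(.glorot(a, 1L)),
    Wd1 = .glorot(h2, spec$dense1_units), bd1 = numeric(spec$dense1_units),
    Wd2 = .glorot(spec$dense1_units, spec$dense2_units),
    bd2 = numeric(spec$dense2_units),
    Wo = .glorot(spec$dense2_units, spec$n_classes),
    bo = numeric(spec$n_classes)
  )
  structure(list(spec = spec, params = params, rng_seed = as.integer(seed),
                 feature_mean = NULL, feature_sd = NULL),
            class = "bilstm_a")
}

#' @export
print.bilstm_a <- function(x, ...) {
  cat(sprintf(
    "<bilstm_a> input %dx%d | biLSTM %d | LSTM %d | attn %d | dense %d/%d | %d classes | %s parameters\n",
    x$spec$input_shape[1L], x$spec$input_shape[2L], x$spec$bilstm_units,
    x$spec$lstm_units, x$spec$attention_units, x$spec$dense1_units,
    x$spec$dense2_units, x$spec$n_classes,
    format(count_parameters(x$spec), big.mark = ",")))
  invisible(x)
}

# coerce batch input (array n x T x d, single matrix T x d, or list of
# matrices) to the C++ layout cube n x d x T, applying normalisation
.batch_cube <- function(model, batch) {
  if (is.matrix(batch)) batch <- list(batch)
  if (is.list(batch)) {
    arr <- array(0, c(length(batch), nrow(batch[[1L]]), ncol(batch[[1L]])))
    for (i in seq_along(batch)) arr[i, , ] <- batch[[i]]
    batch <- arr
  }
  stopifnot(length(dim(batch)) == 3L)
  if (dim(batch)[2L] != model$spec$input_shape[1L] ||
      dim(batch)[3L] != model$spec$input_shape[2L]) {
    stop("batch shape ", paste(dim(batch)[-1L], collapse = "x"),
         " does not match model input ",
         paste(model$spec$input_shape, collapse = "x"))
  }
  if (!is.null(model$feature_mean)) {
    for (j in seq_len(dim(batch)[3L])) {
      batch[, , j] <- (batch[, , j] - model$feature_mean[j]) /
        model$feature_sd[j]
    }
  }
  aperm(batch, c(1L, 3L, 2L))
}

#' Forward pass
#'
#' Runs the network on a batch of feature segments. Inference mode
#' (`training = FALSE`, the default) disables dropout and is deterministic;
#' training mode applies an inverted-dropout mask which is drawn from R's
#' RNG (seed it for reproducibility) unless supplied.
#'
#' @param model A `bilstm_a` model.
#' @param batch `n x frames x coefficients` array, a single `frames x
#'   coefficients` matrix, or a list of such matrices.
#' @param training Apply dropout?
#' @param dropout_mask Optional pre-drawn `n x dense1_units` mask of
#'   `0 / (1/(1-rate))` values.
#' @return List with `probs` (`n x n_classes` rows on the simplex) and
#'   `attention` (`n x frames` attention weights).
#' @export
forward <- function(model, batch, training = FALSE, dropout_mask = NULL) {
  stopifnot(inherits(model, "bilstm_a"))
  x <- .batch_cube(model, batch)
  n <- dim(x)[1L]
  if (training && is.null(dropout_mask)) {
    dropout_mask <- draw_dropout_mask(n, model$spec$dense1_units,
                                      model$spec$dropout_rate)
  }
  if (is.null(dropout_mask)) {
    dropout_mask <- matrix(1, n, model$spec$dense1_units)
  }
  out <- nn_predict_cpp(model$params, x, dropout_mask, isTRUE(training))
  list(probs = out$probs, attention = out$attention)
}

#' Draw an inverted-dropout mask
#' @param n Batch size.
#' @param units Width of the dropped layer.
#' @param rate Dropout rate in `[0, 1)`.
#' @return `n x units` matrix of `0` or `1/(1-rate)`.
#' @export
draw_dropout_mask <- function(n, units, rate) {
  if (rate <= 0) return(matrix(1, n, units))
  matrix((stats::runif(n * units) >= rate) / (1 - rate), n, units)
}

#' Additive attention pooling (reference implementation)
#'
#' Scores each timestep with `e_t = v' tanh(W' h_t + b)`, softmaxes the
#' scores over time, and returns the weighted sum of the steps. This is the
#' plain-R counterpart of the pooling layer inside the compiled network and
#' is cross-checked against it in the test suite.
#'
#' @param sequence `T x d` matrix of hidden states.
#' @param parameters List with `W` (`d x attention_units`), `b`
#'   (`attention_units`), `v` (`attention_units`).
#' @return List with `context` (length-`d` vector) and `weights`
#'   (length-`T` softmax weights).
#' @export
attention_pool <- function(sequence, parameters) {
  sequence <- as.matrix(sequence)
  if (nrow(sequence) < 1L) stop("attention_pool: empty sequence")
  u <- tanh(sweep(sequence %*% parameters$W, 2L, parameters$b, "+"))
  e <- as.numeric(u %*% parameters$v)
  w <- exp(e - max(e))
  w <- w / sum(w)
  list(context = as.numeric(crossprod(sequence, w)), weights = w)
}
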