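#' Discrete hyperparameter search space
#'
#' Each dimension is an ordered set of pre-defined candidate values (e.g.
#' learning rates, batch sizes, momentum values, per-layer unit counts).
#' Particles fly in the continuous index space of each dimension and are
#' decoded to candidates by clamp-then-round.
#'
#' @param ... Named arguments, each a vector of >= 1 distinct candidates.
#' @return A list of class `hparam_space` with `dimensions` (named list) and
#'   `n_dims`.
#' @export
hparam_space <- function(...) {
  dims <- list(...)
  if (length(dims) == 1L && is.list(dims[[1L]]) && is.null(names(dims))) {
    dims <- dims[[1L]]
  }
  if (length(dims) == 0L) stop("hparam_space: empty space")
  if (is.null(names(dims)) || any(!nzchar(names(dims)))) {
    stop("hparam_space: every dimension must be named")
  }
  for (nm in names(dims)) {
    if (length(dims[[nm]]) < 1L) stop("hparam_space: empty dimension ", nm)
    if (anyDuplicated(dims[[nm]])) {
      stop("hparam_space: duplicate candidates in ", nm)
    }
  }
  structure(list(dimensions = dims, n_dims = length(dims)),
            class = "hparam_space")
}

#' Number of candidate combinations in a space
#' @param space An `hparam_space`.
#' @return Product of candidate counts.
#' @export
space_size <- function(space) {
  prod(vapply(space$dimensions, length, integer(1)))
}

#' Decode a continuous position to a hyperparameter assignment
#'
#' Each coordinate is clamped to `[0, n_candidates - 1]` and rounded to the
#' nearest integer index, with exact half-integer ties rounding DOWN
#' (2.5 -> index 2); the candidate at that index is returned.
#'
#' @param position Numeric vector, one coordinate per dimension.
#' @param space An `hparam_space`.
#' @return Named list of chosen candidate values.
#' @export
decode_position <- function(position, space) {
  if (length(position) != space$n_dims) {
    stop("decode_position: position length does not match space")
  }
  out <- vector("list", space$n_dims)
  names(out) <- names(space$dimensions)
  for (j in seq_len(space$n_dims)) {
    cand <- space$dimensions[[j]]
    x <- min(max(position[j], 0), length(cand) - 1L)
    idx <- ceiling(x - 0.5)            # round half down
    out[[j]] <- cand[idx + 1L]
  }
  out
}

#' Initialise a particle swarm
#'
#' Positions uniform over each dimension's index range `[0, k-1]`; velocities
#' uniform in `+/- range/2`; personal bests start at the initial positions
#' with unset (`NA`) fitness until the first evaluation.
#'
#' @param space An `hparam_space`.
#' @param n_particles Swarm size, >= 1.
#' @param seed RNG seed.
#' @return A list of class `swarm_state`.
#' @export
initialize_swarm <- function(space, n_particles = 15L, seed = 1L) {
  stopifnot(inherits(space, "hparam_space"), n_particles >= 1L)
  set.seed(seed)
  ranges <- vapply(space$dimensions, length, integer(1)) - 1L
  d <- space$n_dims
  pos <- matrix(stats::runif(n_particles * d, 0,
                             rep(ranges, each = n_particles)),
                n_particles, d)
  vel <- matrix(stats::runif(n_particles * d,
                             rep(-ranges / 2, each = n_particles),
                             rep(ranges / 2, each = n_particles)),
                n_particles, d)
  structure(
    list(position = pos, velocity = vel,
         pbest_position = pos,
         pbest_fitness = rep(NA_real_, n_particles),
         gbest_position = rep(NA_real_, d),
         gbest_fitness = NA_real_,
         iteration = 0L, space = space,
         rng_state = get(".Random.seed", .GlobalEnv)),
    class = "swarm_state"
  )
}

#' Advance the swarm by one iteration
#'
#' Evaluates every particle's decoded position with `fitness` (minimised),
#' updates personal and global bests by strict improvement, then applies the
#' canonical velocity/position update
#' `v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)`, `x <- x + v`, with
#' fresh uniform `r1`, `r2` per particle and dimension. Velocities are
#' clamped to the dimension range and positions to the index bounds.
#'
#' Velocities hitting a clamped position bound are zeroed (absorbing
#' walls). With `rescatter_duplicates = TRUE`, particles that decode to the
#' current global-best cell are re-scattered uniformly with probability 1/2
#' after the update — a standard anti-stagnation device for discrete
#' candidate spaces, where many continuous positions alias to one cell and
#' a collapsed swarm stops exploring.
#'
#' @param state A `swarm_state`.
#' @param fitness Function taking a decoded assignment (named list) and
#'   returning a scalar to minimise.
#' @param w Inertia weight.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param rescatter_duplicates Re-scatter particles aliasing the global
#'   best cell? Default `FALSE` (pure canonical update).
#' @return The updated `swarm_state`.
#' @export
step_swarm <- function(state, fitness, w = 0.729, c1 = 1.49445,
                       c2 = 1.49445, rescatter_duplicates = FALSE) {
  stopifnot(inherits(state, "swarm_state"))
  assign(".Random.seed", state$rng_state, .GlobalEnv)
  space <- state$space
  n <- nrow(state$position)
  d <- space$n_dims
  ranges <- vapply(space$dimensions, length, integer(1)) - 1L

  for (i in seq_len(n)) {
    f <- tryCatch(
      fitness(decode_position(state$position[i, ], space)),
      error = function(e) {
        stop("step_swarm: fitness failed for particle ", i, ": ",
             conditionMessage(e))
      }
    )
    if (is.na(state$pbest_fitness[i]) || f < state$pbest_fitness[i]) {
      state$pbest_fitness[i] <- f
      state$pbest_position[i, ] <- state$position[i, ]
    }
  }
  b <- which.min(state$pbest_fitness)
  if (length(b) == 1L &&
      (is.na(state$gbest_fitness) ||
       state$pbest_fitness[b] < state$gbest_fitness)) {
    state$gbest_fitness <- state$pbest_fitness[b]
    state$gbest_position <- state$pbest_position[b, ]
  }

  r1 <- matrix(stats::runif(n * d), n, d)
  r2 <- matrix(stats::runif(n * d), n, d)
  gb <- matrix(state$gbest_position, n, d, byrow = TRUE)
  v <- w * state$velocity +
    c1 * r1 * (state$pbest_position - state$position) +
    c2 * r2 * (gb - state$position)
  vmax <- matrix(pmax(ranges, 1e-12), n, d, byrow = TRUE)
  v <- pmin(pmax(v, -vmax), vmax)
  x <- state$position + v
  bounds <- matrix(ranges, n, d, byrow = TRUE)
  v[x < 0 | x > bounds] <- 0                  # absorbing walls
  x <- pmin(pmax(x, 0), bounds)
  if (rescatter_duplicates) {
    gcell <- unname(unlist(decode_position(state$gbest_position, space)))
    same <- vapply(seq_len(n), function(i) {
      identical(unname(unlist(decode_position(x[i, ], space))), gcell)
    }, logical(1))
    kick <- same & stats::runif(n) < 0.5
    ns <- sum(kick)
    if (ns > 0L) {
      x[kick, ] <- matrix(stats::runif(ns * d, 0, rep(ranges, each = ns)),
                          ns, d)
      v[kick, ] <- matrix(stats::runif(ns * d, rep(-ranges / 2, each = ns),
                                       rep(ranges / 2, each = ns)), ns, d)
    }
  }
  state$velocity <- v
  state$position <- x
  state$iteration <- state$iteration + 1L
  state$rng_state <- get(".Random.seed", .GlobalEnv)
  state
}

#' Particle swarm optimisation over a discrete candidate space
#'
#' Runs [initialize_swarm] followed by iterated [step_swarm] until
#' `max_iterations` are exhausted or the global best has not improved for
#' `patience` consecutive iterations. Fitness is minimised (by convention,
#' the trained model's best validation loss).
#'
#' @param space An `hparam_space`.
#' @param fitness Function from decoded assignment to scalar.
#' @param n_particles Swarm size.
#' @param max_iterations Iteration budget, >= 1.
#' @param seed RNG seed; the whole run is reproducible from it.
#' @param patience Iterations without global-best improvement tolerated
#'   before stopping; defaults to `max_iterations` (run the whole budget —
#'   on small discrete spaces the budget is cheap and early stopping costs
#'   solution quality).
#' @param w,c1,c2 Update coefficients (constriction-equivalent defaults).
#' @param rescatter_duplicates Anti-stagnation re-scatter (see
#'   [step_swarm]); on by default here.
#' @return List with `best` (decoded assignment), `fitness` (scalar),
#'   `trace` (data.frame: iteration, gbest_fitness, one column per decoded
#'   dimension), and the final `state`.
#' @export
pso_optimize <- function(space, fitness, n_particles = 15L,
                         max_iterations = 30L, seed = 1L,
                         patience = max_iterations,
                         w = 0.729, c1 = 1.49445, c2 = 1.49445,
                         rescatter_duplicates = TRUE) {
  stopifnot(max_iterations >= 1L)
  state <- initialize_swarm(space, n_particles, seed)
  trace <- vector("list", max_iterations)
  best_so_far <- Inf
  stall <- 0L
  it <- 0L
  while (it < max_iterations) {
    state <- step_swarm(state, fitness, w = w, c1 = c1, c2 = c2,
                        rescatter_duplicates = rescatter_duplicates)
    it <- it + 1L
    decoded <- decode_position(state$gbest_position, space)
    trace[[it]] <- data.frame(iteration = it,
                              gbest_fitness = state$gbest_fitness,
                              as.data.frame(decoded,
                                            stringsAsFactors = FALSE))
    if (state$gbest_fitness < best_so_far) {
      best_so_far <- state$gbest_fitness
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (stall >= patience && patience > 0L) break
  }
  list(best = decode_position(state$gbest_position, space),
       fitness = state$gbest_fitness,
       trace = do.call(rbind, trace[seq_len(it)]),
       state = state)
}

#' Write a PSO trace to CSV
#' @param trace Trace data.frame from [pso_optimize].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pso_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
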