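#' Swarm optimizer configuration
#'
#' Bundles the hyperparameters shared by the baseline PSO and its pyramid
#' variant. Defaults follow the common thresholding setup: a swarm of
#' `N = 30` particles run for `T = 100` iterations with cognitive/social
#' factors `c1 = c2 = 1.5`; the baseline uses a fixed inertia weight
#' `omega = 0.8` while the adaptive pair spans `[omega_min, omega_max] =
#' [0.5, 0.9]`. `rate = 0.9` puts `round((1 - rate) * N)` particles into the
#' worst pyramid tier (`rate = 1` disables that tier). Velocities are
#' clamped to `v_max = v_max_fraction * (UB - LB)`.
#'
#' @param N population size (>= 4).
#' @param T_max number of iterations (>= 1).
#' @param D dimension of the search space (= number of thresholds).
#' @param c1,c2 cognitive and social acceleration factors.
#' @param omega fixed inertia weight (baseline PSO only).
#' @param omega_min,omega_max bounds of the adaptive inertia-weight pair
#'   (`omega_min <= omega_max`).
#' @param rate middle-tier fraction in (0, 1]; the worst tier holds
#'   `round((1 - rate) * N)` particles (at least 1 when `rate < 1`).
#' @param LB,UB search-space bounds (threshold space: `[1, L - 1]`).
#' @param v_max_fraction velocity clamp as a fraction of `UB - LB`.
#' @param seed integer seed for the run's random stream.
#' @param rol_per_dim draw the opposition factor `r` per dimension (`TRUE`,
#'   default) or one scalar per particle.
#' @return A list of class `swarm_config`.
#' @export
swarm_config <- function(N = 30L, T_max = 100L, D, c1 = 1.5, c2 = 1.5,
                         omega = 0.8, omega_min = 0.5, omega_max = 0.9,
                         rate = 0.9, LB, UB, v_max_fraction = 0.2,
                         seed = 1L, rol_per_dim = TRUE) {
  N <- as.integer(N); T_max <- as.integer(T_max); D <- as.integer(D)
  stopifnot(N >= 4L, T_max >= 1L, D >= 1L, LB < UB,
            omega_min > 0, omega_min <= omega_max,
            rate > 0, rate <= 1, v_max_fraction > 0)
  structure(list(N = N, T_max = T_max, D = D, c1 = c1, c2 = c2,
                 omega = omega, omega_min = omega_min, omega_max = omega_max,
                 rate = rate, LB = LB, UB = UB,
                 v_max = v_max_fraction * (UB - LB),
                 seed = as.integer(seed), rol_per_dim = isTRUE(rol_per_dim)),
            class = "swarm_config")
}

#' Initialize a particle swarm
#'
#' Positions are uniform on `[LB, UB]^D`, velocities uniform on
#' `[-v_max, v_max]`; personal bests start at the initial state with
#' fitness `-Inf` (not yet evaluated). The caller controls the random
#' stream via `set.seed` before calling.
#'
#' @param config a `swarm_config`.
#' @return A list with matrices `position`, `velocity`, `pbest_position`
#'   (N x D) and vectors `fitness`, `pbest_fitness`.
#' @export
init_swarm <- function(config) {
  N <- config$N; D <- config$D
  position <- matrix(stats::runif(N * D, config$LB, config$UB), N, D)
  velocity <- matrix(stats::runif(N * D, -config$v_max, config$v_max), N, D)
  list(position = position, velocity = velocity,
       fitness = rep(-Inf, N),
       pbest_position = position, pbest_fitness = rep(-Inf, N))
}

#' Decode a real-valued particle position into integer thresholds
#'
#' Components are rounded half-up, sorted ascending, and duplicate values
#' repaired by pushing the later duplicate up to the next unused integer;
#' if that overruns `L - 1` the tail is pulled down instead. The result is
#' always a valid strictly increasing threshold set in `[1, L - 1]`.
#'
#' @param position numeric vector within `[1, L - 1]` (clamped if not).
#' @param L number of gray levels.
#' @return A `threshold_set`.
#' @export
decode_position <- function(position, L) {
  D <- length(position)
  if (D > L - 1L)
    stop("infeasible dimension: more thresholds than available levels",
         call. = FALSE)
  v <- sort(.round_half_up(position))
  v <- pmin(pmax(v, 1), L - 1)
  # upward pass: enforce strict increase by incrementing later duplicates
  for (i in seq_len(D)[-1]) if (v[i] <= v[i - 1]) v[i] <- v[i - 1] + 1
  # downward pass: pull back below the ceiling while keeping strictness
  if (v[D] > L - 1) v[D] <- L - 1
  for (i in rev(seq_len(D - 1))) if (v[i] >= v[i + 1]) v[i] <- v[i + 1] - 1
  threshold_set(v, L)
}

# One particle's velocity/position update (Kennedy-Eberhart form with an
# extra weight on the attraction term; w_social = 1 recovers the baseline).
# r1, r2 are uniform[0,1] vectors drawn per dimension by the caller.
.update_particle <- function(x, v, pbest, gbest, w_inertia, w_social,
                             c1, c2, r1, r2, v_max, LB, UB) {
  v_new <- w_inertia * v +
    w_social * (c1 * r1 * (pbest - x) + c2 * r2 * (gbest - x))
  v_new <- pmin(pmax(v_new, -v_max), v_max)
  x_new <- pmin(pmax(x + v_new, LB), UB)
  list(x = x_new, v = v_new)
}

#' One baseline PSO step
#'
#' Applies the classic velocity update `v <- omega*v + c1*r1*(pbest - x) +
#' c2*r2*(gbest - x)` followed by `x <- x + v`, with `r1`, `r2` drawn
#' independently per particle and per dimension, velocity clamped to
#' `±v_max` and position clamped to `[LB, UB]`.
#'
#' @param swarm swarm state from [init_swarm()] with fitness evaluated.
#' @param gbest global-best position (length-D vector).
#' @param config a `swarm_config`.
#' @param skip integer indices of particles left untouched this step (their
#'   random draws are not consumed); used for elitism.
#' @return The updated swarm.
#' @export
pso_step <- function(swarm, gbest, config, skip = integer(0)) {
  D <- config$D
  for (i in seq_len(config$N)) {
    if (i %in% skip) next
    r1 <- stats::runif(D); r2 <- stats::runif(D)
    upd <- .update_particle(swarm$position[i, ], swarm$velocity[i, ],
                            swarm$pbest_position[i, ], gbest,
                            config$omega, 1, config$c1, config$c2,
                            r1, r2, config$v_max, config$LB, config$UB)
    swarm$position[i, ] <- upd$x
    swarm$velocity[i, ] <- upd$v
  }
  swarm
}

# Evaluate all particles and refresh pbest/gbest bookkeeping (maximization).
.evaluate_swarm <- function(swarm, objective, L) {
  for (i in seq_len(nrow(swarm$position))) {
    th <- decode_position(swarm$position[i, ], L)$values
    swarm$fitness[i] <- objective(th)
  }
  improved <- swarm$fitness > swarm$pbest_fitness
  swarm$pbest_fitness[improved] <- swarm$fitness[improved]
  swarm$pbest_position[improved, ] <- swarm$position[improved, , drop = FALSE]
  swarm
}

# Shared driver for both optimizers. `step_fun(swarm, gbest_pos, t)` returns
# the updated swarm; it may consult current fitness values.
.run_swarm <- function(hist, nTh, config, step_fun) {
  L <- hist$levels
  objective <- kapur_objective(hist)
  set.seed(config$seed)
  swarm <- init_swarm(config)
  gbest_fitness <- -Inf
  gbest_position <- swarm$position[1L, ]
  convergence <- numeric(config$T_max)
  for (t in seq_len(config$T_max)) {
    swarm <- .evaluate_swarm(swarm, objective, L)
    b <- which.max(swarm$pbest_fitness)
    if (swarm$pbest_fitness[b] > gbest_fitness) {
      gbest_fitness <- swarm$pbest_fitness[b]
      gbest_position <- swarm$pbest_position[b, ]
    }
    convergence[t] <- gbest_fitness
    swarm <- step_fun(swarm, gbest_position, t)
  }
  best_th <- decode_position(gbest_position, L)
  structure(list(best_position = gbest_position,
                 best_thresholds = best_th,
                 best_fitness = gbest_fitness,
                 convergence = convergence,
                 final_swarm = swarm),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result> best fitness %.6f at thresholds {%s}\n",
              x$best_fitness, paste(x$best_thresholds$values, collapse = ", ")))
  invisible(x)
}

#' Run the baseline particle swarm optimizer
#'
#' Maximizes Kapur entropy of `hist` over `nTh` integer thresholds: each
#' iteration evaluates all particles (`kapur_entropy` of the decoded
#' position), updates personal/global bests, then applies [pso_step()].
#'
#' @param hist a `gray_histogram`.
#' @param nTh number of thresholds (search dimension).
#' @param config a `swarm_config`; if `NULL`, defaults with
#'   `LB = 1, UB = L - 1` are used.
#' @param elitism if `TRUE`, the particle with the best current fitness is
#'   frozen each iteration (no update, no random draws), mirroring the
#'   pyramid variant's elite tier.
#' @return A `run_result` with the best thresholds, best fitness and the
#'   non-decreasing best-so-far convergence curve.
#' @export
run_pso <- function(hist, nTh, config = NULL, elitism = FALSE) {
  stopifnot(inherits(hist, "gray_histogram"))
  if (is.null(config))
    config <- swarm_config(D = nTh, LB = 1, UB = hist$levels - 1)
  stopifnot(config$D == nTh)
  step_fun <- function(swarm, gbest_pos, t) {
    skip <- if (elitism) which.max(swarm$fitness) else integer(0)
    pso_step(swarm, gbest_pos, config, skip = skip)
  }
  .run_swarm(hist, nTh, config, step_fun)
}
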