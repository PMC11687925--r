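#' Parameters of the complementary inertia-weight pair
#'
#' The pair is built on a scaled logit ("inverse sigmoid"): `s_x` pulls the
#' argument just inside the logit's singularities at `±0.5`, `s_y` rescales
#' the output, and `m_x` centres it. The defaults (0.96, 7.8, 0.5) make the
#' weight sweep almost exactly `[omega_min, omega_max]` as the normalized
#' fitness runs from worst to best.
#'
#' @param omega_min,omega_max inertia-weight range.
#' @param s_x x-axis scaling factor, in (0, 1).
#' @param s_y y-axis scaling factor, > 0.
#' @param m_x x-axis shift.
#' @return A list of class `weight_params`.
#' @export
weight_params <- function(omega_min = 0.5, omega_max = 0.9,
                          s_x = 0.96, s_y = 7.8, m_x = 0.5) {
  stopifnot(s_x > 0, s_x < 1, s_y > 0, omega_min <= omega_max)
  structure(list(omega_min = omega_min, omega_max = omega_max,
                 s_x = s_x, s_y = s_y, m_x = m_x),
            class = "weight_params")
}

#' Scaled inverse-sigmoid (logit) basis function
#'
#' `S(x) = ln((s_x*x + m_x) / (m_x - s_x*x)) / s_y` for `x` in
#' `[-0.5, 0.5]`: an odd, strictly increasing map whose slope is largest at
#' the ends of the range, so weight changes concentrate on particles with
#' extreme fitness ranks. Inputs outside `[-0.5, 0.5]` are clamped (with a
#' warning).
#'
#' @param x numeric vector in `[-0.5, 0.5]`.
#' @param params a `weight_params`.
#' @return `S(x)`, same length as `x`.
#' @export
inverse_sigmoid <- function(x, params = weight_params()) {
  if (any(abs(x) > 0.5)) {
    warning("inverse_sigmoid input clamped to [-0.5, 0.5]")
    x <- pmin(pmax(x, -0.5), 0.5)
  }
  log((params$s_x * x + params$m_x) / (params$m_x - params$s_x * x)) /
    params$s_y
}

#' Complementary inertia-weight pair for one fitness value
#'
#' Maps a particle's fitness to the normalized coordinate
#' `x = (f - (f_best + f_worst)/2) / (f_best - f_worst)` in `[-0.5, 0.5]`
#' and returns
#' `omega = (omega_min + omega_max)/2 + (omega_max - omega_min) * S(x)` and
#' its mirror `omega_reverse` with the sign flipped, so that
#' `omega + omega_reverse = omega_min + omega_max` identically. A fit
#' particle keeps a large inertia (stay put) and a small reverse weight
#' (small attraction step); a poor particle gets the opposite. When
#' `f_best == f_worst` the coordinate degenerates to `x = 0` and both
#' weights equal the midpoint.
#'
#' @param f particle fitness, `f_worst <= f <= f_best`.
#' @param f_best,f_worst current swarm extremes.
#' @param params a `weight_params`.
#' @return `c(omega, omega_reverse)`.
#' @export
complementary_weights <- function(f, f_best, f_worst,
                                  params = weight_params()) {
  x <- if (f_best == f_worst) 0 else
    (f - (f_best + f_worst) / 2) / (f_best - f_worst)
  # round-off can push x past +/-0.5 when f sits at an extreme; the
  # precondition f_worst <= f <= f_best holds, so clamp silently
  x <- min(max(x, -0.5), 0.5)
  s <- inverse_sigmoid(x, params)
  mid <- (params$omega_min + params$omega_max) / 2
  amp <- (params$omega_max - params$omega_min)
  c(omega = mid + amp * s, omega_reverse = mid - amp * s)
}

#' Partition a swarm into the three pyramid tiers
#'
#' Particles are ranked by fitness, descending, ties broken by lower index.
#' The single best particle forms the elite tier; the worst
#' `round((1 - rate) * N)` (at least 1 when `rate < 1`, empty when
#' `rate = 1`) form the worst tier; everyone else is the middle tier.
#'
#' @param fitness numeric vector of current fitness values.
#' @param rate middle-tier fraction in (0, 1].
#' @return A list with `elite` (one index), `middle` and `worst`
#'   (index vectors, disjoint, covering `1..N`).
#' @export
partition_layers <- function(fitness, rate = 0.9) {
  N <- length(fitness)
  if (N < 3L) stop("need at least 3 particles to form three tiers",
                   call. = FALSE)
  stopifnot(rate > 0, rate <= 1)
  ord <- order(fitness, seq_len(N), decreasing = c(TRUE, FALSE),
               method = "radix")
  n_worst <- if (rate == 1) 0L else max(1L, as.integer(round((1 - rate) * N)))
  if (n_worst > N - 2L) n_worst <- N - 2L
  elite <- ord[1L]
  worst <- if (n_worst > 0L) ord[(N - n_worst + 1L):N] else integer(0)
  middle <- if (N - 1L - n_worst > 0L) ord[2L:(N - n_worst)] else integer(0)
  list(elite = elite, middle = middle, worst = worst)
}

#' Random-opposition move for one position vector
#'
#' Teleports a poorly performing particle toward the mirrored region of the
#' search space: per dimension, `P' = LB + UB - r * P` with
#' `r ~ Uniform[0, 1]` drawn independently per dimension (default) or once
#' per particle, then clamped to `[LB, UB]`.
#'
#' @param position numeric vector in `[LB, UB]`.
#' @param LB,UB search bounds.
#' @param per_dim draw `r` per dimension (`TRUE`) or one scalar.
#' @param r optional fixed opposition factor(s) instead of random draws.
#' @return The opposed position vector.
#' @export
rol_update <- function(position, LB, UB, per_dim = TRUE, r = NULL) {
  if (is.null(r))
    r <- if (per_dim) stats::runif(length(position)) else stats::runif(1)
  pmin(pmax(LB + UB - r * position, LB), UB)
}

#' One CIWP-PSO step over a partitioned swarm
#'
#' The elite particle is frozen for the iteration. Middle-tier particles
#' use the complementary-weight velocity update
#' `v <- omega(f)*v + omega_reverse(f)*(c1*r1*(pbest - x) + c2*r2*(gbest - x))`
#' with per-particle weights from the current swarm's fitness extremes.
#' Worst-tier particles are relocated by [rol_update()] (velocity and
#' personal-best history kept). Particles are visited in index order so a
#' run is reproducible from its seed.
#'
#' @param swarm evaluated swarm state.
#' @param partition output of [partition_layers()] for the current fitness.
#' @param gbest global-best position.
#' @param config a `swarm_config`.
#' @param params a `weight_params` (defaults derived from `config`).
#' @return The updated swarm.
#' @export
ciwp_step <- function(swarm, partition, gbest, config,
                      params = NULL) {
  if (is.null(params))
    params <- weight_params(config$omega_min, config$omega_max)
  f_best <- max(swarm$fitness)
  f_worst <- min(swarm$fitness)
  D <- config$D
  in_worst <- seq_len(config$N) %in% partition$worst
  for (i in seq_len(config$N)) {
    if (i == partition$elite) next
    if (in_worst[i]) {
      swarm$position[i, ] <- rol_update(swarm$position[i, ],
                                        config$LB, config$UB,
                                        per_dim = config$rol_per_dim)
      next
    }
    w <- complementary_weights(swarm$fitness[i], f_best, f_worst, params)
    r1 <- stats::runif(D); r2 <- stats::runif(D)
    upd <- .update_particle(swarm$position[i, ], swarm$velocity[i, ],
                            swarm$pbest_position[i, ], gbest,
                            w[["omega"]], w[["omega_reverse"]],
                            config$c1, config$c2,
                            r1, r2, config$v_max, config$LB, config$UB)
    swarm$position[i, ] <- upd$x
    swarm$velocity[i, ] <- upd$v
  }
  swarm
}

#' Run the pyramid PSO with complementary inertia weights (CIWP-PSO)
#'
#' Each iteration: evaluate every particle (Kapur entropy of the decoded
#' thresholds, so particles moved by random opposition are re-scored too),
#' refresh personal/global bests, partition the swarm into elite / middle /
#' worst tiers by current fitness, then apply [ciwp_step()].
#'
#' @inheritParams run_pso
#' @param params optional `weight_params`; defaults to the config's
#'   `omega_min`/`omega_max` with the standard logit scaling.
#' @return A `run_result`.
#' @export
run_ciwp_pso <- function(hist, nTh, config = NULL, params = NULL) {
  stopifnot(inherits(hist, "gray_histogram"))
  if (is.null(config))
    config <- swarm_config(D = nTh, LB = 1, UB = hist$levels - 1)
  stopifnot(config$D == nTh)
  if (is.null(params))
    params <- weight_params(config$omega_min, config$omega_max)
  step_fun <- function(swarm, gbest_pos, t) {
    part <- partition_layers(swarm$fitness, config$rate)
    ciwp_step(swarm, part, gbest_pos, config, params)
  }
  .run_swarm(hist, nTh, config, step_fun)
}

#' Run an optimizer selected by name
#'
#' @param algorithm `"pso"` or `"ciwp-pso"`.
#' @inheritParams run_pso
#' @return A `run_result`.
#' @export
run_optimizer <- function(algorithm, hist, nTh, config = NULL) {
  switch(algorithm,
         "pso" = run_pso(hist, nTh, config),
         "ciwp-pso" = run_ciwp_pso(hist, nTh, config),
         stop("unknown algorithm: ", algorithm, call. = FALSE))
}
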