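test_that("pyramid partition sizes and membership follow the rate", {
  p <- partition_layers(c(5, 3, 1, 9), rate = 0.75)
  expect_equal(p$elite, 4L)
  expect_equal(p$worst, 3L)
  expect_setequal(p$middle, c(1L, 2L))

  set.seed(1)
  p30 <- partition_layers(stats::runif(30), rate = 0.9)
  expect_equal(length(p30$worst), 3L)    # round(0.1 * 30)
  expect_equal(length(p30$middle), 26L)
  expect_equal(length(p30$elite), 1L)
  expect_setequal(c(p30$elite, p30$middle, p30$worst), 1:30)
})

test_that("partition ties break toward the lower particle index", {
  p <- partition_layers(rep(1, 10), rate = 0.8)
  expect_equal(p$elite, 1L)
  expect_equal(sort(p$worst), c(9L, 10L))
})

test_that("worst tier never undercuts fitness ordering", {
  set.seed(7)
  for (k in 1:50) {
    f <- stats::rnorm(sample(5:40, 1))
    p <- partition_layers(f, rate = 0.85)
    expect_true(max(f[p$worst]) <= min(f[p$middle]))
    expect_true(max(f[p$middle]) <= f[p$elite])
  }
})

test_that("inverse sigmoid is an odd, bounded, increasing logit", {
  expect_equal(inverse_sigmoid(0), 0)
  expect_equal(inverse_sigmoid(0.5), log(49) / 7.8, tolerance = 1e-12)
  expect_equal(inverse_sigmoid(0.5), 0.498950, tolerance = 1e-5)
  set.seed(3)
  x <- stats::runif(100, -0.5, 0.5)
  expect_equal(inverse_sigmoid(-x), -inverse_sigmoid(x), tolerance = 1e-12)
  expect_true(all(diff(inverse_sigmoid(sort(x))) > 0))
  expect_warning(inverse_sigmoid(0.7), "clamped")
})

test_that("complementary weights sum to the range ends and hit endpoints", {
  w_mid <- complementary_weights(5, 8, 2)  # f at the midpoint
  expect_equal(unname(w_mid), c(0.7, 0.7))

  w_best <- complementary_weights(8, 8, 2)
  expect_equal(w_best[["omega"]], 0.7 + 0.4 * log(49) / 7.8,
               tolerance = 1e-12)
  expect_equal(w_best[["omega"]], 0.899580, tolerance = 1e-5)
  expect_equal(w_best[["omega_reverse"]], 0.500420, tolerance = 1e-5)

  set.seed(11)
  for (k in 1:1000) {
    fw <- stats::rnorm(1); fb <- fw + stats::rexp(1)
    f <- stats::runif(1, fw, fb)
    w <- complementary_weights(f, fb, fw)
    expect_identical(sum(w), 1.4)  # complementary by construction
  }
  # degenerate swarm: everyone equal, both weights at the midpoint
  expect_equal(unname(complementary_weights(3, 3, 3)), c(0.7, 0.7))
})

test_that("omega is increasing in fitness, omega_reverse decreasing", {
  f <- seq(0, 1, length.out = 101)
  w <- t(vapply(f, complementary_weights, numeric(2), f_best = 1,
                f_worst = 0))
  expect_true(all(diff(w[, 1]) > 0))
  expect_true(all(diff(w[, 2]) < 0))
  gap <- (0.5 - log(49) / 7.8) * 0.4  # endpoint gap from s_x < 1
  expect_true(all(w[, 1] >= 0.5 - gap - 1e-12 & w[, 1] <= 0.9 + gap + 1e-12))
})

test_that("random opposition mirrors positions into [LB+UB-P, LB+UB]", {
  expect_equal(rol_update(10, 0, 10, r = 1), 0)
  expect_equal(rol_update(5, 0, 10, r = 1), 5)       # midpoint fixed
  expect_equal(rol_update(100, 0, 4095, r = 0.01), 4094)
  set.seed(21)
  for (k in 1:200) {
    p <- stats::runif(4, 1, 255)
    out <- rol_update(p, 1, 255)
    expect_true(all(out >= 1 & out <= 255))
    expect_true(all(out >= 256 - p - 1e-9))  # pre-clamp support lower edge
  }
})

test_that("the elite particle is frozen during a CIWP step", {
  cfg <- swarm_config(N = 10, T_max = 1, D = 3, LB = 1, UB = 255, seed = 4)
  set.seed(cfg$seed)
  swarm <- init_swarm(cfg)
  swarm$fitness <- stats::runif(10)
  part <- partition_layers(swarm$fitness, cfg$rate)
  before <- swarm$position[part$elite, ]
  out <- ciwp_step(swarm, part, rep(128, 3), cfg)
  expect_identical(out$position[part$elite, ], before)
  # everyone stays in bounds
  expect_true(all(out$position >= 1 & out$position <= 255))
})

test_that("middle update degenerates to weighted inertia when c1 = c2 = 0", {
  cfg <- swarm_config(N = 6, T_max = 1, D = 2, c1 = 0, c2 = 0,
                      LB = 0, UB = 100, rate = 1, seed = 9)
  set.seed(cfg$seed)
  swarm <- init_swarm(cfg)
  swarm$fitness <- c(1, 2, 3, 4, 5, 6)
  part <- partition_layers(swarm$fitness, 1)
  out <- ciwp_step(swarm, part, rep(50, 2), cfg)
  for (i in part$middle) {
    w <- complementary_weights(swarm$fitness[i], 6, 1)
    v_exp <- pmin(pmax(w[["omega"]] * swarm$velocity[i, ], -cfg$v_max),
                  cfg$v_max)
    expect_equal(out$position[i, ],
                 pmin(pmax(swarm$position[i, ] + v_exp, 0), 100))
  }
})

test_that("layer sizes conserve N and convergence is monotone in a full run", {
  img <- generate_synthetic_image(bimodal_spec(seed = 14))
  h <- rebin_histogram(compute_histogram(img), 256)
  cfg <- swarm_config(N = 20, T_max = 40, D = 3, LB = 1, UB = 255, seed = 2)
  res <- run_ciwp_pso(h, 3, cfg)
  expect_true(all(diff(res$convergence) >= 0))
  expect_gte(res$best_fitness, res$convergence[1])
  part <- partition_layers(res$final_swarm$fitness, cfg$rate)
  expect_equal(length(part$elite) + length(part$middle) + length(part$worst),
               cfg$N)
})

test_that("CIWP-PSO reaches the certified optimum on a bimodal histogram", {
  img <- generate_synthetic_image(bimodal_spec(seed = 3))
  h <- rebin_histogram(compute_histogram(img), 256)
  oracle <- exhaustive_optimal_thresholds(h, 2)
  res <- run_ciwp_pso(h, 2, swarm_config(D = 2, LB = 1, UB = 255, seed = 10))
  expect_lte(res$best_fitness, oracle$entropy + 1e-12)
  expect_equal(res$best_fitness, oracle$entropy, tolerance = 1e-6)
})

test_that("disabling ROL and fixing the weights reduces CIWP-PSO to PSO", {
  img <- generate_synthetic_image(bimodal_spec(seed = 8))
  h <- rebin_histogram(compute_histogram(img), 256)
  # omega_min = omega_max = 1 makes both complementary weights exactly 1;
  # rate = 1 empties the worst tier; elitism aligns the skipped particle
  cfg <- swarm_config(N = 12, T_max = 50, D = 2, omega = 1,
                      omega_min = 1, omega_max = 1, rate = 1,
                      LB = 1, UB = 255, seed = 123)
  res_ciwp <- run_ciwp_pso(h, 2, cfg)
  res_pso <- run_pso(h, 2, cfg, elitism = TRUE)
  expect_identical(res_ciwp$final_swarm$position, res_pso$final_swarm$position)
  expect_identical(res_ciwp$final_swarm$velocity, res_pso$final_swarm$velocity)
  expect_identical(res_ciwp$convergence, res_pso$convergence)
})
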