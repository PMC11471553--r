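test_that("inertia schedule is exactly linear between its endpoints", {
  cfg <- pso_config()
  expect_identical(inertia_weight(0, cfg), 0.9)
  expect_identical(inertia_weight(cfg$k_max, cfg), 0.2)
  expect_equal(inertia_weight(cfg$k_max / 2, cfg), (0.9 + 0.2) / 2)
  ks <- 0:cfg$k_max
  expect_equal(diff(inertia_weight(ks, cfg), differences = 2),
               rep(0, cfg$k_max - 1), tolerance = 1e-14)
  expect_true(all(diff(inertia_weight(ks, cfg)) < 0))
  expect_error(inertia_weight(-1, cfg), "\\[0, k_max\\]")
  expect_error(inertia_weight(cfg$k_max + 1, cfg), "\\[0, k_max\\]")
})

test_that("velocity update implements the canonical swarm rule", {
  cfg <- pso_config(v_max = 10)
  # hand arithmetic: 0.5*1 + 2*0.5*(1-0) + 2*0.5*(2-0) = 3.5
  expect_equal(velocity_update(1, 0, 1, 2, omega = 0.5, r1 = 0.5, r2 = 0.5, cfg), 3.5)
  # vanishing attraction terms leave pure inertia
  v <- c(0.2, -0.4)
  expect_equal(velocity_update(v, c(0, 0), c(1, 1), c(1, 1), 0.7, 0, 0, cfg), 0.7 * v)
  x <- c(0.3, -0.1)
  expect_equal(velocity_update(v, x, x, x, 0.7, 0.9, 0.4, cfg), 0.7 * v)
  # componentwise clamp
  clamped <- velocity_update(1, 0, 1, 2, 0.5, 0.5, 0.5, pso_config(v_max = 1))
  expect_equal(clamped, 1)
  expect_error(velocity_update(v, c(0, 0, 0), c(1, 1), c(1, 1), 0.5, 0, 0, cfg),
               "dimension")
  expect_error(velocity_update(v, c(0, 0), c(1, 1), c(1, 1), 0.5, 1.2, 0, cfg),
               "\\[0, 1\\]")
})

test_that("position update adds velocity and clips at the box", {
  cfg <- pso_config()
  expect_equal(position_update(c(0.1, -0.2), c(0.2, 0), cfg), c(0.3, -0.2))
  expect_equal(position_update(0.9, 0.3, cfg), 1.0)
  free <- pso_config(clip_position = FALSE)
  expect_equal(position_update(0.9, 0.3, free), 1.2)
})

test_that("velocities decay geometrically without attraction", {
  cfg <- pso_config(c1 = 0, c2 = 0, v_max = 10)
  v <- c(0.4, -0.3, 0.1)
  omega <- 0.8
  for (step in 1:5) {
    v_new <- velocity_update(v, rnorm(3), rnorm(3), rnorm(3), omega, runif(1), runif(1), cfg)
    expect_equal(v_new, omega * v, tolerance = 1e-14)
    v <- v_new
  }
})

test_that("optimization converges on classic test functions", {
  sphere <- pso_optimize(function(x) sum(x^2), dim = 5, pso_config(seed = 42))
  expect_lt(sphere$best_fitness, 1e-2)
  quad <- pso_optimize(function(x) (x - 0.3)^2, dim = 1, pso_config(seed = 42))
  expect_lt(abs(quad$best_position - 0.3), 1e-3) # closed-form optimum 0.3
})

test_that("global best history is elitist and reproducible", {
  res <- pso_optimize(function(x) sum((x - 0.2)^2), dim = 4,
                      pso_config(k_max = 40, seed = 11))
  expect_equal(nrow(res$history), 41)
  expect_true(all(diff(res$history$best_fitness) <= 0))
  res2 <- pso_optimize(function(x) sum((x - 0.2)^2), dim = 4,
                       pso_config(k_max = 40, seed = 11))
  expect_identical(res$history, res2$history)
  expect_identical(res$best_position, res2$best_position)

  const <- pso_optimize(function(x) 5, dim = 3, pso_config(k_max = 5, seed = 1))
  expect_equal(const$best_fitness, 5)
  expect_equal(const$history$best_fitness[1], 5) # settled at iteration 0
})

test_that("non-finite objectives are quarantined with a warning", {
  bad <- function(x) if (x[1] > 0) NaN else sum(x^2)
  expect_warning(res <- pso_optimize(bad, dim = 2, pso_config(k_max = 5, seed = 2)),
                 "non-finite")
  expect_true(is.finite(res$best_fitness))
})

test_that("configuration invariants are enforced", {
  expect_error(pso_config(w_max = 0.1, w_min = 0.5), "w_max")
  expect_error(pso_config(k_max = 0), "k_max")
  expect_error(pso_config(n_particles = 1), "n_particles")
  expect_error(pso_config(c1 = -1), "non-negative")
  expect_error(pso_config(bounds = c(1, -1)), "bounds")
  expect_equal(pso_config()$v_max, 1) # half the default bound width
})
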