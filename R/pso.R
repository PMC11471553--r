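#' Particle swarm optimizer configuration
#'
#' Defaults follow the tuned swarm settings of the hybrid classifier:
#' cognitive and social coefficients `c1 = c2 = 2`, inertia weight
#' decaying linearly from 0.9 to 0.2, and 40 particles. The iteration
#' budget `k_max` defaults to 100. Velocity clamping and position
#' clipping are stabilizers for the `c1 = c2 = 2` regime and can be
#' switched off.
#'
#' @param c1,c2 Cognitive and social acceleration coefficients (>= 0).
#' @param w_max,w_min Inertia weight range (w_max >= w_min).
#' @param k_max Number of iterations (>= 1).
#' @param n_particles Swarm size (>= 2).
#' @param bounds Length-2 position bounds applied per dimension.
#' @param v_max Velocity clamp; default half the bound width. `Inf`
#'   disables clamping.
#' @param clip_position Clip positions to `bounds` after each move?
#'   Default TRUE.
#' @param r_mode `"particle"` draws the stochastic factors r1, r2 as
#'   per-particle scalars (default); `"dimension"` draws them per
#'   dimension.
#' @param seed Optional integer seed.
#' @return An object of class `"pso_config"`.
#' @export
pso_config <- function(c1 = 2, c2 = 2, w_max = 0.9, w_min = 0.2,
                       k_max = 100, n_particles = 40, bounds = c(-1, 1),
                       v_max = NULL, clip_position = TRUE,
                       r_mode = c("particle", "dimension"), seed = NULL) {
  r_mode <- match.arg(r_mode)
  if (w_max < w_min) abort("`w_max` must be >= `w_min`.")
  if (k_max < 1) abort("`k_max` must be >= 1.")
  if (n_particles < 2) abort("`n_particles` must be >= 2.")
  if (c1 < 0 || c2 < 0) abort("`c1` and `c2` must be non-negative.")
  if (length(bounds) != 2 || bounds[1] >= bounds[2]) {
    abort("`bounds` must be c(lower, upper) with lower < upper.")
  }
  if (is.null(v_max)) v_max <- 0.5 * diff(bounds)
  structure(list(c1 = c1, c2 = c2, w_max = w_max, w_min = w_min,
                 k_max = as.integer(k_max),
                 n_particles = as.integer(n_particles), bounds = bounds,
                 v_max = v_max, clip_position = clip_position,
                 r_mode = r_mode, seed = seed),
            class = "pso_config")
}

#' Linearly decaying inertia weight
#'
#' `omega(k) = w_max - ((w_max - w_min) / k_max) * k`, the linear
#' schedule shifting the swarm from exploration (large omega, early) to
#' exploitation (small omega, late). The iteration index is 0-based:
#' `omega(0) = w_max` exactly and `omega(k_max) = w_min` exactly.
#'
#' @param k Iteration index (0 <= k <= k_max), vectorized.
#' @param config A [pso_config()].
#' @return The inertia weight(s).
#' @examples
#' inertia_weight(0, pso_config())   # 0.9
#' inertia_weight(100, pso_config()) # 0.2
#' @export
inertia_weight <- function(k, config = pso_config()) {
  if (any(k < 0 | k > config$k_max)) {
    abort("`k` must lie in [0, k_max].")
  }
  # convex-combination form of the linear schedule: algebraically equal to
  # w_max - ((w_max - w_min)/k_max) * k, but exact at both endpoints
  t <- k / config$k_max
  config$w_max * (1 - t) + config$w_min * t
}

#' Velocity and position updates
#'
#' `velocity_update()` implements the canonical swarm rule
#' `v' = omega * v + c1 * r1 * (p_best - x) + c2 * r2 * (g_best - x)`,
#' clamped componentwise to `[-v_max, v_max]`. `position_update()` adds
#' the new velocity to the position and clips to the box bounds.
#'
#' @param v,x,p_best,g_best Numeric vectors of equal length.
#' @param omega Inertia weight for this iteration.
#' @param r1,r2 Stochastic factors in [0, 1]; scalars or per-dimension
#'   vectors.
#' @param config A [pso_config()].
#' @return The updated velocity / position vector.
#' @export
velocity_update <- function(v, x, p_best, g_best, omega, r1, r2,
                            config = pso_config()) {
  n <- length(x)
  if (length(v) != n || length(p_best) != n || length(g_best) != n) {
    abort("Velocity/position/best vectors must share one dimension.")
  }
  if (any(r1 < 0 | r1 > 1) || any(r2 < 0 | r2 > 1)) {
    abort("`r1` and `r2` must lie in [0, 1].")
  }
  v_new <- omega * v + config$c1 * r1 * (p_best - x) + config$c2 * r2 * (g_best - x)
  pmin(pmax(v_new, -config$v_max), config$v_max)
}

#' @rdname velocity_update
#' @export
position_update <- function(x, v, config = pso_config()) {
  if (length(x) != length(v)) abort("`x` and `v` must share one dimension.")
  x_new <- x + v
  if (isTRUE(config$clip_position)) {
    x_new <- pmin(pmax(x_new, config$bounds[1]), config$bounds[2])
  }
  x_new
}

#' Particle swarm optimization
#'
#' Minimizes an arbitrary objective over a `dim`-dimensional box.
#' Particles start uniformly inside the bounds with velocities uniform
#' in +/- v_max / 2; each of the `k_max` iterations applies the inertia
#' schedule (0-based, so the first update uses exactly `w_max`), the
#' velocity and position updates, and the personal/global best
#' bookkeeping. The global best is elitist, so the fitness history is
#' non-increasing. A non-finite objective value is treated as `+Inf`
#' with a warning.
#'
#' @param objective Function mapping a numeric vector to a scalar
#'   fitness (lower is better).
#' @param dim Problem dimensionality.
#' @param config A [pso_config()].
#' @return An object of class `"pso_result"`: list with `best_position`,
#'   `best_fitness`, `history` (tibble `iteration`, `best_fitness`,
#'   `mean_fitness`; `k_max + 1` rows including the initial swarm), and
#'   the `config`.
#' @examples
#' res <- pso_optimize(function(x) sum(x^2), dim = 3,
#'                     pso_config(k_max = 50, seed = 1))
#' res$best_fitness
#' @export
pso_optimize <- function(objective, dim, config = pso_config()) {
  stopifnot(inherits(config, "pso_config"))
  n <- config$n_particles
  warned_nonfinite <- FALSE
  eval_fitness <- function(X) {
    f <- apply(X, 1, objective)
    if (any(!is.finite(f))) {
      if (!warned_nonfinite) {
        warn("Objective returned non-finite value(s); treated as +Inf.")
        warned_nonfinite <<- TRUE
      }
      f[!is.finite(f)] <- Inf
    }
    f
  }
  with_seed_if(config$seed, {
    X <- matrix(runif(n * dim, config$bounds[1], config$bounds[2]), n, dim)
    V <- matrix(runif(n * dim, -config$v_max / 2, config$v_max / 2), n, dim)
    fit <- eval_fitness(X)
    P <- X
    p_fit <- fit
    g_idx <- which.min(p_fit)
    g_best <- P[g_idx, ]
    g_fit <- p_fit[g_idx]
    history <- tibble::tibble(iteration = 0L, best_fitness = g_fit,
                              mean_fitness = mean(fit[is.finite(fit)]))
    for (k in seq_len(config$k_max)) {
      omega <- inertia_weight(k - 1L, config)  # 0-based schedule
      if (config$r_mode == "particle") {
        r1 <- matrix(runif(n), n, dim)
        r2 <- matrix(runif(n), n, dim)
      } else {
        r1 <- matrix(runif(n * dim), n, dim)
        r2 <- matrix(runif(n * dim), n, dim)
      }
      V <- omega * V + config$c1 * r1 * (P - X) +
        config$c2 * r2 * (matrix(g_best, n, dim, byrow = TRUE) - X)
      V <- pmin(pmax(V, -config$v_max), config$v_max)
      X <- X + V
      if (isTRUE(config$clip_position)) {
        X <- pmin(pmax(X, config$bounds[1]), config$bounds[2])
      }
      fit <- eval_fitness(X)
      improved <- fit < p_fit
      P[improved, ] <- X[improved, , drop = FALSE]
      p_fit[improved] <- fit[improved]
      if (min(p_fit) < g_fit) {
        g_idx <- which.min(p_fit)
        g_best <- P[g_idx, ]
        g_fit <- p_fit[g_idx]
      }
      history <- dplyr::bind_rows(history, tibble::tibble(
        iteration = k, best_fitness = g_fit,
        mean_fitness = mean(fit[is.finite(fit)])))
    }
    structure(list(best_position = g_best, best_fitness = g_fit,
                   history = history, config = config),
              class = "pso_result")
  })
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf("<pso_result> dim=%d particles=%d iterations=%d best fitness=%.6g\n",
              length(x$best_position), x$config$n_particles,
              x$config$k_max, x$best_fitness))
  invisible(x)
}
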