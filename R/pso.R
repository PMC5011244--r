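#' Particle swarm optimizer configuration
#'
#' @param swarm_size number of particles `m` (default 10).
#' @param omega_max,omega_min inertia weight at the first / last iteration
#'   (defaults 0.9 and 0.4); the weight decreases linearly with iteration.
#' @param c1,c2 cognitive and social learning factors (default 2).
#' @param iter_max number of iterations (default 50).
#' @param seed integer seed.
#' @return Object of class `"pso_config"`.
#' @export
pso_config <- function(swarm_size = 10L, omega_max = 0.9, omega_min = 0.4,
                       c1 = 2, c2 = 2, iter_max = 50L, seed = 1L) {
  stopifnot(swarm_size >= 2, omega_max >= omega_min, iter_max >= 1)
  structure(list(swarm_size = as.integer(swarm_size),
                 omega_max = omega_max, omega_min = omega_min,
                 c1 = c1, c2 = c2, iter_max = as.integer(iter_max),
                 seed = as.integer(seed)),
            class = "pso_config")
}

#' Minimize a function by particle swarm optimization
#'
#' Inertia-weighted velocity/position updates
#' \deqn{v \leftarrow \omega v + c_1 r_1 (p_{best} - x) +
#'       c_2 r_2 (g_{best} - x), \quad x \leftarrow x + v,}
#' with the inertia weight decreasing linearly from `omega_max` to
#' `omega_min` over the run. Velocities are clamped to 20% of each bound's
#' range; positions leaving the box are clamped to it with the velocity
#' zeroed in that dimension. A particle whose fitness evaluates non-finite
#' is re-initialized uniformly inside the bounds.
#'
#' @param fitness function of a position vector returning a scalar to
#'   minimize.
#' @param lower,upper numeric bounds per dimension (finite).
#' @param cfg a [pso_config()].
#' @return A list of class `"pso_result"`: `par` (best position), `value`
#'   (best fitness), `trace` (global best fitness per iteration,
#'   non-increasing), `n_restarts`.
#' @export
#' @examples
#' pso_optimize(function(p) sum(p^2), c(-5, -5), c(5, 5),
#'              pso_config(iter_max = 25, seed = 7))$value
pso_optimize <- function(fitness, lower, upper, cfg = pso_config()) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(upper > lower))
  D <- length(lower)
  m <- cfg$swarm_size
  rng <- upper - lower
  vmax <- 0.2 * rng

  with_seed(cfg$seed, {
    X <- t(replicate(m, lower + runif(D) * rng))
    V <- t(replicate(m, (runif(D) - 0.5) * vmax))
    if (D == 1L) { X <- matrix(X, ncol = 1L); V <- matrix(V, ncol = 1L) }
    n_restarts <- 0L
    eval_safe <- function(p) {
      f <- fitness(p)
      if (!is.numeric(f) || length(f) != 1L) return(NA_real_)
      f
    }
    fit <- apply(X, 1L, eval_safe)
    for (i in which(!is.finite(fit))) {
      X[i, ] <- lower + runif(D) * rng
      fit[i] <- eval_safe(X[i, ])
      n_restarts <- n_restarts + 1L
    }
    fit[!is.finite(fit)] <- Inf
    P <- X; pfit <- fit
    g <- which.min(pfit)
    gbest <- P[g, ]; gfit <- pfit[g]
    trace <- numeric(cfg$iter_max)

    for (iter in seq_len(cfg$iter_max)) {
      omega <- cfg$omega_min +
        (cfg$iter_max - iter) * (cfg$omega_max - cfg$omega_min) / cfg$iter_max
      for (i in seq_len(m)) {
        r1 <- runif(D); r2 <- runif(D)
        V[i, ] <- omega * V[i, ] + cfg$c1 * r1 * (P[i, ] - X[i, ]) +
          cfg$c2 * r2 * (gbest - X[i, ])
        V[i, ] <- pmin(pmax(V[i, ], -vmax), vmax)
        X[i, ] <- X[i, ] + V[i, ]
        out <- X[i, ] < lower | X[i, ] > upper
        if (any(out)) {
          X[i, out] <- pmin(pmax(X[i, out], lower[out]), upper[out])
          V[i, out] <- 0
        }
        f <- eval_safe(X[i, ])
        if (!is.finite(f)) {
          X[i, ] <- lower + runif(D) * rng
          V[i, ] <- 0
          f <- eval_safe(X[i, ])
          if (!is.finite(f)) f <- Inf
          n_restarts <- n_restarts + 1L
        }
        if (f < pfit[i]) { pfit[i] <- f; P[i, ] <- X[i, ] }
        if (f < gfit) { gfit <- f; gbest <- X[i, ] }
      }
      trace[iter] <- gfit
    }
    structure(list(par = gbest, value = gfit, trace = trace,
                   n_restarts = n_restarts),
              class = "pso_result")
  })
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf("PSO: best fitness %.6g at (%s) after %d iterations\n",
              x$value, paste(signif(x$par, 5), collapse = ", "),
              length(x$trace)))
  invisible(x)
}
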