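# Shared synthetic worlds, built once per test run and cached.
.world_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.world_cache[[name]])) .world_cache[[name]] <- builder()
  .world_cache[[name]]
}

# small two-substrate world with one planted inhibition (S1 inhibits S2),
# noiseless, densely sampled: fast enough for per-operation fit tests
tiny_world <- function() cached("tiny", function() {
  A <- matrix(0, 2, 2)
  A[2, 1] <- 50
  up <- uptake_params(mu = c(0.6, 0.4), K = c(0.3, 0.2), A = A)
  gr <- growth_params(y_E = c(30, 20), r_E = 0.5, y_V = 0.012, m = 0.02)
  spec <- synthetic_spec(up, gr, S0 = c(5, 6), V0 = 5e-3, n_replicates = 4,
                         times = seq(0, 50.4, length.out = 48),
                         noise_level = 0, seed = 7)
  generate_experiment(spec)
})

# the canonical noiseless four-substrate recovery world
recovery_world <- function() cached("recovery", function() {
  generate_experiment(recovery_demo_spec())
})

# grid-search oracle for the depletion-curve dissimilarity: the objective at
# fixed beta is a ratio of quadratics, evaluated on a dense log-spaced grid
dissimilarity_grid_oracle <- function(x, y, n_grid = 1e6) {
  beta <- exp(seq(log(1e-4), log(1e4), length.out = n_grid))
  A <- sum(x^2); B <- sum(x * y); C <- sum(y^2)
  Qx <- sum((x - mean(x))^2); Qy <- sum((y - mean(y))^2)
  d <- 2 * (A - 2 * beta * B + beta^2 * C) / (beta^2 * Qy + Qx)
  min(d)
}

# brute-force digraph cycle test: any positive path returning to its start
has_cycle_bruteforce <- function(A) {
  adj <- (t(A) > 0)  # edge j -> i for A[i, j] > 0
  diag(adj) <- diag(A) > 0
  n <- nrow(adj)
  reach <- adj
  p <- adj
  for (k in seq_len(n - 1)) {
    p <- (p %*% adj) > 0
    reach <- reach | p
  }
  any(diag(reach))
}

# independent scalar Monod-DEB integrator: classic RK4 at a fixed fine step,
# coded without reference to the package's solver
monod_deb_rk4 <- function(mu, K, y_E, r_E, y_V, m, S0, E0, V0, t_end,
                          n_steps = 20000) {
  h <- t_end / n_steps
  deriv <- function(s) {
    S <- max(s[1], 0)
    f <- if (S > 0) mu * S / (K + S) else 0
    c(-f * s[3], y_E * f * s[3] - r_E * s[2],
      y_V * (r_E * s[2] - m * s[3]))
  }
  s <- c(S0, E0, V0)
  out <- matrix(NA_real_, n_steps + 1, 3)
  out[1, ] <- s
  for (i in seq_len(n_steps)) {
    k1 <- deriv(s)
    k2 <- deriv(s + h / 2 * k1)
    k3 <- deriv(s + h / 2 * k2)
    k4 <- deriv(s + h * k3)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- s
  }
  list(times = seq(0, t_end, length.out = n_steps + 1), states = out)
}
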