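test_that("uptake_rate matches the inhibited Monod form", {
  up <- uptake_params(mu = c(1.0, 0.8, 0.5, 0.5), K = rep(2.5, 4))
  S0 <- c(6.7, 6.8, 6.9, 7.0)

  # no inhibitors: direct evaluation mu_1 S_1 / (K_1 + S_1)
  expect_equal(uptake_rate(S0, up, 1), 6.7 / 9.2, tolerance = 1e-12)

  # zero concentration annihilates the rate regardless of inhibitors
  A <- matrix(0, 4, 4); A[1, 2] <- 1e6
  upA <- uptake_params(up$mu, up$K, A)
  expect_identical(uptake_rate(c(0, 5, 5, 5), upA, 1), 0)

  # half-saturation: S_i = K_i gives mu_i / 2
  expect_equal(uptake_rate(c(2.5, 0, 0, 0), up, 1), 0.5, tolerance = 1e-12)

  # a very strong inhibitor drives the rate toward zero
  expect_lt(uptake_rate(c(6.7, 5, 0, 0), upA, 1), 1e-5)

  # monotonicity: increasing in own concentration, decreasing in inhibitor
  s_grid <- seq(0.5, 10, length.out = 20)
  for (rep in 1:20) {
    mu <- runif(1, 0.1, 2); K <- runif(1, 0.05, 3); a <- runif(1, 0.5, 100)
    A2 <- matrix(0, 2, 2); A2[1, 2] <- a
    u2 <- uptake_params(c(mu, 1), c(K, 1), A2)
    own <- vapply(s_grid, function(s) uptake_rate(c(s, 1), u2, 1), numeric(1))
    expect_true(all(diff(own) > 0))
    inh <- vapply(s_grid, function(s) uptake_rate(c(1, s), u2, 1), numeric(1))
    expect_true(all(diff(inh) < 0))
  }

  expect_error(uptake_rate(c(-1, 1, 1, 1), up, 1), "non-negative")
  expect_error(uptake_rate(S0, up, 9), "index")
})

test_that("model_rhs reflects the energy-budget structure", {
  up <- uptake_params(mu = c(1, 0.8), K = c(2.5, 2.5))
  gr <- growth_params(y_E = c(40, 25), r_E = 0.35, y_V = 0.002, m = 0.05)

  # no biomass: no uptake, no growth; the reserve still drains
  d <- model_rhs(list(S = c(5, 5), E = 2, V = 0), up, gr)
  expect_equal(d$S, c(0, 0))
  expect_equal(d$E, -0.35 * 2)
  expect_equal(d$V, 0.002 * 0.35 * 2)

  # starvation: empty substrate and reserve, maintenance shrinks structure
  d <- model_rhs(list(S = c(0, 0), E = 0, V = 1), up, gr)
  expect_equal(d$S, c(0, 0))
  expect_equal(d$E, 0)
  expect_equal(d$V, -0.002 * 0.05)

  # composition with uptake_rate at the four-substrate example start
  up4 <- uptake_params(mu = c(1.0, 0.8, 0.5, 0.5), K = rep(2.5, 4))
  gr4 <- growth_params(y_E = c(40, 25, 23, 18), r_E = 0.35, y_V = 0.002,
                       m = 0.05)
  st <- list(S = c(6.7, 6.8, 6.9, 7.0), E = 0, V = 0.1)
  d <- model_rhs(st, up4, gr4)
  expect_equal(d$S[1], -(6.7 / 9.2) * 0.1, tolerance = 1e-12)

  expect_error(model_rhs(list(S = c(1, 1, 1), E = 0, V = 1), up, gr),
               "dimension")
})

test_that("simulation conserves mass and respects monotone depletion", {
  exp <- tiny_world()
  up <- exp$truth$uptake; gr <- exp$truth$growth
  times <- seq(0, 50, length.out = 2001)
  tr <- simulate_growth(up, gr, list(S = c(5, 6), E = 0, V = 5e-3), times)

  expect_true(all(tr$S > -1e-8))
  expect_true(all(tr$E > -1e-10) && all(tr$V > 0))
  expect_true(all(apply(tr$S, 2, function(s) all(diff(s) <= 1e-8))))

  # mass balance: S_i(0) - S_i(T) equals the integrated uptake flux f_i V
  for (i in 1:2) {
    f <- vapply(seq_along(times), function(k)
      uptake_rate(pmax(tr$S[k, ], 0), up, i), numeric(1))
    flux <- f * tr$V
    integral <- sum((flux[-1] + flux[-length(flux)]) / 2 * diff(times))
    expect_lt(abs((tr$S[1, i] - tr$S[nrow(tr$S), i]) - integral),
              1e-6 * tr$S[1, i])
  }
})

test_that("single-substrate dynamics match an independent Monod-DEB integrator", {
  up <- uptake_params(mu = 0.8, K = 0.5)
  gr <- growth_params(y_E = 30, r_E = 0.4, y_V = 0.01, m = 0.03)
  tr <- simulate_growth(up, gr, list(S = 8, E = 0, V = 0.01),
                        seq(0, 40, length.out = 81))
  ref <- monod_deb_rk4(0.8, 0.5, 30, 0.4, 0.01, 0.03, 8, 0, 0.01, 40)
  idx <- match(tr$times, ref$times)
  expect_false(anyNA(idx))
  scale <- c(8, max(ref$states[, 2]), max(ref$states[, 3]))
  err <- cbind(tr$S[, 1], tr$E, tr$V) - ref$states[idx, ]
  expect_lt(max(abs(sweep(err, 2, scale, "/"))), 1e-6)

  # decoupled limit: no interactions, no maintenance -> full consumption,
  # biomass increases monotonically and then stays level
  gr0 <- growth_params(y_E = 30, r_E = 0.4, y_V = 0.01, m = 0)
  tr0 <- simulate_growth(up, gr0, list(S = 8, E = 0, V = 0.01),
                         seq(0, 120, length.out = 241))
  expect_lt(tr0$S[241, 1], 1e-6)
  expect_true(all(diff(tr0$V) > -1e-10))
})

test_that("validate_network flags self-loops, mutual pairs and cycles", {
  ok <- function(A) validate_network(A)$ok

  A <- matrix(0, 2, 2); A[1, 2] <- 1; A[2, 1] <- 1
  expect_false(ok(A))
  expect_equal(nrow(validate_network(A)$mutual_pairs), 1)

  A <- matrix(0, 2, 2); A[1, 1] <- 0.5
  expect_false(ok(A))
  expect_equal(validate_network(A)$self_inhibition, 1)

  # the four-substrate demo chain S1 -> S2 -> S4 plus S1 -> S3 is a DAG
  A <- matrix(0, 4, 4); A[2, 1] <- 1; A[4, 2] <- 1; A[3, 1] <- 1
  expect_true(ok(A))

  # a directed 3-cycle is rejected
  A <- matrix(0, 3, 3); A[2, 1] <- 1; A[3, 2] <- 1; A[1, 3] <- 1
  expect_false(ok(A))
  expect_gte(length(validate_network(A)$cycles), 1)

  expect_error(validate_network(matrix(0, 2, 3)), "square")
})

test_that("validate_network agrees with brute-force cycle enumeration", {
  set.seed(11)
  for (rep in 1:300) {
    n <- sample(2:5, 1)
    A <- matrix(rbinom(n * n, 1, 0.35) * runif(n * n, 0.1, 5), n, n)
    expect_identical(validate_network(A)$ok,
                     !has_cycle_bruteforce(A) &&
                       !any(A > 0 & t(A) > 0 & row(A) != col(A)) &&
                       all(diag(A) == 0),
                     info = paste("digraph rep", rep))
  }
})

test_that("partial order and strictness follow the network topology", {
  A <- matrix(0, 4, 4,
              dimnames = list(paste0("S", 1:4), paste0("S", 1:4)))
  A[2, 1] <- 1; A[4, 2] <- 1; A[3, 1] <- 1  # S1->S2->S4, S1->S3
  po <- partial_order(A)
  got <- paste(po$earlier, po$later, sep = ">")
  expect_setequal(got, c("S1>S2", "S1>S3", "S1>S4", "S2>S4"))

  # non-strict: the transitive pair S1 > S4 has no direct edge
  expect_false(is_strict_prioritization(A))
  A[4, 1] <- 1
  expect_true(is_strict_prioritization(A))

  expect_equal(nrow(partial_order(matrix(0, 3, 3))), 0)
  expect_true(is_strict_prioritization(matrix(0, 3, 3)))

  A1 <- matrix(0, 2, 2); A1[2, 1] <- 3
  expect_equal(nrow(partial_order(A1)), 1)

  # total order: full lower-triangular positive matrix is strict
  At <- matrix(0, 3, 3); At[lower.tri(At)] <- 1
  expect_true(is_strict_prioritization(At))

  Ac <- matrix(0, 3, 3); Ac[2, 1] <- 1; Ac[3, 2] <- 1; Ac[1, 3] <- 1
  expect_error(partial_order(Ac), "not a valid")
})

test_that("parameter constructors enforce their invariants", {
  expect_error(uptake_params(mu = c(1, -1), K = c(1, 1)), "mu")
  expect_error(uptake_params(mu = c(1, 1), K = c(0, 1)), "K")
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(uptake_params(mu = c(1, 1), K = c(1, 1), A = A), "mutually")
  expect_error(growth_params(y_E = -1, r_E = 1, y_V = 1, m = 0), "y_E")
  expect_error(growth_params(y_E = 1, r_E = 1, y_V = 1, m = -2), "m")
})
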