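#' Uptake kinetics parameters
#'
#' Bundles the Monod-type uptake parameters of the growth model: per-substrate
#' maximal specific uptake rates `mu`, half-saturation constants `K`, and the
#' inhibition matrix `A`. Entry `A[i, j]` is the dimensionless coefficient by
#' which the concentration of substrate `j` inflates the denominator of
#' substrate `i`'s uptake rate, i.e. `A[i, j] > 0` means "substrate j inhibits
#' the uptake of substrate i". Network edges are rendered in the direction
#' inhibitor -> inhibited.
#'
#' The constructor enforces the structural constraints on `A`: zero diagonal
#' (no self-inhibition) and no mutually inhibitory pair (`A[i, j] > 0` together
#' with `A[j, i] > 0` is rejected). Acyclicity of the full network is checked
#' separately by [validate_network()].
#'
#' @param mu numeric vector of maximal specific uptake rates (> 0), in
#'   substrate amount per unit biomass per hour.
#' @param K numeric vector of half-saturation constants (> 0), in mM.
#' @param A inhibition matrix (N x N, non-negative, zero diagonal); defaults to
#'   no interactions.
#' @param substrates optional character vector of substrate names; defaults to
#'   names of `mu`, or `S1..SN`.
#' @return An object of class `uptake_params`.
#' @seealso [growth_params()], [uptake_rate()], [simulate_growth()]
#' @export
uptake_params <- function(mu, K, A = NULL, substrates = NULL) {
  N <- length(mu)
  if (length(K) != N) stop("mu and K must have the same length")
  if (is.null(substrates)) {
    substrates <- names(mu)
    if (is.null(substrates)) substrates <- paste0("S", seq_len(N))
  }
  if (anyDuplicated(substrates)) stop("substrate names must be unique")
  if (is.null(A)) A <- matrix(0, N, N)
  A <- as.matrix(A)
  if (!all(dim(A) == c(N, N))) stop("A must be an N x N matrix")
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be finite and > 0")
  if (any(!is.finite(K)) || any(K <= 0)) stop("K must be finite and > 0")
  if (any(!is.finite(A)) || any(A < 0)) stop("A must be finite and non-negative")
  if (any(diag(A) != 0)) stop("A must have a zero diagonal (no self-inhibition)")
  mut <- which(A > 0 & t(A) > 0, arr.ind = TRUE)
  if (nrow(mut) > 0) {
    stop(sprintf("mutually inhibitory pair not allowed: %s <-> %s",
                 substrates[mut[1, 1]], substrates[mut[1, 2]]))
  }
  dimnames(A) <- list(substrates, substrates)
  structure(list(mu = setNames(as.numeric(mu), substrates),
                 K = setNames(as.numeric(K), substrates),
                 A = A, substrates = substrates, N = N),
            class = "uptake_params")
}

#' Growth (energy-budget) parameters
#'
#' Parameters of the reserve/structure part of the model: per-substrate energy
#' yields `y_E` (energy extracted into the reserve per unit substrate taken
#' up), the reserve mobilization rate `r_E` (1/h), the biomass yield per unit
#' mobilized energy `y_V`, and the maintenance cost `m` per unit structural
#' biomass per hour.
#'
#' @param y_E numeric vector of per-substrate energy yields (>= 0).
#' @param r_E reserve mobilization rate (1/h, > 0).
#' @param y_V biomass yield per unit energy (> 0).
#' @param m maintenance rate (1/h, >= 0).
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(y_E, r_E, y_V, m) {
  if (any(!is.finite(y_E)) || any(y_E < 0)) stop("y_E must be finite and >= 0")
  if (!is.finite(r_E) || r_E <= 0) stop("r_E must be finite and > 0")
  if (!is.finite(y_V) || y_V <= 0) stop("y_V must be finite and > 0")
  if (!is.finite(m) || m < 0) stop("m must be finite and >= 0")
  structure(list(y_E = as.numeric(y_E), r_E = r_E, y_V = y_V, m = m),
            class = "growth_params")
}

#' Specific uptake rate under competitive inhibition
#'
#' Evaluates the uptake kinetics
#' \deqn{f_i(S) = \frac{\mu_i S_i}{K_i + S_i + \sum_{j \ne i} a_{i,j} S_j},}
#' the Monod form generalized so that the presence of inhibiting substrates
#' inflates the half-saturation denominator.
#'
#' @param S non-negative concentration vector (mM), one entry per substrate.
#' @param params an [uptake_params()] object.
#' @param i substrate index (or indices); default all substrates.
#' @return Numeric vector of specific uptake rates, one per requested index.
#' @export
uptake_rate <- function(S, params, i = seq_len(params$N)) {
  stopifnot(inherits(params, "uptake_params"))
  if (length(S) != params$N) stop("S has wrong length")
  if (any(S < 0)) stop("S must be non-negative")
  if (any(i < 1 | i > params$N)) stop("substrate index out of range")
  vapply(i, function(ii) {
    den <- params$K[ii] + S[ii] + sum(params$A[ii, -ii] * S[-ii])
    if (S[ii] == 0) 0 else unname(params$mu[ii] * S[ii] / den)
  }, numeric(1))
}

#' Right-hand side of the growth model
#'
#' Time derivative of the state (S, E, V): substrates are consumed at rates
#' `f_i(S) V`, assimilated energy `sum(y_E f_i) V` feeds the reserve `E`, which
#' drains at mobilization rate `r_E`; structure `V` grows with yield `y_V` on
#' mobilized energy net of maintenance `m V`. Concentrations are clamped at
#' zero from below before evaluating uptake, so the derivative is well defined
#' slightly past depletion (as the integrator may momentarily step there).
#'
#' @param state list with components `S` (numeric vector), `E`, `V`.
#' @param uptake an [uptake_params()] object.
#' @param growth a [growth_params()] object.
#' @return List with components `S`, `E`, `V` holding the derivatives.
#' @export
model_rhs <- function(state, uptake, growth) {
  stopifnot(inherits(uptake, "uptake_params"), inherits(growth, "growth_params"))
  S <- pmax(state$S, 0)
  if (length(S) != uptake$N) stop("state/parameter dimension mismatch")
  if (length(growth$y_E) != uptake$N) stop("y_E/parameter dimension mismatch")
  f <- uptake_rate(S, uptake)
  dS <- -f * state$V
  dE <- sum(growth$y_E * f) * state$V - growth$r_E * state$E
  dV <- growth$y_V * (growth$r_E * state$E - growth$m * state$V)
  list(S = dS, E = dE, V = dV)
}

#' Simulate the growth model
#'
#' Integrates the full model forward with an adaptive embedded Runge-Kutta
#' pair (Dormand-Prince 5(4)). Depletion corners are locally stiff; the tight
#' default tolerances keep the solution non-negative and mass-balanced there.
#'
#' @param uptake an [uptake_params()] object.
#' @param growth a [growth_params()] object.
#' @param init list with `S` (initial concentrations, mM), `E` (initial
#'   reserve, default 0) and `V` (initial biomass, g CDW/L).
#' @param times strictly increasing time grid (h) at which to report states.
#' @param rtol,atol relative and absolute integration tolerance.
#' @return A `deb_trajectory`: list with `times`, matrix `S` (one column per
#'   substrate), vectors `E` and `V`.
#' @examples
#' up <- uptake_params(mu = c(1, 0.8), K = c(2.5, 2.5))
#' gr <- growth_params(y_E = c(40, 25), r_E = 0.35, y_V = 0.002, m = 0.05)
#' tr <- simulate_growth(up, gr, list(S = c(6.7, 6.8), E = 0, V = 0.001),
#'                       times = seq(0, 40, by = 0.5))
#' @export
simulate_growth <- function(uptake, growth, init, times,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(uptake, "uptake_params"), inherits(growth, "growth_params"))
  if (length(growth$y_E) != uptake$N) stop("y_E/parameter dimension mismatch")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(init$E)) init$E <- 0
  if (any(init$S < 0) || init$E < 0 || init$V < 0)
    stop("initial state must be non-negative")
  if (length(init$S) != uptake$N) stop("init$S has wrong length")
  out <- .sim_deb_cpp(as.numeric(times), as.numeric(init$S), init$E, init$V,
                      unname(uptake$mu), unname(uptake$K), unname(uptake$A),
                      growth$y_E, growth$r_E, growth$y_V, growth$m, rtol, atol)
  S <- out[, seq_len(uptake$N), drop = FALSE]
  colnames(S) <- uptake$substrates
  structure(list(times = as.numeric(times), S = S,
                 E = out[, uptake$N + 1], V = out[, uptake$N + 2],
                 substrates = uptake$substrates),
            class = "deb_trajectory")
}

#' @export
as.data.frame.deb_trajectory <- function(x, ...) {
  vars <- cbind(x$S, E = x$E, V = x$V)
  data.frame(time = rep(x$times, ncol(vars)),
             variable = rep(colnames(vars), each = length(x$times)),
             value = as.vector(vars), row.names = NULL)
}

#' Depletion times of simulated substrates
#'
#' First time at which each substrate falls below a fraction of its initial
#' concentration (linear interpolation between grid points), used to read a
#' qualitative utilization sequence off a trajectory.
#'
#' @param traj a `deb_trajectory` from [simulate_growth()].
#' @param frac depletion threshold as a fraction of the initial value.
#' @return Named numeric vector of depletion times; `NA` when the threshold is
#'   never reached (or the substrate starts at zero).
#' @export
depletion_times <- function(traj, frac = 0.05) {
  stopifnot(inherits(traj, "deb_trajectory"))
  vapply(seq_along(traj$substrates), function(i) {
    s <- traj$S[, i]
    if (s[1] <= 0) return(NA_real_)
    thr <- frac * s[1]
    k <- which(s < thr)
    if (length(k) == 0) return(NA_real_)
    k <- k[1]
    if (k == 1) return(traj$times[1])
    # linear interpolation within the bracketing interval
    t0 <- traj$times[k - 1]; t1 <- traj$times[k]
    s0 <- s[k - 1]; s1 <- s[k]
    t0 + (s0 - thr) / (s0 - s1) * (t1 - t0)
  }, numeric(1), USE.NAMES = FALSE) -> out
  setNames(out, traj$substrates)
}

# adjacency of the inhibition network: edge j -> i (j inhibits i) iff A[i,j] > 0
.adjacency <- function(A) t(A > 0)

#' Validate an inhibition network
#'
#' Checks the structural constraints on an interaction matrix: zero diagonal,
#' no mutually inhibitory pair, and no directed cycle of any length among the
#' edges `A[i, j] > 0` (read as "j inhibits i"). A valid network is a directed
#' acyclic graph, which guarantees the absence of inhibitory deadlocks.
#'
#' @param A square non-negative interaction matrix.
#' @return A list of class `network_validation` with `ok` (logical),
#'   `self_inhibition` (indices), `mutual_pairs` (2-column matrix) and
#'   `cycles` (list of index vectors, each a directed cycle).
#' @export
validate_network <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("A must be square")
  if (any(!is.finite(A)) || any(A < 0)) stop("A must be finite and non-negative")
  self <- which(diag(A) != 0)
  mut <- which(A > 0 & t(A) > 0, arr.ind = TRUE)
  mut <- mut[mut[, 1] < mut[, 2], , drop = FALSE]
  adj <- .adjacency(A)  # adj[j, i]: edge j -> i
  diag(adj) <- FALSE    # self-loops reported separately
  cycles <- .find_cycles(adj)
  structure(list(ok = length(self) == 0 && nrow(mut) == 0 && length(cycles) == 0,
                 self_inhibition = self, mutual_pairs = mut, cycles = cycles),
            class = "network_validation")
}

# DFS cycle detection on a logical adjacency matrix (edge from row to column);
# returns a list of cycles (vertex index vectors), one per back edge found.
.find_cycles <- function(adj) {
  n <- nrow(adj)
  color <- integer(n)  # 0 white, 1 grey, 2 black
  stack <- integer(0)
  cycles <- list()
  visit <- function(u) {
    color[u] <<- 1L
    stack <<- c(stack, u)
    for (w in which(adj[u, ])) {
      if (color[w] == 0L) visit(w)
      else if (color[w] == 1L) {
        pos <- which(stack == w)
        cycles[[length(cycles) + 1L]] <<- stack[pos:length(stack)]
      }
    }
    color[u] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (u in seq_len(n)) if (color[u] == 0L) visit(u)
  cycles
}

#' Partial order induced by an inhibition network
#'
#' The transitive closure of the inhibition DAG: all ordered pairs
#' (inhibitor ahead of inhibited) connected by a directed path. The network
#' thereby encodes a priority ranking of substrates.
#'
#' @param A interaction matrix passing [validate_network()].
#' @return Data frame with columns `earlier` and `later` (substrate indices or
#'   names when `A` has dimnames): `earlier` is consumed with priority over
#'   `later`.
#' @export
partial_order <- function(A) {
  v <- validate_network(A)
  if (!v$ok) stop("A is not a valid inhibition network (cycle, self-loop or mutual pair)")
  adj <- .adjacency(A)
  n <- nrow(adj)
  reach <- adj
  for (k in seq_len(n))  # Warshall transitive closure
    reach <- reach | (outer(reach[, k], reach[k, ], "&"))
  idx <- which(reach, arr.ind = TRUE)
  nm <- rownames(A)
  if (is.null(nm)) nm <- as.character(seq_len(n))
  out <- data.frame(earlier = nm[idx[, 1]], later = nm[idx[, 2]],
                    stringsAsFactors = FALSE)
  out[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Is a prioritization strict?
#'
#' A prioritization is strict when the inhibition DAG is maximal with respect
#' to its induced partial order: every ordered pair is realized by a direct
#' inhibition edge. Non-strict networks can show order reversals when an
#' intermediate substrate is initially absent.
#'
#' @inheritParams partial_order
#' @return `TRUE` or `FALSE`.
#' @export
is_strict_prioritization <- function(A) {
  po <- partial_order(A)
  if (nrow(po) == 0) return(TRUE)
  nm <- rownames(A)
  if (is.null(nm)) nm <- as.character(seq_len(nrow(A)))
  adj <- .adjacency(A)
  dimnames(adj) <- list(nm, nm)
  all(mapply(function(e, l) adj[e, l], po$earlier, po$later))
}
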