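#' Observed specific uptake rates
#'
#' Finite-difference specific rates from observed concentration and biomass
#' series on a shared grid:
#' \deqn{[\Delta s]_k = \frac{2\,(s(t_{k+1}) - s(t_k))}
#'   {(v(t_k) + v(t_{k+1}))\,\Delta t_k},}
#' i.e. the concentration change per unit time per unit (trapezoidal mean)
#' biomass. Negative for depleting substrates.
#'
#' @param s observed concentrations (mM).
#' @param v observed biomass (g CDW/L), same grid.
#' @param times sampling times (h), strictly increasing.
#' @return Numeric vector of length `length(times) - 1`; `NA` where the
#'   biomass vanishes at both interval endpoints.
#' @export
specific_rates_observed <- function(s, v, times) {
  if (length(s) != length(times) || length(v) != length(times))
    stop("s, v and times must share one grid")
  K <- length(times)
  vm <- v[-K] + v[-1]
  out <- 2 * diff(s) / (vm * diff(times))
  out[vm == 0] <- NA_real_
  out
}

# Model specific rates at interval midpoints: 2 * dS/dt(mid) / (v_k + v_{k+1})
.specific_rates_model <- function(dS_mid, v) {
  K <- length(v)
  2 * dS_mid / (v[-K] + v[-1])
}

#' Model specific uptake rates of a fitted decoupled system
#'
#' Evaluates the fitted model derivative at interval midpoints and normalizes
#' by the trapezoidal mean of the observed biomass, making the values directly
#' comparable to [specific_rates_observed()].
#'
#' @param fit an `uptake_fit` from [fit_uptake()].
#' @param replicate replicate name (default: first).
#' @return Numeric vector of length K - 1.
#' @export
specific_rates_model <- function(fit, replicate = NULL) {
  stopifnot(inherits(fit, "uptake_fit"))
  reps <- fit$problem$reps
  if (is.null(replicate)) replicate <- names(reps)[1]
  rep <- reps[[replicate]]
  if (is.null(rep)) stop("unknown replicate: ", replicate)
  t <- rep$t
  mids <- (t[-length(t)] + t[-1]) / 2
  sim <- .sim_decoupled_cpp(c(t[1], mids), rep$s[1], fit$mu, fit$K,
                            unname(fit$a), rep$t, rep$inhib, rep$v,
                            1e-8, 1e-10)
  .specific_rates_model(sim$dS[-1], rep$v)
}

#' Build a decoupled single-substrate fitting problem
#'
#' Decouples one substrate (or substrate cluster) from the full model by
#' replacing every other state variable with a piecewise-linear interpolant of
#' its observations: the target's uptake ODE
#' \eqn{\dot S_i = -f_i(s_1(t), ..., S_i, ...)\, v(t)} is then a scalar
#' equation whose free parameters are `mu`, `K`, and one inhibition
#' coefficient per candidate inhibitor.
#'
#' @param dataset a [growth_experiment()] (typically the cluster-reduced one
#'   from [reduce_by_clusters()]).
#' @param target name of the target substrate/cluster column.
#' @param candidates names of candidate inhibitor columns (free `a`
#'   coefficients); must not contain the target.
#' @param k0 optional integer (or per-replicate named vector): first index
#'   from which specific-rate errors are counted. Default: the first time
#'   point at which biomass reaches 5% of its maximum, where finite-difference
#'   rates stop being dominated by inoculum noise.
#' @return An object of class `decoupled_problem`.
#' @export
decoupled_problem <- function(dataset, target, candidates = character(0),
                              k0 = NULL) {
  stopifnot(inherits(dataset, "growth_experiment"))
  subs <- dataset$substrates
  if (!target %in% subs) stop("unknown target: ", target)
  if (target %in% candidates) stop("target cannot inhibit itself")
  if (!all(candidates %in% subs))
    stop("unknown candidates: ",
         paste(setdiff(candidates, subs), collapse = ", "))
  reps <- lapply(names(dataset$replicates), function(rn) {
    r <- dataset$replicates[[rn]]
    s <- r$conc[, target]
    v <- r$cdw
    K <- length(r$times)
    k0r <- if (is.null(k0)) which(v >= 0.05 * max(v))[1]
           else if (length(k0) > 1) k0[[rn]] else k0
    ds <- specific_rates_observed(s, v, r$times)
    smax <- max(s)
    if (smax <= 0) stop(sprintf("replicate %s: target series is all zero", rn))
    rate_max <- max(abs(ds[k0r:(K - 1)]), na.rm = TRUE)
    list(t = r$times, s = s, v = v,
         inhib = r$conc[, candidates, drop = FALSE],
         ds_obs = ds, k0 = as.integer(k0r),
         w1 = 1 / smax,
         # |.| guard: depletion rates are negative, a signed max would sit
         # near zero and blow the weight up
         w2 = if (rate_max > 0) 1 / rate_max else 0)
  })
  names(reps) <- names(dataset$replicates)
  structure(list(target = target, candidates = candidates, reps = reps),
            class = "decoupled_problem")
}

#' Composite decoupled objective
#'
#' Sum over replicates of the weighted squared errors
#' \eqn{F = w_1 F_1 + w_2 F_2} with \eqn{F_1} the concentration error at the
#' observation times, \eqn{F_2} the specific-rate error from `k0` on, and
#' weights \eqn{w_1 = 1/\max_k s(t_k)},
#' \eqn{w_2 = 1/\max_{k \ge k_0} |[\Delta s]_k|} balancing the two scales.
#' Integration failures return a large finite penalty so derivative-free
#' searches survive hostile parameter regions.
#'
#' @param pars list or vector with `mu`, `K` and (optionally) `a`, one entry
#'   per candidate; negative `a` entries are clamped to zero.
#' @param problem a [decoupled_problem()].
#' @return Objective value (>= 0).
#' @export
uptake_objective <- function(pars, problem) {
  stopifnot(inherits(problem, "decoupled_problem"))
  if (is.list(pars)) {
    mu <- pars$mu; K <- pars$K
    a <- if (is.null(pars$a)) numeric(0) else pars$a
  } else {
    mu <- pars[1]; K <- pars[2]; a <- pars[-(1:2)]
  }
  if (length(a) != length(problem$candidates))
    stop("wrong number of interaction coefficients")
  if (!is.finite(mu) || !is.finite(K) || mu <= 0 || K <= 0)
    return(1e12)
  tryCatch(.decoupled_F_cpp(mu, K, pmax(as.numeric(a), 0), problem$reps),
           error = function(e) 1e12)
}

.default_uptake_bounds <- list(mu = c(1e-4, 1e2), K = c(1e-6, 1e2),
                               a = c(0, 1e4))

# data-driven initial guess: mu from the largest observed specific rate
# magnitude (f <= mu), K from a mid-range concentration
.uptake_init <- function(problem, bounds) {
  rate <- max(unlist(lapply(problem$reps, function(r)
    abs(r$ds_obs[r$k0:length(r$ds_obs)]))), na.rm = TRUE)
  smax <- max(unlist(lapply(problem$reps, function(r) max(r$s))))
  c(mu = min(max(rate, bounds$mu[1] * 10), bounds$mu[2] / 10),
    K = min(max(0.1 * smax, bounds$K[1] * 10), bounds$K[2] / 10),
    setNames(rep(1, length(problem$candidates)), problem$candidates))
}

#' Fit the decoupled uptake model
#'
#' Minimizes [uptake_objective()] by a derivative-free simplex (Nelder-Mead)
#' local search over log-transformed `(mu, K)` and linearly scaled `a >= 0`,
#' multi-started from `restarts` log-uniform draws plus the supplied (or
#' data-driven) initial guess. All replicates are fitted simultaneously with
#' one shared parameter set.
#'
#' @param problem a [decoupled_problem()].
#' @param init optional named initial guess `c(mu, K, a...)`.
#' @param restarts number of additional random starts (default 8).
#' @param seed RNG seed for the random starts.
#' @param bounds list with elements `mu`, `K`, `a`, each `c(lower, upper)`.
#' @param maxit maximum simplex iterations per start.
#' @return An object of class `uptake_fit`: fitted `mu`, `K`, `a` (named by
#'   candidate), objective `F`, `r_squared`, per-replicate `predictions`, and
#'   optimizer `diagnostics`.
#' @export
fit_uptake <- function(problem, init = NULL, restarts = 8, seed = 1,
                       bounds = .default_uptake_bounds, maxit = 2000) {
  stopifnot(inherits(problem, "decoupled_problem"))
  nc <- length(problem$candidates)
  if (is.null(init)) init <- .uptake_init(problem, bounds)
  if (length(init) != 2 + nc) stop("init has wrong length")

  lb <- log(c(bounds$mu[1], bounds$K[1]))
  ub <- log(c(bounds$mu[2], bounds$K[2]))
  a_ub <- bounds$a[2]

  # theta = (log mu, log K, a...); soft box penalty keeps the simplex inside
  obj <- function(theta) {
    lmk <- theta[1:2]
    pen <- sum(pmax(lmk - ub, 0)^2) + sum(pmax(lb - lmk, 0)^2)
    a <- theta[-(1:2)]
    if (nc > 0) pen <- pen + sum(pmax(a - a_ub, 0)^2 / a_ub^2) +
        sum(pmax(-a, 0)^2)
    uptake_objective(c(exp(pmin(pmax(lmk, lb), ub)),
                       pmin(pmax(a, 0), a_ub)), problem) + 1e3 * pen
  }

  starts <- list(c(log(init[1:2]), init[-(1:2)]))
  if (restarts > 0) {
    rng <- .with_seed(seed, {
      lapply(seq_len(restarts), function(i)
        c(runif(1, log(1e-3), log(1e1)),        # mu
          runif(1, log(1e-4), log(1e1)),        # K
          if (nc > 0) 10^runif(nc, -1, 3) else numeric(0)))
    })
    starts <- c(starts, rng)
  }

  # cheap screening pass over all starts, then a full polish of the winner
  best <- NULL
  evals <- 0L
  for (th0 in starts) {
    ps <- c(1, 1, pmax(abs(th0[-(1:2)]), 1))[seq_along(th0)]
    res <- optim(th0, obj, method = "Nelder-Mead",
                 control = list(maxit = min(300, maxit), reltol = 1e-8,
                                parscale = ps))
    evals <- evals + res$counts[1]
    if (is.null(best) || res$value < best$value) best <- res
  }
  ps <- c(1, 1, pmax(abs(best$par[-(1:2)]), 1))[seq_along(best$par)]
  res <- optim(best$par, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-12, parscale = ps))
  evals <- evals + res$counts[1]
  if (res$value <= best$value) best <- res

  theta <- best$par
  mu <- exp(min(max(theta[1], lb[1]), ub[1]))
  Kc <- exp(min(max(theta[2], lb[2]), ub[2]))
  a <- setNames(pmin(pmax(theta[-(1:2)], 0), a_ub), problem$candidates)

  preds <- lapply(problem$reps, function(r)
    .sim_decoupled_cpp(r$t, r$s[1], mu, Kc, unname(a), r$t, r$inhib, r$v,
                       1e-8, 1e-10)$S)
  r2 <- .pooled_r2(preds, lapply(problem$reps, function(r) r$s))

  structure(list(target = problem$target, candidates = problem$candidates,
                 mu = unname(mu), K = unname(Kc), a = a,
                 F = unname(best$value), r_squared = r2,
                 predictions = preds, problem = problem,
                 diagnostics = list(converged = best$convergence == 0,
                                    evals = unname(evals),
                                    starts = length(starts))),
            class = "uptake_fit")
}

#' @export
print.uptake_fit <- function(x, ...) {
  cat(sprintf("uptake_fit [%s]: mu = %.4g, K = %.4g mM, F = %.4g, R2 = %.4f\n",
              x$target, x$mu, x$K, x$F, x$r_squared))
  if (length(x$a) > 0)
    for (nm in names(x$a)) cat(sprintf("  a[%s <- %s] = %.4g\n",
                                       x$target, nm, x$a[[nm]]))
  invisible(x)
}

# pooled coefficient of determination across replicates (grand-mean SST)
.pooled_r2 <- function(pred_list, obs_list) {
  obs <- unlist(obs_list)
  pred <- unlist(pred_list)
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop("constant observations: R-squared undefined")
  1 - sum((pred - obs)^2) / sst
}

#' Coefficient of determination of a fit
#'
#' Concentration-only R-squared, pooled across replicates:
#' \eqn{R^2 = 1 - \sum (S(t_k) - s(t_k))^2 / \sum (s(t_k) - \bar s)^2},
#' where the sums run over all observation points of all replicates and
#' \eqn{\bar s} is the pooled mean. Specific-rate residuals enter the fitting
#' objective but not this summary.
#'
#' @param fit an `uptake_fit` (or any object with `predictions` and `problem`).
#' @return R-squared (<= 1).
#' @export
r_squared <- function(fit) {
  .pooled_r2(fit$predictions, lapply(fit$problem$reps, function(r) r$s))
}

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
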