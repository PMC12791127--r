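#' Count the free parameters of a full-model fit
#'
#' The joint fit frees 2 uptake parameters (`mu`, `K`) per substrate, one
#' inhibition coefficient per accepted edge, 3 growth parameters (`r_E`,
#' `y_V`, `m`) and one initial biomass per replicate:
#' `2 N + |edges| + 3 + R`. Energy yields `y_E` and initial concentrations are
#' held fixed at their supplied/observed values.
#'
#' @param n_substrates,n_edges,n_replicates integers, or a `full_fit_spec` as
#'   first argument.
#' @return Integer parameter count.
#' @examples
#' count_parameters(11, 2, 4)  # 31
#' @export
count_parameters <- function(n_substrates, n_edges = NULL,
                             n_replicates = NULL) {
  if (inherits(n_substrates, "full_fit_spec")) {
    spec <- n_substrates
    return(2L * length(spec$substrates) + nrow(spec$edges) + 3L +
             length(spec$dataset$replicates))
  }
  as.integer(2L * n_substrates + n_edges + 3L + n_replicates)
}

#' Specify a full-model joint fit
#'
#' Fixes the structure of the joint fit: which inhibition edges are present
#' (sparsity from the interaction scan), the per-substrate energy yields
#' `y_E` (held fixed, e.g. theoretical ATP yields), and the data. Edges may
#' name substrate clusters (labels joined by `+`); all member pairs then share
#' one coefficient, the cluster-identifiability constraint.
#'
#' @param dataset a [growth_experiment()] on raw (un-aggregated) substrates.
#' @param edges data frame with columns `inhibitor`, `inhibited` (substrate or
#'   `+`-joined cluster labels); zero rows for an interaction-free model.
#' @param y_E named per-substrate energy yields; defaults to
#'   `dataset$y_E`.
#' @return An object of class `full_fit_spec`.
#' @export
full_fit_spec <- function(dataset, edges, y_E = NULL) {
  stopifnot(inherits(dataset, "growth_experiment"))
  if (is.null(y_E)) y_E <- dataset$y_E
  if (is.null(y_E)) stop("y_E is required (fixed energy yields)")
  if (is.null(names(y_E))) names(y_E) <- dataset$substrates
  if (!all(dataset$substrates %in% names(y_E)))
    stop("y_E must cover every substrate")
  y_E <- y_E[dataset$substrates]
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0 && !all(c("inhibitor", "inhibited") %in% names(edges)))
    stop("edges needs columns inhibitor, inhibited")
  # expand cluster labels to member substrates; one shared a per edge row
  expand <- function(lab) {
    mem <- strsplit(lab, "+", fixed = TRUE)[[1]]
    if (!all(mem %in% dataset$substrates))
      stop("unknown substrate(s) in edge label: ", lab)
    mem
  }
  members <- lapply(seq_len(nrow(edges)), function(r)
    list(inhibitor = expand(edges$inhibitor[r]),
         inhibited = expand(edges$inhibited[r])))
  # per-substrate/replicate observation weights, reused by the objective
  obs <- lapply(dataset$replicates, function(r) {
    K <- length(r$times)
    k0 <- which(r$cdw >= 0.05 * max(r$cdw))[1]
    per_sub <- lapply(dataset$substrates, function(sn) {
      s <- r$conc[, sn]
      ds <- specific_rates_observed(s, r$cdw, r$times)
      rate_max <- max(abs(ds[k0:(K - 1)]), na.rm = TRUE)
      list(s = s, ds_obs = ds,
           w1 = if (max(s) > 0) 1 / max(s) else 0,
           w2 = if (is.finite(rate_max) && rate_max > 0) 1 / rate_max else 0)
    })
    names(per_sub) <- dataset$substrates
    list(times = r$times, cdw = r$cdw, k0 = k0, w_V = 1 / max(r$cdw),
         per_sub = per_sub)
  })
  structure(list(dataset = dataset, substrates = dataset$substrates,
                 edges = edges, edge_members = members,
                 y_E = y_E, obs = obs),
            class = "full_fit_spec")
}

# assemble the interaction matrix from edge coefficients
.spec_A <- function(spec, a) {
  N <- length(spec$substrates)
  A <- matrix(0, N, N, dimnames = list(spec$substrates, spec$substrates))
  for (r in seq_along(spec$edge_members)) {
    em <- spec$edge_members[[r]]
    A[em$inhibited, em$inhibitor] <- a[r]
  }
  A
}

# split a flat parameter vector into named components
.split_full_pars <- function(pars, spec) {
  N <- length(spec$substrates)
  E <- nrow(spec$edges)
  R <- length(spec$dataset$replicates)
  if (length(pars) != 2 * N + E + 3 + R)
    stop("parameter vector has wrong length")
  list(mu = pars[seq_len(N)],
       K = pars[N + seq_len(N)],
       a = if (E > 0) pars[2 * N + seq_len(E)] else numeric(0),
       r_E = pars[2 * N + E + 1],
       y_V = pars[2 * N + E + 2],
       m = pars[2 * N + E + 3],
       V0 = pars[2 * N + E + 3 + seq_len(R)])
}

#' Full-model objective
#'
#' Simulates the complete growth model per replicate from the observed initial
#' concentrations, `E(0) = 0` and the replicate's free initial biomass, and
#' sums the per-substrate concentration-plus-rate errors (the same weighted
#' form as the decoupled objective) and a biomass error
#' `sum((V - cdw)^2) / max(cdw)` per replicate.
#'
#' @param pars flat vector `c(mu (N), K (N), a (per edge), r_E, y_V, m,
#'   V0 (per replicate))`.
#' @param spec a [full_fit_spec()].
#' @return Objective value; a large finite penalty on integration failure.
#' @export
full_objective <- function(pars, spec) {
  stopifnot(inherits(spec, "full_fit_spec"))
  p <- .split_full_pars(pars, spec)
  if (any(!is.finite(pars)) || any(p$mu <= 0) || any(p$K <= 0) ||
      any(p$a < 0) || p$r_E <= 0 || p$y_V <= 0 || p$m < 0 || any(p$V0 <= 0))
    return(1e12)
  A <- .spec_A(spec, p$a)
  total <- 0
  for (ri in seq_along(spec$obs)) {
    ob <- spec$obs[[ri]]
    t <- ob$times
    K <- length(t)
    mids <- (t[-K] + t[-1]) / 2
    grid <- sort(c(t, mids))
    sim <- tryCatch(
      .sim_deb_cpp(grid, spec$dataset$replicates[[ri]]$conc[1, ], 0,
                   p$V0[ri], p$mu, p$K, A, spec$y_E, p$r_E, p$y_V, p$m,
                   1e-8, 1e-10),
      error = function(e) NULL)
    if (is.null(sim)) return(1e12)
    at_obs <- match(t, grid)
    at_mid <- match(mids, grid)
    N <- length(spec$substrates)
    Smid <- pmax(sim[at_mid, seq_len(N), drop = FALSE], 0)
    Vmid <- sim[at_mid, N + 2]
    # model derivative dS_i/dt at midpoints
    den <- matrix(p$K, nrow(Smid), N, byrow = TRUE) + Smid + Smid %*% t(A)
    dS <- -(matrix(p$mu, nrow(Smid), N, byrow = TRUE) * Smid / den) * Vmid
    for (si in seq_len(N)) {
      os <- ob$per_sub[[si]]
      pred <- sim[at_obs, si]
      F1 <- sum((pred - os$s)^2)
      rate_model <- .specific_rates_model(dS[, si], ob$cdw)
      idx <- ob$k0:(K - 1)
      F2 <- sum((rate_model[idx] - os$ds_obs[idx])^2, na.rm = TRUE)
      total <- total + os$w1 * F1 + os$w2 * F2
    }
    total <- total + ob$w_V * sum((sim[at_obs, N + 2] - ob$cdw)^2)
  }
  total
}

#' Pre-fit the growth parameters
#'
#' With all substrate curves fixed to their observed interpolants and the
#' uptake parameters held at supplied values (from decoupled fits), fits the
#' growth parameters `r_E`, `y_V`, `m` and one initial biomass `V0` per
#' replicate to the observed CDW curves by normalized least squares. Used to
#' seed the joint fit.
#'
#' @param dataset a [growth_experiment()].
#' @param uptake an [uptake_params()] on the dataset's substrates.
#' @param y_E named per-substrate energy yields; defaults to `dataset$y_E`.
#' @param init optional named list `r_E`, `y_V`, `m`, `V0` overriding the
#'   data-driven initial guess.
#' @param maxit simplex iteration cap.
#' @return List of class `growth_prefit`: `growth` ([growth_params()]), `V0`
#'   (per replicate), `objective`, `r_squared` (pooled CDW).
#' @export
prefit_growth <- function(dataset, uptake, y_E = NULL, init = NULL,
                          maxit = 5000) {
  stopifnot(inherits(dataset, "growth_experiment"),
            inherits(uptake, "uptake_params"))
  if (is.null(y_E)) y_E <- dataset$y_E
  if (is.null(y_E)) stop("y_E is required")
  y_E <- unname(y_E[dataset$substrates])
  reps <- dataset$replicates
  R <- length(reps)

  if (is.null(init)) {
    # crude energy balance: biomass gained per unit assimilated energy
    yv0 <- mean(vapply(reps, function(r) {
      energy <- sum(y_E * (r$conc[1, ] - r$conc[nrow(r$conc), ]))
      if (energy <= 0) return(NA_real_)
      (max(r$cdw) - r$cdw[1]) / energy
    }, numeric(1)), na.rm = TRUE)
    if (!is.finite(yv0) || yv0 <= 0) yv0 <- 1e-3
    init <- list(r_E = 0.3, y_V = yv0, m = 0.01,
                 V0 = vapply(reps, function(r) max(r$cdw[1], 1e-5),
                             numeric(1)))
  }

  sim_V <- function(rE, yV, m, V0) {
    lapply(seq_len(R), function(ri) {
      r <- reps[[ri]]
      .sim_reserve_cpp(r$times, 0, V0[ri], r$times, r$conc,
                       unname(uptake$mu), unname(uptake$K), unname(uptake$A),
                       y_E, rE, yV, m, 1e-8, 1e-12)[, 2]
    })
  }
  obj <- function(theta) {
    rE <- exp(theta[1]); yV <- exp(theta[2]); m <- max(theta[3], 0)
    V0 <- exp(theta[3 + seq_len(R)])
    pen <- 1e3 * pmax(-theta[3], 0)^2
    Vs <- tryCatch(sim_V(rE, yV, m, V0), error = function(e) NULL)
    if (is.null(Vs)) return(1e12)
    sum(vapply(seq_len(R), function(ri)
      sum((Vs[[ri]] - reps[[ri]]$cdw)^2) / max(reps[[ri]]$cdw),
      numeric(1))) + pen
  }
  th0 <- c(log(init$r_E), log(init$y_V), init$m, log(init$V0))
  res <- optim(th0, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-12))
  rE <- exp(res$par[1]); yV <- exp(res$par[2]); m <- max(res$par[3], 0)
  V0 <- exp(res$par[3 + seq_len(R)])
  Vs <- sim_V(rE, yV, m, V0)
  structure(list(growth = growth_params(y_E, rE, yV, m),
                 V0 = setNames(V0, names(reps)),
                 objective = res$value,
                 r_squared = .pooled_r2(Vs, lapply(reps, `[[`, "cdw")),
                 diagnostics = list(converged = res$convergence == 0)),
            class = "growth_prefit")
}

#' Joint fit of the full growth model
#'
#' Minimizes [full_objective()] over all `2N + |edges| + 3 + R` free
#' parameters with a derivative-free simplex search. A joint fit of this size
#' only converges from a good starting point, so an initial value (normally
#' assembled from the decoupled uptake fits and [prefit_growth()]) is
#' required; set `force = TRUE` to start from an arbitrary guess anyway.
#'
#' @param spec a [full_fit_spec()].
#' @param init named list with `mu`, `K` (per substrate), `a` (per edge),
#'   `r_E`, `y_V`, `m`, `V0` (per replicate).
#' @param maxit simplex iteration cap.
#' @param force allow running without `init`.
#' @return An object of class `full_fit`: fitted `uptake` and `growth`
#'   parameter objects, `V0`, `objective`, pooled concentration `r_squared`,
#'   `r_squared_by_substrate`, per-replicate `predictions` (trajectories at
#'   the observation times) and diagnostics.
#' @export
fit_full <- function(spec, init = NULL, maxit = 20000, force = FALSE) {
  stopifnot(inherits(spec, "full_fit_spec"))
  N <- length(spec$substrates)
  E <- nrow(spec$edges)
  R <- length(spec$dataset$replicates)
  if (is.null(init)) {
    if (!force)
      stop("fit_full requires an initial value (decoupled fits + growth ",
           "pre-fit); use force = TRUE to start from a default guess")
    init <- list(mu = rep(0.3, N), K = rep(0.5, N), a = rep(10, E),
                 r_E = 0.3, y_V = 1e-3, m = 0.01,
                 V0 = vapply(spec$dataset$replicates,
                             function(r) max(r$cdw[1], 1e-5), numeric(1)))
  }
  pars0 <- c(init$mu, init$K, if (E > 0) init$a else numeric(0),
             init$r_E, init$y_V, init$m, init$V0)
  F0 <- full_objective(pars0, spec)

  # log-transform positive parameters; a and m stay linear (may be 0)
  pos_idx <- c(seq_len(2 * N), 2 * N + E + 1, 2 * N + E + 2,
               2 * N + E + 3 + seq_len(R))
  to_theta <- function(p) { p[pos_idx] <- log(p[pos_idx]); p }
  to_pars <- function(th) {
    th[pos_idx] <- exp(pmin(th[pos_idx], 50))
    ai <- if (E > 0) 2 * N + seq_len(E) else integer(0)
    th[ai] <- pmax(th[ai], 0)
    mi <- 2 * N + E + 3
    th[mi] <- max(th[mi], 0)
    th
  }
  obj <- function(th) full_objective(to_pars(th), spec)
  th0 <- to_theta(pars0)
  ps <- rep(1, length(th0))
  if (E > 0) ps[2 * N + seq_len(E)] <- pmax(abs(init$a), 1)
  res <- optim(th0, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-10, parscale = ps))
  # restart once from the optimum: a fresh simplex routinely escapes the
  # degenerate shapes Nelder-Mead collapses into at this dimension
  res2 <- optim(res$par, obj, method = "Nelder-Mead",
                control = list(maxit = maxit, reltol = 1e-10,
                               parscale = ps))
  if (res2$value <= res$value) {
    res2$counts <- res$counts + res2$counts
    res <- res2
  }
  pars <- to_pars(res$par)
  p <- .split_full_pars(pars, spec)
  A <- .spec_A(spec, p$a)
  up <- uptake_params(setNames(p$mu, spec$substrates),
                      setNames(p$K, spec$substrates), A)
  gr <- growth_params(unname(spec$y_E), p$r_E, p$y_V, p$m)

  preds <- lapply(seq_len(R), function(ri) {
    r <- spec$dataset$replicates[[ri]]
    simulate_growth(up, gr, list(S = r$conc[1, ], E = 0, V = p$V0[ri]),
                    r$times)
  })
  names(preds) <- names(spec$dataset$replicates)
  obs_all <- lapply(spec$dataset$replicates, function(r) as.vector(r$conc))
  pred_all <- lapply(preds, function(tr) as.vector(tr$S))
  r2 <- .pooled_r2(pred_all, obs_all)
  r2_sub <- vapply(seq_len(N), function(si) .pooled_r2(
    lapply(preds, function(tr) tr$S[, si]),
    lapply(spec$dataset$replicates, function(r) r$conc[, si])), numeric(1))

  structure(list(uptake = up, growth = gr,
                 V0 = setNames(p$V0, names(spec$dataset$replicates)),
                 objective = res$value, objective_init = F0,
                 r_squared = r2,
                 r_squared_by_substrate = setNames(r2_sub, spec$substrates),
                 predictions = preds,
                 diagnostics = list(converged = res$convergence == 0,
                                    evals = unname(res$counts[1]),
                                    n_parameters = count_parameters(spec))),
            class = "full_fit")
}

#' @export
print.full_fit <- function(x, ...) {
  cat(sprintf("full_fit: %d parameters, objective %.4g, pooled R2 = %.4f\n",
              x$diagnostics$n_parameters, x$objective, x$r_squared))
  invisible(x)
}
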