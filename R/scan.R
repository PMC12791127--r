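#' Enumerate candidate inhibitor sets for a target
#'
#' All sets of 1..`max_order` foreign clusters, excluding the target's own
#' cluster and excluding any candidate that would create a mutually inhibitory
#' pair or a directed cycle given already-accepted edges.
#'
#' @param target target cluster label.
#' @param clusters character vector of all cluster labels.
#' @param max_order largest candidate-set size (1 or 2).
#' @param existing_edges optional data frame with columns `inhibitor`,
#'   `inhibited` of already-accepted edges.
#' @return List of character vectors (candidate inhibitor sets).
#' @export
enumerate_candidates <- function(target, clusters, max_order = 1,
                                 existing_edges = NULL) {
  pool <- setdiff(clusters, target)
  if (!is.null(existing_edges) && nrow(existing_edges) > 0) {
    # j is excluded as an inhibitor of `target` whenever the accepted edges
    # already contain a directed path target -> ... -> j
    adj <- matrix(FALSE, length(clusters), length(clusters),
                  dimnames = list(clusters, clusters))
    for (r in seq_len(nrow(existing_edges)))
      adj[existing_edges$inhibitor[r], existing_edges$inhibited[r]] <- TRUE
    for (k in clusters) adj <- adj | outer(adj[, k], adj[k, ], "&")
    pool <- pool[!adj[target, pool]]
  }
  if (length(pool) == 0) return(list())
  out <- lapply(pool, function(p) p)
  if (max_order >= 2 && length(pool) >= 2) {
    prs <- combn(pool, 2, simplify = FALSE)
    out <- c(out, prs)
  }
  out
}

#' Scan one target for inhibitory interactions
#'
#' Fits the decoupled uptake model for the target without interactions
#' (baseline), then once per candidate inhibitor, recording the fit
#' improvement \eqn{\Delta R^2} relative to baseline. Candidate fits are
#' seeded from the baseline optimum (nesting: a richer model never scores
#' worse than the model it extends, up to optimizer tolerance). Second-order
#' candidate pairs are scanned only when the best single candidate already
#' improves the fit beyond `weak` — the incremental protocol.
#'
#' @param dataset a (typically cluster-reduced) [growth_experiment()].
#' @param target target column name.
#' @param max_order 1 (singles) or 2 (also pairs).
#' @param weak threshold gating the second-order scan.
#' @param candidates optional list of candidate sets; default
#'   [enumerate_candidates()] over all other columns.
#' @param restarts,seed,maxit forwarded to [fit_uptake()].
#' @param inits optional named list mapping a candidate label (members joined
#'   by `+`) to an initial parameter vector, used to warm-start subset refits.
#' @return An object of class `scan_result` with the baseline fit and a table
#'   of candidate fits.
#' @export
scan_target <- function(dataset, target, max_order = 2, weak = 0.025,
                        candidates = NULL, restarts = 4, seed = 1,
                        maxit = 2000, inits = NULL) {
  stopifnot(inherits(dataset, "growth_experiment"))
  if (is.null(candidates))
    candidates <- enumerate_candidates(target, dataset$substrates,
                                       max_order = 1)
  base_prob <- decoupled_problem(dataset, target)
  base_init <- if (!is.null(inits) && !is.null(inits[[".baseline"]]))
    inits[[".baseline"]] else NULL
  baseline <- fit_uptake(base_prob, init = base_init, restarts = restarts,
                         seed = seed, maxit = maxit)

  fit_set <- function(set, init) {
    prob <- decoupled_problem(dataset, target, candidates = set)
    fit_uptake(prob, init = init, restarts = restarts, seed = seed,
               maxit = maxit)
  }

  results <- list()
  for (set in candidates) {
    lab <- paste(set, collapse = "+")
    init <- if (!is.null(inits) && !is.null(inits[[lab]])) inits[[lab]]
            else c(baseline$mu, baseline$K, setNames(rep(1, length(set)), set))
    fit <- tryCatch(fit_set(set, init), error = function(e) e)
    results[[lab]] <- list(set = set, fit = fit, order = length(set))
  }

  # incremental second-order scan, gated on the best single improvement
  singles_dr2 <- vapply(results, function(x) {
    if (inherits(x$fit, "error") || x$order != 1) -Inf
    else x$fit$r_squared - baseline$r_squared
  }, numeric(1))
  if (max_order >= 2 && length(singles_dr2) > 0 && max(singles_dr2) > weak) {
    pool <- unlist(lapply(results[vapply(results, function(x) x$order == 1,
                                         TRUE)], `[[`, "set"))
    if (length(pool) >= 2) {
      for (pr in combn(pool, 2, simplify = FALSE)) {
        lab <- paste(pr, collapse = "+")
        if (!is.null(results[[lab]])) next
        # seed from the better of the two single-candidate optima
        sel <- pr[which.max(singles_dr2[pr])]
        sf <- results[[sel]]$fit
        init <- c(sf$mu, sf$K, setNames(rep(1, 2), pr))
        init[2 + which(pr == sel)] <- sf$a[[sel]]
        fit <- tryCatch(fit_set(pr, init), error = function(e) e)
        results[[lab]] <- list(set = pr, fit = fit, order = 2L)
      }
    }
  }

  empty_tab <- data.frame(candidate = character(0), order = integer(0),
                          r_squared = numeric(0), delta_r2 = numeric(0),
                          a = numeric(0), error = character(0),
                          stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(names(results), function(lab) {
    x <- results[[lab]]
    if (inherits(x$fit, "error"))
      return(data.frame(candidate = lab, order = x$order, r_squared = NA,
                        delta_r2 = NA, a = NA, error = conditionMessage(x$fit),
                        stringsAsFactors = FALSE))
    data.frame(candidate = lab, order = x$order,
               r_squared = x$fit$r_squared,
               delta_r2 = x$fit$r_squared - baseline$r_squared,
               a = if (x$order == 1) unname(x$fit$a[1]) else NA,
               error = NA_character_, stringsAsFactors = FALSE)
  }))
  if (is.null(tab)) tab <- empty_tab

  structure(list(target = target, baseline = baseline, fits = results,
                 table = tab), class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result [%s]: baseline R2 = %.4f\n",
              x$target, x$baseline$r_squared))
  tab <- x$table[order(-x$table$delta_r2), ]
  for (r in seq_len(min(nrow(tab), 8)))
    cat(sprintf("  + %-20s dR2 = %+.4f\n", tab$candidate[r], tab$delta_r2[r]))
  invisible(x)
}

#' Scan every target in a dataset
#'
#' @inheritParams scan_target
#' @return Named list of [scan_target()] results, one per column.
#' @export
scan_all <- function(dataset, max_order = 2, weak = 0.025, restarts = 4,
                     seed = 1, maxit = 2000) {
  out <- lapply(dataset$substrates, function(tg)
    scan_target(dataset, tg, max_order = max_order, weak = weak,
                restarts = restarts, seed = seed, maxit = maxit))
  names(out) <- dataset$substrates
  out
}

#' Assemble the inhibition network from scan results
#'
#' For each target, retains the single-candidate edge with the largest
#' \eqn{\Delta R^2} provided it exceeds `weak`; further candidates whose
#' \eqn{\Delta R^2} also exceeds `weak` and lies within `margin` of the best
#' are retained as unresolved alternatives (an identifiability statement, not
#' two simultaneous edges). Edges are classed `strong` when
#' \eqn{\Delta R^2 >} `strong`, `weak` otherwise. The assembled edge set must
#' form a DAG; a cycle (only detectable globally, since per-target scans are
#' independent) raises an error naming the offending edges.
#'
#' @param scans list of `scan_result`s (one per target).
#' @param strong,weak classification thresholds on \eqn{\Delta R^2}.
#' @param margin equivalence margin for retaining alternatives.
#' @return An `inhibition_network`: `nodes`, `edges` data frame (`inhibitor`,
#'   `inhibited`, `a`, `delta_r2`, `class`, `alternative_group`), and the
#'   interaction matrix `A` of the primary (best) edges.
#' @export
build_network <- function(scans, strong = 0.1, weak = 0.025, margin = 0.02) {
  nodes <- vapply(scans, function(s) s$target, "")
  edges <- list()
  for (s in scans) {
    tab <- s$table[s$table$order == 1 & !is.na(s$table$delta_r2), ,
                   drop = FALSE]
    if (nrow(tab) == 0) next
    best <- max(tab$delta_r2)
    if (best <= weak) next
    keep <- tab[tab$delta_r2 > weak & tab$delta_r2 >= best - margin, ,
                drop = FALSE]
    keep <- keep[order(-keep$delta_r2), , drop = FALSE]
    grp <- if (nrow(keep) > 1) s$target else NA_character_
    for (r in seq_len(nrow(keep))) {
      edges[[length(edges) + 1]] <- data.frame(
        inhibitor = keep$candidate[r], inhibited = s$target,
        a = keep$a[r], delta_r2 = keep$delta_r2[r],
        class = if (keep$delta_r2[r] > strong) "strong" else "weak",
        alternative_group = grp, primary = r == 1,
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges)
    else data.frame(inhibitor = character(0), inhibited = character(0),
                    a = numeric(0), delta_r2 = numeric(0),
                    class = character(0), alternative_group = character(0),
                    primary = logical(0), stringsAsFactors = FALSE)

  nodes <- union(nodes, unlist(edges[c("inhibitor", "inhibited")]))
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  prim <- edges[edges$primary, , drop = FALSE]
  for (r in seq_len(nrow(prim)))
    A[prim$inhibited[r], prim$inhibitor[r]] <- prim$a[r]
  val <- validate_network(A)
  if (!val$ok) {
    cyc <- vapply(val$cycles, function(cy)
      paste(nodes[cy], collapse = " -> "), "")
    stop("assembled edge set is not acyclic: ",
         paste(c(cyc, if (nrow(val$mutual_pairs) > 0) "mutual pair"),
               collapse = "; "))
  }
  structure(list(nodes = nodes, edges = edges, A = A,
                 thresholds = c(strong = strong, weak = weak,
                                margin = margin)),
            class = "inhibition_network")
}

#' @export
print.inhibition_network <- function(x, ...) {
  cat(sprintf("inhibition_network: %d nodes, %d edge records\n",
              length(x$nodes), nrow(x$edges)))
  for (r in seq_len(nrow(x$edges)))
    cat(sprintf("  %s -> %s  (a = %.3g, dR2 = %.3f, %s%s)\n",
                x$edges$inhibitor[r], x$edges$inhibited[r], x$edges$a[r],
                x$edges$delta_r2[r], x$edges$class[r],
                if (!is.na(x$edges$alternative_group[r])) ", alternative"
                else ""))
  invisible(x)
}

#' Subset the replicates of an experiment
#'
#' @param dataset a [growth_experiment()].
#' @param replicates replicate names or indices to keep.
#' @return A [growth_experiment()] with the selected replicates.
#' @export
subset_replicates <- function(dataset, replicates) {
  stopifnot(inherits(dataset, "growth_experiment"))
  growth_experiment(dataset$replicates[replicates], dataset$substrates,
                    dataset$y_E)
}

#' Replicate-subset resampling of interaction estimates
#'
#' Reruns the single-candidate scan for one target on every replicate subset
#' of size >= `min_size`, warm-starting each subset fit from the full-data
#' optimum, and reports the spread (standard deviation) of \eqn{\Delta R^2}
#' and of the fitted coefficient per candidate across the subsets.
#'
#' @param dataset a (cluster-reduced) [growth_experiment()] with >= 3
#'   replicates.
#' @param target target column name.
#' @param full_scan the full-data [scan_target()] result for this target.
#' @param min_size smallest subset size (default 2).
#' @inheritParams scan_target
#' @return List with `spread` (data frame: candidate, sd_delta_r2, sd_a,
#'   n_subsets) and `subsets` (the long per-subset table).
#' @export
resample_replicates <- function(dataset, target, full_scan = NULL,
                                min_size = 2, restarts = 0, seed = 1,
                                maxit = 2000) {
  stopifnot(inherits(dataset, "growth_experiment"))
  R <- length(dataset$replicates)
  if (R < 3) stop("resampling needs at least 3 replicates")
  if (is.null(full_scan))
    full_scan <- scan_target(dataset, target, max_order = 1, seed = seed,
                             maxit = maxit)
  singles <- Filter(function(x) x$order == 1 && !inherits(x$fit, "error"),
                    full_scan$fits)
  inits <- lapply(singles, function(x) c(x$fit$mu, x$fit$K, x$fit$a))
  inits[[".baseline"]] <- c(full_scan$baseline$mu, full_scan$baseline$K)

  rep_names <- names(dataset$replicates)
  subsets <- unlist(lapply(seq(min_size, R), function(k)
    combn(rep_names, k, simplify = FALSE)), recursive = FALSE)

  rows <- list()
  for (ss in subsets) {
    sub <- subset_replicates(dataset, ss)
    sc <- scan_target(sub, target, max_order = 1,
                      candidates = lapply(names(singles), identity),
                      restarts = restarts, seed = seed, maxit = maxit,
                      inits = inits)
    tab <- sc$table[sc$table$order == 1, , drop = FALSE]
    tab$subset <- paste(ss, collapse = "+")
    tab$size <- length(ss)
    rows[[length(rows) + 1]] <- tab
  }
  long <- do.call(rbind, rows)
  spread <- do.call(rbind, lapply(split(long, long$candidate), function(d)
    data.frame(candidate = d$candidate[1],
               sd_delta_r2 = sd(d$delta_r2, na.rm = TRUE),
               sd_a = sd(d$a, na.rm = TRUE),
               mean_delta_r2 = mean(d$delta_r2, na.rm = TRUE),
               n_subsets = nrow(d), stringsAsFactors = FALSE)))
  rownames(spread) <- NULL
  list(spread = spread, subsets = long)
}

#' Uptake-blockade diagnostic
#'
#' Checks, per replicate, whether a fitted inhibition is strong enough to
#' effectively block the target's uptake: the model's specific uptake rate
#' stays below `rate_threshold` for as long as the inhibitor concentration
#' exceeds `conc_threshold`.
#'
#' @param fit an `uptake_fit` containing at least one inhibition coefficient.
#' @param inhibitor which fitted inhibitor to examine (default: first).
#' @param rate_threshold specific uptake rate bound (1/h).
#' @param conc_threshold inhibitor concentration bound (mM; default 0.05 mM =
#'   50 uM).
#' @param n_grid evaluation grid size per replicate.
#' @return Data frame, one row per replicate: `blocked` (logical), the maximal
#'   specific rate while the inhibitor persists, and the time the inhibitor
#'   drops below `conc_threshold`.
#' @export
blockade_diagnostic <- function(fit, inhibitor = NULL, rate_threshold = 0.1,
                                conc_threshold = 0.05, n_grid = 200) {
  stopifnot(inherits(fit, "uptake_fit"))
  if (length(fit$a) == 0) stop("fit contains no inhibition edge")
  if (is.null(inhibitor)) inhibitor <- names(fit$a)[1]
  out <- lapply(names(fit$problem$reps), function(rn) {
    r <- fit$problem$reps[[rn]]
    tt <- seq(min(r$t), max(r$t), length.out = n_grid)
    sim <- .sim_decoupled_cpp(tt, r$s[1], fit$mu, fit$K, unname(fit$a),
                              r$t, r$inhib, r$v, 1e-8, 1e-10)
    v <- approx(r$t, r$v, tt)$y
    rate <- ifelse(v > 0, -sim$dS / v, 0)  # specific uptake rate f_i (1/h)
    ic <- approx(r$t, r$inhib[, inhibitor], tt)$y
    present <- ic > conc_threshold
    clear_t <- if (any(!present)) tt[which(!present)[1]] else NA_real_
    data.frame(replicate = rn,
               blocked = !any(present & rate >= rate_threshold),
               max_rate_while_present = if (any(present))
                 max(rate[present]) else NA_real_,
               inhibitor_cleared_at = clear_t, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
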