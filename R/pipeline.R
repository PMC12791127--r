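#' Analysis configuration
#'
#' One bag of tunables for [run_pipeline()]; every stage consumes only this
#' and the dataset, so a config plus a seed fully reproduces a run.
#'
#' @param cut_height dendrogram cut height for substrate clustering.
#' @param strong,weak \eqn{\Delta R^2} classification thresholds
#'   (strong > weak > 0).
#' @param margin equivalence margin for retaining alternative inhibitors.
#' @param max_order largest candidate interaction set scanned (1 or 2).
#' @param restarts random multi-starts per decoupled fit.
#' @param seed RNG seed consumed by all stochastic stages.
#' @param maxit simplex iteration cap per fit.
#' @param do_full_fit also run the joint full-model fit (needs `y_E` on the
#'   dataset).
#' @param resample also run replicate-subset resampling for scanned targets
#'   with at least one network edge.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(cut_height = 0.075, strong = 0.1, weak = 0.025,
                            margin = 0.02, max_order = 2, restarts = 4,
                            seed = 1, maxit = 2000, do_full_fit = FALSE,
                            resample = FALSE) {
  if (!(strong > weak && weak > 0)) stop("need strong > weak > 0")
  structure(list(cut_height = cut_height, strong = strong, weak = weak,
                 margin = margin, max_order = max_order, restarts = restarts,
                 seed = seed, maxit = maxit, do_full_fit = do_full_fit,
                 resample = resample),
            class = "analysis_config")
}

#' Run the full inference pipeline
#'
#' Executes the workflow end to end: depletion-curve distance matrix ->
#' substrate clustering -> decoupled interaction scans per cluster ->
#' network assembly -> optional replicate resampling and joint full-model
#' fit (seeded from the decoupled fits and a growth pre-fit).
#'
#' @param dataset a [growth_experiment()].
#' @param config an [analysis_config()].
#' @param out_dir optional directory; when given, all stage artifacts are
#'   written there (CSV/TSV/JSON).
#' @return List of class `pipeline_result` with `distance`, `clusters`,
#'   `reduced`, `scans`, `network`, and optionally `resampling` and
#'   `full_fit`.
#' @export
run_pipeline <- function(dataset, config = analysis_config(),
                         out_dir = NULL) {
  stopifnot(inherits(dataset, "growth_experiment"))
  D <- dissimilarity_matrix(dataset)
  clusters <- cluster_substrates(D, config$cut_height)
  red <- reduce_by_clusters(dataset, clusters)

  scans <- scan_all(red$dataset, max_order = config$max_order,
                    weak = config$weak, restarts = config$restarts,
                    seed = config$seed, maxit = config$maxit)
  network <- build_network(scans, strong = config$strong, weak = config$weak,
                           margin = config$margin)

  resampling <- NULL
  if (config$resample && length(dataset$replicates) >= 3 &&
      nrow(network$edges) > 0) {
    targets <- unique(network$edges$inhibited)
    resampling <- lapply(targets, function(tg)
      resample_replicates(red$dataset, tg, full_scan = scans[[tg]],
                          seed = config$seed, maxit = config$maxit))
    names(resampling) <- targets
  }

  full <- NULL
  if (config$do_full_fit) {
    if (is.null(dataset$y_E))
      stop("full fit requires y_E on the dataset")
    full <- .pipeline_full_fit(dataset, clusters, scans, network, config)
  }

  res <- structure(list(distance = D, clusters = clusters, reduced = red,
                        scans = scans, network = network,
                        resampling = resampling, full_fit = full,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

# assemble the full-fit spec and initial value from pipeline stages
.pipeline_full_fit <- function(dataset, clusters, scans, network, config) {
  prim <- network$edges[network$edges$primary, , drop = FALSE]
  spec <- full_fit_spec(dataset, prim[, c("inhibitor", "inhibited")])
  # member substrates inherit their cluster's decoupled mu and K
  mu <- K <- setNames(numeric(length(dataset$substrates)),
                      dataset$substrates)
  for (lab in names(scans)) {
    mem <- strsplit(lab, "+", fixed = TRUE)[[1]]
    best <- .best_fit(scans[[lab]], config$weak)
    mu[mem] <- best$mu
    K[mem] <- best$K
  }
  a <- vapply(seq_len(nrow(prim)), function(r) {
    f <- scans[[prim$inhibited[r]]]$fits[[prim$inhibitor[r]]]$fit
    unname(f$a[[prim$inhibitor[r]]])
  }, numeric(1))
  up0 <- uptake_params(mu, K, .spec_A(spec, a))
  pre <- prefit_growth(dataset, up0)
  init <- list(mu = unname(mu), K = unname(K), a = a,
               r_E = pre$growth$r_E, y_V = pre$growth$y_V,
               m = pre$growth$m, V0 = unname(pre$V0))
  list(fit = fit_full(spec, init), prefit = pre, spec = spec, init = init)
}

# best-supported fit of a scan: the top single candidate above the weak
# threshold, otherwise the baseline
.best_fit <- function(scan, weak) {
  tab <- scan$table[scan$table$order == 1 & !is.na(scan$table$delta_r2), ,
                    drop = FALSE]
  if (nrow(tab) > 0 && max(tab$delta_r2) > weak)
    scan$fits[[tab$candidate[which.max(tab$delta_r2)]]]$fit
  else scan$baseline
}

#' Write pipeline artifacts
#'
#' Exports every stage result in plain-text formats: the distance matrix and
#' per-target scan tables as CSV, the network as a TSV edge list plus JSON,
#' cluster assignment and (when present) full-fit parameters as JSON.
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$distance, file.path(out_dir, "distance_matrix.csv"))
  jsonlite::write_json(
    list(cut_height = result$clusters$cut_height,
         members = result$clusters$members),
    file.path(out_dir, "clusters.json"), auto_unbox = TRUE, digits = NA)
  scan_tab <- do.call(rbind, lapply(result$scans, function(s) {
    tab <- s$table
    tab$target <- s$target
    tab$baseline_r2 <- s$baseline$r_squared
    tab
  }))
  write.csv(scan_tab, file.path(out_dir, "scans.csv"), row.names = FALSE)
  ed <- result$network$edges
  if (!is.null(result$resampling)) {
    ed$sd_delta_r2 <- NA_real_
    ed$sd_a <- NA_real_
    for (tg in names(result$resampling)) {
      sp <- result$resampling[[tg]]$spread
      for (r in which(ed$inhibited == tg)) {
        row <- sp[sp$candidate == ed$inhibitor[r], ]
        if (nrow(row) == 1) {
          ed$sd_delta_r2[r] <- row$sd_delta_r2
          ed$sd_a[r] <- row$sd_a
        }
      }
    }
  }
  write.table(ed, file.path(out_dir, "network.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(nodes = result$network$nodes, edges = ed),
                       file.path(out_dir, "network.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(result$full_fit)) {
    ff <- result$full_fit$fit
    jsonlite::write_json(
      list(mu = as.list(ff$uptake$mu), K = as.list(ff$uptake$K),
           A = ff$uptake$A,
           r_E = ff$growth$r_E, y_V = ff$growth$y_V, m = ff$growth$m,
           V0 = as.list(ff$V0), objective = ff$objective,
           r_squared = ff$r_squared,
           r_squared_by_substrate = as.list(ff$r_squared_by_substrate)),
      file.path(out_dir, "full_fit.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' Serialize model parameters to JSON
#'
#' Named blocks (substrates, mu, K, sparse edge list for A, y_E, r_E, y_V, m)
#' in full precision.
#'
#' @param uptake an [uptake_params()]; @param growth a [growth_params()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(uptake, growth, path) {
  idx <- which(uptake$A > 0, arr.ind = TRUE)
  edges <- lapply(seq_len(nrow(idx)), function(r)
    list(inhibitor = uptake$substrates[idx[r, 2]],
         inhibited = uptake$substrates[idx[r, 1]],
         a = uptake$A[idx[r, , drop = FALSE]]))
  jsonlite::write_json(
    list(substrates = uptake$substrates, mu = as.list(uptake$mu),
         K = as.list(uptake$K), interactions = edges,
         y_E = growth$y_E, r_E = growth$r_E, y_V = growth$y_V,
         m = growth$m),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
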