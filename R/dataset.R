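#' Batch-culture growth experiment container
#'
#' Holds replicated observed time series of substrate concentrations (mM) and
#' biomass (cell dry weight, g/L). Within a replicate all series share one
#' sampling grid; different replicates may be sampled on different grids.
#'
#' @param replicates named list, one entry per replicate, each a list with
#'   `times` (strictly increasing, h), `conc` (matrix, one column per
#'   substrate, mM) and `cdw` (biomass, g CDW/L).
#' @param substrates character vector of substrate names (must match the
#'   `conc` column names of every replicate).
#' @param y_E optional named numeric vector of per-substrate energy yields
#'   (e.g. theoretical ATP yields), carried as metadata for full-model fits.
#' @return An object of class `growth_experiment`.
#' @export
growth_experiment <- function(replicates, substrates = NULL, y_E = NULL) {
  if (is.null(names(replicates)) || any(names(replicates) == ""))
    names(replicates) <- paste0("R", seq_along(replicates))
  if (is.null(substrates)) substrates <- colnames(replicates[[1]]$conc)
  if (is.null(substrates)) stop("substrate names are required")
  for (rn in names(replicates)) {
    r <- replicates[[rn]]
    if (any(diff(r$times) <= 0))
      stop(sprintf("replicate %s: times must be strictly increasing", rn))
    if (length(r$times) < 3)
      stop(sprintf("replicate %s: at least 3 time points required", rn))
    r$conc <- as.matrix(r$conc)
    if (is.null(colnames(r$conc))) colnames(r$conc) <- substrates
    if (!identical(sort(colnames(r$conc)), sort(substrates)))
      stop(sprintf("replicate %s: substrate names inconsistent", rn))
    r$conc <- r$conc[, substrates, drop = FALSE]
    if (nrow(r$conc) != length(r$times) || length(r$cdw) != length(r$times))
      stop(sprintf("replicate %s: series lengths differ from time grid", rn))
    if (any(r$conc < 0) || any(r$cdw < 0))
      stop(sprintf("replicate %s: negative concentrations or CDW", rn))
    replicates[[rn]] <- r
  }
  if (!is.null(y_E)) {
    if (is.null(names(y_E))) names(y_E) <- substrates
    y_E <- y_E[substrates]
  }
  structure(list(replicates = replicates, substrates = substrates, y_E = y_E),
            class = "growth_experiment")
}

#' @export
print.growth_experiment <- function(x, ...) {
  cat(sprintf("growth_experiment: %d substrates x %d replicates\n",
              length(x$substrates), length(x$replicates)))
  cat("  substrates:", paste(x$substrates, collapse = ", "), "\n")
  for (rn in names(x$replicates)) {
    r <- x$replicates[[rn]]
    cat(sprintf("  %s: %d time points over [%g, %g] h\n", rn,
                length(r$times), min(r$times), max(r$times)))
  }
  invisible(x)
}

#' @export
as.data.frame.growth_experiment <- function(x, ...) {
  do.call(rbind, lapply(names(x$replicates), function(rn) {
    r <- x$replicates[[rn]]
    vars <- cbind(r$conc, CDW = r$cdw)
    data.frame(time = rep(r$times, ncol(vars)),
               replicate = rn,
               variable = rep(colnames(vars), each = length(r$times)),
               value = as.vector(vars), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

#' Read a growth experiment from tidy CSV
#'
#' Expects long format with columns `time`, `replicate`, `variable`, `value`;
#' `variable` is a substrate name or `CDW`. Within each replicate every
#' variable must be observed on the same time grid. Negative values are
#' rejected with the offending row numbers.
#'
#' @param path CSV file path.
#' @return A [growth_experiment()].
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "replicate", "variable", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$value) | df$value < 0)
  if (length(bad) > 0)
    stop("negative or non-finite values at rows: ",
         paste(head(bad, 10), collapse = ", "))
  if (!"CDW" %in% df$variable) stop("no CDW (biomass) series found")
  substrates <- setdiff(unique(df$variable), "CDW")
  reps <- lapply(split(df, df$replicate), function(d) {
    times <- sort(unique(d$time))
    series <- lapply(split(d, d$variable), function(v) {
      v <- v[order(v$time), ]
      if (!isTRUE(all.equal(v$time, times)))
        stop(sprintf("replicate %s: variable %s not on the shared grid",
                     d$replicate[1], v$variable[1]))
      v$value
    })
    miss <- setdiff(c(substrates, "CDW"), names(series))
    if (length(miss) > 0)
      stop(sprintf("replicate %s: missing variables %s",
                   d$replicate[1], paste(miss, collapse = ", ")))
    conc <- do.call(cbind, series[substrates])
    colnames(conc) <- substrates
    list(times = times, conc = conc, cdw = series[["CDW"]])
  })
  growth_experiment(reps, substrates)
}

#' Write a growth experiment to tidy CSV
#'
#' @param dataset a [growth_experiment()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "growth_experiment"))
  write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}
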