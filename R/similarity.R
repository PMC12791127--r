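#' Scale-invariant dissimilarity between depletion curves
#'
#' Two substrates whose depletion curves are proportional cannot be
#' distinguished as inhibitors of a third substrate: swapping their interaction
#' coefficients leaves the model output unchanged. The dissimilarity used here
#' quantifies the distance from exact proportionality,
#' \deqn{d(x, y) = \inf_{\beta > 0}
#'   \frac{2 \sum_k (x_k - \beta y_k)^2}
#'        {\beta^2 \sum_k (y_k - \bar y)^2 + \sum_k (x_k - \bar x)^2},}
#' which is symmetric, zero iff the series are proportional, and invariant
#' under positive rescaling of either series.
#'
#' The minimizing \eqn{\beta} solves a quadratic stationarity condition and is
#' computed in closed form: with \eqn{A = \sum x^2}, \eqn{B = \sum x y},
#' \eqn{C = \sum y^2}, \eqn{Q_x = \sum (x-\bar x)^2}, \eqn{Q_y = \sum (y-\bar
#' y)^2}, the unique positive root of
#' \eqn{B Q_y \beta^2 + (C Q_x - A Q_y)\beta - B Q_x = 0}.
#' Under the preconditions (non-negative series with a jointly positive time
#' point) \eqn{B > 0}, so the root exists and is the interior minimum.
#'
#' @param x,y numeric vectors of concentrations sampled on a shared time grid
#'   (non-negative, non-constant, length >= 3, at least one time point where
#'   both are positive).
#' @return Dissimilarity value (>= 0) with the optimal scaling factor attached
#'   as attribute `beta`.
#' @export
depletion_dissimilarity <- function(x, y) {
  if (length(x) != length(y)) stop("series must share one time grid")
  if (length(x) < 3) stop("series too short (need >= 3 points)")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0) || any(y < 0))
    stop("series must be finite and non-negative")
  Qx <- sum((x - mean(x))^2)
  Qy <- sum((y - mean(y))^2)
  if (Qx == 0 || Qy == 0) stop("constant series have no defined dissimilarity")
  B <- sum(x * y)
  if (B == 0) stop("series have disjoint support (no jointly positive time point)")
  A <- sum(x^2)
  C <- sum(y^2)
  b <- C * Qx - A * Qy
  beta <- (-b + sqrt(b^2 + 4 * B^2 * Qx * Qy)) / (2 * B * Qy)
  d <- 2 * sum((x - beta * y)^2) / (beta^2 * Qy + Qx)
  structure(d, beta = beta)
}

#' Pairwise depletion-curve distance matrix
#'
#' Evaluates [depletion_dissimilarity()] for every substrate pair within each
#' replicate (on that replicate's grid) and averages across replicates.
#'
#' @param dataset a [growth_experiment()].
#' @return Symmetric matrix with zero diagonal, dimnames = substrate names.
#' @export
dissimilarity_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "growth_experiment"))
  subs <- dataset$substrates
  N <- length(subs)
  acc <- matrix(0, N, N, dimnames = list(subs, subs))
  for (r in dataset$replicates) {
    for (i in seq_len(N - 1)) {
      for (j in (i + 1):N) {
        d <- as.numeric(depletion_dissimilarity(r$conc[, i], r$conc[, j]))
        acc[i, j] <- acc[i, j] + d
        acc[j, i] <- acc[j, i] + d
      }
    }
  }
  acc / length(dataset$replicates)
}

#' Cluster substrates into identifiability classes
#'
#' Agglomerative hierarchical clustering with complete (farthest-point)
#' linkage on a depletion-curve distance matrix, cut at a fixed height.
#' Substrates in one cluster are treated as a single state variable in
#' downstream fits, with shared interaction coefficients.
#'
#' @param D symmetric non-negative distance matrix with zero diagonal (from
#'   [dissimilarity_matrix()]).
#' @param cut_height tree cut height; the default 0.075 suits depletion-curve
#'   dissimilarities on the unit-free scale of [depletion_dissimilarity()],
#'   but the appropriate value is problem specific.
#' @return An object of class `substrate_clusters`: `assignment` (named
#'   integer vector), `members` (list of substrate names per cluster, named by
#'   a `+`-joined label), `tree` (the `hclust` object), `cut_height`.
#' @export
cluster_substrates <- function(D, cut_height = 0.075) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("D must be square")
  if (any(D < 0) || any(abs(diag(D)) > 1e-12) || any(abs(D - t(D)) > 1e-8))
    stop("D must be symmetric and non-negative with a zero diagonal")
  if (is.null(rownames(D))) dimnames(D) <- list(paste0("S", seq_len(nrow(D))),
                                                paste0("S", seq_len(nrow(D))))
  if (nrow(D) == 1) {
    members <- list(rownames(D))
    names(members) <- rownames(D)
    return(structure(list(assignment = setNames(1L, rownames(D)),
                          members = members, tree = NULL,
                          cut_height = cut_height),
                     class = "substrate_clusters"))
  }
  tree <- hclust(as.dist(D), method = "complete")
  assignment <- cutree(tree, h = cut_height)
  members <- split(names(assignment), assignment)
  names(members) <- vapply(members, paste, "", collapse = "+")
  # relabel clusters by their member label, keep integer ids stable
  structure(list(assignment = assignment, members = members, tree = tree,
                 cut_height = cut_height),
            class = "substrate_clusters")
}

#' @export
print.substrate_clusters <- function(x, ...) {
  cat(sprintf("substrate_clusters: %d clusters at cut height %g\n",
              length(x$members), x$cut_height))
  for (nm in names(x$members))
    cat("  ", nm, "\n")
  invisible(x)
}

#' Aggregate a dataset by substrate clusters
#'
#' Replaces each cluster's member substrates by a single aggregate series (the
#' sum of member concentrations per time point, preserving total substrate
#' mass) and records the constraint map tying interaction coefficients of
#' co-clustered substrates to one shared parameter.
#'
#' @param dataset a [growth_experiment()].
#' @param clusters a [cluster_substrates()] assignment.
#' @return List with `dataset` (the reduced [growth_experiment()], one
#'   variable per cluster) and `constraints` (named list: cluster label ->
#'   member substrate names; singletons omitted).
#' @export
reduce_by_clusters <- function(dataset, clusters) {
  stopifnot(inherits(dataset, "growth_experiment"),
            inherits(clusters, "substrate_clusters"))
  if (!setequal(names(clusters$assignment), dataset$substrates))
    stop("cluster assignment does not match dataset substrates")
  labels <- names(clusters$members)
  reps <- lapply(dataset$replicates, function(r) {
    agg <- vapply(clusters$members, function(mem)
      rowSums(r$conc[, mem, drop = FALSE]), numeric(length(r$times)))
    agg <- matrix(agg, nrow = length(r$times),
                  dimnames = list(NULL, labels))
    list(times = r$times, conc = agg, cdw = r$cdw)
  })
  constraints <- clusters$members[vapply(clusters$members, length, 1L) > 1]
  list(dataset = growth_experiment(reps, labels),
       constraints = constraints)
}
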