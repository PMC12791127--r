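test_that("dissimilarity is zero for proportional series and matches its oracle", {
  x <- c(4, 2, 1, 0.5)
  expect_lt(depletion_dissimilarity(x, 3 * x), 1e-12)

  # worked example against the dense grid-search oracle, 4 significant digits
  y <- c(9, 3, 1, 0.4)
  d <- as.numeric(depletion_dissimilarity(x, y))
  d_oracle <- dissimilarity_grid_oracle(x, y)
  expect_equal(d, d_oracle, tolerance = 5e-4)

  expect_error(depletion_dissimilarity(rep(2, 4), y), "constant")
  expect_error(depletion_dissimilarity(c(1, 0, 0, 0), c(0, 0, 1, 2)),
               "disjoint")
  expect_error(depletion_dissimilarity(x, y[1:3]), "grid")
  expect_error(depletion_dissimilarity(x[1:2], y[1:2]), "short")
})

test_that("dissimilarity is symmetric, scale invariant, and oracle-exact on random pairs", {
  set.seed(101)
  for (rep in 1:100) {
    K <- sample(5:25, 1)
    x <- cumprod(runif(K, 0.6, 1))[sample(K)] * runif(1, 0.5, 10)
    y <- cumprod(runif(K, 0.6, 1))[sample(K)] * runif(1, 0.5, 10)
    d_xy <- as.numeric(depletion_dissimilarity(x, y))
    expect_equal(d_xy, as.numeric(depletion_dissimilarity(y, x)),
                 tolerance = 1e-8)
    for (cc in c(0.1, 10)) {
      expect_equal(as.numeric(depletion_dissimilarity(cc * x, y)), d_xy,
                   tolerance = 1e-8)
      expect_equal(as.numeric(depletion_dissimilarity(x, cc * y)), d_xy,
                   tolerance = 1e-8)
    }
    # closed-form beta minimizer vs grid search, 4 significant digits
    expect_equal(d_xy, dissimilarity_grid_oracle(x, y, n_grid = 2e5),
                 tolerance = 5e-4, info = paste("pair", rep))
  }
})

test_that("distance matrix averages per-replicate dissimilarities", {
  t5 <- seq(0, 4)
  mk <- function(conc) list(times = t5, conc = conc, cdw = rep(0.1, 5))
  # substrate B is exactly 2A in both replicates -> distance 0
  A1 <- cbind(A = c(5, 4, 2, 1, 0.3), B = 2 * c(5, 4, 2, 1, 0.3),
              C = c(6, 5.5, 5, 4, 3))
  A2 <- cbind(A = c(4, 3, 2, 0.7, 0.1), B = 2 * c(4, 3, 2, 0.7, 0.1),
              C = c(7, 6, 5.8, 5, 4.5))
  ds <- growth_experiment(list(R1 = mk(A1), R2 = mk(A2)))
  D <- dissimilarity_matrix(ds)
  expect_lt(D["A", "B"], 1e-12)
  expect_equal(unname(diag(D)), rep(0, 3))

  # two replicates: mean of the per-replicate oracle values
  d1 <- dissimilarity_grid_oracle(A1[, "A"], A1[, "C"], n_grid = 2e5)
  d2 <- dissimilarity_grid_oracle(A2[, "A"], A2[, "C"], n_grid = 2e5)
  expect_equal(D["A", "C"], (d1 + d2) / 2, tolerance = 1e-3)

  # single replicate: matrix equals the pairwise dissimilarity
  D1 <- dissimilarity_matrix(growth_experiment(list(R1 = mk(A1))))
  expect_equal(D1["A", "C"],
               as.numeric(depletion_dissimilarity(A1[, "A"], A1[, "C"])),
               tolerance = 1e-12)
})

test_that("complete-linkage clustering cuts where expected", {
  # two tight pairs separated widely
  D <- matrix(c(0, 0.01, 1, 1,
                0.01, 0, 1, 1,
                1, 1, 0, 0.02,
                1, 1, 0.02, 0), 4, 4,
              dimnames = list(paste0("S", 1:4), paste0("S", 1:4)))
  cl <- cluster_substrates(D, cut_height = 0.5)
  expect_equal(length(cl$members), 2)
  expect_setequal(cl$members[["S1+S2"]], c("S1", "S2"))
  expect_setequal(cl$members[["S3+S4"]], c("S3", "S4"))

  expect_equal(length(cluster_substrates(D, 0.005)$members), 4)
  expect_equal(length(cluster_substrates(D, 2)$members), 1)

  # relabeling invariance: permuting D permutes the assignment identically
  perm <- c(3, 1, 4, 2)
  Dp <- D[perm, perm]
  clp <- cluster_substrates(Dp, cut_height = 0.5)
  part <- function(cl) unname(lapply(cl$members, sort))
  expect_setequal(vapply(part(clp), paste, "", collapse = ","),
                  vapply(part(cl), paste, "", collapse = ","))

  expect_error(cluster_substrates(D - 0.5), "symmetric and non-negative")
})

test_that("cluster reduction aggregates series and records constraints", {
  t5 <- 0:4
  # B is close to, but not exactly, proportional to A
  conc <- cbind(A = c(5, 4, 2, 1, 0.3), B = c(10, 8.1, 3.9, 2.05, 0.6),
                C = c(6, 5.5, 5, 4, 3))
  ds <- growth_experiment(list(R1 = list(times = t5, conc = conc,
                                         cdw = rep(0.1, 5))))
  D <- dissimilarity_matrix(ds)
  cl <- cluster_substrates(D, cut_height = 0.05)  # merges A and B only
  red <- reduce_by_clusters(ds, cl)
  expect_setequal(red$dataset$substrates, c("A+B", "C"))
  expect_equal(red$dataset$replicates$R1$conc[, "A+B"],
               conc[, "A"] + conc[, "B"])
  expect_equal(red$constraints, list("A+B" = c("A", "B")))

  # singleton clusters leave the dataset unchanged
  cl1 <- cluster_substrates(D, cut_height = 1e-9)
  red1 <- reduce_by_clusters(ds, cl1)
  expect_setequal(red1$dataset$substrates, c("A", "B", "C"))
  expect_equal(length(red1$constraints), 0)

  # everything in one cluster: a single aggregate series
  clall <- cluster_substrates(D, cut_height = 10)
  redall <- reduce_by_clusters(ds, clall)
  expect_equal(length(redall$dataset$substrates), 1)
  expect_equal(unname(redall$dataset$replicates$R1$conc[, 1]),
               unname(rowSums(conc)))
})
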