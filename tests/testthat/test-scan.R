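test_that("candidate enumeration respects exclusions and combinatorics", {
  cl <- c("C1", "C2", "C3")
  expect_setequal(vapply(enumerate_candidates("C1", cl, 1), paste, "",
                         collapse = "+"), c("C2", "C3"))

  # an accepted edge "C1 inhibits C2" forbids the reverse candidate
  ed <- data.frame(inhibitor = "C1", inhibited = "C2")
  expect_setequal(vapply(enumerate_candidates("C1", cl, 1, ed), paste, "",
                         collapse = "+"), "C3")
  # indirect paths count too: C1 -> C2 -> C3 forbids C3 as inhibitor of C1
  ed2 <- rbind(ed, data.frame(inhibitor = "C2", inhibited = "C3"))
  expect_equal(length(enumerate_candidates("C1", cl, 1, ed2)), 0)

  # singletons plus pairs over four foreign clusters
  out <- enumerate_candidates("T", c("T", paste0("C", 1:4)), 2)
  expect_equal(sum(lengths(out) == 1), 4)
  expect_equal(sum(lengths(out) == 2), 6)
})

test_that("scan finds the planted inhibitor and stays quiet without one", {
  # positive control: the planted edge has the top delta R2, above threshold
  exp <- generate_experiment(surrogate_spec(seed = 2, planted = TRUE))
  tr <- exp$truth$edges
  cl <- cluster_substrates(dissimilarity_matrix(exp$dataset))
  red <- reduce_by_clusters(exp$dataset, cl)
  lab_of <- function(s)
    names(which(vapply(cl$members, function(m) s %in% m, TRUE)))
  sc <- scan_target(red$dataset, lab_of(tr$inhibited), max_order = 1,
                    seed = 1)
  tab <- sc$table[order(-sc$table$delta_r2), ]
  expect_equal(tab$candidate[1], lab_of(tr$inhibitor))
  expect_gt(tab$delta_r2[1], 0.1)

  # negative control: an interaction-free world at low noise shows no signal
  exp0 <- generate_experiment(surrogate_spec(seed = 2, planted = FALSE,
                                             noise_level = 0.01))
  cl0 <- cluster_substrates(dissimilarity_matrix(exp0$dataset))
  red0 <- reduce_by_clusters(exp0$dataset, cl0)
  scans0 <- scan_all(red0$dataset, max_order = 1, seed = 1)
  expect_lt(max(unlist(lapply(scans0, function(s) s$table$delta_r2)),
                na.rm = TRUE), 0.025)

  # a single-cluster dataset leaves only the baseline fit
  one <- subset_replicates(exp0$dataset, 1:2)
  agg <- reduce_by_clusters(one,
                            cluster_substrates(dissimilarity_matrix(one),
                                               cut_height = 1e3))
  sc1 <- scan_target(agg$dataset, agg$dataset$substrates[1], seed = 1)
  expect_equal(nrow(sc1$table), 0)
  expect_s3_class(sc1$baseline, "uptake_fit")
})

test_that("network assembly applies thresholds, alternatives and DAG checks", {
  fake_scan <- function(target, cands, dr2, a = rep(1, length(cands))) {
    structure(list(
      target = target,
      baseline = list(r_squared = 0.8),
      table = data.frame(candidate = cands, order = 1,
                         r_squared = 0.8 + dr2, delta_r2 = dr2, a = a,
                         error = NA_character_, stringsAsFactors = FALSE)),
      class = "scan_result")
  }
  scans <- list(
    fake_scan("A", c("B", "C"), c(0.15, 0.01)),
    fake_scan("B", c("A", "C"), c(0.01, 0.05)),
    fake_scan("C", c("A", "B"), c(0.012, 0.015)))
  net <- build_network(scans)
  expect_s3_class(net, "inhibition_network")
  expect_equal(nrow(net$edges), 2)
  eA <- net$edges[net$edges$inhibited == "A", ]
  expect_equal(eA$inhibitor, "B")
  expect_equal(eA$class, "strong")
  eB <- net$edges[net$edges$inhibited == "B", ]
  expect_equal(eB$class, "weak")
  expect_true(all(is.na(net$edges$alternative_group)))

  # near-equal candidates are both retained as alternatives
  scans2 <- list(fake_scan("A", c("B", "C"), c(0.15, 0.135)))
  net2 <- build_network(scans2)
  expect_equal(nrow(net2$edges), 2)
  expect_equal(unique(net2$edges$alternative_group), "A")
  expect_equal(net2$edges$inhibitor[net2$edges$primary], "B")

  # conflicting selections form a 2-cycle and must be rejected globally
  scans3 <- list(fake_scan("A", "B", 0.2), fake_scan("B", "A", 0.2))
  expect_error(build_network(scans3), "acyclic|mutual")
})

test_that("replicate resampling reports spread across subsets", {
  exp <- tiny_world()  # 4 identical noiseless replicates
  rs <- resample_replicates(exp$dataset, "S2", seed = 1)
  # 6 pairs + 4 triples + 1 quadruple
  expect_equal(sort(unique(rs$subsets$size)), c(2, 3, 4))
  expect_equal(nrow(rs$subsets) / length(unique(rs$subsets$candidate)), 11)
  # identical replicates: essentially zero spread
  expect_true(all(rs$spread$sd_delta_r2 < 1e-3))

  expect_error(resample_replicates(subset_replicates(exp$dataset, 1:2), "S2"),
               "3 replicates")
})

test_that("blockade diagnostic reflects the inhibition limit cases", {
  exp <- tiny_world()
  prob <- decoupled_problem(exp$dataset, "S2", candidates = "S1")
  fit <- fit_uptake(prob, restarts = 2, seed = 1)

  # a -> infinity: uptake fully blocked while the inhibitor persists
  f_inf <- fit; f_inf$a[["S1"]] <- 1e7
  bd <- blockade_diagnostic(f_inf, conc_threshold = 0.05)
  expect_true(all(bd$blocked))

  # a = 0: uptake active despite the inhibitor
  f0 <- fit; f0$a[["S1"]] <- 0
  bd0 <- blockade_diagnostic(f0, conc_threshold = 0.05)
  expect_false(any(bd0$blocked))

  # the fitted strong inhibitor blocks uptake until its concentration falls
  # below a world-appropriate release level
  bd1 <- blockade_diagnostic(fit, conc_threshold = 1.5)
  expect_true(all(bd1$blocked))
  expect_true(all(is.finite(bd1$inhibitor_cleared_at)))

  expect_error(blockade_diagnostic(fit_uptake(
    decoupled_problem(exp$dataset, "S1"), restarts = 0, seed = 1)),
    "no inhibition edge")
})
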