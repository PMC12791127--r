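test_that("generation is exact at zero noise and reproducible by seed", {
  spec <- recovery_demo_spec()
  e1 <- generate_experiment(spec)
  e2 <- generate_experiment(spec)
  expect_identical(e1$dataset$replicates, e2$dataset$replicates)

  # zero noise: sampled values equal the simulated trajectory exactly
  tr <- e1$truth$trajectory
  expect_equal(unname(e1$dataset$replicates$R1$conc), unname(tr$S))
  expect_equal(e1$dataset$replicates$R1$cdw, tr$V)
  # replicates share one inoculum here, so they are identical
  expect_identical(e1$dataset$replicates$R1, e1$dataset$replicates$R4)

  # noisy: replicates differ from the trajectory and from each other,
  # values stay non-negative, and the seed still pins everything down
  spn <- recovery_demo_spec(noise_level = 0.05)
  n1 <- generate_experiment(spn)
  n2 <- generate_experiment(spn)
  expect_identical(n1$dataset$replicates, n2$dataset$replicates)
  expect_gt(max(abs(n1$dataset$replicates$R1$conc - tr$S)), 0.01)
  expect_gt(max(abs(n1$dataset$replicates$R1$conc -
                    n1$dataset$replicates$R2$conc)), 0.01)
  expect_true(all(n1$dataset$replicates$R1$conc >= 0))

  # a different seed gives different noise
  spn2 <- recovery_demo_spec(noise_level = 0.05, seed = 99)
  expect_gt(max(abs(generate_experiment(spn2)$dataset$replicates$R1$conc -
                    n1$dataset$replicates$R1$conc)), 0.01)
})

test_that("spec validation rejects invalid planted networks", {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(uptake_params(mu = c(1, 1), K = c(1, 1), A = A), "mutually")
  # cycles pass the constructor but not the spec validation
  A3 <- matrix(0, 3, 3); A3[2, 1] <- 1; A3[3, 2] <- 1; A3[1, 3] <- 1
  up <- uptake_params(mu = rep(1, 3), K = rep(1, 3), A3)
  gr <- growth_params(y_E = rep(20, 3), r_E = 0.4, y_V = 1e-3, m = 0)
  expect_error(synthetic_spec(up, gr, S0 = rep(5, 3)), "DAG")
  expect_error(synthetic_spec(uptake_params(rep(1, 3), rep(1, 3)), gr,
                              S0 = rep(5, 3), noise_level = -0.1), "noise")
})

test_that("the four-substrate demonstration produces its advertised fixtures", {
  sa <- four_substrate_demo_spec("a")
  expect_equal(sa$S0, c(6.7, 6.8, 6.9, 7.0))
  expect_equal(unname(sa$uptake$mu), c(1.0, 0.8, 0.5, 0.5))
  expect_equal(unname(sa$uptake$K), rep(2.5, 4))
  expect_equal(sa$growth$y_E, c(40, 25, 23, 18))
  expect_equal(sa$growth$r_E, 0.35)
  expect_equal(sa$growth$y_V, 0.002)
  expect_equal(sa$growth$m, 0.05)
  edges <- which(sa$uptake$A > 0, arr.ind = TRUE)
  got <- paste(edges[, 2], edges[, 1], sep = ">")  # inhibitor > inhibited
  expect_setequal(got, c("1>2", "1>3", "2>4"))

  sb <- four_substrate_demo_spec("b")
  expect_equal(sb$S0[2], 0)
  expect_equal(sb$S0[-2], sa$S0[-2])
})

test_that("recovery scoring counts edges, alternatives and misses", {
  net <- function(edges) structure(list(nodes = c("S1", "S2", "S3"),
                                        edges = edges),
                                   class = "inhibition_network")
  truth <- data.frame(inhibitor = "S1", inhibited = "S3")
  ed <- function(inh, tgt, grp = NA_character_, primary = TRUE)
    data.frame(inhibitor = inh, inhibited = tgt, a = 1, delta_r2 = 0.2,
               class = "strong", alternative_group = grp, primary = primary,
               stringsAsFactors = FALSE)

  s <- score_recovery(net(ed("S1", "S3")), truth)
  expect_equal(s$precision, 1)
  expect_equal(s$recall, 1)

  s0 <- score_recovery(net(ed("S2", "S3")), truth)
  expect_equal(s0$precision, 0)
  expect_equal(s0$recall, 0)

  # empty network, non-empty truth
  se <- score_recovery(net(ed("S1", "S3")[0, ]), truth)
  expect_equal(se$recall, 0)

  # one correct and one spurious claim
  s2 <- score_recovery(net(rbind(ed("S1", "S3"), ed("S3", "S2"))), truth)
  expect_equal(s2$precision, 0.5)
  expect_equal(s2$recall, 1)

  # alternatives count as one claim, hit if any member matches
  alt <- rbind(ed("S1", "S3", "S3"), ed("S2", "S3", "S3", primary = FALSE))
  sa <- score_recovery(net(alt), truth)
  expect_equal(sa$n_claims, 1)
  expect_equal(sa$precision, 1)
  expect_equal(sa$recall, 1)
})

test_that("edge recovery degrades with noise on matched seeds", {
  # statistical trend over 10 matched seeds: what noise destroys is the
  # discrimination between the true inhibitor and competing candidates (the
  # top-hit rate), not the true candidate's own fit improvement, which is
  # nearly noise-robust until the curves drown
  seeds <- 1:10
  levels <- c(0, 0.05, 0.15)
  hit <- matrix(NA_real_, length(seeds), length(levels))
  for (i in seq_along(seeds)) {
    for (j in seq_along(levels)) {
      exp <- generate_experiment(surrogate_spec(seed = seeds[i],
                                                noise_level = levels[j]))
      tr <- exp$truth$edges
      sc <- scan_target(exp$dataset, tr$inhibited, max_order = 1,
                        restarts = 2, seed = 1)
      tab <- sc$table[order(-sc$table$delta_r2), ]
      hit[i, j] <- as.numeric(identical(tab$candidate[1], tr$inhibitor))
    }
  }
  rate <- colMeans(hit)
  expect_true(all(diff(rate) <= 0))
  expect_gt(rate[1], rate[3])
})
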