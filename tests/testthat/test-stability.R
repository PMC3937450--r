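test_that("resampling plans have the prescribed shapes", {
  loo <- resampling_plan(10, "loo")
  expect_length(loo$subsets, 10)
  expect_true(all(lengths(loo$subsets) == 9))
  expect_false(any(vapply(seq_len(10), function(i) i %in% loo$subsets[[i]],
                          logical(1))))

  kf <- resampling_plan(100, "kfold", k = 4, instances = 10, seed = 1)
  expect_length(kf$subsets, 40)
  expect_true(all(lengths(kf$subsets) == 75))
  # within one instance the four discarded folds partition the samples
  discarded <- lapply(kf$subsets[1:4], function(s) setdiff(1:100, s))
  expect_setequal(unlist(discarded), 1:100)

  sub <- resampling_plan(100, "subsample", r = 50, s = 20, seed = 2)
  expect_length(sub$subsets, 50)
  expect_true(all(lengths(sub$subsets) == 20))
  expect_true(all(vapply(sub$subsets, anyDuplicated, integer(1)) == 0))

  expect_identical(resampling_plan(30, "subsample", r = 5, s = 10, seed = 9),
                   resampling_plan(30, "subsample", r = 5, s = 10, seed = 9))
  expect_error(resampling_plan(10, "subsample", r = 5, s = 10), "s must")
  expect_error(resampling_plan(10, "kfold", k = 11), "k must")
  expect_error(resampling_plan(2, "loo"), "3 samples")
})

test_that("ensembles are deterministic and sized by the plan", {
  x <- netsi:::with_seed(1, matrix(stats::rnorm(20 * 5), 20, 5))
  plan <- resampling_plan(20, "loo")
  ens <- infer_ensemble(x, "cor", plan)
  expect_length(ens$nets, 20)
  expect_s3_class(ens$full_net, "netsi_network")

  # stochastic method: same master seed, same ensemble
  plan2 <- resampling_plan(20, "subsample", r = 4, s = 15, seed = 3)
  e1 <- infer_ensemble(x, "cor_fdr", plan2, alpha = 0.2, n_perm = 49, seed = 7)
  e2 <- infer_ensemble(x, "cor_fdr", plan2, alpha = 0.2, n_perm = 49, seed = 7)
  expect_equal(e1$nets, e2$nets)

  expect_error(infer_ensemble(x, "cor", resampling_plan(10, "loo")),
               "built for n = 10")
})

test_that("a subset equal to the full sample reproduces the full network", {
  x <- netsi:::with_seed(2, matrix(stats::rnorm(15 * 4), 15, 4))
  plan <- resampling_plan(15, "loo")
  plan$subsets <- list(1:15)
  ens <- infer_ensemble(x, "cor", plan)
  expect_equal(ens$nets[[1]], ens$full_net)
  stab <- network_stability(ens, "him")
  expect_equal(stab$S, 0, tolerance = 1e-9)
})

test_that("S and S_I equal means of independently computed distances", {
  x <- netsi:::with_seed(3, matrix(stats::rnorm(12 * 5), 12, 5))
  plan <- resampling_plan(12, "subsample", r = 5, s = 8, seed = 4)
  ens <- infer_ensemble(x, "cor", plan)
  stab <- network_stability(ens, "him", B = 200, seed = 5)

  s_oracle <- vapply(ens$nets, function(g)
    him_distance(ens$full_net, g)$him, numeric(1))
  expect_equal(stab$S_values, s_oracle, tolerance = 1e-10)
  expect_equal(stab$S, mean(s_oracle))

  si_oracle <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    si_oracle <- c(si_oracle, him_distance(ens$nets[[i]], ens$nets[[j]])$him)
  }
  expect_length(stab$SI_values, choose(5, 2))
  expect_equal(sort(stab$SI_values), sort(si_oracle), tolerance = 1e-10)
  expect_equal(stab$S_I, mean(si_oracle))

  # order of subsets is immaterial for the indicator values
  ens_shuf <- ens
  ens_shuf$nets <- ens$nets[c(4, 2, 5, 1, 3)]
  stab_shuf <- network_stability(ens_shuf, "him", B = 200, seed = 5)
  expect_equal(stab_shuf$S, stab$S)
  expect_equal(stab_shuf$S_I, stab$S_I)

  # two resampled networks: S_I is their single distance
  ens2 <- ens
  ens2$nets <- ens$nets[1:2]
  expect_equal(network_stability(ens2)$S_I,
               him_distance(ens$nets[[1]], ens$nets[[2]])$him,
               tolerance = 1e-10)
})

test_that("a data-independent method is perfectly stable", {
  g <- random_network(6, seed = 10)
  ens <- manual_ensemble(g, list(g, g, g, g))
  stab <- network_stability(ens)
  expect_equal(stab$S, 0, tolerance = 1e-9)
  expect_equal(stab$S_I, 0, tolerance = 1e-9)
  ew <- edge_stability(ens)
  expect_true(all(ew$score[!ew$void] == 0))
  nd <- node_stability(ens)
  expect_true(all(nd$score[!nd$void] == 0))
})

test_that("edge and node variability scores are coefficients of variation", {
  a1 <- matrix(0, 3, 3); a2 <- a1
  a1[1, 2] <- a1[2, 1] <- 0.4
  a2[1, 2] <- a2[2, 1] <- 0.6
  a1[1, 3] <- a1[3, 1] <- 0.5
  a2[1, 3] <- a2[3, 1] <- 0.5
  ens <- manual_ensemble(a2, list(a1, a2))

  ew <- edge_stability(ens)
  v12 <- ew[ew$from == "v1" & ew$to == "v2", ]
  expect_equal(v12$score, stats::sd(c(0.4, 0.6)) / 0.5, tolerance = 1e-9)
  expect_equal(round(v12$score, 5), 0.28284)
  v13 <- ew[ew$from == "v1" & ew$to == "v3", ]
  expect_equal(v13$score, 0)  # constant nonzero weight: most stable
  expect_equal(v13$rank, 1L)
  v23 <- ew[ew$from == "v2" & ew$to == "v3", ]
  expect_true(v23$void)       # never wired: void, excluded from ranking
  expect_true(is.na(v23$rank))

  nd <- node_stability(ens)
  expect_false(any(nd$void))  # every node has positive degree somewhere
  d1 <- c(0.9, 1.1)           # degrees of v1 across the two resamples
  expect_equal(nd$score[nd$node == "v1"], stats::sd(d1) / mean(d1),
               tolerance = 1e-9)

  # a never-wired node is void for the degree ranking
  b <- matrix(0, 3, 3); b[1, 2] <- b[2, 1] <- 0.5
  ens2 <- manual_ensemble(b, list(b, b))
  nd2 <- node_stability(ens2)
  expect_true(nd2$void[nd2$node == "v3"])
  # tiny mean with nonzero sd yields a CV far above 1 (least stable)
  c1 <- matrix(0, 3, 3); c2 <- c1
  c1[1, 2] <- c1[2, 1] <- 0.001
  c2[1, 2] <- c2[2, 1] <- 0.1
  nd3 <- node_stability(manual_ensemble(c2, list(c1, c2)))
  expect_gt(max(nd3$score), 1)
})

test_that("bootstrap-t intervals behave and cover the mean", {
  expect_equal(bootstrap_ci(rep(2.5, 6)), c(lo = 2.5, hi = 2.5))
  v <- netsi:::with_seed(20, stats::rnorm(25))
  ci <- bootstrap_ci(v, B = 500, seed = 21)
  expect_lt(ci[1], mean(v))
  expect_gt(ci[2], mean(v))
  expect_identical(bootstrap_ci(v, B = 500, seed = 21),
                   bootstrap_ci(v, B = 500, seed = 21))
  expect_error(bootstrap_ci(1), "2 values")
  expect_error(bootstrap_ci(v, B = 10), "at least 100")

  # empirical coverage of the known mean, Gaussian n=30
  hits <- vapply(1:400, function(i) {
    vv <- netsi:::with_seed(1000 + i, stats::rnorm(30, 3, 2))
    ci <- bootstrap_ci(vv, B = 299, seed = i)
    ci[1] <= 3 && 3 <= ci[2]
  }, logical(1))
  expect_gt(mean(hits), 0.91)
  expect_lt(mean(hits), 0.99)
})

test_that("netsi_run bundles consistent indicators and serializes stably", {
  x <- netsi:::with_seed(30, matrix(stats::rnorm(15 * 5), 15, 5))
  rep1 <- netsi_run(x, method = "cor", scheme = "subsample", r = 5, s = 10,
                    B = 200, seed = 11)
  expect_s3_class(rep1$stability, "netsi_stability")
  expect_gte(rep1$stability$S, 0)
  expect_equal(nrow(rep1$edges), choose(5, 2))
  expect_equal(nrow(rep1$nodes), 5)

  # matches standalone recomputation on the same ensemble
  stab <- network_stability(rep1$ensemble, "him", B = 200,
                            seed = netsi:::child_seed(11, 303L))
  expect_equal(rep1$stability$S, stab$S)
  expect_equal(rep1$stability$ci_S, stab$ci_S)

  # byte-identical JSON on rerun with the same seed
  rep2 <- netsi_run(x, method = "cor", scheme = "subsample", r = 5, s = 10,
                    B = 200, seed = 11)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  netsi:::report_to_json(rep1, f1)
  netsi:::report_to_json(rep2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # broom-style accessors
  g <- glance(rep1)
  expect_equal(g$S, rep1$stability$S)
  td <- tidy(rep1)
  expect_equal(sum(td$indicator == "S"), 5)
  expect_equal(sum(td$indicator == "S_I"), choose(5, 2))
})

test_that("stability is flat across modular structures for correlation nets", {
  s_vals <- vapply(seq(2, 10, by = 2), function(c_) {
    mc <- modular_network(50, c_)
    x <- surrogate_expression(mc$network, m = 50, strength = 0.6,
                              seed = 40 + c_)
    plan <- resampling_plan(50, "subsample", r = 6, s = 40, seed = 50 + c_)
    ens <- infer_ensemble(x, "cor", plan)
    network_stability(ens, "him", B = 200, seed = 1)$S
  }, numeric(1))
  expect_lt(diff(range(s_vals)), 0.1)
})

test_that("the permutation gate stabilizes inference of strong blocks", {
  # two unambiguous blocks: no marginal correlations near the gate boundary
  sigma <- block_correlation_matrix(blocks = list(list(1:5, 0.9),
                                                  list(6:10, 0.7)))
  wins <- 0
  for (s in 1:5) {
    x <- sample_gaussian(sigma, 100, seed = 60 + s)
    plan <- resampling_plan(100, "kfold", k = 2, instances = 1, seed = 70 + s)
    e_fdr <- infer_ensemble(x, "cor_fdr", plan, alpha = 0.001, n_perm = 999,
                            seed = 80 + s)
    e_w <- infer_ensemble(x, "wgcna", plan)
    s_fdr <- network_stability(e_fdr, "him", B = 200, seed = 1)$S
    s_w <- network_stability(e_w, "him", B = 200, seed = 1)$S
    wins <- wins + (s_fdr <= s_w)
  }
  expect_gte(wins, 4)
})

test_that("stability plots build without error", {
  x <- netsi:::with_seed(90, matrix(stats::rnorm(15 * 4), 15, 4))
  rep1 <- netsi_run(x, method = "cor", scheme = "loo", B = 200, seed = 2)
  p1 <- autoplot(rep1)
  expect_s3_class(p1, "ggplot")
  p2 <- plot_stability_ranking(rep1$edges)
  expect_s3_class(p2, "ggplot")
  p3 <- plot_him_plane(tibble::tibble(h = c(0.2, 0.6), im = c(0.1, 0.8)))
  expect_s3_class(p3, "ggplot")
})
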