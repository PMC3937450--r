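make_data <- function(m, p, seed = 1) {
  netsi:::with_seed(seed, {
    x <- matrix(stats::rnorm(m * p), m, p)
    colnames(x) <- paste0("g", seq_len(p))
    x
  })
}

test_that("correlation network captures linear dependence exactly", {
  x <- make_data(30, 1)
  d <- cbind(a = x[, 1], b = 2 * x[, 1] + 1, c = -x[, 1])
  net <- cor_network(d)
  expect_equal(unclass(net)["a", "b"], 1)
  expect_equal(unclass(net)["a", "c"], 1)  # absolute value
  expect_equal(diag(unclass(net)), c(a = 0, b = 0, c = 0))

  big <- make_data(5000, 5, seed = 2)
  expect_lt(max(unclass(cor_network(big))), 0.05)

  bad <- cbind(make_data(10, 2), flat = rep(1, 10))
  expect_error(cor_network(bad), "flat")
})

test_that("soft thresholding is an entrywise power of |r|", {
  x <- make_data(40, 6, seed = 3)
  c1 <- unclass(cor_network(x))
  w6 <- unclass(wgcna_network(x, beta = 6))
  expect_equal(w6, c1^6, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(wgcna_network(x, beta = 1)), c1, tolerance = 1e-15,
               ignore_attr = TRUE)
  expect_true(all(w6 <= c1 + 1e-15))  # monotone soft-thresholding
  expect_error(wgcna_network(x, beta = 0.5), "beta")
})

test_that("biweight midcorrelation is robust and affine-equivariant", {
  x <- make_data(50, 1, seed = 4)
  d <- cbind(a = x[, 1], b = x[, 1])
  expect_equal(unclass(bicor_network(d))["a", "b"], 1, tolerance = 1e-12)

  pair <- contaminated_pair(m = 50, rho = 0.9, outlier = 40, seed = 5)
  bc_clean <- unclass(bicor_network(pair$clean))["x", "y"]
  bc_dirty <- unclass(bicor_network(pair$dirty))["x", "y"]
  pe_clean <- unclass(cor_network(pair$clean))["x", "y"]
  pe_dirty <- unclass(cor_network(pair$dirty))["x", "y"]
  expect_lt(abs(bc_dirty - bc_clean), abs(pe_dirty - pe_clean))

  # affine rescaling of either variable leaves bicor unchanged
  resc <- cbind(x = 3 * pair$clean[, "x"] - 7, y = pair$clean[, "y"] / 2)
  expect_equal(unclass(bicor_network(resc))["x", "y"], bc_clean,
               tolerance = 1e-12)
})

test_that("topological overlap saturates on cliques and stays in [0,1]", {
  x <- make_data(30, 1, seed = 6)
  tri <- cbind(a = x[, 1], b = x[, 1], c = x[, 1])  # perfect triangle
  tm <- unclass(tom_network(tri))
  expect_equal(tm[upper.tri(tm)], rep(1, 3), tolerance = 1e-12)
  rnd <- make_data(40, 7, seed = 7)
  tw <- unclass(tom_network(rnd))
  expect_true(all(tw >= 0 & tw <= 1))
  expect_equal(tw, t(tw))
})

test_that("MI estimator satisfies the entropy identity and independence bound", {
  x <- make_data(100, 1, seed = 8)
  d <- cbind(a = x[, 1], b = x[, 1])
  mi <- mutual_information(d)  # default 5 equal-frequency bins at m=100
  expect_equal(mi["a", "b"], log(5), tolerance = 1e-12)

  big <- netsi:::with_seed(9, matrix(stats::runif(5000 * 3), 5000, 3))
  # with 8 bins the plug-in bias (bins-1)^2 / (2m) is ~0.005
  mi_ind <- mutual_information(big, bins = 8)
  expect_lt(max(mi_ind), 0.05)
  expect_equal(mi_ind, t(mi_ind))
  expect_true(all(mi_ind >= 0))
  expect_error(mutual_information(big, bins = 1), "bins")
})

test_that("ARACNE removes the indirect edge of a Markov chain", {
  dat <- netsi:::with_seed(10, {
    x <- stats::rnorm(2000)
    y <- x + 0.3 * stats::rnorm(2000)
    z <- y + 0.3 * stats::rnorm(2000)
    cbind(x = x, y = y, z = z)
  })
  net <- unclass(aracne_network(dat))
  expect_equal(net["x", "z"], 0)
  expect_gt(net["x", "y"], 0)
  expect_gt(net["y", "z"], 0)
  # brute-force DPI oracle on the MI matrix
  mi <- mutual_information(dat)
  expect_true(mi["x", "z"] < min(mi["x", "y"], mi["y", "z"]))

  # independent columns with a threshold above the noise floor -> empty
  ind <- make_data(500, 4, seed = 11)
  mi_ind <- mutual_information(ind)
  thr <- max(mi_ind) + 1e-9
  expect_equal(sum(unclass(aracne_network(ind, mi_threshold = thr))), 0)

  # two features: no triplets, DPI is a no-op up to max rescaling
  two <- dat[, 1:2]
  a2 <- unclass(aracne_network(two))
  expect_equal(a2["x", "y"], 1)  # single edge rescaled to its own max
})

test_that("CLR scores contrast against each node's MI background", {
  dat <- netsi:::with_seed(12, {
    x <- stats::rnorm(300)
    cbind(a = x, b = x + 0.2 * stats::rnorm(300),
          c = stats::rnorm(300), d = stats::rnorm(300), e = stats::rnorm(300))
  })
  net <- unclass(clr_network(dat))
  expect_equal(net, t(net))
  top <- which(net == max(net), arr.ind = TRUE)[1, ]
  expect_setequal(rownames(net)[top], c("a", "b"))
  expect_error(clr_network(dat[, 1:2]), "3 features")

  # feature permutation equivariance
  perm <- c(3, 5, 1, 2, 4)
  net_p <- unclass(clr_network(dat[, perm]))
  expect_equal(net_p, net[perm, perm], tolerance = 1e-12)
  ar <- unclass(aracne_network(dat))
  ar_p <- unclass(aracne_network(dat[, perm]))
  expect_equal(ar_p, ar[perm, perm], tolerance = 1e-12)
})

test_that("MIC saturates on functional relationships", {
  x <- netsi:::with_seed(13, stats::rnorm(50))
  expect_equal(mic_statistic(x, x), 1, tolerance = 1e-9)
  expect_equal(mic_statistic(x, -2 * x + 5), 1, tolerance = 1e-9)
  x2 <- netsi:::with_seed(14, stats::rnorm(100))
  expect_gte(mic_statistic(x2, x2^2), 0.9)
  y <- netsi:::with_seed(15, stats::rnorm(100))
  expect_equal(mic_statistic(x2, y), mic_statistic(y, x2), tolerance = 1e-12)
  expect_lt(mic_statistic(x2, y), 0.5)
  expect_error(mic_statistic(x2[1:5], y[1:5]), "too small")
  net <- mic_network(cbind(a = x2, b = x2, c = y))
  expect_equal(unclass(net)["a", "b"], 1, tolerance = 1e-9)
})

test_that("permutation gate keeps certain edges and rejects unattainable alpha", {
  x <- netsi:::with_seed(16, stats::rnorm(100))
  d <- cbind(a = x, b = x, c = netsi:::with_seed(17, stats::rnorm(100)))
  net <- fdr_network(d, alpha = 0.05, n_perm = 999, seed = 1)
  expect_equal(unclass(net)["a", "b"], 1)  # p = 1/1000 for an exact copy
  expect_error(fdr_network(d, alpha = 0.0001, n_perm = 99), "unattainable")
  expect_error(fdr_network(d, alpha = 0.05, n_perm = 10), "n_perm")

  # wgcna measure gates on |r| but outputs |r|^beta
  net_w <- fdr_network(d, alpha = 0.05, n_perm = 99, measure = "wgcna",
                       beta = 6, seed = 1)
  expect_equal(unclass(net_w)["a", "b"], 1)
  kept <- unclass(net_w) > 0
  expect_equal(unclass(net_w)[kept],
               (abs(stats::cor(d))^6)[kept], tolerance = 1e-12)
})

test_that("every inference method returns a valid network surface", {
  x <- make_data(40, 8, seed = 18)
  methods <- list(
    cor = cor_network(x),
    wgcna = wgcna_network(x),
    bicor = bicor_network(x),
    tom = tom_network(x),
    aracne = aracne_network(x),
    clr = clr_network(x),
    mic = mic_network(x),
    cor_fdr = fdr_network(x, alpha = 0.1, n_perm = 49, seed = 3)
  )
  for (nm in names(methods)) {
    w <- unclass(methods[[nm]])
    expect_true(all(w >= 0 & w <= 1), label = paste(nm, "range"))
    expect_equal(w, t(w), label = paste(nm, "symmetry"))
    expect_equal(max(abs(diag(w))), 0, label = paste(nm, "diagonal"))
  }
  # dispatcher routes by name
  expect_equal(infer_network(x, "wgcna", beta = 2),
               wgcna_network(x, beta = 2))
})
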