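# shared fixture builders (all generated in code; no files)

# random symmetric weighted network with weights in [0, 1]
random_network <- function(n, density = 0.5, weighted = TRUE, seed = NULL) {
  netsi:::with_seed(seed, {
    a <- matrix(0, n, n)
    up <- upper.tri(a)
    w <- ifelse(stats::runif(sum(up)) < density,
                if (weighted) stats::runif(sum(up)) else 1, 0)
    a[up] <- w
    a <- a + t(a)
    as_network(a)
  })
}

# path graph on n nodes (unit weights)
path_network <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  as_network(a)
}

# hand-built ensemble from an explicit list of adjacency matrices
manual_ensemble <- function(full, nets, n_samples = 10) {
  plan <- resampling_plan(n_samples, "loo")
  plan$subsets <- plan$subsets[seq_along(nets)]
  structure(
    list(full_net = as_network(full), nets = lapply(nets, as_network),
         method = "manual", args = list(), seed = NULL, plan = plan),
    class = "netsi_ensemble"
  )
}

# correlated bivariate sample with one contaminated entry
contaminated_pair <- function(m = 50, rho = 0.9, outlier = 50, seed = 1) {
  netsi:::with_seed(seed, {
    x <- stats::rnorm(m)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(m)
    clean <- cbind(x = x, y = y)
    dirty <- clean
    dirty[1, "y"] <- outlier
    list(clean = clean, dirty = dirty)
  })
}
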