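#' Modular benchmark network of bridged cliques
#'
#' Builds the 50-node family of benchmark networks: `modules` fully
#' connected subgroups of equal-as-possible size, consecutive modules joined
#' by exactly one unweighted edge between their lowest-index nodes. With the
#' default `"ring"` topology the last module is also linked back to the
#' first (for `modules = 2` that closing edge coincides with the bridge, so
#' ring and chain agree); `"chain"` omits the closing link. `modules = 1`
#' returns the complete loop-free network.
#'
#' @param n Total node count (default 50).
#' @param modules Number of modules `c` (1 to `n`).
#' @param topology `"ring"` (default) or `"chain"` inter-module linking.
#' @return A list with `network` (a `netsi_network`) and `membership`
#'   (integer vector of module indices, the design partition).
#' @examples
#' m5 <- modular_network(50, 5)
#' net_density(m5$network)
#' net_modularity(m5$network, m5$membership)
#' @export
modular_network <- function(n = 50, modules = 2,
                            topology = c("ring", "chain")) {
  topology <- match.arg(topology)
  n <- as.integer(n)
  modules <- as.integer(modules)
  if (modules < 1 || modules > n) {
    stop("modules must be between 1 and n", call. = FALSE)
  }
  sizes <- rep(n %/% modules, modules)
  extra <- n %% modules
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  membership <- rep(seq_len(modules), times = sizes)
  a <- matrix(0, n, n)
  start <- cumsum(c(1L, sizes[-modules]))
  for (g in seq_len(modules)) {
    idx <- which(membership == g)
    a[idx, idx] <- 1
  }
  diag(a) <- 0
  if (modules >= 2) {
    links <- cbind(seq_len(modules - 1), seq_len(modules - 1) + 1L)
    if (topology == "ring") links <- rbind(links, c(modules, 1L))
    for (rw in seq_len(nrow(links))) {
      u <- start[links[rw, 1]]
      v <- start[links[rw, 2]]
      a[u, v] <- a[v, u] <- 1
    }
  }
  list(network = as_network(a), membership = membership)
}

#' Block-structured correlation matrix
#'
#' Builds the design correlation matrix behind the block-correlated
#' Gaussian dataset: unit diagonal, constant correlation within each listed
#' feature block, `background` elsewhere. The default (20 features) has two
#' strongly correlated blocks (features 1-5 at 0.9 and 6-10 at 0.7), one
#' moderate block (11-15 at 0.3), five free features, and zero background.
#' Positive definiteness is verified by Cholesky decomposition.
#'
#' @param p Number of features.
#' @param blocks List of `list(range, rho)` pairs with disjoint index ranges
#'   and correlations in `(-1, 1)`.
#' @param background Off-block correlation (default 0).
#' @return A `p x p` correlation matrix.
#' @export
block_correlation_matrix <- function(p = 20,
                                     blocks = list(list(1:5, 0.9),
                                                   list(6:10, 0.7),
                                                   list(11:15, 0.3)),
                                     background = 0) {
  sigma <- matrix(background, p, p)
  used <- integer(0)
  for (b in blocks) {
    idx <- b[[1]]
    rho <- b[[2]]
    if (any(idx < 1) || any(idx > p)) stop("block range outside 1..p", call. = FALSE)
    if (any(idx %in% used)) stop("block ranges must be disjoint", call. = FALSE)
    if (rho <= -1 || rho >= 1) stop("block correlation must be in (-1, 1)",
                                    call. = FALSE)
    used <- c(used, idx)
    sigma[idx, idx] <- rho
  }
  diag(sigma) <- 1
  ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
  if (!ok) {
    stop("requested correlation matrix is not positive definite; ",
         "reduce block correlations or add diagonal jitter", call. = FALSE)
  }
  dimnames(sigma) <- list(paste0("v", seq_len(p)), paste0("v", seq_len(p)))
  sigma
}

#' Sample multivariate Gaussian data from a correlation matrix
#'
#' Draws `m` i.i.d. rows `z %*% t(chol(sigma))` with standard normal `z`:
#' the Cholesky construction of correlated Gaussian features.
#'
#' @param sigma Positive-definite correlation (or covariance) matrix.
#' @param m Number of samples.
#' @param seed Integer seed.
#' @return An `m x p` matrix with feature labels from `sigma`'s dimnames.
#' @export
sample_gaussian <- function(sigma, m, seed = NULL) {
  sigma <- as.matrix(sigma)
  L <- tryCatch(chol(sigma), error = function(e) {
    stop("sigma is not positive definite", call. = FALSE)
  })
  p <- ncol(sigma)
  x <- with_seed(seed, matrix(stats::rnorm(m * p), m, p) %*% L)
  colnames(x) <- colnames(sigma)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(p))
  x
}

#' Gaussian expression surrogate for a network
#'
#' Desk-scale linear-Gaussian stand-in for a kinetic regulatory simulator:
#' the target correlation matrix is `I + strength * A`, shrunk toward the
#' identity until positive definite, then sampled with [sample_gaussian()].
#' Adjacent nodes thus receive higher expected sample correlation than
#' non-adjacent ones; no regulatory dynamics are emulated.
#'
#' @param net A `netsi_network`.
#' @param m Number of samples.
#' @param strength Off-diagonal correlation scale in `(0, 1)`.
#' @param seed Integer seed.
#' @return An `m x n` expression matrix, features = nodes.
#' @export
surrogate_expression <- function(net, m, strength = 0.6, seed = NULL) {
  net <- as_network(net)
  if (!is.numeric(strength) || length(strength) != 1 ||
      strength <= 0 || strength >= 1) {
    stop("strength must be in (0, 1)", call. = FALSE)
  }
  a <- unclass(net)
  n <- nrow(a)
  sigma <- diag(n) + strength * a
  ev_min <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 1e-8) {
    # shrink toward I so the smallest eigenvalue clears a safe floor
    lam <- (1e-6 - ev_min) / (1 - ev_min)
    sigma <- (1 - lam) * sigma + lam * diag(n)
    # renormalize to unit diagonal (shrinkage preserves it here, but be safe)
    d <- sqrt(diag(sigma))
    sigma <- sigma / tcrossprod(d)
  }
  dimnames(sigma) <- list(node_labels(net), node_labels(net))
  sample_gaussian(sigma, m, seed)
}
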