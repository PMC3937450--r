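#' Construct a weighted undirected network
#'
#' The basic container consumed by every distance and stability function in
#' the package: a simple undirected graph on `n` nodes stored as a symmetric
#' adjacency matrix with weights in `[0, 1]` and a zero diagonal.
#'
#' Small asymmetries (up to `1e-6`, e.g. file round-trip noise) are repaired
#' by averaging `(A + t(A)) / 2`; larger ones raise an error, since directed
#' networks are out of scope. The diagonal is forced to zero (tolerance
#' `1e-12`).
#'
#' @param adjacency Square numeric matrix of link weights in `[0, 1]`.
#' @param labels Optional character vector of unique node labels; defaults to
#'   the matrix dimnames or `"v1".."vn"`.
#' @return An object of class `netsi_network`: the validated adjacency matrix
#'   with node labels as dimnames.
#' @examples
#' a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- 0.5
#' net <- as_network(a)
#' net_density(net)
#' @export
as_network <- function(adjacency, labels = NULL) {
  if (inherits(adjacency, "netsi_network")) return(adjacency)
  adjacency <- as.matrix(adjacency)
  if (!is.numeric(adjacency)) stop("adjacency must be numeric", call. = FALSE)
  if (nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency must be square, got ", nrow(adjacency), "x", ncol(adjacency),
         call. = FALSE)
  }
  n <- nrow(adjacency)
  if (n < 1L) stop("network needs at least one node", call. = FALSE)
  if (anyNA(adjacency)) stop("adjacency contains missing values", call. = FALSE)
  asym <- max(abs(adjacency - t(adjacency)))
  if (asym > 1e-6) {
    stop("adjacency is asymmetric (max |A - t(A)| = ", signif(asym, 3),
         "); directed networks are not supported", call. = FALSE)
  }
  adjacency <- (adjacency + t(adjacency)) / 2
  if (any(abs(diag(adjacency)) > 1e-12)) {
    stop("diagonal entries must be zero (no self-loops)", call. = FALSE)
  }
  diag(adjacency) <- 0
  tol <- 1e-12
  if (any(adjacency < -tol) || any(adjacency > 1 + tol)) {
    bad <- range(adjacency)
    stop("link weights must lie in [0, 1]; observed range [",
         signif(bad[1], 4), ", ", signif(bad[2], 4),
         "]. Rescale weights before building the network.", call. = FALSE)
  }
  adjacency[adjacency < 0] <- 0
  adjacency[adjacency > 1] <- 1
  if (is.null(labels)) {
    labels <- rownames(adjacency)
    if (is.null(labels)) labels <- paste0("v", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n) stop("need ", n, " node labels", call. = FALSE)
  if (anyDuplicated(labels)) stop("node labels must be unique", call. = FALSE)
  dimnames(adjacency) <- list(labels, labels)
  structure(adjacency, class = c("netsi_network", "matrix", "array"))
}

#' @export
print.netsi_network <- function(x, ...) {
  n <- nrow(x)
  nedges <- sum(x[upper.tri(x)] > 0)
  cat("<netsi_network> ", n, " nodes, ", nedges, " edges",
      if (n >= 2) sprintf(", density %.3f", net_density(x)), "\n", sep = "")
  invisible(x)
}

#' Empty and complete reference networks
#'
#' `empty_network(n)` has no edges; `full_network(n)` is the complete
#' (loop-free) graph with unit weights. The pair defines the normalization of
#' the Hamming and Ipsen-Mikhailov distances: they are the two complementary
#' extremes at distance 1.
#'
#' @param n Node count.
#' @param labels Optional node labels.
#' @return A `netsi_network`.
#' @export
empty_network <- function(n, labels = NULL) {
  as_network(matrix(0, n, n), labels)
}

#' @rdname empty_network
#' @export
full_network <- function(n, labels = NULL) {
  a <- matrix(1, n, n)
  diag(a) <- 0
  as_network(a, labels)
}

node_labels <- function(net) rownames(net)

#' Network density
#'
#' Fraction of realized edges: the number of node pairs with weight > 0 over
#' `n(n-1)/2`. For binary networks this is the usual edge density.
#'
#' @param net A `netsi_network`.
#' @return A number in `[0, 1]`.
#' @export
net_density <- function(net) {
  net <- as_network(net)
  n <- nrow(net)
  if (n < 2) stop("density undefined for networks with fewer than 2 nodes",
                  call. = FALSE)
  sum(net[upper.tri(net)] > 0) / (n * (n - 1) / 2)
}

#' Weighted degree vector
#'
#' Row sums of the adjacency matrix; equals the integer degree for binary
#' networks.
#'
#' @param net A `netsi_network`.
#' @return Named numeric vector of length `n`.
#' @export
net_degree <- function(net) {
  net <- as_network(net)
  rowSums(unclass(net))
}

#' Graph Laplacian
#'
#' `L = D - A` with `D` the diagonal matrix of weighted degrees. `L` is
#' symmetric positive semidefinite with zero row sums; its eigenvalues are
#' the squared natural vibrational frequencies used by the Ipsen-Mikhailov
#' distance.
#'
#' @param net A `netsi_network`.
#' @return An `n x n` numeric matrix.
#' @export
net_laplacian <- function(net) {
  net <- as_network(net)
  a <- unclass(net)
  diag(rowSums(a), nrow(a)) - a
}

#' Newman-Girvan modularity of a fixed partition
#'
#' Evaluates `Q = sum_i (e_ii - a_i^2)` over communities, where `e_ii` is the
#' fraction of edge weight inside community `i` and `a_i` the fraction of
#' edge endpoints attached to community `i`. For binary networks this is the
#' standard unweighted Newman-Girvan modularity; weighted networks use weight
#' fractions. The partition is supplied, never inferred.
#'
#' @param net A `netsi_network` with at least one edge.
#' @param membership Integer/character vector of length `n` assigning each
#'   node to a community.
#' @return The modularity `Q` (at most 1, may be negative).
#' @export
net_modularity <- function(net, membership) {
  net <- as_network(net)
  a <- unclass(net)
  n <- nrow(a)
  if (length(membership) != n) {
    stop("membership must assign all ", n, " nodes", call. = FALSE)
  }
  w2 <- sum(a)  # 2 * total edge weight
  if (w2 <= 0) stop("modularity undefined for a network with no edges",
                    call. = FALSE)
  groups <- split(seq_len(n), membership)
  q <- 0
  for (idx in groups) {
    e_ii <- sum(a[idx, idx, drop = FALSE]) / w2
    a_i <- sum(a[idx, , drop = FALSE]) / w2
    q <- q + e_ii - a_i^2
  }
  q
}

#' Network complement
#'
#' Off-diagonal weights are mapped `w -> 1 - w`, so the complement of the
#' empty network is the full network and `complement(complement(G)) = G`.
#'
#' @param net A `netsi_network`.
#' @return A `netsi_network`.
#' @export
net_complement <- function(net) {
  net <- as_network(net)
  a <- 1 - unclass(net)
  diag(a) <- 0
  as_network(a, node_labels(net))
}

#' Binarize a weighted network
#'
#' Weights strictly greater than `threshold` become 1, the rest 0.
#'
#' @param net A `netsi_network`.
#' @param threshold Cut point in `(0, 1)`.
#' @return An unweighted `netsi_network`.
#' @export
net_binarize <- function(net, threshold) {
  net <- as_network(net)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single number in (0, 1)", call. = FALSE)
  }
  as_network((unclass(net) > threshold) * 1, node_labels(net))
}

# Align net2's node order to net1's labels. Returns net2 reordered, warning
# when the orders differ. Errors on different node counts or label sets.
align_networks <- function(net1, net2, warn = TRUE) {
  if (nrow(net1) != nrow(net2)) {
    stop("networks have different node counts (", nrow(net1), " vs ",
         nrow(net2), ")", call. = FALSE)
  }
  l1 <- node_labels(net1)
  l2 <- node_labels(net2)
  if (identical(l1, l2)) return(net2)
  if (setequal(l1, l2)) {
    if (warn) warning("node orders differ; realigning by label", call. = FALSE)
    return(as_network(unclass(net2)[l1, l1], l1))
  }
  # disjoint label sets: compare positionally
  net2
}

#' Convert a network to a tidy edge table
#'
#' @param x A `netsi_network`.
#' @param ... Unused.
#' @param keep_zero Keep zero-weight pairs? Default drops them.
#' @return A tibble with columns `from`, `to`, `weight` (upper triangle only).
#' @export
tidy.netsi_network <- function(x, keep_zero = FALSE, ...) {
  a <- unclass(x)
  idx <- which(upper.tri(a), arr.ind = TRUE)
  out <- tibble::tibble(
    from = rownames(a)[idx[, 1]],
    to = colnames(a)[idx[, 2]],
    weight = a[idx]
  )
  if (!keep_zero) out <- out[out$weight > 0, ]
  out
}
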