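#' @keywords internal
# Natural vibrational frequencies: square roots of Laplacian eigenvalues,
# ascending. Tiny negative eigenvalues from roundoff are clipped at 0.
laplacian_frequencies <- function(net) {
  ev <- eigen(net_laplacian(net), symmetric = TRUE, only.values = TRUE)$values
  sort(sqrt(pmax(ev, 0)))
}

# Normalization constant K of the Lorentzian spectral density: each mode
# contributes the closed-form integral of a Lorentzian over [0, Inf),
# arctan(w_i / gamma) + pi/2, so that the total density integrates to 1.
lorentz_K <- function(freqs, gamma) {
  1 / sum(atan(freqs / gamma) + pi / 2)
}

# Vectorized Lorentzian spectral density rho(omega) for a frequency list.
lorentz_density <- function(omega, freqs, gamma, K = lorentz_K(freqs, gamma)) {
  d <- outer(omega, freqs, function(w, f) gamma / ((w - f)^2 + gamma^2))
  K * rowSums(d)
}

#' Lorentzian-smoothed Laplacian spectral density
#'
#' Represents a network by the density `rho(omega) = K sum_i gamma /
#' ((omega - omega_i)^2 + gamma^2)` over its natural vibrational frequencies
#' `omega_i = sqrt(lambda_i)` (Laplacian eigenvalues `lambda_i`, including the
#' zero mode), normalized to integrate to 1 on `[0, Inf)`. `gamma` is the
#' common half-width at half-maximum of the Lorentzian bells.
#'
#' @param net A `netsi_network`.
#' @param gamma Positive Lorentz width; defaults to the calibrated width for
#'   the network's node count.
#' @return A list of class `netsi_spectral_density` with elements
#'   `frequencies`, `gamma`, `K` and the density function `density(omega)`.
#' @export
spectral_density <- function(net, gamma = NULL) {
  net <- as_network(net)
  if (is.null(gamma)) gamma <- calibrate_gamma(nrow(net))
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    stop("gamma must be a single positive number", call. = FALSE)
  }
  freqs <- laplacian_frequencies(net)
  K <- lorentz_K(freqs, gamma)
  structure(
    list(frequencies = freqs, gamma = gamma, K = K,
         density = function(omega) lorentz_density(omega, freqs, gamma, K)),
    class = "netsi_spectral_density"
  )
}

# L2 distance between two Lorentzian spectral densities, integrated over
# [0, Inf). The integrand is smooth with peaks at the frequencies, so we
# integrate piecewise between the (deduplicated) peak locations and add the
# analytic-decay tail via an infinite-range call.
im_integral <- function(f1, f2, gamma) {
  K1 <- lorentz_K(f1, gamma)
  K2 <- lorentz_K(f2, gamma)
  g <- function(omega) {
    (lorentz_density(omega, f1, gamma, K1) -
       lorentz_density(omega, f2, gamma, K2))^2
  }
  knots <- sort(c(0, f1, f2))
  knots <- knots[c(TRUE, diff(knots) > 1e-8)]
  upper <- max(knots) + 30 * gamma
  # extra breakpoints flanking each peak so narrow Lorentzians (small gamma)
  # are resolved by the adaptive rule
  flank <- as.vector(outer(knots, gamma * c(-100, -10, -1, 1, 10, 100), `+`))
  pts <- sort(unique(c(knots, flank[flank > 0 & flank < upper], upper)))
  pts <- pts[c(TRUE, diff(pts) > 1e-12)]
  total <- 0
  for (i in seq_len(length(pts) - 1)) {
    total <- total + stats::integrate(
      g, pts[i], pts[i + 1],
      rel.tol = 1e-10, abs.tol = 1e-13, subdivisions = 400L
    )$value
  }
  tail <- stats::integrate(g, upper, Inf, rel.tol = 1e-9, abs.tol = 1e-13,
                           subdivisions = 400L)$value
  sqrt(total + tail)
}

# frequencies of the two calibration extremes on n nodes: the edgeless
# network (all-zero spectrum) and the complete graph (eigenvalue n with
# multiplicity n - 1).
freq_empty <- function(n) rep(0, n)
freq_full <- function(n) c(0, rep(sqrt(n), n - 1))

# per-session cache of calibrated widths, keyed by node count
gamma_cache <- new.env(parent = emptyenv())

#' Calibrate the Ipsen-Mikhailov Lorentz width
#'
#' Solves for the unique width `gamma` at which the raw spectral distance
#' between the empty and the complete network on `n` nodes equals 1, so that
#' the normalized Ipsen-Mikhailov distance attains its maximum 1 exactly on
#' that extreme pair. The solution is found by bracketed root finding
#' (bracket expanded from `(1e-4, 10)` as needed) and cached per `n`.
#'
#' @param n Node count (>= 2).
#' @param tol Tolerance on `|IM(E_n, F_n) - 1|`.
#' @return The calibrated width, a positive scalar.
#' @export
calibrate_gamma <- function(n, tol = 1e-6) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    stop("n must be a single integer >= 2", call. = FALSE)
  }
  key <- as.character(as.integer(n))
  hit <- gamma_cache[[key]]
  if (!is.null(hit)) return(hit)
  fe <- freq_empty(n)
  ff <- freq_full(n)
  f <- function(gamma) im_integral(fe, ff, gamma) - 1
  lo <- 1e-4
  hi <- 10
  flo <- f(lo)
  fhi <- f(hi)
  tries <- 0
  while (flo * fhi > 0 && tries < 60) {
    if (abs(flo) < abs(fhi)) { lo <- lo / 4; flo <- f(lo) }
    else { hi <- hi * 4; fhi <- f(hi) }
    tries <- tries + 1
  }
  if (flo * fhi > 0) {
    stop("failed to bracket the calibration root for n = ", n,
         " (f(", signif(lo, 3), ") = ", signif(flo, 3),
         ", f(", signif(hi, 3), ") = ", signif(fhi, 3), ")", call. = FALSE)
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  if (abs(f(root)) > tol) {
    stop("gamma calibration did not reach tolerance for n = ", n, call. = FALSE)
  }
  gamma_cache[[key]] <- root
  root
}

#' Normalized Hamming distance between two networks
#'
#' Mean absolute entrywise difference of the adjacency matrices over the
#' `n(n-1)/2` node pairs: the fraction of mismatched links for unweighted
#' networks. 0 only for identical adjacencies; 1 for complementary networks.
#'
#' @param net1,net2 `netsi_network` objects on the same node set.
#' @return A number in `[0, 1]`.
#' @export
hamming_distance <- function(net1, net2) {
  net1 <- as_network(net1)
  net2 <- align_networks(net1, as_network(net2))
  n <- nrow(net1)
  if (n < 2) stop("distance undefined for single-node networks", call. = FALSE)
  sum(abs(unclass(net1) - unclass(net2))) / (n * (n - 1))
}

#' Normalized Ipsen-Mikhailov spectral distance
#'
#' L2 distance between the Lorentzian-smoothed Laplacian spectral densities
#' of the two networks, divided by its maximal value (attained by the
#' empty-vs-full pair). With the calibrated width (the default) the divisor
#' is 1 by construction. Isospectral networks -- in particular isomorphic
#' ones -- are at distance 0.
#'
#' @param net1,net2 `netsi_network` objects on the same node set.
#' @param gamma Lorentz width; default is the calibrated width for `n`.
#' @return A number in `[0, 1]`.
#' @export
ipsen_mikhailov_distance <- function(net1, net2, gamma = NULL) {
  net1 <- as_network(net1)
  net2 <- align_networks(net1, as_network(net2))
  n <- nrow(net1)
  if (n < 2) stop("distance undefined for single-node networks", call. = FALSE)
  calibrated <- is.null(gamma)
  if (calibrated) gamma <- calibrate_gamma(n)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  f1 <- laplacian_frequencies(net1)
  f2 <- laplacian_frequencies(net2)
  raw <- im_integral(f1, f2, gamma)
  scale <- if (calibrated) 1 else im_integral(freq_empty(n), freq_full(n), gamma)
  min(raw / scale, 1)
}

him_combine <- function(h, im, xi) sqrt(h^2 + xi * im^2) / sqrt(1 + xi)

#' The Hamming-Ipsen-Mikhailov (HIM) network distance
#'
#' The product metric `HIM_xi = sqrt(H^2 + xi * IM^2) / sqrt(1 + xi)`
#' combining the local Hamming component with the global spectral
#' Ipsen-Mikhailov component; `xi` weights the spectral term and the leading
#' factor renormalizes the upper bound to 1 (attained by the empty-vs-full
#' pair).
#'
#' @param net1,net2 `netsi_network` objects on the same node set.
#' @param xi Positive combination factor; default 1.
#' @param gamma Optional Lorentz width passed to the IM component.
#' @return A one-row tibble with columns `h`, `im`, `him`, `xi`.
#' @examples
#' e <- empty_network(6)
#' f <- full_network(6)
#' him_distance(e, f)  # h = im = him = 1
#' @export
him_distance <- function(net1, net2, xi = 1, gamma = NULL) {
  if (!is.numeric(xi) || length(xi) != 1 || xi <= 0) {
    stop("xi must be a single positive number", call. = FALSE)
  }
  h <- hamming_distance(net1, net2)
  im <- ipsen_mikhailov_distance(net1, net2, gamma)
  tibble::tibble(h = h, im = im, him = him_combine(h, im, xi), xi = xi)
}

# Fast path for repeated distances over a fixed network collection:
# adjacency list + precomputed frequency list, calibrated gamma computed once.
pairwise_distances <- function(adjs, freqs, metric = "him", xi = 1,
                               gamma = NULL, pairs) {
  n <- nrow(adjs[[1]])
  need_im <- metric %in% c("him", "im")
  if (need_im && is.null(gamma)) gamma <- calibrate_gamma(n)
  vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]
    j <- pairs[r, 2]
    h <- if (metric %in% c("him", "h"))
      sum(abs(adjs[[i]] - adjs[[j]])) / (n * (n - 1)) else 0
    im <- if (need_im) min(im_integral(freqs[[i]], freqs[[j]], gamma), 1) else 0
    switch(metric, h = h, im = im, him = him_combine(h, im, xi))
  }, numeric(1))
}

#' Pairwise distance matrix over a list of networks
#'
#' @param nets List of `netsi_network` objects sharing node count and order.
#' @param metric `"him"`, `"h"` (Hamming) or `"im"` (Ipsen-Mikhailov).
#' @param xi Combination factor for `"him"`.
#' @return A symmetric matrix with zero diagonal; dimnames from the list
#'   names when present.
#' @export
net_distance_matrix <- function(nets, metric = c("him", "h", "im"), xi = 1) {
  metric <- match.arg(metric)
  nets <- lapply(nets, as_network)
  if (length(nets) < 2) stop("need at least two networks", call. = FALSE)
  sizes <- vapply(nets, nrow, integer(1))
  if (length(unique(sizes)) != 1) {
    stop("all networks must share the same node count", call. = FALSE)
  }
  nets[-1] <- lapply(nets[-1], function(g) align_networks(nets[[1]], g))
  adjs <- lapply(nets, unclass)
  freqs <- if (metric %in% c("him", "im")) {
    lapply(nets, laplacian_frequencies)
  } else {
    vector("list", length(nets))
  }
  m <- length(nets)
  pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  vals <- pairwise_distances(adjs, freqs, metric, xi, pairs = pairs)
  out <- matrix(0, m, m, dimnames = list(names(nets), names(nets)))
  out[pairs] <- vals
  out[pairs[, 2:1, drop = FALSE]] <- vals
  out
}
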