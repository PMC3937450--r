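#' Build a resampling plan
#'
#' The subset schemes under which network inference is repeated:
#' \describe{
#'   \item{`"loo"`}{leave-one-out: `n` subsets of size `n - 1`.}
#'   \item{`"kfold"`}{`instances` independent shuffles split into `k` folds;
#'     each subset is the *retained* training portion (the complement of one
#'     fold), giving `k * instances` subsets.}
#'   \item{`"subsample"`}{`r` random subsets of `s` samples each.}
#' }
#' Deterministic given `seed`.
#'
#' @param n Total sample count (>= 3).
#' @param scheme `"loo"`, `"kfold"` or `"subsample"`.
#' @param k Folds for `"kfold"` (2 <= k <= n).
#' @param instances Number of k-fold repetitions (default 10).
#' @param r Number of subsets for `"subsample"`.
#' @param s Subset size for `"subsample"` (1 <= s < n).
#' @param seed Integer seed.
#' @return An object of class `netsi_plan`.
#' @export
resampling_plan <- function(n, scheme = c("loo", "kfold", "subsample"),
                            k = 5, instances = 10, r = 50, s = NULL,
                            seed = NULL) {
  scheme <- match.arg(scheme)
  n <- as.integer(n)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  subsets <- switch(scheme,
    loo = lapply(seq_len(n), function(i) setdiff(seq_len(n), i)),
    kfold = {
      k <- as.integer(k)
      if (k < 2 || k > n) stop("k must satisfy 2 <= k <= n", call. = FALSE)
      with_seed(seed, {
        out <- list()
        for (inst in seq_len(instances)) {
          fold <- sample(rep_len(seq_len(k), n))
          for (f in seq_len(k)) {
            out[[length(out) + 1L]] <- which(fold != f)
          }
        }
        out
      })
    },
    subsample = {
      if (is.null(s)) stop("subsample scheme needs a subset size s", call. = FALSE)
      s <- as.integer(s)
      if (s < 1 || s >= n) stop("s must satisfy 1 <= s < n", call. = FALSE)
      with_seed(seed, {
        lapply(seq_len(r), function(i) sort(sample.int(n, s)))
      })
    }
  )
  structure(
    list(scheme = scheme, subsets = subsets, n = n, seed = seed,
         params = switch(scheme,
                         loo = list(),
                         kfold = list(k = k, instances = instances),
                         subsample = list(r = r, s = s))),
    class = "netsi_plan"
  )
}

#' @export
print.netsi_plan <- function(x, ...) {
  cat("<netsi_plan> ", x$scheme, ": ", length(x$subsets), " subsets of ",
      paste(unique(lengths(x$subsets)), collapse = "/"), " of ", x$n,
      " samples\n", sep = "")
  invisible(x)
}

#' Infer the network ensemble for a resampling plan
#'
#' Reconstructs the network once from the full dataset and once per plan
#' subset with identical settings. Stochastic methods receive a fresh child
#' seed per subset derived from the master `seed` by a counter scheme, so
#' results do not depend on execution order.
#'
#' @inheritParams infer_network
#' @param plan A `netsi_plan` whose `n` matches `nrow(data)`.
#' @param seed Master seed forwarded (as child seeds) to stochastic methods.
#' @return An object of class `netsi_ensemble`: list with `full_net`,
#'   `nets`, `method`, `args`, `plan`.
#' @export
infer_ensemble <- function(data, method, plan, ..., seed = NULL) {
  x <- as_expression_matrix(data)
  if (!inherits(plan, "netsi_plan")) stop("plan must be a netsi_plan", call. = FALSE)
  if (plan$n != nrow(x)) {
    stop("plan was built for n = ", plan$n, " but data has ", nrow(x),
         " samples", call. = FALSE)
  }
  args <- list(...)
  stochastic <- method %in% c("cor_fdr", "wgcna_fdr", "mic_fdr")
  infer_one <- function(rows, idx) {
    a <- args
    if (stochastic) a$seed <- child_seed(seed, idx)
    tryCatch(
      do.call(infer_network,
              c(list(data = x[rows, , drop = FALSE], method = method), a)),
      error = function(e) {
        stop("inference failed on subset ", idx, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
  }
  full_net <- infer_one(seq_len(nrow(x)), 0L)
  nets <- lapply(seq_along(plan$subsets), function(i) {
    infer_one(plan$subsets[[i]], i)
  })
  structure(
    list(full_net = full_net, nets = nets, method = method, args = args,
         seed = seed, plan = plan),
    class = "netsi_ensemble"
  )
}

#' @export
print.netsi_ensemble <- function(x, ...) {
  cat("<netsi_ensemble> method ", x$method, ": full network + ",
      length(x$nets), " resampled networks on ", nrow(x$full_net),
      " nodes\n", sep = "")
  invisible(x)
}

#' Studentized bootstrap confidence interval for a mean
#'
#' Bootstrap-t interval: `B` resamples with replacement give the pivot
#' `t* = (mean* - mean) / se*`, and the interval is
#' `mean - quantile(t*, c(1 - a/2, a/2)) * se`. Degenerate (constant) inputs
#' return the point interval.
#'
#' @param values Numeric vector (>= 2 values).
#' @param level Coverage level, default 0.95.
#' @param B Bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @return Numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(values, level = 0.95, B = 1000, seed = NULL) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  if (B < 100) stop("B must be at least 100", call. = FALSE)
  m0 <- mean(values)
  s0 <- stats::sd(values)
  if (s0 == 0) return(c(lo = m0, hi = m0))
  se0 <- s0 / sqrt(n)
  tstar <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
    vapply(seq_len(B), function(b) {
      v <- values[idx[b, ]]
      se <- stats::sd(v) / sqrt(n)
      if (se == 0) 0 else (mean(v) - m0) / se
    }, numeric(1))
  })
  a <- (1 - level) / 2
  q <- stats::quantile(tstar, c(1 - a, a), names = FALSE, type = 7)
  c(lo = m0 - q[1] * se0, hi = m0 - q[2] * se0)
}

ensemble_distance_sets <- function(ens, metric, xi, which = c("S", "SI")) {
  nets <- c(list(ens$full_net), ens$nets)
  nets[-1] <- lapply(nets[-1], function(g) align_networks(nets[[1]], g))
  adjs <- lapply(nets, unclass)
  need_im <- metric %in% c("him", "im")
  freqs <- if (need_im) lapply(nets, laplacian_frequencies)
           else vector("list", length(nets))
  r <- length(ens$nets)
  out <- list()
  if ("S" %in% which) {
    pairs <- cbind(1L, seq_len(r) + 1L)
    out$S_values <- pairwise_distances(adjs, freqs, metric, xi, pairs = pairs)
  }
  if ("SI" %in% which && r >= 2) {
    pairs <- which(upper.tri(matrix(0, r, r)), arr.ind = TRUE) + 1L
    out$SI_values <- pairwise_distances(adjs, freqs, metric, xi, pairs = pairs)
  }
  out
}

#' NetSI whole-network stability indicators
#'
#' Computes the stability indicator `S` (mean distance between the full-data
#' network and each resampled network) and the internal stability indicator
#' `S_I` (mean distance over all unordered pairs of resampled networks),
#' with ranges and studentized bootstrap confidence intervals. Smaller
#' values mean a more stable reconstruction.
#'
#' @param ens A `netsi_ensemble`.
#' @param metric Network metric: `"him"`, `"h"` or `"im"`.
#' @param xi HIM combination factor.
#' @param level CI coverage level.
#' @param B Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return An object of class `netsi_stability` with fields `S`, `S_values`,
#'   `ci_S`, `range_S`, and (when at least two resampled networks exist)
#'   `S_I`, `SI_values`, `ci_SI`, `range_SI`.
#' @export
network_stability <- function(ens, metric = c("him", "h", "im"), xi = 1,
                              level = 0.95, B = 1000, seed = NULL) {
  metric <- match.arg(metric)
  if (!inherits(ens, "netsi_ensemble")) stop("ens must be a netsi_ensemble",
                                             call. = FALSE)
  if (length(ens$nets) < 1) stop("empty ensemble", call. = FALSE)
  d <- ensemble_distance_sets(ens, metric, xi)
  out <- list(
    metric = metric, xi = xi, method = ens$method,
    scheme = ens$plan$scheme,
    S = mean(d$S_values), S_values = d$S_values,
    range_S = range(d$S_values),
    ci_S = if (length(d$S_values) >= 2)
      bootstrap_ci(d$S_values, level, B, child_seed(seed, 1L))
      else c(lo = d$S_values, hi = d$S_values)
  )
  if (!is.null(d$SI_values)) {
    out$S_I <- mean(d$SI_values)
    out$SI_values <- d$SI_values
    out$range_SI <- range(d$SI_values)
    out$ci_SI <- if (length(d$SI_values) >= 2)
      bootstrap_ci(d$SI_values, level, B, child_seed(seed, 2L))
      else c(lo = out$S_I, hi = out$S_I)
  }
  structure(out, class = "netsi_stability")
}

#' @export
print.netsi_stability <- function(x, ...) {
  cat("<netsi_stability> method ", x$method, ", metric ", x$metric,
      " (xi = ", x$xi, ")\n", sep = "")
  cat(sprintf("  S   = %.4f  CI (%.4f; %.4f)  range (%.4f; %.4f)  [%d distances]\n",
              x$S, x$ci_S[1], x$ci_S[2], x$range_S[1], x$range_S[2],
              length(x$S_values)))
  if (!is.null(x$S_I)) {
    cat(sprintf("  S_I = %.4f  CI (%.4f; %.4f)  range (%.4f; %.4f)  [%d distances]\n",
                x$S_I, x$ci_SI[1], x$ci_SI[2], x$range_SI[1], x$range_SI[2],
                length(x$SI_values)))
  }
  invisible(x)
}

cv_ranking <- function(values_mat, ids) {
  mu <- unname(colMeans(values_mat))
  sdv <- unname(apply(values_mat, 2, stats::sd))
  rng <- unname(apply(values_mat, 2, function(v) diff(range(v))))
  void <- mu == 0 & rng == 0
  score <- ifelse(void, 0, sdv / mu)
  ord <- c(which(void), setdiff(order(score, ids), which(void)))
  out <- tibble::tibble(
    id = ids[ord],
    score = score[ord],
    void = void[ord]
  )
  out$rank <- NA_integer_
  out$rank[!out$void] <- seq_len(sum(!out$void))
  out
}

#' Edge-weight stability ranking
#'
#' For every node pair, the weights observed across the resampled networks
#' are summarized by their coefficient of variation (sample sd / mean), the
#' normalized variability score `S_w`. Pairs never wired in any resample
#' (mean and range both zero) are *void*: excluded from the numeric ranking
#' and listed first with `void = TRUE` and score 0. Smaller scores mean more
#' stable edges.
#'
#' @param ens A `netsi_ensemble` with at least two resampled networks.
#' @return A tibble with columns `from`, `to`, `score`, `void`, `rank`,
#'   sorted most stable first (void rows leading).
#' @export
edge_stability <- function(ens) {
  if (!inherits(ens, "netsi_ensemble")) stop("ens must be a netsi_ensemble",
                                             call. = FALSE)
  r <- length(ens$nets)
  if (r < 2) stop("need at least 2 resampled networks", call. = FALSE)
  nets <- lapply(ens$nets, function(g) align_networks(ens$full_net, g))
  labels <- node_labels(ens$full_net)
  n <- length(labels)
  up <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  w <- t(vapply(nets, function(g) unclass(g)[up], numeric(nrow(up))))
  rk <- cv_ranking(w, paste(labels[up[, 1]], labels[up[, 2]], sep = "--"))
  parts <- strsplit(rk$id, "--", fixed = TRUE)
  tibble::tibble(
    from = vapply(parts, `[`, "", 1),
    to = vapply(parts, `[`, "", 2),
    score = rk$score, void = rk$void, rank = rk$rank
  )
}

#' Node-degree stability ranking
#'
#' Same construction as [edge_stability()], applied to the weighted degree
#' of each node across the resampled networks: the score `S_d` is the
#' coefficient of variation of the degrees, nodes never wired in any
#' resample are void.
#'
#' @inheritParams edge_stability
#' @return A tibble with columns `node`, `score`, `void`, `rank`.
#' @export
node_stability <- function(ens) {
  if (!inherits(ens, "netsi_ensemble")) stop("ens must be a netsi_ensemble",
                                             call. = FALSE)
  r <- length(ens$nets)
  if (r < 2) stop("need at least 2 resampled networks", call. = FALSE)
  nets <- lapply(ens$nets, function(g) align_networks(ens$full_net, g))
  deg <- t(vapply(nets, net_degree, numeric(nrow(ens$full_net))))
  rk <- cv_ranking(deg, node_labels(ens$full_net))
  tibble::tibble(node = rk$id, score = rk$score, void = rk$void,
                 rank = rk$rank)
}

#' Run a full NetSI stability analysis
#'
#' One-call orchestration: builds the resampling plan, infers the network
#' ensemble, and computes the whole-network indicators together with the
#' edge and node stability rankings.
#'
#' @inheritParams infer_ensemble
#' @inheritParams resampling_plan
#' @inheritParams network_stability
#' @param scheme Resampling scheme (see [resampling_plan()]).
#' @param B Bootstrap resamples for the confidence intervals.
#' @return An object of class `netsi_report`: list with `stability`
#'   (`netsi_stability`), `edges`, `nodes` (ranking tibbles), `ensemble`,
#'   and the run configuration.
#' @examples
#' set.seed(7)
#' x <- matrix(rnorm(30 * 6), 30, 6)
#' rep <- netsi_run(x, method = "cor", scheme = "subsample", r = 8, s = 20,
#'                  seed = 1)
#' glance(rep)
#' @export
netsi_run <- function(data, method = "cor", scheme = "kfold", k = 5,
                      instances = 10, r = 50, s = NULL,
                      metric = "him", xi = 1, level = 0.95, B = 1000,
                      seed = NULL, ...) {
  x <- as_expression_matrix(data)
  plan <- resampling_plan(nrow(x), scheme, k = k, instances = instances,
                          r = r, s = s, seed = child_seed(seed, 101L))
  ens <- infer_ensemble(x, method, plan, ..., seed = child_seed(seed, 202L))
  stab <- network_stability(ens, metric, xi, level, B,
                            seed = child_seed(seed, 303L))
  structure(
    list(stability = stab,
         edges = edge_stability(ens),
         nodes = node_stability(ens),
         ensemble = ens,
         config = list(method = method, scheme = scheme, metric = metric,
                       xi = xi, level = level, B = B, seed = seed,
                       extra = list(...))),
    class = "netsi_report"
  )
}

#' @export
print.netsi_report <- function(x, ...) {
  print(x$stability)
  cat("  edge ranking: ", sum(!x$edges$void), " scored + ",
      sum(x$edges$void), " void; node ranking: ", sum(!x$nodes$void),
      " scored + ", sum(x$nodes$void), " void\n", sep = "")
  invisible(x)
}
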