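# score matrices used by the permutation gate; entry [i, j] scores
# (x_i, x_j). For the permuted pass the second argument carries the
# row-permuted data so that [i, j] = score(x_i, pi(x_j)).
pair_scores <- function(x, y = x, measure, mic_alpha = 0.6, mic_c = 15) {
  if (measure %in% c("pearson", "wgcna")) {
    abs(stats::cor(x, y))
  } else {
    p <- ncol(x)
    s <- matrix(0, p, p)
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (i == j && identical(x, y)) next
        s[i, j] <- mic_statistic(x[, i], y[, j], mic_alpha, mic_c)
      }
    }
    s
  }
}

#' Permutation-FDR filtered association network
#'
#' Edgewise permutation gate: for each feature pair the observed association
#' score is compared with the scores obtained on `n_perm` random row
#' permutations of the second feature (one shared, seeded permutation pool
#' for all pairs). The permutation p-value uses the add-one estimator
#' `p = (1 + #{permuted score >= observed}) / (n_perm + 1)`; the edge keeps
#' its observed weight when `p <= alpha`, and is zeroed otherwise.
#'
#' With `measure = "pearson"` the score is `|r|` (the CORFDR network);
#' `"wgcna"` gates on the same `|r|` but outputs `|r|^beta` weights;
#' `"mic"` scores with the maximal information coefficient (slow: one MIC
#' matrix per permutation).
#'
#' An optional Benjamini-Hochberg step across edges can be switched on with
#' `bh = TRUE`; the default reproduces the plain edgewise gate.
#'
#' @inheritParams cor_network
#' @param alpha Significance level in `(0, 1)`; must be attainable, i.e.
#'   `alpha >= 1 / (n_perm + 1)`.
#' @param n_perm Number of permutations (>= 19).
#' @param measure `"pearson"`, `"wgcna"` or `"mic"`.
#' @param beta Soft power for the `"wgcna"` weights.
#' @param seed Integer seed for the shared permutation pool.
#' @param bh Apply a Benjamini-Hochberg correction across edges before
#'   thresholding? Default `FALSE`.
#' @param mic_alpha,mic_c MIC grid parameters.
#' @return A `netsi_network`; rejected edges have weight 0.
#' @export
fdr_network <- function(data, alpha = 0.05, n_perm = 1000,
                        measure = c("pearson", "wgcna", "mic"),
                        beta = 6, seed = NULL, bh = FALSE,
                        mic_alpha = 0.6, mic_c = 15) {
  measure <- match.arg(measure)
  x <- check_variances(as_expression_matrix(data))
  m <- nrow(x)
  p <- ncol(x)
  if (n_perm < 19) stop("n_perm must be at least 19", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (alpha < 1 / (n_perm + 1)) {
    stop("alpha = ", alpha, " is unattainable with n_perm = ", n_perm,
         " (minimum p-value is 1/(n_perm + 1)); increase n_perm",
         call. = FALSE)
  }
  obs <- pair_scores(x, x, measure, mic_alpha, mic_c)
  counts <- matrix(0L, p, p)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(m)
      s <- pair_scores(x, x[perm, , drop = FALSE], measure, mic_alpha, mic_c)
      counts <- counts + (s >= obs - 1e-15)
    }
  })
  pvals <- (1 + counts) / (n_perm + 1)
  # the pair statistic is score(x_i, pi(x_j)) with i < j
  pv <- pvals
  pv[lower.tri(pv)] <- t(pvals)[lower.tri(pvals)]
  if (bh) {
    up <- upper.tri(pv)
    adj <- stats::p.adjust(pv[up], method = "BH")
    pv[up] <- adj
    pv[lower.tri(pv)] <- t(pv)[lower.tri(pv)]
  }
  w <- if (measure == "wgcna") obs^beta else obs
  w[pv > alpha] <- 0
  diag(w) <- 0
  finish_net(w, colnames(x))
}

#' Infer a network from expression data by name
#'
#' Uniform front end over the reconstruction methods: `"cor"`, `"wgcna"`,
#' `"bicor"`, `"tom"`, `"mic"`, `"aracne"`, `"clr"` and the permutation-FDR
#' gated `"cor_fdr"`, `"wgcna_fdr"`, `"mic_fdr"`. Extra arguments are passed
#' to the method function.
#'
#' @inheritParams cor_network
#' @param method Method name.
#' @param ... Method parameters (`beta`, `alpha`, `n_perm`, `bins`,
#'   `dpi_tol`, `mic_alpha`, `mic_c`, `seed`, ...).
#' @return A `netsi_network`.
#' @export
infer_network <- function(data, method = c("cor", "wgcna", "bicor", "tom",
                                           "mic", "aracne", "clr", "cor_fdr",
                                           "wgcna_fdr", "mic_fdr"), ...) {
  method <- match.arg(method)
  switch(method,
    cor = cor_network(data),
    wgcna = wgcna_network(data, ...),
    bicor = bicor_network(data),
    tom = tom_network(data, ...),
    mic = mic_network(data, ...),
    aracne = aracne_network(data, ...),
    clr = clr_network(data, ...),
    cor_fdr = fdr_network(data, measure = "pearson", ...),
    wgcna_fdr = fdr_network(data, measure = "wgcna", ...),
    mic_fdr = fdr_network(data, measure = "mic", ...)
  )
}
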