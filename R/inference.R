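#' Validate an expression-like data matrix
#'
#' Accepts a samples x features data frame or matrix, checks for missing
#' values and duplicate feature labels, and returns a plain numeric matrix
#' with feature labels as column names.
#'
#' @param data Data frame or matrix, samples in rows, features in columns.
#' @return Numeric matrix.
#' @export
as_expression_matrix <- function(data) {
  if (is.data.frame(data)) {
    numeric_cols <- vapply(data, is.numeric, logical(1))
    if (!all(numeric_cols)) {
      stop("non-numeric columns in expression data: ",
           paste(names(data)[!numeric_cols], collapse = ", "), call. = FALSE)
    }
    data <- as.matrix(data)
  }
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("expression data must be a numeric matrix or data frame", call. = FALSE)
  }
  if (anyNA(data)) {
    idx <- which(is.na(data), arr.ind = TRUE)[1, ]
    stop("missing value at sample ", idx[1], ", feature ", idx[2],
         "; impute or drop before inference", call. = FALSE)
  }
  if (is.null(colnames(data))) colnames(data) <- paste0("v", seq_len(ncol(data)))
  if (anyDuplicated(colnames(data))) {
    stop("duplicate feature labels", call. = FALSE)
  }
  data
}

check_variances <- function(x) {
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance feature(s): ",
         paste(colnames(x)[v == 0], collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

finish_net <- function(w, labels) {
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w[w < 0] <- 0
  w[w > 1] <- 1
  as_network(w, labels)
}

#' Absolute Pearson correlation network
#'
#' Link weight is `|Pearson r|` between the two feature columns.
#'
#' @param data Samples x features data frame or matrix.
#' @return A `netsi_network` over the features.
#' @export
cor_network <- function(data) {
  x <- check_variances(as_expression_matrix(data))
  if (nrow(x) < 3) stop("need at least 3 samples", call. = FALSE)
  finish_net(abs(stats::cor(x)), colnames(x))
}

#' Soft-thresholded correlation network
#'
#' Link weight is `|Pearson r|^beta`, the classic weighted co-expression
#' adjacency; the conventional soft power is `beta = 6`, and `beta = 1`
#' reduces to [cor_network()].
#'
#' @inheritParams cor_network
#' @param beta Soft-thresholding power (>= 1).
#' @return A `netsi_network`.
#' @export
wgcna_network <- function(data, beta = 6) {
  if (!is.numeric(beta) || length(beta) != 1 || beta < 1) {
    stop("beta must be a single number >= 1", call. = FALSE)
  }
  x <- check_variances(as_expression_matrix(data))
  if (nrow(x) < 3) stop("need at least 3 samples", call. = FALSE)
  finish_net(abs(stats::cor(x))^beta, colnames(x))
}

# Tukey biweight transform of one column: median-centred, weighted by
# (1 - u^2)^2 with u = (x - med) / (9 * mad), zero weight beyond |u| >= 1.
# Columns with zero MAD fall back to the Pearson (mean/sd) transform.
biweight_columns <- function(x) {
  p <- ncol(x)
  out <- x
  fallback <- logical(p)
  for (j in seq_len(p)) {
    xj <- x[, j]
    med <- stats::median(xj)
    madj <- stats::median(abs(xj - med))
    if (madj == 0) {
      s <- stats::sd(xj)
      if (s == 0) stop("constant feature: ", colnames(x)[j], call. = FALSE)
      out[, j] <- (xj - mean(xj)) / s
      fallback[j] <- TRUE
    } else {
      u <- (xj - med) / (9 * madj)
      w <- (1 - u^2)^2 * (abs(u) < 1)
      out[, j] <- (xj - med) * w
    }
  }
  if (any(fallback)) {
    warning("zero MAD, Pearson fallback for feature(s): ",
            paste(colnames(x)[fallback], collapse = ", "), call. = FALSE)
  }
  out
}

#' Biweight midcorrelation network
#'
#' Robust correlation built from median/MAD-based Tukey biweights (tuning
#' constant 9): gross outliers get zero weight, so single contaminated
#' samples perturb the link weights far less than with Pearson correlation.
#'
#' @inheritParams cor_network
#' @return A `netsi_network` with weights `|bicor|`.
#' @export
bicor_network <- function(data) {
  x <- as_expression_matrix(data)
  if (nrow(x) < 5) stop("need at least 5 samples for bicor", call. = FALSE)
  check_variances(x)
  xt <- biweight_columns(x)
  norms <- sqrt(colSums(xt^2))
  if (any(norms == 0)) {
    stop("degenerate biweight transform for feature(s): ",
         paste(colnames(x)[norms == 0], collapse = ", "), call. = FALSE)
  }
  r <- crossprod(sweep(xt, 2, norms, "/"))
  finish_net(abs(r), colnames(x))
}

#' Topological overlap network
#'
#' Shared-neighbour smoothing of the soft-thresholded correlation adjacency
#' `a`: `TOM(i,j) = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with `k` the weighted degrees. Values lie in `[0, 1]`; highly
#' interconnected pairs approach 1.
#'
#' @inheritParams wgcna_network
#' @return A `netsi_network`.
#' @export
tom_network <- function(data, beta = 6) {
  a <- unclass(wgcna_network(data, beta))
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  finish_net(num / den, colnames(a))
}

#' Mutual information matrix
#'
#' Pairwise mutual information in nats from equal-frequency binning and the
#' empirical plug-in entropy estimator. The bin count defaults to
#' `ceiling(sqrt(m / 5))` (at least 2) for `m` samples.
#'
#' @inheritParams cor_network
#' @param bins Number of equal-frequency bins per variable.
#' @return Symmetric nonnegative matrix with zero diagonal (by convention).
#' @export
mutual_information <- function(data, bins = NULL) {
  x <- as_expression_matrix(data)
  m <- nrow(x)
  if (m < 10) stop("need at least 10 samples for MI estimation", call. = FALSE)
  if (is.null(bins)) bins <- max(2L, ceiling(sqrt(m / 5)))
  bins <- as.integer(bins)
  if (bins < 2) stop("bins must be at least 2", call. = FALSE)
  # equal-frequency bin index per column
  b <- apply(x, 2, function(col) {
    ceiling(rank(col, ties.method = "first") * bins / m)
  })
  p <- ncol(x)
  xlogx <- function(n) ifelse(n > 0, n * log(n), 0)
  hmarg <- apply(b, 2, function(col) {
    cnt <- tabulate(col, bins)
    log(m) - sum(xlogx(cnt)) / m
  })
  mi <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      cnt <- tabulate((b[, i] - 1L) * bins + b[, j], bins * bins)
      hj <- log(m) - sum(xlogx(cnt)) / m
      mi[i, j] <- mi[j, i] <- max(0, hmarg[i] + hmarg[j] - hj)
    }
  }
  mi
}

#' ARACNE network
#'
#' Mutual-information network pruned by the Data Processing Inequality: in
#' every triplet whose three edges are all present, the weakest edge is
#' removed (up to the tolerance `dpi_tol`), eliminating most indirect links.
#' Surviving MI values are rescaled to `[0, 1]` by dividing by the maximum.
#'
#' @inheritParams mutual_information
#' @param dpi_tol DPI tolerance in `[0, 1)`: edge `(i,j)` is removed when
#'   `MI_ij < min(MI_ik, MI_jk) * (1 - dpi_tol)` for some `k`.
#' @param mi_threshold Optional floor; MI values at or below it are zeroed
#'   before the DPI step.
#' @return A `netsi_network`.
#' @export
aracne_network <- function(data, dpi_tol = 0, mi_threshold = NULL, bins = NULL) {
  mi <- mutual_information(data, bins)
  if (!is.null(mi_threshold)) mi[mi <= mi_threshold] <- 0
  p <- nrow(mi)
  remove <- matrix(FALSE, p, p)
  if (p >= 3) {
    for (k in seq_len(p)) {
      mk <- mi[, k]
      present_k <- mk > 0
      cond <- outer(present_k, present_k, `&`) &
        (mi < (1 - dpi_tol) * outer(mk, mk, pmin)) & (mi > 0)
      cond[k, ] <- FALSE
      cond[, k] <- FALSE
      remove <- remove | cond
    }
  }
  mi[remove] <- 0
  mx <- max(mi)
  if (mx > 0) mi <- mi / mx
  finish_net(mi, rownames(mi))
}

#' CLR network
#'
#' Context Likelihood of Relatedness: each mutual-information score is
#' background-corrected against the MI distributions of its two endpoints.
#' For node `i`, `z_i(j) = max(0, (MI_ij - mu_i) / sigma_i)` over the
#' off-diagonal row statistics, and the link weight is
#' `sqrt(z_i(j)^2 + z_j(i)^2)`, rescaled to `[0, 1]` by the maximum.
#'
#' @inheritParams mutual_information
#' @return A `netsi_network`.
#' @export
clr_network <- function(data, bins = NULL) {
  mi <- mutual_information(data, bins)
  p <- nrow(mi)
  if (p < 3) stop("CLR background undefined for fewer than 3 features",
                  call. = FALSE)
  off <- mi
  diag(off) <- NA
  mu <- rowMeans(off, na.rm = TRUE)
  sig <- apply(off, 1, stats::sd, na.rm = TRUE)
  z <- (mi - mu) / ifelse(sig > 0, sig, Inf)
  z[z < 0] <- 0
  w <- sqrt(z^2 + t(z)^2)
  diag(w) <- 0
  mx <- max(w)
  if (mx > 0) w <- w / mx
  finish_net(w, rownames(mi))
}
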