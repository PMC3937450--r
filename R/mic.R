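# Maximal Information Coefficient (MINE family), built-in approximation.
#
# For every grid shape (nx, ny) with nx * ny <= B = m^alpha, the y axis is
# equipartitioned into ny equal-frequency rows and the x-axis partition is
# optimized exactly by dynamic programming over equal-frequency candidate cut
# positions (all m - 1 positions when c * nx_max >= m - 1, the usual case at
# desk scale). The characteristic value is MI / log(min(nx, ny)); MIC is the
# maximum over grid shapes and both axis orientations.

xlogx <- function(n) {
  out <- numeric(length(n))
  pos <- n > 0
  out[pos] <- n[pos] * log(n[pos])
  dim(out) <- dim(n)
  out
}

# max over nx of normalized MI for one orientation: rows = equal-frequency
# bins of y, columns optimized on x. Returns a matrix best[nx, ny] of MI
# values (nats), NA where nx * ny > B.
mic_orientation_best <- function(x, y, B, c_par) {
  m <- length(x)
  ord <- order(x)  # stable tie-break
  ny_max <- B %/% 2L
  nx_max <- B %/% 2L
  npos <- min(m - 1L, c_par * nx_max)
  # candidate boundaries: equal-frequency positions 0 = q_0 < ... < q_P = m
  q <- unique(c(0L, round(seq_len(npos) * m / (npos + 1)), m))
  q <- sort(unique(pmin(pmax(q, 0L), m)))
  P <- length(q) - 1L
  best <- matrix(NA_real_, nx_max, ny_max)
  for (ny in 2:ny_max) {
    if (2L * ny > B) break
    ybin <- ceiling(rank(y, ties.method = "first") * ny / m)
    yb <- ybin[ord]
    # cumulative per-row counts along the x order, at the candidate cuts
    C <- matrix(0L, P + 1L, ny)
    cum <- apply(outer(yb, seq_len(ny), `==`), 2, cumsum)
    C[-1L, ] <- cum[q[-1L], , drop = FALSE]
    tot <- q  # cumulative total counts at cuts
    # additive gain of an x-bin (q_s, q_t]: sum_y n log n - n log n
    gain <- matrix(-Inf, P + 1L, P + 1L)  # [s+1, t+1], s < t
    cellsum <- matrix(0, P + 1L, P + 1L)
    for (r in seq_len(ny)) {
      d <- outer(C[, r], C[, r], function(a, b) b - a)  # [s+1, t+1]
      cellsum <- cellsum + xlogx(d)
    }
    totd <- outer(tot, tot, function(a, b) b - a)
    gain <- cellsum - xlogx(totd)
    nx_lim <- min(nx_max, B %/% ny)
    # DP: F[t+1, k] = best total gain splitting (0, q_t] into k bins
    Fk <- gain[1L, ]  # k = 1
    rowcnt <- tabulate(ybin, ny)
    rowterm <- sum(xlogx(rowcnt))
    mi_k <- numeric(nx_lim)
    mi_k[1] <- 0
    if (nx_lim >= 2) {
      for (k in 2:nx_lim) {
        Fnew <- rep(-Inf, P + 1L)
        for (t in k:P) {
          s_range <- (k - 1L):(t - 1L)
          Fnew[t + 1L] <- max(Fk[s_range + 1L] + gain[s_range + 1L, t + 1L])
        }
        Fk <- Fnew
        mi_k[k] <- max(0, (Fk[P + 1L] - rowterm) / m + log(m))
      }
    }
    best[seq_len(nx_lim), ny] <- mi_k
  }
  best
}

#' Maximal Information Coefficient of two vectors
#'
#' @param x,y Numeric vectors of equal length (>= 10 samples recommended).
#' @param mic_alpha Grid-size exponent: grids are limited to
#'   `nx * ny <= m^mic_alpha`.
#' @param mic_c Candidate-cut multiplier controlling how many equal-frequency
#'   cut positions the x-axis optimizer may use.
#' @return MIC in `[0, 1]`.
#' @export
mic_statistic <- function(x, y, mic_alpha = 0.6, mic_c = 15) {
  m <- length(x)
  if (length(y) != m) stop("x and y must have equal length", call. = FALSE)
  B <- floor(m^mic_alpha)
  if (B < 4) {
    stop("sample size too small: grid bound m^mic_alpha = ", signif(B, 3),
         " < 4", call. = FALSE)
  }
  b1 <- mic_orientation_best(x, y, B, mic_c)
  b2 <- mic_orientation_best(y, x, B, mic_c)
  mic <- 0
  for (nx in 2:nrow(b1)) {
    for (ny in 2:ncol(b1)) {
      if (nx * ny > B) next
      denom <- log(min(nx, ny))
      v <- max(b1[nx, ny], b2[ny, nx], na.rm = TRUE)
      mic <- max(mic, v / denom)
    }
  }
  min(mic, 1)
}

#' Maximal Information Coefficient network
#'
#' Pairwise MIC over all feature pairs; MIC lies in `[0, 1]` and equals 1
#' for noiseless functional relationships.
#'
#' @inheritParams cor_network
#' @inheritParams mic_statistic
#' @return A `netsi_network`.
#' @export
mic_network <- function(data, mic_alpha = 0.6, mic_c = 15) {
  x <- as_expression_matrix(data)
  m <- nrow(x)
  if (m < 10) stop("need at least 10 samples for MIC", call. = FALSE)
  p <- ncol(x)
  w <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      w[i, j] <- w[j, i] <- mic_statistic(x[, i], x[, j], mic_alpha, mic_c)
    }
  }
  finish_net(w, colnames(x))
}
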