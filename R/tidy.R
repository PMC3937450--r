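#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the distance distributions of a stability result
#'
#' @param x A `netsi_stability`.
#' @param ... Unused.
#' @return A tibble with one row per computed distance: columns `indicator`
#'   (`"S"` or `"S_I"`) and `distance`.
#' @export
tidy.netsi_stability <- function(x, ...) {
  out <- tibble::tibble(indicator = "S", distance = x$S_values)
  if (!is.null(x$SI_values)) {
    out <- dplyr::bind_rows(
      out, tibble::tibble(indicator = "S_I", distance = x$SI_values))
  }
  out
}

#' One-row summary of a stability result
#'
#' @param x A `netsi_stability`.
#' @param ... Unused.
#' @return A one-row tibble: method, scheme, metric, xi, `S` with CI and
#'   range, and `S_I` with CI and range when available.
#' @export
glance.netsi_stability <- function(x, ...) {
  tibble::tibble(
    method = x$method, scheme = x$scheme, metric = x$metric, xi = x$xi,
    S = x$S, S_ci_lo = x$ci_S[[1]], S_ci_hi = x$ci_S[[2]],
    S_min = x$range_S[1], S_max = x$range_S[2],
    S_I = if (is.null(x$S_I)) NA_real_ else x$S_I,
    SI_ci_lo = if (is.null(x$ci_SI)) NA_real_ else x$ci_SI[[1]],
    SI_ci_hi = if (is.null(x$ci_SI)) NA_real_ else x$ci_SI[[2]]
  )
}

#' @export
tidy.netsi_report <- function(x, ...) tidy(x$stability, ...)

#' @export
glance.netsi_report <- function(x, ...) glance(x$stability, ...)

#' Plot the distance distributions behind S and S_I
#'
#' @param object A `netsi_stability` or `netsi_report`.
#' @param ... Unused.
#' @return A ggplot: one boxplot (with jittered points) per indicator.
#' @export
autoplot.netsi_stability <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$indicator, y = .data$distance)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.4, size = 0.8) +
    ggplot2::labs(
      x = NULL, y = paste0(toupper(object$metric), " distance"),
      title = sprintf("Network stability (%s, %s resampling)",
                      object$method, object$scheme),
      subtitle = sprintf("S = %.4f, S_I = %s", object$S,
                         if (is.null(object$S_I)) "-" else
                           sprintf("%.4f", object$S_I))
    )
}

#' @export
autoplot.netsi_report <- function(object, ...) autoplot(object$stability, ...)

#' Plot a stability ranking
#'
#' Dot chart of the normalized variability scores from [edge_stability()] or
#' [node_stability()], most stable at the top; void items are excluded.
#'
#' @param ranking Ranking tibble.
#' @param top Show only the `top` most stable items (default 30).
#' @return A ggplot.
#' @export
plot_stability_ranking <- function(ranking, top = 30) {
  df <- ranking[!ranking$void, , drop = FALSE]
  df <- utils::head(df[order(df$rank), ], top)
  df$label <- if ("node" %in% names(df)) df$node else paste(df$from, df$to, sep = "--")
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "coefficient of variation (lower = more stable)",
                  y = NULL)
}

#' Plot a pair of networks in the Hamming / Ipsen-Mikhailov plane
#'
#' Scatter of `(h, im)` distance points (e.g. rows accumulated from
#' [him_distance()]); the quarter-circle contours are HIM level sets for
#' `xi = 1`.
#'
#' @param points Tibble with columns `h` and `im` (and optionally `label`).
#' @return A ggplot with unit axes.
#' @export
plot_him_plane <- function(points) {
  arc <- tibble::tibble(t = seq(0, pi / 2, length.out = 100))
  levels <- c(0.25, 0.5, 0.75, 1)
  arcs <- dplyr::bind_rows(lapply(levels, function(r) {
    tibble::tibble(h = r * sqrt(2) * cos(arc$t), im = r * sqrt(2) * sin(arc$t),
                   level = r)
  }))
  arcs <- arcs[arcs$h <= 1 & arcs$im <= 1, ]
  p <- ggplot2::ggplot(points, ggplot2::aes(x = .data$h, y = .data$im)) +
    ggplot2::geom_path(data = arcs,
                       ggplot2::aes(group = .data$level),
                       linetype = 3, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Hamming (H)", y = "Ipsen-Mikhailov (IM)")
  if ("label" %in% names(points)) {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$label),
                                vjust = -0.8, size = 3)
  }
  p
}
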