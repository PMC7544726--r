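#' Monte Carlo sample of assigned-share values
#'
#' Container for the per-iteration assigned-share values with summary
#' statistics: mean, median, a percentile table, and the 68% (16--84) and
#' 95% (2.5--97.5) intervals. Percentiles use linear interpolation between
#' order statistics (quantile type 7).
#'
#' @param z Numeric vector of Z values, each in [0, 1).
#' @param models Optional character vector of the model id used per
#'   iteration.
#' @param percentiles Percentiles (percent) to tabulate.
#' @param meta List of run metadata (seed, iterations, model set id).
#' @return Object of class `z_distribution`.
#' @export
z_distribution <- function(z, models = NULL,
                           percentiles = c(2.5, 16, 50, 84, 97.5),
                           meta = list()) {
  if (length(z) == 0) abort("Z sample must be non-empty")
  if (any(z < 0) || any(z >= 1)) abort("every Z must lie in [0, 1)")
  pct <- sort(unique(c(percentiles, 2.5, 16, 50, 84, 97.5)))
  q <- quantile(z, probs = pct / 100, type = 7, names = FALSE)
  structure(list(
    z = z, models = models,
    summary = tibble(statistic = c("mean", "median"),
                     value = c(mean(z), median(z))),
    percentiles = tibble(percentile = pct, value = q),
    meta = meta), class = "z_distribution")
}

#' @export
print.z_distribution <- function(x, ...) {
  ci68 <- ci_of(x, 68); ci95 <- ci_of(x, 95)
  cat(sprintf("<z_distribution> %d iterations\n", length(x$z)))
  cat(sprintf("  median Z: %.4f   mean Z: %.4f\n",
              median(x$z), mean(x$z)))
  cat(sprintf("  68%% CI: [%.4f, %.4f]   95%% CI: [%.4f, %.4f]\n",
              ci68[1], ci68[2], ci95[1], ci95[2]))
  invisible(x)
}

ci_of <- function(x, level) {
  lo <- (100 - level) / 2
  p <- x$percentiles
  c(p$value[match(lo, p$percentile)], p$value[match(100 - lo, p$percentile)])
}

#' Tidy the percentile table of a Z distribution
#'
#' @param x A [z_distribution()].
#' @param ... Unused.
#' @return Tibble with columns `percentile` and `value`.
#' @export
tidy.z_distribution <- function(x, ...) x$percentiles

#' One-row summary of a Z distribution
#'
#' @param x A [z_distribution()].
#' @param ... Unused.
#' @return Tibble with mean, median, interval bounds and iteration count.
#' @export
glance.z_distribution <- function(x, ...) {
  ci68 <- ci_of(x, 68); ci95 <- ci_of(x, 95)
  tibble(mean = mean(x$z), median = median(x$z),
         ci68_low = ci68[1], ci68_high = ci68[2],
         ci95_low = ci95[1], ci95_high = ci95[2],
         iterations = length(x$z))
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot the cumulative distribution of the assigned share
#'
#' @param object A [z_distribution()].
#' @param ... Unused.
#' @return A ggplot object: empirical CDF of Z with the tabulated
#'   percentiles marked.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.z_distribution <- function(object, ...) {
  df <- tibble(z = sort(object$z),
               p = seq_along(object$z) / length(object$z))
  pts <- object$percentiles
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$p)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = tibble(z = pts$value, p = pts$percentile / 100),
                        colour = "red") +
    ggplot2::labs(x = "assigned share Z", y = "cumulative probability") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Summarise a raw Z sample
#'
#' Convenience wrapper constructing a [z_distribution()] from a bare sample.
#'
#' @param z Numeric sample of assigned-share values.
#' @param percentiles Percentiles (percent).
#' @return A `z_distribution`.
#' @export
summarize_z <- function(z, percentiles = c(2.5, 16, 50, 84, 97.5)) {
  z_distribution(z, percentiles = percentiles)
}
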