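#' Plot a buildup curve
#'
#' Probability of segregation over time with its bootstrap confidence band.
#'
#' @param object An `eva_buildup` tibble from [buildup()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eva_buildup <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$time_s, y = .data$p_seg))
  if (!all(is.na(object$ci_low))) {
    p <- p + geom_ribbon(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         fill = "grey80")
  }
  p +
    geom_line(colour = "firebrick") +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "Time since stimulus onset (s)",
         y = "P(segregation)", title = "Buildup function") +
    theme_minimal()
}

#' Plot a two-parameter response diagram
#'
#' Mean-duration ratio map over the (target-against, noise) grid with
#' distribution-shape region labels.
#'
#' @param object An `eva_sweep` tibble from [sweep_eva()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eva_sweep <- function(object, ...) {
  ggplot(object, aes(x = .data$sigma_a, y = .data$t_a)) +
    geom_tile(aes(fill = log2(.data$mu_ratio))) +
    geom_text(aes(label = .data$region), size = 3) +
    scale_fill_gradient2(low = "steelblue", mid = "green3", high = "orange",
                         na.value = "grey70",
                         name = expression(log[2](mu / mu[exp]))) +
    labs(x = expression(sigma[a]), y = expression(T[a]),
         title = sprintf("Response diagram: %s %s, DF = %s",
                         object$ordinal[1], object$label[1], object$df[1])) +
    theme_minimal()
}

#' Plot a gamma fit over the duration histogram
#'
#' @param object A `gamma_fit` from [gamma_mle()].
#' @param binwidth Histogram bin width on the normalized scale.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gamma_fit <- function(object, binwidth = 0.25, ...) {
  d <- tibble(d_tilde = object$data)
  grid <- tibble(x = seq(1e-3, max(d$d_tilde) * 1.05, length.out = 200))
  grid$y <- stats::dgamma(grid$x, shape = object$alpha,
                          scale = object$mu_tilde / object$alpha)
  ggplot(d, aes(x = .data$d_tilde)) +
    geom_histogram(aes(y = ggplot2::after_stat(density)),
                   binwidth = binwidth, boundary = 0,
                   fill = "grey75", colour = "white") +
    geom_line(data = grid, aes(x = .data$x, y = .data$y),
              colour = "firebrick", linewidth = 1) +
    labs(x = "Normalized duration", y = "Density",
         title = sprintf("Gamma fit: alpha = %.2f, n = %d",
                         object$alpha, object$n)) +
    theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
plot.eva_buildup <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.eva_sweep <- function(x, ...) print(autoplot(x, ...))

#' @export
plot.gamma_fit <- function(x, ...) print(autoplot(x, ...))
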