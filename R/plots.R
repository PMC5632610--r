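#' Plot a contrast set
#'
#' Diverging bar chart of the log10 relative richness of each sister-clade
#' contrast; bars above zero are contrasts where the higher-host-diversity
#' side is the more species-rich.
#'
#' @param object A `contrast_set`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.contrast_set <- function(object, ...) {
  df <- as_tibble(object)
  df$pair <- factor(df$pair, levels = df$pair[order(df$log10rel)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log10rel, y = .data$pair,
                                   fill = .data$positive)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = expression(log[10] ~ "relative richness (R1/R2)"),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a PGLS fit
#'
#' Scatter of the response against the single predictor with the fitted
#' GLS line.
#'
#' @param object A `pgls_fit` with one predictor.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.pgls_fit <- function(object, ...) {
  mf <- stats::model.frame(object$formula, object$data)
  if (ncol(mf) != 2) abort("autoplot supports single-predictor fits")
  df <- tibble(x = mf[[2]], y = mf[[1]])
  lab <- names(mf)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$beta,
                         colour = "steelblue") +
    ggplot2::labs(
      x = lab[2], y = lab[1],
      subtitle = sprintf("PGLS: beta = %.2f, R2 = %.2f, lambda = %.2f",
                         object$beta, object$r_squared, object$lambda_hat)) +
    ggplot2::theme_minimal()
}

#' Plot MacroCAIC contrasts
#'
#' Richness contrasts against trait contrasts with the fitted
#' through-origin line.
#'
#' @param object A `caic_fit`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.caic_fit <- function(object, ...) {
  ggplot2::ggplot(object$contrasts,
                  ggplot2::aes(.data$trait_contrast, .data$richness_contrast)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(intercept = 0, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "trait contrast (standardized)",
                  y = "richness contrast ln(N1/N2)") +
    ggplot2::theme_minimal()
}

#' Plot a signal-test table
#'
#' Transition rates per trait, marking traits whose permutation p-value
#' falls below 0.05 (high phylogenetic signal = low rate).
#'
#' @param object A `signal_table` from [batch_signal()].
#' @param alpha Significance threshold to mark.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.signal_table <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object)
  df$significant <- df$p_value <= alpha
  df$trait <- factor(df$trait, levels = df$trait[order(df$t_rate)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_rate, y = .data$trait,
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ML transition rate (log scale)", y = NULL,
                  colour = sprintf("p <= %.2g", alpha)) +
    ggplot2::theme_minimal()
}
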