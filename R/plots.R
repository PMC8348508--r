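#' Diagnostic plots for a validated model
#'
#' `plot_williams` draws leverage against standardized residuals with the
#' `h*` and residual-cutoff boundaries; `plot_observed_predicted` the fit
#' scatter with the identity line; `plot_yscramble` scrambled R2/Q2 against
#' the Kxy correlation of the scrambled block; `plot_breaking_point` the
#' R2/Q2 curve over model sizes.
#'
#' @param report a `validation_report` from [validate_model()].
#' @param resid_cut residual cutoff drawn as horizontal lines.
#' @return a ggplot object.
#' @export
plot_williams <- function(report, resid_cut = 2.5) {
  tab <- report$ad$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$leverage,
                                    y = .data$std_residual,
                                    colour = .data$set)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = report$ad$h_star, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(-resid_cut, resid_cut),
                        linetype = "dashed") +
    ggplot2::labs(x = "leverage h", y = "standardized residual",
                  title = sprintf("Williams plot (h* = %.3f)",
                                  report$ad$h_star)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_williams
#' @param y,yhat observed and predicted response.
#' @export
plot_observed_predicted <- function(y, yhat) {
  df <- data.frame(observed = y, predicted = yhat)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = "experimental pKi", y = "predicted pKi") +
    ggplot2::theme_minimal()
}

#' @rdname plot_williams
#' @export
plot_yscramble <- function(report) {
  tab <- report$yscr$table
  long <- rbind(
    data.frame(kxy = tab$kxy, value = tab$r2, statistic = "R2_scr"),
    data.frame(kxy = tab$kxy, value = tab$q2, statistic = "Q2_scr")
  )
  real <- data.frame(
    kxy = report$training$Kxy,
    value = c(report$training$R2_tr, report$cv$Q2_LOO),
    statistic = c("R2_scr", "Q2_scr")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$kxy, y = .data$value,
                                     colour = .data$statistic)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_point(data = real, shape = 17, size = 3) +
    ggplot2::labs(x = "Kxy of scrambled block", y = "R2 / Q2",
                  title = "Y-scrambling (triangles: unscrambled model)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_williams
#' @param scores data.frame `m`, `r2_tr`, `q2_loo` from [model_size_scan()].
#' @param m_best optional chosen size drawn as a vertical line.
#' @export
plot_breaking_point <- function(scores, m_best = NULL) {
  long <- rbind(
    data.frame(m = scores$m, value = scores$r2_tr, statistic = "R2_tr"),
    data.frame(m = scores$m, value = scores$q2_loo, statistic = "Q2_LOO")
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$m, y = .data$value,
                                          colour = .data$statistic)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of descriptors", y = "R2 / Q2") +
    ggplot2::theme_minimal()
  if (!is.null(m_best)) {
    p <- p + ggplot2::geom_vline(xintercept = m_best, linetype = "dotted")
  }
  p
}

#' @importFrom ggplot2 .data
NULL
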