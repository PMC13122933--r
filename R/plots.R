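#' Forest plot of MR results
#'
#' One row per condition-outcome-method with the point estimate and 95%
#' interval, on the odds-ratio scale where available (binary outcomes,
#' per-doubling) and otherwise on the estimate scale.
#'
#' @param results results tibble from [mr_estimate()] or [mr_run_grid()].
#' @param odds_ratio plot `or_scaled` with a reference line at 1 (default
#'   when any OR is present); otherwise plots `beta` with a reference at 0.
#' @return A ggplot object.
#' @export
plot_forest <- function(results, odds_ratio = any(!is.na(results$or_scaled))) {
  assert_columns(results, c("condition", "outcome", "method"), "results table")
  df <- results |>
    mutate(label = paste(.data$condition, .data$outcome, sep = " → "))
  if (odds_ratio) {
    df <- df |> filter(!is.na(.data$or_scaled))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$or_scaled, y = .data$label,
                                          colour = .data$method)) +
      ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
      ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$or_ci_low,
                                            xmax = .data$or_ci_high),
                               position = ggplot2::position_dodge(width = 0.5)) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "odds ratio per doubling of liability odds", y = NULL)
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$beta, y = .data$label,
                                          colour = .data$method)) +
      ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
      ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                            xmax = .data$ci_high),
                               position = ggplot2::position_dodge(width = 0.5)) +
      ggplot2::labs(x = "causal estimate", y = NULL)
  }
  p + ggplot2::theme_minimal()
}

#' Scatter plot of instrument effects with the fitted slope
#'
#' SNP-exposure effects against SNP-outcome effects, error bars at one
#' standard error, with the fitted causal slope (and the Egger intercept,
#' when present) overlaid. The classic per-analysis diagnostic for spotting
#' outlying instruments.
#'
#' @param object an `mr_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.mr_fit <- function(object, ...) {
  df <- object$data
  sgn <- ifelse(df$beta_exp < 0, -1, 1)
  df$bx <- df$beta_exp * sgn
  df$by <- df$beta_out * sgn
  icpt <- if (is.finite(object$intercept)) object$intercept else 0
  slope <- if (identical(object$scale, "per_doubling")) {
    object$beta / log(2)
  } else {
    object$beta
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bx, y = .data$by)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$by - .data$se_out,
                                        ymax = .data$by + .data$se_out),
                           width = 0, colour = "grey70") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$bx - .data$se_exp,
                                         xmax = .data$bx + .data$se_exp),
                            height = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = icpt, slope = slope, colour = "steelblue") +
    ggplot2::labs(
      x = "SNP effect on condition liability (log-odds)",
      y = "SNP effect on outcome",
      title = sprintf("%s: %s → %s", object$method,
                      object$condition_id, object$outcome_id)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
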