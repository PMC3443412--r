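#' @method autoplot sns_roc
#' @export
autoplot.sns_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot sns_mode_comparison
#' @export
autoplot.sns_mode_comparison <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$fpr, y = .data$tpr,
    colour = .data$mode)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate", colour = NULL,
      title = sprintf("%s: AUC %.3f (simple) vs %.3f (extended)",
        object$category, object$simple$auc, object$extended$auc)
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot sns_ks
#' @export
autoplot.sns_ks <- function(object, ...) {
  dat <- tidy(object) %>%
    mutate(group = ifelse(.data$connected, "connected", "unconnected")) %>%
    count(.data$group, .data$shared_count) %>%
    group_by(.data$group) %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    ungroup()
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$shared_count, y = .data$fraction,
    colour = .data$group, shape = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Shared neighbor count", y = "Fraction of pairs", colour = NULL, shape = NULL,
      title = sprintf("%s: KS D = %.3f, p = %.2g",
        object$category, object$statistic, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot sns_calibration
#' @export
autoplot.sns_calibration <- function(object, ...) {
  dat <- tidy(object)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$n, y = .data$p_empirical))
  if ("pairs_total" %in% names(dat)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(size = .data$pairs_total), alpha = 0.7) +
      ggplot2::scale_size_continuous(name = "pairs")
  } else {
    p <- p + ggplot2::geom_point()
  }
  if (!is.null(object$fit)) {
    grid <- tibble(n = seq(0, max(dat$n) + 1, length.out = 200))
    grid$p <- logistic_eval(object$fit, grid$n)
    p <- p + ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$n, y = .data$p),
      colour = "steelblue")
  }
  p + ggplot2::labs(
    x = "Shared neighbor count n", y = "Connection probability P(n)",
    title = paste0(object$category, " calibration (policy: ", object$policy, ")")
  ) + ggplot2::theme_minimal()
}
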