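#' Plot a receiver operating characteristic curve
#'
#' @param object A `pp_roc` from [roc_points()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pp_roc
#' @export
autoplot.pp_roc <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC (area = %.3f)", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Plot posterior effect sizes of a fitted model
#'
#' Shows the posterior median and 90% interval of every parameter on the
#' logit scale, separating fixed coefficients from domain effects. Positive
#' effects support pathogenicity.
#'
#' @param object A `pp_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pp_fit
#' @export
autoplot.pp_fit <- function(object, ...) {
  td <- tidy(object)
  kind <- c(setNames(object$model$columns$kind, object$model$columns$name),
            sigma2_domain = "variance")
  td$kind <- unname(kind[td$parameter])
  td <- td[td$kind != "variance", ]
  ggplot2::ggplot(td, ggplot2::aes(
    x = .data$estimate,
    y = stats::reorder(.data$parameter, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$q05,
                                          xmax = .data$q95)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$kind), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "Effect size (logit scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot pooled cross-validation predictions as a ROC curve
#'
#' @param object A `pp_cv` from [evaluate_cv()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pp_cv
#' @export
autoplot.pp_cv <- function(object, ...) {
  autoplot(object$roc)
}
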