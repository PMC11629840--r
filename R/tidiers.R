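#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a ROC analysis
#'
#' @param x A `premo_roc` object from [roc_curve()].
#' @param ... Unused.
#' @return The per-threshold curve tibble (`threshold`, confusion counts,
#'   `sensitivity`, `specificity`, `fpr`, `youden_j`).
#' @export
tidy.premo_roc <- function(x, ...) x$curve

#' One-row summary of a ROC analysis
#'
#' @inheritParams tidy.premo_roc
#' @return One-row tibble: `feature`, `direction`, `auc`,
#'   `optimal_cutoff`, `youden_j`, `n_myopic`, `n_nonmyopic`.
#' @export
glance.premo_roc <- function(x, ...) {
  tibble::tibble(
    feature = x$feature, direction = x$direction, auc = x$auc,
    optimal_cutoff = x$optimal_cutoff, youden_j = x$youden_j,
    n_myopic = x$n_myopic, n_nonmyopic = x$n_nonmyopic
  )
}

#' @export
print.premo_roc <- function(x, ...) {
  cat(sprintf(
    "ROC analysis of %s (positive call: %s cut-off)\n",
    x$feature, if (x$direction == "ge") ">=" else "<"
  ))
  cat(sprintf("  %d myopic / %d non-myopic records\n", x$n_myopic, x$n_nonmyopic))
  cat(sprintf("  AUC (trapezoidal): %.3f\n", x$auc))
  cat(sprintf("  Youden-optimal cut-off: %s (J = %.3f)\n",
              format(x$optimal_cutoff), x$youden_j))
  invisible(x)
}

#' Plot a ROC curve
#'
#' Sensitivity against false positive rate with the chance diagonal and
#' the Youden-optimal operating point marked.
#'
#' @param object A `premo_roc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.premo_roc <- function(object, ...) {
  curve <- object$curve[order(object$curve$fpr, object$curve$sensitivity), ]
  opt <- object$curve[object$curve$threshold == object$optimal_cutoff, ][1, ]
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(data = opt, colour = "red", size = 2) +
    ggplot2::annotate(
      "text", x = opt$fpr, y = opt$sensitivity,
      label = sprintf("  cut-off %s", format(object$optimal_cutoff)),
      hjust = 0, vjust = 1.5, size = 3
    ) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)", y = "Sensitivity",
      title = sprintf("%s, AUC = %.3f", object$feature, object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Score distribution by refractive outcome
#'
#' Bar chart of PreMO totals split by whether the child became myopic by
#' follow-up — the at-a-glance view of how well the score separates the
#' outcomes.
#'
#' @param data Scored cohort with `total` and `myopic` columns.
#' @return A ggplot.
#' @export
plot_score_distribution <- function(data) {
  .check_outcomes(data)
  d <- dplyr::mutate(
    data,
    outcome = factor(ifelse(.data$myopic, "myopic", "non-myopic"),
                     levels = c("non-myopic", "myopic"))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$total, fill = .data$outcome)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::scale_x_continuous(breaks = 0:9) +
    ggplot2::labs(x = "PreMO total score", y = "Children",
                  fill = "Outcome at ≥ 15 y") +
    ggplot2::theme_minimal()
}
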