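#' Plot group-averaged learning curves
#'
#' One panel per task class, session accuracy by group, with a chance
#' line at 0.5.
#'
#' @param curves Tibble from [make_learning_curves()] (or observed
#'   curves with the same columns).
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(curves) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$session, y = .data$accuracy,
                               colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_wrap(~task_class) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Training session", y = "Session accuracy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a SUSTAIN training run
#'
#' Learning curve plus the attention-weight trajectory of a single run.
#'
#' @param object A `sustain_run` from [run_training()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sustain_run <- function(object, ...) {
  lam <- object$trace |>
    dplyr::select("trial", "lambda_x", "lambda_y") |>
    tidyr::pivot_longer(-"trial", names_to = "dimension",
                        values_to = "lambda")
  p1 <- ggplot2::ggplot(object$curve,
                        ggplot2::aes(.data$session, .data$accuracy)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Session", y = "Accuracy") +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(lam, ggplot2::aes(.data$trial, .data$lambda,
                                          colour = .data$dimension)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Trial", y = expression(lambda), colour = NULL) +
    ggplot2::theme_minimal()
  p1 <- p1 + ggplot2::ggtitle(
    sprintf("%s task (rotation %d deg), %d clusters",
            object$task_class, object$rotation_deg, object$n_clusters)
  )
  patchwork::wrap_plots(p1, p2)
}

#' Plot observed versus fitted learning curves
#'
#' @param object A `sustain_fit` from [fit_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sustain_fit <- function(object, ...) {
  obs <- dplyr::mutate(object$curves, what = "observed")
  fit <- dplyr::mutate(object$sim_curves, what = "fitted")
  ggplot2::ggplot(dplyr::bind_rows(obs, fit),
                  ggplot2::aes(.data$session, .data$accuracy,
                               colour = .data$group,
                               linetype = .data$what)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~task_class) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Session", y = "Accuracy", colour = NULL,
                  linetype = NULL,
                  title = sprintf("Model %d (AIC %.1f)",
                                  object$spec$model_id, object$aic)) +
    ggplot2::theme_minimal()
}

#' Plot recency scores with the permutation band
#'
#' Per-bin recency scores (observed minus permuted-mean accuracy)
#' averaged over subjects.
#'
#' @param bins The `bins` tibble from [recency_scores()], optionally
#'   with a `group` column.
#' @return A ggplot object.
#' @export
plot_recency <- function(bins) {
  has_group <- "group" %in% names(bins)
  grp <- if (has_group) c("group", "bin") else "bin"
  summ <- bins |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(score = mean(.data$score, na.rm = TRUE),
                     .groups = "drop")
  p <- ggplot2::ggplot(summ, ggplot2::aes(.data$bin, .data$score)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Similarity bin (low to high)",
                  y = "Recency score") +
    ggplot2::theme_minimal()
  if (has_group) p <- p + ggplot2::facet_wrap(~group)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
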