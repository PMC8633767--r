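#' Tidy a fitted SUSTAIN model
#'
#' Returns the fitted free parameters as one row per term, broom-style.
#'
#' @param x A `sustain_fit` from [fit_model()].
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`.
#' @export
tidy.sustain_fit <- function(x, ...) {
  est <- c(unlist(x$params[c("r", "beta", "d_dec", "eta", "eta_lambda",
                             "tau")]))
  if (!is.na(x$tau_lesion)) est <- c(est, tau_lesion = x$tau_lesion)
  tibble::tibble(term = names(est), estimate = unname(est))
}

#' Glance at a fitted SUSTAIN model
#'
#' @param x A `sustain_fit` from [fit_model()].
#' @param ... Unused.
#' @return One-row tibble with `model_id`, `k`, `objective`, `aic`,
#'   `converged`.
#' @export
glance.sustain_fit <- function(x, ...) {
  tibble::tibble(model_id = x$spec$model_id, k = x$k,
                 objective = x$objective, aic = x$aic,
                 converged = x$converged)
}

#' Tidy a SUSTAIN training run
#'
#' @param x A `sustain_run` from [run_training()].
#' @param ... Unused.
#' @return The per-trial trace tibble.
#' @export
tidy.sustain_run <- function(x, ...) x$trace

#' Glance at a SUSTAIN training run
#'
#' @param x A `sustain_run` from [run_training()].
#' @param ... Unused.
#' @return One-row tibble with task metadata, final accuracy, cluster
#'   count, and final attention weights.
#' @export
glance.sustain_run <- function(x, ...) {
  tibble::tibble(
    rotation_deg = x$rotation_deg, task_class = x$task_class,
    n_trials = nrow(x$trace),
    final_accuracy = tail(x$curve$accuracy, 1),
    n_clusters = x$n_clusters,
    lambda_x = x$state$lam[1], lambda_y = x$state$lam[2]
  )
}
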