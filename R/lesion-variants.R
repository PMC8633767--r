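#' Declare a SUSTAIN model variant
#'
#' A model specification expresses one configuration of the three
#' lesion-simulating manipulations layered on the control network:
#' \describe{
#'   \item{static attention}{the feature-tuning mechanism is disabled by
#'     setting the attention focus `r` and the attention learning rate
#'     `eta_lambda` to 0, so attention weights never differentiate;}
#'   \item{attention shuffling}{the attention weights are permuted
#'     uniformly at random before every trial, so attention can still be
#'     learned but cannot be maintained on the relevant dimension;}
#'   \item{raised threshold}{the cluster recruitment threshold is raised
#'     above the control value (`tau_lesion` > `tau`), making surprise
#'     rarer and category representations sparser.}
#' }
#'
#' @param model_id Integer 0--5 (0 is the unlesioned control).
#' @param static_attention,shuffle_attention,raised_threshold Logical
#'   manipulation flags.
#' @param tau_lesion Recruitment threshold used when `raised_threshold`
#'   is set; must exceed the control `tau` at run time. `NA` leaves it
#'   free for fitting.
#' @return A `model_spec` object.
#' @seealso [make_model_table()], [apply_model_spec()]
#' @export
model_spec <- function(model_id, static_attention = FALSE,
                       shuffle_attention = FALSE, raised_threshold = FALSE,
                       tau_lesion = NA_real_) {
  stopifnot(length(model_id) == 1, model_id %in% 0:5)
  if (model_id == 0 && (static_attention || shuffle_attention || raised_threshold)) {
    stop("model 0 is the control: all flags must be off", call. = FALSE)
  }
  if (!raised_threshold && !is.na(tau_lesion)) {
    stop("`tau_lesion` only applies when `raised_threshold` is set", call. = FALSE)
  }
  structure(
    list(model_id = as.integer(model_id),
         static_attention = isTRUE(static_attention),
         shuffle_attention = isTRUE(shuffle_attention),
         raised_threshold = isTRUE(raised_threshold),
         tau_lesion = tau_lesion),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  flags <- c("static_attention", "shuffle_attention", "raised_threshold")
  on <- flags[vapply(x[flags], isTRUE, logical(1))]
  cat("<model_spec> model", x$model_id, ":",
      if (length(on) == 0) "control (no manipulation)" else paste(on, collapse = " + "),
      "\n")
  if (isTRUE(x$raised_threshold) && !is.na(x$tau_lesion)) {
    cat("  tau_lesion =", x$tau_lesion, "\n")
  }
  invisible(x)
}

#' Disable the feature-tuning mechanism
#'
#' Returns a parameter set with the attention focus `r` and the
#' attention learning rate `eta_lambda` set to 0 (the static-attention
#' lesion); all other parameters are untouched. Idempotent.
#'
#' @param params A [sustain_params()].
#' @return A `sustain_params` whose attention focus and attention
#'   learning rate are both zero.
#' @export
apply_static_attention <- function(params) {
  stopifnot(inherits(params, "sustain_params"))
  params$r <- 0
  params$eta_lambda <- 0
  params
}

#' Permute attention weights uniformly at random
#'
#' The trial-wise shuffling lesion: the attention-weight vector is
#' replaced by a uniformly random permutation of itself (with two
#' dimensions, a swap with probability 1/2). The multiset of weights is
#' conserved; the permutation is not undone afterward, so weights live
#' in their shuffled slots for subsequent updates. Uses the global RNG.
#'
#' @param lam Numeric attention-weight vector.
#' @return A permutation of `lam`.
#' @export
shuffle_attention <- function(lam) {
  lam[sample.int(length(lam))]
}

#' The six model variants fitted to learning curves
#'
#' One control plus five lesion variants built from the three
#' manipulations: model 1 = static attention; model 2 = attention
#' shuffling; model 3 = raised threshold; model 4 = static attention +
#' raised threshold; model 5 = attention shuffling + raised threshold
#' (the variant that best describes prelimbic-lesion behavior, pinning
#' the composition of the table).
#'
#' @return A tibble with columns `model_id`, `static_attention`,
#'   `shuffle_attention`, `raised_threshold`, and a list-column `spec`
#'   of [model_spec()] objects.
#' @export
#' @examples
#' make_model_table()
make_model_table <- function() {
  defs <- list(
    model_spec(0),
    model_spec(1, static_attention = TRUE),
    model_spec(2, shuffle_attention = TRUE),
    model_spec(3, raised_threshold = TRUE),
    model_spec(4, static_attention = TRUE, raised_threshold = TRUE),
    model_spec(5, shuffle_attention = TRUE, raised_threshold = TRUE)
  )
  tibble::tibble(
    model_id = vapply(defs, `[[`, integer(1), "model_id"),
    static_attention = vapply(defs, `[[`, logical(1), "static_attention"),
    shuffle_attention = vapply(defs, `[[`, logical(1), "shuffle_attention"),
    raised_threshold = vapply(defs, `[[`, logical(1), "raised_threshold"),
    spec = defs
  )
}

#' Resolve a model spec against a parameter set
#'
#' Applies the static-attention manipulation to the parameters and
#' selects the effective recruitment threshold and shuffle flag for the
#' simulation engine.
#'
#' @param params A [sustain_params()].
#' @param spec A [model_spec()] or `NULL` (control).
#' @return List with `params` (possibly static-attention-lesioned),
#'   `tau` (effective threshold), and `shuffle` (logical).
#' @export
apply_model_spec <- function(params, spec) {
  resolve_model_spec(params, spec)
}

resolve_model_spec <- function(params, spec) {
  stopifnot(inherits(params, "sustain_params"))
  if (is.null(spec)) {
    return(list(params = params, tau = params$tau, shuffle = FALSE))
  }
  stopifnot(inherits(spec, "model_spec"))
  eff <- params
  if (spec$static_attention) eff <- apply_static_attention(eff)
  tau <- params$tau
  if (spec$raised_threshold) {
    if (is.na(spec$tau_lesion)) {
      stop("`tau_lesion` is unset for a raised-threshold model", call. = FALSE)
    }
    if (spec$tau_lesion <= params$tau) {
      stop("`tau_lesion` must exceed the control `tau`", call. = FALSE)
    }
    tau <- spec$tau_lesion
  }
  list(params = eff, tau = tau, shuffle = spec$shuffle_attention)
}
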