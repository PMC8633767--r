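#' Attention-weighted psychological distance
#'
#' City-block distance between two stimuli with non-negative
#' per-dimension attention weights:
#' \eqn{d_{ij} = \sum_m w_m |x_{im} - x_{jm}|}. Computed on model
#' coordinates (the \eqn{[0,1]^2} scale), where the derived similarity
#' \eqn{e^{-d}} spans a useful range.
#'
#' @param x_i,x_j Two-column matrices (or length-2 vectors) of model
#'   coordinates.
#' @param w Two-column matrix (or length-2 vector) of non-negative
#'   attention weights.
#' @return Numeric vector of distances.
#' @export
#' @examples
#' psychological_distance(c(0, 0), c(0.2, 0.4), w = c(0.5, 0.5))
psychological_distance <- function(x_i, x_j, w) {
  x_i <- matrix(x_i, ncol = 2)
  x_j <- matrix(x_j, ncol = 2)
  w <- matrix(w, ncol = 2)
  if (any(w < 0)) stop("attention weights must be non-negative", call. = FALSE)
  rowSums(w * abs(x_i - x_j))
}

#' Perceptual similarity from psychological distance
#'
#' Exponential generalization gradient \eqn{s = e^{-d}}, strictly
#' decreasing in distance, equal to 1 for identical stimuli.
#'
#' @param d Non-negative distances.
#' @return Similarities in \eqn{(0, 1]}.
#' @export
perceptual_similarity <- function(d) {
  if (any(d < 0)) stop("distance must be non-negative", call. = FALSE)
  exp(-d)
}

#' Per-trial attention weights from a model trace
#'
#' Normalizes the traced attention weights of each trial to sum to 1,
#' so similarity magnitudes are comparable across training as the raw
#' weights grow. A degenerate all-zero weight pair falls back to
#' uniform (0.5, 0.5).
#'
#' @param lambda_x,lambda_y Traced attention weights per trial.
#' @return Two-column matrix of normalized weights (`w_x`, `w_y`).
#' @export
trial_weights <- function(lambda_x, lambda_y) {
  tot <- lambda_x + lambda_y
  w_x <- ifelse(tot > 0, lambda_x / tot, 0.5)
  cbind(w_x = w_x, w_y = ifelse(tot > 0, 1 - lambda_x / tot, 0.5))
}

.binned_accuracy <- function(s, correct, n_bins) {
  edges <- quantile(s, probs = seq(0, 1, length.out = n_bins + 1),
                    names = FALSE, type = 7)
  edges[1] <- -Inf
  edges[n_bins + 1] <- Inf
  edges <- unique(edges)   # heavy ties can collapse bins
  bin <- cut(s, edges, labels = FALSE)
  acc <- tapply(correct, factor(bin, levels = seq_len(length(edges) - 1)),
                mean)
  as.numeric(acc)
}

.median_split_accuracy <- function(s, correct) {
  med <- median(s)
  c(high = mean(correct[s > med]), low = mean(correct[s <= med]))
}

#' Permutation-null perceptual recency scores
#'
#' Quantifies how much first-attempt accuracy depends on the perceptual
#' similarity between the current exemplar (n) and the immediately
#' preceding exemplar (n-1), against a trial-order permutation null.
#' For each subject: similarity `s(n, n-1)` is the exponential of the
#' attention-weighted city-block distance using that trial's normalized
#' attention weights; accuracy is binned by similarity quantiles (and
#' by a median split); then trial order is shuffled `n_perm` times --
#' whole (stimulus, correctness, weight) triplets move together, so
#' marginal accuracy is preserved and only adjacency is destroyed --
#' and the mean permuted binned accuracy is subtracted. Positive scores
#' mean trial order helped accuracy at that similarity level.
#' Correction trials must be excluded beforehand (the generator's
#' traces contain first attempts only). Uses the global RNG.
#'
#' @param traces Model-trace tibble (training phase) with columns
#'   `subject_id`, `x`, `y`, `correct`, `lambda_x`, `lambda_y`, in
#'   trial order.
#' @param n_perm Number of permutations (default 1000).
#' @param n_bins Number of similarity quantile bins (default 8).
#' @return A list of tibbles: `bins` (per subject and similarity bin:
#'   observed accuracy, permuted mean, recency `score`, permutation
#'   `perm_se`, and the 2.5/97.5% permutation band `perm_lo`,
#'   `perm_hi`) and `splits` (per subject and median-split half:
#'   `score`, `perm_se`).
#' @export
recency_scores <- function(traces, n_perm = 1000, n_bins = 8) {
  stopifnot(n_perm >= 1, n_bins >= 2)
  need <- c("subject_id", "x", "y", "correct", "lambda_x", "lambda_y")
  if (!all(need %in% names(traces))) {
    stop("`traces` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }

  traces |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) .recency_one(df, n_perm, n_bins)) |>
    dplyr::ungroup() |>
    (\(res) list(
      bins = dplyr::select(
        dplyr::filter(res, .data$kind == "bin"),
        "subject_id", bin = "level", "observed", "perm_mean",
        "score", "perm_se", "perm_lo", "perm_hi"
      ),
      splits = dplyr::select(
        dplyr::filter(res, .data$kind == "split"),
        "subject_id", split = "level_chr", "observed", "perm_mean",
        "score", "perm_se"
      )
    ))()
}

.recency_one <- function(df, n_perm, n_bins) {
  n <- nrow(df)
  if (n < 2) stop("need at least 2 trials per subject", call. = FALSE)
  X <- cbind(df$x, df$y)
  W <- trial_weights(df$lambda_x, df$lambda_y)
  correct <- as.numeric(df$correct)

  seq_sim <- function(ord) {
    cur <- ord[-1]
    prev <- ord[-length(ord)]
    # weight of the current trial n, similarity to trial n-1
    s <- perceptual_similarity(
      psychological_distance(X[cur, , drop = FALSE],
                             X[prev, , drop = FALSE],
                             W[cur, , drop = FALSE])
    )
    list(s = s, acc = correct[cur])
  }

  obs <- seq_sim(seq_len(n))
  obs_bins <- .binned_accuracy(obs$s, obs$acc, n_bins)
  obs_split <- .median_split_accuracy(obs$s, obs$acc)

  perm_bins <- matrix(NA_real_, n_perm, length(obs_bins))
  perm_split <- matrix(NA_real_, n_perm, 2)
  for (k in seq_len(n_perm)) {
    pm <- seq_sim(sample.int(n))
    perm_bins[k, ] <- .binned_accuracy(pm$s, pm$acc, n_bins)
    perm_split[k, ] <- .median_split_accuracy(pm$s, pm$acc)
  }

  pm_bin_mean <- colMeans(perm_bins, na.rm = TRUE)
  pm_bin_se <- apply(perm_bins, 2, sd, na.rm = TRUE) / sqrt(n_perm)
  pm_bin_lo <- apply(perm_bins, 2, quantile, 0.025, na.rm = TRUE)
  pm_bin_hi <- apply(perm_bins, 2, quantile, 0.975, na.rm = TRUE)
  pm_sp_mean <- colMeans(perm_split)
  pm_sp_se <- apply(perm_split, 2, sd) / sqrt(n_perm)

  dplyr::bind_rows(
    tibble::tibble(
      kind = "bin", level = seq_along(obs_bins), level_chr = NA_character_,
      observed = obs_bins, perm_mean = pm_bin_mean,
      score = obs_bins - pm_bin_mean, perm_se = pm_bin_se,
      perm_lo = pm_bin_lo, perm_hi = pm_bin_hi
    ),
    tibble::tibble(
      kind = "split", level = NA_integer_, level_chr = c("high", "low"),
      observed = as.numeric(obs_split), perm_mean = pm_sp_mean,
      score = as.numeric(obs_split) - pm_sp_mean, perm_se = pm_sp_se
    )
  )
}

#' One-sample t-tests of recency scores against zero
#'
#' Tests, per group and median-split half, whether subjects' recency
#' scores differ from zero. A degenerate spread (all scores equal)
#' yields `NA` statistics with a flag instead of an error.
#'
#' @param splits The `splits` tibble from [recency_scores()], joined
#'   with a `group` column (one row per subject and split).
#' @return Tibble with one row per group x split: `n`, `mean_score`,
#'   `t`, `df`, `p_value`, `degenerate`.
#' @export
group_recency_test <- function(splits) {
  stopifnot(all(c("group", "split", "score") %in% names(splits)))
  splits |>
    dplyr::group_by(.data$group, .data$split) |>
    dplyr::summarise(.t_one(.data$score), .groups = "drop")
}

.t_one <- function(x) {
  n <- length(x)
  if (n < 2) {
    return(tibble::tibble(n = n, mean_score = mean(x), t = NA_real_,
                          df = NA_real_, p_value = NA_real_,
                          degenerate = TRUE))
  }
  if (sd(x) == 0) {
    return(tibble::tibble(n = n, mean_score = mean(x),
                          t = if (mean(x) == 0) 0 else NA_real_,
                          df = n - 1, p_value = NA_real_,
                          degenerate = TRUE))
  }
  tt <- t.test(x, mu = 0)
  tibble::tibble(n = n, mean_score = mean(x),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, degenerate = FALSE)
}
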