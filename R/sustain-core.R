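#' SUSTAIN network parameters
#'
#' Bundles the free parameters of the SUSTAIN adaptive clustering
#' network. Defaults are the package's control configuration, chosen so
#' that an unlesioned agent on the study schedule (15 sessions of 80
#' trials) learns from chance to above 75% accuracy, represents 1D tasks
#' with a cluster per category, and recruits several clusters per
#' category on 2D tasks.
#'
#' @param r Attention focus: exponent weighting high-attention dimensions
#'   in cluster activation (>= 0, dimensionless).
#' @param beta Cluster competition exponent (>= 0).
#' @param d_dec Decision consistency: softmax temperature inverse on the
#'   category-unit activations (>= 0).
#' @param eta Learning rate for cluster positions and association
#'   weights, in \eqn{[0, 1]}.
#' @param eta_lambda Attention learning rate (>= 0). The classic
#'   single-rate network is recovered with `eta_lambda = eta`.
#' @param tau Cluster recruitment threshold in \eqn{[0, 1]}: an incorrect
#'   response whose winning-cluster activation exceeds `tau` (a confident
#'   error, i.e. a surprising stimulus) recruits a new cluster.
#' @return A `sustain_params` object (named list).
#' @export
#' @examples
#' sustain_params(r = 3, tau = 0.9)
sustain_params <- function(r = 4, beta = 2, d_dec = 8, eta = 0.03,
                           eta_lambda = 0.01, tau = 0.6) {
  vals <- list(r = r, beta = beta, d_dec = d_dec, eta = eta,
               eta_lambda = eta_lambda, tau = tau)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) != 1 || !is.finite(v) || v < 0) {
      stop("`", nm, "` must be a single non-negative number", call. = FALSE)
    }
  }
  if (eta > 1) stop("`eta` must lie in [0, 1]", call. = FALSE)
  if (tau > 1) stop("`tau` must lie in [0, 1]", call. = FALSE)
  structure(vals, class = "sustain_params")
}

#' @export
print.sustain_params <- function(x, ...) {
  cat("<sustain_params>",
      sprintf("r=%g beta=%g d_dec=%g eta=%g eta_lambda=%g tau=%g",
              x$r, x$beta, x$d_dec, x$eta, x$eta_lambda, x$tau), "\n")
  invisible(x)
}

#' Convert normalized stimulus coordinates to model coordinates
#'
#' The network operates on the normalized stimulus space scaled by 1/100,
#' so coordinates lie in \eqn{[0, 1]^2} and the exponential receptive
#' fields `exp(-lambda * mu)` are non-degenerate at the initial attention
#' weight of 1. The same scale is used by the recency analysis.
#'
#' @param x_norm,y_norm Coordinates on the normalized 0--100 scale.
#' @return A two-column matrix of model coordinates.
#' @export
to_model_coords <- function(x_norm, y_norm) {
  cbind(x = x_norm / 100, y = y_norm / 100)
}

#' Create a SUSTAIN network state
#'
#' The state holds the recruited clusters (positions in model
#' coordinates and association weights to the two category units) and
#' the per-dimension attention weights lambda, initialized equal (at 1).
#' A fresh state has no clusters; the first training stimulus seeds one.
#'
#' @param pos Numeric matrix (clusters x 2) of cluster positions, or
#'   `NULL` for a fresh state.
#' @param assoc Numeric matrix (clusters x 2) of association weights to
#'   categories A and B.
#' @param lam Length-2 attention weight vector.
#' @return A `sustain_state` object.
#' @export
sustain_state <- function(pos = NULL, assoc = NULL, lam = c(1, 1)) {
  if (is.null(pos)) {
    pos <- matrix(numeric(0), 0, 2)
    assoc <- matrix(numeric(0), 0, 2)
  }
  pos <- as.matrix(pos); assoc <- as.matrix(assoc)
  stopifnot(ncol(pos) == 2, ncol(assoc) == 2, nrow(pos) == nrow(assoc),
            length(lam) == 2, all(lam >= 0))
  structure(list(pos = pos, assoc = assoc, lam = as.numeric(lam),
                 n_trials_seen = 0L),
            class = "sustain_state")
}

#' @export
print.sustain_state <- function(x, ...) {
  cat("<sustain_state>", nrow(x$pos), "cluster(s), lambda = (",
      paste(signif(x$lam, 4), collapse = ", "), ")\n")
  invisible(x)
}

#' Attention-weighted cluster activations
#'
#' Each cluster's activation is the attention-weighted average of
#' exponential receptive-field responses across dimensions:
#' \deqn{H_j = \sum_i \lambda_i^r e^{-\lambda_i \mu_{ij}} / \sum_i \lambda_i^r,}
#' where \eqn{\mu_{ij}} is the city-block distance between stimulus and
#' cluster position on dimension i. Activations lie in (0, 1], reaching 1
#' only when the stimulus coincides with the cluster.
#'
#' @param state A [sustain_state()] with at least one cluster.
#' @param x Length-2 stimulus in model coordinates.
#' @param params A [sustain_params()].
#' @return Numeric vector of per-cluster activations.
#' @export
cluster_activations <- function(state, x, params) {
  if (nrow(state$pos) == 0) stop("state has no clusters", call. = FALSE)
  lam <- state$lam
  a <- lam^params$r
  if (sum(a) <= 0) a <- c(0.5, 0.5)
  mu <- abs(sweep(state$pos, 2, x))          # clusters x dims
  resp <- exp(-sweep(mu, 2, lam, `*`))
  drop(resp %*% a) / sum(a)
}

#' Winner-take-all cluster competition
#'
#' Clusters compete by lateral inhibition: the most activated cluster
#' (ties broken toward the lowest index) passes
#' \eqn{H_{win}^\beta / \sum_k H_k^\beta \cdot H_{win}} to the decision
#' layer; all other outputs are zero.
#'
#' @param h_act Activation vector from [cluster_activations()].
#' @param beta Competition exponent.
#' @return Output vector with a single nonzero entry (the winner's).
#' @export
compete <- function(h_act, beta) {
  stopifnot(length(h_act) >= 1)
  win <- which.max(h_act)                    # which.max takes lowest index on ties
  s <- sum(h_act^beta)
  out <- numeric(length(h_act))
  out[win] <- if (s > 0) h_act[win]^beta / s * h_act[win] else h_act[win]
  out
}

#' Probabilistic category decision
#'
#' Category-unit activations are the association-weighted cluster
#' outputs, \eqn{C_z = \sum_j w_{jz} H_j^{out}}, and the response is
#' sampled from the softmax \eqn{p(z) \propto e^{d \cdot C_z}}. Uses the
#' global RNG.
#'
#' @param state A [sustain_state()].
#' @param outputs Cluster output vector from [compete()].
#' @param d_dec Decision consistency.
#' @return A list with `c_out` (category-unit activations, A then B),
#'   `p` (choice probabilities), and `choice` ("A" or "B").
#' @export
decide <- function(state, outputs, d_dec) {
  c_out <- drop(t(state$assoc) %*% outputs)
  p_a <- 1 / (1 + exp(-d_dec * (c_out[1] - c_out[2])))
  p <- c(A = p_a, B = 1 - p_a)
  choice <- if (runif(1) < p_a) "A" else "B"
  list(c_out = setNames(c_out, c("A", "B")), p = p, choice = choice)
}

#' Surprise-gated cluster recruitment
#'
#' A new cluster is recruited when the sampled response was incorrect
#' and the winning cluster's activation exceeds the threshold `tau`
#' (the network was confident in a wrong answer). The new cluster is
#' centered on the stimulus with zero association weights and becomes
#' the winner for the trial's update step.
#'
#' @param state A [sustain_state()].
#' @param x Stimulus in model coordinates.
#' @param h_act Activations from [cluster_activations()].
#' @param choice Sampled response ("A" or "B").
#' @param feedback_category True category ("A" or "B").
#' @param params A [sustain_params()].
#' @param recruit How "misclassifies" is read: `"predict"` (default)
#'   recruits when the winner's predicted category -- the argmax of its
#'   association weights, ties to A -- differs from the feedback;
#'   `"choice"` recruits when the sampled response was wrong.
#' @return List with the (possibly extended) `state`, logical
#'   `recruited`, and `winner` (index to use for the update step).
#' @export
maybe_recruit <- function(state, x, h_act, choice, feedback_category, params,
                          recruit = c("predict", "choice")) {
  recruit <- match.arg(recruit)
  win <- which.max(h_act)
  recruited <- FALSE
  misclassified <- if (recruit == "choice") {
    choice != feedback_category
  } else {
    predicted <- if (state$assoc[win, 1] >= state$assoc[win, 2]) "A" else "B"
    predicted != feedback_category
  }
  if (misclassified && h_act[win] > params$tau) {
    state$pos <- rbind(state$pos, x)
    state$assoc <- rbind(state$assoc, c(0, 0))
    win <- nrow(state$pos)
    recruited <- TRUE
  }
  list(state = state, recruited = recruited, winner = win)
}

#' Feedback-driven state update
#'
#' Applies the per-trial learning step to the winning cluster and the
#' attention weights: the winner's position moves toward the stimulus
#' (`eta`), attention follows the receptive-field tuning gradient
#' \eqn{\Delta\lambda_i = \eta_\lambda e^{-\lambda_i \mu_i}(1 - \lambda_i \mu_i)}
#' (floored at 0), and the winner's association weights follow a
#' humble-teacher delta rule (target 1 for the fed-back category, 0
#' otherwise, with no penalty for overshoot).
#'
#' @param state A [sustain_state()].
#' @param x Stimulus in model coordinates.
#' @param winner Index of the cluster to update (post-recruitment winner
#'   if recruitment occurred).
#' @param h_out Winner's competition output used for the weight update.
#' @param feedback_category True category ("A" or "B").
#' @param params A [sustain_params()].
#' @return The updated `sustain_state`.
#' @export
sustain_update <- function(state, x, winner, h_out, feedback_category, params) {
  mu <- abs(x - state$pos[winner, ])
  lam <- state$lam
  state$lam <- pmax(0, lam + params$eta_lambda * exp(-lam * mu) * (1 - lam * mu))
  c_out <- state$assoc[winner, ] * h_out
  target <- if (feedback_category == "A") c(1, 0) else c(0, 1)
  err <- ifelse(target == 1,
                pmax(0, 1 - c_out),               # overshoot above 1 not punished
                ifelse(c_out > 0, -c_out, 0))     # undershoot below 0 not punished
  state$assoc[winner, ] <- state$assoc[winner, ] + params$eta * err * h_out
  state$pos[winner, ] <- state$pos[winner, ] + params$eta * (x - state$pos[winner, ])
  state$n_trials_seen <- state$n_trials_seen + 1L
  state
}

#' One full SUSTAIN trial (reference implementation)
#'
#' Steps the network through a single supervised trial in pure R:
#' optional attention shuffling, activation, competition, decision,
#' surprise-gated recruitment, and the feedback update. This is the
#' readable reference path; [run_training()] uses an equivalent compiled
#' loop.
#'
#' @param state A [sustain_state()] (a fresh state seeds its first
#'   cluster on `x`).
#' @param x Length-2 stimulus in model coordinates.
#' @param category True category ("A" or "B").
#' @param params A [sustain_params()].
#' @param shuffle If `TRUE`, apply a uniformly random permutation to the
#'   attention weights before the trial (lesion manipulation).
#' @param learn If `FALSE`, decide only (no recruitment or update).
#' @param recruit Recruitment rule, `"predict"` or `"choice"`; see
#'   [maybe_recruit()].
#' @return List with the updated `state` and an `outcome` list
#'   (`h_act`, `winner`, `c_out`, `p`, `choice`, `correct`, `recruited`,
#'   `lam_used`).
#' @export
sustain_step <- function(state, x, category, params,
                         shuffle = FALSE, learn = TRUE,
                         recruit = c("predict", "choice")) {
  recruit <- match.arg(recruit)
  if (nrow(state$pos) == 0) {
    state$pos <- matrix(x, 1, 2)
    state$assoc <- matrix(0, 1, 2)
  }
  if (shuffle && state$lam[1] != state$lam[2]) {
    state$lam <- shuffle_attention(state$lam)
  }
  lam_used <- state$lam

  h_act <- cluster_activations(state, x, params)
  outputs <- compete(h_act, params$beta)
  dec <- decide(state, outputs, params$d_dec)
  correct <- dec$choice == category

  rec <- list(state = state, recruited = FALSE, winner = which.max(h_act))
  h_out <- outputs[rec$winner]
  if (learn) {
    rec <- maybe_recruit(state, x, h_act, dec$choice, category, params,
                         recruit = recruit)
    state <- rec$state
    if (rec$recruited) {
      # recompute competition with the new cluster (activation exactly 1)
      h_out <- 1 / (sum(h_act^params$beta) + 1)
    }
    state <- sustain_update(state, x, rec$winner, h_out, category, params)
  }
  list(
    state = state,
    outcome = list(h_act = h_act, winner = rec$winner, c_out = dec$c_out,
                   p = dec$p, choice = dec$choice, correct = correct,
                   recruited = rec$recruited, lam_used = lam_used)
  )
}

.stimuli_to_cpp <- function(exemplars) {
  list(
    X = to_model_coords(exemplars$x_norm, exemplars$y_norm),
    cat = as.integer(exemplars$category == "B")
  )
}

#' Train a SUSTAIN agent on a category task
#'
#' Simulates a full training schedule (by default 15 sessions of 80
#' trials) of one agent on one task: exemplars are sampled from the
#' task's training distributions, and the network runs the supervised
#' trial loop with feedback after every trial. Returns the per-session
#' learning curve, the per-trial trace, and the final network state.
#' Uses the global RNG; call [set.seed()] for reproducibility.
#'
#' @param task A [build_task()] object.
#' @param params A [sustain_params()].
#' @param n_sessions,trials_per_session Training schedule.
#' @param spec Optional [model_spec()] applying lesion manipulations
#'   (static attention, trial-wise attention shuffling, raised
#'   recruitment threshold). `NULL` runs the control network.
#' @param exemplars Optional pre-sampled exemplar tibble (from
#'   [sample_exemplars()]); by default sampled fresh.
#' @param recruit Recruitment rule, `"predict"` (default) or `"choice"`;
#'   see [maybe_recruit()].
#' @return A `sustain_run` object: list with `curve` (tibble of
#'   per-session first-attempt accuracy), `trace` (per-trial tibble:
#'   trial, session, coordinates, category, winner, n_clusters,
#'   lambda_x, lambda_y, p_correct, choice, correct, recruited),
#'   `state` (final [sustain_state()]), `n_clusters`, and the task
#'   metadata.
#' @export
#' @examples
#' set.seed(1)
#' run <- run_training(build_task(0), sustain_params(),
#'                     n_sessions = 3, trials_per_session = 40)
#' run$curve
run_training <- function(task, params, n_sessions = 15,
                         trials_per_session = 80, spec = NULL,
                         exemplars = NULL,
                         recruit = c("predict", "choice")) {
  recruit <- match.arg(recruit)
  stopifnot(inherits(task, "category_task"), inherits(params, "sustain_params"),
            n_sessions >= 1, trials_per_session >= 1)
  eff <- resolve_model_spec(params, spec)
  n <- n_sessions * trials_per_session
  if (is.null(exemplars)) {
    exemplars <- sample_exemplars(task, n, "train")
  }
  stopifnot(nrow(exemplars) == n)
  inp <- .stimuli_to_cpp(exemplars)

  res <- sustain_run_cpp(
    inp$X, inp$cat,
    eff$params$r, eff$params$beta, eff$params$d_dec, eff$params$eta,
    eff$params$eta_lambda, eff$tau, eff$shuffle,
    learn = TRUE, emit_corrections = FALSE, correction_cap = 0L,
    recruit_on_choice = (recruit == "choice")
  )

  session <- rep(seq_len(n_sessions), each = trials_per_session)
  trace <- tibble::tibble(
    trial = seq_len(n),
    session = session,
    x = inp$X[, 1], y = inp$X[, 2],
    category = exemplars$category,
    winner = res$winner,
    n_clusters = res$n_clusters,
    lambda_x = res$lam_x, lambda_y = res$lam_y,
    p_correct = res$p_correct,
    choice = factor(c("A", "B")[res$choice + 1], levels = c("A", "B")),
    correct = res$correct,
    recruited = res$recruited
  )
  curve <- trace |>
    dplyr::group_by(session) |>
    dplyr::summarise(accuracy = mean(correct), .groups = "drop")

  state <- sustain_state(res$pos, res$assoc, res$lam)
  state$n_trials_seen <- n

  structure(
    list(curve = curve, trace = trace, state = state,
         n_clusters = nrow(res$pos),
         rotation_deg = task$rotation_deg, task_class = task$task_class),
    class = "sustain_run"
  )
}

#' @export
print.sustain_run <- function(x, ...) {
  cat("<sustain_run>", x$task_class, "task (rotation", x$rotation_deg,
      "deg):", nrow(x$trace), "trials,", x$n_clusters, "clusters\n")
  cat("  final-session accuracy:",
      round(tail(x$curve$accuracy, 1), 3), "\n")
  invisible(x)
}
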