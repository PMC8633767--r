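#' Configuration for a synthetic touchscreen cohort
#'
#' Bundles the design constants and noise-model parameters used by
#' [generate_cohort()]. The defaults reproduce the study design exactly:
#' 8 subjects per group (control/lesion crossed with 1D/2D task class,
#' rotations balanced within class), 15 training sessions of 80 trials
#' with correction-trial loops, and 5 testing sessions of 80 trials
#' drawn from the expanded testing distributions without corrections.
#'
#' Reaction-time and touch-coordinate generators are simulation
#' conveniences (the behavioural study reports no generative model for
#' them); their parameters are exposed here so the dependent-measure
#' pipeline can be exercised and recovered against known values.
#'
#' @param n_per_group Subjects per group x task-class cell.
#' @param rotations Task rotations to include.
#' @param n_train_sessions,trials_per_session,n_test_sessions Schedule.
#' @param control_params [sustain_params()] driving every agent.
#' @param lesion_spec [model_spec()] applied to lesion-group agents
#'   (default: model 5, attention shuffling + recruitment threshold
#'   raised to 0.85).
#' @param correction_cap Maximum correction replays per trial.
#' @param cue_rt_start,cue_rt_asym Mean cue-phase RT (seconds) at the
#'   start of training and asymptotically; the mean decays
#'   exponentially with training progress.
#' @param cue_rt_lesion_1d Multiplicative cue-RT factor for lesion
#'   subjects on 1D tasks (> 1 slows them; choice RT is never scaled).
#' @param choice_rt_start,choice_rt_asym Mean choice-phase RT (seconds).
#' @param rt_sdlog Log-normal shape parameter for both RTs.
#' @param touch_center Screen x-coordinate (pixels) of the cue stimulus.
#' @param touch_gain Horizontal drift gain (pixels per unit choice
#'   confidence) applied to the third, pre-choice touch.
#' @param touch_jitter Gaussian jitter SD (pixels) on each touch.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 8,
                          rotations = c(0, 45, 90, 135),
                          n_train_sessions = 15,
                          trials_per_session = 80,
                          n_test_sessions = 5,
                          control_params = sustain_params(),
                          lesion_spec = model_spec(
                            5, shuffle_attention = TRUE,
                            raised_threshold = TRUE, tau_lesion = 0.85
                          ),
                          correction_cap = 10,
                          cue_rt_start = 4, cue_rt_asym = 1.5,
                          cue_rt_lesion_1d = 1.3,
                          choice_rt_start = 2, choice_rt_asym = 1,
                          rt_sdlog = 0.35,
                          touch_center = 400,
                          touch_gain = 60,
                          touch_jitter = 30) {
  stopifnot(n_per_group >= 1, all(rotations %in% c(0, 45, 90, 135)),
            inherits(control_params, "sustain_params"),
            inherits(lesion_spec, "model_spec"))
  structure(as.list(environment()), class = "cohort_config")
}

#' Reaction-time noise model
#'
#' Log-normal cue- and choice-phase reaction times whose means decay
#' exponentially with training progress. The cue-phase mean is
#' multiplied by `factor` (the group-by-task modifier, > 1 for lesion
#' subjects on 1D tasks); the choice-phase mean never is, emulating a
#' stimulus-evaluation (not motor) slowing. Uses the global RNG.
#'
#' @param progress Training progress in \eqn{[0, 1]} (testing sessions
#'   use 1), vectorized.
#' @param factor Cue-RT multiplier (scalar or vector).
#' @param config A [cohort_config()] supplying the RT constants.
#' @return Tibble with columns `cue_rt`, `choice_rt` (seconds).
#' @export
rt_model <- function(progress, factor = 1, config = cohort_config()) {
  stopifnot(all(progress >= 0 & progress <= 1), all(factor > 0))
  n <- length(progress)
  decay <- exp(-3 * progress)
  cue_mean <- (config$cue_rt_asym +
                 (config$cue_rt_start - config$cue_rt_asym) * decay) * factor
  choice_mean <- config$choice_rt_asym +
    (config$choice_rt_start - config$choice_rt_asym) * decay
  sdl <- config$rt_sdlog
  tibble::tibble(
    cue_rt = rlnorm(n, log(cue_mean) - sdl^2 / 2, sdl),
    choice_rt = rlnorm(n, log(choice_mean) - sdl^2 / 2, sdl)
  )
}

#' Touch-coordinate noise model
#'
#' Generates the three cue-phase touch x-coordinates of a trial. The
#' first two touches scatter around the stimulus center; the third
#' (pre-choice) touch drifts toward the chosen side by
#' `touch_gain * confidence` pixels, emulating anticipatory movement
#' that grows with choice confidence. Under mean-centred touch
#' separation this yields an expected third-touch separation of
#' `2/3 * touch_gain * confidence` toward the chosen side. Uses the
#' global RNG.
#'
#' @param choice_side Character vector, `"left"` or `"right"`.
#' @param confidence Choice confidence in \eqn{[0, 0.5]} (distance of
#'   the choice probability from 0.5), vectorized.
#' @param config A [cohort_config()] supplying center, gain, jitter.
#' @return Tibble with columns `touch_x1`, `touch_x2`, `touch_x3`
#'   (pixels).
#' @export
touch_model <- function(choice_side, confidence, config = cohort_config()) {
  stopifnot(all(choice_side %in% c("left", "right")),
            all(confidence >= 0 & confidence <= 0.5))
  n <- length(choice_side)
  confidence <- rep_len(confidence, n)
  sgn <- ifelse(choice_side == "right", 1, -1)
  ctr <- config$touch_center
  jit <- config$touch_jitter
  tibble::tibble(
    touch_x1 = rnorm(n, ctr, jit),
    touch_x2 = rnorm(n, ctr, jit),
    touch_x3 = rnorm(n, ctr + sgn * config$touch_gain * confidence, jit)
  )
}

.subject_plan <- function(config) {
  rot_1d <- intersect(c(0, 90), config$rotations)
  rot_2d <- intersect(c(45, 135), config$rotations)
  plan <- list()
  idx <- 0
  for (group in c("control", "lesion")) {
    for (class_rots in list(rot_1d, rot_2d)) {
      if (length(class_rots) == 0) next
      for (k in seq_len(config$n_per_group)) {
        idx <- idx + 1
        plan[[idx]] <- list(
          group = group,
          rotation_deg = class_rots[(k - 1) %% length(class_rots) + 1],
          subject_index = idx
        )
      }
    }
  }
  plan
}

#' Generate a complete synthetic cohort
#'
#' Simulates every subject of a touchscreen category-learning study:
#' SUSTAIN agents (lesion-group agents run the configured
#' [model_spec()] manipulations) are trained trial by trial on their
#' assigned task, errors trigger correction-trial replays of the same
#' stimulus (decision-only, capped), and testing sessions draw from the
#' expanded distributions with no corrections. Reaction times and touch
#' coordinates are attached from the cohort noise models. Subjects are
#' seeded deterministically from the master seed, so regeneration is
#' row-identical.
#'
#' @param config A [cohort_config()].
#' @param seed Master seed (integer).
#' @return List with elements `trials` (one row per trial attempt:
#'   subject, group, rotation, task class, phase, session, trial,
#'   attempt, correction/capped flags, stimulus coordinates, category,
#'   trial type for testing rows, response, correctness, RTs, touch
#'   coordinates) and `traces` (per first-attempt model trace: winner,
#'   cluster count, attention weights, choice probability, recruitment
#'   flag).
#' @export
#' @examples
#' cfg <- cohort_config(n_per_group = 1, n_train_sessions = 2,
#'                      trials_per_session = 20, n_test_sessions = 1)
#' cohort <- generate_cohort(cfg, seed = 1)
#' dplyr::count(cohort$trials, group, phase)
generate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  plan <- .subject_plan(config)
  out <- purrr::map(plan, function(sub) {
    set.seed((seed + 7919L * sub$subject_index) %% .Machine$integer.max)
    .simulate_subject(sub, config)
  })
  list(
    trials = dplyr::bind_rows(purrr::map(out, "trials")),
    traces = dplyr::bind_rows(purrr::map(out, "traces"))
  )
}

.simulate_subject <- function(sub, config) {
  task <- build_task(sub$rotation_deg)
  lesioned <- sub$group == "lesion"
  eff <- resolve_model_spec(config$control_params,
                            if (lesioned) config$lesion_spec else NULL)
  id <- sprintf("%s-%s-%02d", substr(sub$group, 1, 1),
                tolower(task$task_class), sub$subject_index)

  n_train <- config$n_train_sessions * config$trials_per_session
  n_test <- config$n_test_sessions * config$trials_per_session
  ex_train <- sample_exemplars(task, n_train, "train")
  ex_test <- sample_exemplars(task, n_test, "test")

  inp <- .stimuli_to_cpp(ex_train)
  p <- eff$params
  res_tr <- sustain_run_cpp(
    inp$X, inp$cat, p$r, p$beta, p$d_dec, p$eta, p$eta_lambda, eff$tau,
    eff$shuffle, learn = TRUE, emit_corrections = TRUE,
    correction_cap = as.integer(config$correction_cap)
  )
  inp_te <- .stimuli_to_cpp(ex_test)
  res_te <- sustain_run_cpp(
    inp_te$X, inp_te$cat, p$r, p$beta, p$d_dec, p$eta, p$eta_lambda, eff$tau,
    eff$shuffle, learn = TRUE, emit_corrections = FALSE, correction_cap = 0L,
    init_pos = res_tr$pos, init_assoc = res_tr$assoc, init_lam = res_tr$lam
  )

  first_attempts <- function(res, ex, phase, session_offset, n_sess) {
    n <- nrow(ex)
    tibble::tibble(
      phase = phase,
      session = session_offset + rep(seq_len(n_sess),
                                     each = config$trials_per_session),
      trial = rep(seq_len(config$trials_per_session), n_sess),
      attempt = 0L, is_correction = FALSE, capped = FALSE,
      x_norm = ex$x_norm, y_norm = ex$y_norm,
      category = ex$category,
      response = ifelse(res$choice == 0, "left", "right"),
      correct = res$correct,
      p_correct = res$p_correct
    )
  }
  tr_rows <- first_attempts(res_tr, ex_train, "train", 0L,
                            config$n_train_sessions)
  te_rows <- first_attempts(res_te, ex_test, "test", config$n_train_sessions,
                            config$n_test_sessions)
  te_rows$trial_type <- classify_trial_type(ex_test, task)$trial_type

  # correction replays: same stimulus, re-decided, no reinforcement
  if (length(res_tr$corr_trial) > 0) {
    parent <- res_tr$corr_trial                 # global first-attempt index
    co_rows <- tr_rows[parent, ]
    co_rows$attempt <- res_tr$corr_attempt
    co_rows$is_correction <- TRUE
    co_rows$capped <- res_tr$corr_capped == 1
    co_rows$response <- ifelse(res_tr$corr_choice == 0, "left", "right")
    co_rows$correct <- res_tr$corr_correct == 1
    tr_rows <- dplyr::bind_rows(tr_rows, co_rows) |>
      dplyr::arrange(session, trial, attempt)
  }

  trials <- dplyr::bind_rows(tr_rows, te_rows)
  progress <- ifelse(
    trials$phase == "test", 1,
    ((trials$session - 1) * config$trials_per_session + trials$trial - 1) /
      max(1, n_train - 1)
  )
  rt_fac <- if (lesioned && task$task_class == "1D") config$cue_rt_lesion_1d else 1
  rts <- rt_model(progress, rt_fac, config)
  conf <- abs(trials$p_correct - 0.5)
  touches <- touch_model(trials$response, conf, config)

  trials <- dplyr::bind_cols(
    tibble::tibble(subject_id = id, group = sub$group,
                   rotation_deg = sub$rotation_deg,
                   task_class = task$task_class),
    trials, rts, touches
  )

  trace_tbl <- function(res, rows, ex) {
    tibble::tibble(
      subject_id = id, group = sub$group,
      rotation_deg = sub$rotation_deg, task_class = task$task_class,
      phase = rows$phase, session = rows$session, trial = rows$trial,
      x = ex$x_norm / 100, y = ex$y_norm / 100,
      category = ex$category,
      winner = res$winner, n_clusters = res$n_clusters,
      lambda_x = res$lam_x, lambda_y = res$lam_y,
      p_correct = res$p_correct,
      choice = factor(c("A", "B")[res$choice + 1], levels = c("A", "B")),
      correct = res$correct, recruited = res$recruited
    )
  }
  traces <- dplyr::bind_rows(
    trace_tbl(res_tr, tr_rows[!tr_rows$is_correction, ], ex_train),
    trace_tbl(res_te, te_rows, ex_test)
  )
  list(trials = trials, traces = traces)
}

#' Group-averaged learning curves from a trial log
#'
#' Collapses a trial log to per-session group-mean first-attempt
#' accuracy, the format consumed by [fit_model()]. Correction rows and
#' testing sessions are excluded; pooling is the unweighted mean over
#' subjects.
#'
#' @param trials Trial log from [generate_cohort()] (or any log with
#'   the same columns).
#' @return Tibble with columns `group`, `task_class`, `session`,
#'   `accuracy`, `n_subjects`, `trials_per_session`.
#' @export
make_learning_curves <- function(trials) {
  trials |>
    dplyr::filter(.data$phase == "train", !.data$is_correction) |>
    dplyr::group_by(.data$group, .data$task_class, .data$subject_id,
                    .data$session) |>
    dplyr::summarise(accuracy = mean(.data$correct),
                     n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$group, .data$task_class, .data$session) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      trials_per_session = as.integer(round(mean(.data$n_trials))),
      accuracy = mean(.data$accuracy),
      .groups = "drop"
    ) |>
    dplyr::select("group", "task_class", "session", "accuracy",
                  "n_subjects", "trials_per_session")
}
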