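#' Fitting configuration
#'
#' Controls for [fit_model()]: Monte-Carlo averaging size, multi-start
#' budget, the likelihood behind the objective, and the master seed
#' that makes the whole fit deterministic (stimulus sequences and
#' choice sampling use common random numbers across parameter
#' evaluations, so the stochastic objective is quasi-deterministic for
#' the optimizer).
#'
#' @param n_sim Simulated training runs averaged per group x task-class
#'   prediction (default 100; 20 is a reasonable floor for quick fits).
#' @param n_starts Local searches launched (default 8).
#' @param n_screen Latin-hypercube points screened with a single
#'   objective evaluation each; the best `n_starts` of them seed the
#'   local searches (default 32). Screening cheaply locates promising
#'   basins of the multimodal objective before spending Nelder-Mead
#'   iterations.
#' @param maxit Nelder-Mead iteration budget per start.
#' @param seed Master seed for the fit.
#' @param objective `"binomial"` (negative log-likelihood of per-session
#'   success counts; AIC = 2k + 2 NLL) or `"gaussian"` (sum of squared
#'   errors; AIC = n log(SSE/n) + 2k).
#' @return A `fit_config` list.
#' @export
fit_config <- function(n_sim = 100, n_starts = 8, n_screen = 32,
                       maxit = 200, seed = 1,
                       objective = c("binomial", "gaussian")) {
  stopifnot(n_sim >= 1, n_starts >= 1, n_screen >= n_starts, maxit >= 10)
  structure(list(n_sim = n_sim, n_starts = n_starts, n_screen = n_screen,
                 maxit = maxit, seed = seed,
                 objective = match.arg(objective)),
            class = "fit_config")
}

# free-parameter box constraints
.par_bounds <- list(
  r = c(0, 10), beta = c(0, 10), d_dec = c(0, 20),
  eta = c(0, 1), eta_lambda = c(0, 2), tau = c(0, 1),
  tau_lesion_frac = c(0, 1)   # tau_lesion = tau + frac * (1 - tau)
)

.theta_names <- function(spec) {
  nm <- c("r", "beta", "d_dec", "eta", "eta_lambda", "tau")
  if (!is.null(spec) && spec$raised_threshold) nm <- c(nm, "tau_lesion_frac")
  nm
}

.theta_to_params <- function(theta, spec) {
  nm <- names(theta)
  vals <- purrr::map2_dbl(theta, nm, function(v, n) {
    b <- .par_bounds[[if (n == "tau_lesion_frac") "tau_lesion_frac" else n]]
    b[1] + v * (b[2] - b[1])
  })
  p <- sustain_params(
    r = vals[["r"]], beta = vals[["beta"]], d_dec = vals[["d_dec"]],
    eta = vals[["eta"]], eta_lambda = vals[["eta_lambda"]],
    tau = vals[["tau"]]
  )
  tau_lesion <- NA_real_
  if ("tau_lesion_frac" %in% nm) {
    # strictly above the control threshold, within (tau, 1]
    tau_lesion <- vals[["tau"]] +
      max(vals[["tau_lesion_frac"]], 1e-6) * (1 - vals[["tau"]])
  }
  list(params = p, tau_lesion = tau_lesion)
}

# pre-generated stimulus sequences per task class (both rotations pooled)
.fit_stimuli <- function(task_class, n_sim, n_sessions, trials_per_session) {
  rots <- if (task_class == "1D") c(0, 90) else c(45, 135)
  n <- n_sessions * trials_per_session
  purrr::map(seq_len(n_sim), function(i) {
    task <- build_task(rots[(i - 1) %% 2 + 1])
    .stimuli_to_cpp(sample_exemplars(task, n, "train"))
  })
}

.predict_curve <- function(stims, params, tau, shuffle, trials_per_session) {
  acc <- sustain_curve_batch_cpp(
    purrr::map(stims, "X"), purrr::map(stims, "cat"),
    params$r, params$beta, params$d_dec, params$eta, params$eta_lambda,
    tau, shuffle, as.integer(trials_per_session)
  )
  colMeans(acc)
}

#' Monte-Carlo mean learning curve of a model variant
#'
#' Averages `n_sim` independent simulated training runs of a model
#' configuration on one task class; the two rotations of the class (0
#' and 90 degrees for 1D, 45 and 135 for 2D) are pooled with equal
#' weight. This is the forward model behind [fit_model()].
#'
#' @param params A [sustain_params()].
#' @param task_class `"1D"` or `"2D"`.
#' @param spec Optional [model_spec()] applying lesion manipulations.
#' @param n_sim Number of runs averaged.
#' @param seed Seed (stimuli and choice sampling).
#' @param n_sessions,trials_per_session Schedule.
#' @return Tibble with columns `session`, `accuracy`.
#' @export
simulate_mean_curve <- function(params, task_class, spec = NULL, n_sim = 100,
                                seed = 1, n_sessions = 15,
                                trials_per_session = 80) {
  stopifnot(task_class %in% c("1D", "2D"))
  eff <- resolve_model_spec(params, spec)
  set.seed(seed)
  stims <- .fit_stimuli(task_class, n_sim, n_sessions, trials_per_session)
  acc <- .predict_curve(stims, eff$params, eff$tau, eff$shuffle,
                        trials_per_session)
  tibble::tibble(session = seq_len(n_sessions), accuracy = acc)
}

.curve_matrix <- function(curves) {
  need <- c("group", "task_class", "session", "accuracy", "n_subjects",
            "trials_per_session")
  if (!all(need %in% names(curves))) {
    stop("`curves` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dplyr::arrange(curves, .data$group, .data$task_class, .data$session)
}

.fit_objective <- function(curves, preds, objective) {
  p_hat <- pmin(pmax(preds, 1e-4), 1 - 1e-4)
  if (objective == "binomial") {
    size <- curves$trials_per_session * curves$n_subjects
    succ <- round(curves$accuracy * size)
    -sum(dbinom(succ, size, p_hat, log = TRUE))
  } else {
    sum((curves$accuracy - preds)^2)
  }
}

.fit_aic <- function(objective_value, k, n_points, objective) {
  if (objective == "binomial") 2 * k + 2 * objective_value
  else n_points * log(objective_value / n_points) + 2 * k
}

# Monte-Carlo predictor for both groups and task classes. The lesion
# group is always simulated with its own seed (even for the control
# spec, whose manipulations are no-ops), so nested specs evaluated at
# equivalent parameters reproduce the same predictions exactly.
.make_predictor <- function(spec, stims, tps, eval_seed) {
  function(theta) {
    tp <- .theta_to_params(theta, spec)
    out <- list()
    for (cls in names(stims)) {
      set.seed(eval_seed)
      out[[paste0("control.", cls)]] <- .predict_curve(
        stims[[cls]], tp$params, tp$params$tau, shuffle = FALSE, tps
      )
      eff_p <- if (spec$static_attention) {
        apply_static_attention(tp$params)
      } else {
        tp$params
      }
      eff_tau <- if (spec$raised_threshold) tp$tau_lesion else tp$params$tau
      set.seed(eval_seed + 1L)
      out[[paste0("lesion.", cls)]] <- .predict_curve(
        stims[[cls]], eff_p, eff_tau, shuffle = spec$shuffle_attention, tps
      )
    }
    out
  }
}

# natural parameter values -> unit-box theta
.params_to_theta <- function(params, spec, tau_lesion = NA) {
  nm <- .theta_names(spec)
  vals <- c(r = params$r, beta = params$beta, d_dec = params$d_dec,
            eta = params$eta, eta_lambda = params$eta_lambda,
            tau = params$tau)
  if ("tau_lesion_frac" %in% nm) {
    frac <- if (is.na(tau_lesion)) 0.01 else {
      (tau_lesion - params$tau) / max(1e-12, 1 - params$tau)
    }
    vals <- c(vals, tau_lesion_frac = frac)
  }
  theta <- vapply(nm, function(n) {
    b <- .par_bounds[[n]]
    (vals[[n]] - b[1]) / (b[2] - b[1])
  }, numeric(1))
  pmin(pmax(theta, 0), 1)
}

#' Objective value of a model variant at given parameters
#'
#' Evaluates the fitting objective (without optimizing) for a parameter
#' set under a [model_spec()], using the same common-random-number
#' Monte-Carlo predictions as [fit_model()]. Useful for objective
#' diagnostics and parameter-sensitivity checks.
#'
#' @param params A [sustain_params()].
#' @param curves Learning-curve tibble.
#' @param spec A [model_spec()] (default control).
#' @param tau_lesion Lesion threshold for raised-threshold specs.
#' @param config A [fit_config()].
#' @return The scalar objective value.
#' @export
curve_objective <- function(params, curves, spec = model_spec(0),
                            tau_lesion = NA, config = fit_config()) {
  curves <- .curve_matrix(curves)
  n_sessions <- max(curves$session)
  tps <- curves$trials_per_session[1]
  set.seed(config$seed)
  stims <- list(
    `1D` = .fit_stimuli("1D", config$n_sim, n_sessions, tps),
    `2D` = .fit_stimuli("2D", config$n_sim, n_sessions, tps)
  )
  eval_seed <- sample.int(2^31 - 2, 1)
  predict_all <- .make_predictor(spec, stims, tps, eval_seed)
  theta <- .params_to_theta(params, spec, tau_lesion)
  preds <- predict_all(theta)
  pv <- vapply(seq_len(nrow(curves)), function(i) {
    preds[[paste(curves$group[i], curves$task_class[i], sep = ".")]][
      curves$session[i]
    ]
  }, numeric(1))
  .fit_objective(curves, pv, config$objective)
}

#' Fit a model variant to group-averaged learning curves
#'
#' Optimizes the free parameters of one [model_spec()] against observed
#' per-session accuracies of both groups and both task classes jointly.
#' Parameters are shared across groups; the variant's lesion
#' manipulations apply only to the lesion group's predictions (the control model
#' predicts identical curves for both groups). The predicted curve for
#' each condition is the Monte-Carlo mean of `n_sim` simulated runs
#' with common random numbers, and the objective is by default the
#' binomial negative log-likelihood of per-session success counts.
#' Optimization is bounded multi-start Nelder-Mead from Latin-hypercube
#' starting points; identical seeds and configuration give bit-identical
#' results.
#'
#' @param spec A [model_spec()].
#' @param curves Learning-curve tibble (see [make_learning_curves()]):
#'   columns `group`, `task_class`, `session`, `accuracy`,
#'   `n_subjects`, `trials_per_session`.
#' @param config A [fit_config()].
#' @param warm_start Optional list with a [sustain_params()] element
#'   `params` (and `tau_lesion` for raised-threshold specs) added as an
#'   extra starting point -- e.g. the optimum of a nested model.
#' @return A `sustain_fit` object: the spec, fitted [sustain_params()]
#'   (+ `tau_lesion` where applicable), the objective value, free
#'   parameter count `k`, `aic`, predicted curves, and a convergence
#'   flag.
#' @export
fit_model <- function(spec, curves, config = fit_config(),
                      warm_start = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(config, "fit_config"))
  curves <- .curve_matrix(curves)
  n_sessions <- max(curves$session)
  tps <- curves$trials_per_session[1]
  nm <- .theta_names(spec)
  k <- length(nm)

  set.seed(config$seed)
  stims <- list(
    `1D` = .fit_stimuli("1D", config$n_sim, n_sessions, tps),
    `2D` = .fit_stimuli("2D", config$n_sim, n_sessions, tps)
  )
  candidates <- lhs::randomLHS(config$n_screen, k)
  eval_seed <- sample.int(2^31 - 2, 1)

  predict_all <- .make_predictor(spec, stims, tps, eval_seed)
  pred_vector <- function(theta) {
    preds <- predict_all(theta)
    vapply(seq_len(nrow(curves)), function(i) {
      preds[[paste(curves$group[i], curves$task_class[i], sep = ".")]][
        curves$session[i]
      ]
    }, numeric(1))
  }

  theta_objective <- function(theta) {
    names(theta) <- nm
    .fit_objective(curves, pred_vector(theta), config$objective)
  }
  objfun <- function(z) theta_objective(stats::plogis(z))

  # screen the candidate grid, start local searches from the best points
  screened <- vapply(seq_len(nrow(candidates)), function(i) {
    theta_objective(candidates[i, ])
  }, numeric(1))
  starts <- candidates[order(screened)[seq_len(config$n_starts)], ,
                       drop = FALSE]
  if (!is.null(warm_start)) {
    ws <- .params_to_theta(warm_start$params, spec,
                           warm_start$tau_lesion %||% NA)
    starts <- rbind(starts, ws)
  }

  best <- NULL
  converged <- FALSE
  for (s in seq_len(nrow(starts))) {
    z0 <- stats::qlogis(pmin(pmax(starts[s, ], 0.02), 0.98))
    opt <- optim(z0, objfun, method = "Nelder-Mead",
                 control = list(maxit = config$maxit))
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0) converged <- TRUE
  }

  theta_hat <- stats::plogis(best$par)
  names(theta_hat) <- nm
  tp <- .theta_to_params(theta_hat, spec)
  preds <- predict_all(theta_hat)
  sim_curves <- tidyr::expand_grid(
    group = c("control", "lesion"), task_class = c("1D", "2D"),
    session = seq_len(n_sessions)
  ) |>
    dplyr::mutate(accuracy = purrr::pmap_dbl(
      list(.data$group, .data$task_class, .data$session),
      function(g, cl, s) preds[[paste(g, cl, sep = ".")]][s]
    ))

  structure(
    list(spec = spec, params = tp$params, tau_lesion = tp$tau_lesion,
         objective = best$value, k = k,
         aic = .fit_aic(best$value, k, nrow(curves), config$objective),
         sim_curves = sim_curves, curves = curves,
         converged = converged, config = config),
    class = "sustain_fit"
  )
}

#' @export
print.sustain_fit <- function(x, ...) {
  cat("<sustain_fit> model", x$spec$model_id,
      sprintf("| k=%d NLL/SSE=%.2f AIC=%.2f%s\n", x$k, x$objective, x$aic,
              if (x$converged) "" else " (no start converged)"))
  print(x$params)
  if (!is.na(x$tau_lesion)) cat("  tau_lesion =", round(x$tau_lesion, 3), "\n")
  invisible(x)
}

#' Fit all model variants
#'
#' Runs [fit_model()] for every row of a model table.
#'
#' @param curves Learning-curve tibble.
#' @param model_table Tibble from [make_model_table()].
#' @param config A [fit_config()].
#' @return List of `sustain_fit` objects, one per model.
#' @export
fit_models <- function(curves, model_table = make_model_table(),
                       config = fit_config()) {
  purrr::map(model_table$spec, fit_model, curves = curves, config = config)
}

#' Rank fitted models by AIC
#'
#' @param fits List of `sustain_fit` objects (from [fit_models()]).
#' @return Tibble in ascending AIC order with `model_id`, `k`,
#'   `objective`, `aic`, `delta_aic`, and `winner` flag on the
#'   smallest-AIC model.
#' @export
compare_models <- function(fits) {
  tbl <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(model_id = f$spec$model_id, k = f$k,
                   objective = f$objective, aic = f$aic)
  }) |>
    dplyr::arrange(.data$aic) |>
    dplyr::mutate(delta_aic = .data$aic - min(.data$aic),
                  winner = dplyr::row_number() == 1)
  tbl
}

#' Cluster-count and attention diagnostics of a fitted model
#'
#' Re-simulates the fitted model and reports, per group and task class,
#' the distribution of final cluster counts (total, and per category by
#' each cluster's dominant association weight) and the mean attention
#' trajectory. For 1D tasks attention is reported as
#' relevant/irrelevant (pooling the 0- and 90-degree rotations onto
#' their relevant screen axis); for 2D tasks both dimensions are
#' relevant and are reported as x/y.
#'
#' @param fit A `sustain_fit`.
#' @param n_sim Simulated runs per condition.
#' @param seed Seed.
#' @return List of tibbles `clusters` (group, task_class, mean_total,
#'   modal_total, mean_per_category) and `attention` (group,
#'   task_class, trial, lambda_relevant, lambda_irrelevant).
#' @export
winner_diagnostics <- function(fit, n_sim = 50, seed = 1) {
  stopifnot(inherits(fit, "sustain_fit"))
  spec <- fit$spec
  params <- fit$params
  les_spec <- if (!is.na(fit$tau_lesion)) {
    sp <- spec
    sp$tau_lesion <- fit$tau_lesion
    sp
  } else {
    spec
  }

  conds <- tidyr::expand_grid(group = c("control", "lesion"),
                              rotation = c(0, 45, 90, 135))
  res <- purrr::pmap_dfr(conds, function(group, rotation) {
    task <- build_task(rotation)
    use_spec <- if (group == "lesion" && les_spec$model_id > 0) les_spec else NULL
    set.seed(seed + rotation + ifelse(group == "lesion", 1000, 0))
    runs <- purrr::map(seq_len(n_sim), function(i) {
      run_training(task, params, spec = use_spec)
    })
    tot <- purrr::map_int(runs, "n_clusters")
    per_cat <- purrr::map_dbl(runs, function(r) {
      a <- sum(r$state$assoc[, 1] >= r$state$assoc[, 2])
      mean(c(a, r$n_clusters - a))
    })
    lam <- purrr::map(runs, function(r) {
      cbind(r$trace$lambda_x, r$trace$lambda_y)
    })
    lam_x <- rowMeans(do.call(cbind, purrr::map(lam, function(m) m[, 1])))
    lam_y <- rowMeans(do.call(cbind, purrr::map(lam, function(m) m[, 2])))
    rel_is_x <- rotation != 90   # rotation 90: relevant screen axis is y
    tibble::tibble(
      group = group, rotation = rotation, task_class = task$task_class,
      trial = seq_along(lam_x),
      lambda_relevant = if (rel_is_x) lam_x else lam_y,
      lambda_irrelevant = if (rel_is_x) lam_y else lam_x,
      mean_total = mean(tot),
      modal_total = as.integer(names(sort(table(tot), decreasing = TRUE))[1]),
      mean_per_category = mean(per_cat)
    )
  })

  clusters <- res |>
    dplyr::distinct(.data$group, .data$rotation, .data$task_class,
                    .data$mean_total, .data$modal_total,
                    .data$mean_per_category) |>
    dplyr::group_by(.data$group, .data$task_class) |>
    dplyr::summarise(mean_total = mean(.data$mean_total),
                     modal_total = as.integer(round(mean(.data$modal_total))),
                     mean_per_category = mean(.data$mean_per_category),
                     .groups = "drop")
  attention <- res |>
    dplyr::group_by(.data$group, .data$task_class, .data$trial) |>
    dplyr::summarise(lambda_relevant = mean(.data$lambda_relevant),
                     lambda_irrelevant = mean(.data$lambda_irrelevant),
                     .groups = "drop")
  list(clusters = clusters, attention = attention)
}
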