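# shared fixtures: small schedules keep module tests fast

tiny_cohort <- function(seed = 1, ...) {
  cfg <- cohort_config(n_per_group = 2, n_train_sessions = 3,
                       trials_per_session = 30, n_test_sessions = 1, ...)
  generate_cohort(cfg, seed = seed)
}

# straight-line forward pass written independently of the package
# internals: plain arithmetic on one stimulus, used as the oracle
oracle_forward <- function(pos, assoc, lam, x, r, beta, d_dec) {
  n <- nrow(pos)
  H <- numeric(n)
  for (j in seq_len(n)) {
    num <- 0; den <- 0
    for (i in 1:2) {
      num <- num + lam[i]^r * exp(-lam[i] * abs(x[i] - pos[j, i]))
      den <- den + lam[i]^r
    }
    H[j] <- num / den
  }
  win <- which.max(H)
  hout <- H[win]^beta / sum(H^beta) * H[win]
  CA <- assoc[win, 1] * hout
  CB <- assoc[win, 2] * hout
  pA <- exp(d_dec * CA) / (exp(d_dec * CA) + exp(d_dec * CB))
  list(H = H, win = win, hout = hout, c_out = c(CA, CB), p = c(pA, 1 - pA))
}

# simulated training traces for a batch of control subjects, as the
# recency analysis consumes them
agent_traces <- function(n_subjects, params = sustain_params(),
                         n_trials = 1200, seed_base = 5000,
                         learn_after_session1 = TRUE,
                         trials_per_session = 80) {
  dplyr::bind_rows(lapply(seq_len(n_subjects), function(i) {
    set.seed(seed_base + i)
    task <- build_task(c(0, 90, 45, 135)[(i - 1) %% 4 + 1])
    ex <- sample_exemplars(task, n_trials, "train")
    run <- run_training(task, params, n_sessions = n_trials %/% trials_per_session,
                        trials_per_session = trials_per_session,
                        exemplars = ex)
    tr <- run$trace
    if (!learn_after_session1) {
      # freeze the network after session 1 and replay the rest
      n1 <- trials_per_session
      set.seed(seed_base + i)
      ex2 <- sample_exemplars(task, n_trials, "train")
      inp <- to_model_coords(ex2$x_norm, ex2$y_norm)
      cat01 <- as.integer(ex2$category == "B")
      r1 <- ratcat:::sustain_run_cpp(inp[1:n1, ], cat01[1:n1],
                            params$r, params$beta, params$d_dec, params$eta,
                            params$eta_lambda, params$tau,
                            FALSE, TRUE, FALSE, 0L, FALSE)
      r2 <- ratcat:::sustain_run_cpp(inp[(n1 + 1):n_trials, ], cat01[(n1 + 1):n_trials],
                            params$r, params$beta, params$d_dec, params$eta,
                            params$eta_lambda, params$tau,
                            FALSE, FALSE, FALSE, 0L, FALSE,
                            init_pos = r1$pos, init_assoc = r1$assoc,
                            init_lam = r1$lam)
      tr <- tibble::tibble(
        trial = (n1 + 1):n_trials,
        x = inp[(n1 + 1):n_trials, 1], y = inp[(n1 + 1):n_trials, 2],
        correct = r2$correct, lambda_x = r2$lam_x, lambda_y = r2$lam_y
      )
    }
    dplyr::mutate(tr[, c("x", "y", "correct", "lambda_x", "lambda_y")],
                  subject_id = sprintf("s%03d", i), .before = 1)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
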