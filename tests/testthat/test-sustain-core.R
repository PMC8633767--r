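test_that("cluster activations follow the attention-weighted receptive fields", {
  p <- sustain_params(r = 1)
  st <- sustain_state(pos = rbind(c(0.3, 0.5)), assoc = rbind(c(0, 0)))

  # coincident stimulus activates fully
  expect_equal(cluster_activations(st, c(0.3, 0.5), p), 1)

  # hand evaluation: lambda = (1,1), r = 1, mu = (0.2, 0.4)
  expect_equal(cluster_activations(st, c(0.5, 0.9), p),
               (exp(-0.2) + exp(-0.4)) / 2, tolerance = 1e-12)
  expect_equal((exp(-0.2) + exp(-0.4)) / 2, 0.74452, tolerance = 1e-5)

  # r = 0 neutralizes the attention exponent
  st2 <- st; st2$lam <- c(7, 0.2)
  expect_equal(cluster_activations(st2, c(0.5, 0.9), sustain_params(r = 0)),
               (7^0 * exp(-7 * 0.2) + 0.2^0 * exp(-0.2 * 0.4)) / 2,
               tolerance = 1e-12)
})

test_that("competition is winner-take-all with lowest-index tie-breaking", {
  expect_equal(compete(0.8, beta = 2), 0.8)
  expect_equal(compete(c(0.8, 0.4), beta = 1), c(0.8^2 / 1.2, 0))
  out <- compete(c(0.5, 0.5), beta = 1)
  expect_equal(out, c(0.25, 0))           # first cluster wins exact ties
})

test_that("decisions are a softmax over association-weighted outputs", {
  st <- sustain_state(pos = rbind(c(0.3, 0.5)), assoc = rbind(c(2, 1)))
  set.seed(1)
  d0 <- decide(st, outputs = 0.5, d_dec = 0)
  expect_equal(unname(d0$p), c(0.5, 0.5))

  st2 <- sustain_state(pos = rbind(c(0.3, 0.5)), assoc = rbind(c(2, 0)))
  d2 <- decide(st2, outputs = 0.5, d_dec = 2)    # C = (1, 0), d = 2
  expect_equal(unname(d2$p[1]), exp(2) / (exp(2) + 1), tolerance = 1e-12)
  expect_equal(unname(d2$p[1]), 0.88080, tolerance = 1e-5)

  st3 <- sustain_state(pos = rbind(c(0.3, 0.5)), assoc = rbind(c(0, 0)))
  expect_equal(unname(decide(st3, outputs = 0.9, d_dec = 10)$p),
               c(0.5, 0.5))
  # probabilities always sum to one
  for (i in 1:20) {
    stx <- sustain_state(pos = rbind(runif(2)), assoc = rbind(rnorm(2)))
    expect_equal(sum(decide(stx, runif(1), runif(1, 0, 20))$p), 1,
                 tolerance = 1e-12)
  }
})

test_that("recruitment requires a confident misclassification", {
  p <- sustain_params(tau = 0.5)
  st <- sustain_state(pos = rbind(c(0.3, 0.5)), assoc = rbind(c(1, 0)))
  h_hi <- 0.9
  h_lo <- 0.3

  # correct choice never recruits under the sampled-choice rule
  r <- maybe_recruit(st, c(0.4, 0.5), h_hi, "A", "A", p, recruit = "choice")
  expect_false(r$recruited)

  # incorrect and confident: recruit, new cluster becomes the winner
  r <- maybe_recruit(st, c(0.4, 0.5), h_hi, "B", "A", p, recruit = "choice")
  expect_true(r$recruited)
  expect_equal(nrow(r$state$pos), 2)
  expect_equal(r$winner, 2)
  expect_equal(r$state$assoc[2, ], c(0, 0))

  # below threshold: no recruitment however wrong
  r <- maybe_recruit(st, c(0.4, 0.5), h_lo, "B", "A", p, recruit = "choice")
  expect_false(r$recruited)

  # prediction rule: winner predicts A (w = (1,0)); feedback B recruits
  # even when the sampled choice was B (and thus correct)
  r <- maybe_recruit(st, c(0.4, 0.5), h_hi, "B", "B", p, recruit = "predict")
  expect_true(r$recruited)
  r <- maybe_recruit(st, c(0.4, 0.5), h_hi, "A", "A", p, recruit = "predict")
  expect_false(r$recruited)
})

test_that("the feedback update moves the winner and tunes attention", {
  x <- c(0.4, 0.6)
  st <- sustain_state(pos = rbind(c(0.3, 0.5)), assoc = rbind(c(0.2, 0.1)))

  # zero learning rates change nothing
  p0 <- sustain_params(eta = 0, eta_lambda = 0)
  st2 <- sustain_update(st, x, winner = 1, h_out = 0.5,
                        feedback_category = "A", p0)
  expect_equal(st2$pos, st$pos)
  expect_equal(st2$assoc, st$assoc)
  expect_equal(st2$lam, st$lam)

  # lambda * mu = 1 is the fixed point of the attention rule
  p1 <- sustain_params(eta = 0, eta_lambda = 0.3)
  stf <- sustain_state(pos = rbind(c(0.3, 0.5)), assoc = rbind(c(0, 0)),
                       lam = c(10, 10))
  stf2 <- sustain_update(stf, c(0.4, 0.6), winner = 1, h_out = 0.5,
                         feedback_category = "A", p1)
  expect_equal(stf2$lam, c(10, 10), tolerance = 1e-12)

  # mu = 0: delta lambda = eta_lambda exactly
  p2 <- sustain_params(eta = 0, eta_lambda = 0.1)
  stz <- sustain_state(pos = rbind(c(0.4, 0.6)), assoc = rbind(c(0, 0)))
  stz2 <- sustain_update(stz, c(0.4, 0.6), winner = 1, h_out = 0.5,
                         feedback_category = "A", p2)
  expect_equal(stz2$lam, c(1.1, 1.1), tolerance = 1e-12)

  # humble teacher: drives the fed-back category up, the other down,
  # and never punishes overshoot
  p3 <- sustain_params(eta = 0.5)
  sth <- sustain_state(pos = rbind(c(0.4, 0.6)), assoc = rbind(c(3, 0.5)))
  sth2 <- sustain_update(sth, c(0.4, 0.6), winner = 1, h_out = 0.5,
                         feedback_category = "A", p3)
  expect_equal(sth2$assoc[1, 1], 3)        # C_A = 1.5 > 1: clipped
  expect_lt(sth2$assoc[1, 2], 0.5)
})

test_that("single-trial forward pass matches a straight-line oracle", {
  set.seed(42)
  for (i in 1:10) {
    nc <- sample(1:5, 1)
    pos <- matrix(runif(2 * nc), nc, 2)
    assoc <- matrix(rnorm(2 * nc), nc, 2)
    lam <- runif(2, 0, 5)
    x <- runif(2)
    r <- runif(1, 0, 6); beta <- runif(1, 0, 4); d <- runif(1, 0, 15)

    st <- sustain_state(pos, assoc, lam)
    p <- sustain_params(r = r, beta = beta, d_dec = d)
    H <- cluster_activations(st, x, p)
    out <- compete(H, beta)
    dec <- decide(st, out, d)

    orc <- oracle_forward(pos, assoc, lam, x, r, beta, d)
    expect_equal(H, orc$H, tolerance = 1e-10)
    expect_equal(which(out > 0), orc$win)
    expect_equal(max(out), orc$hout, tolerance = 1e-10)
    expect_equal(unname(dec$c_out), orc$c_out, tolerance = 1e-10)
    expect_equal(unname(dec$p), orc$p, tolerance = 1e-10)
  }
})

test_that("the compiled trial loop reproduces the pure-R reference path", {
  set.seed(77)
  task <- build_task(45)
  ex <- sample_exemplars(task, 120, "train")
  p <- sustain_params()

  set.seed(123)
  run <- run_training(task, p, n_sessions = 3, trials_per_session = 40,
                      exemplars = ex)

  set.seed(123)
  st <- sustain_state()
  X <- to_model_coords(ex$x_norm, ex$y_norm)
  for (t in 1:120) {
    res <- sustain_step(st, X[t, ], as.character(ex$category[t]), p)
    st <- res$state
    expect_equal(res$outcome$correct, run$trace$correct[t])
    expect_equal(unname(res$outcome$p[1]),
                 ifelse(ex$category[t] == "A", run$trace$p_correct[t],
                        1 - run$trace$p_correct[t]),
                 tolerance = 1e-12)
    expect_equal(res$outcome$recruited, run$trace$recruited[t])
    expect_equal(nrow(st$pos), run$trace$n_clusters[t])
  }
  expect_equal(st$lam, run$state$lam, tolerance = 1e-12)
  expect_equal(unname(st$pos), unname(run$state$pos), tolerance = 1e-12)
})

test_that("training runs learn the task and recruit sensibly", {
  p <- sustain_params()
  final_acc_1d <- numeric(20); clusters_1d <- integer(20)
  lam_sep <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    run <- run_training(build_task(0), p)
    final_acc_1d[s] <- mean(tail(run$curve$accuracy, 3))
    clusters_1d[s] <- run$n_clusters
    last <- run$trace[run$trace$session == 15, ]
    lam_sep[s] <- mean(last$lambda_x - last$lambda_y)
  }
  # monotone-trending curve from near chance to above 0.75
  expect_gt(mean(final_acc_1d), 0.75)
  # modal final cluster count is one per category
  tab <- table(clusters_1d)
  expect_equal(as.integer(names(tab)[which.max(tab)]), 2)
  # attention separates toward the relevant dimension (one-sided t)
  expect_gt(mean(lam_sep) / (sd(lam_sep) / sqrt(20)), qt(0.95, 19))

  # 2D task: attention stays (approximately) equivalent across dimensions
  ratio <- numeric(10)
  for (s in 1:10) {
    set.seed(100 + s)
    run2 <- run_training(build_task(45), p)
    ratio[s] <- log(run2$state$lam[1] / run2$state$lam[2])
  }
  expect_lt(abs(mean(ratio)), 0.2)
})

test_that("attention is inert when the focus exponent and its learning rate are zero", {
  p <- apply_static_attention(sustain_params())
  acc_plain <- numeric(50); acc_shuffled <- numeric(50)
  for (s in 1:50) {
    set.seed(s)
    acc_plain[s] <- mean(tail(run_training(build_task(0), p)$curve$accuracy, 3))
    set.seed(s + 500)
    acc_shuffled[s] <- mean(tail(run_training(
      build_task(0), p,
      spec = model_spec(2, shuffle_attention = TRUE)
    )$curve$accuracy, 3))
  }
  expect_gt(suppressWarnings(ks.test(acc_plain, acc_shuffled))$p.value, 0.01)
})

test_that("mean recruitment is non-increasing in the threshold", {
  # the threshold gates choice-error recruitment directly, so the
  # monotonicity property is stated for that rule; under the default
  # prediction rule the threshold acts indirectly (blocking corrective
  # recruitment can prolong errors), which is checked on the 2D task
  taus <- c(0.3, 0.5, 0.7, 0.9)
  for (rot in c(0, 45)) {
    means <- vapply(taus, function(tau) {
      p <- sustain_params(tau = tau)
      mean(vapply(1:50, function(s) {
        set.seed(s)
        run_training(build_task(rot), p, n_sessions = 5,
                     trials_per_session = 40,
                     recruit = "choice")$n_clusters
      }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(means) <= 1e-9))
  }
  means_2d <- vapply(taus, function(tau) {
    p <- sustain_params(tau = tau)
    mean(vapply(1:20, function(s) {
      set.seed(s)
      run_training(build_task(45), p)$n_clusters
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means_2d) <= 1e-9))
})
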