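test_that("frequency and orientation normalizations match the printed transformations", {
  # printed raw range maps onto the 0-100 common range
  expect_equal(normalize_frequency(1.2232), 100.00309, tolerance = 1e-6)
  expect_equal(normalize_frequency(0.2532), 0.003093, tolerance = 1e-3)
  expect_equal(normalize_frequency(0.0097 * (26.10 + 50)), 50)
  expect_equal(normalize_orientation(0), 0)
  expect_equal(normalize_orientation(pi / 2), 90)
  expect_equal(normalize_orientation(1.75), 1.75 * 180 / pi, tolerance = 1e-9)
  expect_equal(normalize_orientation(1.75), 100.2676, tolerance = 1e-4)

  expect_error(normalize_frequency(0), "positive")
  expect_error(normalize_frequency(-1), "positive")
  expect_error(normalize_orientation(-0.1), "1.75")
  expect_error(normalize_orientation(1.8), "1.75")
})

test_that("normalization round-trips through its inverse", {
  x <- seq(0, 100, length.out = 21)
  expect_equal(normalize_frequency(denormalize_frequency(x)), x,
               tolerance = 1e-9)
  expect_equal(normalize_orientation(denormalize_orientation(x)), x,
               tolerance = 1e-9)
})

test_that("build_task places and rotates the category distributions correctly", {
  t0 <- build_task(0)
  expect_equal(t0$mu_a, c(30, 50))
  expect_equal(t0$mu_b, c(70, 50))
  expect_equal(t0$task_class, "1D")
  expect_equal(t0$relevant_axis, c(1, 0))

  t90 <- build_task(90)
  expect_equal(t90$mu_a, c(50, 30))
  expect_equal(t90$mu_b, c(50, 70))
  expect_equal(t90$task_class, "1D")

  t45 <- build_task(45)
  expect_equal(t45$task_class, "2D")
  # rotation by 45 degrees equalizes the marginal variances and couples
  # the dimensions
  expect_equal(t45$cov[1, 1], t45$cov[2, 2])
  expect_true(abs(t45$cov[1, 2]) > 1)

  expect_error(build_task(30), "must be one of")
})

test_that("rotation is an isometry of the task geometry", {
  for (rot in c(0, 45, 90, 135)) {
    tk <- build_task(rot)
    expect_equal(sqrt(sum((tk$mu_a - tk$mu_b)^2)), 40, tolerance = 1e-9)
    ev <- sort(eigen(tk$cov, symmetric = TRUE)$values)
    expect_equal(ev, c(2.5^2, 20^2), tolerance = 1e-9)
  }
})

test_that("sampled exemplars follow the task distributions and stay displayable", {
  set.seed(11)
  task <- build_task(0)
  n <- 1e4
  ex <- sample_exemplars(task, n, "train")
  expect_true(all(ex$x_norm >= 0 & ex$x_norm <= 100))
  expect_true(all(ex$y_norm >= 0 & ex$y_norm <= 100))
  # raw units consistent with the normalized coordinates
  expect_equal(normalize_frequency(ex$freq_cpd), ex$x_norm, tolerance = 1e-9)

  a <- ex[ex$category == "A", ]
  expect_equal(mean(a$x_norm), 30, tolerance = 5 * 2.5 / sqrt(nrow(a)))
  # equiprobable labels: fair-coin balance bound
  expect_lt(abs(mean(ex$category == "A") - 0.5), 3 / (2 * sqrt(n)))

  te <- sample_exemplars(task, n, "test")
  a_te <- te[te$category == "A", ]
  # testing phase widens the relevant-axis spread to sigma = 10
  expect_equal(sd(a_te$x_norm), 10, tolerance = 0.5)

  # block balancing yields exact within-block balance
  exb <- sample_exemplars(task, 80, "train", balance = "block", block_size = 8)
  expect_equal(mean(exb$category == "A"), 0.5)
})

test_that("trial typing partitions testing exemplars as Trained/Proximal/Distal", {
  task <- build_task(0)
  ex <- tibble::tibble(x_norm = c(30, 42, 18), y_norm = 50,
                       category = factor("A", levels = c("A", "B")))
  ty <- classify_trial_type(ex, task)
  expect_equal(as.character(ty$trial_type), c("Trained", "Proximal", "Distal"))

  set.seed(12)
  te <- sample_exemplars(task, 1e4, "test")
  ty <- classify_trial_type(te, task)
  expect_false(any(is.na(ty$trial_type)))   # exhaustive and disjoint by construction

  # counts near their truncated-normal expectations ("about half were
  # closer ... and half were farther"): u ~ N(0, 10) truncated to the
  # displayable band [-30, 70] along the relevant axis
  k <- pnorm(7) - pnorm(-3)
  p_exp <- c(Trained = (pnorm(0.5) - pnorm(-0.5)) / k,
             Proximal = (pnorm(7) - pnorm(0.5)) / k,
             Distal = (pnorm(-0.5) - pnorm(-3)) / k)
  n <- nrow(ty)
  for (lv in names(p_exp)) {
    obs <- sum(ty$trial_type == lv)
    expect_lt(abs(obs - n * p_exp[[lv]]),
              3 * sqrt(n * p_exp[[lv]] * (1 - p_exp[[lv]])))
  }

  bad <- tibble::tibble(x_norm = 130, y_norm = 50,
                        category = factor("A", levels = c("A", "B")))
  expect_error(classify_trial_type(bad, task), "outside")
})
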