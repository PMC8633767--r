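make_log <- function(correct, is_correction = rep(FALSE, length(correct)),
                     response = NULL, trial = NULL, attempt = NULL) {
  n <- length(correct)
  tibble::tibble(
    subject_id = "s1", session = 1L,
    trial = trial %||% seq_len(n),
    attempt = attempt %||% rep(0L, n),
    is_correction = is_correction,
    response = response %||% ifelse(correct, "left", "right"),
    correct = correct
  )
}

test_that("session accuracy uses first attempts only", {
  log <- make_log(rep(c(TRUE, FALSE), c(60, 20)))
  expect_equal(session_accuracy(log)$accuracy, 0.75)

  # correction rows are excluded from the denominator
  first <- make_log(rep(c(TRUE, FALSE), each = 40))
  corr <- make_log(rep(FALSE, 55), is_correction = TRUE,
                   trial = rep(41:80, length.out = 55),
                   attempt = rep(1L, 55))
  expect_equal(session_accuracy(dplyr::bind_rows(first, corr))$accuracy, 0.5)

  expect_equal(session_accuracy(make_log(rep(TRUE, 10)))$accuracy, 1)
  expect_error(session_accuracy(make_log(TRUE, is_correction = TRUE)),
               "non-correction")
})

test_that("perseverative errors count repeated keys within correction loops", {
  # error(left) -> correction error(left) -> correction correct(right)
  log1 <- tibble::tibble(
    subject_id = "s1", session = 1L, trial = c(1L, 1L, 1L),
    attempt = 0:2, is_correction = c(FALSE, TRUE, TRUE),
    response = c("left", "left", "right"),
    correct = c(FALSE, FALSE, TRUE)
  )
  expect_equal(count_perseverative_errors(log1)$n_perseverative, 1)

  # switch after feedback: no perseveration
  log2 <- log1[c(1, 3), ]
  log2$attempt <- 0:1
  expect_equal(count_perseverative_errors(log2)$n_perseverative, 0)

  # every repeat counts
  log3 <- tibble::tibble(
    subject_id = "s1", session = 1L, trial = rep(1L, 4),
    attempt = 0:3, is_correction = c(FALSE, TRUE, TRUE, TRUE),
    response = c("left", "left", "left", "right"),
    correct = c(FALSE, FALSE, FALSE, TRUE)
  )
  expect_equal(count_perseverative_errors(log3)$n_perseverative, 2)
})

test_that("metrics are invariant to row order", {
  co <- tiny_cohort(seed = 4)
  tr <- co$trials[co$trials$phase == "train", ]
  set.seed(1)
  shuffled <- tr[sample.int(nrow(tr)), ]
  a <- dplyr::arrange(session_accuracy(tr), subject_id, session)
  b <- dplyr::arrange(session_accuracy(shuffled), subject_id, session)
  expect_equal(a, b)
  pa <- dplyr::arrange(count_perseverative_errors(tr), subject_id, session)
  pb <- dplyr::arrange(count_perseverative_errors(shuffled), subject_id, session)
  expect_equal(pa, pb)
})

test_that("the reaction-time filter removes incorrect trials then a single 2-SD pass", {
  rts <- c(rep(1, 19), 10)
  kept <- filter_rt_outliers(rts, rep(TRUE, 20))
  expect_equal(kept, rep(1, 19))          # z of the 10 s outlier ~ 4.4

  # all values equal: degenerate SD keeps everything
  expect_equal(filter_rt_outliers(rep(2, 10), rep(TRUE, 10)), rep(2, 10))

  # values within two SD pass untouched
  x <- c(1, 1.2, 0.9, 1.1, 1.05)
  expect_equal(filter_rt_outliers(x, rep(TRUE, 5)), x)

  # incorrect trials are dropped before the filter
  expect_equal(filter_rt_outliers(c(1, 1, 1, 50), c(TRUE, TRUE, TRUE, FALSE)),
               c(1, 1, 1))

  # fewer than three correct values: unfiltered, flagged
  out <- filter_rt_outliers(c(1, 9), c(TRUE, TRUE))
  expect_true(attr(out, "flagged"))
  expect_equal(as.numeric(out), c(1, 9))

  # single pass: the second-largest value is judged against the
  # original mean/SD, not re-estimated after removal
  y <- c(rep(1, 30), 6, 20)
  kept2 <- filter_rt_outliers(y, rep(TRUE, 32))
  expect_true(6 %in% kept2)
  expect_false(20 %in% kept2)
})

test_that("touch separation is signed toward the correct side and mean-centred", {
  sep <- touch_separation(100, 110, 120, "right")
  expect_equal(sep$sep3, 10)
  expect_equal(touch_separation(100, 110, 120, "left")$sep3, -10)
  expect_equal(touch_separation(50, 50, 50, "right")$sep3, 0)

  set.seed(8)
  t1 <- rnorm(100); t2 <- rnorm(100); t3 <- rnorm(100)
  side <- sample(c("left", "right"), 100, replace = TRUE)
  s <- touch_separation(t1, t2, t3, side)
  expect_equal(s$sep1 + s$sep2 + s$sep3, rep(0, 100), tolerance = 1e-12)
})

test_that("session summaries assemble all dependent measures tidily", {
  co <- tiny_cohort(seed = 6)
  summ <- summarize_sessions(co$trials)
  expect_true(all(c("accuracy", "n_corrections", "n_perseverative",
                    "mean_cue_rt", "mean_choice_rt", "mean_touch_sep3") %in%
                    names(summ)))
  # one row per subject-phase-session
  expect_equal(nrow(summ), length(unique(co$trials$subject_id)) * (3 + 1))
  expect_true(all(summ$accuracy >= 0 & summ$accuracy <= 1))
  expect_true(all(summ$n_corrections[summ$phase == "test"] == 0))
  expect_true(all(summ$n_perseverative >= 0))
})
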