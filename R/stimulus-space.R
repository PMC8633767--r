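#' Normalize grating spatial frequency to the common stimulus scale
#'
#' The two grating dimensions (spatial frequency in cycles per visual
#' degree, orientation in radians) are mapped by linear transformations
#' onto a common 0--100 scale so that category distributions can be
#' defined on an isotropic two-dimensional stimulus space. Frequency maps
#' as `cpd / 0.0097 - 26.10`, which carries the usable range
#' 0.2532--1.2232 cpd onto approximately 0--100.
#'
#' @param freq_cpd Numeric vector of spatial frequencies (cycles per
#'   visual degree). Must be positive.
#' @return Numeric vector of normalized frequency values.
#' @seealso [normalize_orientation()], [denormalize_frequency()]
#' @export
#' @examples
#' normalize_frequency(c(0.2532, 1.2232))
normalize_frequency <- function(freq_cpd) {
  if (!is.numeric(freq_cpd) || any(!is.finite(freq_cpd)) || any(freq_cpd <= 0)) {
    stop("`freq_cpd` must be positive and finite", call. = FALSE)
  }
  freq_cpd / 0.0097 - 26.10
}

#' Normalize grating orientation to the common stimulus scale
#'
#' Orientation in radians maps onto the common 0--100 scale as
#' `radians * 180 / pi` (i.e., degrees). The usable orientation range is
#' 0--1.75 rad; the upper bound maps to 100.27, marginally above 100, so
#' sampling is defined directly on the normalized space and the raw-unit
#' bound is advisory.
#'
#' @param ori_rad Numeric vector of orientations in radians, in
#'   \eqn{[0, 1.75]}.
#' @return Numeric vector of normalized orientation values.
#' @seealso [normalize_frequency()], [denormalize_orientation()]
#' @export
#' @examples
#' normalize_orientation(c(0, pi / 2))
normalize_orientation <- function(ori_rad) {
  if (!is.numeric(ori_rad) || any(!is.finite(ori_rad)) ||
      any(ori_rad < 0) || any(ori_rad > 1.75)) {
    stop("`ori_rad` must lie in [0, 1.75] radians", call. = FALSE)
  }
  ori_rad * 180 / pi
}

#' Invert the stimulus-scale normalizations
#'
#' @param x_norm,y_norm Numeric vectors on the normalized 0--100 scale.
#' @return Raw stimulus values: cycles per visual degree for
#'   `denormalize_frequency()`, radians for `denormalize_orientation()`.
#' @export
denormalize_frequency <- function(x_norm) 0.0097 * (x_norm + 26.10)

#' @rdname denormalize_frequency
#' @export
denormalize_orientation <- function(y_norm) y_norm * pi / 180

# base (unrotated) task geometry on the normalized space
.task_base <- list(
  mu_a = c(30, 50), mu_b = c(70, 50),
  sigma_relevant = 2.5, sigma_irrelevant = 20,
  sigma_relevant_test = 10,
  center = c(50, 50)
)

.rotmat <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Build one of the four rotated category tasks
#'
#' Category tasks place a pair of bivariate normal distributions on the
#' normalized stimulus space: category A at (30, 50) and category B at
#' (70, 50), each with standard deviation 2.5 along the axis joining the
#' means (the relevant axis) and 20 along the orthogonal axis. The three
#' further tasks rotate this geometry in 45-degree increments about the
#' center of the space (50, 50), which preserves the between-mean
#' distance and the covariance eigenvalues. Rotations of 0 and 90 degrees
#' leave the distributions perpendicular to one screen axis (1D tasks;
#' one dimension is category-relevant); rotations of 45 and 135 degrees
#' make both dimensions informative (2D tasks).
#'
#' @param rotation_deg Task rotation, one of 0, 45, 90, 135.
#' @return A `category_task` object: a list with elements `rotation_deg`,
#'   `mu_a`, `mu_b`, `cov` (shared 2x2 covariance), `task_class` ("1D" or
#'   "2D"), `relevant_axis` (unit vector from the A mean toward the B
#'   mean), and the training/testing standard deviations.
#' @export
#' @examples
#' build_task(45)
build_task <- function(rotation_deg) {
  if (length(rotation_deg) != 1 || !rotation_deg %in% c(0, 45, 90, 135)) {
    stop("`rotation_deg` must be one of 0, 45, 90, 135", call. = FALSE)
  }
  R <- .rotmat(rotation_deg)
  ctr <- .task_base$center
  mu_a <- drop(R %*% (.task_base$mu_a - ctr)) + ctr
  mu_b <- drop(R %*% (.task_base$mu_b - ctr)) + ctr
  S <- diag(c(.task_base$sigma_relevant^2, .task_base$sigma_irrelevant^2))
  cov <- R %*% S %*% t(R)
  axis <- drop(R %*% c(1, 0))
  structure(
    list(
      rotation_deg = rotation_deg,
      mu_a = mu_a, mu_b = mu_b, cov = cov,
      task_class = if (rotation_deg %in% c(0, 90)) "1D" else "2D",
      relevant_axis = axis,
      sigma_relevant = .task_base$sigma_relevant,
      sigma_irrelevant = .task_base$sigma_irrelevant,
      sigma_relevant_test = .task_base$sigma_relevant_test,
      center = ctr
    ),
    class = "category_task"
  )
}

#' @export
print.category_task <- function(x, ...) {
  cat("<category_task> rotation", x$rotation_deg, "deg (", x$task_class, ")\n")
  cat("  mu_A = (", paste(round(x$mu_a, 2), collapse = ", "), ")",
      "  mu_B = (", paste(round(x$mu_b, 2), collapse = ", "), ")\n")
  cat("  sigma: relevant", x$sigma_relevant,
      "(test", x$sigma_relevant_test, "), irrelevant", x$sigma_irrelevant, "\n")
  invisible(x)
}

#' Sample category exemplars from a task
#'
#' Draws stimuli from the phase-appropriate bivariate normal
#' distributions. Training draws use the training standard deviation
#' (2.5) along the relevant axis; testing draws use the expanded value
#' (10), which spreads exemplars into novel portions of the space. Draws
#' falling outside the displayable square \eqn{[0, 100]^2} are
#' rejection-resampled (truncation), so every exemplar is displayable.
#' Category labels are drawn per trial as an independent fair coin by
#' default; `balance = "block"` instead balances labels within
#' consecutive blocks of `block_size` trials.
#'
#' Randomness comes from R's global RNG; call [set.seed()] for
#' reproducibility.
#'
#' @param task A [build_task()] object.
#' @param n Number of exemplars.
#' @param phase `"train"` or `"test"`.
#' @param balance Category assignment scheme: `"coin"` (default) or
#'   `"block"`.
#' @param block_size Block length for `balance = "block"` (must be even).
#' @return A tibble with columns `freq_cpd`, `ori_rad`, `x_norm`,
#'   `y_norm`, `category` (factor with levels A, B).
#' @export
#' @examples
#' set.seed(1)
#' sample_exemplars(build_task(0), 5, "train")
sample_exemplars <- function(task, n, phase = c("train", "test"),
                             balance = c("coin", "block"), block_size = 8) {
  stopifnot(inherits(task, "category_task"), n >= 1)
  phase <- match.arg(phase)
  balance <- match.arg(balance)

  category <- if (balance == "coin") {
    sample(c("A", "B"), n, replace = TRUE)
  } else {
    stopifnot(block_size %% 2 == 0)
    n_blocks <- ceiling(n / block_size)
    lab <- unlist(lapply(seq_len(n_blocks), function(i) {
      sample(rep(c("A", "B"), block_size / 2))
    }))
    lab[seq_len(n)]
  }

  sig_rel <- if (phase == "train") task$sigma_relevant else task$sigma_relevant_test
  axis <- task$relevant_axis
  perp <- c(-axis[2], axis[1])

  xy <- matrix(NA_real_, n, 2)
  todo <- seq_len(n)
  mu <- rbind(A = task$mu_a, B = task$mu_b)
  while (length(todo) > 0) {
    m <- length(todo)
    u <- rnorm(m, 0, sig_rel)
    v <- rnorm(m, 0, task$sigma_irrelevant)
    pts <- mu[category[todo], , drop = FALSE] +
      outer(u, axis) + outer(v, perp)
    ok <- pts[, 1] >= 0 & pts[, 1] <= 100 & pts[, 2] >= 0 & pts[, 2] <= 100
    xy[todo[ok], ] <- pts[ok, , drop = FALSE]
    todo <- todo[!ok]
  }

  tibble::tibble(
    freq_cpd = denormalize_frequency(xy[, 1]),
    ori_rad = denormalize_orientation(xy[, 2]),
    x_norm = xy[, 1],
    y_norm = xy[, 2],
    category = factor(category, levels = c("A", "B"))
  )
}

#' Classify testing exemplars as Trained, Proximal, or Distal
#'
#' Testing exemplars are typed by their signed position along the task's
#' relevant axis, measured from their own category's training mean with
#' the positive direction toward the category boundary. Exemplars within
#' two training standard deviations (5 normalized units) of the mean
#' overlap the training distribution (`Trained`); novel exemplars nearer
#' the boundary are `Proximal`, and novel exemplars farther from the
#' boundary are `Distal`.
#'
#' @param exemplars A data frame with columns `x_norm`, `y_norm`,
#'   `category` (as produced by [sample_exemplars()]).
#' @param task The [build_task()] the exemplars were sampled from.
#' @return The input as a tibble with an added factor column
#'   `trial_type` (levels Trained, Proximal, Distal).
#' @export
classify_trial_type <- function(exemplars, task) {
  stopifnot(inherits(task, "category_task"))
  need <- c("x_norm", "y_norm", "category")
  if (!all(need %in% names(exemplars))) {
    stop("`exemplars` needs columns x_norm, y_norm, category", call. = FALSE)
  }
  x <- exemplars$x_norm
  y <- exemplars$y_norm
  if (any(!is.finite(x)) || any(!is.finite(y)) ||
      any(x < 0 | x > 100 | y < 0 | y > 100)) {
    stop("exemplar coordinates outside [0, 100]^2: not from this task",
         call. = FALSE)
  }
  cat_chr <- as.character(exemplars$category)
  if (!all(cat_chr %in% c("A", "B"))) {
    stop("`category` must be A or B", call. = FALSE)
  }

  axis <- task$relevant_axis
  proj <- cbind(x, y) %*% axis
  mu_proj <- c(A = sum(task$mu_a * axis), B = sum(task$mu_b * axis))
  # positive direction points toward the boundary: +axis for A, -axis for B
  sgn <- ifelse(cat_chr == "A", 1, -1)
  u <- sgn * (drop(proj) - mu_proj[cat_chr])

  band <- 2 * task$sigma_relevant
  type <- ifelse(abs(u) <= band, "Trained",
                 ifelse(u > band, "Proximal", "Distal"))
  out <- tibble::as_tibble(exemplars)
  out$trial_type <- factor(type, levels = c("Trained", "Proximal", "Distal"))
  out
}
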