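#' Shooting angle from a 2-D trajectory
#'
#' The shooting angle is the direction of the point where the outward
#' trajectory crosses the (invisible) target circle, obtained by linear
#' interpolation in x-y between the two samples closest to the circle: the
#' last sample inside and the first sample outside. The crossing point is the
#' analytic intersection of that segment with the circle.
#'
#' @param traj data frame with columns `x_cm`, `y_cm` ordered outward from the
#'   home position at the origin.
#' @param circle_radius target-circle radius in cm (default 5.3).
#' @param id optional trial identifier used in the no-crossing error message.
#' @return Angle in degrees (CCW from +x), wrapped to `(-180, 180]`.
#' @examples
#' r <- 1:6
#' shooting_angle(data.frame(x_cm = r * cospi(1/6), y_cm = r * sinpi(1/6)))
#' @export
shooting_angle <- function(traj, circle_radius = 5.3, id = NULL) {
  stopifnot(all(c("x_cm", "y_cm") %in% names(traj)))
  x <- traj$x_cm; y <- traj$y_cm
  r <- sqrt(x^2 + y^2)
  out <- which(r > circle_radius)
  if (!length(out)) {
    where <- if (is.null(id)) "" else paste0(" (trial ", id, ")")
    stop("no-crossing: trajectory never leaves the ", circle_radius,
         " cm circle", where, call. = FALSE)
  }
  i <- out[1L]
  if (i == 1L) {
    where <- if (is.null(id)) "" else paste0(" (trial ", id, ")")
    stop("no-crossing: first trajectory sample already outside the circle",
         where, call. = FALSE)
  }
  # segment p1 + s*(p2 - p1), |p| = R  =>  quadratic in s, root in [0, 1]
  p1 <- c(x[i - 1L], y[i - 1L]); p2 <- c(x[i], y[i])
  d <- p2 - p1
  aa <- sum(d * d)
  bb <- 2 * sum(p1 * d)
  cc <- sum(p1 * p1) - circle_radius^2
  disc <- bb^2 - 4 * aa * cc
  s <- (-bb + sqrt(max(disc, 0))) / (2 * aa)
  pt <- p1 + s * d
  wrap_angle(atan2(pt[2], pt[1]) * 180 / pi)
}

#' Signed angular error
#'
#' Difference between the shooting direction and the main target direction,
#' wrapped to `(-180, 180]`. CCW-positive, so the implicit drift under a CCW
#' rotation (hand rotating clockwise away from the target) is negative.
#'
#' @param target_angle main target angle, degrees.
#' @param shooting_angle shooting angle, degrees.
#' @return Signed error in degrees.
#' @examples
#' angular_error(0, -45)    # full strategy aim, no adaptation: -45
#' angular_error(170, -170) # wraps across the cut: +20
#' @export
angular_error <- function(target_angle, shooting_angle) {
  wrap_angle(shooting_angle - target_angle)
}

#' Add the signed angular error column to a trial table
#'
#' The analyzed error is the angle between the main target and the point
#' where the movement crossed the target circle *on the screen* — i.e. the
#' cursor direction, since the display (not the hand) is what the experiment
#' records and shows. On trials without rotation the cursor and hand
#' directions coincide. This is the error that is near zero right after the
#' strategy is introduced and then drifts clockwise (negative).
#'
#' @param table a trial table (see [simulate_cohort()]).
#' @return The table with an `error` column (`NA` on no-feedback trials,
#'   which have no target).
#' @export
add_errors <- function(table) {
  dplyr::mutate(table, error = angular_error(.data$target_angle,
                                             .data$cursor_angle))
}

window_mean <- function(x, which = c("middle", "last", "first"), k = 10L) {
  which <- match.arg(which)
  L <- length(x)
  if (L < k)
    stop("window of ", k, " trials exceeds block length ", L, call. = FALSE)
  idx <- switch(which,
                middle = (floor(L / 2) - 4L):(floor(L / 2) + 5L),
                last = (L - k + 1L):L,
                first = 1:k)
  mean(x[idx])
}

#' Per-participant block-window summaries
#'
#' For every participant, the mean signed angular error over the middle 10
#' and last 10 trials of the adaptation block and the first 10 trials of the
#' washout block. The middle-10 window of a length-`L` block is within-block
#' trials `floor(L/2)-4 ... floor(L/2)+5` (1-based), so for the default 198
#' adaptation trials it is trials 95-104.
#'
#' @param table a trial table; the `error` column is added if absent.
#' @param participant optional single participant id to restrict to.
#' @return A tibble with columns `participant`, `condition`, `adapt_mid10`,
#'   `adapt_last10`, `washout_first10` (degrees).
#' @export
block_summary <- function(table, participant = NULL) {
  if (!"error" %in% names(table)) table <- add_errors(table)
  if (!is.null(participant))
    table <- dplyr::filter(table, .data$participant == !!participant)
  need <- c("adaptation", "washout")
  have <- unique(table$block)
  if (!all(need %in% have))
    stop("trial table lacks block(s): ",
         paste(setdiff(need, have), collapse = ", "), call. = FALSE)
  table |>
    dplyr::filter(.data$block %in% need) |>
    dplyr::arrange(.data$participant, .data$trial) |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::summarise(
      adapt_mid10 = window_mean(.data$error[.data$block == "adaptation"], "middle"),
      adapt_last10 = window_mean(.data$error[.data$block == "adaptation"], "last"),
      washout_first10 = window_mean(.data$error[.data$block == "washout"], "first"),
      .groups = "drop")
}

# Profiled least squares for y ~ A * exp(-t / tau), t = 0, 1, ...:
# for fixed tau the optimal A is closed-form, so the fit is a 1-D search
# over tau (coarse log grid, then local refinement). Deterministic.
fit_exp_core <- function(y) {
  n <- length(y)
  t <- seq_len(n) - 1
  sse <- function(log_tau) {
    x <- exp(-t / exp(log_tau))
    A <- sum(x * y) / sum(x * x)
    sum((y - A * x)^2)
  }
  grid <- seq(log(0.1), log(50 * n), length.out = 80L)
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(sse, c(lo, hi), tol = 1e-10)
  tau <- exp(opt$minimum)
  x <- exp(-t / tau)
  A <- sum(x * y) / sum(x * x)
  ss_res <- sum((y - A * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  c(A = A, tau = tau, r2 = r2)
}

#' Fit a single-exponential decay to an error series
#'
#' Least-squares fit of `Err(t) = A * exp(-t / tau)` with `t = 0, 1, 2, ...`
#' starting at the first trial of the series, so `A` is the initial-error
#' amplitude and `tau` the time constant in trials. The amplitude is profiled
#' out (closed-form for fixed `tau`), leaving a robust deterministic 1-D
#' search over `tau > 0`. Fits operate on signed errors; `A` carries the sign.
#'
#' @param series numeric vector of per-trial (typically across-participant
#'   mean) signed errors, length >= 3.
#' @return An object of class `exp_fit`: list with `A` (degrees), `tau`
#'   (trials; `NA` and `tau_defined = FALSE` for an all-zero series), and
#'   `r2` (`1 - SS_res / SS_tot`).
#' @examples
#' fit_exponential(40 * exp(-(0:79) / 20))
#' @export
fit_exponential <- function(series) {
  y <- as.numeric(series)
  if (length(y) < 3L) stop("series must have length >= 3", call. = FALSE)
  if (anyNA(y)) stop("series contains NA", call. = FALSE)
  if (all(y == 0)) {
    return(structure(list(A = 0, tau = NA_real_, r2 = NA_real_,
                          tau_defined = FALSE), class = "exp_fit"))
  }
  est <- fit_exp_core(y)
  structure(list(A = unname(est["A"]), tau = unname(est["tau"]),
                 r2 = unname(est["r2"]), tau_defined = TRUE),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("exponential fit: A = %.3f deg, tau = %s trials, R^2 = %s\n",
              x$A, if (x$tau_defined) sprintf("%.3f", x$tau) else "undefined",
              if (is.na(x$r2)) "NA" else sprintf("%.3f", x$r2)))
  invisible(x)
}

block_error_matrix <- function(table, block) {
  if (!"error" %in% names(table)) table <- add_errors(table)
  sub <- dplyr::filter(table, .data$block == !!block)
  if (!nrow(sub)) stop("no trials in block `", block, "`", call. = FALSE)
  sub <- dplyr::arrange(sub, .data$participant, .data$trial)
  sub <- dplyr::mutate(dplyr::group_by(sub, .data$participant),
                       t_in_block = dplyr::row_number() - 1L)
  wide <- tidyr::pivot_wider(dplyr::ungroup(sub),
                             id_cols = "participant",
                             names_from = "t_in_block",
                             values_from = "error")
  mat <- as.matrix(wide[-1])
  rownames(mat) <- wide$participant
  mat
}

#' Participant bootstrap of the exponential fit
#'
#' Draws participants with replacement (10000 resamples by default), averages
#' the resampled participants' per-trial signed errors into one series, fits
#' the single exponential, and records `A`, `tau` and `R^2` per resample.
#' Point estimates come from the fit to the full-sample mean series;
#' confidence intervals are percentile intervals over the resamples.
#'
#' @param table trial table restricted to (or containing) one condition.
#' @param block block to fit, `"adaptation"` or `"washout"`.
#' @param n_resamples number of bootstrap resamples (default 10000).
#' @param seed integer seed for the resampling.
#' @param level confidence level (default 0.95).
#' @return An object of class `bootstrap_result`: list with `point` (named
#'   `A`, `tau`, `r2`), `ci` (tibble: `param`, `lower`, `upper`), `samples`
#'   (tibble of per-resample values), `n_resamples`, `seed`.
#' @export
bootstrap_fit <- function(table, block = "washout", n_resamples = 10000,
                          seed = 1, level = 0.95) {
  mat <- block_error_matrix(table, block)
  if (nrow(mat) < 2L)
    stop("bootstrap needs at least 2 participants, got ", nrow(mat),
         call. = FALSE)
  point <- fit_exponential(colMeans(mat))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  np <- nrow(mat)
  draws <- matrix(sample.int(np, np * n_resamples, replace = TRUE),
                  nrow = n_resamples)
  samples <- matrix(NA_real_, n_resamples, 3,
                    dimnames = list(NULL, c("A", "tau", "r2")))
  for (i in seq_len(n_resamples)) {
    y <- colMeans(mat[draws[i, ], , drop = FALSE])
    samples[i, ] <- if (all(y == 0)) c(0, NA, NA) else fit_exp_core(y)
  }
  alpha <- (1 - level) / 2
  ci <- tibble::tibble(
    param = c("A", "tau", "r2"),
    lower = apply(samples, 2, stats::quantile, probs = alpha, na.rm = TRUE),
    upper = apply(samples, 2, stats::quantile, probs = 1 - alpha, na.rm = TRUE))
  structure(list(point = c(A = point$A, tau = point$tau, r2 = point$r2),
                 ci = ci, samples = tibble::as_tibble(samples),
                 n_resamples = n_resamples, seed = seed, block = block),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("participant bootstrap (%d resamples, block = %s)\n",
              x$n_resamples, x$block))
  for (p in x$ci$param) {
    ci <- x$ci[x$ci$param == p, ]
    cat(sprintf("  %-3s %8.3f  [%.3f, %.3f]\n", p, x$point[[p]],
                ci$lower, ci$upper))
  }
  invisible(x)
}

#' One-way ANOVA across conditions with Tukey post-hoc
#'
#' Standard one-way ANOVA on per-participant block-window means (one value per
#' participant) with condition as the factor, followed by Tukey's HSD on all
#' pairwise condition contrasts.
#'
#' @param summaries output of [block_summary()].
#' @param window which window to test: `"adapt_mid10"`, `"adapt_last10"` or
#'   `"washout_first10"`.
#' @return List with `F` (statistic), `df` (numerator, denominator), `p`
#'   (ANOVA p-value), and `tukey` (tibble: `contrast`, `diff`, `lwr`, `upr`,
#'   `p_adj`).
#' @export
condition_anova <- function(summaries,
                            window = c("adapt_last10", "adapt_mid10",
                                       "washout_first10")) {
  window <- match.arg(window)
  if (length(unique(summaries$condition)) < 2L)
    stop("ANOVA needs at least 2 conditions", call. = FALSE)
  if (any(table(summaries$condition) < 2L))
    stop("each condition needs at least 2 participants", call. = FALSE)
  dat <- data.frame(y = summaries[[window]],
                    condition = factor(summaries$condition))
  fit <- stats::aov(y ~ condition, data = dat)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$condition
  list(F = an[["F value"]][1],
       df = c(an[["Df"]][1], an[["Df"]][2]),
       p = an[["Pr(>F)"]][1],
       window = window,
       tukey = tibble::tibble(contrast = rownames(tk),
                              diff = tk[, "diff"], lwr = tk[, "lwr"],
                              upr = tk[, "upr"], p_adj = tk[, "p adj"]))
}

#' End-of-adaptation vs washout correlation, per condition
#'
#' Pearson correlation, within each condition, between each participant's mean
#' error over the last 10 adaptation trials and over the first 10 washout
#' trials. A positive correlation says participants who drifted further also
#' show larger after-effects.
#'
#' @param summaries output of [block_summary()].
#' @return Tibble with one row per condition: `condition`, `n`, `r`, `p`.
#' @export
adaptation_washout_correlation <- function(summaries) {
  res <- lapply(sort(unique(summaries$condition)), function(cond) {
    sub <- summaries[summaries$condition == cond, ]
    if (nrow(sub) < 3L)
      stop("condition ", cond, " has fewer than 3 participants", call. = FALSE)
    ct <- stats::cor.test(sub$adapt_last10, sub$washout_first10)
    tibble::tibble(condition = cond, n = nrow(sub),
                   r = unname(ct$estimate), p = ct$p.value)
  })
  dplyr::bind_rows(res)
}

#' Across-participant mean error series for one block
#'
#' @param table trial table (one or more conditions).
#' @param block block name.
#' @return Tibble with `condition`, `t` (0-based trial within block) and
#'   `mean_error` (degrees).
#' @export
mean_error_series <- function(table, block = "washout") {
  if (!"error" %in% names(table)) table <- add_errors(table)
  table |>
    dplyr::filter(.data$block == !!block) |>
    dplyr::arrange(.data$participant, .data$trial) |>
    dplyr::group_by(.data$condition, .data$participant) |>
    dplyr::mutate(t = dplyr::row_number() - 1L) |>
    dplyr::group_by(.data$condition, .data$t) |>
    dplyr::summarise(mean_error = mean(.data$error), .groups = "drop")
}
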