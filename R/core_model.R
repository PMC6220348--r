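#' Learner parameters for the state-space adaptation model
#'
#' Bundles the four parameters of the single-state model of visuomotor
#' adaptation: a multiplicative retention (forgetting) rate `a` applied to the
#' internal perturbation estimate on every trial, a learning rate `b` scaling
#' how much of each sensory prediction error (SPE) is incorporated into the
#' estimate, and the standard deviations of motor noise (`sigma_u`, added to
#' the hand direction) and perturbation noise (`sigma_p`, added to the cursor
#' rotation). All angles are in degrees, counter-clockwise positive.
#'
#' @param a retention rate, in `[0, 1]`. `a = 1` means no forgetting.
#' @param b learning rate, in `[0, 1]`. Fraction of the SPE written into the
#'   perturbation estimate each feedback trial.
#' @param sigma_u motor-noise SD in degrees (non-negative).
#' @param sigma_p perturbation-noise SD in degrees (non-negative).
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' model_params(a = 0.98, b = 0.02, sigma_u = 6.1, sigma_p = 0.5)
#' @export
model_params <- function(a = 0.98, b = 0.015, sigma_u = 6.1, sigma_p = 0.5) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b))
  if (a < 0 || a > 1) stop("retention rate `a` must lie in [0, 1]", call. = FALSE)
  if (b < 0 || b > 1) stop("learning rate `b` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(sigma_u) || sigma_u < 0) stop("`sigma_u` must be >= 0", call. = FALSE)
  if (!is.numeric(sigma_p) || sigma_p < 0) stop("`sigma_p` must be >= 0", call. = FALSE)
  structure(list(a = a, b = b, sigma_u = sigma_u, sigma_p = sigma_p),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "state-space learner: a = %g, b = %g, sigma_u = %g deg, sigma_p = %g deg\n",
    x$a, x$b, x$sigma_u, x$sigma_p))
  invisible(x)
}

#' Motor command on one trial
#'
#' The learner aims to hit the main target (at 0 degrees by convention) by
#' compensating its current internal estimate of the perturbation, plus any
#' explicit strategy/correction offset and motor noise:
#' `u = -p_hat + S + n_u`.
#'
#' @param p_hat current perturbation estimate (degrees).
#' @param S strategy-plus-correction term (degrees); e.g. `-45` when aiming at
#'   the clockwise neighboring target.
#' @param n_u motor-noise draw (degrees).
#' @return Hand direction `u` relative to the main target, degrees.
#' @examples
#' motor_command(p_hat = 0, S = -45)  # first strategy trial: aim at neighbor
#' @export
motor_command <- function(p_hat, S = 0, n_u = 0) {
  -p_hat + S + n_u
}

#' Cursor feedback on one trial
#'
#' The cursor shows the hand direction rotated by the applied perturbation
#' plus perturbation noise: `c = u + p + n_p`. The hand direction itself is
#' `u` (shooting movements; no online correction).
#'
#' @param u hand direction (degrees, relative to main target).
#' @param p applied perturbation (degrees, CCW-positive; 45 during rotation).
#' @param n_p perturbation-noise draw (degrees).
#' @return Cursor direction relative to the main target, degrees.
#' @examples
#' cursor_feedback(u = -45, p = 45)  # strategy cancels the rotation: c = 0
#' @export
cursor_feedback <- function(u, p = 0, n_p = 0) {
  u + p + n_p
}

#' Sensory prediction error
#'
#' The forward model predicts the cursor from the efference copy and the
#' current perturbation estimate, `h_pred = u + p_hat`; the SPE is the
#' difference between observed and predicted feedback,
#' `spe = c - (u + p_hat) = p + n_p - p_hat`. The motor command cancels in the
#' subtraction, which is why the memory update is independent of what the
#' hand actually did.
#'
#' @param c_obs observed cursor direction (degrees).
#' @param u hand direction (degrees).
#' @param p_hat current perturbation estimate (degrees).
#' @return SPE in degrees.
#' @examples
#' compute_spe(c_obs = 0, u = -45, p_hat = 0)  # first strategy trial: 45
#' @export
compute_spe <- function(c_obs, u, p_hat) {
  c_obs - (u + p_hat)
}

#' Update the perturbation estimate from one SPE
#'
#' `p_hat_next = a * p_hat + b * spe`. The updated estimate is the one used
#' for prediction and motor command on the next trial.
#'
#' @param p_hat current estimate (degrees).
#' @param spe sensory prediction error (degrees).
#' @param params a [model_params()] object (only `a` and `b` are used).
#' @return Updated estimate, degrees.
#' @export
update_estimate <- function(p_hat, spe, params) {
  params$a * p_hat + params$b * spe
}

#' Decay the estimate across a trial without feedback
#'
#' With no cursor there is no SPE, so only retention applies:
#' `p_hat_next = a * p_hat`.
#'
#' @inheritParams update_estimate
#' @return Updated estimate, degrees.
#' @export
no_feedback_step <- function(p_hat, params) {
  params$a * p_hat
}

#' Simulate a sequence of trials through the state-space model
#'
#' Threads the perturbation estimate through a fixed sequence of trial inputs,
#' applying the motor command, cursor feedback, prediction, SPE and update
#' equations in order. Deterministic given the noise draws in `inputs`; all
#' stochasticity lives in the `n_u` / `n_p` columns supplied by the caller.
#'
#' The estimate used on trial `t` is the post-update value from trial `t - 1`
#' (trial-wise state-space convention); the update applies after the trial's
#' feedback. Rows with `feedback = FALSE` contribute no SPE and the estimate
#' only decays by `a`.
#'
#' @param inputs a data frame with one row per trial and columns `p` (applied
#'   perturbation, degrees), `S` (strategy/correction term, degrees), and
#'   optionally `n_u`, `n_p` (noise draws, default 0) and `feedback` (logical,
#'   default `TRUE`).
#' @param params a [model_params()] object.
#' @param p_hat0 initial perturbation estimate (degrees), default 0.
#'
#' @return A tibble with one row per trial: `u` (hand direction), `c_obs`
#'   (cursor direction), `h_pred` (predicted hand/cursor direction), `spe`
#'   (NA on no-feedback trials), `p_hat` (estimate used on that trial) and
#'   `p_hat_next` (estimate after the trial's update).
#' @examples
#' inputs <- data.frame(p = 45, S = -45)[rep(1, 50), ]
#' out <- simulate_phase(inputs, model_params(a = 1, b = 0.1, sigma_u = 0, sigma_p = 0))
#' tail(out$c_obs)  # cursor error drifts towards -45
#' @export
simulate_phase <- function(inputs, params, p_hat0 = 0) {
  stopifnot(inherits(params, "model_params"))
  if (!is.data.frame(inputs) || nrow(inputs) == 0L)
    stop("`inputs` must be a data frame with at least one trial", call. = FALSE)
  if (!all(c("p", "S") %in% names(inputs)))
    stop("`inputs` must have columns `p` and `S`", call. = FALSE)
  n <- nrow(inputs)
  n_u <- if ("n_u" %in% names(inputs)) inputs$n_u else rep(0, n)
  n_p <- if ("n_p" %in% names(inputs)) inputs$n_p else rep(0, n)
  fb  <- if ("feedback" %in% names(inputs)) inputs$feedback else rep(TRUE, n)

  u <- c_obs <- h_pred <- spe <- p_hat <- p_hat_next <- numeric(n)
  est <- p_hat0
  for (t in seq_len(n)) {
    p_hat[t]  <- est
    u[t]      <- motor_command(est, inputs$S[t], n_u[t])
    c_obs[t]  <- cursor_feedback(u[t], inputs$p[t], n_p[t])
    h_pred[t] <- u[t] + est
    if (isTRUE(fb[t])) {
      spe[t] <- compute_spe(c_obs[t], u[t], est)
      est    <- update_estimate(est, spe[t], params)
    } else {
      spe[t] <- NA_real_
      est    <- no_feedback_step(est, params)
    }
    p_hat_next[t] <- est
  }
  tibble::tibble(u = u, c_obs = c_obs, h_pred = h_pred, spe = spe,
                 p_hat = p_hat, p_hat_next = p_hat_next)
}
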