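#' Default cohort-generation configuration
#'
#' Returns the full set of tunable knobs for the synthetic cohort, mirroring
#' the study design: 4 conditions x 13 participants, 45 deg CCW rotation with
#' trial noise `N(0, sigma_r^2)`, `sigma_r = 0.5` deg, baseline motor noise
#' `sigma_u = 6.1` deg, block lengths 110/40/2/198/10/80, and 10000 bootstrap
#' resamples. Participant heterogeneity is drawn per participant: retention
#' `a` and learning rate `b` uniform over `[a_min, a_max]` and `[b_min,
#' b_max]`, PE1-correction gain uniform over `[gain_min, gain_max]` and lapse
#' probability uniform over `[lapse_min, lapse_max]`.
#'
#' @param ... named overrides of any default; unknown names are an error.
#' @return Named list of configuration values.
#' @examples
#' cfg <- default_config(n_per_condition = 2, n_boot = 100)
#' @export
default_config <- function(...) {
  cfg <- list(
    n_per_condition = 13L,
    rotation = 45,
    sigma_r = 0.5,
    sigma_u = 6.1,
    a_min = 0.98, a_max = 0.98,
    b_min = 0.008, b_max = 0.020,
    gain_min = 0.01, gain_max = 0.12,
    lapse_min = 0.00, lapse_max = 0.60,
    washout_rotation = FALSE,
    block_familiarization = 110L,
    block_baseline = 40L,
    block_pre_strategy = 2L,
    block_adaptation = 198L,
    block_no_feedback = 10L,
    block_washout = 80L,
    use_trajectories = TRUE,
    traj_jitter = 0.05,
    traj_step = 0.5,
    traj_rmax = 6.5,
    n_boot = 10000L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num <- function(k, lo = -Inf, hi = Inf) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < lo || v > hi)
      stop(sprintf("config key `%s` must be a number in [%s, %s]", k, lo, hi),
           call. = FALSE)
  }
  num("n_per_condition", 1); num("rotation"); num("sigma_r", 0); num("sigma_u", 0)
  num("a_min", 0, 1); num("a_max", 0, 1); num("b_min", 0, 1); num("b_max", 0, 1)
  num("gain_min", 0); num("gain_max", 0); num("lapse_min", 0, 1); num("lapse_max", 0, 1)
  num("traj_jitter", 0); num("traj_step", 1e-6); num("traj_rmax", 5.4)
  num("n_boot", 1)
  for (k in grep("^block_", names(cfg), value = TRUE)) num(k, 0)
  if (cfg$a_min > cfg$a_max || cfg$b_min > cfg$b_max ||
      cfg$gain_min > cfg$gain_max || cfg$lapse_min > cfg$lapse_max)
    stop("config ranges must have min <= max", call. = FALSE)
  if (!is.logical(cfg$washout_rotation) || !is.logical(cfg$use_trajectories))
    stop("`washout_rotation` and `use_trajectories` must be logical", call. = FALSE)
  cfg
}

config_blocks <- function(cfg) {
  c(familiarization = cfg$block_familiarization,
    baseline = cfg$block_baseline,
    pre_strategy = cfg$block_pre_strategy,
    adaptation = cfg$block_adaptation,
    no_feedback = cfg$block_no_feedback,
    washout = cfg$block_washout)
}

#' Participant traits
#'
#' One synthetic participant's identity and behavioral parameters: the
#' state-space rates `a` (retention) and `b` (learning), motor-noise SD,
#' the gain of the corrective response to the previous trial's PE1 (the
#' cursor-to-main-target error) and the probability of lapsing (not updating
#' the correction) on a given trial. Corrections only operate where PE1 is
#' visible, so the gain is inert in Conditions 2 and 4.
#'
#' @param id participant identifier.
#' @param condition experimental condition 1-4.
#' @param a,b retention and learning rate (see [model_params()]).
#' @param sigma_u motor-noise SD, degrees.
#' @param correction_gain PE1-feedback gain (>= 0, unitless).
#' @param correction_lapse_prob per-trial probability the correction is not
#'   updated, in `[0, 1]`.
#' @param seed private RNG seed for this participant's motor noise, lapses and
#'   trajectory jitter.
#' @param seed_shared RNG seed for the streams shared across conditions
#'   (rotation noise and the `a`, `b` draws), keyed by the participant's index
#'   within condition so that matched participants experience identical
#'   perturbation sequences.
#' @return A `participant_traits` list.
#' @export
participant_traits <- function(id, condition, a = 0.98, b = 0.015,
                               sigma_u = 6.1, correction_gain = 0,
                               correction_lapse_prob = 0,
                               seed = 1L, seed_shared = seed) {
  check_condition(condition)
  stopifnot(a >= 0, a <= 1, b >= 0, b <= 1, sigma_u >= 0,
            correction_gain >= 0,
            correction_lapse_prob >= 0, correction_lapse_prob <= 1)
  structure(list(id = id, condition = as.integer(condition), a = a, b = b,
                 sigma_u = sigma_u, correction_gain = correction_gain,
                 correction_lapse_prob = correction_lapse_prob,
                 seed = as.integer(seed), seed_shared = as.integer(seed_shared)),
            class = "participant_traits")
}

#' Strategy-plus-correction term for one trial
#'
#' During the adaptation block the instructed strategy is to aim at the
#' neighboring target 45 degrees clockwise (`-rotation`); on top of it,
#' participants who can see the main target integrate corrections against the
#' drift: the running correction is decremented by `gain * prev_pe1` whenever
#' the previous trial's PE1 was available and no lapse occurs. Outside the
#' adaptation block the strategy (and any accumulated correction) is dropped
#' and `S = 0`.
#'
#' @param traits a [participant_traits()] object.
#' @param prev_pe1 previous adaptation trial's PE1 in degrees, or `NA` if the
#'   main target was not visible (no correction update possible).
#' @param prev_S the `S` used on the previous adaptation trial (carries the
#'   accumulated correction); use `NA` on the first strategy trial.
#' @param block block name; only `"adaptation"` engages the strategy.
#' @param lapse logical; did this trial lapse (skip the correction update)?
#'   The caller draws it with probability `correction_lapse_prob`.
#' @param rotation rotation magnitude, degrees (default 45).
#' @return `S` in degrees.
#' @export
correction_policy <- function(traits, prev_pe1, prev_S, block,
                              lapse = FALSE, rotation = 45) {
  if (!identical(block, "adaptation")) return(0)
  base <- -rotation
  corr_prev <- if (is.na(prev_S)) 0 else prev_S - base
  corr <- if (!is.na(prev_pe1) && !isTRUE(lapse))
    corr_prev - traits$correction_gain * prev_pe1
  else corr_prev
  base + corr
}

#' Synthesize a 2-D shooting trajectory
#'
#' Samples a near-straight outward ray at the given absolute shooting angle,
#' at fixed radial steps spanning the target circle, with isotropic Gaussian
#' positional jitter. Purely a fixture for the circle-crossing interpolation
#' used to extract shooting angles.
#'
#' @param angle absolute shooting angle in degrees (CCW from +x).
#' @param jitter positional jitter SD in cm (per coordinate).
#' @param step radial step in cm.
#' @param rmax final sampled radius in cm (must exceed the 5.3 cm circle).
#' @return A tibble with columns `x_cm`, `y_cm`, ordered outward from the home
#'   position.
#' @examples
#' traj <- synth_trajectory(30, jitter = 0)
#' shooting_angle(traj)  # recovers 30 exactly
#' @export
synth_trajectory <- function(angle, jitter = 0.05, step = 0.5, rmax = 6.5) {
  r <- seq(step, rmax, by = step)
  th <- angle * pi / 180
  tibble::tibble(
    x_cm = r * cos(th) + stats::rnorm(length(r), 0, jitter),
    y_cm = r * sin(th) + stats::rnorm(length(r), 0, jitter)
  )
}

#' Simulate one participant through the full schedule
#'
#' Binds the state-space learner to the experiment: per-block target sequences
#' (each target once per aligned 8-trial window), the rotation with its trial
#' noise, the condition's target-removal visibility, the instructed strategy
#' and PE1-driven corrections, and (optionally) synthetic 2-D trajectories
#' from which the recorded shooting angle is extracted by circle-crossing
#' interpolation.
#'
#' Two RNG streams are used: a shared stream (`seed_shared`) for the rotation
#' noise, so that matched participants across conditions experience identical
#' perturbation sequences and hence identical latent memory trajectories, and
#' a private stream (`seed`) for motor noise, lapses, target shuffles and
#' trajectory jitter.
#'
#' @param traits a [participant_traits()] object.
#' @param schedule an [make_schedule()] schedule for the same condition.
#' @param use_trajectories derive the recorded shooting angle from a jittered
#'   synthetic trajectory (`TRUE`, default) or record the model hand angle
#'   exactly (`FALSE`).
#' @param keep_trajectories attach the trajectory samples as attribute
#'   `"trajectories"` (long tibble)?
#' @param config a [default_config()] list supplying trajectory geometry.
#' @return A tibble with one row per trial: `participant`, `condition`,
#'   `block`, `trial` (0-based within experiment), `target_angle`,
#'   `neighbor_angle`, `rotation_applied`, `shooting_angle`, `cursor_angle`,
#'   `pe1`, `pe2`, `main_target_visible`, `neighbor_visible`, `latent_p_hat`,
#'   `latent_spe`. Angles in degrees wrapped to `(-180, 180]`; `pe1`/`pe2`
#'   are `NA` when the corresponding target was not visible at feedback,
#'   `latent_spe` is `NA` on no-feedback trials.
#' @export
simulate_participant <- function(traits, schedule,
                                 use_trajectories = TRUE,
                                 keep_trajectories = FALSE,
                                 config = default_config()) {
  stopifnot(inherits(traits, "participant_traits"),
            inherits(schedule, "experiment_schedule"))
  if (attr(schedule, "condition") != traits$condition)
    stop("schedule condition does not match participant condition", call. = FALSE)

  rotation <- attr(schedule, "rotation")
  radius <- attr(schedule, "circle_radius")
  vis <- feedback_visibility(traits$condition)
  params <- model_params(a = traits$a, b = traits$b,
                         sigma_u = traits$sigma_u, sigma_p = config$sigma_r)

  n_total <- sum(schedule$n_trials)
  # shared stream: rotation noise for every trial slot (consumed identically
  # in all conditions so latent dynamics line up across matched participants)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(child_seed(traits$seed_shared, 11L))
  n_r_all <- stats::rnorm(n_total, 0, config$sigma_r)

  set.seed(child_seed(traits$seed, 23L))

  rows <- vector("list", n_total)
  trajs <- if (keep_trajectories) vector("list", n_total) else NULL
  est <- 0
  prev_pe1 <- NA_real_
  prev_S <- NA_real_
  trial_idx <- 0L

  for (bi in seq_len(nrow(schedule))) {
    blk <- schedule$block[bi]
    nb <- schedule$n_trials[bi]
    if (nb == 0L) next
    rot_on <- schedule$rotation_on[bi]
    fb_on <- schedule$feedback_on[bi]
    has_target <- blk != "no_feedback"
    # target-removal manipulation operates in the rotation blocks with the
    # neighboring target present; elsewhere the main target is simply shown
    manipulated <- blk %in% c("pre_strategy", "adaptation")
    main_vis <- if (!fb_on) FALSE else if (manipulated) unname(vis["main_target_visible"]) else TRUE
    nbr_vis <- if (manipulated) unname(vis["neighbor_visible"]) else FALSE

    targets <- if (has_target) target_sequence(nb) else rep(NA_real_, nb)

    for (k in seq_len(nb)) {
      trial_idx <- trial_idx + 1L
      tgt <- targets[k]
      p_t <- if (rot_on) rotation + n_r_all[trial_idx] else 0

      if (!has_target) {
        # shoot anywhere on the forward 180-degree arc; no feedback, no SPE
        shoot_abs <- stats::runif(1, -90, 90)
        rows[[trial_idx]] <- list(
          block = blk, trial = trial_idx - 1L, target_angle = NA_real_,
          neighbor_angle = NA_real_, rotation_applied = 0,
          shooting_angle = wrap_angle(shoot_abs), cursor_angle = NA_real_,
          pe1 = NA_real_, pe2 = NA_real_,
          main_target_visible = FALSE, neighbor_visible = FALSE,
          latent_p_hat = est, latent_spe = NA_real_)
        est <- no_feedback_step(est, params)
        next
      }

      S <- if (schedule$strategy_instructed[bi]) {
        lapse <- stats::runif(1) < traits$correction_lapse_prob
        correction_policy(traits, prev_pe1, prev_S, "adaptation",
                          lapse = lapse, rotation = rotation)
      } else 0
      n_u <- stats::rnorm(1, 0, traits$sigma_u)
      u <- motor_command(est, S, n_u)
      hand_abs <- tgt + u

      if (use_trajectories) {
        traj <- synth_trajectory(hand_abs, jitter = config$traj_jitter,
                                 step = config$traj_step, rmax = config$traj_rmax)
        shoot <- shooting_angle(traj, circle_radius = radius)
        if (keep_trajectories) trajs[[trial_idx]] <- traj
      } else {
        shoot <- wrap_angle(hand_abs)
      }
      cursor <- wrap_angle(shoot + p_t)
      nbr <- wrap_angle(tgt - 45)
      pe1 <- if (main_vis) wrap_angle(cursor - tgt) else NA_real_
      pe2 <- if (nbr_vis) wrap_angle(cursor - nbr) else NA_real_

      spe <- NA_real_
      p_hat_t <- est
      if (fb_on) {
        # learning operates on the intended command's efference copy; the
        # trajectory jitter is recording noise and does not enter the SPE
        c_model <- cursor_feedback(u, p_t, 0)
        spe <- compute_spe(c_model, u, est)
        est <- update_estimate(est, spe, params)
      } else {
        est <- no_feedback_step(est, params)
      }

      rows[[trial_idx]] <- list(
        block = blk, trial = trial_idx - 1L, target_angle = wrap_angle(tgt),
        neighbor_angle = if (manipulated) nbr else NA_real_,
        rotation_applied = p_t, shooting_angle = shoot, cursor_angle = cursor,
        pe1 = pe1, pe2 = pe2,
        main_target_visible = main_vis, neighbor_visible = nbr_vis,
        latent_p_hat = p_hat_t, latent_spe = spe)

      if (schedule$strategy_instructed[bi]) {
        prev_pe1 <- pe1
        prev_S <- S
      }
    }
  }

  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  out <- tibble::add_column(out,
                            participant = traits$id,
                            condition = traits$condition,
                            .before = 1)
  if (keep_trajectories) {
    keep <- !vapply(trajs, is.null, logical(1))
    tr <- dplyr::bind_rows(lapply(which(keep), function(i) {
      tibble::add_column(trajs[[i]],
                         participant = traits$id, trial = i - 1L,
                         sample_index = seq_len(nrow(trajs[[i]])), .before = 1)
    }))
    attr(out, "trajectories") <- tr
  }
  out
}

#' Simulate a full synthetic cohort
#'
#' Generates `n_per_condition` participants in each of the four conditions.
#' Traits are drawn from the configured distributions; the state-space rates
#' and the rotation-noise stream are keyed by the participant's index within
#' condition (not by condition), so cohort members are matched across
#' conditions and their latent memory trajectories coincide — the model's
#' statement that the memory update is blind to the strategy and to target
#' visibility.
#'
#' @param n_per_condition participants per condition (default 13).
#' @param config a [default_config()] list.
#' @param seed master integer seed; every stream is derived from it.
#' @param keep_trajectories attach trajectories (attribute `"trajectories"`)?
#' @return Trial table (tibble) for all participants, one row per trial, with
#'   the traits table attached as attribute `"traits"`.
#' @examples
#' tab <- simulate_cohort(n_per_condition = 1,
#'                        config = default_config(use_trajectories = FALSE),
#'                        seed = 1)
#' @export
simulate_cohort <- function(n_per_condition = 13, config = default_config(),
                            seed = 1, keep_trajectories = FALSE) {
  stopifnot(n_per_condition >= 1)
  config <- validate_config(config)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)

  tables <- list()
  traits_rows <- list()
  trajs <- list()
  pid <- 0L
  for (cond in 1:4) {
    sched <- make_schedule(cond, block_lengths = config_blocks(config),
                           washout_rotation = config$washout_rotation,
                           rotation = config$rotation)
    for (idx in seq_len(n_per_condition)) {
      pid <- pid + 1L
      # learner rates come from the idx-keyed shared stream (matched across
      # conditions); correction style from the condition-specific stream
      set.seed(child_seed(seed, 1000L + idx))
      a <- stats::runif(1, config$a_min, config$a_max)
      b <- stats::runif(1, config$b_min, config$b_max)
      set.seed(child_seed(seed, cond * 100000L + idx))
      gain <- stats::runif(1, config$gain_min, config$gain_max)
      lapse <- stats::runif(1, config$lapse_min, config$lapse_max)
      tr <- participant_traits(
        id = sprintf("C%d_P%02d", cond, idx), condition = cond,
        a = a, b = b, sigma_u = config$sigma_u,
        correction_gain = gain, correction_lapse_prob = lapse,
        seed = child_seed(seed, cond * 100000L + idx, 7L),
        seed_shared = child_seed(seed, 1000L + idx, 7L))
      tab <- simulate_participant(tr, sched,
                                  use_trajectories = config$use_trajectories,
                                  keep_trajectories = keep_trajectories,
                                  config = config)
      if (keep_trajectories) trajs[[pid]] <- attr(tab, "trajectories")
      attr(tab, "trajectories") <- NULL
      tables[[pid]] <- tab
      traits_rows[[pid]] <- tibble::tibble(
        participant = tr$id, condition = cond, a = a, b = b,
        sigma_u = config$sigma_u, correction_gain = gain,
        correction_lapse_prob = lapse, seed = tr$seed,
        seed_shared = tr$seed_shared)
    }
  }
  out <- dplyr::bind_rows(tables)
  attr(out, "traits") <- dplyr::bind_rows(traits_rows)
  if (keep_trajectories) attr(out, "trajectories") <- dplyr::bind_rows(trajs)
  out
}

trial_table_cols <- c("participant", "condition", "block", "trial",
                      "target_angle", "neighbor_angle", "rotation_applied",
                      "shooting_angle", "cursor_angle", "pe1", "pe2",
                      "main_target_visible", "neighbor_visible",
                      "latent_p_hat", "latent_spe")

#' Write / read a tidy trial table
#'
#' Plain UTF-8 CSV with header, `.` decimal, full double precision; flags are
#' written as TRUE/FALSE. `read_trial_table()` validates the schema and
#' reports the offending columns.
#'
#' @param table trial table as produced by [simulate_cohort()].
#' @param path file path.
#' @return `read_trial_table()` returns the tibble; `write_trial_table()`
#'   returns `path` invisibly.
#' @export
write_trial_table <- function(table, path) {
  stopifnot(all(trial_table_cols %in% names(table)))
  readr::write_csv(table[trial_table_cols], path)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(trial_table_cols, names(tab))
  if (length(missing))
    stop("trial table at `", path, "` is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in c("trial", "target_angle", "shooting_angle", "latent_p_hat")) {
    if (!is.numeric(tab[[col]]))
      stop("trial table column `", col, "` must be numeric", call. = FALSE)
  }
  tab
}
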