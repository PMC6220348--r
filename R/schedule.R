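#' Experiment schedule for one condition
#'
#' Builds the ordered block table of the shooting experiment: familiarization
#' (110 trials, no rotation), baseline (40), two pre-strategy rotation trials,
#' strategy adaptation (198), a no-feedback block (10) and a delayed washout
#' block (80). The 45-degree counter-clockwise rotation is applied from the
#' pre-strategy block onward; the explicit re-aiming strategy is instructed
#' only during the adaptation block and dropped again in washout.
#'
#' Whether the rotation stays on during washout is not part of the design and
#' is configurable via `washout_rotation`; by default it is removed, so washout
#' shows a pure after-effect decaying to zero.
#'
#' @param condition experimental condition, 1-4 (target-removal design; see
#'   [feedback_visibility()]).
#' @param block_lengths named integer overrides for any of `familiarization`,
#'   `baseline`, `pre_strategy`, `adaptation`, `no_feedback`, `washout`.
#' @param washout_rotation logical; keep the rotation applied during washout?
#'   Default `FALSE`.
#' @param rotation rotation magnitude in degrees (CCW-positive), default 45.
#'
#' @return A tibble of class `experiment_schedule` with columns `block`,
#'   `n_trials`, `rotation_on`, `strategy_instructed`, `feedback_on`, and
#'   geometry constants attached as attributes: `circle_radius` (5.3 cm),
#'   `target_spacing` (45 deg), `n_targets` (8), `cursor_cutoff_fraction`
#'   (1/3), `rotation` (deg).
#' @examples
#' make_schedule(1)
#' make_schedule(4, block_lengths = c(adaptation = 10))
#' @export
make_schedule <- function(condition, block_lengths = NULL,
                          washout_rotation = FALSE, rotation = 45) {
  check_condition(condition)
  lengths <- c(familiarization = 110L, baseline = 40L, pre_strategy = 2L,
               adaptation = 198L, no_feedback = 10L, washout = 80L)
  if (!is.null(block_lengths)) {
    bad <- setdiff(names(block_lengths), names(lengths))
    if (length(bad))
      stop("unknown block name(s): ", paste(bad, collapse = ", "), call. = FALSE)
    lengths[names(block_lengths)] <- as.integer(block_lengths)
  }
  sched <- tibble::tibble(
    block = names(lengths),
    n_trials = unname(lengths),
    rotation_on = c(FALSE, FALSE, TRUE, TRUE, FALSE, isTRUE(washout_rotation)),
    strategy_instructed = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    feedback_on = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  )
  structure(sched,
            condition = as.integer(condition),
            circle_radius = 5.3,
            target_spacing = 45,
            n_targets = 8L,
            cursor_cutoff_fraction = 1 / 3,
            rotation = rotation,
            washout_rotation = isTRUE(washout_rotation),
            class = c("experiment_schedule", class(sched)))
}

check_condition <- function(condition) {
  if (length(condition) != 1L || !condition %in% 1:4)
    stop("`condition` must be one of 1, 2, 3, 4", call. = FALSE)
  invisible(condition)
}

#' Target visibility at feedback time for each condition
#'
#' In the 2x2 target-removal design, targets vanish once the cursor passes one
#' third of the distance to the target circle: Condition 1 keeps both the main
#' (bull's eye) and the neighboring target visible; Condition 2 removes the
#' main target (only the aiming error PE2 remains available); Condition 3
#' removes the neighboring target (only PE1 remains); Condition 4 removes both.
#'
#' @param condition experimental condition, 1-4.
#' @return Named logical vector `c(main_target_visible, neighbor_visible)`.
#' @examples
#' feedback_visibility(2)
#' @export
feedback_visibility <- function(condition) {
  check_condition(condition)
  main <- c(TRUE, FALSE, TRUE, FALSE)[condition]
  neighbor <- c(TRUE, TRUE, FALSE, FALSE)[condition]
  c(main_target_visible = main, neighbor_visible = neighbor)
}

#' Pseudo-random target sequence
#'
#' Targets sit at 8 locations 45 degrees apart on the circle; presentation is
#' pseudo-random with each target shown exactly once in every consecutive
#' aligned block of eight trials (shuffled per 8-block).
#'
#' @param n_trials number of trials (>= 0).
#' @param seed optional integer seed for the shuffle; if `NULL` the current RNG
#'   state is used.
#' @return Numeric vector of `n_trials` target angles in degrees, wrapped to
#'   `(-180, 180]`.
#' @examples
#' sort(target_sequence(8, seed = 1))
#' @export
target_sequence <- function(n_trials, seed = NULL) {
  stopifnot(n_trials >= 0)
  if (n_trials == 0L) return(numeric(0))
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  targets <- wrap_angle(seq(0, 315, by = 45))
  n_blocks <- ceiling(n_trials / 8)
  seq_full <- unlist(lapply(seq_len(n_blocks), function(i) sample(targets)))
  seq_full[seq_len(n_trials)]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
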