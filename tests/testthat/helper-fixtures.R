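# Small study configuration for fast unit tests: shortened blocks (windows
# still >= 10 trials where summarised), no trajectories, tiny bootstrap.
tiny_config <- function(...) {
  default_config(use_trajectories = FALSE, n_boot = 50,
                 block_familiarization = 8L, block_baseline = 16L,
                 block_adaptation = 40L, block_no_feedback = 4L,
                 block_washout = 16L, ...)
}

sim_tiny_cohort <- function(seed = 42, n_per_condition = 3, ...) {
  simulate_cohort(n_per_condition, tiny_config(...), seed = seed)
}

# One deterministic participant with explicit parameters.
sim_one <- function(condition = 4, a = 1, b = 0.1, sigma_u = 0, sigma_r = 0,
                    gain = 0, lapse = 0, seed = 7,
                    config = default_config(use_trajectories = FALSE),
                    block_lengths = NULL) {
  config$sigma_r <- sigma_r
  sched <- make_schedule(condition,
                         block_lengths = block_lengths %||% config_blocks_t(config))
  tr <- participant_traits("P1", condition, a = a, b = b, sigma_u = sigma_u,
                           correction_gain = gain,
                           correction_lapse_prob = lapse, seed = seed)
  simulate_participant(tr, sched, use_trajectories = FALSE, config = config)
}

config_blocks_t <- function(cfg) {
  c(familiarization = cfg$block_familiarization, baseline = cfg$block_baseline,
    pre_strategy = cfg$block_pre_strategy, adaptation = cfg$block_adaptation,
    no_feedback = cfg$block_no_feedback, washout = cfg$block_washout)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
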