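#!/usr/bin/env Rscript
# Generate the default synthetic cohort: 4 feedback conditions x 13
# participants, full block schedule (familiarization 110 / baseline 40 /
# 2 pre-strategy rotation trials / 198 strategy trials / 10 no-feedback /
# 80 washout), 45 deg CCW rotation with 0.5 deg trial noise, 6.1 deg motor
# noise, jittered 2-D trajectories. Writes the tidy trial table, the
# participant traits and a manifest under results/simulation/.

library(vmradapt)

seed <- 1
run_simulate(default_config(), seed = seed, out_dir = "results/simulation")

tab <- read_trial_table("results/simulation/trial_table.csv")
cat(sprintf("\n%d participants, %d trials each, %d rows total\n",
            length(unique(tab$participant)),
            nrow(tab) / length(unique(tab$participant)), nrow(tab)))
cat("blocks:", paste(unique(tab$block), collapse = ", "), "\n")
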