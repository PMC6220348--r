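#!/usr/bin/env Rscript
# Render the human-readable summary of the analysis results
# (results/analysis/report.txt), echoing it to the console.

library(vmradapt)

run_report("results/analysis")
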