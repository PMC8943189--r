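#!/usr/bin/env Rscript
# Step 5 — single-call end-to-end reproduction.
#
# Runs the whole analysis (simulate -> split -> TFNBS -> metrics -> group
# statistics) through run_pipeline() with one root seed, writing a complete
# report bundle under results/report/ and printing the summary. Stages 01-04
# expose the same computations piecewise; this script demonstrates that the
# orchestrated run is deterministic and self-contained.

library(hemiconn)

cfg <- analysis_config(
  mode = "synthetic",
  generator = generator_config(),
  tfnbs = tfnbs_params(n_perm = 1000),
  subgroups = c("all", "precentral", "insular"),
  n_rand = 25,
  out_dir = "results/report",
  seed = 2026L
)
bundle <- run_pipeline(cfg)
cat(summarize_report(bundle), sep = "\n")
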