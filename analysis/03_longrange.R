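#!/usr/bin/env Rscript
# Stage 3 — long-range periodic oral dosing.
# Integrates dx/dt = D(t) DR - k_gi x, dy/dt = k_gi x - k_plasma y by
# fixed-step RK4 (dt = 0.01 h, 15 dose periods) with the dissolution-derived
# dose scalings (NC: /12, TAbCD: /32 relative to the fast-dissolving HPbCD
# complex), then summarises the limit cycle each compound settles onto.
suppressPackageStartupMessages(library(ncpk))

cfg <- read_run_config()
res <- run_pipeline(cfg, stages = "longrange", outdir = "results")

lc <- read_csv_commented("results/limit_cycles.csv")
cat("Limit-cycle summary (burn-in 10 cycles):\n")
print(lc)
cat("\nEach compound locks onto the dosing period (6 h for NC, 24 h for the",
    "\ncomplexes); convergence_ratio is the relative change between the last",
    "\ntwo plasma peaks.\n")
cat("Written:", paste(res$files, collapse = ", "), "\n")
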