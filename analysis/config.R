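# Shared configuration for the numbered analysis scripts.
#
# Every script regenerates the cohort deterministically from this config, so
# the scripts can be run independently and in any order; results land under
# results/.

library(tlntcp)

results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)

# Study-scale synthetic cohort: 78 patients, two lobes each, ground-truth
# NTCP on the plain-sum D1.5cc (slope 0.067/Gy, intercept -8.216).
cohort_config <- simulation_config(n_patients = 78, seed = 20100)

split_seed <- 20101
split_ratio <- c(2, 1)

a_grid <- seq(0, 0.01, by = 2e-4)
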