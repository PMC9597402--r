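## Shared settings for the numbered analysis drivers. Run every script from
## the repository root, in order:
##
##   Rscript analysis/01_simulate_study.R
##   Rscript analysis/02_events_and_summary.R
##   ...
##
## To analyse real field data instead of the simulated study, place
## detections.csv, deployments.csv and covariates.csv under DATA_DIR and skip
## step 01.

SEED <- 2022L
DATA_DIR <- "analysis/data"
RESULTS_DIR <- "results"
N_RESAMPLES <- 1e5

dir.create(DATA_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
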