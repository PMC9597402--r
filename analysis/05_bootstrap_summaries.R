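#!/usr/bin/env Rscript
## Step 5 -- site-level summary statistics (proportion of carcasses used and
## proportion of foraging time) per species, with percentile bootstrap
## confidence intervals over sites within region.

library(scavsurv)
source("analysis/00_settings.R")

deployments <- read_deployments(file.path(DATA_DIR, "deployments.csv"))
detections <- read_detections(file.path(DATA_DIR, "detections.csv"), deployments)
covariates <- read_site_covariates(file.path(DATA_DIR, "covariates.csv"))
events <- build_foraging_events(detections)

out <- list()
for (sp in c("devil", "quoll", "raven", "cat")) {
  rec <- use_records(events, deployments, covariates, sp)
  for (stat in c("prop_used", "prop_time")) {
    sm <- tryCatch(suppressWarnings(site_means(rec, stat, events = events)),
                   scavsurv_data_error = function(e) NULL)
    if (is.null(sm) || !nrow(sm)) next
    rb <- regional_bootstrap(sm, sprintf("%s %s", sp, stat),
                             n_resamples = N_RESAMPLES, seed = SEED)
    rb$species <- sp
    rb$statistic_name <- stat
    out[[length(out) + 1L]] <- rb
  }
}

boot <- do.call(rbind, out)
write.csv(boot, file.path(RESULTS_DIR, "bootstrap_summaries.csv"),
          row.names = FALSE)
print(boot)
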