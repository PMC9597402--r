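#!/usr/bin/env Rscript
## Step 4 -- carcass-use GLMMs: a hurdle of a binomial use model (did the
## species feed at the carcass at all?) and a Gamma foraging-duration model on
## the used carcasses, for ravens and cats, with AUC and per-term effect sizes.

library(scavsurv)
source("analysis/00_settings.R")

deployments <- read_deployments(file.path(DATA_DIR, "deployments.csv"))
detections <- read_detections(file.path(DATA_DIR, "detections.csv"), deployments)
covariates <- read_site_covariates(file.path(DATA_DIR, "covariates.csv"))
events <- build_foraging_events(detections)

model_terms <- list(
  raven = list(occupancy = c("devil_activity", "habitat_wet", "weight_kg"),
               intensity = c("devil_forage_min", "weight_kg")),
  cat = list(occupancy = c("devil_activity", "weight_kg"),
             intensity = c("devil_forage_min", "weight_kg")))

effects <- list()
for (sp in names(model_terms)) {
  rec <- use_records(events, deployments, covariates, sp)
  cat(sprintf("\n== %s: %d carcasses, %d used ==\n", sp, nrow(rec),
              sum(rec$used)))
  hur <- fit_hurdle(rec, occupancy_terms = model_terms[[sp]]$occupancy,
                    intensity_terms = model_terms[[sp]]$intensity)
  if (!is.null(hur$occupancy)) {
    print(hur$occupancy)
    cat(sprintf("occupancy AUC: %.3f\n", auc(hur$occupancy)))
    for (tm in model_terms[[sp]]$occupancy) {
      es <- effect_size(hur$occupancy, tm)
      effects[[length(effects) + 1L]] <-
        data.frame(species = sp, model = "occupancy", variable = es$variable,
                   p0 = es$p0, p1 = es$p1, es = es$es, contrast = es$contrast)
    }
  }
  if (!is.null(hur$intensity)) print(hur$intensity)
  if (length(hur$skipped)) {
    cat("skipped:", paste(names(hur$skipped), unlist(hur$skipped),
                          sep = ": ", collapse = "; "), "\n")
  }
}

if (length(effects)) {
  write.csv(do.call(rbind, effects),
            file.path(RESULTS_DIR, "use_effect_sizes.csv"), row.names = FALSE)
}
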