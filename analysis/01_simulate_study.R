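#!/usr/bin/env Rscript
## Step 1 -- simulate a study at the scale of the field design (three regions,
## 136 carcasses) and write the raw CSV inputs consumed by the later steps.

library(scavsurv)
source("analysis/00_settings.R")

config <- paperlike_scenario(seed = SEED)
study <- generate_study(config)
write_study_csv(study, DATA_DIR)

## keep the generating bout table so the round trip can be audited later
write.csv(study$truth$bouts, file.path(DATA_DIR, "truth_bouts.csv"),
          row.names = FALSE)

cat(sprintf("wrote %d detections for %d carcasses across %d sites to %s\n",
            nrow(study$detections), nrow(study$deployments),
            length(unique(study$deployments$site_id)), DATA_DIR))
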