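#!/usr/bin/env Rscript
## Step 2 -- ingest the raw CSVs, reconstruct foraging events with the 4-minute
## gap rule, and produce the regional foraging summary (the Table-1-style
## percentages and foraging-time shares).

library(scavsurv)
source("analysis/00_settings.R")

deployments <- read_deployments(file.path(DATA_DIR, "deployments.csv"))
detections <- read_detections(file.path(DATA_DIR, "detections.csv"), deployments)

events <- build_foraging_events(detections)
write.csv(events, file.path(RESULTS_DIR, "foraging_events.csv"),
          row.names = FALSE)

table1 <- region_summary(events, deployments)
write.csv(table1, file.path(RESULTS_DIR, "region_summary.csv"),
          row.names = FALSE)

cat(sprintf("%d foraging events from %d photos\n",
            nrow(events), nrow(detections)))
print(table1)
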