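test_that("gap rule splits events strictly above the threshold", {
  ## photos at 0,3,6 then a 4-min gap (10), then a >4-min gap (15)
  det <- make_detections("c1", "raven", c(0, 3, 6, 10, 15))
  ev <- build_foraging_events(det)
  expect_equal(nrow(ev), 2L)            # gap of exactly 4 keeps one event
  expect_equal(ev$n_photos, c(4L, 1L))
  expect_equal(ev$duration_min, c(10, 1))  # singleton floored at 1 min

  ev3 <- build_foraging_events(det, gap_min = 3)
  expect_equal(nrow(ev3), 3L)           # stricter threshold splits the 4-min gap
})

test_that("events never mix species or carcasses", {
  det <- rbind(make_detections("c1", "raven", c(0, 2)),
               make_detections("c1", "cat", c(1, 3)),
               make_detections("c2", "raven", c(0, 2)))
  ev <- build_foraging_events(det)
  expect_equal(nrow(ev), 3L)
  expect_setequal(paste(ev$carcass_id, ev$species),
                  c("c1 raven", "c1 cat", "c2 raven"))
})

test_that("non-feeding photos are ignored and empty input yields empty events", {
  det <- make_detections("c1", "raven", c(0, 3, 6), feeding = FALSE)
  ev <- build_foraging_events(det)
  expect_equal(nrow(ev), 0L)
  expect_true(all(c("carcass_id", "species", "start", "end", "n_photos",
                    "duration_min") %in% names(ev)))
  expect_error(build_foraging_events(make_detections("c1", "raven", 0),
                                     gap_min = -1),
               class = "scavsurv_parameter_error")
})

test_that("gap rule matches the brute-force scan on random photo streams", {
  set.seed(7)
  for (rep in 1:5) {
    det <- do.call(rbind, lapply(1:4, function(i) {
      make_detections(paste0("c", i), sample(c("raven", "devil"), 1),
                      sort(sample(0:240, sample(3:25, 1))))
    }))
    det <- det[sample(nrow(det)), ]     # order must not matter
    ev <- build_foraging_events(det)
    or <- oracle_gap_events(det)
    ev <- ev[order(ev$carcass_id, ev$species, ev$start), ]
    expect_equal(nrow(ev), nrow(or))
    expect_equal(ev$n_photos, or$n_photos)
    expect_equal(ev$duration_min, or$duration_min)
    expect_equal(as.numeric(ev$start), as.numeric(or$start))
  }
})

test_that("read_detections validates schema, parses times, drops out-of-window rows", {
  dep <- read_deployments(make_deployments(2))
  det <- data.frame(site_id = "s1", carcass_id = "c01",
                    timestamp = c("2020-08-15T10:00:00", "2020-09-30T10:00:00"),
                    species = "raven", feeding = TRUE)
  expect_warning(out <- read_detections(det, dep), "outside the deployment window")
  expect_equal(nrow(out), 1L)
  expect_s3_class(out$timestamp, "POSIXct")

  expect_error(read_detections(det[, -4], dep), class = "scavsurv_schema_error")
  det_bad <- det; det_bad$carcass_id <- "zz"
  expect_error(read_detections(det_bad, dep), class = "scavsurv_consistency_error")
  det_bad2 <- det; det_bad2$timestamp[1] <- "not a time"
  expect_error(read_detections(det_bad2, dep), class = "scavsurv_parse_error")
  det_bad3 <- det; det_bad3$species <- ""
  expect_error(read_detections(det_bad3, dep), class = "scavsurv_schema_error")
})

test_that("read_deployments enforces invariants", {
  dep <- make_deployments(3)
  expect_silent(read_deployments(dep))
  bad <- dep; bad$weight_kg[2] <- 0
  expect_error(read_deployments(bad), class = "scavsurv_schema_error")
  bad <- dep; bad$end_time[1] <- bad$deploy_time[1]
  expect_error(read_deployments(bad), class = "scavsurv_schema_error")
  bad <- dep; bad$consumed_time[1] <- bad$deploy_time[1] - 10
  expect_error(read_deployments(bad), class = "scavsurv_consistency_error")
})

test_that("read_site_covariates rejects negative or non-finite activity", {
  expect_error(read_site_covariates(make_covariates("s1", devil = -1)),
               class = "scavsurv_schema_error")
  expect_error(read_site_covariates(make_covariates("s1", devil = NA)),
               class = "scavsurv_schema_error")
})

test_that("csv round trip through the readers is faithful", {
  st <- generate_study(tiny_config(seed = 2))
  tmp <- withr::local_tempdir()
  write_study_csv(st, tmp)
  dep <- read_deployments(file.path(tmp, "deployments.csv"))
  det <- read_detections(file.path(tmp, "detections.csv"), dep)
  cov <- read_site_covariates(file.path(tmp, "covariates.csv"))
  expect_equal(nrow(dep), nrow(st$deployments))
  expect_equal(nrow(det), nrow(st$detections))
  expect_equal(sort(cov$site_id), sort(st$covariates$site_id))
  expect_equal(build_foraging_events(det), build_foraging_events(st$detections))
})

test_that("discovery records censor undiscovered carcasses at their own end time", {
  dep <- read_deployments(make_deployments(3))
  dep$end_time[3] <- dep$deploy_time[3] + 10 * 86400   # early camera failure
  cov <- make_covariates("s1")
  det <- make_detections("c01", "raven", c(60, 63))
  ev <- build_foraging_events(det)
  rec <- discovery_records(ev, dep, cov)
  expect_equal(rec$status, c(1L, 0L, 0L))
  expect_equal(rec$time[1], (8 * 60 + 60) / (24 * 60))  # first photo, days
  expect_equal(rec$time[2:3], c(21, 10))

  ## species filter: no cat events -> all censored
  rec_cat <- discovery_records(ev, dep, cov, species_filter = "cat")
  expect_equal(rec_cat$status, c(0L, 0L, 0L))

  ## unknown carcass in events
  ev_bad <- ev; ev_bad$carcass_id <- "zz"
  expect_error(discovery_records(ev_bad, dep, cov),
               class = "scavsurv_consistency_error")
})

test_that("persistence records use consumed_time and validate it", {
  dep <- read_deployments(make_deployments(2))
  dep$consumed_time[1] <- dep$deploy_time[1] + 5 * 86400
  cov <- make_covariates("s1")
  rec <- persistence_records(dep, cov)
  expect_equal(rec$status, c(1L, 0L))
  expect_equal(rec$time, c(5, 21))
  expect_equal(rec$habitat_wet, c(0, 0))
  expect_equal(rec$weight_kg, dep$weight_kg)

  dep$consumed_time[2] <- dep$end_time[2] + 1
  expect_error(persistence_records(dep, cov),
               class = "scavsurv_consistency_error")

  ## site missing from covariates
  expect_error(persistence_records(dep[1, ], make_covariates("other")),
               class = "scavsurv_consistency_error")
})

test_that("region_summary computes counts, percentages, and time shares", {
  dep <- make_deployments(4)
  dep$region <- c("full", "full", "simple", "simple")
  det <- rbind(make_detections("c01", "raven", c(0, 3)),       # 3 min
               make_detections("c02", "raven", c(0, 3, 6)),    # 6 min
               make_detections("c02", "devil", c(20, 23)))     # 3 min
  ev <- build_foraging_events(det)
  rs <- region_summary(ev, dep)
  raven <- rs[rs$region == "full" & rs$species == "raven", ]
  expect_equal(raven$n_foraged, 2L)
  expect_equal(raven$pct_foraged, 100)
  expect_equal(raven$hours_foraging, 9 / 60)
  expect_equal(raven$prop_total_time, 9 / 12)
  devil <- rs[rs$region == "full" & rs$species == "devil", ]
  expect_equal(devil$prop_total_time, 3 / 12)
  ## region with no events still gets a zero row
  simple <- rs[rs$region == "simple", ]
  expect_equal(simple$n_foraged, 0L)
  expect_equal(simple$n_deployed, 2L)
})

test_that("region_summary denominator policy distinguishes deployed from analysed", {
  dep <- make_deployments(4)
  dep$removed[4] <- TRUE
  det <- make_detections("c01", "raven", c(0, 3))
  ev <- build_foraging_events(det)
  rs_dep <- region_summary(ev, dep, "deployed")
  rs_ana <- region_summary(ev, dep, "analysed")
  expect_equal(rs_dep$pct_foraged, 100 * 1 / 4)
  expect_equal(rs_ana$pct_foraged, 100 * 1 / 3)
  expect_equal(rs_dep$n_analysed, 3L)
})

test_that("use_records excludes removed carcasses and totals foraging minutes", {
  dep <- make_deployments(3)
  dep$removed[3] <- TRUE
  cov <- make_covariates("s1")
  det <- rbind(make_detections("c01", "raven", c(0, 3, 6)),
               make_detections("c01", "devil", c(30, 33)),
               make_detections("c03", "raven", c(0, 3)))
  ev <- build_foraging_events(det)
  expect_message(ur <- use_records(ev, dep, cov, "raven"), "excluding 1")
  expect_equal(nrow(ur), 2L)            # c03 removed
  expect_equal(ur$used, c(TRUE, FALSE))
  expect_equal(ur$duration_min, c(6, 0))
  expect_equal(ur$devil_forage_min, c(3, 0))
  expect_equal(ur$quoll_forage_min, c(0, 0))
})
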