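test_that("same seed gives identical studies; different seeds differ", {
  a <- generate_study(tiny_config(seed = 5))
  b <- generate_study(tiny_config(seed = 5))
  expect_identical(a$detections, b$detections)
  expect_identical(a$deployments, b$deployments)
  expect_identical(a$covariates, b$covariates)
  c2 <- generate_study(tiny_config(seed = 6))
  expect_false(identical(a$detections, c2$detections))
})

test_that("zero scavenger hazards give an empty world, all records censored", {
  cfg <- tiny_config(seed = 3)
  cfg$persistence$baseline <- 0
  for (g in names(cfg$guilds)) cfg$guilds[[g]]$discovery$baseline <- 0
  st <- generate_study(cfg)
  expect_equal(nrow(st$detections), 0L)
  rec <- persistence_records(st$deployments, st$covariates)
  expect_true(all(rec$status == 0))
  expect_true(all(rec$time == cfg$follow_up_days))
})

test_that("photo emission arithmetic: one 10-min bout gives photos at 0,3,6,9", {
  cfg <- tiny_config(seed = 1)
  truth <- list(bouts = data.frame(carcass_id = "c01", site_id = "s1",
                                   species = "raven", start_min = 0,
                                   end_min = 10),
                config = cfg)
  det <- render_photo_stream(truth, cfg)
  mins <- as.numeric(difftime(det$timestamp, min(det$timestamp), units = "mins"))
  expect_equal(mins, c(0, 3, 6, 9))
  ## bout shorter than the trigger wait -> single photo
  truth$bouts$end_min <- 2
  expect_equal(nrow(render_photo_stream(truth, cfg)), 1L)
})

test_that("overlapping bouts of one species are merged with a message", {
  cfg <- tiny_config(seed = 1)
  truth <- list(bouts = data.frame(carcass_id = "c01", site_id = "s1",
                                   species = "raven",
                                   start_min = c(0, 5), end_min = c(8, 12)),
                config = cfg)
  expect_message(det <- render_photo_stream(truth, cfg), "merg")
  ## merged into one 0-12 bout: photos every 3 min, no gap > 4
  gaps <- diff(as.numeric(det$timestamp)) / 60
  expect_true(all(gaps <= 4))
})

test_that("round trip: gap rule recovers generated bouts one for one", {
  for (seed in c(11, 23, 37)) {
    st <- generate_study(tiny_config(seed = seed))
    truth_bouts <- st$truth$bouts
    ev <- build_foraging_events(st$detections)
    ## same number of events per carcass x species as generated bouts
    key_t <- paste(truth_bouts$carcass_id, truth_bouts$species)
    key_e <- paste(ev$carcass_id, ev$species)
    tt <- table(key_t)
    te <- table(key_e)
    expect_setequal(names(te), names(tt))
    expect_equal(as.integer(te[names(tt)]), as.integer(tt))
    ## reconstructed durations within one trigger interval of the truth
    ev <- ev[order(ev$carcass_id, ev$species, ev$start), ]
    tb <- truth_bouts[order(truth_bouts$carcass_id, truth_bouts$species,
                            truth_bouts$start_min), ]
    true_dur <- tb$end_min - tb$start_min
    expect_true(all(abs(ev$duration_min - true_dur) <=
                      tiny_config()$trigger_wait_min + 1))
  }
})

test_that("empirical discovery rate matches the configured hazard (MC check)", {
  ## large-n single-site world with only the raven guild active
  cfg <- sim_config(
    regions = list(list(name = "full", n_sites = 1L,
                        devil_activity_range = c(4, 4),
                        quoll_activity_range = c(0, 0))),
    carcasses_per_site = c(2000L, 2000L),
    sigma_site = 0,
    persistence = list(baseline = 0, beta = c(devil_activity = 0)),
    seed = 99)
  for (g in names(cfg$guilds)) if (g != "raven") cfg$guilds[[g]]$discovery$baseline <- 0
  cfg$guilds$raven$discovery <- list(baseline = 0.2,
                                     beta = c(devil_activity = 0))
  st <- generate_study(cfg)
  disc <- st$truth$guilds$raven$discovery_min / (24 * 60)   # days
  obs <- disc[!is.na(disc)]
  ## discovery times at used carcasses are exponential(0.2/day) truncated to
  ## the 21-day window; compare the sample mean to the closed-form truncated
  ## mean within 3 MC standard errors
  lam <- 0.2; U <- cfg$follow_up_days
  mean_true <- 1 / lam - U * exp(-lam * U) / (1 - exp(-lam * U))
  se <- sd(obs) / sqrt(length(obs))
  expect_gt(length(obs), 1000)
  expect_lt(abs(mean(obs) - mean_true), 3 * se)
})

test_that("censoring increases monotonically as baseline hazards decrease", {
  frac_censored <- vapply(c(0.05, 0.01, 0.002), function(h0) {
    cfg <- tiny_config(seed = 77)
    cfg$persistence$baseline <- h0
    st <- generate_study(cfg)
    rec <- persistence_records(st$deployments, st$covariates)
    mean(rec$status == 0)
  }, numeric(1))
  expect_true(all(diff(frac_censored) >= 0))
})

test_that("paperlike scenario matches the study design counts", {
  st <- generate_study(paperlike_scenario(seed = 12))
  dep <- st$deployments
  expect_equal(nrow(dep), 136L)
  counts <- table(dep$region)
  expect_equal(unname(counts[c("full", "reduced", "simple")]),
               c(40L, 56L, 40L), ignore_attr = TRUE)
  sites <- unique(dep[, c("site_id", "region")])
  expect_equal(unname(table(sites$region)[c("full", "reduced", "simple")]),
               c(7L, 5L, 6L), ignore_attr = TRUE)
  ## extirpated region: devil activity identically zero
  cov <- st$covariates
  simple_sites <- sites$site_id[sites$region == "simple"]
  expect_true(all(cov$devil_activity[cov$site_id %in% simple_sites] == 0))
  expect_true(any(cov$devil_activity[!cov$site_id %in% simple_sites] > 0))
  ## predictors not collinear (fitting condition for the full model)
  rec <- persistence_records(dep, cov)
  cc <- cor(rec[, c("devil_activity", "quoll_activity", "habitat_wet", "weight_kg")])
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.7)
  ## weights follow the two carcass species ranges
  expect_true(all(dep$weight_kg[dep$carcass_species == "wallaby"] >= 13.8 &
                    dep$weight_kg[dep$carcass_species == "wallaby"] <= 18.6))
  expect_true(all(dep$weight_kg[dep$carcass_species == "pademelon"] >= 1.5 &
                    dep$weight_kg[dep$carcass_species == "pademelon"] <= 8))
})

test_that("config validation rejects bad parameters", {
  expect_error(sim_config(regions = list(list(name = "a", n_sites = 0L,
                                              devil_activity_range = c(0, 1),
                                              quoll_activity_range = c(0, 1)))),
               class = "scavsurv_config_error")
  expect_error(tiny_config(sigma_site = -1), class = "scavsurv_config_error")
  expect_error(tiny_config(follow_up_days = 0), class = "scavsurv_config_error")
  bad <- tiny_config()
  bad$regions[[1]]$devil_activity_range <- c(5, 1)
  expect_error(generate_study(bad), class = "scavsurv_config_error")
})

test_that("simulated detections carry the schema the readers expect", {
  st <- generate_study(tiny_config(seed = 15))
  dep <- read_deployments(st$deployments)
  det <- read_detections(st$detections, dep)
  expect_equal(nrow(det), nrow(st$detections))   # nothing out of window
  expect_true(all(det$feeding))
  expect_s3_class(det$timestamp, "POSIXct")
  ## integer-minute timestamps
  expect_true(all(as.numeric(det$timestamp) %% 60 == 0))
})
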