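## Shared small data builders for the test suite.

## Detection-table builder: one row per photo, minute offsets from a base time.
make_detections <- function(carcass_id, species, minutes,
                            site_id = "s1", feeding = TRUE,
                            base = as.POSIXct("2020-08-15 08:00:00", tz = "UTC")) {
  data.frame(site_id = site_id, carcass_id = carcass_id,
             timestamp = base + minutes * 60, species = species,
             feeding = feeding)
}

## Minimal valid deployment table, n carcasses across the given sites.
make_deployments <- function(n, sites = "s1", region = "full",
                             habitat = "dry", weight = 15,
                             follow_up_days = 21,
                             base = as.POSIXct("2020-08-15 00:00:00", tz = "UTC")) {
  data.frame(carcass_id = sprintf("c%02d", seq_len(n)),
             site_id = rep_len(sites, n),
             region = rep_len(region, n),
             habitat = rep_len(habitat, n),
             carcass_species = "wallaby",
             weight_kg = rep_len(weight, n),
             deploy_time = base,
             end_time = base + follow_up_days * 86400,
             consumed_time = as.POSIXct(NA),
             secured = TRUE, removed = FALSE)
}

make_covariates <- function(sites, devil = 5, quoll = 2) {
  data.frame(site_id = sites,
             devil_activity = rep_len(devil, length(sites)),
             quoll_activity = rep_len(quoll, length(sites)))
}

## Small but active simulated study: 2 regions x 2 sites, lively hazards so
## most carcasses get discovered and consumed within follow-up.
tiny_config <- function(seed = 1L, ...) {
  sim_config(
    regions = list(
      list(name = "full", n_sites = 2L, devil_activity_range = c(8, 16),
           quoll_activity_range = c(0, 4)),
      list(name = "simple", n_sites = 2L, devil_activity_range = c(0, 0),
           quoll_activity_range = c(0, 0))),
    carcasses_per_site = c(6L, 8L),
    persistence = list(baseline = 0.02,
                       beta = c(devil_activity = log(1.2),
                                quoll_activity = log(1.2),
                                habitat_wet = -0.2, weight_kg = -0.02)),
    seed = seed, ...)
}

## Fixed-effects survival records with a known structure for Cox tests.
sim_cox_records <- function(n, beta = c(devil_activity = 0.2, weight_kg = -0.1),
                            n_sites = 4L, sigma_site = 0, seed = 1L,
                            censor_at = 30) {
  set.seed(seed)
  site <- sample(sprintf("s%d", seq_len(n_sites)), n, replace = TRUE)
  b <- rnorm(n_sites, 0, sigma_site)
  names(b) <- sprintf("s%d", seq_len(n_sites))
  d <- data.frame(carcass_id = sprintf("c%03d", seq_len(n)),
                  site_id = site, region = "full",
                  devil_activity = runif(n, 0, 10),
                  quoll_activity = runif(n, 0, 5),
                  habitat_wet = rbinom(n, 1, 0.5),
                  weight_kg = runif(n, 2, 18))
  eta <- b[site]
  for (tm in names(beta)) eta <- eta + beta[[tm]] * d[[tm]]
  t_latent <- rexp(n, rate = 0.05 * exp(unname(eta)))
  d$time <- pmin(t_latent, censor_at)
  d$status <- as.integer(t_latent <= censor_at)
  attr(d, "site_intercepts") <- b
  d
}
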