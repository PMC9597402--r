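#' Configuration for a synthetic scavenging study
#'
#' Defines the world a simulated study is drawn from: community regions with
#' site counts and devil/quoll activity ranges, carcasses per site, a Gaussian
#' site random intercept shared across outcomes, proportional-hazards
#' coefficients for carcass consumption and per-guild discovery, logit
#' coefficients for carcass use, Gamma coefficients for total foraging
#' duration, the camera trigger wait, and the follow-up length.
#'
#' Latent event times are exponential (log hazard linear in the covariates
#' plus the site intercept), so proportional hazards holds by construction and
#' closed-form checks exist; a Weibull shape can be supplied for
#' proportional-hazards stress tests.
#'
#' @param regions list of region definitions: each a list with `name`,
#'   `n_sites`, `devil_activity_range`, `quoll_activity_range`, optional
#'   `n_carcasses` (total in the region, spread as evenly as possible over its
#'   sites; otherwise counts are drawn from `carcasses_per_site`), optional
#'   `species_mix` (named probabilities over `pademelon`/`wallaby`) and
#'   `secured` flag.
#' @param carcasses_per_site integer range, default 6 to 8.
#' @param sigma_site SD of the Gaussian site random intercept.
#' @param persistence list: `baseline` hazard (per day) and named `beta` on
#'   the log hazard of full consumption.
#' @param guilds named list (devil, quoll, raven, cat): each with `discovery`
#'   (baseline + beta), `use` (named logit coefficients incl. `intercept`),
#'   `duration` (named log-mean coefficients incl. `intercept`, plus `shape`),
#'   and optional `requires` (an activity column that must be positive at the
#'   site for the guild to occur at all).
#' @param follow_up_days camera deployment length (days), default 21.
#' @param trigger_wait_min camera wait period between photos (minutes),
#'   default 3.
#' @param weibull_shape shape of the latent-time distribution (1 =
#'   exponential).
#' @param deploy_date first day of deployment (UTC midnight).
#' @param seed integer seed governing every random draw.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(regions = NULL,
                       carcasses_per_site = c(6L, 8L),
                       sigma_site = 0.3,
                       persistence = list(
                         baseline = 0.004,
                         beta = c(devil_activity = log(1.2),
                                  quoll_activity = log(1.2),
                                  habitat_wet = -0.2,
                                  weight_kg = -0.02)),
                       guilds = default_guilds(),
                       follow_up_days = 21,
                       trigger_wait_min = 3,
                       weibull_shape = 1,
                       deploy_date = "2020-08-15",
                       seed = 1L) {
  if (is.null(regions)) {
    regions <- list(
      list(name = "full", n_sites = 3L,
           devil_activity_range = c(10, 20), quoll_activity_range = c(2, 6)),
      list(name = "reduced", n_sites = 3L,
           devil_activity_range = c(1, 5), quoll_activity_range = c(2, 6)),
      list(name = "simple", n_sites = 3L,
           devil_activity_range = c(0, 0), quoll_activity_range = c(0, 0)))
  }
  out <- structure(list(regions = regions,
                 carcasses_per_site = as.integer(carcasses_per_site),
                 sigma_site = sigma_site, persistence = persistence,
                 guilds = guilds, follow_up_days = follow_up_days,
                 trigger_wait_min = trigger_wait_min,
                 weibull_shape = weibull_shape,
                 deploy_date = deploy_date, seed = as.integer(seed)),
            class = "sim_config")
  validate_sim_config(out)
}

validate_sim_config <- function(config) {
  ok <- length(config$carcasses_per_site) == 2L &&
    config$carcasses_per_site[1] <= config$carcasses_per_site[2] &&
    config$carcasses_per_site[1] >= 1L &&
    config$sigma_site >= 0 && config$persistence$baseline >= 0 &&
    config$follow_up_days > 0 && config$trigger_wait_min > 0 &&
    config$weibull_shape > 0
  if (!isTRUE(ok)) {
    stop_scav("invalid simulation parameters: carcass range must be ordered and >= 1; sigma_site and baseline non-negative; follow-up, trigger wait and shape positive",
              class = "scavsurv_config_error")
  }
  bad_range <- function(rg) length(rg) != 2L || any(!is.finite(rg)) ||
    rg[1] > rg[2] || rg[1] < 0
  for (r in config$regions) {
    if (is.null(r$name) || is.null(r$n_sites) || r$n_sites < 1L ||
        bad_range(r$devil_activity_range) || bad_range(r$quoll_activity_range)) {
      stop_scav("invalid region definition '%s': need name, n_sites >= 1, and well-ordered non-negative activity ranges",
                r$name %||% "<unnamed>", class = "scavsurv_config_error")
    }
  }
  for (g in config$guilds) {
    if (g$duration[["shape"]] <= 0 || g$discovery$baseline < 0) {
      stop_scav("guild durations need positive shape and non-negative hazards",
                class = "scavsurv_config_error")
    }
  }
  invisible(config)
}

#' @rdname sim_config
#' @export
default_guilds <- function() {
  list(
    devil = list(requires = "devil_activity",
                 discovery = list(baseline = 0.30,
                                  beta = c(devil_activity = 0.05)),
                 use = c(intercept = -1.0, devil_activity = 0.30),
                 duration = c(intercept = log(150), devil_activity = 0.02,
                              shape = 1.5)),
    quoll = list(requires = "quoll_activity",
                 discovery = list(baseline = 0.10,
                                  beta = c(quoll_activity = 0.05)),
                 use = c(intercept = -1.2, quoll_activity = 0.25),
                 duration = c(intercept = log(120), shape = 1.5)),
    raven = list(discovery = list(baseline = 0.25,
                                  beta = c(devil_activity = log(0.91),
                                           habitat_wet = log(0.48))),
                 use = c(intercept = 1.4, devil_activity = -0.15,
                         habitat_wet = -0.5),
                 duration = c(intercept = log(500), devil_activity = -0.05,
                              shape = 1.2)),
    cat = list(discovery = list(baseline = 0.03,
                                beta = c(devil_activity = log(0.88))),
               use = c(intercept = -0.25, devil_activity = -0.15),
               duration = c(intercept = log(60), shape = 1.0)))
}

#' Ready-made configuration mirroring the study design
#'
#' Three community regions with 7/5/6 sites and 40/56/40 carcasses (136
#' total), region-scaled devil and quoll activity (identically zero in the
#' simple region, where both species are extirpated), mostly wallaby carcasses
#' in the simple region and pademelons elsewhere, and coefficients under which
#' devil activity accelerates carcass consumption (hazard ratio above 1) and
#' suppresses discovery by ravens and cats (hazard ratios below 1).
#'
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
paperlike_scenario <- function(seed = 1L) {
  sim_config(
    regions = list(
      list(name = "full", n_sites = 7L, n_carcasses = 40L,
           devil_activity_range = c(10, 20), quoll_activity_range = c(0, 6),
           species_mix = c(pademelon = 1), secured = TRUE),
      list(name = "reduced", n_sites = 5L, n_carcasses = 56L,
           devil_activity_range = c(1, 5), quoll_activity_range = c(0, 8),
           species_mix = c(pademelon = 1), secured = TRUE),
      list(name = "simple", n_sites = 6L, n_carcasses = 40L,
           devil_activity_range = c(0, 0), quoll_activity_range = c(0, 0),
           species_mix = c(wallaby = 0.95, pademelon = 0.05),
           secured = FALSE)),
    seed = seed)
}

weight_range <- function(species) {
  switch(species, pademelon = c(1.5, 8), wallaby = c(13.8, 18.6),
         stop_scav("unknown carcass species: %s", species,
                   class = "scavsurv_config_error"))
}

## latent event time (days): Weibull with proportional hazards; shape 1 is
## exponential. rate <= 0 means the event never happens.
draw_latent_time <- function(n, rate, shape) {
  out <- rep(Inf, n)
  pos <- rate > 0
  if (any(pos)) {
    u <- stats::runif(sum(pos))
    out[pos] <- (-log(u) / rate[pos])^(1 / shape)
  }
  out
}

## truncated draw of an exponential on (0, upper)
draw_truncated_exp <- function(rate, upper) {
  u <- stats::runif(length(rate))
  -log(1 - u * (1 - exp(-rate * upper))) / rate
}

lin_pred <- function(coefs, covars) {
  eta <- if ("intercept" %in% names(coefs)) coefs[["intercept"]] else 0
  for (nm in setdiff(names(coefs), c("intercept", "shape"))) {
    eta <- eta + coefs[[nm]] * covars[[nm]]
  }
  eta
}

#' Generate a complete synthetic scavenging study
#'
#' Draws sites with activity covariates, a Gaussian site intercept, carcasses
#' with habitat/species/weight, a latent full-consumption time per carcass
#' (proportional hazards), per-guild carcass use (Bernoulli on the logit
#' scale), discovery times and Gamma total foraging durations, lays the
#' foraging time out as bouts separated by more than the gap threshold, and
#' renders the camera photo stream (one photo at bout start, then every
#' `trigger_wait_min` minutes). Everything is reproducible from the seed.
#'
#' @param config a [sim_config()].
#' @return list: `detections`, `deployments`, `covariates` (the exact CSV
#'   schemas consumed by the ingest functions) and `truth` (site intercepts,
#'   latent times, use flags, durations, bouts, and all generating
#'   coefficients).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  deploy0 <- as.POSIXct(paste(config$deploy_date, "00:00:00"), tz = "UTC")
  fu_min <- config$follow_up_days * 1440

  sites <- do.call(rbind, lapply(config$regions, function(r) {
    ids <- sprintf("%s_s%d", r$name, seq_len(r$n_sites))
    data.frame(site_id = ids, region = r$name,
               devil_activity = round(stats::runif(r$n_sites,
                                                   r$devil_activity_range[1],
                                                   r$devil_activity_range[2]), 2),
               quoll_activity = round(stats::runif(r$n_sites,
                                                   r$quoll_activity_range[1],
                                                   r$quoll_activity_range[2]), 2))
  }))
  b_site <- stats::setNames(stats::rnorm(nrow(sites), 0, config$sigma_site),
                            sites$site_id)

  deployments <- do.call(rbind, lapply(config$regions, function(r) {
    rs <- sites[sites$region == r$name, , drop = FALSE]
    counts <- if (!is.null(r$n_carcasses)) {
      base <- r$n_carcasses %/% r$n_sites
      extra <- r$n_carcasses %% r$n_sites
      base + as.integer(seq_len(r$n_sites) <= extra)
    } else {
      rng <- seq(config$carcasses_per_site[1], config$carcasses_per_site[2])
      ## sample() treats a length-one vector as 1:n, so guard the scalar case
      if (length(rng) == 1L) rep(rng, r$n_sites)
      else sample(rng, r$n_sites, replace = TRUE)
    }
    mix <- r$species_mix %||% c(pademelon = 1)
    do.call(rbind, lapply(seq_len(r$n_sites), function(j) {
      n <- counts[j]
      sp <- sample(names(mix), n, replace = TRUE, prob = mix)
      w <- vapply(sp, function(s) {
        rng <- weight_range(s)
        round(stats::runif(1, rng[1], rng[2]), 1)
      }, numeric(1))
      data.frame(carcass_id = sprintf("%s_c%d", rs$site_id[j], seq_len(n)),
                 site_id = rs$site_id[j], region = r$name,
                 habitat = sample(c("wet", "dry"), n, replace = TRUE),
                 carcass_species = sp, weight_kg = w,
                 secured = isTRUE(r$secured %||% TRUE),
                 removed = FALSE)
    }))
  }))
  n_carc <- nrow(deployments)
  deployments$deploy_time <- rep(deploy0, n_carc)
  deployments$end_time <- deploy0 + config$follow_up_days * 86400

  covars <- deployments
  covars$devil_activity <- sites$devil_activity[match(covars$site_id, sites$site_id)]
  covars$quoll_activity <- sites$quoll_activity[match(covars$site_id, sites$site_id)]
  covars$habitat_wet <- as.numeric(covars$habitat == "wet")
  b <- b_site[covars$site_id]

  ## latent full-consumption time (days)
  rate_c <- config$persistence$baseline *
    exp(lin_pred(as.list(config$persistence$beta), covars) + b)
  t_consume <- draw_latent_time(n_carc, rate_c, config$weibull_shape)
  consumed <- t_consume <= config$follow_up_days
  deployments$consumed_time <- deploy0 + ifelse(consumed, t_consume * 86400, NA)
  deployments$consumed_time <- as.POSIXct(deployments$consumed_time,
                                          origin = "1970-01-01", tz = "UTC")

  ## per-guild use, discovery and foraging bouts
  window_min <- pmin(t_consume, config$follow_up_days) * 1440
  bouts <- list()
  truth_guild <- list()
  for (gname in names(config$guilds)) {
    g <- config$guilds[[gname]]
    gate <- if (!is.null(g$requires)) covars[[g$requires]] > 0 else rep(TRUE, n_carc)
    rate_d <- g$discovery$baseline * exp(lin_pred(as.list(g$discovery$beta), covars) + b)
    p_use <- stats::plogis(lin_pred(as.list(g$use), covars) + b)
    used <- gate & rate_d > 0 & stats::runif(n_carc) < p_use
    mu_dur <- exp(lin_pred(as.list(g$duration), covars) + b)
    shape <- g$duration[["shape"]]
    t_disc_min <- rep(NA_real_, n_carc)
    dur_min <- rep(0, n_carc)
    for (i in which(used)) {
      t_disc <- draw_truncated_exp(rate_d[i], window_min[i] / 1440) * 1440
      start0 <- max(1, round(t_disc))
      avail <- window_min[i] - start0
      if (avail < 1) { used[i] <- FALSE; next }
      total <- stats::rgamma(1, shape = shape, rate = shape / mu_dur[i])
      total <- min(max(total, 1), 0.8 * avail)
      k <- 1L + min(stats::rpois(1, total / 60), 4L)
      parts <- stats::rgamma(k, 1, 1)
      parts <- total * parts / sum(parts)
      parts <- pmax(parts, 0.5)
      gaps <- 6 + stats::rexp(k, 1 / 30)
      ## compress if the bout train overruns the observation window
      overhang <- start0 + sum(parts) + sum(gaps[-1]) - window_min[i]
      if (overhang > 0) {
        gaps <- pmax(6, gaps - overhang / max(k - 1, 1))
        room <- window_min[i] - start0 - sum(gaps[-1])
        if (room < sum(parts)) parts <- parts * max(room, 1) / sum(parts)
      }
      st <- start0 + cumsum(c(0, utils::head(parts, -1) + gaps[-1]))
      en <- st + parts
      keep <- en <= window_min[i] & parts > 0
      if (!any(keep)) { used[i] <- FALSE; next }
      st <- round(st[keep]); en <- pmax(st + 1, round(en[keep]))
      ## rounding guard: keep inter-bout gaps strictly above the 4-min rule
      if (length(st) > 1L) {
        ok <- c(TRUE, st[-1] - en[-length(en)] > 5)
        st <- st[ok]; en <- en[ok]
      }
      t_disc_min[i] <- st[1]
      dur_min[i] <- sum(en - st)
      bouts[[length(bouts) + 1L]] <- data.frame(
        carcass_id = deployments$carcass_id[i],
        site_id = deployments$site_id[i],
        species = gname, start_min = st, end_min = en)
    }
    truth_guild[[gname]] <- data.frame(
      carcass_id = deployments$carcass_id,
      used = used, discovery_min = t_disc_min, duration_min = dur_min)
  }
  bouts <- if (length(bouts)) do.call(rbind, bouts) else
    data.frame(carcass_id = character(0), site_id = character(0),
               species = character(0), start_min = numeric(0),
               end_min = numeric(0))

  truth <- list(site_intercepts = b_site,
                consumption_days = t_consume,
                consumption_rate = rate_c,
                guilds = truth_guild, bouts = bouts,
                config = config)
  detections <- render_photo_stream(truth, config)
  covariates <- unique(sites[, c("site_id", "devil_activity", "quoll_activity")])
  rownames(deployments) <- rownames(covariates) <- NULL
  list(detections = detections,
       deployments = deployments[, c("carcass_id", "site_id", "region",
                                     "habitat", "carcass_species", "weight_kg",
                                     "deploy_time", "end_time", "consumed_time",
                                     "secured", "removed")],
       covariates = covariates,
       truth = truth)
}

#' Render the camera photo stream from feeding bouts
#'
#' Emits one photo at each bout's start and then every `trigger_wait_min`
#' minutes until the bout ends; timestamps are at minute resolution. Bouts of
#' the same species at the same carcass that overlap (possible only in
#' hand-built truth tables) are merged first, with a message. Inter-bout gaps
#' exceed the 4-minute rule by construction, so event reconstruction is
#' exactly invertible.
#'
#' @param truth a `generate_study()` truth list (needs `bouts` and the
#'   deployment start implied by `config$deploy_date`).
#' @param config the [sim_config()] used.
#' @return detection table (`site_id, carcass_id, timestamp, species,
#'   feeding`).
#' @export
render_photo_stream <- function(truth, config) {
  bouts <- truth$bouts
  deploy0 <- as.POSIXct(paste(config$deploy_date, "00:00:00"), tz = "UTC")
  if (!nrow(bouts)) {
    return(data.frame(site_id = character(0), carcass_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      species = character(0), feeding = logical(0)))
  }
  ## merge overlapping bouts per carcass/species
  key <- paste(bouts$carcass_id, bouts$species, sep = "\r")
  merged <- lapply(split(bouts, key), function(bb) {
    bb <- bb[order(bb$start_min), , drop = FALSE]
    if (nrow(bb) > 1L && any(bb$start_min[-1] <= bb$end_min[-nrow(bb)])) {
      message("render_photo_stream: merging overlapping bouts for ",
              bb$carcass_id[1], "/", bb$species[1])
      keep <- integer(0)
      cur <- 1L
      for (j in seq_len(nrow(bb))[-1]) {
        if (bb$start_min[j] <= bb$end_min[cur]) {
          bb$end_min[cur] <- max(bb$end_min[cur], bb$end_min[j])
        } else {
          keep <- c(keep, cur); cur <- j
        }
      }
      bb <- bb[c(keep, cur), , drop = FALSE]
    }
    bb
  })
  bouts <- do.call(rbind, merged)
  wait <- config$trigger_wait_min
  photo_rows <- lapply(seq_len(nrow(bouts)), function(j) {
    offs <- seq(bouts$start_min[j], bouts$end_min[j], by = wait)
    data.frame(site_id = bouts$site_id[j], carcass_id = bouts$carcass_id[j],
               timestamp = deploy0 + offs * 60, species = bouts$species[j],
               feeding = TRUE)
  })
  det <- do.call(rbind, photo_rows)
  det <- det[order(det$carcass_id, det$timestamp), , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Write a simulated study to CSV files
#'
#' Emits `detections.csv`, `deployments.csv`, `covariates.csv` in the schemas
#' consumed by [read_detections()], [read_deployments()],
#' [read_site_covariates()].
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study_csv <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  det <- study$detections
  det$timestamp <- fmt(det$timestamp)
  dep <- study$deployments
  for (col in c("deploy_time", "end_time", "consumed_time")) {
    dep[[col]] <- ifelse(is.na(dep[[col]]), "", fmt(dep[[col]]))
  }
  utils::write.csv(det, file.path(dir, "detections.csv"), row.names = FALSE)
  utils::write.csv(dep, file.path(dir, "deployments.csv"), row.names = FALSE)
  utils::write.csv(study$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  invisible(dir)
}
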