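#' Read a camera-trap detection table
#'
#' Reads a CSV of time-stamped photo records (`site_id, carcass_id, timestamp,
#' species, feeding`), parses ISO-8601 timestamps, drops rows that fall
#' outside their carcass's deployment window (with a warning giving the
#' count), and returns rows sorted by carcass then timestamp.
#'
#' @param path CSV file path, or a data frame already in the detection schema.
#' @param deployments deployment table (see [read_deployments()]).
#' @return detection data frame sorted by `(carcass_id, timestamp)` with
#'   parsed `timestamp` and logical `feeding`.
#' @export
read_detections <- function(path, deployments) {
  det <- if (is.data.frame(path)) path
         else {
           if (!file.exists(path)) {
             stop_scav("detections file not found: %s", path,
                       class = "scavsurv_io_error")
           }
           utils::read.csv(path, stringsAsFactors = FALSE)
         }
  assert_columns(det, c("site_id", "carcass_id", "timestamp", "species", "feeding"),
                 "detections")
  if (any(is.na(det$species) | det$species == "")) {
    stop_scav("empty species code in detections", class = "scavsurv_schema_error")
  }
  if (!inherits(det$timestamp, "POSIXct")) {
    det$timestamp <- parse_timestamp(det$timestamp)
  }
  det$feeding <- as.logical(det$feeding)
  dep <- as.data.frame(deployments)
  idx <- match(det$carcass_id, dep$carcass_id)
  if (anyNA(idx)) {
    stop_scav("detections reference carcass(es) absent from deployments: %s",
              paste(unique(det$carcass_id[is.na(idx)]), collapse = ", "),
              class = "scavsurv_consistency_error")
  }
  inside <- det$timestamp >= dep$deploy_time[idx] &
    det$timestamp <= dep$end_time[idx]
  if (any(!inside)) {
    warning(sprintf("dropped %d detection(s) outside the deployment window",
                    sum(!inside)), call. = FALSE)
    det <- det[inside, , drop = FALSE]
  }
  det <- det[order(det$carcass_id, det$timestamp), , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Read a carcass deployment table
#'
#' Columns: `carcass_id, site_id, region, habitat, carcass_species, weight_kg,
#' deploy_time, end_time, consumed_time, secured` and optionally `removed`.
#' @param path CSV file path or data frame.
#' @return deployment data frame with parsed times and validated invariants.
#' @export
read_deployments <- function(path) {
  dep <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(dep, c("carcass_id", "site_id", "region", "habitat",
                        "carcass_species", "weight_kg", "deploy_time",
                        "end_time"), "deployments")
  for (col in c("deploy_time", "end_time", "consumed_time")) {
    if (!is.null(dep[[col]]) && !inherits(dep[[col]], "POSIXct")) {
      dep[[col]] <- parse_timestamp(dep[[col]], col)
    }
  }
  if (is.null(dep$consumed_time)) dep$consumed_time <- as.POSIXct(NA)
  if (is.null(dep$removed)) dep$removed <- FALSE
  dep$removed <- !is.na(dep$removed) & as.logical(dep$removed)
  if (any(dep$weight_kg <= 0)) {
    stop_scav("initial carcass weight must be positive", class = "scavsurv_schema_error")
  }
  if (any(dep$deploy_time >= dep$end_time)) {
    stop_scav("deploy_time must precede end_time", class = "scavsurv_schema_error")
  }
  bad <- !is.na(dep$consumed_time) &
    (dep$consumed_time <= dep$deploy_time | dep$consumed_time > dep$end_time)
  if (any(bad)) {
    stop_scav("consumed_time outside (deploy_time, end_time] for carcass(es): %s",
              paste(dep$carcass_id[bad], collapse = ", "),
              class = "scavsurv_consistency_error")
  }
  dep
}

#' Read a site covariate table (`site_id, devil_activity, quoll_activity`,
#' detections per 100 camera-nights)
#' @param path CSV file path or data frame.
#' @export
read_site_covariates <- function(path) {
  cov <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(cov, c("site_id", "devil_activity", "quoll_activity"),
                 "site covariates")
  if (any(!is.finite(cov$devil_activity)) || any(!is.finite(cov$quoll_activity)) ||
      any(cov$devil_activity < 0) || any(cov$quoll_activity < 0)) {
    stop_scav("activity indices must be finite and non-negative",
              class = "scavsurv_schema_error")
  }
  cov
}

#' Reconstruct foraging events from feeding photos with the gap rule
#'
#' Consecutive feeding photos of one species at one carcass belong to the same
#' foraging event unless separated by a gap of inactivity strictly greater
#' than `gap_min` minutes (a gap of exactly `gap_min` keeps one event). A
#' single-photo event has zero span; its duration is floored at
#' `singleton_floor_min` so it still contributes feeding time.
#'
#' @param detections detection table ([read_detections()]); only rows with
#'   `feeding = TRUE` are used.
#' @param gap_min gap threshold in minutes (default 4).
#' @param singleton_floor_min minimum event duration in minutes (default 1).
#' @return data frame of events: `carcass_id, site_id, species, start, end,
#'   n_photos, duration_min` where `duration_min = max(end - start,
#'   singleton_floor_min)`.
#' @export
build_foraging_events <- function(detections, gap_min = 4,
                                  singleton_floor_min = 1) {
  if (!is.numeric(gap_min) || length(gap_min) != 1L || gap_min < 0) {
    stop_scav("gap_min must be a single non-negative number",
              class = "scavsurv_parameter_error")
  }
  det <- detections[detections$feeding %in% TRUE, , drop = FALSE]
  if (!nrow(det)) {
    return(data.frame(carcass_id = character(0), site_id = character(0),
                      species = character(0),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      n_photos = integer(0), duration_min = numeric(0)))
  }
  det <- det[order(det$carcass_id, det$species, det$timestamp), , drop = FALSE]
  key <- paste(det$carcass_id, det$species, sep = "\r")
  new_group <- c(TRUE, key[-1] != key[-nrow(det)])
  gap <- c(Inf, diff_min(det$timestamp[-1], det$timestamp[-nrow(det)]))
  new_event <- new_group | gap > gap_min
  event_id <- cumsum(new_event)
  starts <- tapply(det$timestamp, event_id, min)
  ends <- tapply(det$timestamp, event_id, max)
  first <- which(new_event)
  out <- data.frame(
    carcass_id = det$carcass_id[first],
    site_id = det$site_id[first],
    species = det$species[first],
    start = as.POSIXct(as.numeric(starts), origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(as.numeric(ends), origin = "1970-01-01", tz = "UTC"),
    n_photos = as.integer(tabulate(event_id)),
    row.names = NULL)
  out$duration_min <- pmax(diff_min(out$end, out$start), singleton_floor_min)
  out
}

#' Time-to-discovery survival records
#'
#' Discovery is the first time an animal (optionally restricted to
#' `species_filter`) found and fed on the carcass. Time is measured in days
#' from deployment; carcasses never discovered are right-censored at their own
#' end of observation (camera retrieval or failure).
#'
#' @param events foraging events ([build_foraging_events()]).
#' @param deployments deployment table.
#' @param covariates site covariate table.
#' @param species_filter optional character vector of species codes; `NULL`
#'   means any vertebrate scavenger.
#' @return survival records: `carcass_id, site_id, region, time, status,
#'   devil_activity, quoll_activity, habitat_wet, weight_kg`.
#' @export
discovery_records <- function(events, deployments, covariates,
                              species_filter = NULL) {
  dep <- as.data.frame(deployments)
  ev <- as.data.frame(events)
  unknown <- setdiff(unique(ev$carcass_id), dep$carcass_id)
  if (length(unknown)) {
    stop_scav("events reference carcass(es) absent from deployments: %s",
              paste(unknown, collapse = ", "),
              class = "scavsurv_consistency_error")
  }
  if (!is.null(species_filter)) {
    ev <- ev[ev$species %in% species_filter, , drop = FALSE]
  }
  first <- if (nrow(ev)) {
    stats::aggregate(start ~ carcass_id, data = ev, FUN = min)
  } else data.frame(carcass_id = character(0), start = as.POSIXct(character(0)))
  idx <- match(dep$carcass_id, first$carcass_id)
  disc_time <- diff_days(first$start[idx], dep$deploy_time)
  follow_up <- diff_days(dep$end_time, dep$deploy_time)
  status <- as.integer(!is.na(disc_time))
  time <- ifelse(status == 1, disc_time, follow_up)
  build_survival_records(dep, covariates, time, status)
}

#' Carcass persistence (time to full consumption) survival records
#'
#' Time is days from deployment to the clear final consumption event
#' (`consumed_time`); carcasses not fully consumed are right-censored at their
#' own end of observation.
#'
#' @inheritParams discovery_records
#' @export
persistence_records <- function(deployments, covariates) {
  dep <- as.data.frame(deployments)
  bad <- !is.na(dep$consumed_time) & dep$consumed_time > dep$end_time
  if (any(bad)) {
    stop_scav("consumed_time after end_time for carcass(es): %s",
              paste(dep$carcass_id[bad], collapse = ", "),
              class = "scavsurv_consistency_error")
  }
  status <- as.integer(!is.na(dep$consumed_time))
  time <- ifelse(status == 1,
                 diff_days(dep$consumed_time, dep$deploy_time),
                 diff_days(dep$end_time, dep$deploy_time))
  build_survival_records(dep, covariates, time, status)
}

build_survival_records <- function(dep, covariates, time, status) {
  cov <- as.data.frame(covariates)
  cidx <- match(dep$site_id, cov$site_id)
  if (anyNA(cidx)) {
    stop_scav("deployment site(s) absent from covariates: %s",
              paste(unique(dep$site_id[is.na(cidx)]), collapse = ", "),
              class = "scavsurv_consistency_error")
  }
  data.frame(carcass_id = dep$carcass_id, site_id = dep$site_id,
             region = dep$region, time = as.numeric(time),
             status = as.integer(status),
             devil_activity = cov$devil_activity[cidx],
             quoll_activity = cov$quoll_activity[cidx],
             habitat_wet = as.numeric(dep$habitat == "wet"),
             weight_kg = dep$weight_kg,
             row.names = NULL)
}

#' Regional foraging summary per species
#'
#' For each region and species: the number of carcasses with at least one
#' foraging event, that count as a percentage of the region's carcasses,
#' total hours spent foraging, and the species' share of all-species foraging
#' time in the region.
#'
#' @param events foraging events.
#' @param deployments deployment table.
#' @param denominator_policy `"deployed"` (all carcasses deployed in the
#'   region; default) or `"analysed"` (excluding carcasses flagged `removed`).
#'   The analysed count is recorded either way.
#' @return data frame: `region, species, n_foraged, pct_foraged,
#'   hours_foraging, prop_total_time, n_deployed, n_analysed`.
#' @export
region_summary <- function(events, deployments,
                           denominator_policy = c("deployed", "analysed")) {
  denominator_policy <- match.arg(denominator_policy)
  dep <- as.data.frame(deployments)
  ev <- as.data.frame(events)
  ev$region <- dep$region[match(ev$carcass_id, dep$carcass_id)]
  regions <- unique(dep$region)
  rows <- list()
  for (r in regions) {
    dr <- dep[dep$region == r, , drop = FALSE]
    er <- ev[!is.na(ev$region) & ev$region == r, , drop = FALSE]
    n_dep <- nrow(dr)
    n_ana <- sum(!dr$removed)
    denom <- if (denominator_policy == "deployed") n_dep else n_ana
    total_min <- sum(er$duration_min)
    species <- sort(unique(er$species))
    if (!length(species)) {
      rows[[r]] <- data.frame(region = r, species = NA_character_,
                              n_foraged = 0L, pct_foraged = 0,
                              hours_foraging = 0, prop_total_time = NA_real_,
                              n_deployed = n_dep, n_analysed = n_ana)
      next
    }
    rows[[r]] <- do.call(rbind, lapply(species, function(sp) {
      es <- er[er$species == sp, , drop = FALSE]
      n_f <- length(unique(es$carcass_id))
      mins <- sum(es$duration_min)
      data.frame(region = r, species = sp, n_foraged = n_f,
                 pct_foraged = if (denom > 0) 100 * n_f / denom else 0,
                 hours_foraging = mins / 60,
                 prop_total_time = if (total_min > 0) mins / total_min else NA_real_,
                 n_deployed = n_dep, n_analysed = n_ana)
    }))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-carcass use records for the carcass-use and foraging-duration models
#'
#' One row per analysable carcass: whether the target species fed there, its
#' total foraging minutes (0 when unused), site covariates, habitat, weight,
#' and the total devil and quoll foraging minutes at that carcass (predictors
#' for the use models). Carcasses flagged `removed` (premature removal or
#' camera failure) are excluded, with a message giving the counts.
#'
#' @param events foraging events.
#' @param deployments deployment table.
#' @param covariates site covariate table.
#' @param species target species code (e.g. `"raven"`, `"cat"`).
#' @return data frame: `carcass_id, site_id, region, used, duration_min,
#'   devil_activity, quoll_activity, habitat_wet, weight_kg,
#'   devil_forage_min, quoll_forage_min`.
#' @export
use_records <- function(events, deployments, covariates, species) {
  dep <- as.data.frame(deployments)
  n_removed <- sum(dep$removed)
  if (n_removed > 0) {
    message(sprintf("use_records: excluding %d removed/failed carcass(es); %d analysed",
                    n_removed, nrow(dep) - n_removed))
  }
  dep <- dep[!dep$removed, , drop = FALSE]
  ev <- as.data.frame(events)
  ev <- ev[ev$carcass_id %in% dep$carcass_id, , drop = FALSE]
  sum_minutes <- function(sp) {
    es <- ev[ev$species == sp, , drop = FALSE]
    agg <- tapply(es$duration_min, es$carcass_id, sum)
    out <- agg[as.character(dep$carcass_id)]
    out[is.na(out)] <- 0
    unname(out)
  }
  dur <- sum_minutes(species)
  cov <- as.data.frame(covariates)
  cidx <- match(dep$site_id, cov$site_id)
  data.frame(carcass_id = dep$carcass_id, site_id = dep$site_id,
             region = dep$region,
             used = dur > 0, duration_min = dur,
             devil_activity = cov$devil_activity[cidx],
             quoll_activity = cov$quoll_activity[cidx],
             habitat_wet = as.numeric(dep$habitat == "wet"),
             weight_kg = dep$weight_kg,
             devil_forage_min = sum_minutes("devil"),
             quoll_forage_min = sum_minutes("quoll"),
             row.names = NULL)
}
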