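#' Run the full scavenging analysis
#'
#' Orchestrates ingest, event reconstruction, the four survival analyses
#' (persistence and discovery by all species / ravens / cats) with LOOCV model
#' selection and Kaplan-Meier curves per region, the carcass-use and
#' foraging-duration GLMMs for ravens and cats, regional Table-style
#' summaries, and bootstrap confidence intervals. Sections whose inputs are
#' missing or degenerate are skipped with explicit reasons rather than
#' failing the run.
#'
#' @param input one of: a [sim_config()] (the study is simulated), a directory
#'   containing `detections.csv`, `deployments.csv`, `covariates.csv`, or a
#'   list with elements `detections`, `deployments`, `covariates`.
#' @param out_dir optional directory; when given, tables are written as CSV /
#'   JSON together with a run manifest.
#' @param seed seed for the bootstrap resamples (and the simulation when
#'   `input` is a config without its own seed).
#' @param gap_min,singleton_floor_min event-reconstruction settings.
#' @param denominator_policy passed to [region_summary()].
#' @param n_resamples bootstrap resamples (default 1e5).
#' @param raven_occupancy_terms,raven_intensity_terms,cat_occupancy_terms
#'   GLMM term sets.
#' @param candidate_families optional list of term families for the survival
#'   candidate grid (see [candidate_cox_specs()]).
#' @return a report bundle (list) with elements `events`, `table1`,
#'   `survival` (per outcome: selection table, selected fit, hazard ratios,
#'   KM curves, comparison with the full model), `use` (per species), `bootstrap`,
#'   `skipped` (named reasons), `manifest`.
#' @export
run_analysis <- function(input, out_dir = NULL, seed = 1L,
                         gap_min = 4, singleton_floor_min = 1,
                         denominator_policy = "deployed",
                         n_resamples = 1e5,
                         raven_occupancy_terms = c("devil_activity", "habitat_wet", "weight_kg"),
                         raven_intensity_terms = c("devil_forage_min", "weight_kg"),
                         cat_occupancy_terms = c("devil_activity", "weight_kg"),
                         candidate_families = NULL) {
  skipped <- character(0)
  input_digests <- list()

  if (inherits(input, "sim_config")) {
    study <- generate_study(input)
    detections <- study$detections
    deployments <- study$deployments
    covariates <- study$covariates
    input_digests$simulation_seed <- input$seed
  } else if (is.character(input) && length(input) == 1L) {
    paths <- file.path(input, c("detections.csv", "deployments.csv", "covariates.csv"))
    deployments <- read_deployments(paths[2])
    covariates <- read_site_covariates(paths[3])
    detections <- if (file.exists(paths[1])) read_detections(paths[1], deployments)
                  else NULL
    input_digests <- as.list(tools::md5sum(paths[file.exists(paths)]))
  } else {
    deployments <- read_deployments(input$deployments)
    covariates <- read_site_covariates(input$covariates)
    detections <- if (!is.null(input$detections))
      read_detections(input$detections, deployments) else NULL
  }

  have_detections <- !is.null(detections) && nrow(detections) > 0
  events <- if (have_detections) {
    build_foraging_events(detections, gap_min, singleton_floor_min)
  } else {
    if (!have_detections) skipped["detections"] <- "no detections supplied; survival sections are all-censored and use sections skipped"
    build_foraging_events(data.frame(site_id = character(0),
                                     carcass_id = character(0),
                                     timestamp = as.POSIXct(character(0), tz = "UTC"),
                                     species = character(0),
                                     feeding = logical(0)))
  }

  table1 <- region_summary(events, deployments, denominator_policy)

  ## survival analyses
  outcomes <- list(
    persistence = list(records = persistence_records(deployments, covariates)),
    discovery_all = list(records = discovery_records(events, deployments, covariates)),
    discovery_raven = list(records = discovery_records(events, deployments,
                                                       covariates, "raven")),
    discovery_cat = list(records = discovery_records(events, deployments,
                                                     covariates, "cat")))
  survival_out <- list()
  for (oc in names(outcomes)) {
    rec <- outcomes[[oc]]$records
    if (!any(rec$status == 1)) {
      skipped[oc] <- sprintf("%s: no events observed; Kaplan-Meier only", oc)
      survival_out[[oc]] <- list(records = rec, km = km_estimate(rec, "region"))
      next
    }
    specs <- candidate_cox_specs(oc, families = candidate_families)
    scores <- lapply(specs, score_model, records = rec)
    sel <- select_model(scores)
    sel_fit <- scores[[match(sel$selected_id,
                             vapply(scores, `[[`, character(1), "model_id"))]]$fit
    full_fit <- scores[[length(scores)]]$fit
    survival_out[[oc]] <- list(
      records = rec,
      selection = sel,
      selected_fit = sel_fit,
      hazard_ratios = if (isTRUE(sel_fit$converged)) hazard_ratios(sel_fit) else NULL,
      full_comparison = if (isTRUE(sel_fit$converged) && isTRUE(full_fit$converged))
        compare_full_model(sel_fit, full_fit) else NULL,
      km = km_estimate(rec, "region"))
  }
  med_ratio <- if (!is.null(survival_out$persistence$km))
    median_persistence_ratio(survival_out$persistence$km) else NULL

  ## carcass use and foraging duration
  use_out <- list()
  boot_out <- NULL
  if (have_detections) {
    for (sp in c("raven", "cat")) {
      ur <- use_records(events, deployments, covariates, sp)
      if (all(ur$used) || !any(ur$used)) {
        skipped[paste0("use_", sp)] <- sprintf(
          "%s use is constant across carcasses; use model skipped", sp)
        use_out[[sp]] <- list(records = ur)
        next
      }
      occ_terms <- if (sp == "raven") raven_occupancy_terms else cat_occupancy_terms
      hur <- fit_hurdle(ur, occupancy_terms = occ_terms,
                        intensity_terms = raven_intensity_terms)
      if (sp == "cat" && "intensity" %in% names(hur$skip_reasons)) {
        skipped["cat_duration"] <- hur$skip_reasons[["intensity"]]
      }
      es <- NULL
      auc_val <- NULL
      if (!is.null(hur$occupancy) && isTRUE(hur$occupancy$converged)) {
        auc_val <- c(conditional = auc(hur$occupancy, "conditional"),
                     population = auc(hur$occupancy, "population"))
        es <- lapply(hur$occupancy$terms, function(v)
          effect_size(hur$occupancy, v))
        names(es) <- hur$occupancy$terms
      }
      use_out[[sp]] <- list(records = ur, hurdle = hur, auc = auc_val,
                            effect_sizes = es)
    }
    ## bootstrap summaries of site means
    boot_rows <- list()
    for (sp in names(use_out)) {
      ur <- use_out[[sp]]$records
      if (is.null(ur) || !nrow(ur)) next
      sm_use <- site_means(ur, "prop_used")
      boot_rows[[paste0(sp, "_prop_used")]] <-
        regional_bootstrap(sm_use, paste0(sp, " prop. carcasses used"),
                           n_resamples = n_resamples, seed = seed)
      sm_time <- suppressWarnings(site_means(ur, "prop_time", events = events))
      if (nrow(sm_time)) {
        boot_rows[[paste0(sp, "_prop_time")]] <-
          regional_bootstrap(sm_time, paste0(sp, " share of foraging time"),
                             n_resamples = n_resamples, seed = seed)
      }
    }
    boot_out <- do.call(rbind, boot_rows)
    if (!is.null(boot_out)) rownames(boot_out) <- NULL
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("scavsurv")),
    seed = seed,
    settings = list(gap_min = gap_min,
                    singleton_floor_min = singleton_floor_min,
                    tie_method = "efron",
                    denominator_policy = denominator_policy,
                    covariate_scaling = "raw",
                    cv_evaluation = "conditional fixed-effects partial likelihood at trained (beta, BLUPs)",
                    se_rule = "paired per-observation contribution differences",
                    bootstrap = list(n_resamples = n_resamples,
                                     method = "percentile",
                                     resample_unit = "site")),
    inputs = input_digests,
    counts = list(n_carcasses = nrow(deployments),
                  n_detections = if (have_detections) nrow(detections) else 0L,
                  n_events = nrow(events),
                  n_removed = sum(deployments$removed)),
    skipped = as.list(skipped))

  bundle <- list(events = events, table1 = table1, survival = survival_out,
                 median_persistence_ratio = med_ratio,
                 use = use_out, bootstrap = boot_out,
                 skipped = skipped, manifest = manifest)
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$table1, file.path(out_dir, "region_summary.csv"),
                   row.names = FALSE)
  for (oc in names(bundle$survival)) {
    so <- bundle$survival[[oc]]
    if (!is.null(so$selection)) {
      utils::write.csv(so$selection$table,
                       file.path(out_dir, paste0("selection_", oc, ".csv")),
                       row.names = FALSE)
    }
    if (!is.null(so$hazard_ratios)) {
      utils::write.csv(so$hazard_ratios,
                       file.path(out_dir, paste0("hazard_ratios_", oc, ".csv")),
                       row.names = FALSE)
    }
    if (!is.null(so$km)) {
      write_km_csv(so$km, file.path(out_dir, paste0("km_", oc, ".csv")))
    }
  }
  if (!is.null(bundle$bootstrap)) {
    utils::write.csv(bundle$bootstrap, file.path(out_dir, "bootstrap_summaries.csv"),
                     row.names = FALSE)
  }
  fits <- list()
  for (oc in names(bundle$survival)) {
    f <- bundle$survival[[oc]]$selected_fit
    if (is.null(f)) next
    fits[[oc]] <- list(model_id = f$spec$model_id, beta = as.list(f$beta),
                       se = as.list(f$se), sigma2_site = f$sigma2_site,
                       lp_conditional = f$lp_conditional,
                       lp_marginal = f$lp_marginal, converged = f$converged)
  }
  jsonlite::write_json(fits, file.path(out_dir, "survival_fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Simulation-based recovery study
#'
#' Repeatedly generates a study from `config`, fits the persistence Cox model
#' (the generating terms, with the site random intercept) and the raven and
#' cat carcass-use GLMMs, and summarises bias, RMSE and Wald 95% CI coverage
#' per coefficient against the generating truth. Non-convergent replicates are
#' counted and reported, not silently dropped.
#'
#' @param config a [sim_config()]; its hazard/use coefficients are the truth.
#' @param n_replicates number of simulated studies (0 gives an empty table).
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param cox_terms fixed terms of the persistence model fitted per replicate.
#' @param use_models named list (species -> term vector) of binomial use
#'   models fitted per replicate.
#' @return list: `estimates` (per replicate x coefficient), `summary` (per
#'   coefficient: truth, mean estimate, bias, rmse, coverage),
#'   `n_nonconverged`.
#' @export
run_recovery_study <- function(config, n_replicates, seed = 1L,
                               cox_terms = c("devil_activity", "quoll_activity",
                                             "habitat_wet", "weight_kg"),
                               use_models = list(
                                 raven = c("devil_activity", "habitat_wet"),
                                 cat = c("devil_activity"))) {
  if (n_replicates <= 0) {
    return(list(estimates = data.frame(), summary = data.frame(),
                n_nonconverged = 0L))
  }
  set.seed(seed)
  rep_seeds <- sample.int(2^31 - 2, n_replicates)
  truth <- c(stats::setNames(config$persistence$beta[cox_terms],
                             paste0("persistence.", cox_terms)),
             unlist(lapply(names(use_models), function(sp) {
               tm <- use_models[[sp]]
               stats::setNames(config$guilds[[sp]]$use[tm],
                               paste0("use_", sp, ".", tm))
             })))
  rows <- list()
  n_bad <- 0L
  for (k in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- rep_seeds[k]
    study <- generate_study(cfg)
    ev <- build_foraging_events(study$detections)
    est <- se <- stats::setNames(rep(NA_real_, length(truth)), names(truth))
    ok <- TRUE
    pr <- persistence_records(study$deployments, study$covariates)
    fit <- tryCatch(fit_cox(cox_spec("persistence", cox_terms), pr),
                    error = function(e) NULL)
    if (!is.null(fit) && isTRUE(fit$converged)) {
      est[paste0("persistence.", cox_terms)] <- fit$beta[cox_terms]
      se[paste0("persistence.", cox_terms)] <- fit$se[cox_terms]
    } else ok <- FALSE
    for (sp in names(use_models)) {
      tm <- use_models[[sp]]
      ur <- use_records(ev, study$deployments, study$covariates, sp)
      gf <- tryCatch(
        suppressWarnings(fit_glmm(ur, "used", tm, "binomial_logit")),
        error = function(e) NULL)
      if (!is.null(gf) && isTRUE(gf$converged)) {
        est[paste0("use_", sp, ".", tm)] <- gf$beta[tm]
        se[paste0("use_", sp, ".", tm)] <- gf$se[tm]
      } else ok <- FALSE
    }
    if (!ok) n_bad <- n_bad + 1L
    rows[[k]] <- data.frame(replicate = k, coefficient = names(truth),
                            truth = unname(truth), estimate = unname(est),
                            se = unname(se), row.names = NULL)
  }
  estimates <- do.call(rbind, rows)
  z <- stats::qnorm(0.975)
  summ <- do.call(rbind, lapply(split(estimates, estimates$coefficient), function(d) {
    cover <- abs(d$estimate - d$truth) <= z * d$se
    data.frame(coefficient = d$coefficient[1], truth = d$truth[1],
               mean_estimate = mean(d$estimate, na.rm = TRUE),
               bias = mean(d$estimate - d$truth, na.rm = TRUE),
               rmse = sqrt(mean((d$estimate - d$truth)^2, na.rm = TRUE)),
               coverage = mean(cover, na.rm = TRUE),
               n_fit = sum(!is.na(d$estimate)), row.names = NULL)
  }))
  rownames(summ) <- NULL
  list(estimates = estimates, summary = summ, n_nonconverged = n_bad)
}

#' Refit the selected survival models to the deposited field data
#'
#' Expects a directory with the deposited tables exported to this package's
#' CSV schemas (`detections.csv`, `deployments.csv`, `covariates.csv`) and
#' refits the cross-validation-selected models: persistence on devil and
#' quoll activity, all-species discovery on quoll activity and habitat, raven
#' discovery on devil activity and habitat, cat discovery on devil activity
#' (all with carcass weight and the site random intercept). Returns the hazard
#' ratio tables and the pairwise median-persistence ratios per region.
#'
#' @param dir directory with the exported data.
#' @return list: `hazard_ratios` (per outcome), `median_ratio`.
#' @export
dryad_reproduction <- function(dir) {
  if (!dir.exists(dir)) {
    stop_scav(paste0("deposited-data directory not found: %s (the field data ",
                     "must be downloaded and exported separately; see README)"),
              dir, class = "scavsurv_io_error")
  }
  deployments <- read_deployments(file.path(dir, "deployments.csv"))
  covariates <- read_site_covariates(file.path(dir, "covariates.csv"))
  detections <- read_detections(file.path(dir, "detections.csv"), deployments)
  events <- build_foraging_events(detections)
  models <- list(
    persistence = list(rec = persistence_records(deployments, covariates),
                       terms = c("devil_activity", "quoll_activity", "weight_kg")),
    discovery_all = list(rec = discovery_records(events, deployments, covariates),
                         terms = c("quoll_activity", "habitat_wet", "weight_kg")),
    discovery_raven = list(rec = discovery_records(events, deployments, covariates, "raven"),
                           terms = c("devil_activity", "habitat_wet", "weight_kg")),
    discovery_cat = list(rec = discovery_records(events, deployments, covariates, "cat"),
                         terms = c("devil_activity", "weight_kg")))
  hrs <- lapply(names(models), function(oc) {
    m <- models[[oc]]
    hazard_ratios(fit_cox(cox_spec(oc, m$terms), m$rec))
  })
  names(hrs) <- names(models)
  km <- km_estimate(models$persistence$rec, "region")
  list(hazard_ratios = hrs, median_ratio = median_persistence_ratio(km))
}
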