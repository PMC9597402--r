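#' Site-level mean statistics grouped by region
#'
#' For each site: the proportion of its analysable carcasses that the target
#' species fed at (`prop_used`), or the species' share of all-species foraging
#' time at the site (`prop_time`). Sites with no analysable carcasses are
#' excluded with a warning.
#'
#' @param records use records for the target species ([use_records()]). For
#'   `prop_time`, a `total_forage_min` column (all-species foraging minutes
#'   per carcass) must be present or supplied via `events`.
#' @param statistic `"prop_used"` or `"prop_time"`.
#' @param events optional foraging events table used to derive all-species
#'   foraging minutes for `prop_time`.
#' @return data frame: `region, site_id, value, n_carcasses`.
#' @export
site_means <- function(records, statistic = c("prop_used", "prop_time"),
                       events = NULL) {
  statistic <- match.arg(statistic)
  records <- as.data.frame(records)
  if (statistic == "prop_time" && is.null(records$total_forage_min)) {
    if (is.null(events)) {
      stop_scav("prop_time needs a total_forage_min column or an events table",
                class = "scavsurv_data_error")
    }
    ev <- as.data.frame(events)
    tot <- tapply(ev$duration_min, ev$carcass_id, sum)
    v <- tot[as.character(records$carcass_id)]
    v[is.na(v)] <- 0
    records$total_forage_min <- unname(v)
  }
  sites <- split(records, records$site_id, drop = TRUE)
  rows <- lapply(sites, function(d) {
    if (!nrow(d)) return(NULL)
    value <- if (statistic == "prop_used") {
      mean(d$used)
    } else {
      tot <- sum(d$total_forage_min)
      if (tot <= 0) NA_real_ else sum(d$duration_min) / tot
    }
    data.frame(region = d$region[1], site_id = d$site_id[1],
               value = value, n_carcasses = nrow(d))
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  drop_na <- is.na(out$value)
  if (any(drop_na)) {
    warning(sprintf("excluding %d site(s) with no analysable foraging time",
                    sum(drop_na)), call. = FALSE)
    out <- out[!drop_na, , drop = FALSE]
  }
  rownames(out) <- NULL
  out[order(out$region, out$site_id), ]
}

#' Non-parametric bootstrap percentile confidence interval for a regional mean
#'
#' Resamples the supplied values (site-level means by default) with
#' replacement within the region, takes the mean of each resample, and reports
#' the percentile interval. Fully reproducible given `seed`. A single value
#' yields a degenerate interval equal to the value, flagged.
#'
#' @param values numeric vector (one region's site-level values).
#' @param n_resamples number of bootstrap resamples (default 1e5).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; required for reproducibility.
#' @param statistic_label,resample_unit metadata carried into the result.
#' @return list of class `scav_bootci`: `statistic`, `point` (observed mean),
#'   `ci_low`, `ci_high`, `n_values`, `n_resamples`, `resample_unit`, `seed`,
#'   `degenerate`.
#' @export
bootstrap_ci <- function(values, n_resamples = 1e5, level = 0.95, seed = 1L,
                         statistic_label = "mean", resample_unit = "site") {
  values <- as.numeric(values)
  if (!length(values)) {
    stop_scav("no values to bootstrap", class = "scavsurv_data_error")
  }
  if (n_resamples < 1) {
    stop_scav("n_resamples must be >= 1", class = "scavsurv_parameter_error")
  }
  point <- mean(values)
  degenerate <- length(values) == 1L || stats::var(values) == 0
  if (degenerate) {
    ci <- c(point, point)
  } else {
    means <- local({
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
      n <- length(values)
      idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE),
                    nrow = n_resamples)
      rowMeans(matrix(values[idx], nrow = n_resamples))
    })
    alpha <- (1 - level) / 2
    ci <- unname(stats::quantile(means, c(alpha, 1 - alpha), type = 7))
  }
  structure(list(statistic = statistic_label, point = point,
                 ci_low = ci[1], ci_high = ci[2],
                 n_values = length(values), n_resamples = as.integer(n_resamples),
                 resample_unit = resample_unit, seed = as.integer(seed),
                 degenerate = degenerate),
            class = "scav_bootci")
}

#' @export
print.scav_bootci <- function(x, ...) {
  cat(sprintf("%s: %.4f  [%.4f, %.4f]  (%d %s values, %d resamples%s)\n",
              x$statistic, x$point, x$ci_low, x$ci_high, x$n_values,
              x$resample_unit, x$n_resamples,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Regional bootstrap summary of site-level means
#'
#' Applies [bootstrap_ci()] within each region of a [site_means()] table.
#'
#' @param site_values a [site_means()] result.
#' @inheritParams bootstrap_ci
#' @return data frame: `region, statistic, point, ci_low, ci_high, n_sites,
#'   n_resamples, seed`.
#' @export
regional_bootstrap <- function(site_values, statistic_label,
                               n_resamples = 1e5, level = 0.95, seed = 1L,
                               resample_unit = "site") {
  regions <- split(site_values, site_values$region, drop = TRUE)
  out <- lapply(names(regions), function(r) {
    ci <- bootstrap_ci(regions[[r]]$value, n_resamples = n_resamples,
                       level = level, seed = seed,
                       statistic_label = statistic_label,
                       resample_unit = resample_unit)
    data.frame(region = r, statistic = statistic_label, point = ci$point,
               ci_low = ci$ci_low, ci_high = ci$ci_high,
               n_sites = ci$n_values, n_resamples = ci$n_resamples,
               seed = ci$seed)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
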