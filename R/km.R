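#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimates with Greenwood variance and log-transformed 95%
#' confidence intervals, computed via [survival::survfit()]. The median is the
#' smallest time at which the estimated survival drops to 0.5 or below; if the
#' curve never reaches 0.5 the median is undefined and flagged, with the last
#' observed follow-up time reported as a lower bound.
#'
#' @param records survival records (`time`, `status`, optionally a grouping
#'   column).
#' @param group optional name of a grouping column (e.g. `"region"`); `NULL`
#'   pools all records into one curve.
#' @return a list of class `scav_km`, one element per group, each containing a
#'   data frame `curve` (`time`, `n_risk`, `n_event`, `surv`, `ci_low`,
#'   `ci_high`) plus `median`, `median_defined`, `median_lower_bound`, `n`,
#'   `n_events`.
#' @export
km_estimate <- function(records, group = NULL) {
  records <- as.data.frame(records)
  groups <- if (is.null(group)) list(all = records)
            else split(records, records[[group]], drop = TRUE)
  out <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    if (!nrow(d)) {
      return(list(group = g, curve = data.frame(time = numeric(0),
                                                n_risk = integer(0),
                                                n_event = integer(0),
                                                surv = numeric(0),
                                                ci_low = numeric(0),
                                                ci_high = numeric(0)),
                  median = NA_real_, median_defined = FALSE,
                  median_lower_bound = NA_real_, n = 0L, n_events = 0L))
    }
    sf <- survival::survfit(survival::Surv(time, status) ~ 1, data = d,
                            conf.type = "log", conf.int = 0.95)
    curve <- data.frame(time = sf$time, n_risk = sf$n.risk,
                        n_event = sf$n.event, surv = sf$surv,
                        ci_low = pmin(pmax(sf$lower, 0), 1),
                        ci_high = pmin(pmax(sf$upper, 0), 1))
    curve$ci_low[is.na(curve$ci_low)] <- 0
    curve$ci_high[is.na(curve$ci_high)] <- 1
    reach <- which(curve$surv <= 0.5 & curve$n_event > 0)
    if (length(reach)) {
      med <- curve$time[min(reach)]
      defined <- TRUE
    } else {
      med <- NA_real_
      defined <- FALSE
    }
    list(group = g, curve = curve, median = med, median_defined = defined,
         median_lower_bound = max(d$time), n = nrow(d),
         n_events = sum(d$status == 1))
  })
  names(out) <- names(groups)
  structure(out, class = "scav_km")
}

#' Pairwise ratios of median survival between groups
#'
#' When a group's median is undefined (the curve never reaches 0.5), its last
#' observed follow-up time is used as a lower bound and the ratio is flagged
#' as a bound ("at least"). When both medians are undefined the ratio is
#' undefined.
#'
#' @param curves a [km_estimate()] result.
#' @return data frame with `numerator`, `denominator`, `ratio`, `is_bound`
#'   (TRUE when the numerator median is a lower bound), `defined`.
#' @export
median_persistence_ratio <- function(curves) {
  stopifnot(inherits(curves, "scav_km"))
  gs <- names(curves)
  rows <- list()
  for (a in gs) for (b in gs) {
    if (a == b) next
    ca <- curves[[a]]; cb <- curves[[b]]
    num <- if (ca$median_defined) ca$median else ca$median_lower_bound
    den <- if (cb$median_defined) cb$median else cb$median_lower_bound
    defined <- !(is.na(num) || is.na(den)) && !(!ca$median_defined && !cb$median_defined)
    rows[[paste(a, b)]] <- data.frame(
      numerator = a, denominator = b,
      ratio = if (defined) num / den else NA_real_,
      is_bound = !ca$median_defined,
      defined = defined)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write Kaplan-Meier curves to CSV
#'
#' One row per (group, time): `group, time, surv, ci_low, ci_high, n_risk`.
#' @param curves a [km_estimate()] result.
#' @param path output file.
#' @export
write_km_csv <- function(curves, path) {
  stopifnot(inherits(curves, "scav_km"))
  tabs <- lapply(curves, function(cv) {
    if (!nrow(cv$curve)) return(NULL)
    cbind(group = cv$group, cv$curve[, c("time", "surv", "ci_low", "ci_high", "n_risk")])
  })
  out <- do.call(rbind, Filter(Negate(is.null), tabs))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
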