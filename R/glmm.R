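#' Fit a generalized linear mixed model for carcass use or foraging duration
#'
#' Binomial (logit link) models for whether a species fed at a carcass, and
#' Gamma (log link) models for total foraging duration at carcasses where it
#' fed, with an optional Gaussian site random intercept estimated by Laplace
#' approximation (via \pkg{glmmTMB}). With `site_re = FALSE` the fit reduces
#' exactly to the corresponding GLM ([stats::glm()]); the Gamma shape is then
#' re-estimated by maximum likelihood given the IRLS coefficients.
#'
#' @param records use records ([use_records()]) or any data frame containing
#'   `response`, the `terms` and `site_id`.
#' @param response name of the response column (`"used"` for binomial,
#'   `"duration_min"` for Gamma).
#' @param terms character vector of fixed-effect covariate columns.
#' @param family `"binomial_logit"` or `"gamma_log"`.
#' @param site_re include the site random intercept.
#' @return object of class `scav_glmmfit`: `beta` (named, incl. intercept),
#'   `se`, `sigma2_site`, `shape` (Gamma shape by ML, `NA` for binomial),
#'   `loglik`, `blups` (named site intercepts), `fitted_conditional`,
#'   `fitted_population`, `converged`, `diagnostic`, `term_means`, `model_id`.
#' @export
fit_glmm <- function(records, response, terms,
                     family = c("binomial_logit", "gamma_log"),
                     site_re = TRUE, model_id = NULL) {
  family <- match.arg(family)
  records <- as.data.frame(records)
  assert_columns(records, c(response, terms, "site_id"), "use records")
  y <- records[[response]]
  if (is.logical(y)) y <- as.numeric(y)
  if (family == "binomial_logit") {
    if (!any(y == 1) || !any(y == 0)) {
      stop_scav("binomial fit needs at least one success and one failure",
                class = "scavsurv_data_error")
    }
  } else {
    if (any(y <= 0)) {
      stop_scav(paste0("Gamma family requires strictly positive responses; ",
                       "model zeros with the hurdle composition (fit_hurdle)"),
                class = "scavsurv_data_error")
    }
  }
  d <- records
  d$.y <- y
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fam_obj <- if (family == "binomial_logit") stats::binomial("logit")
             else stats::Gamma(link = "log")

  if (site_re && length(unique(d$site_id)) >= 2L) {
    fml <- stats::as.formula(paste(".y ~", rhs, "+ (1 | site_id)"))
    fit <- glmmTMB::glmmTMB(fml, data = d, family = fam_obj)
    sm <- summary(fit)$coefficients$cond
    beta <- stats::setNames(sm[, "Estimate"], rownames(sm))
    se <- stats::setNames(sm[, "Std. Error"], rownames(sm))
    vc <- glmmTMB::VarCorr(fit)$cond$site_id
    sigma2 <- if (is.null(vc)) 0 else as.numeric(vc[1, 1])
    ## glmmTMB's sigma() for Gamma is the coefficient of variation 1/sqrt(shape)
    shape <- if (family == "gamma_log") 1 / glmmTMB::sigma(fit)^2 else NA_real_
    re <- glmmTMB::ranef(fit)$cond$site_id
    blups <- stats::setNames(re[["(Intercept)"]], rownames(re))
    fitted_cond <- stats::predict(fit, type = "response")
    fitted_pop <- stats::predict(fit, type = "response", re.form = NA)
    ll <- as.numeric(stats::logLik(fit))
    conv <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
  } else {
    fml <- stats::as.formula(paste(".y ~", rhs))
    fit <- stats::glm(fml, data = d, family = fam_obj)
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    sigma2 <- 0
    blups <- stats::setNames(numeric(0), character(0))
    fitted_cond <- fitted_pop <- stats::fitted(fit)
    if (family == "gamma_log") {
      shape <- gamma_shape_ml(y, fitted_cond)
      ll <- sum(stats::dgamma(y, shape = shape, rate = shape / fitted_cond,
                              log = TRUE))
      ## SEs from the IRLS fit use the ML dispersion for consistency
      se <- se * sqrt(summary(fit)$dispersion * shape)
    } else {
      shape <- NA_real_
      ll <- as.numeric(stats::logLik(fit))
    }
    conv <- fit$converged
  }

  diagnostic <- NULL
  if (family == "binomial_logit" && any(abs(beta) > 15)) {
    conv <- FALSE
    diagnostic <- "complete separation suspected (|coefficient| > 15)"
  }
  term_means <- if (length(terms)) {
    vapply(terms, function(tm) mean(as.numeric(d[[tm]])), numeric(1))
  } else stats::setNames(numeric(0), character(0))
  term_binary <- if (length(terms)) {
    vapply(terms, function(tm) all(as.numeric(d[[tm]]) %in% c(0, 1)), logical(1))
  } else stats::setNames(logical(0), character(0))
  structure(list(
    family = family, response = response, terms = terms,
    beta = beta, se = se, sigma2_site = max(sigma2, 0), shape = shape,
    loglik = ll, blups = blups,
    fitted_conditional = as.numeric(fitted_cond),
    fitted_population = as.numeric(fitted_pop),
    y = y, site_id = as.character(d$site_id),
    term_means = term_means, term_binary = term_binary,
    converged = conv, diagnostic = diagnostic,
    n = nrow(d),
    model_id = model_id %||% paste0(response, "[", family, "]:",
                                    if (length(terms)) paste(sort(terms), collapse = "+")
                                    else "null",
                                    if (site_re) "+re(site)" else "")
  ), class = "scav_glmmfit")
}

## 1-D ML estimate of the Gamma shape given fitted means
gamma_shape_ml <- function(y, mu) {
  nll <- function(log_shape) {
    s <- exp(log_shape)
    -sum(stats::dgamma(y, shape = s, rate = s / mu, log = TRUE))
  }
  exp(stats::optimize(nll, c(log(1e-3), log(1e4)))$minimum)
}

#' @export
print.scav_glmmfit <- function(x, ...) {
  cat(sprintf("GLMM [%s]: n = %d, sigma2_site = %.4g%s\n", x$model_id, x$n,
              x$sigma2_site,
              if (!is.na(x$shape)) sprintf(", Gamma shape = %.3g", x$shape) else ""))
  print(data.frame(beta = x$beta, se = x$se))
  cat(sprintf("  logLik = %.4f, converged: %s\n", x$loglik, x$converged))
  invisible(x)
}

#' Hurdle model for zero-inflated foraging data
#'
#' Two independently fitted parts: a binomial occupancy model for whether the
#' species fed at a carcass, and a Gamma (log link) intensity model for total
#' foraging duration at the carcasses where it fed. The intensity part is
#' refused, with an explicit reason, when fewer than `min_positive` carcasses
#' were used (insufficient data, as for feral-cat durations).
#'
#' @param records use records for the target species.
#' @param occupancy_terms,intensity_terms fixed-effect terms for each part.
#' @param site_re include site random intercepts.
#' @param min_positive minimum used-carcass count for the intensity fit.
#' @return object of class `scav_hurdle`: `occupancy`, `intensity` (either may
#'   be `NULL`), `skip_reasons` (named character), and `loglik` (sum of the
#'   fitted parts).
#' @export
fit_hurdle <- function(records, occupancy_terms, intensity_terms = occupancy_terms,
                       site_re = TRUE, min_positive = 5L) {
  records <- as.data.frame(records)
  reasons <- character(0)
  occupancy <- NULL
  if (all(records$used) || !any(records$used)) {
    reasons["occupancy"] <- sprintf(
      "occupancy part degenerate: carcass use is constant (%s)",
      if (all(records$used)) "all used" else "none used")
  } else {
    occupancy <- fit_glmm(records, "used", occupancy_terms,
                          family = "binomial_logit", site_re = site_re)
  }
  pos <- records[records$used, , drop = FALSE]
  intensity <- NULL
  if (nrow(pos) < min_positive) {
    reasons["intensity"] <- sprintf(
      "intensity part refused: only %d used carcass(es) (< %d), insufficient data",
      nrow(pos), min_positive)
  } else {
    intensity <- fit_glmm(pos, "duration_min", intensity_terms,
                          family = "gamma_log", site_re = site_re)
  }
  ll <- sum(c(if (!is.null(occupancy)) occupancy$loglik,
              if (!is.null(intensity)) intensity$loglik))
  structure(list(occupancy = occupancy, intensity = intensity,
                 skip_reasons = reasons, loglik = ll,
                 n = nrow(records), n_positive = nrow(pos)),
            class = "scav_hurdle")
}

#' Area under the ROC curve for a binomial fit
#'
#' Rank-based AUC (ties counted one half), identical to the Mann-Whitney U
#' statistic divided by `n1 * n0`. Uses the fit's conditional (BLUP-inclusive)
#' predictions by default.
#'
#' @param fit a binomial [fit_glmm()] result.
#' @param level `"conditional"` (default) or `"population"`.
#' @return scalar in `[0, 1]`.
#' @export
auc <- function(fit, level = c("conditional", "population")) {
  stopifnot(inherits(fit, "scav_glmmfit"))
  if (fit$family != "binomial_logit") {
    stop_scav("AUC is defined for binomial fits only", class = "scavsurv_spec_error")
  }
  level <- match.arg(level)
  pred <- if (level == "conditional") fit$fitted_conditional else fit$fitted_population
  auc_rank(pred, fit$y)
}

auc_rank <- function(pred, y) {
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop_scav("AUC undefined: only one outcome class present",
              class = "scavsurv_data_error")
  }
  r <- rank(pred, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multiplicative effect size from predicted responses
#'
#' The effect size of a variable is the ratio of the population-level
#' predicted response (site intercept 0, other covariates at their training
#' means) with the effect applied to the prediction with the effect absent.
#' For a binary indicator the contrast is level 1 versus level 0; for a
#' continuous variable it is one raw unit above the covariate mean versus the
#' mean.
#'
#' @param fit a [fit_glmm()] result.
#' @param variable model term to contrast.
#' @param contrast optional numeric `c(absent, applied)` pair overriding the
#'   default contrast.
#' @return list of class `scav_effectsize`: `variable`, `p0`, `p1`,
#'   `es = p1 / p0`, `contrast` (human-readable definition).
#' @export
effect_size <- function(fit, variable, contrast = NULL) {
  stopifnot(inherits(fit, "scav_glmmfit"))
  if (!variable %in% fit$terms) {
    stop_scav("variable '%s' is not a term of the model", variable,
              class = "scavsurv_spec_error")
  }
  means <- fit$term_means
  if (is.null(contrast)) {
    vals <- unname(means[variable])
    ## a 0/1 indicator is contrasted absent (0) vs applied (1); a continuous
    ## covariate at its mean vs one raw unit above
    if (isTRUE(fit$term_binary[[variable]])) {
      contrast <- c(0, 1)
      desc <- sprintf("%s applied (1) vs absent (0), other covariates at means, site intercept 0",
                      variable)
    } else {
      contrast <- c(vals, vals + 1)
      desc <- sprintf("%s at mean + 1 raw unit vs mean, other covariates at means, site intercept 0",
                      variable)
    }
  } else {
    desc <- sprintf("%s at %g vs %g, other covariates at means, site intercept 0",
                    variable, contrast[2], contrast[1])
  }
  eta_at <- function(v) {
    x <- means
    x[variable] <- v
    unname(fit$beta["(Intercept)"] + sum(fit$beta[names(x)] * x))
  }
  linkinv <- if (fit$family == "binomial_logit") stats::plogis else exp
  p0 <- linkinv(eta_at(contrast[1]))
  p1 <- linkinv(eta_at(contrast[2]))
  structure(list(variable = variable, p0 = p0, p1 = p1, es = p1 / p0,
                 contrast = desc),
            class = "scav_effectsize")
}

#' @export
print.scav_effectsize <- function(x, ...) {
  cat(sprintf("ES(%s) = %.3f  [p0 = %.4f, p1 = %.4f]\n  contrast: %s\n",
              x$variable, x$es, x$p0, x$p1, x$contrast))
  invisible(x)
}

## conditional log likelihood of a fitted GLMM evaluated on arbitrary records,
## at the trained coefficients, BLUPs (0 for unseen sites) and dispersion
glmm_loglik_at <- function(fit, records) {
  y <- records[[fit$response]]
  if (is.logical(y)) y <- as.numeric(y)
  eta <- rep(unname(fit$beta["(Intercept)"]), nrow(records))
  for (tm in fit$terms) eta <- eta + fit$beta[[tm]] * as.numeric(records[[tm]])
  if (length(fit$blups)) {
    b <- fit$blups[as.character(records$site_id)]
    b[is.na(b)] <- 0
    eta <- eta + unname(b)
  }
  if (fit$family == "binomial_logit") {
    sum(stats::dbinom(y, 1, stats::plogis(eta), log = TRUE))
  } else {
    mu <- exp(eta)
    sum(stats::dgamma(y, shape = fit$shape, rate = fit$shape / mu, log = TRUE))
  }
}

#' LOOCV score for a GLMM candidate, reusing the survival-model machinery
#'
#' Same construction as [score_model()], with the conditional full-data log
#' likelihood in place of the partial likelihood: each contribution is
#' `loglik(all data; trained) - loglik(training data; trained)`.
#'
#' @inheritParams fit_glmm
#' @return a `scav_cvscore`, usable with [select_model()].
#' @export
score_glmm <- function(records, response, terms,
                       family = c("binomial_logit", "gamma_log"),
                       site_re = TRUE, model_id = NULL) {
  family <- match.arg(family)
  records <- as.data.frame(records)
  n <- nrow(records)
  full <- fit_glmm(records, response, terms, family, site_re, model_id)
  ll_all_full <- glmm_loglik_at(full, records)
  contrib <- rep(NA_real_, n)
  within_contrib <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    train <- records[-i, , drop = FALSE]
    ft <- tryCatch(
      suppressWarnings(fit_glmm(train, response, terms, family, site_re)),
      error = function(e) NULL)
    if (is.null(ft) || !isTRUE(ft$converged)) next
    contrib[i] <- glmm_loglik_at(ft, records) - glmm_loglik_at(ft, train)
    within_contrib[i] <- ll_all_full - glmm_loglik_at(full, train)
  }
  n_missing <- sum(is.na(contrib))
  valid <- n_missing <= 0.1 * n
  use <- !is.na(contrib)
  cv_loglik <- if (valid) sum(contrib[use]) else NA_real_
  within <- if (valid) sum(within_contrib[use]) else NA_real_
  structure(list(model_id = full$model_id,
                 spec = list(fixed_terms = terms, family = family,
                             random_intercept = site_re),
                 fold_contributions = contrib,
                 within_contributions = within_contrib,
                 cv_loglik = cv_loglik, within_loglik = within,
                 lp_full = ll_all_full,
                 p_eff = within - cv_loglik,
                 n = n, n_missing = n_missing, valid = valid, fit = full),
            class = "scav_cvscore")
}
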