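#' Specify a Cox proportional-hazards model for carcass survival data
#'
#' Describes one candidate model: which survival outcome it targets, which
#' fixed-effect covariates enter the log hazard, whether a Gaussian site
#' random intercept (shared frailty on the log scale) is included, and how
#' tied event times are handled.
#'
#' @param outcome one of `"persistence"`, `"discovery_all"`,
#'   `"discovery_raven"`, `"discovery_cat"` (a label carried through to
#'   reports; the records passed to [fit_cox()] define the actual data).
#' @param fixed_terms character vector of covariate columns, a subset of
#'   `devil_activity`, `quoll_activity`, `habitat` (alias for the
#'   `habitat_wet` indicator) and `weight_kg`. Empty for the null model.
#' @param random_intercept logical; include a Gaussian site random intercept.
#' @param tie_method `"efron"` (default) or `"breslow"`.
#' @param model_id optional identifier; defaults to a label built from the
#'   terms.
#' @return an object of class `cox_spec`.
#' @export
cox_spec <- function(outcome = c("persistence", "discovery_all",
                                 "discovery_raven", "discovery_cat"),
                     fixed_terms = character(),
                     random_intercept = TRUE,
                     tie_method = c("efron", "breslow"),
                     model_id = NULL) {
  outcome <- match.arg(outcome)
  tie_method <- match.arg(tie_method)
  fixed_terms <- resolve_cox_terms(fixed_terms)
  if (is.null(model_id)) {
    model_id <- paste0(outcome, ":",
                       if (length(fixed_terms)) paste(sort(fixed_terms), collapse = "+")
                       else "null",
                       if (random_intercept) "+re(site)" else "")
  }
  structure(list(outcome = outcome, fixed_terms = fixed_terms,
                 random_intercept = isTRUE(random_intercept),
                 tie_method = tie_method, model_id = model_id),
            class = "cox_spec")
}

resolve_cox_terms <- function(terms) {
  terms <- as.character(terms)
  terms[terms == "habitat"] <- "habitat_wet"
  allowed <- c("devil_activity", "quoll_activity", "habitat_wet", "weight_kg")
  bad <- setdiff(terms, allowed)
  if (length(bad)) {
    stop_scav("unknown model term(s): %s", paste(bad, collapse = ", "),
              class = "scavsurv_spec_error")
  }
  unique(terms)
}

## design pieces for a spec on a set of survival records
cox_design <- function(spec, records) {
  assert_columns(records, c("time", "status", "site_id", spec$fixed_terms),
                 "survival records")
  X <- if (length(spec$fixed_terms)) {
    as.matrix(records[, spec$fixed_terms, drop = FALSE])
  } else {
    matrix(numeric(0), nrow(records), 0L)
  }
  storage.mode(X) <- "double"
  sites <- sort(unique(as.character(records$site_id)))
  Z <- NULL
  if (spec$random_intercept && length(sites) >= 2L) {
    Z <- matrix(0, nrow(records), length(sites),
                dimnames = list(NULL, sites))
    Z[cbind(seq_len(nrow(records)), match(as.character(records$site_id), sites))] <- 1
  }
  list(X = X, Z = Z, sites = sites)
}

#' Fit a Cox proportional-hazards model with a Gaussian site random intercept
#'
#' Maximizes the log partial likelihood penalized by \eqn{b'b / (2\sigma^2)}
#' jointly over the fixed coefficients and the site intercepts (inner Newton
#' iterations with step halving), and profiles the random-intercept variance
#' \eqn{\sigma^2} by a 1-D search of the Laplace-approximated integrated log
#' partial likelihood on the log scale over \eqn{[10^{-8}, 10]}. With
#' `random_intercept = FALSE` (or a single site) the fit reduces exactly to an
#' ordinary Cox model. Covariates enter on their raw scales.
#'
#' @param spec a [cox_spec()].
#' @param records survival records: a data frame with columns `time` (days,
#'   > 0), `status` (1 = event, 0 = censored), `site_id`, and the covariate
#'   columns named in the spec.
#' @param reltol relative convergence tolerance on the penalized objective.
#' @param theta0 optional warm-start coefficient vector (fixed then site
#'   effects), used by the cross-validation machinery.
#' @return an object of class `scav_coxfit` with elements `beta`, `se`,
#'   `vcov_beta`, `sigma2_site`, `blups`, `lp_penalized`, `lp_marginal`,
#'   `lp_conditional` (the unpenalized fixed-effects partial likelihood
#'   evaluated at the estimates), `converged`, `n`, `n_events`.
#' @export
fit_cox <- function(spec, records, reltol = 1e-9, theta0 = NULL) {
  stopifnot(inherits(spec, "cox_spec"))
  records <- as.data.frame(records)
  if (!any(records$status == 1)) {
    stop_scav("no events in the survival records; nothing to fit",
              class = "scavsurv_data_error")
  }
  if (any(records$time <= 0)) {
    stop_scav("survival times must be positive", class = "scavsurv_data_error")
  }

  ## drop constant covariates, warn on strong collinearity
  terms <- spec$fixed_terms
  keep <- vapply(terms, function(tm) stats::var(records[[tm]]) > 0, logical(1))
  if (any(!keep)) {
    warning(sprintf("dropping constant covariate(s): %s",
                    paste(terms[!keep], collapse = ", ")),
            call. = FALSE)
    spec$fixed_terms <- terms[keep]
  }
  if (length(spec$fixed_terms) >= 2L) {
    cc <- stats::cor(records[, spec$fixed_terms, drop = FALSE])
    mx <- max(abs(cc[upper.tri(cc)]))
    if (mx >= 0.7) {
      warning(sprintf("fixed terms have |Pearson r| = %.2f >= 0.7", mx),
              call. = FALSE)
    }
  }

  des <- cox_design(spec, records)
  p <- ncol(des$X)
  time <- records$time
  status <- records$status
  ties <- spec$tie_method

  if (is.null(des$Z)) {
    Xall <- des$X
    pen <- rep(0, p)
    inner <- cox_penalized_newton(Xall, time, status, pen, ties,
                                  theta0 = theta0, reltol = reltol)
    q <- 0L
    sigma2 <- 0
    b_idx <- integer(0)
  } else {
    q <- ncol(des$Z)
    Xall <- cbind(des$X, des$Z)
    b_idx <- p + seq_len(q)
    warm <- theta0 %||% numeric(p + q)
    ws <- cox_pl_workspace(Xall, time, status)
    marginal_at <- function(log_s2) {
      s2 <- exp(log_s2)
      pen <- c(rep(0, p), rep(1 / s2, q))
      inner <- cox_penalized_newton(Xall, time, status, pen, ties,
                                    theta0 = warm, reltol = reltol, ws = ws)
      warm <<- inner$theta
      list(lml = cox_laplace_marginal(inner, q, s2, b_idx), inner = inner)
    }
    opt <- stats::optimize(function(ls2) marginal_at(ls2)$lml,
                           interval = log(c(1e-8, 10)), maximum = TRUE,
                           tol = 1e-4)
    ## guard the sigma2 -> 0 boundary, where the marginal equals the plain
    ## Cox partial likelihood
    at_floor <- marginal_at(log(1e-8))
    if (at_floor$lml >= opt$objective) {
      sigma2 <- 1e-8
      inner <- at_floor$inner
      lml <- at_floor$lml
    } else {
      res <- marginal_at(opt$maximum)
      sigma2 <- exp(opt$maximum)
      inner <- res$inner
      lml <- res$lml
    }
  }

  theta <- inner$theta
  Hpen <- inner$hess_pen
  V <- tryCatch(solve(Hpen), error = function(e) matrix(NA_real_, p + q, p + q))
  se_all <- sqrt(pmax(diag(V), 0))
  beta <- theta[seq_len(p)]
  names(beta) <- colnames(des$X)
  se <- se_all[seq_len(p)]
  names(se) <- colnames(des$X)
  blups <- if (q > 0L) stats::setNames(theta[b_idx], colnames(des$Z))
           else stats::setNames(numeric(0), character(0))

  monotone <- p > 0L && any(abs(beta) > 20)
  converged <- inner$converged && !monotone
  diagnostic <- if (monotone) {
    "monotone partial likelihood suspected (|beta| > 20): risk ordering may be completely separated"
  } else if (!inner$converged) "Newton iterations did not converge" else NULL

  eta <- drop(Xall %*% theta)
  lp_cond <- cox_pl_value(eta, time, status, ties)
  structure(list(
    spec = spec,
    beta = beta, se = se,
    vcov_beta = V[seq_len(p), seq_len(p), drop = FALSE],
    sigma2_site = if (q > 0L) max(sigma2, 0) else 0,
    blups = blups,
    lp_penalized = inner$objective,
    lp_marginal = if (q > 0L) lml else lp_cond,
    lp_conditional = lp_cond,
    converged = converged, diagnostic = diagnostic,
    n = nrow(records), n_events = sum(status == 1),
    sites = des$sites
  ), class = "scav_coxfit")
}

#' @export
print.scav_coxfit <- function(x, ...) {
  cat(sprintf("Cox fit [%s]: n = %d, events = %d, sigma2_site = %.4g\n",
              x$spec$model_id, x$n, x$n_events, x$sigma2_site))
  if (length(x$beta)) {
    print(data.frame(beta = x$beta, se = x$se, hr = exp(x$beta)))
  } else cat("  (null model: no fixed terms)\n")
  cat(sprintf("  log PL (conditional) = %.4f, integrated = %.4f, converged: %s\n",
              x$lp_conditional, x$lp_marginal, x$converged))
  invisible(x)
}

#' Hazard ratios with Wald 95% confidence intervals
#'
#' @param fit a converged [fit_cox()] result.
#' @return data frame with one row per fixed term: `term`, `beta`, `se`,
#'   `hr = exp(beta)`, `ci_low`, `ci_high` (Wald, `exp(beta +/- 1.96 se)`).
#' @export
hazard_ratios <- function(fit) {
  stopifnot(inherits(fit, "scav_coxfit"))
  if (!isTRUE(fit$converged)) {
    stop_scav("refusing hazard ratios from a non-converged fit: %s",
              fit$diagnostic %||% "unknown cause",
              class = "scavsurv_convergence_error")
  }
  z <- stats::qnorm(0.975)
  data.frame(term = names(fit$beta),
             beta = unname(fit$beta), se = unname(fit$se),
             hr = exp(unname(fit$beta)),
             ci_low = exp(unname(fit$beta) - z * unname(fit$se)),
             ci_high = exp(unname(fit$beta) + z * unname(fit$se)),
             row.names = NULL)
}

## Fixed-effects log partial likelihood of `records` evaluated at externally
## supplied estimates: eta = X beta + b[site], with 0 for sites absent from
## `site_effects`. This is the evaluation likelihood used by the LOOCV score.
cox_pl_at <- function(spec, records, beta, site_effects, ties = spec$tie_method) {
  des <- cox_design(cox_spec(spec$outcome, spec$fixed_terms,
                             random_intercept = FALSE,
                             tie_method = spec$tie_method),
                    records)
  eta <- if (ncol(des$X)) drop(des$X %*% beta[colnames(des$X)]) else numeric(nrow(records))
  if (length(site_effects)) {
    b <- site_effects[as.character(records$site_id)]
    b[is.na(b)] <- 0
    eta <- eta + unname(b)
  }
  cox_pl_value(eta, records$time, records$status, ties)
}
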