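## Leave-one-out cross-validated log partial likelihood, effective degrees of
## freedom, and the modified one-standard-error selection rule.
##
## Ordinary LOOCV cannot score a Cox model because a single held-out record
## carries no risk set of its own. Instead each observation's contribution is
##   l_cv_i = lp(all data; trained estimates) - lp(training data; trained estimates)
## where the training data are all records minus observation i and lp is the
## fixed-effects log partial likelihood evaluated at the trained coefficients
## and trained site intercepts (0 for a site absent from training). The sum of
## contributions estimates the Kullback-Leibler discrepancy of the model (up
## to sign and a constant), and
##   p_eff = within-sample log likelihood - cross-validated log likelihood
## counts the effective parameters contributed by fixed and random effects.
##
## The within-sample log likelihood is decomposed the same way as the CV
## score, with the full-data estimates in place of the trained ones:
##   w_i = lp(all data; full-fit estimates) - lp(training data; full-fit estimates).
## The partial likelihood is not additive over observations, so this
## decomposition (rather than the raw full-data lp) is what makes w_i and
## l_cv_i comparable; a model with no estimated parameters then has p_eff = 0
## exactly, and a p-parameter fixed-effects model has p_eff ~ p.

#' Leave-one-out cross-validation contribution of one observation
#'
#' @param spec a [cox_spec()].
#' @param records survival records.
#' @param held_out_index row index of the held-out observation.
#' @param theta0 optional warm start for the training fit.
#' @return the scalar contribution, or `NA` if the training fit fails to
#'   converge.
#' @export
cv_contribution <- function(spec, records, held_out_index, theta0 = NULL) {
  records <- as.data.frame(records)
  n <- nrow(records)
  stopifnot(held_out_index >= 1L, held_out_index <= n)
  if (n < 3L) {
    stop_scav("need at least 3 records for the cross-validation contribution",
              class = "scavsurv_data_error")
  }
  train <- records[-held_out_index, , drop = FALSE]
  if (!any(train$status == 1)) return(NA_real_)
  fit <- tryCatch(fit_cox(spec, train, theta0 = theta0),
                  error = function(e) NULL)
  if (is.null(fit) || !isTRUE(fit$converged)) return(NA_real_)
  cox_pl_at(spec, records, fit$beta, fit$blups) -
    cox_pl_at(spec, train, fit$beta, fit$blups)
}

#' Cross-validated score of a candidate Cox model
#'
#' Fits the model to all records, then computes each observation's LOOCV
#' contribution (refitting without that observation, warm-started at the
#' full-data estimates). Fitting is deterministic, so the score is exactly
#' reproducible with no seed.
#'
#' @param spec a [cox_spec()].
#' @param records survival records.
#' @return an object of class `scav_cvscore`: `model_id`, `spec`,
#'   `fold_contributions` (one per observation, `NA` where a training fit
#'   failed), `cv_loglik` (their sum), `within_loglik` (the matching
#'   within-sample decomposition at the full-data estimates),
#'   `p_eff = within_loglik - cv_loglik`, `lp_full` (raw full-data log partial
#'   likelihood), `valid` (FALSE when more than 10% of contributions are
#'   missing), and the full-data `fit`.
#' @export
score_model <- function(spec, records) {
  records <- as.data.frame(records)
  n <- nrow(records)
  full <- fit_cox(spec, records)
  lp_all_full <- cox_pl_at(spec, records, full$beta, full$blups)
  contrib <- rep(NA_real_, n)
  within_contrib <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    train <- records[-i, , drop = FALSE]
    theta0 <- NULL
    if (isTRUE(full$converged)) {
      tr_sites <- if (spec$random_intercept)
        sort(unique(as.character(train$site_id))) else character(0)
      if (length(tr_sites) >= 2L || !spec$random_intercept) {
        b0 <- full$blups[tr_sites]
        b0[is.na(b0)] <- 0
        theta0 <- c(unname(full$beta), unname(b0))
      }
    }
    contrib[i] <- tryCatch(cv_contribution(spec, records, i, theta0 = theta0),
                           error = function(e) NA_real_)
    within_contrib[i] <- lp_all_full - cox_pl_at(spec, train, full$beta, full$blups)
  }
  n_missing <- sum(is.na(contrib))
  valid <- n_missing <= 0.1 * n
  use <- !is.na(contrib)
  cv_loglik <- if (valid) sum(contrib[use]) else NA_real_
  within <- if (valid) sum(within_contrib[use]) else NA_real_
  structure(list(model_id = spec$model_id, spec = spec,
                 fold_contributions = contrib,
                 within_contributions = within_contrib,
                 cv_loglik = cv_loglik, within_loglik = within,
                 lp_full = full$lp_conditional,
                 p_eff = within - cv_loglik,
                 n = n, n_missing = n_missing, valid = valid,
                 fit = full),
            class = "scav_cvscore")
}

#' Select a model by the modified one-standard-error rule
#'
#' The best model maximizes the cross-validated log likelihood. For each model
#' m the score deficit is `delta_m = cv_best - cv_m`, with a standard error
#' computed from the paired per-observation contribution differences
#' (`sd(d_i) * sqrt(n)`), which accounts for the correlation of scores across
#' models on the same observations. Models with `delta <= se(delta)` form the
#' candidate set; among those the model with the smallest effective degrees of
#' freedom is selected, ties broken by fewer fixed terms, then by model id.
#'
#' @param scores list of [score_model()] results (any mix of Cox and GLMM
#'   scores sharing the same observations).
#' @param se_method `"paired"` (default) or `"per_model"` (plain SE of the
#'   model's own contributions, ignoring pairing).
#' @return list of class `scav_selection`: `table` (one row per model:
#'   `model_id, n_terms, cv_loglik, p_eff, delta, se_delta, in_candidate_set,
#'   selected`), `selected_id`, `candidate_ids`, `best_id`.
#' @export
select_model <- function(scores, se_method = c("paired", "per_model")) {
  se_method <- match.arg(se_method)
  if (inherits(scores, "scav_cvscore")) scores <- list(scores)
  scores <- Filter(function(s) isTRUE(s$valid), scores)
  if (!length(scores)) {
    stop_scav("no valid cross-validation scores to select from",
              class = "scavsurv_selection_error")
  }
  ids <- vapply(scores, `[[`, character(1), "model_id")
  cv <- vapply(scores, `[[`, numeric(1), "cv_loglik")
  peff <- vapply(scores, `[[`, numeric(1), "p_eff")
  nterms <- vapply(scores, function(s) length(s$spec$fixed_terms), integer(1))
  best <- which.max(cv)
  cb <- scores[[best]]$fold_contributions
  delta <- cv[best] - cv
  se_delta <- vapply(seq_along(scores), function(m) {
    cm <- scores[[m]]$fold_contributions
    if (m == best) return(0)
    if (se_method == "paired") {
      d <- cb - cm
      d <- d[!is.na(d)]
      stats::sd(d) * sqrt(length(d))
    } else {
      cmv <- cm[!is.na(cm)]
      stats::sd(cmv) * sqrt(length(cmv))
    }
  }, numeric(1))
  in_set <- delta <= se_delta | seq_along(scores) == best
  cand <- which(in_set)
  ord <- order(peff[cand], nterms[cand], ids[cand])
  selected <- cand[ord[1L]]
  tab <- data.frame(model_id = ids, n_terms = nterms, cv_loglik = cv,
                    p_eff = peff, delta = delta, se_delta = se_delta,
                    in_candidate_set = in_set,
                    selected = seq_along(scores) == selected)
  tab <- tab[order(-tab$cv_loglik), ]
  rownames(tab) <- NULL
  structure(list(table = tab, selected_id = ids[selected],
                 candidate_ids = ids[cand], best_id = ids[best]),
            class = "scav_selection")
}

#' @export
print.scav_selection <- function(x, ...) {
  cat("Model selection (LOOCV log likelihood, modified one-SE rule)\n")
  print(x$table, digits = 4)
  cat("selected:", x$selected_id, "\n")
  invisible(x)
}

#' Compare the selected model's estimates with the full model's
#'
#' Post-selection inference can be biased; comparing the selected model's
#' coefficients against the full (all-terms) model, which closely approximates
#' valid post-selection inference, checks that the two lead to the same
#' conclusions.
#'
#' @param selected_fit,full_fit converged [fit_cox()] (or [fit_glmm()])
#'   results on the same records.
#' @return data frame per shared term: `term`, `beta_selected`, `beta_full`,
#'   `ratio`, `pooled_se`, `flagged` (sign disagreement or absolute difference
#'   exceeding one pooled SE).
#' @export
compare_full_model <- function(selected_fit, full_fit) {
  shared <- intersect(names(selected_fit$beta), names(full_fit$beta))
  if (!setequal(names(selected_fit$beta), names(full_fit$beta)) &&
      length(shared) < length(names(selected_fit$beta))) {
    warning("term sets differ; comparison limited to shared terms", call. = FALSE)
  }
  if (!length(shared)) {
    warning("no shared terms to compare", call. = FALSE)
    return(data.frame(term = character(0), beta_selected = numeric(0),
                      beta_full = numeric(0), ratio = numeric(0),
                      pooled_se = numeric(0), flagged = logical(0)))
  }
  bs <- selected_fit$beta[shared]
  bf <- full_fit$beta[shared]
  pooled <- sqrt(selected_fit$se[shared]^2 + full_fit$se[shared]^2)
  data.frame(term = shared, beta_selected = unname(bs), beta_full = unname(bf),
             ratio = unname(bs / bf), pooled_se = unname(pooled),
             flagged = unname(sign(bs) != sign(bf) | abs(bs - bf) > pooled),
             row.names = NULL)
}

#' Default candidate model grid for a survival outcome
#'
#' All subsets of `{devil_activity, quoll_activity, habitat}` as predictor
#' families, with initial carcass weight always included as a covariate and
#' the site random intercept always present. The grid is configurable: pass
#' any list of term vectors.
#'
#' @param outcome passed to [cox_spec()].
#' @param families list of character vectors of optional terms; default all
#'   8 subsets of the three activity/habitat predictors.
#' @param always terms included in every model (default `"weight_kg"`).
#' @param random_intercept,tie_method passed to [cox_spec()].
#' @return list of [cox_spec()] objects (the first is the null-family model,
#'   the last the full model).
#' @export
candidate_cox_specs <- function(outcome,
                                families = NULL,
                                always = "weight_kg",
                                random_intercept = TRUE,
                                tie_method = "efron") {
  base_terms <- c("devil_activity", "quoll_activity", "habitat_wet")
  if (is.null(families)) {
    families <- unlist(lapply(0:3, function(k)
      utils::combn(base_terms, k, simplify = FALSE)), recursive = FALSE)
  }
  lapply(families, function(fam) {
    cox_spec(outcome, fixed_terms = c(always, fam),
             random_intercept = random_intercept, tie_method = tie_method)
  })
}
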