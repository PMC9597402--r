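## simulated use records with a known logit structure
sim_use_records <- function(n, beta0 = -1, beta_devil = 0.3, seed = 1L,
                            n_sites = 4L, sigma_site = 0) {
  set.seed(seed)
  site <- sample(sprintf("s%d", seq_len(n_sites)), n, replace = TRUE)
  b <- rnorm(n_sites, 0, sigma_site)
  names(b) <- sprintf("s%d", seq_len(n_sites))
  d <- data.frame(carcass_id = sprintf("c%03d", seq_len(n)), site_id = site,
                  region = "full",
                  devil_activity = runif(n, 0, 10),
                  quoll_activity = runif(n, 0, 5),
                  habitat_wet = rbinom(n, 1, 0.5),
                  weight_kg = runif(n, 2, 18),
                  devil_forage_min = rgamma(n, 2, 0.02))
  eta <- beta0 + beta_devil * d$devil_activity + b[site]
  d$used <- rbinom(n, 1, plogis(eta)) == 1
  d$duration_min <- rgamma(n, shape = 2.5, rate = 2.5 / exp(4 + 0.05 * d$devil_activity))
  d
}

test_that("binomial GLM path matches the hand-coded IRLS oracle", {
  d <- sim_use_records(150, seed = 5)
  fit <- fit_glmm(d, "used", c("devil_activity", "weight_kg"),
                  family = "binomial_logit", site_re = FALSE)
  or <- oracle_irls(as.matrix(d[, c("devil_activity", "weight_kg")]),
                    as.numeric(d$used), "binomial_logit")
  expect_equal(unname(fit$beta), unname(or), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_true(is.na(fit$shape))
  ## loglik matches the binomial density at the fit
  eta <- fit$beta[1] + as.matrix(d[, c("devil_activity", "weight_kg")]) %*% fit$beta[-1]
  expect_equal(fit$loglik,
               sum(dbinom(as.numeric(d$used), 1, plogis(drop(eta)), log = TRUE)),
               tolerance = 1e-6)
})

test_that("gamma GLM path matches IRLS and recovers the shape by ML", {
  d <- sim_use_records(400, seed = 6)
  fit <- fit_glmm(d, "duration_min", "devil_activity",
                  family = "gamma_log", site_re = FALSE)
  or <- oracle_irls(as.matrix(d[, "devil_activity", drop = FALSE]),
                    d$duration_min, "gamma_log")
  expect_equal(unname(fit$beta), unname(or), tolerance = 1e-6)
  expect_equal(fit$shape, 2.5, tolerance = 0.4)
  expect_error(fit_glmm(transform(d, duration_min = duration_min - min(duration_min)),
                        "duration_min", "devil_activity", family = "gamma_log"),
               class = "scavsurv_data_error")
})

test_that("mixed binomial fit recovers coefficients and collapses without site effects", {
  d <- sim_use_records(600, beta_devil = 0.35, seed = 7, n_sites = 12L,
                       sigma_site = 0.8)
  fit <- fit_glmm(d, "used", "devil_activity", family = "binomial_logit")
  expect_true(fit$converged)
  expect_equal(unname(fit$beta[["devil_activity"]]), 0.35, tolerance = 0.12)
  expect_gt(fit$sigma2_site, 0.1)
  expect_equal(length(fit$blups), 12L)

  d0 <- sim_use_records(400, seed = 8, sigma_site = 0)
  fit0 <- fit_glmm(d0, "used", "devil_activity", family = "binomial_logit")
  glm0 <- fit_glmm(d0, "used", "devil_activity", family = "binomial_logit",
                   site_re = FALSE)
  expect_lt(fit0$sigma2_site, 0.05)
  expect_equal(unname(fit0$beta), unname(glm0$beta), tolerance = 0.02)
})

test_that("AUC equals the Mann-Whitney U ratio, ties counted half", {
  pred <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.2)
  y <- c(1, 1, 0, 1, 0, 0)
  expect_equal(auc_rank <- scavsurv:::auc_rank(pred, y), oracle_auc(pred, y))
  d <- sim_use_records(120, seed = 9)
  fit <- fit_glmm(d, "used", "devil_activity", family = "binomial_logit",
                  site_re = FALSE)
  expect_equal(auc(fit), oracle_auc(fit$fitted_conditional, as.numeric(d$used)))
  expect_gte(auc(fit, "population"), 0.5)
  gfit <- fit_glmm(d, "duration_min", "devil_activity", family = "gamma_log",
                   site_re = FALSE)
  expect_error(auc(gfit), class = "scavsurv_spec_error")
})

test_that("effect sizes contrast binary 0->1 and continuous mean->mean+1", {
  d <- sim_use_records(300, seed = 10)
  fit <- fit_glmm(d, "used", c("devil_activity", "habitat_wet"),
                  family = "binomial_logit", site_re = FALSE)
  es_d <- effect_size(fit, "devil_activity")
  m <- mean(d$devil_activity); mh <- mean(d$habitat_wet)
  p0 <- plogis(fit$beta[["(Intercept)"]] + fit$beta[["devil_activity"]] * m +
                 fit$beta[["habitat_wet"]] * mh)
  p1 <- plogis(fit$beta[["(Intercept)"]] + fit$beta[["devil_activity"]] * (m + 1) +
                 fit$beta[["habitat_wet"]] * mh)
  expect_equal(es_d$p0, unname(p0), tolerance = 1e-10)
  expect_equal(es_d$es, unname(p1 / p0), tolerance = 1e-10)

  es_h <- effect_size(fit, "habitat_wet")
  q0 <- plogis(fit$beta[["(Intercept)"]] + fit$beta[["devil_activity"]] * m)
  q1 <- plogis(fit$beta[["(Intercept)"]] + fit$beta[["devil_activity"]] * m +
                 fit$beta[["habitat_wet"]])
  expect_equal(es_h$p0, unname(q0), tolerance = 1e-10)
  expect_equal(es_h$p1, unname(q1), tolerance = 1e-10)
  expect_match(es_h$contrast, "0")
})

test_that("hurdle composes parts and refuses sparse intensity data with a reason", {
  d <- sim_use_records(80, seed = 12)
  d$used[seq_len(nrow(d))] <- FALSE
  d$used[1:3] <- TRUE                   # only 3 positives
  d$duration_min[!d$used] <- 0
  hur <- fit_hurdle(d, occupancy_terms = "devil_activity", site_re = FALSE)
  expect_null(hur$intensity)
  expect_match(hur$skip_reasons[["intensity"]], "insufficient data")
  expect_false(is.null(hur$occupancy))
  expect_equal(hur$loglik, hur$occupancy$loglik)

  ## degenerate occupancy
  d2 <- d; d2$used <- TRUE; d2$duration_min <- rgamma(nrow(d2), 2, 0.01)
  hur2 <- fit_hurdle(d2, occupancy_terms = "devil_activity", site_re = FALSE)
  expect_null(hur2$occupancy)
  expect_match(hur2$skip_reasons[["occupancy"]], "degenerate")
  expect_false(is.null(hur2$intensity))

  ## healthy data: loglik is the sum of parts
  d3 <- sim_use_records(120, seed = 13)
  d3$duration_min[!d3$used] <- 0
  hur3 <- fit_hurdle(d3, occupancy_terms = "devil_activity", site_re = FALSE)
  expect_equal(hur3$loglik, hur3$occupancy$loglik + hur3$intensity$loglik)
})

test_that("score_glmm mirrors the Cox CV score and plugs into select_model", {
  d <- sim_use_records(60, seed = 14)
  sc1 <- score_glmm(d, "used", "devil_activity", family = "binomial_logit",
                    site_re = FALSE)
  sc0 <- score_glmm(d, "used", character(0), family = "binomial_logit",
                    site_re = FALSE)
  expect_s3_class(sc1, "scav_cvscore")
  expect_true(sc1$valid)
  ## intercept-only model has ~1 effective parameter, 2-term model more
  expect_equal(sc0$p_eff, 1, tolerance = 0.5)
  expect_gt(sc1$p_eff, sc0$p_eff)
  sel <- select_model(list(sc0, sc1))
  expect_true(sel$selected_id %in% c(sc0$model_id, sc1$model_id))

  ## naive check of one contribution
  tr <- d[-1, , drop = FALSE]
  ftr <- fit_glmm(tr, "used", "devil_activity", family = "binomial_logit",
                  site_re = FALSE)
  expect_equal(sc1$fold_contributions[1],
               scavsurv:::glmm_loglik_at(ftr, d) - scavsurv:::glmm_loglik_at(ftr, tr),
               tolerance = 1e-8)
})
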