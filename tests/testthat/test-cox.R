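test_that("null-model log partial likelihood has its closed form", {
  ## 3 events at distinct times, no covariates: lp = -log 3 - log 2 - log 1
  rec <- data.frame(carcass_id = c("a", "b", "c"), site_id = "s1",
                    time = c(1, 2, 3), status = 1,
                    weight_kg = 10, devil_activity = 0, quoll_activity = 0,
                    habitat_wet = 0)
  sp <- cox_spec("persistence", character(), random_intercept = FALSE)
  expect_warning(fit <- fit_cox(sp, rec), NA)
  expect_equal(fit$lp_conditional, -log(6))
  expect_equal(length(fit$beta), 0L)
  expect_equal(fit$sigma2_site, 0)
})

test_that("fixed-effects fit matches survival::coxph exactly", {
  d <- sim_cox_records(60, seed = 11)
  for (ties in c("efron", "breslow")) {
    sp <- cox_spec("persistence", c("devil_activity", "weight_kg"),
                   random_intercept = FALSE, tie_method = ties)
    fit <- fit_cox(sp, d)
    cf <- survival::coxph(survival::Surv(time, status) ~ devil_activity + weight_kg,
                          data = d, ties = ties)
    expect_equal(unname(fit$beta), unname(coef(cf)), tolerance = 1e-7)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(cf)))), tolerance = 1e-6)
    expect_equal(fit$lp_conditional, cf$loglik[2], tolerance = 1e-9)
  }
})

test_that("tied event times are handled exactly (both methods)", {
  d <- sim_cox_records(50, seed = 3)
  d$time <- round(d$time)               # force heavy ties
  d$time[d$time == 0] <- 1
  for (ties in c("efron", "breslow")) {
    sp <- cox_spec("persistence", c("devil_activity", "weight_kg"),
                   random_intercept = FALSE, tie_method = ties)
    fit <- fit_cox(sp, d)
    cf <- survival::coxph(survival::Surv(time, status) ~ devil_activity + weight_kg,
                          data = d, ties = ties)
    expect_equal(unname(fit$beta), unname(coef(cf)), tolerance = 1e-7)
    expect_equal(fit$lp_conditional, cf$loglik[2], tolerance = 1e-9)
    ## value also matches the naive O(n^2) oracle at arbitrary coefficients
    eta <- drop(as.matrix(d[, c("devil_activity", "weight_kg")]) %*% c(0.1, -0.2))
    expect_equal(cox_pl_at(sp, d, c(devil_activity = 0.1, weight_kg = -0.2),
                           numeric(0)),
                 oracle_cox_pl(eta, d$time, d$status, ties), tolerance = 1e-10)
  }
})

test_that("penalized fit reduces to plain Cox when site variance collapses", {
  ## records generated with no site effect: profiled sigma2 should hit the
  ## floor and beta should match the fixed-effects fit
  d <- sim_cox_records(120, n_sites = 4L, sigma_site = 0, seed = 5)
  sp_re <- cox_spec("persistence", c("devil_activity", "weight_kg"))
  sp_fe <- cox_spec("persistence", c("devil_activity", "weight_kg"),
                    random_intercept = FALSE)
  fit_re <- fit_cox(sp_re, d)
  fit_fe <- fit_cox(sp_fe, d)
  expect_lt(fit_re$sigma2_site, 0.05)
  expect_equal(unname(fit_re$beta), unname(fit_fe$beta), tolerance = 0.02)
  expect_equal(fit_re$lp_marginal, fit_fe$lp_conditional, tolerance = 0.02)
})

test_that("random-intercept variance and coefficients are recovered from frailty data", {
  d <- sim_cox_records(400, beta = c(devil_activity = 0.25),
                       n_sites = 25L, sigma_site = 0.6, seed = 9)
  sp <- cox_spec("persistence", "devil_activity")
  fit <- fit_cox(sp, d)
  expect_true(fit$converged)
  expect_gt(fit$sigma2_site, 0.05)
  expect_equal(unname(fit$beta[["devil_activity"]]), 0.25, tolerance = 0.15)
  ## BLUPs: centred near zero and correlated with the generating intercepts
  b_true <- attr(d, "site_intercepts")[names(fit$blups)]
  expect_lt(abs(mean(fit$blups)), 0.15)
  expect_gt(cor(fit$blups, b_true), 0.5)
})

test_that("fit_cox validates input and flags pathologies", {
  d <- sim_cox_records(30, seed = 2)
  sp <- cox_spec("persistence", "devil_activity")
  d0 <- d; d0$status <- 0
  expect_error(fit_cox(sp, d0), class = "scavsurv_data_error")
  dneg <- d; dneg$time[1] <- 0
  expect_error(fit_cox(sp, dneg), class = "scavsurv_data_error")
  ## constant covariate dropped with a warning
  dc <- d; dc$devil_activity <- 3
  expect_warning(fitc <- fit_cox(sp, dc), "constant covariate")
  expect_equal(length(fitc$beta), 0L)
  ## collinear covariates warned
  dcol <- d; dcol$quoll_activity <- dcol$devil_activity * 2
  expect_warning(fit_cox(cox_spec("persistence",
                                  c("devil_activity", "quoll_activity"),
                                  random_intercept = FALSE), dcol),
                 "Pearson")
  ## monotone likelihood (perfect separation in risk ordering)
  dsep <- data.frame(carcass_id = sprintf("c%d", 1:8), site_id = "s1",
                     time = 1:8, status = 1,
                     devil_activity = 8:1, quoll_activity = 0,
                     habitat_wet = 0, weight_kg = 10)
  fit_sep <- suppressWarnings(
    fit_cox(cox_spec("persistence", "devil_activity",
                     random_intercept = FALSE), dsep))
  expect_false(fit_sep$converged)
  expect_match(fit_sep$diagnostic, "monotone")
  expect_error(hazard_ratios(fit_sep), class = "scavsurv_convergence_error")
})

test_that("hazard ratios exponentiate coefficients with Wald intervals", {
  d <- sim_cox_records(80, seed = 13)
  fit <- fit_cox(cox_spec("persistence", c("devil_activity", "weight_kg"),
                          random_intercept = FALSE), d)
  hr <- hazard_ratios(fit)
  expect_equal(hr$hr, exp(hr$beta))
  expect_equal(hr$ci_low, exp(hr$beta - qnorm(0.975) * hr$se))
  expect_equal(hr$ci_high, exp(hr$beta + qnorm(0.975) * hr$se))
  expect_true(all(hr$ci_low < hr$hr & hr$hr < hr$ci_high))
})

test_that("habitat alias and unknown terms are handled by cox_spec", {
  sp <- cox_spec("persistence", c("habitat", "weight_kg"))
  expect_true("habitat_wet" %in% sp$fixed_terms)
  expect_error(cox_spec("persistence", "rainfall"), class = "scavsurv_spec_error")
})

test_that("cox_pl_at evaluates external estimates, unseen sites at zero", {
  d <- sim_cox_records(40, n_sites = 3L, seed = 21)
  sp <- cox_spec("persistence", "devil_activity")
  blups <- c(s1 = 0.3, s2 = -0.2)       # s3 unseen -> 0
  eta <- 0.15 * d$devil_activity +
    ifelse(d$site_id == "s1", 0.3, ifelse(d$site_id == "s2", -0.2, 0))
  expect_equal(cox_pl_at(sp, d, c(devil_activity = 0.15), blups),
               oracle_cox_pl(eta, d$time, d$status), tolerance = 1e-10)
})
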