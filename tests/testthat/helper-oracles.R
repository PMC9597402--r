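## Independent, deliberately naive reimplementations used as test oracles.
## Everything here favours obvious correctness over speed and shares no code
## with the package internals.

## Brute-force gap-rule scan: walk the sorted photos of each carcass x species
## one at a time, opening a new event whenever the gap strictly exceeds
## gap_min minutes.
oracle_gap_events <- function(det, gap_min = 4, singleton_floor_min = 1) {
  det <- det[det$feeding %in% TRUE, , drop = FALSE]
  out <- list()
  for (cid in unique(det$carcass_id)) {
    for (sp in unique(det$species[det$carcass_id == cid])) {
      ts <- sort(det$timestamp[det$carcass_id == cid & det$species == sp])
      if (!length(ts)) next
      start <- ts[1]; last <- ts[1]; n <- 1L
      for (t in ts[-1]) {
        gap <- as.numeric(difftime(t, last, units = "mins"))
        if (gap > gap_min) {
          out[[length(out) + 1L]] <- data.frame(
            carcass_id = cid, species = sp, start = start, end = last,
            n_photos = n,
            duration_min = max(as.numeric(difftime(last, start, units = "mins")),
                               singleton_floor_min))
          start <- t; n <- 0L
        }
        last <- t; n <- n + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        carcass_id = cid, species = sp, start = start, end = last,
        n_photos = n,
        duration_min = max(as.numeric(difftime(last, start, units = "mins")),
                           singleton_floor_min))
    }
  }
  out <- do.call(rbind, out)
  out[order(out$carcass_id, out$species, out$start), , drop = FALSE]
}

## Naive O(n^2) Cox log partial likelihood (Efron or Breslow), one risk-set
## scan per event time, no suffix sums.
oracle_cox_pl <- function(eta, time, status, ties = "efron") {
  lp <- 0
  for (tk in sort(unique(time[status == 1]))) {
    D <- which(time == tk & status == 1)
    R <- which(time >= tk)
    d <- length(D)
    lp <- lp + sum(eta[D])
    if (ties == "breslow") {
      lp <- lp - d * log(sum(exp(eta[R])))
    } else {
      for (l in seq_len(d) - 1) {
        lp <- lp - log(sum(exp(eta[R])) - (l / d) * sum(exp(eta[D])))
      }
    }
  }
  lp
}

## Hand-coded IRLS for binomial-logit and Gamma-log GLMs (no weights, no
## offset), run to tight convergence.
oracle_irls <- function(X, y, family = c("binomial_logit", "gamma_log"),
                        max_iter = 100L) {
  family <- match.arg(family)
  X <- cbind(1, X)
  beta <- numeric(ncol(X))
  if (family == "gamma_log") beta[1] <- log(mean(y))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    if (family == "binomial_logit") {
      mu <- plogis(eta)
      w <- mu * (1 - mu)            # (dmu/deta)^2 / V(mu)
      z <- eta + (y - mu) / pmax(mu * (1 - mu), 1e-12)
    } else {
      mu <- exp(eta)
      w <- rep(1, length(y))        # log link, V(mu) = mu^2: w = mu^2/mu^2
      z <- eta + (y - mu) / mu
    }
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-12) { beta <- drop(beta_new); break }
    beta <- drop(beta_new)
  }
  beta
}

## Mann-Whitney U by double loop; AUC = U / (n1 * n0) with ties counted half.
oracle_auc <- function(pred, y) {
  pos <- pred[y == 1]; neg <- pred[y == 0]
  u <- 0
  for (a in pos) for (b in neg) u <- u + (a > b) + 0.5 * (a == b)
  u / (length(pos) * length(neg))
}

## Hand product-limit table with Greenwood variance and log-transformed CI.
oracle_km <- function(time, status, conf = 0.95) {
  tk <- sort(unique(time))
  s <- 1; gw <- 0
  z <- qnorm(1 - (1 - conf) / 2)
  rows <- list()
  for (t in tk) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & status == 1)
    s <- s * (1 - d / n_risk)
    if (d > 0 && n_risk > d) gw <- gw + d / (n_risk * (n_risk - d))
    se_log <- sqrt(gw)
    ci <- if (s > 0) exp(log(s) + c(-1, 1) * z * se_log) else c(NA, NA)
    rows[[length(rows) + 1L]] <- data.frame(
      time = t, n_risk = n_risk, n_event = d, surv = s,
      ci_low = min(max(ci[1], 0), 1), ci_high = min(ci[2], 1))
  }
  do.call(rbind, rows)
}

## Naive double-loop LOOCV of a Cox spec: refit with fit_cox directly (no warm
## starts, no shortcuts) and evaluate with a naive partial likelihood.
oracle_cv_contributions <- function(spec, records) {
  n <- nrow(records)
  eta_at <- function(d, beta, blups) {
    e <- numeric(nrow(d))
    for (tm in names(beta)) e <- e + beta[[tm]] * d[[tm]]
    b <- blups[as.character(d$site_id)]
    b[is.na(b)] <- 0
    e + unname(b)
  }
  vapply(seq_len(n), function(i) {
    train <- records[-i, , drop = FALSE]
    fit <- fit_cox(spec, train)
    oracle_cox_pl(eta_at(records, fit$beta, fit$blups),
                  records$time, records$status, spec$tie_method) -
      oracle_cox_pl(eta_at(train, fit$beta, fit$blups),
                    train$time, train$status, spec$tie_method)
  }, numeric(1))
}
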