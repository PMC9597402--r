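## Core Cox partial-likelihood machinery.
##
## The log partial likelihood, its gradient and Hessian are computed over risk
## sets at event times, with Efron or Breslow handling of tied event times.
## A Gaussian site random intercept enters the linear predictor through an
## indicator design block and is estimated by maximizing the partial
## likelihood penalized by b'b / (2 sigma^2); sigma^2 itself is profiled by a
## 1-D search over the Laplace-approximated integrated log partial likelihood.

## Value of the log partial likelihood for a given linear predictor.
## time, status (1 = event, 0 = censored), eta all length n.
cox_pl_value <- function(eta, time, status, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  d <- cox_pl_derivs(X = NULL, beta = numeric(0), offset = eta,
                     time = time, status = status, ties = ties,
                     value_only = TRUE)
  d$lp
}

## Quantities that depend only on (X, time, status), computed once per fit and
## reused across Newton iterations and line-search evaluations: the sort
## order, the sorted design, the packed x x' rows, the death sets, and the
## risk-set block structure. x x' is symmetric, so only the p(p+1)/2 upper
## triangle is stored (pack_i/pack_j map packed columns back to (i, j)); and
## suffix sums are only ever read at risk-set boundaries, so sorted rows are
## aggregated into one block per distinct event time before cumulating.
cox_pl_workspace <- function(X, time, status) {
  n <- length(time)
  p <- if (is.null(X)) 0L else ncol(X)
  ord <- order(time)            # ties within a time form one death set; order
  time_s <- time[ord]           # among them never affects the likelihood
  status_s <- status[ord]
  Xs <- if (p > 0L) X[ord, , drop = FALSE] else NULL
  ev <- which(status_s == 1)
  etimes <- unique(time_s[ev])
  ## first sorted position at or after each event time (risk-set boundary)
  boundary <- match(etimes, time_s)
  pack_i <- pack_j <- integer(0)
  XXp <- NULL
  if (p > 0L) {
    ut <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
    pack_i <- ut[, 1L]
    pack_j <- ut[, 2L]
    XXp <- Xs[, pack_i, drop = FALSE] * Xs[, pack_j, drop = FALSE]
  }
  ## block id (index into etimes) for every sorted row in some risk set
  in_risk <- if (length(boundary)) seq.int(boundary[1L], n) else integer(0)
  block <- findInterval(in_risk, boundary)
  list(n = n, p = p, ord = ord, time_s = time_s, status_s = status_s,
       Xs = Xs, XXp = XXp, pack_i = pack_i, pack_j = pack_j,
       ev = ev, etimes = etimes, boundary = boundary,
       in_risk = in_risk, block = block,
       death_sets = lapply(etimes, function(t_k) ev[time_s[ev] == t_k]))
}

## expand a packed upper-triangle vector into the full symmetric p x p matrix
unpack_sym <- function(v, p, pack_i, pack_j) {
  M <- matrix(0, p, p)
  M[cbind(pack_i, pack_j)] <- v
  M[cbind(pack_j, pack_i)] <- v
  M
}

## Log partial likelihood with gradient/Hessian in beta for eta = offset + X beta.
## X may be NULL or have zero columns (null model): derivatives are empty.
## Pass a precomputed `ws` from cox_pl_workspace(X, time, status) to reuse the
## sorted design across calls.
cox_pl_derivs <- function(X, beta, time, status, offset = NULL,
                          ties = c("efron", "breslow"), value_only = FALSE,
                          ws = NULL) {
  ties <- match.arg(ties)
  if (is.null(ws)) ws <- cox_pl_workspace(X, time, status)
  n <- ws$n
  p <- ws$p
  if (is.null(offset)) offset <- numeric(n)
  eta <- offset + if (p > 0L) drop(X %*% beta) else 0
  if (any(!is.finite(eta))) {
    return(list(lp = -Inf, grad = rep(NA_real_, p),
                hess = matrix(NA_real_, p, p)))
  }

  if (!length(ws$ev)) {
    return(list(lp = 0, grad = numeric(p), hess = matrix(0, p, p)))
  }
  eta_s <- eta[ws$ord]
  w <- exp(eta_s)
  Xs <- ws$Xs

  ## per-boundary suffix sums via block aggregation: rows are summed into one
  ## block per distinct event time, then suffix-cumulated over the K blocks
  S0_all <- rev(cumsum(rev(
    rowsum(w[ws$in_risk], ws$block, reorder = TRUE))))
  if (p > 0L && !value_only) {
    Xw <- Xs * w
    XXw <- ws$XXp * w
    cs1 <- rev_cumsum_rows(
      rowsum(Xw[ws$in_risk, , drop = FALSE], ws$block, reorder = TRUE))  # K x p
    cs2 <- rev_cumsum_rows(
      rowsum(XXw[ws$in_risk, , drop = FALSE], ws$block, reorder = TRUE)) # K x p(p+1)/2
  }
  d_k <- lengths(ws$death_sets)

  ## event times with d_k = 1 (or any multiplicity under Breslow) contribute
  ## the same closed form, accumulated without looping; Efron corrections for
  ## tied times are handled in the loop below
  plain <- if (ties == "breslow") rep(TRUE, length(d_k)) else d_k == 1L
  lp <- sum(eta_s[ws$ev]) - sum(d_k[plain] * log(S0_all[plain]))
  if (p == 0L || value_only) {
    for (k in which(!plain)) {
      D <- ws$death_sets[[k]]
      f <- (seq_len(d_k[k]) - 1L) / d_k[k]
      lp <- lp - sum(log(S0_all[k] - f * sum(w[D])))
    }
    return(list(lp = lp, grad = numeric(p), hess = matrix(0, p, p)))
  }

  grad <- colSums(Xs[ws$ev, , drop = FALSE])
  hess <- matrix(0, p, p)
  if (any(plain)) {
    dpl <- d_k[plain]
    Mu <- cs1[plain, , drop = FALSE] / S0_all[plain]               # K x p
    grad <- grad - colSums(Mu * dpl)
    hess <- hess -
      unpack_sym(colSums(cs2[plain, , drop = FALSE] * (dpl / S0_all[plain])),
                 p, ws$pack_i, ws$pack_j) +
      crossprod(Mu, Mu * dpl)
  }
  for (k in which(!plain)) {
    D <- ws$death_sets[[k]]
    S0 <- S0_all[k]
    S1 <- cs1[k, ]
    S2 <- unpack_sym(cs2[k, ], p, ws$pack_i, ws$pack_j)
    S0d <- sum(w[D])
    S1d <- colSums(Xw[D, , drop = FALSE])
    S2d <- unpack_sym(colSums(XXw[D, , drop = FALSE]), p, ws$pack_i, ws$pack_j)
    for (l in seq_len(d_k[k]) - 1L) {
      f <- l / d_k[k]
      a0 <- S0 - f * S0d
      lp <- lp - log(a0)
      a1 <- S1 - f * S1d
      a2 <- S2 - f * S2d
      mu <- a1 / a0
      grad <- grad - mu
      hess <- hess - (a2 / a0 - tcrossprod(mu))
    }
  }
  list(lp = lp, grad = grad, hess = hess)
}

## Newton maximization of the penalized log partial likelihood
##   l(beta, b) - sum(penalty * theta^2) / 2
## where theta = c(beta, b) and penalty is 0 for fixed effects, 1/sigma^2 for
## random-intercept columns. Returns theta-hat and the penalized Hessian.
cox_penalized_newton <- function(X, time, status, penalty, ties,
                                 theta0 = NULL, reltol = 1e-9, max_iter = 50L,
                                 ws = NULL) {
  p <- ncol(X)
  if (p == 0L) {
    lp <- cox_pl_value(numeric(length(time)), time, status, ties)
    return(list(theta = numeric(0), lp = lp, objective = lp,
                hess_pen = matrix(0, 0, 0), grad_pen = numeric(0),
                converged = TRUE, iterations = 0L))
  }
  theta <- theta0 %||% numeric(p)
  if (is.null(ws)) ws <- cox_pl_workspace(X, time, status)
  obj <- function(th) {
    cox_pl_derivs(X, th, time, status, ties = ties, value_only = TRUE,
                  ws = ws)$lp - sum(penalty * th^2) / 2
  }
  f_old <- obj(theta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d <- cox_pl_derivs(X, theta, time, status, ties = ties, ws = ws)
    g <- d$grad - penalty * theta
    H <- -d$hess + diag(penalty, p, p)
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H + diag(1e-8 + 1e-8 * max(abs(diag(H))), p), g)
    })
    ## step-halving line search on the penalized objective
    lambda <- 1
    repeat {
      theta_new <- theta + lambda * step
      f_new <- obj(theta_new)
      if (is.finite(f_new) && f_new >= f_old - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { theta_new <- theta; f_new <- f_old; break }
    }
    done <- abs(f_new - f_old) < reltol * (abs(f_old) + reltol)
    theta <- theta_new
    f_old <- f_new
    if (done) { converged <- TRUE; break }
  }
  d <- cox_pl_derivs(X, theta, time, status, ties = ties, ws = ws)
  list(theta = theta, lp = d$lp, objective = f_old,
       hess_pen = -d$hess + diag(penalty, p, p),
       grad_pen = d$grad - penalty * theta,
       converged = converged, iterations = it)
}

## Laplace-approximated integrated log partial likelihood at sigma2, with
## (beta, b) profiled out:  l_pen(theta-hat) - (q/2) log(sigma2)
##                          - (1/2) log det(H_bb-penalized)
cox_laplace_marginal <- function(fit_inner, q, sigma2, b_idx) {
  if (q == 0L) return(fit_inner$lp)
  Hbb <- fit_inner$hess_pen[b_idx, b_idx, drop = FALSE]
  ld <- determinant(Hbb, logarithm = TRUE)
  fit_inner$objective - (q / 2) * log(sigma2) - 0.5 * as.numeric(ld$modulus)
}
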