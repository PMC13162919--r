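# Independent brute-force oracles. These are written as direct, naive
# enumerations of the defining formulas and must stay independent of the
# package's implementations.

# Harrell C-index by full pair enumeration.
oracle_cindex <- function(scores, time, event) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  num / den
}

# Kaplan-Meier by hand product-limit over distinct times.
oracle_km <- function(time, event, at) {
  tt <- sort(unique(time))
  s <- 1
  surv <- numeric(length(tt))
  for (k in seq_along(tt)) {
    n_risk <- sum(time >= tt[k])
    d <- sum(time == tt[k] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  vapply(at, function(a) {
    below <- tt <= a
    if (!any(below)) 1 else surv[max(which(below))]
  }, numeric(1))
}

# Left limit G(t-) of the censoring-distribution KM.
oracle_cens_km_left <- function(time, event, at) {
  tt <- sort(unique(time))
  s <- 1
  surv <- numeric(length(tt))
  for (k in seq_along(tt)) {
    n_risk <- sum(time >= tt[k])
    d <- sum(time == tt[k] & event == 0)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  vapply(at, function(a) {
    below <- tt < a
    if (!any(below)) 1 else surv[max(which(below))]
  }, numeric(1))
}

# Cumulative/dynamic IPCW AUC at t by weighted pair summation.
oracle_td_auc <- function(risks, time, event, t) {
  case <- which(time <= t & event == 1)
  ctrl <- which(time > t)
  w <- 1 / oracle_cens_km_left(time, event, time[case])
  num <- 0; den <- 0
  for (a in seq_along(case)) for (b in ctrl) {
    cmp <- if (risks[case[a]] > risks[b]) 1
           else if (risks[case[a]] == risks[b]) 0.5 else 0
    num <- num + w[a] * cmp
    den <- den + w[a]
  }
  num / den
}

# IPCW Brier score at t by direct weighted sum (Graf convention).
oracle_brier <- function(pred_surv, time, event, t) {
  n <- length(time)
  total <- 0
  gt <- oracle_cens_km_left(time, event, t + 1e-12)  # G(t), right-continuous at t
  # recompute G(t) as right-continuous value: S_c(t)
  tt <- sort(unique(time)); s <- 1; surv <- numeric(length(tt))
  for (k in seq_along(tt)) {
    n_risk <- sum(time >= tt[k]); d <- sum(time == tt[k] & event == 0)
    s <- s * (1 - d / n_risk); surv[k] <- s
  }
  gt <- if (any(tt <= t)) surv[max(which(tt <= t))] else 1
  for (i in seq_len(n)) {
    if (time[i] <= t && event[i] == 1) {
      g <- oracle_cens_km_left(time, event, time[i])
      total <- total + (0 - pred_surv[i])^2 / g
    } else if (time[i] > t) {
      total <- total + (1 - pred_surv[i])^2 / gt
    }
  }
  total / n
}

# K-sample log-rank chi-square by direct observed-vs-expected summation.
oracle_logrank <- function(groups, time, event) {
  groups <- factor(groups)
  K <- nlevels(groups)
  ev_times <- sort(unique(time[event == 1]))
  O <- numeric(K); E <- numeric(K); V <- matrix(0, K, K)
  for (t in ev_times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(time == t & event == 1)
    for (g in seq_len(K)) {
      n_g <- sum(at_risk & groups == levels(groups)[g])
      d_g <- sum(time == t & event == 1 & groups == levels(groups)[g])
      O[g] <- O[g] + d_g
      E[g] <- E[g] + d_t * n_g / n_t
    }
    if (n_t > 1) {
      c_t <- d_t * (n_t - d_t) / (n_t - 1)
      p <- vapply(seq_len(K), function(g) {
        sum(at_risk & groups == levels(groups)[g]) / n_t
      }, numeric(1))
      V <- V + c_t * (diag(p, K) - outer(p, p))
    }
  }
  om <- (O - E)[-K]
  as.numeric(t(om) %*% solve(V[-K, -K, drop = FALSE], om))
}

# Negative log partial likelihood (Breslow) by explicit risk-set sums.
oracle_cox_nll <- function(X, time, event, beta) {
  X <- as.matrix(X)
  eta <- as.numeric(X %*% beta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    ll <- ll + sum(eta[D]) - length(D) * log(sum(exp(eta[R])))
  }
  -ll
}

# Maximizer of the toy partial likelihood by dense grid search.
oracle_grid_beta <- function(X, time, event, lo = -5, hi = 5, n_grid = 20001) {
  grid <- seq(lo, hi, length.out = n_grid)
  vals <- vapply(grid, function(b) oracle_cox_nll(X, time, event, b), numeric(1))
  grid[which.min(vals)]
}
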