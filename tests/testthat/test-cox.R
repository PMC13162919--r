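# Cox engine: partial likelihood against closed forms and brute-force
# oracles, Newton fitting against grid search and survival::coxph,
# Breslow baseline, risk scores and landmark absolute risk.

toy4 <- list(time = c(1, 2, 3, 4), event = c(1, 1, 1, 1),
             x = matrix(c(0, 1, 0, 1), ncol = 1, dimnames = list(NULL, "x")))

test_that("null-model value is the sum of log risk-set sizes", {
  set.seed(1)
  n <- 25
  tt <- sort(runif(n))  # distinct times, all events
  y <- surv_outcome(tt, rep(1, n))
  X <- matrix(rnorm(n), ncol = 1)
  out <- neg_log_partial_likelihood(X, y, 0)
  expect_equal(out$value, sum(log(n:1)), tolerance = 1e-12)
})

test_that("a risk set of one contributes zero at any beta", {
  y <- surv_outcome(1, 1)
  X <- matrix(1, 1, 1)
  for (b in c(-2, 0, 3.7)) {
    expect_equal(neg_log_partial_likelihood(X, y, b)$value, 0, tolerance = 1e-12)
  }
})

test_that("partial likelihood matches the risk-set summation oracle", {
  y <- surv_outcome(toy4$time, toy4$event)
  for (b in c(-1, 0.5, 2)) {
    expect_equal(neg_log_partial_likelihood(toy4$x, y, b)$value,
                 oracle_cox_nll(toy4$x, toy4$time, toy4$event, b),
                 tolerance = 1e-10)
  }
  # censored toy with ties
  tt <- c(1, 1, 2, 2, 3, 4); ev <- c(1, 0, 1, 1, 0, 1)
  X <- matrix(c(0.3, -1, 2, 0, 1, -0.5), ncol = 1)
  y2 <- surv_outcome(tt, ev)
  expect_equal(neg_log_partial_likelihood(X, y2, 0.7)$value,
               oracle_cox_nll(X, tt, ev, 0.7), tolerance = 1e-10)
})

test_that("gradient and Hessian match numerical differentiation", {
  set.seed(2)
  n <- 40
  X <- matrix(rnorm(n * 3), n, 3)
  y <- surv_outcome(rexp(n), rbinom(n, 1, 0.7))
  beta <- c(0.3, -0.2, 0.1)
  out <- neg_log_partial_likelihood(X, y, beta, hessian = TRUE)
  eps <- 1e-6
  for (j in 1:3) {
    e <- numeric(3); e[j] <- eps
    g_num <- (neg_log_partial_likelihood(X, y, beta + e)$value -
              neg_log_partial_likelihood(X, y, beta - e)$value) / (2 * eps)
    expect_equal(out$gradient[j], g_num, tolerance = 1e-5)
    h_num <- (neg_log_partial_likelihood(X, y, beta + e)$gradient -
              neg_log_partial_likelihood(X, y, beta - e)$gradient) / (2 * eps)
    expect_equal(out$hessian[, j], h_num, tolerance = 1e-4)
  }
  # convexity: Hessian PSD at random points
  for (k in 1:5) {
    H <- neg_log_partial_likelihood(X, y, rnorm(3, sd = 0.5),
                                    hessian = TRUE)$hessian
    expect_gte(min(eigen(H, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("fit_cox matches the grid-search oracle on the 4-patient toy", {
  y <- surv_outcome(toy4$time, toy4$event)
  fit <- fit_cox(toy4$x, y)
  b_star <- oracle_grid_beta(toy4$x, toy4$time, toy4$event)
  expect_lt(abs(unname(fit$beta) - b_star), 1e-3)  # grid resolution 5e-4
  # risk scores equal beta * covariate
  expect_equal(predict_risk_score(fit, toy4$x),
               as.numeric(toy4$x * fit$beta), tolerance = 1e-12)
})

test_that("fit_cox agrees with survival::coxph (Breslow ties)", {
  skip_if_not_installed("survival")
  set.seed(3)
  n <- 150
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  tt <- round(rexp(n, exp(X %*% c(0.5, -0.3, 0))), 2) + 0.01  # induce ties
  ev <- rbinom(n, 1, 0.8)
  y <- surv_outcome(tt, ev)
  fit <- fit_cox(X, y)
  ref <- survival::coxph(survival::Surv(tt, ev) ~ X, ties = "breslow")
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-7)
  bh <- survival::basehaz(ref, centered = FALSE)
  bh <- bh[bh$time <= max(tt[ev == 1]), ]   # stay inside the event range
  expect_equal(fusesurv:::baseline_cumhaz_at(fit, bh$time), bh$hazard,
               tolerance = 1e-6)
  # gradient max-norm below tolerance at the optimum
  g <- neg_log_partial_likelihood(X, y, fit$beta)$gradient
  expect_lt(max(abs(g)), 1e-8)
})

test_that("null recovery: beta within 3 SE of zero for unrelated covariate", {
  set.seed(4)
  n <- 2000
  X <- matrix(rnorm(n), ncol = 1)
  y <- surv_outcome(rexp(n), rbinom(n, 1, 0.85))
  fit <- fit_cox(X, y)
  H <- neg_log_partial_likelihood(X, y, fit$beta, hessian = TRUE)$hessian
  expect_lt(abs(unname(fit$beta)), 3 * sqrt(1 / H[1, 1]))
})

test_that("one-term Breslow sum: single patient, lp 0 gives H0(1) = 1", {
  y <- surv_outcome(1, 1)
  fit <- fit_cox(matrix(numeric(0), nrow = 1, ncol = 0), y)
  expect_equal(fusesurv:::baseline_cumhaz_at(fit, 1), 1, tolerance = 1e-12)
})

test_that("separation raises an explicit error", {
  tt <- c(1, 2, 3, 4, 5, 6)
  x <- matrix(c(3, 2.5, 2, 1, 0.5, 0), ncol = 1)  # perfectly ordered
  expect_error(fit_cox(x, surv_outcome(tt, rep(1, 6))),
               "separation|diverging")
})

test_that("absolute risk closed forms and monotonicity hold", {
  # H0(1.5) = 0.2, lp = 0 -> risk = 1 - exp(-0.2)
  fit <- structure(list(beta = c(x = 0),
                        baseline = data.frame(time = 1.5, hazard = 0.2,
                                              cumhaz = 0.2),
                        xnames = "x"), class = "cox_fit")
  r <- predict_absolute_risk(fit, matrix(0, 3, 1, dimnames = list(NULL, "x")), 1.5)
  expect_equal(r$risk, rep(1 - exp(-0.2), 3), tolerance = 1e-10)
  # before the first jump H0 = 0 -> risk 0
  r0 <- predict_absolute_risk(fit, matrix(1, 3, 1, dimnames = list(NULL, "x")), 1)
  expect_equal(r0$risk, rep(0, 3))
  # monotone in t*, and extrapolation warns
  set.seed(5)
  n <- 80
  X <- matrix(rnorm(n), ncol = 1)
  y <- surv_outcome(rexp(n, 0.5), rbinom(n, 1, 0.9))
  f2 <- fit_cox(X, y)
  r1 <- predict_absolute_risk(f2, X, 1.0)$risk
  r2 <- predict_absolute_risk(f2, X, 1.5)$risk
  expect_true(all(r2 >= r1 - 1e-12))
  expect_true(all(r1 >= 0 & r2 <= 1))
  expect_warning(predict_absolute_risk(f2, X, max(y$time) + 10), "last observed")
})

test_that("error contracts: zero events, dimension mismatch, constants", {
  expect_error(neg_log_partial_likelihood(matrix(1:4, 2), surv_outcome(1:2, c(0, 0)), c(0, 0)),
               "no events")
  set.seed(6)
  X <- matrix(rnorm(20), 10, 2)
  y <- surv_outcome(rexp(10), rep(1, 10))
  fit <- fit_cox(X, y)
  expect_error(predict_risk_score(fit, matrix(0, 5, 3)), "columns")
  expect_error(fit_cox(cbind(X, 1), y), "constant")
  expect_error(predict_absolute_risk(fit, X, -1), "positive")
})

test_that("C-index of scores is invariant to monotone transforms", {
  set.seed(7)
  n <- 60
  sc <- rnorm(n)
  y <- surv_outcome(rexp(n, exp(sc)), rbinom(n, 1, 0.8))
  expect_equal(harrell_cindex(sc, y), harrell_cindex(exp(sc), y))
})
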