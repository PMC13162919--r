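# Evaluation suite: C-index, Kaplan-Meier, IPCW time-dependent AUC,
# Brier/IBS and calibration, each against closed forms and brute-force
# oracles.

test_that("Harrell C-index: ties, perfect ranking, and the 4-patient example", {
  y3 <- surv_outcome(c(1, 2, 3), c(1, 1, 1))
  expect_equal(harrell_cindex(c(5, 5, 5), y3), 0.5)
  expect_equal(harrell_cindex(c(3, 2, 1), y3), 1.0)
  y4 <- surv_outcome(c(1, 2, 3, 4), c(1, 0, 1, 1))
  expect_equal(harrell_cindex(c(0.9, 0.5, 0.2, 0.7), y4), 0.75)
  expect_error(harrell_cindex(1:3, surv_outcome(c(1, 2, 3), c(0, 0, 0))),
               "comparable")
})

test_that("C-index matches pair-enumeration oracle on random censored data", {
  fusesurv:::with_seed(11, {
    for (rep in 1:5) {
      n <- 30
      tt <- sample(1:12, n, replace = TRUE)  # heavy ties
      ev <- rbinom(n, 1, 0.7)
      if (sum(ev) == 0) ev[1] <- 1
      sc <- round(rnorm(n), 1)
      y <- surv_outcome(tt, ev)
      expect_equal(harrell_cindex(sc, y), oracle_cindex(sc, tt, ev),
                   tolerance = 1e-12)
    }
  })
})

test_that("Kaplan-Meier product limit matches hand computations", {
  km1 <- km_fit(surv_outcome(c(1, 2, 3, 4), c(1, 1, 1, 1)))
  expect_equal(km1$table$surv, c(0.75, 0.5, 0.25, 0), tolerance = 1e-12)
  km2 <- km_fit(surv_outcome(c(1, 2, 3), c(0, 0, 0)))
  expect_true(all(km2$table$surv == 1))
  km3 <- km_fit(surv_outcome(c(1, 2, 3), c(1, 0, 1)))
  expect_equal(km_surv_at(km3, c(1, 2, 3)), c(2 / 3, 2 / 3, 0), tolerance = 1e-12)
  expect_equal(km_median(km3), 3)
  expect_equal(km_median(km2), NA_real_)
  # medians: S(2) = 0.5 exactly -> median 2
  expect_equal(km_median(km1), 2)
  # no censoring: equals the empirical survival function
  fusesurv:::with_seed(12, {
    tt <- rexp(40)
    km <- km_fit(surv_outcome(tt, rep(1, 40)))
    at <- sort(tt)
    expect_equal(km_surv_at(km, at), 1 - ecdf(tt)(at), tolerance = 1e-12)
  })
})

test_that("td_auc: perfect separation, ties, and the IPCW oracle", {
  # no censoring before t, cases uniformly riskier
  y <- surv_outcome(c(0.5, 0.8, 2, 3, 4), c(1, 1, 1, 0, 1))
  expect_equal(td_auc(c(9, 8, 1, 2, 3), y, 1), 1.0)
  expect_equal(td_auc(rep(1, 5), y, 1), 0.5)
  # censored toy, weighted pair enumeration
  tt <- c(0.4, 0.7, 0.9, 1.2, 1.5, 2.0)
  ev <- c(1, 0, 1, 1, 0, 1)
  rk <- c(2.0, 0.3, 1.1, 0.8, 0.2, -0.5)
  y2 <- surv_outcome(tt, ev)
  expect_equal(td_auc(rk, y2, 1.0), oracle_td_auc(rk, tt, ev, 1.0),
               tolerance = 1e-12)
  expect_error(td_auc(rk, y2, 0.1), "cases")
  expect_error(td_auc(rk, y2, 10), "controls")
  # no censoring: equals the classical binary AUC of event-by-t
  fusesurv:::with_seed(13, {
    n <- 50
    tt3 <- rexp(n); rk3 <- -tt3 + rnorm(n)
    y3 <- surv_outcome(tt3, rep(1, n))
    t0 <- median(tt3)
    lab <- tt3 <= t0
    pos <- rk3[lab]; neg <- rk3[!lab]
    auc_bin <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    expect_equal(td_auc(rk3, y3, t0), auc_bin, tolerance = 1e-12)
  })
})

test_that("Brier score: closed forms, oracle, and the MSE equivalence", {
  # no censoring, exact outcome indicator -> 0
  tt <- c(0.5, 1.5, 2.5, 3.5); ev <- rep(1, 4)
  y <- surv_outcome(tt, ev)
  pred <- as.numeric(tt > 2)   # survival prediction at t = 2
  expect_equal(brier(pred, y, 2), 0, tolerance = 1e-12)
  expect_equal(brier(rep(0.5, 4), y, 2), 0.25, tolerance = 1e-12)
  # censored toy vs weighted-sum oracle
  tt2 <- c(0.4, 0.7, 0.9, 1.2, 1.5, 2.0)
  ev2 <- c(1, 0, 1, 1, 0, 1)
  p2 <- c(0.9, 0.8, 0.6, 0.5, 0.4, 0.2)
  y2 <- surv_outcome(tt2, ev2)
  expect_equal(brier(p2, y2, 1.0), oracle_brier(p2, tt2, ev2, 1.0),
               tolerance = 1e-12)
  # no censoring: equals plain mean squared error of survival indicator
  fusesurv:::with_seed(14, {
    n <- 40
    tt3 <- rexp(n); y3 <- surv_outcome(tt3, rep(1, n))
    p3 <- runif(n)
    t0 <- median(tt3)
    expect_equal(brier(p3, y3, t0), mean((as.numeric(tt3 > t0) - p3)^2),
                 tolerance = 1e-12)
  })
})

test_that("integrated Brier score is the trapezoidal average from zero", {
  fusesurv:::with_seed(15, {
    n <- 50
    tt <- rexp(n); y <- surv_outcome(tt, rep(1, n))
    times <- quantile(tt, c(0.2, 0.4, 0.6), names = FALSE)
    P <- matrix(runif(n * 3), n, 3)
    bs <- vapply(1:3, function(j) brier(P[, j], y, times[j]), numeric(1))
    tt0 <- c(0, times); bb <- c(0, bs)
    manual <- sum(diff(tt0) * (head(bb, -1) + tail(bb, -1)) / 2) / max(tt0)
    expect_equal(integrated_brier(P, y, times), manual, tolerance = 1e-12)
    # tau truncation drops later columns
    expect_equal(integrated_brier(P, y, times, tau = times[2]),
                 integrated_brier(P[, 1:2], y, times[1:2]), tolerance = 1e-12)
  })
})

test_that("calibration slope/intercept recover identity and affine shifts", {
  # three clean groups, no censoring, observed = predicted by construction
  fusesurv:::with_seed(16, {
    n_g <- 400
    groups <- rep(c("g1", "g2", "g3"), each = n_g)
    p_true <- rep(c(0.2, 0.5, 0.8), each = n_g)
    t0 <- 1.5
    # exponential times with rate chosen so P(T <= 1.5) = p
    rate <- -log(1 - p_true) / t0
    tt <- rexp(3 * n_g, rate)
    y <- surv_outcome(tt, rep(1, 3 * n_g))
    cal <- calibration_groups(p_true, groups, y, t0)
    expect_equal(cal$slope, 1, tolerance = 0.15)
    expect_lt(abs(cal$intercept), 0.08)
    # affine shift in observed risk moves only the intercept
    pts <- data.frame(predicted = c(0.2, 0.5, 0.8),
                      observed = c(0.3, 0.6, 0.9))
    fit <- lm(observed ~ predicted, pts)
    expect_equal(unname(coef(fit)), c(0.1, 1), tolerance = 1e-12)
  })
  expect_error(calibration_groups(c(0.1, 0.2), c("a", "a"),
                                  surv_outcome(c(1, 2), c(1, 1)), 1), "2 groups")
})

test_that("evaluate_model assembles a finite report and is null-calibrated", {
  fusesurv:::with_seed(17, {
    n <- 300
    lp <- rnorm(n)
    tt <- 1.5 * (-log(runif(n)) * exp(-lp))^(1 / 1.2)
    cens <- rexp(n, 0.1)
    y <- surv_outcome(pmin(tt, cens), as.numeric(tt <= cens))
    g <- default_eval_times(y)
    surv <- exp(-outer(exp(lp), (g$times / 1.5)^1.2))
    rep1 <- evaluate_model(lp, surv, y, times = g$times, tau = g$tau,
                           n_boot = 25, seed = 3)
    expect_true(all(is.finite(c(rep1$c_index, rep1$auc_mean, rep1$ibs))))
    expect_gt(rep1$c_index, 0.6)
    expect_true(all(rep1$auc >= 0 & rep1$auc <= 1, na.rm = TRUE))
    expect_equal(dim(rep1$ci), c(2L, 3L))
    # permuted scores: chance-level discrimination
    perm <- sample(n)
    rep0 <- evaluate_model(lp[perm], surv[perm, , drop = FALSE], y,
                           times = g$times, tau = g$tau)
    expect_lt(abs(rep0$c_index - 0.5), 0.07)
    expect_lt(abs(rep0$auc_mean - 0.5), 0.09)
  })
})
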