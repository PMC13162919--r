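# Fusion orchestration: fold construction, EPV arithmetic, out-of-fold
# leakage bookkeeping, and the five meta-learners.

test_that("outer folds: sizes, determinism and event balance", {
  fusesurv:::with_seed(31, {
    y <- surv_outcome(rexp(398), rbinom(398, 1, 0.882))
  })
  f1 <- make_outer_folds(y, 5, seed = 3)
  f2 <- make_outer_folds(y, 5, seed = 3)
  expect_identical(f1, f2)
  expect_true(all(table(f1) %in% c(79, 80)))
  # event proportion within +/- 5 points of the global rate, many seeds
  glob <- mean(y$event)
  for (s in 1:10) {
    f <- make_outer_folds(y, 5, seed = s)
    props <- tapply(y$event, f, mean)
    expect_true(all(abs(props - glob) < 0.05))
  }
  expect_error(make_outer_folds(surv_outcome(1:6, rep(1, 6)), 5), "too few")
})

test_that("EPV arithmetic matches the published table values", {
  expect_equal(compute_epv(351, 5), 70.2)
  expect_equal(compute_epv(351, 3), 117)
  expect_equal(compute_epv(351, 2), 175.5)
  expect_equal(compute_epv(0, 4), 0)
  expect_error(compute_epv(351, 0), "zero predictors")
})

test_that("landmark labels implement the censoring exclusion rule", {
  y <- surv_outcome(c(0.8, 1.2, 2.0, 1.5), c(1, 0, 0, 1))
  lab <- fusesurv:::landmark_labels(y, 1.5)
  expect_equal(lab, c(1, NA, 0, 1))   # event by t*; censored before t* excluded
})

test_that("oof modality scores are leakage-free by construction", {
  co <- generate_cohort(small_cohort_spec(n = 150, seed = 41))
  y <- cohort_outcome(co)
  folds <- make_outer_folds(y, 5, seed = 1)
  mf <- oof_modality_scores(co, folds, seed = 2, nlambda = 10,
                            lambda_min_ratio = 0.05, inner_k = 3,
                            grlasso_tol = 1e-4)
  expect_identical(mf$meta$fold, folds)
  expect_false(anyNA(mf$meta[, -1]))
  expect_true(all(mf$meta$risk_clinical >= 0 & mf$meta$risk_clinical <= 1))
  expect_true(all(mf$surv$clinical >= 0 & mf$surv$clinical <= 1))
  # survival curves nonincreasing in time
  expect_true(all(apply(mf$surv$clinical, 1, function(s) all(diff(s) <= 1e-12))))
  # fold f scores reproduce from a model fit without fold f
  f <- 1L
  tr <- folds != f
  Xc <- fusesurv:::modality_matrix(co, "clinical")
  st <- fusesurv:::std_fit(Xc[tr, ])
  fit <- fit_cox(fusesurv:::std_apply(Xc[tr, ], st),
                 surv_outcome(y$time[tr], y$event[tr]))
  sc <- predict_risk_score(fit, fusesurv:::std_apply(Xc[!tr, ], st))
  expect_equal(mf$meta$score_clinical[!tr], sc, tolerance = 1e-10)
})

test_that("cox meta: informative score dominates; collinearity warns", {
  sm <- synthetic_meta(n = 2000)
  fit <- fit_cox_meta(sm$mf, sm$y)
  expect_true(all(fit$oof_risk >= 0 & fit$oof_risk <= 1))
  b <- fit$fold_fits[["1"]]$beta
  expect_gt(abs(b["score_clinical"]) / max(abs(b[-1])), 3)
  # duplicated score columns trigger the ridge fallback warning (per fold)
  mf2 <- sm$mf
  mf2$meta$score_demographic <- mf2$meta$score_clinical
  w <- capture_warnings(fit2 <- fit_cox_meta(mf2, sm$y))
  expect_true(any(grepl("collinear", w)))
  expect_true(all(is.finite(fit2$oof_score)))
})

test_that("fused discrimination is not far below the best modality", {
  sm <- synthetic_meta(n = 800)
  fit <- fit_cox_meta(sm$mf, sm$y)
  c_fused <- harrell_cindex(fit$oof_score, sm$y)
  c_best <- max(vapply(c("score_clinical", "score_demographic", "score_radiomic"),
                       function(m) harrell_cindex(sm$mf$meta[[m]], sm$y),
                       numeric(1)))
  expect_gte(c_fused, c_best - 0.02)
})

test_that("weighted average: convexity, symmetry and weight recovery", {
  sm <- synthetic_meta(n = 2000)
  # identical scores: fused equals each of them after rank transform
  mf_id <- sm$mf
  mf_id$meta$score_demographic <- mf_id$meta$score_clinical
  mf_id$meta$score_radiomic <- mf_id$meta$score_clinical
  fit_id <- fit_weighted_average(mf_id, sm$y, mode = "equal")
  tr <- mf_id$folds != 1
  rt <- fusesurv:::rank_transform(mf_id$meta$score_clinical[tr])
  expect_equal(fit_id$oof_score[!tr], rt(mf_id$meta$score_clinical[!tr]),
               tolerance = 1e-12)
  # equal-weight fusion invariant to modality order
  mf_sw <- sm$mf
  mf_sw$meta[, c("score_clinical", "score_radiomic")] <-
    mf_sw$meta[, c("score_radiomic", "score_clinical")]
  f_a <- fit_weighted_average(sm$mf, sm$y, mode = "equal")
  f_b <- fit_weighted_average(mf_sw, sm$y, mode = "equal")
  expect_equal(f_a$oof_score, f_b$oof_score, tolerance = 1e-12)
  # optimized weights load on the informative modality
  f_opt <- fit_weighted_average(sm$mf, sm$y, mode = "optimized")
  w1 <- vapply(f_opt$fold_fits, function(ff) ff$weights[1], numeric(1))
  expect_gte(mean(w1), 0.8)
})

test_that("logistic stacking: label rule, probabilities, monotonicity", {
  sm <- synthetic_meta(n = 600)
  fit <- fit_logistic_stack(sm$mf, sm$y, seed = 4)
  expect_true(all(fit$oof_risk > 0 & fit$oof_risk < 1))
  expect_true(all(is.finite(fit$oof_score)))
  # risk is monotone in the linear score
  ord <- order(fit$oof_score)
  expect_true(all(diff(fit$oof_risk[ord]) >= -1e-12))
  # tuned alpha comes from the grid
  a <- vapply(fit$fold_fits, function(ff) ff$alpha, numeric(1))
  expect_true(all(a %in% c(0, 0.25, 0.5, 0.75, 1)))
})

test_that("tree meta-learners: grid cardinalities and seeded determinism", {
  tc <- tree_meta_config()
  expect_equal(length(tc$rsf$mtry) * length(tc$rsf$node_size) *
                 length(tc$rsf$n_trees) * length(tc$rsf$n_splits), 224)
  expect_gte(tc$rsf$n_sample, 50)
  expect_equal(length(tc$gbt$max_depth) * length(tc$gbt$learning_rate), 9)
  # seeded determinism on a small problem (exercises the python bridge)
  sm <- synthetic_meta(n = 90, k = 3)
  tc2 <- small_tree_config()
  tc2$rsf$n_sample <- 3L
  f1 <- fit_tree_meta(sm$mf, sm$y, "rsf_meta", config = tc2, seed = 11)
  f2 <- fit_tree_meta(sm$mf, sm$y, "rsf_meta", config = tc2, seed = 11)
  expect_identical(f1$oof_risk, f2$oof_risk)
  expect_identical(f1$fold_fits, f2$fold_fits)
  expect_true(all(f1$oof_risk >= 0 & f1$oof_risk <= 1))
  g1 <- fit_tree_meta(sm$mf, sm$y, "xgb_meta", config = tc2, seed = 11)
  g2 <- fit_tree_meta(sm$mf, sm$y, "xgb_meta", config = tc2, seed = 11)
  expect_identical(g1$oof_risk, g2$oof_risk)
  d1 <- g1$fold_fits[["1"]]$params
  expect_true(d1$max_depth %in% tc2$gbt$max_depth)
  expect_true(d1$learning_rate %in% tc2$gbt$learning_rate)
  # missing python executable gives the installation hint
  expect_error(fit_tree_meta(sm$mf, sm$y, "rsf_meta", config = tc2,
                             python = "definitely-not-a-python"),
               "not found")
})
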