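# Group-lasso Cox: penalty arithmetic, lambda_max anchor, path solver
# correctness (KKT certification, group-aligned sparsity, warm starts),
# cross-validated selection and selection-frequency reporting.

# Standardized toy problem with two families and signal in family A.
toy_problem <- function(n = 120, seed = 1) {
  fusesurv:::with_seed(seed, {
    X <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    X <- scale(X)
    attr(X, "scaled:center") <- NULL; attr(X, "scaled:scale") <- NULL
    tt <- rexp(n, exp(X %*% c(0.5, -0.5, 0, 0, 0)))
    y <- surv_outcome(tt, rbinom(n, 1, 0.9))
    gs <- group_structure(colnames(X), c("A", "A", "B", "B", "B"))
    list(X = X, y = y, gs = gs)
  })
}

test_that("group penalty evaluates the weighted l2/l1 norm", {
  gs <- group_structure(c("a1", "a2", "b1", "b2", "b3"),
                        c("A", "A", "B", "B", "B"))
  beta <- c(3, 4, 0, 0, 0)
  expect_equal(group_penalty(numeric(5), gs, 0.7), 0)
  # 0.5 * (sqrt(2) * 5 + 0) = 2.5 sqrt(2)
  expect_equal(group_penalty(beta, gs, 0.5), 2.5 * sqrt(2), tolerance = 1e-12)
  # positive homogeneity
  b2 <- rnorm(5)
  expect_equal(group_penalty(2 * b2, gs, 0.3), 2 * group_penalty(b2, gs, 0.3),
               tolerance = 1e-12)
})

test_that("lambda_max is the exact all-zero anchor", {
  tp <- toy_problem()
  lam_max <- compute_lambda_max(tp$X, tp$y, tp$gs)
  # bisection oracle: smallest lambda on a fine grid with all-zero fit
  probe <- function(lam) {
    all(fit_grlasso_path(tp$X, tp$y, tp$gs, lambda = lam,
                         check_std = FALSE)$beta == 0)
  }
  expect_true(probe(lam_max * 1.0001))
  expect_false(probe(lam_max * 0.98))
  lo <- lam_max * 0.8; hi <- lam_max * 1.2
  for (i in 1:20) {
    mid <- (lo + hi) / 2
    if (probe(mid)) hi <- mid else lo <- mid
  }
  expect_lt(abs((lo + hi) / 2 - lam_max) / lam_max, 0.01)
})

test_that("duplicating one family leaves other families' gradients intact", {
  tp <- toy_problem()
  g0 <- neg_log_partial_likelihood(tp$X, tp$y, numeric(5))$gradient / nrow(tp$X)
  # duplicate family B; its weight becomes sqrt(2 * 3)
  X2 <- cbind(tp$X, tp$X[, 3:5])
  colnames(X2) <- c(colnames(tp$X), paste0("f", 3:5, "dup"))
  gs2 <- group_structure(colnames(X2),
                         c("A", "A", "B", "B", "B", "B", "B", "B"),
                         weights = c(A = sqrt(2), B = sqrt(6)))
  g2 <- neg_log_partial_likelihood(X2, tp$y, numeric(8))$gradient / nrow(X2)
  normA0 <- sqrt(sum(g0[1:2]^2)) / sqrt(2)
  normA2 <- sqrt(sum(g2[1:2]^2)) / sqrt(2)
  expect_equal(normA0, normA2, tolerance = 1e-12)
})

test_that("path anchors: all-zero at lambda_max, Newton Cox at lambda ~ 0", {
  tp <- toy_problem()
  lam_max <- compute_lambda_max(tp$X, tp$y, tp$gs)
  path <- fit_grlasso_path(tp$X, tp$y, tp$gs,
                           lambda = c(lam_max, lam_max / 2, 1e-9),
                           check_std = FALSE)
  expect_true(all(path$beta[, 1] == 0))
  cox <- fit_cox(tp$X, tp$y)
  expect_lt(max(abs(path$beta[, 3] - cox$beta)), 1e-4)
})

test_that("path satisfies KKT, group-aligned sparsity and warm-start identity", {
  tp <- toy_problem()
  path <- fit_grlasso_path(tp$X, tp$y, tp$gs, nlambda = 25, check_std = FALSE)
  expect_true(all(path$kkt < 1e-6))
  for (l in seq_along(path$lambda)) {
    for (fam in names(tp$gs$groups)) {
      b_g <- path$beta[tp$gs$groups[[fam]], l]
      expect_true(all(b_g == 0) || all(b_g != 0))
    }
  }
  # cold start at selected lambdas reproduces warm-started path points
  for (l in c(5L, 15L, 25L)) {
    cold <- fit_grlasso_path(tp$X, tp$y, tp$gs, lambda = path$lambda[l],
                             check_std = FALSE)
    expect_lt(max(abs(cold$beta[, 1] - path$beta[, l])), 1e-6)
  }
})

test_that("non-standardized input triggers a warning", {
  tp <- toy_problem()
  X_raw <- tp$X * 10
  expect_warning(fit_grlasso_path(X_raw, tp$y, tp$gs, nlambda = 3),
                 "standardized")
})

test_that("signal family enters the path first on a synthetic cohort", {
  co <- generate_cohort(small_cohort_spec(n = 800, seed = 19))
  y <- cohort_outcome(co)
  X <- fusesurv:::modality_matrix(co, "radiomic")
  Xs <- fusesurv:::std_apply(X, fusesurv:::std_fit(X))
  gs <- group_structure(co$taxonomy$feature, co$taxonomy$family)
  # per-family gradient norms at beta = 0 predict the first entrant
  g0 <- neg_log_partial_likelihood(Xs, y, numeric(ncol(Xs)))$gradient / nrow(Xs)
  norms <- vapply(gs$groups, function(ix) sqrt(sum(g0[ix]^2)), numeric(1)) /
    gs$weights
  expect_equal(names(which.max(norms)), "ngtdm")
  path <- fit_grlasso_path(Xs, y, gs, nlambda = 20, lambda_min_ratio = 0.05,
                           check_std = FALSE)
  first_active <- path$active[[min(which(lengths(path$active) > 0))]]
  expect_identical(first_active, "ngtdm")
})

test_that("cv_select_lambda is deterministic and stratification is enforced", {
  tp <- toy_problem()
  cv1 <- cv_select_lambda(tp$X, tp$y, tp$gs, seed = 5, nlambda = 15,
                          check_std = FALSE)
  cv2 <- cv_select_lambda(tp$X, tp$y, tp$gs, seed = 5, nlambda = 15,
                          check_std = FALSE)
  expect_identical(cv1$lambda_selected, cv2$lambda_selected)
  expect_identical(cv1$selected_features, cv2$selected_features)
  expect_equal(nrow(cv1$cv), length(cv1$lambda))
  expect_true(all(is.finite(cv1$cv$deviance)))
})

test_that("selection_frequency reports counts and zero-inclusive means", {
  coefs <- list(c(a = 1.0, b = 0, c = 0.5),
                c(a = 2.0, b = 0, c = 0),
                c(a = 3.0, b = 0, c = 0.1))
  sf <- selection_frequency(coefs)
  expect_identical(sf$feature[1], "a")
  expect_equal(sf$coefficient[sf$feature == "a"], 2)
  expect_equal(sf$selection_frequency[sf$feature == "a"], 3)
  expect_equal(sf$selection_frequency[sf$feature == "b"], 0)
  expect_equal(sf$coefficient[sf$feature == "b"], 0)
  expect_equal(sf$coefficient[sf$feature == "c"], 0.2, tolerance = 1e-12)
  expect_equal(sf$selection_frequency[sf$feature == "c"], 2)
})

test_that("sparse selection under a pure-noise design", {
  # scaled-down Monte-Carlo version of the null-selection example
  hits <- 0
  n_seeds <- 12
  for (s in seq_len(n_seeds)) {
    sp <- small_cohort_spec(n = 200, seed = 100 + s,
                            true_group_effects = list(),
                            clinical_effects = c(0, 0, 0),
                            demographic_effects = c(0, 0))
    co <- generate_cohort(sp)
    y <- cohort_outcome(co)
    X <- fusesurv:::modality_matrix(co, "radiomic")
    Xs <- fusesurv:::std_apply(X, fusesurv:::std_fit(X))
    gs <- group_structure(co$taxonomy$feature, co$taxonomy$family)
    cv <- cv_select_lambda(Xs, y, gs, seed = s, nlambda = 12,
                           lambda_min_ratio = 0.05, tol = 1e-4,
                           check_std = FALSE)
    fams <- unique(gs$assignment[cv$selected_features])
    if (length(fams) <= 1) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.8)
})
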