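# Shared fixtures: small cohorts and scaled-down configurations used to
# keep the default test run within budget; statistical properties under
# test do not depend on the scaled dimensions (see the methods vignette).

# Reduced taxonomy: 7 families x 3 features, signal confined to ngtdm.
small_family_sizes <- function() {
  stats::setNames(rep(3L, 7), names(default_family_sizes()))
}

small_cohort_spec <- function(n = 150L, seed = 1L, ...) {
  args <- list(...)
  if (!"true_group_effects" %in% names(args)) {
    args$true_group_effects <- list(ngtdm = c(-0.3, 0.3, 0.2))
  }
  do.call(cohort_spec, c(list(n_patients = n,
                              family_sizes = small_family_sizes(),
                              seed = seed), args))
}

# Tree meta-learner config scaled for tests (grids subsampled, small
# forests, inner k = 3).
small_tree_config <- function() {
  tc <- tree_meta_config(rsf_n_sample = 4L, inner_k = 3L)
  tc$rsf$n_trees <- 50L
  tc$gbt$n_estimators <- 50L
  tc
}

# A simple censored toy outcome used across metric tests.
toy_y <- function() surv_outcome(c(1, 2, 3, 4, 5, 6),
                                 c(1, 0, 1, 1, 0, 1))

# Hand-built meta-features object (bypasses the radiomic stage) for
# meta-learner tests: score_clinical carries the signal.
synthetic_meta <- function(n = 600L, seed = 42L, k = 5L,
                           informative = "score_clinical") {
  with_seed <- fusesurv:::with_seed
  with_seed(seed, {
    lp <- rnorm(n)
    tt <- 2 * (-log(runif(n)) * exp(-lp))^(1 / 1.2)
    cens <- rexp(n, 0.08)
    y <- surv_outcome(pmin(tt, cens), as.numeric(tt <= cens))
    folds <- make_outer_folds(y, k = k, seed = 7)
    meta <- data.frame(id = seq_len(n), fold = folds,
                       score_clinical = rnorm(n, sd = 0.3),
                       score_demographic = rnorm(n, sd = 0.3),
                       score_radiomic = rnorm(n, sd = 0.3))
    meta[[informative]] <- meta[[informative]] + lp
    mf <- structure(list(meta = meta, surv = NULL,
                         eval_times = c(0.5, 1, 1.5, 2),
                         t_star = 1.5, folds = folds, fold_details = NULL),
                    class = "meta_features")
    list(mf = mf, y = y, lp = lp)
  })
}
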