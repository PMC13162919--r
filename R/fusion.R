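# Nested cross-validation orchestrator: leakage-free out-of-fold modality
# risk scores (clinical Cox, demographic Cox, group-lasso radiomic
# signature) and the five late-fusion meta-learners operating on them.

#' Stratified outer folds
#'
#' Near-equal fold sizes, stratified by event status, deterministic given
#' the seed. Events and censored patients are shuffled separately and
#' dealt round-robin so both fold sizes and per-fold event counts differ
#' by at most one.
#'
#' @param y survival outcome.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids (1..k).
#' @export
make_outer_folds <- function(y, k = 5L, seed = 1L) {
  y <- as_surv_outcome(y)
  n <- nrow(y)
  if (n < 2 * k) stop("too few patients for ", k, " folds")
  with_seed(seed, {
    for (attempt in seq_len(100L)) {
      folds <- integer(n)
      idx <- c(sample(which(y$event == 1)), sample(which(y$event == 0)))
      folds[idx] <- rep_len(seq_len(k), n)
      ev_per_fold <- tapply(y$event, folds, sum)
      if (all(ev_per_fold > 0)) return(folds)
    }
    stop("could not build folds with at least one event each after 100 attempts")
  })
}

#' Events-per-variable
#'
#' @param n_events number of observed events.
#' @param n_predictors number of fitted predictors (>= 1).
#' @return n_events / n_predictors.
#' @export
compute_epv <- function(n_events, n_predictors) {
  if (n_predictors < 1) stop("EPV undefined for zero predictors")
  n_events / n_predictors
}

#' Out-of-fold modality risk scores
#'
#' For each outer fold: standardizes predictors with training-fold
#' statistics only; fits the clinical Cox (overall/T/N stage), the
#' demographic Cox (age, gender) and the radiomic model (group-lasso
#' penalized Cox with inner cross-validated penalty selection, then an
#' unpenalized refit on the selected features) on training data only; and
#' emits held-out linear predictors, absolute risks at `t_star` and
#' survival curves on `eval_times`, all using training-fold Breslow
#' baselines.
#'
#' @param cohort a `cohort` (or the output of [read_cohort()]).
#' @param folds outer fold assignment from [make_outer_folds()].
#' @param t_star landmark horizon (years).
#' @param eval_times survival-curve grid; default from [default_eval_times()].
#' @param inner_k inner folds for penalty selection.
#' @param seed base seed for inner-fold assignment.
#' @param nlambda,lambda_min_ratio,lambda_1se group-lasso path controls.
#' @param grlasso_tol KKT tolerance for the radiomic-stage path fits.
#' @return List of class `meta_features`: `meta` (data.frame: id, fold,
#'   score_/risk_ per modality), `surv` (list of patients x times
#'   matrices), `eval_times`, `folds`, `fold_details` (per fold: selected
#'   features, penalized coefficients at the selected lambda, refit).
#' @export
oof_modality_scores <- function(cohort, folds, t_star = 1.5,
                                eval_times = NULL, inner_k = 5L, seed = 1L,
                                nlambda = 100L, lambda_min_ratio = 0.001,
                                lambda_1se = FALSE, grlasso_tol = 1e-6) {
  y <- cohort_outcome(cohort)
  n <- nrow(y)
  if (is.null(eval_times)) eval_times <- default_eval_times(y)$times
  mods <- c("clinical", "demographic", "radiomic")
  X_all <- lapply(stats::setNames(mods, mods),
                  function(m) modality_matrix(cohort, m))
  gs <- group_structure(cohort$taxonomy$feature, cohort$taxonomy$family)
  meta <- data.frame(id = cohort$data$id, fold = folds)
  for (m in mods) {
    meta[[paste0("score_", m)]] <- NA_real_
    meta[[paste0("risk_", m)]] <- NA_real_
  }
  surv <- lapply(stats::setNames(mods, mods),
                 function(m) matrix(NA_real_, n, length(eval_times)))
  fold_details <- list()
  for (f in sort(unique(folds))) {
    tr <- folds != f
    te <- !tr
    y_tr <- surv_outcome(y$time[tr], y$event[tr])
    details <- list()
    for (m in c("clinical", "demographic")) {
      st <- std_fit(X_all[[m]][tr, , drop = FALSE])
      fit <- fit_cox(std_apply(X_all[[m]][tr, , drop = FALSE], st), y_tr)
      Xte <- std_apply(X_all[[m]][te, , drop = FALSE], st)
      meta[[paste0("score_", m)]][te] <- predict_risk_score(fit, Xte)
      meta[[paste0("risk_", m)]][te] <- predict_absolute_risk(fit, Xte, t_star)$risk
      surv[[m]][te, ] <- predict_survival_matrix(fit, Xte, eval_times)
      details[[m]] <- fit
    }
    # Radiomic stage: inner-CV group lasso + unpenalized refit on the
    # selected features (low-dimensional final model).
    st <- std_fit(X_all$radiomic[tr, , drop = FALSE])
    Xtr <- std_apply(X_all$radiomic[tr, , drop = FALSE], st)
    Xte <- std_apply(X_all$radiomic[te, , drop = FALSE], st)
    cvp <- cv_select_lambda(Xtr, y_tr, gs, k_folds = inner_k,
                            seed = child_seed(seed, f),
                            lambda_1se = lambda_1se, nlambda = nlambda,
                            lambda_min_ratio = lambda_min_ratio,
                            tol = grlasso_tol, check_std = FALSE)
    sel <- cvp$selected_features
    refit <- fit_cox(Xtr[, sel, drop = FALSE], y_tr)
    meta$score_radiomic[te] <- predict_risk_score(refit, Xte[, sel, drop = FALSE])
    meta$risk_radiomic[te] <-
      predict_absolute_risk(refit, Xte[, sel, drop = FALSE], t_star)$risk
    surv$radiomic[te, ] <-
      predict_survival_matrix(refit, Xte[, sel, drop = FALSE], eval_times)
    details$radiomic <- list(
      lambda_selected = cvp$lambda_selected,
      selected_features = sel,
      penalized_coef = cvp$beta[, cvp$selected_index],
      refit = refit)
    fold_details[[as.character(f)]] <- details
  }
  structure(list(meta = meta, surv = surv, eval_times = eval_times,
                 t_star = t_star, folds = folds,
                 fold_details = fold_details),
            class = "meta_features")
}

meta_score_matrix <- function(meta) {
  as.matrix(meta[, c("score_clinical", "score_demographic", "score_radiomic")])
}

# Iterate train/test index pairs: the outer folds, or a single in-sample
# pass (train = test = everyone) for whole-dataset evaluation.
fold_sets <- function(mf) {
  n <- nrow(mf$meta)
  if (isTRUE(mf$insample)) {
    return(list(list(f = 0L, tr = rep(TRUE, n), te = rep(TRUE, n))))
  }
  lapply(sort(unique(mf$folds)), function(f) {
    list(f = f, tr = mf$folds != f, te = mf$folds == f)
  })
}

#' Reuse modality scores as in-sample meta-features
#'
#' Marks a `meta_features` object for whole-dataset (in-sample) fusion:
#' the meta-learners train on all patients and predict for all patients.
#' Used for the full-data performance columns, never for cross-validated
#' metrics.
#' @param mf a `meta_features` object.
#' @return The marked object.
#' @export
as_insample_meta <- function(mf) {
  mf$insample <- TRUE
  mf
}

# Shared output shape for every fusion model.
fusion_result <- function(kind, score, risk, surv, fold_fits, t_star) {
  structure(list(kind = kind, oof_score = score, oof_risk = risk,
                 oof_surv = surv, fold_fits = fold_fits, t_star = t_star),
            class = "fusion_fit")
}

# Calibrate an arbitrary risk score into absolute risk / survival curves
# through a one-parameter Cox fit on the training fold.
calibrate_score <- function(score_tr, y_tr, score_te, t_star, eval_times) {
  if (stats::sd(score_tr) < 1e-10) {
    # degenerate (constant) score: fall back to the null baseline model
    fit <- fit_cox(matrix(numeric(0), nrow = length(score_tr), ncol = 0), y_tr)
    Xte <- matrix(numeric(0), nrow = length(score_te), ncol = 0)
    return(list(risk = predict_absolute_risk(fit, Xte, t_star)$risk,
                surv = predict_survival_matrix(fit, Xte, eval_times),
                fit = fit))
  }
  fit <- fit_cox(matrix(score_tr, ncol = 1, dimnames = list(NULL, "score")), y_tr)
  list(risk = predict_absolute_risk(fit, cbind(score = score_te), t_star)$risk,
       surv = predict_survival_matrix(fit, cbind(score = score_te), eval_times),
       fit = fit)
}

#' Cox fusion meta-learner
#'
#' Per outer fold, fits a Cox model (via the package's own engine) on the
#' three out-of-fold modality risk scores of the training patients and
#' emits fused out-of-fold scores, absolute risks at the landmark and
#' survival curves for the held-out patients. Rank-deficient (collinear)
#' score matrices fall back to a tiny ridge penalty with a warning.
#'
#' @param mf a `meta_features` object.
#' @param y survival outcome.
#' @return A `fusion_fit`.
#' @export
fit_cox_meta <- function(mf, y) {
  y <- as_surv_outcome(y)
  S <- meta_score_matrix(mf$meta)
  n <- nrow(S)
  score <- risk <- rep(NA_real_, n)
  surv <- matrix(NA_real_, n, length(mf$eval_times))
  fits <- list()
  for (fs in fold_sets(mf)) {
    f <- fs$f; tr <- fs$tr; te <- fs$te
    y_tr <- surv_outcome(y$time[tr], y$event[tr])
    Xtr <- S[tr, , drop = FALSE]
    keep <- apply(Xtr, 2, stats::sd) > 1e-10
    Xtr <- Xtr[, keep, drop = FALSE]
    ridge <- 0
    if (ncol(Xtr) > 0 && qr(Xtr)$rank < ncol(Xtr)) {
      warning("collinear modality scores in fold ", f, "; ridge fallback (1e-6)")
      ridge <- 1e-6
    }
    fit <- tryCatch(fit_cox(Xtr, y_tr, ridge = ridge), error = function(e) {
      warning("Cox meta fit failed in fold ", f, " (", conditionMessage(e),
              "); ridge fallback (1e-6)")
      fit_cox(Xtr, y_tr, ridge = 1e-6)
    })
    Xte <- S[te, keep, drop = FALSE]
    score[te] <- predict_risk_score(fit, Xte)
    risk[te] <- predict_absolute_risk(fit, Xte, mf$t_star)$risk
    surv[te, ] <- predict_survival_matrix(fit, Xte, mf$eval_times)
    fits[[as.character(f)]] <- fit
  }
  fusion_result("cox_meta", score, risk, surv, fits, mf$t_star)
}

# Simplex grid (resolution `step`) of nonnegative weight triples summing to 1.
simplex_grid <- function(step = 0.05) {
  g <- seq(0, 1, by = step)
  out <- expand.grid(w1 = g, w2 = g)
  out$w3 <- 1 - out$w1 - out$w2
  out[out$w3 > -1e-9, , drop = FALSE]
}

#' Weighted-averaging fusion
#'
#' Modality scores are rank-transformed to [0, 1] with training-fold
#' statistics (raw linear predictors live on modality-specific scales),
#' then averaged with equal weights or with simplex-grid weights
#' (resolution 0.05) maximizing the training-fold Harrell C-index. The
#' fused score is calibrated into absolute risk through a one-parameter
#' Cox fit on the training fold.
#'
#' @param mf a `meta_features` object.
#' @param y survival outcome.
#' @param mode "equal" or "optimized".
#' @return A `fusion_fit` (with per-fold `weights` in `fold_fits`).
#' @export
fit_weighted_average <- function(mf, y, mode = c("optimized", "equal")) {
  mode <- match.arg(mode)
  y <- as_surv_outcome(y)
  S <- meta_score_matrix(mf$meta)
  n <- nrow(S)
  score <- risk <- rep(NA_real_, n)
  surv <- matrix(NA_real_, n, length(mf$eval_times))
  fits <- list()
  grid <- simplex_grid(0.05)
  for (fs in fold_sets(mf)) {
    f <- fs$f; tr <- fs$tr; te <- fs$te
    y_tr <- surv_outcome(y$time[tr], y$event[tr])
    transforms <- lapply(seq_len(ncol(S)), function(j) rank_transform(S[tr, j]))
    R_tr <- vapply(seq_len(ncol(S)), function(j) transforms[[j]](S[tr, j]),
                   numeric(sum(tr)))
    R_te <- vapply(seq_len(ncol(S)), function(j) transforms[[j]](S[te, j]),
                   numeric(sum(te)))
    if (mode == "equal") {
      w <- rep(1 / 3, 3)
    } else {
      cs <- vapply(seq_len(nrow(grid)), function(i) {
        harrell_cindex(as.numeric(R_tr %*% unlist(grid[i, ])), y_tr)
      }, numeric(1))
      best <- which(cs >= max(cs) - 1e-12)
      # tie-break: closest to equal weights
      d <- rowSums((grid[best, , drop = FALSE] - 1 / 3)^2)
      w <- unlist(grid[best[which.min(d)], ])
    }
    s_tr <- as.numeric(R_tr %*% w)
    s_te <- as.numeric(R_te %*% w)
    cal <- calibrate_score(s_tr, y_tr, s_te, mf$t_star, mf$eval_times)
    score[te] <- s_te
    risk[te] <- cal$risk
    surv[te, ] <- cal$surv
    fits[[as.character(f)]] <- list(weights = w, calibration = cal$fit)
  }
  fusion_result(paste0("weighted_average_", mode), score, risk, surv, fits,
                mf$t_star)
}

# Landmark binary labels: 1 = event by t_star, 0 = under observation past
# t_star; NA = censored before t_star (excluded from meta-training).
landmark_labels <- function(y, t_star) {
  y <- as_surv_outcome(y)
  ifelse(y$time > t_star, 0,
         ifelse(y$event == 1, 1, NA_real_))
}

#' Elastic-net logistic stacking
#'
#' Transforms the outcome into the binary endpoint "event by `t_star`"
#' (patients censored before the horizon are excluded from meta-training
#' but still scored), then fits an elastic-net penalized logistic
#' regression on the three modality scores, tuning the mixing parameter
#' alpha over `alpha_grid` and the penalty strength by inner
#' cross-validation on the binomial deviance (log-loss). The predicted
#' event probability is the fused absolute risk at `t_star`; survival
#' curves come from a one-parameter Cox calibration of the linear score.
#'
#' @param mf a `meta_features` object.
#' @param y survival outcome.
#' @param alpha_grid elastic-net mixing grid.
#' @param inner_k inner folds for glmnet CV.
#' @param seed inner fold seed.
#' @return A `fusion_fit`.
#' @export
fit_logistic_stack <- function(mf, y, alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                               inner_k = 5L, seed = 1L) {
  y <- as_surv_outcome(y)
  S <- meta_score_matrix(mf$meta)
  n <- nrow(S)
  score <- risk <- rep(NA_real_, n)
  surv <- matrix(NA_real_, n, length(mf$eval_times))
  fits <- list()
  for (fs in fold_sets(mf)) {
    f <- fs$f; tr <- fs$tr; te <- fs$te
    lab <- landmark_labels(surv_outcome(y$time[tr], y$event[tr]), mf$t_star)
    use <- !is.na(lab)
    lab_use <- lab[use]
    if (length(unique(lab_use)) < 2) {
      stop("logistic stacking fold ", f, ": all labels identical at t* = ",
           mf$t_star)
    }
    Xtr <- S[tr, , drop = FALSE][use, , drop = FALSE]
    # Stratified inner foldid shared across the alpha grid.
    foldid <- integer(length(lab_use))
    foldid[with_seed(child_seed(seed, f), {
      c(sample(which(lab_use == 1)), sample(which(lab_use == 0)))
    })] <- rep_len(seq_len(inner_k), length(lab_use))
    cvs <- lapply(alpha_grid, function(a) {
      glmnet::cv.glmnet(Xtr, lab_use, family = "binomial", alpha = a,
                        foldid = foldid, type.measure = "deviance")
    })
    best_dev <- vapply(cvs, function(cv) min(cv$cvm), numeric(1))
    i_best <- which.min(best_dev)
    cv_best <- cvs[[i_best]]
    lin_te <- as.numeric(stats::predict(cv_best, newx = S[te, , drop = FALSE],
                                        s = "lambda.min", type = "link"))
    lin_tr_all <- as.numeric(stats::predict(cv_best,
                                            newx = S[tr, , drop = FALSE],
                                            s = "lambda.min", type = "link"))
    risk[te] <- stats::plogis(lin_te)
    score[te] <- lin_te
    y_tr <- surv_outcome(y$time[tr], y$event[tr])
    cal <- calibrate_score(lin_tr_all, y_tr, lin_te, mf$t_star, mf$eval_times)
    surv[te, ] <- cal$surv
    fits[[as.character(f)]] <- list(alpha = alpha_grid[i_best],
                                    lambda = cv_best$lambda.min,
                                    glmnet = cv_best, calibration = cal$fit)
  }
  fusion_result("logistic_stack", score, risk, surv, fits, mf$t_star)
}

#' Default tree-meta-learner tuning grids
#'
#' The random-survival-forest grid (mtry 1-2; node size 5-30; 500-1500
#' trees; 1-10 split candidates: 224 configurations, of which
#' `rsf_n_sample` are drawn at random without replacement) and the
#' gradient-boosted-tree grid (max depth 1-3 x learning rate
#' 0.03/0.05/0.1, searched exhaustively).
#'
#' @param rsf_n_sample random-search draw size (>= 50 by default).
#' @param inner_k inner CV folds for tuning.
#' @return List with `rsf` and `gbt` grid definitions.
#' @export
tree_meta_config <- function(rsf_n_sample = 60L, inner_k = 5L) {
  list(
    rsf = list(mtry = c(1L, 2L),
               node_size = c(5L, 8L, 10L, 15L, 20L, 25L, 30L),
               n_trees = c(500L, 750L, 1000L, 1500L),
               n_splits = c(1L, 3L, 5L, 10L),
               n_sample = as.integer(rsf_n_sample)),
    gbt = list(max_depth = c(1L, 2L, 3L),
               learning_rate = c(0.03, 0.05, 0.1),
               n_estimators = 100L),
    inner_k = as.integer(inner_k))
}

# Locate the shipped python helper.
tree_meta_script <- function() {
  p <- system.file("python", "tree_meta.py", package = "fusesurv")
  if (!nzchar(p)) {
    p <- file.path("inst", "python", "tree_meta.py")
  }
  if (!file.exists(p)) stop("tree_meta.py helper not found")
  p
}

#' Tree-based fusion meta-learners (random survival forest / boosted trees)
#'
#' Calls the external tree learners (scikit-survival's random survival
#' forest; a gradient-boosted tree classifier on the binary event-by-t*
#' endpoint) through the shipped Python helper. Everything around the two
#' base learners - fold bookkeeping, tuning protocol, calibration,
#' evaluation - is owned code. Hyperparameters are tuned per outer fold by
#' inner cross-validation: RSF by seeded random search over the printed
#' grid (selected by C-index), boosted trees by exhaustive depth x
#' learning-rate search (selected by log-loss).
#'
#' @param mf a `meta_features` object.
#' @param y survival outcome.
#' @param kind "rsf_meta" or "xgb_meta".
#' @param config grids from [tree_meta_config()].
#' @param seed tuning/search seed.
#' @param python python executable.
#' @return A `fusion_fit` (selected hyperparameters in `fold_fits`).
#' @export
fit_tree_meta <- function(mf, y, kind = c("rsf_meta", "xgb_meta"),
                          config = tree_meta_config(), seed = 1L,
                          python = Sys.getenv("FUSESURV_PYTHON", "python")) {
  kind <- match.arg(kind)
  y <- as_surv_outcome(y)
  if (Sys.which(python) == "" && !file.exists(python)) {
    stop("python executable '", python, "' not found; install Python with ",
         "scikit-survival and scikit-learn (e.g. via conda) to use the ",
         "tree-based meta-learners")
  }
  S <- meta_score_matrix(mf$meta)
  dat <- data.frame(time = y$time, event = y$event,
                    score_clinical = S[, 1], score_demographic = S[, 2],
                    score_radiomic = S[, 3],
                    fold = if (isTRUE(mf$insample)) 0L else mf$folds)
  td <- tempfile("treemeta")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  data_path <- file.path(td, "data.csv")
  cfg_path <- file.path(td, "config.json")
  out_path <- file.path(td, "out.json")
  utils::write.csv(dat, data_path, row.names = FALSE)
  cfg <- list(kind = if (kind == "rsf_meta") "rsf" else "gbt",
              insample = isTRUE(mf$insample),
              t_star = mf$t_star, seed = as.integer(seed),
              eval_times = mf$eval_times,
              inner_k = config$inner_k,
              rsf = config$rsf, gbt = config$gbt)
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  res <- suppressWarnings(system2(python, c(tree_meta_script(),
                                            "--data", data_path,
                                            "--config", cfg_path,
                                            "--out", out_path),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    if (!is.null(status) && status == 3) {
      stop("tree meta-learner unavailable: ", paste(res, collapse = "\n"),
           "\nInstall scikit-survival/scikit-learn in the python environment.")
    }
    stop("tree_meta.py failed (exit ", status, "):\n",
         paste(res, collapse = "\n"))
  }
  out <- jsonlite::read_json(out_path, simplifyVector = FALSE)
  n <- nrow(S)
  score <- risk <- rep(NA_real_, n)
  surv <- matrix(NA_real_, n, length(mf$eval_times))
  fits <- list()
  for (el in out$folds) {
    f <- el$fold
    if (isTRUE(mf$insample)) {
      tr <- rep(TRUE, n); te <- rep(TRUE, n)
    } else {
      tr <- mf$folds != f; te <- !tr
    }
    pred_all <- unlist(el$pred_all)
    risk[te] <- pred_all[te]
    # Monotone score on the log scale; clamp away from {0, 1}.
    sc_all <- stats::qlogis(pmin(pmax(pred_all, 1e-12), 1 - 1e-12))
    score[te] <- sc_all[te]
    if (!is.null(el$surv_test)) {
      surv[te, ] <- do.call(rbind, lapply(el$surv_test, unlist))
    } else {
      y_tr <- surv_outcome(y$time[tr], y$event[tr])
      cal <- calibrate_score(sc_all[tr], y_tr, sc_all[te], mf$t_star,
                             mf$eval_times)
      surv[te, ] <- cal$surv
    }
    fits[[as.character(f)]] <- list(params = el$params)
  }
  fusion_result(kind, score, risk, surv, fits, mf$t_star)
}
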