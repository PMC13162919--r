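# End-to-end pipeline driver: configuration, cohort I/O, model registry,
# stratification and the tabular report bundle.

validation_error <- function(...) {
  stop(structure(class = c("fusesurv_validation", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Pipeline run configuration
#'
#' Exactly one of `spec` (a [cohort_spec()] for simulation) or
#' `cohort_path`+`taxonomy_path` (CSV input) must be given.
#'
#' @param spec optional [cohort_spec()].
#' @param cohort_path,taxonomy_path optional input CSVs (see [read_cohort()]).
#' @param out_dir output directory for the report bundle.
#' @param t_star landmark horizon in years.
#' @param k_folds outer folds.
#' @param seed master seed; all stage seeds derive from it.
#' @param models which models to run (subset of the registry).
#' @param weighted_mode weighting mode for the weighted-average fusion.
#' @param alpha_grid elastic-net mixing grid for logistic stacking.
#' @param nlambda,lambda_min_ratio,lambda_1se,inner_k,grlasso_tol
#'   group-lasso controls.
#' @param tree_config grids from [tree_meta_config()].
#' @param min_frac,search_range,cut_step stratification constraints.
#' @param n_boot bootstrap resamples for metric intervals (0 = none).
#' @param python python executable for the tree meta-learners.
#' @return Object of class `run_config`.
#' @export
run_config <- function(spec = NULL, cohort_path = NULL, taxonomy_path = NULL,
                       out_dir = NULL, t_star = 1.5, k_folds = 5L, seed = 1L,
                       models = c("radiomics", "clinical", "demographics",
                                  "cox_meta", "weighted_average",
                                  "logistic_stack", "rsf_meta", "xgb_meta"),
                       weighted_mode = "optimized",
                       alpha_grid = c(0, 0.25, 0.5, 0.75, 1),
                       nlambda = 100L, lambda_min_ratio = 0.001,
                       lambda_1se = FALSE, inner_k = 5L, grlasso_tol = 1e-6,
                       tree_config = tree_meta_config(),
                       min_frac = 0.15, search_range = c(0.15, 0.85),
                       cut_step = 0.025, n_boot = 0L,
                       python = Sys.getenv("FUSESURV_PYTHON", "python")) {
  has_spec <- !is.null(spec)
  has_paths <- !is.null(cohort_path) || !is.null(taxonomy_path)
  if (has_spec == has_paths) {
    validation_error("exactly one of a simulation spec or input paths must be given")
  }
  if (has_paths) {
    if (is.null(cohort_path) || is.null(taxonomy_path)) {
      validation_error("both cohort_path and taxonomy_path are required")
    }
    for (p in c(cohort_path, taxonomy_path)) {
      if (!file.exists(p)) validation_error("input file not found: ", p)
    }
  }
  if (t_star <= 0) validation_error("t_star must be positive")
  known <- c("radiomics", "clinical", "demographics", "cox_meta",
             "weighted_average", "logistic_stack", "rsf_meta", "xgb_meta")
  bad <- setdiff(models, known)
  if (length(bad)) validation_error("unknown models: ", paste(bad, collapse = ", "))
  structure(list(spec = spec, cohort_path = cohort_path,
                 taxonomy_path = taxonomy_path, out_dir = out_dir,
                 t_star = t_star, k_folds = as.integer(k_folds),
                 seed = as.integer(seed), models = models,
                 weighted_mode = weighted_mode, alpha_grid = alpha_grid,
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 lambda_1se = lambda_1se, inner_k = as.integer(inner_k),
                 grlasso_tol = grlasso_tol,
                 tree_config = tree_config, min_frac = min_frac,
                 search_range = search_range, cut_step = cut_step,
                 n_boot = as.integer(n_boot), python = python),
            class = "run_config")
}

#' Read a cohort from CSV
#'
#' Validates the required columns (id, time_years, event, age, gender,
#' overall_stage, t_stage, n_stage, feature columns), normalizes the
#' categorical stages, drops rows with missing values (logging the count)
#' and checks every feature column against the taxonomy.
#'
#' @param cohort_path patient-level CSV.
#' @param taxonomy_path two-column CSV (feature, family).
#' @return A `cohort` object (without generative truth).
#' @export
read_cohort <- function(cohort_path, taxonomy_path) {
  d <- utils::read.csv(cohort_path, stringsAsFactors = FALSE)
  tax <- utils::read.csv(taxonomy_path, stringsAsFactors = FALSE)
  required <- c("id", "time_years", "event", "age", "gender",
                "overall_stage", "t_stage", "n_stage")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    validation_error("missing required column(s): ",
                     paste(missing_cols, collapse = ", "))
  }
  if (!all(c("feature", "family") %in% names(tax))) {
    validation_error("taxonomy must have columns 'feature' and 'family'")
  }
  extra <- setdiff(names(d), c(required, "tumor_count"))
  not_in_tax <- setdiff(extra, tax$feature)
  if (length(not_in_tax)) {
    validation_error("feature column(s) absent from the taxonomy: ",
                     paste(utils::head(not_in_tax, 5), collapse = ", "))
  }
  not_in_data <- setdiff(tax$feature, names(d))
  if (length(not_in_data)) {
    validation_error("taxonomy feature(s) absent from the data: ",
                     paste(utils::head(not_in_data, 5), collapse = ", "))
  }
  complete <- stats::complete.cases(d)
  n_drop <- sum(!complete)
  if (n_drop > 0) {
    message("read_cohort: dropped ", n_drop, " row(s) with missing values")
    d <- d[complete, , drop = FALSE]
  }
  d$overall_stage <- toupper(trimws(as.character(d$overall_stage)))
  stage_map <- c("1" = "I", "2" = "II", "3" = "III")
  num_like <- d$overall_stage %in% names(stage_map)
  d$overall_stage[num_like] <- stage_map[d$overall_stage[num_like]]
  # IIIa/IIIb style sub-stages collapse to III
  d$overall_stage[startsWith(d$overall_stage, "III")] <- "III"
  if (!all(d$overall_stage %in% c("I", "II", "III"))) {
    validation_error("overall_stage values outside {I, II, III}")
  }
  d$gender <- tolower(trimws(as.character(d$gender)))
  if (!all(d$gender %in% c("male", "female"))) {
    validation_error("gender values outside {male, female}")
  }
  y <- surv_outcome(d$time_years, d$event)  # validates positivity/coding
  structure(list(data = d, taxonomy = tax, truth = NULL, spec = NULL,
                 n_dropped = n_drop, outcome = y),
            class = "cohort")
}

# Deterministic log lines (timings go to stderr via message()).
log_line <- function(log_env, ...) {
  log_env$lines <- c(log_env$lines, paste0(...))
}

#' Run the full late-fusion pipeline
#'
#' simulate/read -> outer folds -> group-lasso radiomic stage ->
#' out-of-fold modality scores -> fusion models and unimodal baselines ->
#' fold-averaged risk stratification -> metrics -> tabular report bundle.
#' With a fixed seed the written bundle is byte-identical across runs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with every computed object and table; tables
#'   are written as CSVs under `config$out_dir` when it is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_env <- new.env()
  log_env$lines <- character(0)
  stage <- function(name, code) {
    t0 <- Sys.time()
    out <- tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[fusesurv] %-22s %6.2f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    log_line(log_env, "stage: ", name)
    out
  }
  log_line(log_env, "fusesurv pipeline, seed ", config$seed,
           ", t* = ", config$t_star, ", folds = ", config$k_folds)

  cohort <- stage("cohort", {
    if (!is.null(config$spec)) generate_cohort(config$spec)
    else read_cohort(config$cohort_path, config$taxonomy_path)
  })
  y <- cohort_outcome(cohort)
  n <- nrow(y)
  grid <- default_eval_times(y)
  log_line(log_env, "patients: ", n, ", events: ", sum(y$event),
           ", tau: ", format(grid$tau, digits = 6))

  folds <- stage("outer folds",
                 make_outer_folds(y, k = config$k_folds,
                                  seed = child_seed(config$seed, 1)))

  mf <- stage("oof modality scores", oof_modality_scores(
    cohort, folds, t_star = config$t_star, eval_times = grid$times,
    inner_k = config$inner_k, seed = child_seed(config$seed, 2),
    nlambda = config$nlambda, lambda_min_ratio = config$lambda_min_ratio,
    lambda_1se = config$lambda_1se, grlasso_tol = config$grlasso_tol))

  # Whole-data unimodal fits (in-sample), reused as meta input for the
  # whole-data fusion variants.
  full <- stage("whole-data unimodal", full_data_modalities(
    cohort, y, t_star = config$t_star, eval_times = grid$times,
    inner_k = config$inner_k, seed = child_seed(config$seed, 3),
    nlambda = config$nlambda, lambda_min_ratio = config$lambda_min_ratio,
    lambda_1se = config$lambda_1se, grlasso_tol = config$grlasso_tol))

  models <- config$models
  cv_fits <- list()
  full_fits <- list()
  unimodal_map <- c(radiomics = "radiomic", clinical = "clinical",
                    demographics = "demographic")
  for (m in intersect(models, names(unimodal_map))) {
    mod <- unimodal_map[[m]]
    cv_fits[[m]] <- fusion_result(
      m, mf$meta[[paste0("score_", mod)]], mf$meta[[paste0("risk_", mod)]],
      mf$surv[[mod]], NULL, config$t_star)
    full_fits[[m]] <- fusion_result(
      m, full$mf$meta[[paste0("score_", mod)]],
      full$mf$meta[[paste0("risk_", mod)]],
      full$mf$surv[[mod]], NULL, config$t_star)
  }
  fusion_kinds <- setdiff(models, names(unimodal_map))
  mf_full <- as_insample_meta(full$mf)
  for (m in fusion_kinds) {
    cv_fits[[m]] <- stage(paste0("fusion cv: ", m),
                          fit_fusion_model(m, mf, y, config))
    full_fits[[m]] <- stage(paste0("fusion full: ", m),
                            fit_fusion_model(m, mf_full, y, config))
  }

  strat <- stage("stratification", {
    out <- list()
    for (m in models) {
      out[[m]] <- tryCatch(
        fold_averaged_stratification(
          cv_fits[[m]]$oof_risk, folds, y, min_frac = config$min_frac,
          search_range = config$search_range, step = config$cut_step),
        error = function(e) {
          warning("stratification degenerate for model '", m, "': ",
                  conditionMessage(e))
          NULL
        })
    }
    out
  })

  metrics <- stage("metrics", {
    out <- list()
    for (m in models) {
      out[[m]] <- list(
        cv = evaluate_model(cv_fits[[m]]$oof_score, cv_fits[[m]]$oof_surv, y,
                            times = grid$times, tau = grid$tau,
                            n_boot = config$n_boot,
                            seed = child_seed(config$seed, 4)),
        full = evaluate_model(full_fits[[m]]$oof_score,
                              full_fits[[m]]$oof_surv, y,
                              times = grid$times, tau = grid$tau))
    }
    out
  })

  calib <- stage("calibration", {
    out <- list()
    for (m in models) {
      out[[m]] <- if (is.null(strat[[m]])) NULL else tryCatch(
        calibration_groups(cv_fits[[m]]$oof_risk, strat[[m]]$groups, y,
                           config$t_star),
        error = function(e) NULL)
    }
    out
  })

  tables <- stage("report tables", build_report_tables(
    cohort, y, folds, mf, full, cv_fits, full_fits, strat, metrics, calib,
    config, grid))

  if (!is.null(config$out_dir)) {
    stage("write bundle", write_report_bundle(tables, log_env, config$out_dir))
  }

  invisible(list(cohort = cohort, folds = folds, meta_features = mf,
                 full_data = full, cv_fits = cv_fits, full_fits = full_fits,
                 stratification = strat, metrics = metrics,
                 calibration = calib, tables = tables,
                 eval_times = grid$times, tau = grid$tau, config = config))
}

# Whole-data (in-sample) unimodal fits packaged as a meta_features object.
full_data_modalities <- function(cohort, y, t_star, eval_times, inner_k, seed,
                                 nlambda, lambda_min_ratio, lambda_1se,
                                 grlasso_tol = 1e-6) {
  n <- nrow(y)
  mods <- c("clinical", "demographic", "radiomic")
  meta <- data.frame(id = cohort$data$id, fold = rep(1L, n))
  surv <- list()
  details <- list()
  gs <- group_structure(cohort$taxonomy$feature, cohort$taxonomy$family)
  for (m in mods) {
    X <- modality_matrix(cohort, m)
    st <- std_fit(X)
    Xs <- std_apply(X, st)
    if (m == "radiomic") {
      cvp <- cv_select_lambda(Xs, y, gs, k_folds = inner_k, seed = seed,
                              lambda_1se = lambda_1se, nlambda = nlambda,
                              lambda_min_ratio = lambda_min_ratio,
                              tol = grlasso_tol, check_std = FALSE)
      sel <- cvp$selected_features
      fit <- fit_cox(Xs[, sel, drop = FALSE], y)
      Xs <- Xs[, sel, drop = FALSE]
      details$radiomic <- list(cv = cvp, selected_features = sel, refit = fit)
    } else {
      fit <- fit_cox(Xs, y)
      details[[m]] <- fit
    }
    meta[[paste0("score_", m)]] <- predict_risk_score(fit, Xs)
    meta[[paste0("risk_", m)]] <- predict_absolute_risk(fit, Xs, t_star)$risk
    surv[[m]] <- predict_survival_matrix(fit, Xs, eval_times)
  }
  mf <- structure(list(meta = meta, surv = surv, eval_times = eval_times,
                       t_star = t_star, folds = rep(1L, n),
                       fold_details = NULL),
                  class = "meta_features")
  list(mf = mf, details = details)
}

# Dispatch a fusion meta-learner by registry name.
fit_fusion_model <- function(kind, mf, y, config) {
  switch(kind,
    cox_meta = fit_cox_meta(mf, y),
    weighted_average = fit_weighted_average(mf, y, mode = config$weighted_mode),
    logistic_stack = fit_logistic_stack(mf, y, alpha_grid = config$alpha_grid,
                                        inner_k = 5L,
                                        seed = child_seed(config$seed, 11)),
    rsf_meta = fit_tree_meta(mf, y, "rsf_meta", config = config$tree_config,
                             seed = child_seed(config$seed, 12),
                             python = config$python),
    xgb_meta = fit_tree_meta(mf, y, "xgb_meta", config = config$tree_config,
                             seed = child_seed(config$seed, 13),
                             python = config$python),
    stop("unknown fusion model: ", kind))
}

model_label <- function(m) {
  c(radiomics = "Radiomics (Cox)", clinical = "Clinical (Cox)",
    demographics = "Demographics (Cox)", cox_meta = "Cox Fusion/Meta",
    weighted_average = "Weighted Average", logistic_stack = "Logistic Stack",
    rsf_meta = "RSF Fusion/Meta", xgb_meta = "XGB Stack")[[m]]
}

build_report_tables <- function(cohort, y, folds, mf, full, cv_fits,
                                full_fits, strat, metrics, calib, config,
                                grid) {
  models <- config$models
  num <- function(x) round(x, 6)

  performance <- do.call(rbind, lapply(models, function(m) {
    data.frame(model = model_label(m),
               c_index_full = num(metrics[[m]]$full$c_index),
               auc_full = num(metrics[[m]]$full$auc_mean),
               ibs_full = num(metrics[[m]]$full$ibs),
               c_index_cv = num(metrics[[m]]$cv$c_index),
               auc_cv = num(metrics[[m]]$cv$auc_mean),
               ibs_cv = num(metrics[[m]]$cv$ibs))
  }))

  sel_freq <- if (!is.null(mf$fold_details)) {
    coefs <- lapply(mf$fold_details, function(d) d$radiomic$penalized_coef)
    sf <- selection_frequency(coefs)
    sf$coefficient <- num(sf$coefficient)
    sf
  } else NULL

  n_events <- sum(y$event)
  n_radiomic <- if (!is.null(full$details$radiomic)) {
    max(1L, length(full$details$radiomic$selected_features))
  } else NA_integer_
  epv_rows <- list(
    c("Radiomics Cox", "Selected radiomic features", n_radiomic),
    c("Clinical Cox", "Overall stage, T stage, N stage", 3L),
    c("Demographic Cox", "Age, Gender", 2L),
    c("Fusion Models",
      "Radiomics risk score, Clinical risk score, Demographic risk score", 3L))
  epv <- do.call(rbind, lapply(epv_rows, function(r) {
    data.frame(model_type = r[[1]], predictors_included = r[[2]],
               n_predictors = as.integer(r[[3]]), n_events = n_events,
               epv = num(compute_epv(n_events, as.integer(r[[3]]))))
  }))

  risk_groups <- do.call(rbind, lapply(models, function(m) {
    if (is.null(strat[[m]])) return(NULL)
    s <- strat[[m]]$summary
    cbind(data.frame(model = model_label(m)), s)
  }))
  if (!is.null(risk_groups)) {
    risk_groups$event_rate <- num(risk_groups$event_rate)
  }

  stratification <- do.call(rbind, lapply(models, function(m) {
    if (is.null(strat[[m]])) {
      return(data.frame(model = model_label(m), cutoff_1 = NA_real_,
                        cutoff_2 = NA_real_, logrank_chisq = NA_real_,
                        degenerate = TRUE))
    }
    data.frame(model = model_label(m),
               cutoff_1 = num(strat[[m]]$cutoffs[[1]]),
               cutoff_2 = num(strat[[m]]$cutoffs[[2]]),
               logrank_chisq = num(strat[[m]]$logrank),
               degenerate = strat[[m]]$degenerate)
  }))

  calibration <- do.call(rbind, lapply(models, function(m) {
    if (is.null(calib[[m]])) {
      return(data.frame(model = model_label(m), slope = NA_real_,
                        intercept = NA_real_))
    }
    data.frame(model = model_label(m), slope = num(calib[[m]]$slope),
               intercept = num(calib[[m]]$intercept))
  }))

  # Stage x risk-group contingency (flow table) for the Cox fusion model
  # when available, else the first model.
  ok_models <- models[!vapply(strat, is.null, logical(1))[models]]
  flow_model <- if ("cox_meta" %in% ok_models) "cox_meta" else ok_models[1]
  flow <- if (length(ok_models)) {
    fl <- as.data.frame(table(stage = cohort$data$overall_stage,
                              risk_group = strat[[flow_model]]$groups))
    names(fl)[3] <- "n"
    fl$model <- model_label(flow_model)
    fl
  } else NULL

  km_curves <- do.call(rbind, lapply(models, function(m) {
    if (is.null(strat[[m]])) return(NULL)
    g <- strat[[m]]$groups
    do.call(rbind, lapply(levels(g), function(lev) {
      sel <- g == lev
      if (!any(sel)) return(NULL)
      km <- km_fit(surv_outcome(y$time[sel], y$event[sel]))
      data.frame(model = model_label(m), group = lev,
                 time = km$table$time, surv = num(km$table$surv))
    }))
  }))

  hazard_ratios <- do.call(rbind, c(lapply(models, function(m) {
    if (is.null(strat[[m]])) {
      return(data.frame(model = model_label(m), term = NA_character_,
                        hr = NA_real_, lo = NA_real_, hi = NA_real_))
    }
    hr_table(strat[[m]]$groups, y, model_label(m))
  }), list(stage_hr_table(cohort, y))))

  list(performance = performance, selection_frequency = sel_freq, epv = epv,
       risk_groups = risk_groups, stratification = stratification,
       calibration = calibration, stage_by_risk_group = flow,
       km_curves = km_curves, hazard_ratios = hazard_ratios)
}

# Hazard ratios (with Wald 95% CI) of risk groups vs the low group.
hr_table <- function(groups, y, label) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) < 2) {
    return(data.frame(model = label, term = NA_character_, hr = NA_real_,
                      lo = NA_real_, hi = NA_real_))
  }
  X <- stats::model.matrix(~ groups)[, -1, drop = FALSE]
  colnames(X) <- sub("^groups", "", colnames(X))
  fit <- tryCatch(fit_cox(X, y), error = function(e) NULL)
  if (is.null(fit)) {
    return(data.frame(model = label, term = colnames(X), hr = NA_real_,
                      lo = NA_real_, hi = NA_real_))
  }
  H <- neg_log_partial_likelihood(X, y, fit$beta, hessian = TRUE)$hessian
  se <- sqrt(diag(solve(H)))
  data.frame(model = label, term = paste0(colnames(X), "_vs_low"),
             hr = round(exp(fit$beta), 6),
             lo = round(exp(fit$beta - 1.96 * se), 6),
             hi = round(exp(fit$beta + 1.96 * se), 6))
}

stage_hr_table <- function(cohort, y) {
  st <- factor(cohort$data$overall_stage, levels = c("I", "II", "III"))
  X <- stats::model.matrix(~ st)[, -1, drop = FALSE]
  colnames(X) <- c("stage_II", "stage_III")
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0) {
    return(data.frame(model = "Clinical stage", term = NA_character_,
                      hr = NA_real_, lo = NA_real_, hi = NA_real_))
  }
  fit <- tryCatch(fit_cox(X, y), error = function(e) NULL)
  if (is.null(fit)) {
    return(data.frame(model = "Clinical stage", term = colnames(X),
                      hr = NA_real_, lo = NA_real_, hi = NA_real_))
  }
  H <- neg_log_partial_likelihood(X, y, fit$beta, hessian = TRUE)$hessian
  se <- sqrt(diag(solve(H)))
  data.frame(model = "Clinical stage", term = paste0(colnames(X), "_vs_I"),
             hr = round(exp(fit$beta), 6),
             lo = round(exp(fit$beta - 1.96 * se), 6),
             hi = round(exp(fit$beta + 1.96 * se), 6))
}

write_report_bundle <- function(tables, log_env, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(performance = "performance.csv",
             selection_frequency = "selection_frequency.csv",
             epv = "epv.csv",
             risk_groups = "risk_groups.csv",
             stratification = "stratification.csv",
             calibration = "calibration.csv",
             stage_by_risk_group = "stage_by_risk_group.csv",
             km_curves = "km_curves.csv",
             hazard_ratios = "hazard_ratios.csv")
  for (nm in names(files)) {
    if (!is.null(tables[[nm]])) {
      utils::write.csv(tables[[nm]], file.path(out_dir, files[[nm]]),
                       row.names = FALSE)
    }
  }
  writeLines(log_env$lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
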