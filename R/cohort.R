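# Synthetic cohort generation emulating the Lung1 data structure: a
# patient-level table with survival outcome, demographics, staging and
# 107 block-correlated radiomic features organized into 7 families.

#' Default radiomic feature-family sizes
#'
#' The standard radiomic taxonomy (first-order, shape, and the five
#' texture families), summing to 107 features.
#' @return Named integer vector of per-family feature counts.
#' @export
default_family_sizes <- function() {
  c(firstorder = 18L, shape = 14L, glcm = 24L, glrlm = 16L,
    glszm = 16L, gldm = 14L, ngtdm = 5L)
}

#' Specification of a synthetic NSCLC-like cohort
#'
#' Describes the generative model for [generate_cohort()]: cohort size and
#' demographic/staging marginals matching the reference cohort
#' (n = 398, stage mix 21.1/9.3/69.6%, age ~ N(68.1, 10.1^2), 68.6% male,
#' 11.8% censored, median survival ~1.5 years), a block-equicorrelated
#' Gaussian radiomic matrix with one block per feature family, and a
#' Weibull proportional-hazards outcome whose log-hazard combines
#' radiomic, clinical (stage-ordinal) and demographic contributions.
#'
#' `true_group_effects` are expressed per standardized (unit-variance)
#' radiomic feature; the stored features are affinely shifted/scaled per
#' family so families have distinct scales. The default places all
#' radiomic signal in the `ngtdm` family, mirroring a five-feature
#' texture signature with mixed coefficient signs.
#'
#' @param n_patients cohort size.
#' @param stage_probs probability triple for overall stage I/II/III.
#' @param age_mean,age_sd age marginal (years).
#' @param male_prob probability of male gender.
#' @param family_sizes named vector of features per family.
#' @param within_family_corr equicorrelation within each family, in [0, 1).
#' @param true_group_effects named list of per-family coefficient vectors
#'   (standardized-feature scale); omitted families get zero vectors.
#' @param clinical_effects length-3 vector: log-hazard per unit of the
#'   centered overall-stage, T-stage and N-stage ordinal codes.
#' @param demographic_effects length-2 vector: log-hazard per SD of age and
#'   for male (vs female, centered).
#' @param baseline_shape,baseline_scale Weibull baseline hazard
#'   H0(t) = (t / scale)^shape. The default scale is calibrated (a fixed
#'   1.38 inflation of the linear-predictor-zero value) so the median
#'   observed survival time of the default cohort is about 1.5 years
#'   under the default effect sizes.
#' @param target_censoring expected censored fraction in [0, 1); an
#'   independent exponential censoring time is calibrated to it.
#' @param include_tumor_count add a `tumor_count` covariate, 1 + Poisson(0.1)
#'   (no effect on hazard; off by default).
#' @param seed integer seed; identical specs produce byte-identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 398L,
                        stage_probs = c(0.211, 0.093, 0.696),
                        age_mean = 68.1, age_sd = 10.1,
                        male_prob = 0.686,
                        family_sizes = default_family_sizes(),
                        within_family_corr = 0.5,
                        true_group_effects = list(
                          ngtdm = c(-0.30, 0.30, 0.20, 0.08, -0.05)),
                        clinical_effects = c(stage = 0.30, t_stage = 0.08,
                                             n_stage = 0.08),
                        demographic_effects = c(age = 0.12, male = 0.15),
                        baseline_shape = 1.2,
                        baseline_scale = 1.38 * 1.5 / log(2)^(1 / 1.2),
                        target_censoring = 0.118,
                        include_tumor_count = FALSE,
                        seed = 1L) {
  stopifnot(n_patients >= 1, length(stage_probs) == 3)
  if (abs(sum(stage_probs) - 1) > 1e-8) stop("stage_probs must sum to 1")
  if (any(family_sizes < 1)) stop("family sizes must be positive")
  if (is.null(names(family_sizes)) || anyDuplicated(names(family_sizes))) {
    stop("family_sizes must have unique names")
  }
  if (within_family_corr < 0 || within_family_corr >= 1) {
    stop("within_family_corr must lie in [0, 1) for a positive-definite block matrix")
  }
  if (target_censoring < 0 || target_censoring >= 1) {
    stop("target_censoring must lie in [0, 1); the exponential censoring ",
         "mechanism can reach any expected censored fraction in that range")
  }
  if (length(clinical_effects) != 3) stop("clinical_effects must have length 3")
  if (length(demographic_effects) != 2) stop("demographic_effects must have length 2")
  unknown <- setdiff(names(true_group_effects), names(family_sizes))
  if (length(unknown)) stop("unknown families in true_group_effects: ",
                            paste(unknown, collapse = ", "))
  for (f in names(true_group_effects)) {
    if (length(true_group_effects[[f]]) != family_sizes[[f]]) {
      stop("effect vector for family '", f, "' must have length ", family_sizes[[f]])
    }
  }
  structure(list(
    n_patients = as.integer(n_patients), stage_probs = stage_probs,
    age_mean = age_mean, age_sd = age_sd, male_prob = male_prob,
    family_sizes = family_sizes, within_family_corr = within_family_corr,
    true_group_effects = true_group_effects,
    clinical_effects = clinical_effects,
    demographic_effects = demographic_effects,
    baseline_shape = baseline_shape, baseline_scale = baseline_scale,
    target_censoring = target_censoring,
    include_tumor_count = include_tumor_count,
    seed = as.integer(seed)), class = "cohort_spec")
}

# Per-family affine display transforms: synthetic convention giving families
# distinct scales; the hazard acts on the standardized (pre-transform) values.
family_affine <- function(families) {
  k <- seq_along(families)
  list(scale = stats::setNames(c(10, 50, 2, 5, 8, 3, 0.5, rep(1, max(0, length(k) - 7)))[k], families),
       shift = stats::setNames(c(100, 500, 0, 10, 20, 5, 1, rep(0, max(0, length(k) - 7)))[k], families))
}

# Conditional distributions of T (codes 1-4) and N (codes 0-3) given overall
# stage; the joint distribution is a synthetic convention, not a reproduction.
tn_stage_tables <- function() {
  list(
    t = rbind(I   = c(0.60, 0.35, 0.05, 0.00),
              II  = c(0.25, 0.45, 0.25, 0.05),
              III = c(0.05, 0.30, 0.40, 0.25)),
    n = rbind(I   = c(0.85, 0.12, 0.03, 0.00),
              II  = c(0.50, 0.35, 0.12, 0.03),
              III = c(0.10, 0.30, 0.40, 0.20)))
}

#' Generate a synthetic cohort
#'
#' Draws a seeded cohort per the generative model in [cohort_spec()]:
#' radiomic features from a zero-mean Gaussian with block-diagonal
#' equicorrelation (one block per family) followed by per-family affine
#' shifts; stage/age/gender from their marginals; T/N stage from a simple
#' conditional table given overall stage; event times from a Weibull
#' proportional-hazards model; independent exponential censoring whose
#' rate is calibrated by root-finding on a large pilot sample so the
#' expected censored fraction equals `target_censoring`.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `cohort`: list with `data` (data.frame:
#'   id, time_years, event, age, gender, overall_stage, t_stage, n_stage,
#'   feature columns), `taxonomy` (data.frame: feature, family), `truth`
#'   (list: per-patient linear predictor `lp`, function `risk_at(t)` giving
#'   the generating-model absolute risk, censoring rate), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    fams <- names(spec$family_sizes)
    sizes <- spec$family_sizes
    p <- sum(sizes)
    feat_names <- unlist(lapply(fams, function(f) {
      sprintf("%s_%02d", f, seq_len(sizes[[f]]))
    }), use.names = FALSE)
    taxonomy <- data.frame(
      feature = feat_names,
      family = rep(fams, times = sizes),
      stringsAsFactors = FALSE)

    # Radiomics: equicorrelated block per family via a shared factor.
    rho <- spec$within_family_corr
    Z <- matrix(stats::rnorm(n * p), n, p)
    fac <- matrix(stats::rnorm(n * length(fams)), n, length(fams))
    Xstd <- matrix(0, n, p, dimnames = list(NULL, feat_names))
    col0 <- 0L
    for (k in seq_along(fams)) {
      idx <- col0 + seq_len(sizes[[k]])
      Xstd[, idx] <- sqrt(rho) * fac[, k] + sqrt(1 - rho) * Z[, idx]
      col0 <- col0 + sizes[[k]]
    }

    # Demographics and staging.
    age <- stats::rnorm(n, spec$age_mean, spec$age_sd)
    male <- stats::rbinom(n, 1, spec$male_prob)
    stage_num <- sample.int(3, n, replace = TRUE, prob = spec$stage_probs)
    tn <- tn_stage_tables()
    t_stage <- vapply(stage_num, function(s) {
      sample.int(4, 1, prob = tn$t[s, ])
    }, integer(1))
    n_stage <- vapply(stage_num, function(s) {
      sample.int(4, 1, prob = tn$n[s, ]) - 1L
    }, integer(1))

    # Linear predictor (log-hazard), covariate contributions centered.
    beta_r <- stats::setNames(numeric(p), feat_names)
    for (f in names(spec$true_group_effects)) {
      beta_r[taxonomy$family == f] <- spec$true_group_effects[[f]]
    }
    lp <- as.numeric(Xstd %*% beta_r) +
      spec$clinical_effects[[1]] * (stage_num - 2) +
      spec$clinical_effects[[2]] * (t_stage - 2) +
      spec$clinical_effects[[3]] * (n_stage - 1.5) +
      spec$demographic_effects[[1]] * (age - spec$age_mean) / spec$age_sd +
      spec$demographic_effects[[2]] * (male - 0.5)

    # Weibull PH event times: H(t|x) = (t/b)^a * exp(lp).
    a <- spec$baseline_shape; b <- spec$baseline_scale
    draw_event_time <- function(lp_vec) {
      u <- stats::runif(length(lp_vec))
      b * (-log(u) * exp(-lp_vec))^(1 / a)
    }

    # Calibrate exponential censoring rate on a pilot sample so that
    # E[censored fraction] = target. P(C < T | T) = 1 - exp(-r T).
    cens_rate <- 0
    if (spec$target_censoring > 0) {
      m <- 20000L
      pilot_lp <- sample(lp, m, replace = TRUE)
      pilot_t <- draw_event_time(pilot_lp)
      frac <- function(logr) mean(1 - exp(-exp(logr) * pilot_t)) - spec$target_censoring
      lo <- -30; hi <- 30
      if (frac(lo) > 0 || frac(hi) < 0) {
        stop("censoring calibration infeasible: achievable censored fraction ",
             "range is (", signif(mean(1 - exp(-exp(lo) * pilot_t)), 3), ", ",
             signif(mean(1 - exp(-exp(hi) * pilot_t)), 3), ") for target ",
             spec$target_censoring)
      }
      cens_rate <- exp(stats::uniroot(frac, c(lo, hi), tol = 1e-10)$root)
    }

    t_event <- draw_event_time(lp)
    t_cens <- if (cens_rate > 0) stats::rexp(n, cens_rate) else rep(Inf, n)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    aff <- family_affine(fams)
    X <- sweep(sweep(Xstd, 2, rep(aff$scale, times = sizes), "*"),
               2, rep(aff$shift, times = sizes), "+")

    dat <- data.frame(
      id = sprintf("P%04d", seq_len(n)),
      time_years = time,
      event = event,
      age = age,
      gender = ifelse(male == 1, "male", "female"),
      overall_stage = c("I", "II", "III")[stage_num],
      t_stage = t_stage,
      n_stage = n_stage,
      stringsAsFactors = FALSE)
    if (spec$include_tumor_count) {
      dat$tumor_count <- 1L + stats::rpois(n, 0.1)
    }
    dat <- cbind(dat, as.data.frame(X))

    structure(list(
      data = dat,
      taxonomy = taxonomy,
      truth = list(
        lp = lp,
        beta_radiomic_std = beta_r,
        risk_at = function(t) 1 - exp(-(t / b)^a * exp(lp)),
        censoring_rate = cens_rate),
      spec = spec), class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  d <- x$data
  cat("Synthetic cohort:", nrow(d), "patients,",
      nrow(x$taxonomy), "radiomic features in",
      length(unique(x$taxonomy$family)), "families\n")
  cat(sprintf("  events: %d (%.1f%%), median follow-up %.2f y\n",
              sum(d$event), 100 * mean(d$event), stats::median(d$time_years)))
  invisible(x)
}

#' Extract the survival outcome of a cohort
#' @param cohort a `cohort` object or cohort data.frame.
#' @return A [surv_outcome()].
#' @export
cohort_outcome <- function(cohort) {
  d <- if (inherits(cohort, "cohort")) cohort$data else cohort
  surv_outcome(d$time_years, d$event)
}

# Numeric design matrix for one modality.
# clinical: centered ordinal overall/T/N stage codes; demographic: age and
# male indicator; radiomic: taxonomy-driven feature columns (raw scale).
modality_matrix <- function(cohort, modality) {
  d <- cohort$data
  switch(modality,
    clinical = cbind(
      overall_stage = match(d$overall_stage, c("I", "II", "III")),
      t_stage = as.numeric(d$t_stage),
      n_stage = as.numeric(d$n_stage)),
    demographic = cbind(
      age = d$age,
      male = as.numeric(d$gender == "male")),
    radiomic = as.matrix(d[, cohort$taxonomy$feature, drop = FALSE]),
    stop("unknown modality: ", modality))
}

#' Write a cohort to plain-text files
#'
#' @param cohort a `cohort` object.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths of the cohort and taxonomy CSVs.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort_path <- file.path(dir, "cohort.csv")
  tax_path <- file.path(dir, "taxonomy.csv")
  utils::write.csv(cohort$data, cohort_path, row.names = FALSE)
  utils::write.csv(cohort$taxonomy, tax_path, row.names = FALSE)
  invisible(c(cohort = cohort_path, taxonomy = tax_path))
}
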