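# From-scratch survival evaluation suite: Harrell C-index, Kaplan-Meier,
# IPCW cumulative/dynamic time-dependent AUC, Brier score and integrated
# Brier score, and group-level calibration slope/intercept.

#' Harrell concordance index
#'
#' Proportion of comparable patient pairs for which the predicted risk
#' ordering is consistent with the observed survival ordering. A pair is
#' comparable iff the earlier observed time belongs to an event; the pair
#' is concordant when the shorter survivor has the higher score; tied
#' scores credit 0.5.
#'
#' @param scores risk scores (higher = higher risk).
#' @param y survival outcome.
#' @return C-index in [0, 1].
#' @export
harrell_cindex <- function(scores, y) {
  y <- as_surv_outcome(y)
  n <- length(scores)
  stopifnot(n == nrow(y))
  ord <- order(y$time)
  t <- y$time[ord]; d <- y$event[ord]; s <- scores[ord]
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    if (d[i] != 1) next
    # comparable partners: strictly later times (ties in time not comparable
    # unless the later is... time ties with both events are incomparable here)
    j <- which(t > t[i])
    if (!length(j)) next
    den <- den + length(j)
    num <- num + sum(s[i] > s[j]) + 0.5 * sum(s[i] == s[j])
  }
  if (den == 0) stop("no comparable pairs (all censored?)")
  num / den
}

#' Kaplan-Meier estimator
#'
#' Product-limit estimator of the survival function; tied times are
#' processed jointly with events preceding censorings at the same time.
#'
#' @param y survival outcome.
#' @return Object of class `km_fit`: data.frame `table` with columns
#'   time (distinct observed times), n_risk, n_event, n_censor, surv.
#' @export
km_fit <- function(y) {
  y <- as_surv_outcome(y)
  tt <- sort(unique(y$time))
  n_risk <- vapply(tt, function(u) sum(y$time >= u), numeric(1))
  n_event <- vapply(tt, function(u) sum(y$time == u & y$event == 1), numeric(1))
  n_censor <- vapply(tt, function(u) sum(y$time == u & y$event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(table = data.frame(time = tt, n_risk = n_risk,
                                    n_event = n_event, n_censor = n_censor,
                                    surv = surv)),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier curve
#'
#' @param km a [km_fit()].
#' @param t times at which to evaluate S(t) (right-continuous step function).
#' @param left evaluate the left limit S(t-) instead.
#' @return Survival probabilities.
#' @export
km_surv_at <- function(km, t, left = FALSE) {
  tab <- km$table
  if (nrow(tab) == 0) return(rep(1, length(t)))
  idx <- if (left) findInterval(t, tab$time, left.open = TRUE)
         else findInterval(t, tab$time)
  c(1, tab$surv)[idx + 1]
}

#' Kaplan-Meier median survival
#'
#' Smallest time at which the KM curve reaches 0.5 or below; `NA`
#' ("not reached") if it never does.
#' @param km a [km_fit()].
#' @return Median survival time or `NA_real_`.
#' @export
km_median <- function(km) {
  tab <- km$table
  i <- which(tab$surv <= 0.5)
  if (!length(i)) return(NA_real_)
  tab$time[i[1]]
}

# KM of the censoring distribution (event indicator flipped); used for
# inverse-probability-of-censoring weights G(t).
censoring_km <- function(y) {
  y <- as_surv_outcome(y)
  km_fit(surv_outcome(y$time, 1 - y$event))
}

#' Time-dependent AUC (cumulative/dynamic, IPCW)
#'
#' Discrimination between cases (event by time t) and controls (under
#' observation beyond t). Cases are weighted by 1/G(T_i-) where G is the
#' Kaplan-Meier estimate of the censoring distribution; score ties credit
#' 0.5. Patients censored at or before t without an event contribute only
#' through the censoring weights.
#'
#' @param risks risk scores (higher = higher risk; any monotone scale).
#' @param y survival outcome.
#' @param t evaluation horizon.
#' @return AUC(t) in [0, 1].
#' @export
td_auc <- function(risks, y, t) {
  y <- as_surv_outcome(y)
  case <- y$time <= t & y$event == 1
  ctrl <- y$time > t
  if (!any(case)) stop("no cases (events by t = ", t, ")")
  if (!any(ctrl)) stop("no controls (patients under observation beyond t = ", t, ")")
  G <- censoring_km(y)
  w_case <- 1 / km_surv_at(G, y$time[case], left = TRUE)
  if (any(!is.finite(w_case))) stop("zero censoring-survival weight at a case time")
  rc <- risks[case]; rt <- risks[ctrl]
  num <- 0
  for (i in seq_along(rc)) {
    num <- num + w_case[i] * (sum(rc[i] > rt) + 0.5 * sum(rc[i] == rt))
  }
  num / (sum(w_case) * length(rt))
}

#' Brier score at a time point (IPCW)
#'
#' Mean squared difference between the predicted survival probability at
#' `t` and the observed status, with inverse-probability-of-censoring
#' weights: events before t weighted by 1/G(T_i-), patients still under
#' observation by 1/G(t); patients censored before t contribute only via
#' the weight normalization (weight 0, divisor n).
#'
#' @param pred_surv_at_t predicted survival probabilities at t, in [0, 1].
#' @param y survival outcome.
#' @param t evaluation time.
#' @return Brier score.
#' @export
brier <- function(pred_surv_at_t, y, t) {
  y <- as_surv_outcome(y)
  n <- nrow(y)
  stopifnot(length(pred_surv_at_t) == n)
  if (any(pred_surv_at_t < -1e-9 | pred_surv_at_t > 1 + 1e-9)) {
    stop("predicted survival probabilities must lie in [0, 1]")
  }
  G <- censoring_km(y)
  contrib <- numeric(n)
  ev_before <- y$time <= t & y$event == 1
  alive <- y$time > t
  if (any(ev_before)) {
    g <- km_surv_at(G, y$time[ev_before], left = TRUE)
    if (any(g <= 0)) stop("zero censoring weight before t; truncate the time grid")
    contrib[ev_before] <- (0 - pred_surv_at_t[ev_before])^2 / g
  }
  if (any(alive)) {
    gt <- km_surv_at(G, t)
    if (gt <= 0) stop("zero censoring weight at t; truncate the time grid")
    contrib[alive] <- (1 - pred_surv_at_t[alive])^2 / gt
  }
  sum(contrib) / n
}

#' Integrated Brier score
#'
#' Trapezoidal average of the Brier score over [0, tau]; BS(0) = 0 is
#' prepended so the integral starts at zero.
#'
#' @param pred_surv matrix of predicted survival probabilities
#'   (patients x times).
#' @param y survival outcome.
#' @param times evaluation grid (same length as `ncol(pred_surv)`).
#' @param tau upper limit; grid times beyond tau are dropped.
#' @return IBS over [0, tau].
#' @export
integrated_brier <- function(pred_surv, y, times, tau = max(times)) {
  pred_surv <- as.matrix(pred_surv)
  stopifnot(ncol(pred_surv) == length(times))
  keep <- times <= tau + 1e-12
  if (!any(keep)) stop("no grid times within [0, tau]")
  times <- times[keep]
  pred_surv <- pred_surv[, keep, drop = FALSE]
  bs <- vapply(seq_along(times), function(j) brier(pred_surv[, j], y, times[j]),
               numeric(1))
  tt <- c(0, times); bb <- c(0, bs)
  sum(diff(tt) * (utils::head(bb, -1) + utils::tail(bb, -1)) / 2) / max(tt)
}

#' Group-level calibration at a horizon
#'
#' Per group: mean predicted absolute risk and observed risk
#' 1 - KM(t) within the group; the calibration slope and intercept are
#' the least-squares coefficients of observed on predicted across the
#' group points (ideal: slope 1, intercept 0).
#'
#' @param pred_risk predicted absolute risks at `t`.
#' @param groups group labels (risk strata or quantile bins), >= 2 groups.
#' @param y survival outcome.
#' @param t horizon.
#' @return List: `points` (data.frame group, n, predicted, observed),
#'   `slope`, `intercept`.
#' @export
calibration_groups <- function(pred_risk, groups, y, t) {
  y <- as_surv_outcome(y)
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) < 2) stop("need at least 2 groups for calibration")
  pts <- lapply(gl, function(g) {
    sel <- groups == g
    km <- km_fit(surv_outcome(y$time[sel], y$event[sel]))
    if (max(y$time[sel]) < t && km$table$surv[nrow(km$table)] > 0) {
      warning("group '", g, "' has no follow-up to t = ", t, "; dropped")
      return(NULL)
    }
    data.frame(group = g, n = sum(sel),
               predicted = mean(pred_risk[sel]),
               observed = 1 - km_surv_at(km, t))
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts) || nrow(pts) < 2) stop("fewer than 2 usable groups")
  fit <- stats::lm(observed ~ predicted, data = pts)
  list(points = pts,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

# Default evaluation grid: deciles of observed event times within
# [t_min, tau]; tau = tau_frac * largest observed time.
default_eval_times <- function(y, t_min = 0.25, tau_frac = 0.8) {
  y <- as_surv_outcome(y)
  tau <- tau_frac * max(y$time)
  et <- y$time[y$event == 1]
  qs <- stats::quantile(et, probs = seq(0.1, 0.9, by = 0.1), names = FALSE)
  times <- sort(unique(pmin(pmax(qs, t_min), tau)))
  list(times = times, tau = tau)
}

#' Assemble a full metric report
#'
#' C-index from the risk scores, time-dependent AUC at the requested grid
#' and its mean, Brier score per grid time, and the integrated Brier score
#' over [0, tau]. Optional seeded patient-level percentile bootstrap.
#'
#' @param scores risk scores (higher = higher risk).
#' @param pred_surv predicted survival matrix (patients x times).
#' @param y survival outcome.
#' @param times evaluation grid; default deciles of event times.
#' @param tau IBS upper limit; default 0.8 x largest observed time.
#' @param n_boot bootstrap resamples (0 = no intervals).
#' @param seed bootstrap seed.
#' @return List of class `metric_report`: `c_index`, `auc_times`, `auc`,
#'   `auc_mean`, `brier_times`, `brier`, `ibs`, optional `ci`.
#' @export
evaluate_model <- function(scores, pred_surv, y, times = NULL, tau = NULL,
                           n_boot = 0L, seed = 1L) {
  y <- as_surv_outcome(y)
  if (is.null(times) || is.null(tau)) {
    g <- default_eval_times(y)
    if (is.null(times)) times <- g$times
    if (is.null(tau)) tau <- g$tau
  }
  pred_surv <- as.matrix(pred_surv)
  stopifnot(length(scores) == nrow(y), nrow(pred_surv) == nrow(y),
            ncol(pred_surv) == length(times))
  compute <- function(idx) {
    yy <- surv_outcome(y$time[idx], y$event[idx])
    auc <- vapply(times, function(t) {
      tryCatch(td_auc(scores[idx], yy, t), error = function(e) NA_real_)
    }, numeric(1))
    bs <- vapply(seq_along(times), function(j) {
      tryCatch(brier(pred_surv[idx, j], yy, times[j]), error = function(e) NA_real_)
    }, numeric(1))
    ok <- !is.na(bs)
    ibs <- if (any(ok)) {
      tt <- c(0, times[ok]); bb <- c(0, bs[ok])
      sum(diff(tt) * (utils::head(bb, -1) + utils::tail(bb, -1)) / 2) / max(tt)
    } else NA_real_
    c(c_index = harrell_cindex(scores[idx], yy),
      auc_mean = mean(auc, na.rm = TRUE), ibs = ibs, auc, bs)
  }
  full <- compute(seq_len(nrow(y)))
  nT <- length(times)
  rep_out <- list(c_index = unname(full[1]),
                  auc_mean = unname(full[2]),
                  ibs = unname(full[3]),
                  auc_times = times,
                  auc = unname(full[3 + seq_len(nT)]),
                  brier_times = times,
                  brier = unname(full[3 + nT + seq_len(nT)]),
                  tau = tau)
  if (n_boot > 0) {
    boot <- with_seed(seed, {
      t(vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(y), replace = TRUE)
        compute(idx)[1:3]
      }, numeric(3)))
    })
    rep_out$ci <- apply(boot, 2, stats::quantile,
                        probs = c(0.025, 0.975), na.rm = TRUE)
  }
  structure(rep_out, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("C-index %.4f | mean td-AUC %.4f | IBS %.4f (tau = %.2f)\n",
              x$c_index, x$auc_mean, x$ibs, x$tau))
  invisible(x)
}
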