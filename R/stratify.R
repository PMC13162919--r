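# Outcome-guided three-group risk stratification: K-sample log-rank
# statistic, constrained two-cutoff search maximizing the log-rank
# chi-square, fold-averaged cutoffs, held-out assignment and summaries.

#' K-sample log-rank chi-square statistic
#'
#' At each distinct event time, the observed minus expected events per
#' group under the hypergeometric model; the statistic is O' V^-1 O over
#' K-1 groups (df = K-1) and is invariant under group relabeling.
#'
#' @param groups group label vector (K >= 2 nonempty groups).
#' @param y survival outcome.
#' @return List: `chisq`, `df`, `observed`, `expected` (per group).
#' @export
logrank_chisq <- function(groups, y) {
  y <- as_surv_outcome(y)
  groups <- factor(groups)
  K <- nlevels(groups)
  if (K < 2) stop("log-rank requires at least 2 groups")
  # Vectorized over distinct event times via reverse cumulative sums.
  ord <- order(y$time)
  tt <- y$time[ord]; ev <- y$event[ord]
  Gs <- stats::model.matrix(~ groups - 1)[ord, , drop = FALSE]  # n x K
  heads <- which(!duplicated(tt))                 # distinct-time group heads
  grp_id <- findInterval(seq_along(tt), heads)
  n_risk_g <- revcumsum(Gs)[heads, , drop = FALSE]              # T x K
  d_g <- rowsum(Gs * ev, grp_id)                                # T x K
  d_t <- rowSums(d_g)
  keep <- d_t > 0
  n_risk_g <- n_risk_g[keep, , drop = FALSE]
  d_g <- d_g[keep, , drop = FALSE]
  d_t <- d_t[keep]
  n_t <- rowSums(n_risk_g)
  P <- n_risk_g / n_t                                           # T x K
  O <- colSums(d_g)
  E <- colSums(d_t * P)
  c_t <- ifelse(n_t > 1, d_t * (n_t - d_t) / (n_t - 1), 0)
  V <- diag(colSums(c_t * P), K) - crossprod(P, c_t * P)
  om <- (O - E)[-K]
  Vm <- V[-K, -K, drop = FALSE]
  chisq <- tryCatch(as.numeric(t(om) %*% solve(Vm, om)),
                    error = function(e) {
                      as.numeric(t(om) %*% MASS_ginv(Vm) %*% om)
                    })
  list(chisq = chisq, df = K - 1,
       observed = stats::setNames(O, levels(groups)),
       expected = stats::setNames(E, levels(groups)))
}

# Moore-Penrose pseudoinverse (fallback for singular log-rank variance).
MASS_ginv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1]
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Candidate cutoff pairs from the central score quantiles
#'
#' All ordered pairs (c1 < c2) from a quantile grid of the scores
#' restricted to the central range (default quantiles 0.15-0.85 in steps
#' of 0.025), avoiding extreme thresholds influenced by outliers.
#'
#' @param scores numeric risk scores.
#' @param search_range quantile range searched.
#' @param step quantile step.
#' @return data.frame with columns `cutoff_1`, `cutoff_2`.
#' @export
candidate_cutoffs <- function(scores, search_range = c(0.15, 0.85),
                              step = 0.025) {
  qs <- stats::quantile(scores, probs = seq(search_range[1], search_range[2],
                                            by = step), names = FALSE)
  qs <- unique(qs)
  if (length(qs) < 2) stop("fewer than 2 distinct quantile grid points")
  pairs <- t(utils::combn(qs, 2))
  data.frame(cutoff_1 = pairs[, 1], cutoff_2 = pairs[, 2])
}

# Assign low/medium/high by two cutoffs (monotone in the score).
assign_groups <- function(scores, c1, c2) {
  factor(ifelse(scores <= c1, "low", ifelse(scores <= c2, "medium", "high")),
         levels = c("low", "medium", "high"))
}

#' Search the optimal cutoff pair
#'
#' Evaluates the log-rank chi-square for each feasible candidate pair;
#' pairs violating the minimum per-group fraction or producing
#' non-monotone per-group event rates (low <= medium <= high required)
#' are discarded; returns the argmax, with ties broken toward the pair
#' closest to the tercile cutoffs.
#'
#' @param scores risk scores (typically absolute risks).
#' @param y survival outcome.
#' @param min_frac minimum per-group fraction (default 0.15).
#' @param search_range,step passed to [candidate_cutoffs()].
#' @return List of class `cutoff_pair`: `cutoff_1`, `cutoff_2`, `chisq`,
#'   `n_candidates`, `n_feasible`.
#' @export
search_cutoffs <- function(scores, y, min_frac = 0.15,
                           search_range = c(0.15, 0.85), step = 0.025) {
  y <- as_surv_outcome(y)
  n <- length(scores)
  if (3 * min_frac > 1) {
    stop("infeasible constraints: 3 * min_frac = ", 3 * min_frac, " > 1")
  }
  cand <- candidate_cutoffs(scores, search_range, step)
  terc <- stats::quantile(scores, c(1 / 3, 2 / 3), names = FALSE)
  # the tercile pair is always a candidate (argmax dominance anchor)
  if (terc[1] < terc[2]) {
    cand <- unique(rbind(cand, data.frame(cutoff_1 = terc[1],
                                          cutoff_2 = terc[2])))
  }
  best <- NULL
  n_feas <- 0L
  viol_size <- 0L; viol_mono <- 0L
  for (i in seq_len(nrow(cand))) {
    g <- assign_groups(scores, cand$cutoff_1[i], cand$cutoff_2[i])
    cnt <- table(g)
    if (any(cnt < min_frac * n)) { viol_size <- viol_size + 1L; next }
    rates <- tapply(y$event, g, mean)
    if (any(diff(rates) < 0)) { viol_mono <- viol_mono + 1L; next }
    n_feas <- n_feas + 1L
    chi <- logrank_chisq(g, y)$chisq
    dist <- abs(cand$cutoff_1[i] - terc[1]) + abs(cand$cutoff_2[i] - terc[2])
    if (is.null(best) || chi > best$chisq + 1e-12 ||
        (abs(chi - best$chisq) <= 1e-12 && dist < best$dist)) {
      best <- list(cutoff_1 = cand$cutoff_1[i], cutoff_2 = cand$cutoff_2[i],
                   chisq = chi, dist = dist)
    }
  }
  if (is.null(best)) {
    stop("no feasible cutoff pair: ", viol_size, " of ", nrow(cand),
         " candidates violated the minimum group size (min_frac = ", min_frac,
         "), ", viol_mono, " violated monotone event-rate ordering")
  }
  structure(list(cutoff_1 = best$cutoff_1, cutoff_2 = best$cutoff_2,
                 chisq = best$chisq, n_candidates = nrow(cand),
                 n_feasible = n_feas),
            class = "cutoff_pair")
}

#' Per-group survival summary
#'
#' @param groups group labels.
#' @param y survival outcome.
#' @return data.frame: group, n, events, event_rate, km_median
#'   (`NA` = median not reached).
#' @export
group_summary <- function(groups, y) {
  y <- as_surv_outcome(y)
  groups <- factor(groups)
  do.call(rbind, lapply(levels(groups), function(g) {
    sel <- groups == g
    if (!any(sel)) {
      return(data.frame(group = g, n = 0L, events = 0L,
                        event_rate = NA_real_, km_median = NA_real_))
    }
    km <- km_fit(surv_outcome(y$time[sel], y$event[sel]))
    data.frame(group = g, n = sum(sel), events = sum(y$event[sel]),
               event_rate = mean(y$event[sel]), km_median = km_median(km))
  }))
}

#' Fold-averaged risk stratification
#'
#' Per outer fold, runs [search_cutoffs()] on the training-fold
#' out-of-fold risks and outcomes; averages the fold cutoff pairs
#' (arithmetic mean on the absolute-risk scale); assigns every patient by
#' their out-of-fold risk against the mean cutoffs; reports group
#' summaries and the overall log-rank chi-square.
#'
#' @param oof_risks out-of-fold absolute risks for all patients.
#' @param folds outer fold assignment (1..k).
#' @param y survival outcome.
#' @param ... constraints passed to [search_cutoffs()].
#' @return List of class `risk_stratification`: `cutoffs` (mean pair),
#'   `fold_cutoffs`, `groups` (per patient), `summary`, `logrank`
#'   (or `NA` with `degenerate = TRUE` if fewer than 2 groups are
#'   populated).
#' @export
fold_averaged_stratification <- function(oof_risks, folds, y, ...) {
  y <- as_surv_outcome(y)
  ks <- sort(unique(folds))
  fold_cuts <- lapply(ks, function(f) {
    tr <- folds != f
    cp <- tryCatch(
      search_cutoffs(oof_risks[tr], surv_outcome(y$time[tr], y$event[tr]), ...),
      error = function(e) stop("cutoff search failed in fold ", f, ": ",
                               conditionMessage(e)))
    c(cutoff_1 = cp$cutoff_1, cutoff_2 = cp$cutoff_2)
  })
  fold_cuts <- do.call(rbind, fold_cuts)
  c1 <- mean(fold_cuts[, 1]); c2 <- mean(fold_cuts[, 2])
  groups <- assign_groups(oof_risks, c1, c2)
  summ <- group_summary(groups, y)
  populated <- sum(table(groups) > 0)
  degenerate <- populated < 2
  lr <- if (degenerate) NA_real_ else {
    logrank_chisq(droplevels(groups), y)$chisq
  }
  structure(list(cutoffs = c(cutoff_1 = c1, cutoff_2 = c2),
                 fold_cutoffs = fold_cuts, groups = groups,
                 summary = summ, logrank = lr, degenerate = degenerate),
            class = "risk_stratification")
}

#' @export
print.risk_stratification <- function(x, ...) {
  cat(sprintf("Risk stratification: cutoffs (%.4f, %.4f), log-rank chi-sq %s\n",
              x$cutoffs[1], x$cutoffs[2],
              if (is.na(x$logrank)) "NA (degenerate)" else
                format(x$logrank, digits = 4)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
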