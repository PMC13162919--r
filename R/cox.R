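# Semi-parametric Cox proportional-hazards core: Breslow-ties partial
# likelihood (value/gradient/Hessian), Newton-Raphson fitting with
# step-halving, Breslow baseline cumulative hazard, and linear-predictor /
# landmark absolute-risk prediction.

# Precompute the sort order and tie structure used by every likelihood call.
cox_prep <- function(y) {
  y <- as_surv_outcome(y)
  ord <- order(y$time)
  time <- y$time[ord]
  event <- y$event[ord]
  # First index of each tie group (shared risk set), per sorted position.
  grp_head <- which(!duplicated(time))
  grp_id <- findInterval(seq_along(time), grp_head)
  list(ord = ord, time = time, event = event,
       grp_head = grp_head, grp_id = grp_id, n = length(time))
}

#' Negative log partial likelihood (Breslow ties)
#'
#' Value, gradient and (optionally) Hessian of the negative log Cox
#' partial likelihood at `beta`, with Breslow's handling of tied event
#' times. The function is convex in `beta`.
#'
#' @param X numeric predictor matrix (patients x predictors).
#' @param y survival outcome ([surv_outcome()] or list with time/event).
#' @param beta coefficient vector.
#' @param hessian compute the Hessian (only sensible for small ncol(X)).
#' @return List with `value`, `gradient` and optionally `hessian`.
#' @export
neg_log_partial_likelihood <- function(X, y, beta, hessian = FALSE) {
  X <- as.matrix(X)
  prep <- cox_prep(y)
  if (sum(prep$event) == 0) stop("no events: partial likelihood undefined")
  if (nrow(X) != prep$n) stop("nrow(X) does not match outcome length")
  if (any(!is.finite(X))) stop("X contains non-finite values")
  cox_nll_prepped(X[prep$ord, , drop = FALSE], prep, beta, hessian)
}

# Core likelihood on pre-sorted data (Xs rows ordered by increasing time).
cox_nll_prepped <- function(Xs, prep, beta, hessian = FALSE) {
  eta <- if (length(beta)) as.numeric(Xs %*% beta) else numeric(prep$n)
  if (any(!is.finite(eta))) stop("non-finite linear predictor")
  # Guard overflow: exp(eta) with eta centered (shift cancels in the PL).
  c0 <- mean(eta)
  e <- exp(eta - c0)
  rc <- revcumsum(e)                       # at-risk sums at sorted positions
  S0 <- rc[prep$grp_head][prep$grp_id]     # shared within tie groups
  ev <- prep$event == 1
  # Distinct event times: tie groups containing at least one event.
  d_by_grp <- as.numeric(rowsum(as.numeric(ev), prep$grp_id))
  has_event <- d_by_grp > 0
  S0_grp <- rc[prep$grp_head]
  value <- -(sum(eta[ev] - c0)) + sum(d_by_grp[has_event] * log(S0_grp[has_event]))

  # Gradient: X'(mu - delta), mu_j = e_j * H0(t_j), H0 cumulative d_k/S0_k.
  h_grp <- ifelse(has_event, d_by_grp / S0_grp, 0)
  H0_sub <- cumsum(h_grp)[prep$grp_id]
  mu <- e * H0_sub
  gradient <- as.numeric(crossprod(Xs, mu - as.numeric(ev)))

  out <- list(value = value, gradient = gradient)
  if (hessian) {
    p <- ncol(Xs)
    B <- Xs * sqrt(e)
    S1 <- revcumsum(Xs * e)                                   # n x p
    BB <- B[, rep(seq_len(p), times = p), drop = FALSE] *
          B[, rep(seq_len(p), each = p), drop = FALSE]        # n x p^2
    S2 <- revcumsum(BB)
    H <- matrix(0, p, p)
    ev_grp <- which(has_event)
    heads <- prep$grp_head[ev_grp]
    for (i in seq_along(ev_grp)) {
      k <- heads[i]
      s0 <- rc[k]
      u <- S1[k, ] / s0
      S2k <- matrix(S2[k, ], p, p)
      H <- H + d_by_grp[ev_grp[i]] * (S2k / s0 - tcrossprod(u))
    }
    out$hessian <- H
  }
  out
}

#' Fit a Cox proportional-hazards model
#'
#' Newton-Raphson on the Breslow-ties negative log partial likelihood with
#' step-halving, followed by the Breslow baseline cumulative hazard
#' evaluated at the event times of the training data:
#' H0(t) = sum over event times t_i <= t of d_i / sum(exp(x_j'beta), j at risk).
#'
#' @param X predictor matrix; columns must not be constant.
#' @param y survival outcome.
#' @param tol convergence tolerance on the gradient max-norm.
#' @param max_iter maximum Newton iterations.
#' @param ridge optional L2 penalty (used as a fallback for collinear
#'   designs, e.g. by the fusion meta-learner).
#' @return An object of class `cox_fit`: `beta`, `baseline` (data.frame of
#'   event times and cumulative hazard), `converged`, `n_iter`, `loglik`,
#'   and the iteration `trace`.
#' @export
fit_cox <- function(X, y, tol = 1e-8, max_iter = 50L, ridge = 0) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) {
    # Null model: no covariates, baseline = Nelson-Aalen type Breslow hazard.
    prep <- cox_prep(y)
    if (sum(prep$event) == 0) stop("no events: cannot fit Cox model")
    Xs <- matrix(0, prep$n, 0)
    fit <- list(beta = numeric(0),
                baseline = breslow_baseline(Xs, prep, numeric(0)),
                converged = TRUE, n_iter = 0L,
                loglik = -cox_nll_prepped(Xs, prep, numeric(0))$value,
                trace = NULL, xnames = character(0))
    class(fit) <- "cox_fit"
    return(fit)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv < 1e-12)) {
    stop("constant column(s) in X: ", paste(colnames(X)[sdv < 1e-12], collapse = ", "))
  }
  prep <- cox_prep(y)
  if (sum(prep$event) == 0) stop("no events: cannot fit Cox model")
  Xs <- X[prep$ord, , drop = FALSE]
  p <- ncol(X)
  beta <- numeric(p)
  cur <- cox_nll_prepped(Xs, prep, beta, hessian = TRUE)
  trace <- data.frame(iter = 0L, nll = cur$value, grad_max = max(abs(cur$gradient)))
  converged <- FALSE
  iter <- 0L
  # Scale-aware separation guard: |beta_j| * sd_j bounded.
  while (iter < max_iter) {
    g <- cur$gradient + 2 * ridge * beta
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    iter <- iter + 1L
    H <- cur$hessian + diag(2 * ridge, p)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {
      H <- H + diag(1e-8 * max(diag(H), 1), p)
      step <- solve(H, g)
    }
    halve <- 0L
    repeat {
      cand <- beta - step
      nxt <- tryCatch(cox_nll_prepped(Xs, prep, cand, hessian = TRUE),
                      error = function(e) NULL)
      pen_cur <- cur$value + ridge * sum(beta^2)
      if (!is.null(nxt) && is.finite(nxt$value) &&
          nxt$value + ridge * sum(cand^2) <= pen_cur + 1e-12) break
      halve <- halve + 1L
      if (halve > 30L) {
        stop("fit_cox: step-halving failed to decrease the partial likelihood")
      }
      step <- step / 2
    }
    beta <- beta - step
    cur <- nxt
    trace <- rbind(trace, data.frame(iter = iter, nll = cur$value,
                                     grad_max = max(abs(cur$gradient))))
    if (max(abs(beta) * sdv) > 30) {
      stop("fit_cox: diverging coefficients (|beta|*sd > 30); ",
           "monotone likelihood / separation suspected")
    }
  }
  if (!converged && max(abs(cur$gradient + 2 * ridge * beta)) >= tol) {
    stop("fit_cox: no convergence after ", max_iter, " iterations; ",
         "final gradient max-norm ",
         format(max(abs(cur$gradient)), digits = 3),
         " (see trace rows: ", nrow(trace), ")")
  }
  names(beta) <- colnames(X)
  fit <- list(beta = beta,
              baseline = breslow_baseline(Xs, prep, beta),
              converged = TRUE, n_iter = iter,
              loglik = -cur$value, trace = trace,
              xnames = colnames(X))
  class(fit) <- "cox_fit"
  fit
}

# Breslow baseline cumulative hazard on pre-sorted training data.
breslow_baseline <- function(Xs, prep, beta) {
  eta <- if (length(beta)) as.numeric(Xs %*% beta) else numeric(prep$n)
  e <- exp(eta)
  rc <- revcumsum(e)
  ev <- prep$event == 1
  d_by_grp <- as.numeric(rowsum(as.numeric(ev), prep$grp_id))
  has_event <- d_by_grp > 0
  S0_grp <- rc[prep$grp_head]
  times <- prep$time[prep$grp_head][has_event]
  jumps <- d_by_grp[has_event] / S0_grp[has_event]
  data.frame(time = times, hazard = jumps, cumhaz = cumsum(jumps))
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox PH fit:", length(x$beta), "predictor(s),",
      x$n_iter, "Newton iterations, log partial likelihood",
      format(x$loglik, digits = 6), "\n")
  print(x$beta)
  invisible(x)
}

# Evaluate the baseline cumulative hazard step function at times t.
baseline_cumhaz_at <- function(fit, t, warn_extrapolate = TRUE) {
  bl <- fit$baseline
  if (nrow(bl) == 0) return(rep(0, length(t)))
  if (warn_extrapolate && any(t > max(bl$time))) {
    warning("t beyond last observed event time; using last baseline value")
  }
  idx <- findInterval(t, bl$time)
  ifelse(idx == 0, 0, bl$cumhaz[pmax(idx, 1)])
}

#' Linear-predictor risk scores
#'
#' @param fit a `cox_fit`.
#' @param X predictor matrix, column-compatible with the fit.
#' @return Numeric vector of relative log-hazards x'beta.
#' @export
predict_risk_score <- function(fit, X) {
  X <- as.matrix(X)
  if (length(fit$beta) == 0L) return(numeric(nrow(X)))
  if (ncol(X) != length(fit$beta)) {
    stop("X has ", ncol(X), " columns; fit expects ", length(fit$beta))
  }
  if (!is.null(colnames(X)) && !is.null(fit$xnames) &&
      !identical(colnames(X), fit$xnames)) {
    if (!all(fit$xnames %in% colnames(X))) {
      stop("X columns do not match the fitted predictors")
    }
    X <- X[, fit$xnames, drop = FALSE]
  }
  as.numeric(X %*% fit$beta)
}

#' Landmark absolute risk
#'
#' Absolute risk at horizon `t_star` (years): 1 - exp(-H0(t*) exp(x'beta)),
#' i.e. one minus the predicted survival probability under the
#' training-data Breslow baseline.
#'
#' @inheritParams predict_risk_score
#' @param t_star horizon in years (default 1.5).
#' @return List of class `absolute_risk`: `t_star` and per-patient `risk`.
#' @export
predict_absolute_risk <- function(fit, X, t_star = 1.5) {
  if (t_star <= 0) stop("t_star must be positive")
  lp <- predict_risk_score(fit, X)
  H0 <- baseline_cumhaz_at(fit, t_star)
  structure(list(t_star = t_star, risk = 1 - exp(-H0 * exp(lp))),
            class = "absolute_risk")
}

# Survival probability matrix at several times (patients x times).
predict_survival_matrix <- function(fit, X, times) {
  lp <- predict_risk_score(fit, X)
  H0 <- baseline_cumhaz_at(fit, times, warn_extrapolate = FALSE)
  exp(-outer(exp(lp), H0))
}
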