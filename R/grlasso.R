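# Group-lasso penalized Cox solver: regularization path by proximal
# gradient with blockwise soft-thresholding, active-set screening, warm
# starts, KKT certification, cross-validated penalty selection
# (Verweij-van Houwelingen deviance) and selection-frequency reporting.
#
# The penalty applies an l2 norm within each predefined feature family and
# an l1 norm across families, so entire families are retained or excluded
# collectively. Objective (per-observation scale):
#   f(beta) = nll(beta)/n + lambda * sum_g w_g * ||beta_g||_2

#' Group structure for the grouped penalty
#'
#' @param features character vector of feature names (columns of X).
#' @param families family label per feature.
#' @param weights optional named per-group weights w_g; default
#'   sqrt(group size), the standard group-lasso choice countering
#'   selection bias toward larger families.
#' @return Object of class `group_structure`: `groups` (named list of
#'   column indices), `assignment`, `weights`.
#' @export
group_structure <- function(features, families, weights = NULL) {
  stopifnot(length(features) == length(families))
  if (anyDuplicated(features)) stop("duplicated feature names")
  fams <- unique(families)
  groups <- lapply(fams, function(f) which(families == f))
  names(groups) <- fams
  if (is.null(weights)) {
    weights <- sqrt(vapply(groups, length, numeric(1)))
  } else {
    weights <- weights[fams]
  }
  if (any(weights <= 0) || any(is.na(weights))) stop("group weights must be positive")
  structure(list(features = features, groups = groups,
                 assignment = stats::setNames(families, features),
                 weights = weights),
            class = "group_structure")
}

#' Group-lasso penalty value
#'
#' lambda * sum_g w_g * ||beta_g||_2.
#'
#' @param beta coefficient vector (ordered as `gs$features`).
#' @param gs a [group_structure()].
#' @param lambda penalty level (>= 0).
#' @return Scalar penalty value.
#' @export
group_penalty <- function(beta, gs, lambda) {
  stopifnot(lambda >= 0)
  norms <- vapply(gs$groups, function(ix) sqrt(sum(beta[ix]^2)), numeric(1))
  lambda * sum(gs$weights * norms)
}

# Per-group l2 norms of a vector.
group_norms <- function(v, gs) {
  vapply(gs$groups, function(ix) sqrt(sum(v[ix]^2)), numeric(1))
}

#' Smallest penalty with an all-zero solution
#'
#' max_g ||grad_g l(0)||_2 / w_g, where l is the per-observation negative
#' log partial likelihood. Fitting at any lambda at or above this value
#' yields the all-zero solution.
#'
#' @param X standardized predictor matrix.
#' @param y survival outcome.
#' @param gs a [group_structure()].
#' @return Scalar lambda_max.
#' @export
compute_lambda_max <- function(X, y, gs) {
  X <- as.matrix(X)
  g0 <- neg_log_partial_likelihood(X, y, numeric(ncol(X)))$gradient / nrow(X)
  max(group_norms(g0, gs) / gs$weights)
}

# Blockwise soft-threshold (proximal map of the group penalty).
prox_group <- function(z, gs, thresh_per_group) {
  out <- z
  for (k in seq_along(gs$groups)) {
    ix <- gs$groups[[k]]
    nz <- sqrt(sum(z[ix]^2))
    out[ix] <- if (nz <= thresh_per_group[k]) 0 else (1 - thresh_per_group[k] / nz) * z[ix]
  }
  out
}

# KKT residual of the group-lasso objective at beta (max over groups):
# inactive groups: max(0, ||grad_g|| - lambda w_g);
# active groups:   ||grad_g + lambda w_g beta_g / ||beta_g|| ||.
grlasso_kkt <- function(grad, beta, gs, lambda) {
  res <- 0
  for (k in seq_along(gs$groups)) {
    ix <- gs$groups[[k]]
    nb <- sqrt(sum(beta[ix]^2))
    lw <- lambda * gs$weights[k]
    r <- if (nb == 0) max(0, sqrt(sum(grad[ix]^2)) - lw)
         else sqrt(sum((grad[ix] + lw * beta[ix] / nb)^2))
    res <- max(res, r)
  }
  res
}

# Per-observation negative log partial likelihood and residual vector
# (in sorted order) from a linear predictor; the gradient w.r.t. beta is
# X' res with res = (mu - delta)/n.
cox_eta_quants <- function(eta, prep) {
  c0 <- mean(eta)
  e <- exp(eta - c0)
  rc <- revcumsum(e)
  ev <- prep$event == 1
  d_by_grp <- as.numeric(rowsum(as.numeric(ev), prep$grp_id))
  has_event <- d_by_grp > 0
  S0_grp <- rc[prep$grp_head]
  value <- (-(sum(eta[ev] - c0)) +
              sum(d_by_grp[has_event] * log(S0_grp[has_event]))) / prep$n
  h_grp <- ifelse(has_event, d_by_grp / S0_grp, 0)
  mu <- e * cumsum(h_grp)[prep$grp_id]
  list(value = value, res = (mu - as.numeric(ev)) / prep$n, w = mu / prep$n)
}

# Exact solution of the block subproblem
#   min_u 0.5 u'A u - c'u + lw * ||u||_2
# given the eigendecomposition of A (values d >= 0, vectors V):
# u = V (V'c) / (d + nu) with nu = lw / ||u|| from the secular equation.
solve_block_eig <- function(d, V, c_vec, lw) {
  nc <- sqrt(sum(c_vec^2))
  if (nc <= lw) return(numeric(length(c_vec)))
  ct <- as.numeric(crossprod(V, c_vec))
  ct2 <- ct^2
  # Secular equation g(nu) = nu * ||u(nu)|| - lw = 0 with
  # ||u(nu)||^2 = sum ct^2/(d+nu)^2; g is increasing in nu. From
  # nc/(max(d)+nu) <= ||u(nu)|| <= nc/(min(d)+nu), the root lies in
  # [lw*min(d), lw*max(d)] / (nc - lw). Safeguarded Newton on that bracket.
  lo <- lw * min(d) / (nc - lw)
  hi <- lw * max(d) / (nc - lw) + 1e-12
  nu <- lw * mean(d) / (nc - lw) + 1e-300
  for (i in 1:100) {
    den <- d + nu
    S <- sum(ct2 / den^2)
    rS <- sqrt(S)
    g <- nu * rS - lw
    if (abs(g) < 1e-11 * max(1, lw)) break
    if (g > 0) hi <- nu else lo <- nu
    gp <- rS - nu * sum(ct2 / den^3) / rS
    step_nu <- g / gp
    nu_new <- nu - step_nu
    if (!is.finite(nu_new) || nu_new <= lo || nu_new >= hi) {
      nu_new <- (lo + hi) / 2
    }
    nu <- nu_new
  }
  as.numeric(V %*% (ct / (d + nu)))
}

# Penalized quadratic subproblem
#   min_b  g'(b - b0) + 0.5 (b - b0)' A (b - b0) + lambda sum_g w_g ||b_g||
# solved by block coordinate descent with exact block updates (blockwise
# soft-thresholding in the eigenbasis of each diagonal block of A).
# Per-block eigendecompositions are computed once and reused across sweeps.
solve_penalized_quadratic <- function(A, g, b0, gs_sub, lambda, tol,
                                      max_sweeps = 40L) {
  K <- length(gs_sub$groups)
  eigs <- lapply(seq_len(K), function(k) {
    ix <- gs_sub$groups[[k]]
    eg <- eigen(A[ix, ix, drop = FALSE], symmetric = TRUE)
    list(d = pmax(eg$values, 0), V = eg$vectors)
  })
  b <- b0
  s <- as.numeric(A %*% (b - b0))   # A (b - b0), updated incrementally
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    for (k in seq_len(K)) {
      ix <- gs_sub$groups[[k]]
      lw <- lambda * gs_sub$weights[k]
      gq <- g[ix] + s[ix]           # gradient of the smooth part at b
      b_k <- b[ix]
      c_vec <- as.numeric(A[ix, ix, drop = FALSE] %*% b_k) - gq
      u <- solve_block_eig(eigs[[k]]$d, eigs[[k]]$V, c_vec, lw)
      dk <- u - b_k
      if (any(dk != 0)) {
        s <- s + as.numeric(A[, ix, drop = FALSE] %*% dk)
        b[ix] <- u
        delta <- max(delta, max(abs(dk)))
      }
    }
    if (delta < tol) break
  }
  b
}

# Monotone solve at a single lambda on the active-set subproblem, by
# proximal Newton: an outer loop fixes the quadratic approximation of the
# partial likelihood (weighted Gram matrix, which majorizes the true
# Hessian at the current point), an inner block-coordinate loop solves the
# penalized quadratic exactly via blockwise soft-thresholding, and a
# backtracking line search on the true objective guarantees monotone
# decrease. `max_iter` caps the number of outer iterations.
grlasso_solve_at <- function(Xs, prep, gs_sub, lambda, beta0, tol, max_iter) {
  n <- prep$n
  beta <- beta0
  eta <- if (length(beta)) as.numeric(Xs %*% beta) else numeric(n)
  q <- cox_eta_quants(eta, prep)
  obj <- function(q, b) q$value + group_penalty(b, gs_sub, lambda)
  f_cur <- obj(q, beta)
  for (it in seq_len(max_iter)) {
    grad <- as.numeric(crossprod(Xs, q$res))
    if (grlasso_kkt(grad, beta, gs_sub, lambda) < tol) {
      return(list(beta = beta, iter = it - 1L, converged = TRUE))
    }
    if (max(abs(beta)) > 30) {
      # monotone likelihood / separation: no minimizer at this lambda
      return(list(beta = beta, iter = it, converged = FALSE))
    }
    A <- crossprod(Xs, Xs * q$w)
    diag(A) <- diag(A) + 1e-10 * (1 + max(diag(A)))
    b_new <- solve_penalized_quadratic(A, grad, beta, gs_sub, lambda,
                                       tol = tol * 0.1)
    d <- b_new - beta
    if (all(d == 0)) {
      return(list(beta = beta, iter = it,
                  converged = grlasso_kkt(grad, beta, gs_sub, lambda) < tol))
    }
    Xd <- as.numeric(Xs %*% d)
    tau <- 1
    repeat {
      q_try <- cox_eta_quants(eta + tau * Xd, prep)
      f_try <- obj(q_try, beta + tau * d)
      if (is.finite(f_try) && f_try <= f_cur + 1e-12) {
        beta <- beta + tau * d
        eta <- eta + tau * Xd
        q <- q_try
        f_cur <- f_try
        break
      }
      tau <- tau / 2
      if (tau < 1e-10) break
    }
    if (tau < 1e-10) {
      grad <- as.numeric(crossprod(Xs, q$res))
      return(list(beta = beta, iter = it,
                  converged = grlasso_kkt(grad, beta, gs_sub, lambda) < tol))
    }
  }
  grad <- as.numeric(crossprod(Xs, q$res))
  list(beta = beta, iter = max_iter,
       converged = grlasso_kkt(grad, beta, gs_sub, lambda) < tol)
}

#' Fit a group-lasso Cox regularization path
#'
#' For each lambda on a decreasing grid (warm-started from the previous
#' solution) minimizes nll(beta)/n + lambda sum_g w_g ||beta_g|| by
#' monotone proximal gradient with blockwise soft-thresholding, using an
#' active-set strategy: solve on the currently active families, then
#' certify group-level KKT conditions on all families and grow the active
#' set with any violators. Every reported path point satisfies the KKT
#' conditions within `tol`.
#'
#' @param X standardized predictor matrix (training-fold statistics; a
#'   warning is raised if column SDs deviate from 1).
#' @param y survival outcome.
#' @param gs a [group_structure()] covering the columns of X.
#' @param lambda optional decreasing grid; default `nlambda` log-spaced
#'   points from lambda_max down to `lambda_min_ratio * lambda_max`.
#' @param nlambda,lambda_min_ratio grid controls.
#' @param tol KKT tolerance.
#' @param max_iter per-lambda proximal iteration cap.
#' @param check_std verify column standardization.
#' @param on_divergence what to do when no minimizer exists at a small
#'   lambda (monotone likelihood / separation, typical when the
#'   unpenalized end of the path is reached with more features than
#'   events): "error" (default) or "truncate" (drop the remaining path
#'   points; used by cross-validation).
#' @return Object of class `grlasso_path`: `lambda`, `beta` (p x L matrix),
#'   `active` (list of active family names per lambda), `kkt` residuals,
#'   `lambda_max`, `gs`.
#' @export
fit_grlasso_path <- function(X, y, gs, lambda = NULL, nlambda = 100L,
                             lambda_min_ratio = 0.001, tol = 1e-6,
                             max_iter = 200L, check_std = TRUE,
                             on_divergence = c("error", "truncate")) {
  on_divergence <- match.arg(on_divergence)
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(length(gs$features) == p)
  if (check_std) {
    sdv <- apply(X, 2, stats::sd)
    if (any(abs(sdv - 1) > 1e-6)) {
      warning("X does not look standardized (column SD != 1); ",
              "pass training-fold standardized predictors")
    }
  }
  prep <- cox_prep(y)
  if (sum(prep$event) == 0) stop("no events")
  Xs_full <- X[prep$ord, , drop = FALSE]
  lam_max <- compute_lambda_max(X, y, gs)
  if (is.null(lambda)) {
    lambda <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                      length.out = nlambda))
  } else {
    lambda <- sort(lambda, decreasing = TRUE)
  }
  L <- length(lambda)
  betas <- matrix(0, p, L, dimnames = list(gs$features, NULL))
  kkt <- numeric(L)
  active <- vector("list", L)
  beta <- numeric(p)
  act <- character(0)  # active family names
  fam_names <- names(gs$groups)
  # KKT certification tolerance slightly below solver tolerance target.
  truncated <- FALSE
  for (l in seq_len(L)) {
    lam <- lambda[l]
    beta_prev <- beta
    diverged <- FALSE
    repeat {
      if (length(act)) {
        cols <- unlist(gs$groups[act], use.names = FALSE)
        gs_sub <- group_structure(gs$features[cols],
                                  gs$assignment[cols],
                                  weights = gs$weights[act])
        sol <- grlasso_solve_at(Xs_full[, cols, drop = FALSE], prep, gs_sub,
                                lam, beta[cols], tol = tol * 0.5,
                                max_iter = max_iter)
        if (!sol$converged || max(abs(sol$beta)) > 30) {
          diverged <- TRUE
          break
        }
        beta[] <- 0
        beta[cols] <- sol$beta
      } else {
        beta[] <- 0
      }
      grad <- cox_nll_prepped(Xs_full, prep, beta)$gradient / prep$n
      viol <- group_norms(grad, gs) - lam * gs$weights > tol * 0.5
      viol_new <- setdiff(fam_names[viol], act)
      if (!length(viol_new)) {
        kkt[l] <- grlasso_kkt(grad, beta, gs, lam)
        break
      }
      act <- union(act, viol_new)
    }
    if (diverged) {
      if (on_divergence == "error" || l == 1L) {
        stop("group-lasso solver failed to converge at lambda = ",
             format(lam, digits = 6),
             " (monotone likelihood / separation suspected)")
      }
      L <- l - 1L
      truncated <- TRUE
      beta <- beta_prev
      break
    }
    act <- fam_names[vapply(gs$groups, function(ix) any(beta[ix] != 0), logical(1))]
    betas[, l] <- beta
    active[[l]] <- act
  }
  structure(list(lambda = lambda[seq_len(L)],
                 beta = betas[, seq_len(L), drop = FALSE],
                 active = active[seq_len(L)], kkt = kkt[seq_len(L)],
                 lambda_max = lam_max, gs = gs, truncated = truncated),
            class = "grlasso_path")
}

#' @export
print.grlasso_path <- function(x, ...) {
  cat("Group-lasso Cox path:", length(x$lambda), "lambda values, lambda_max =",
      format(x$lambda_max, digits = 4), "\n")
  if (!is.null(x$cv)) {
    cat("  CV-selected lambda:", format(x$lambda_selected, digits = 4),
        "| active families:",
        paste(x$active[[x$selected_index]], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Cross-validated penalty selection
#'
#' Verweij-van Houwelingen cross-validated partial-likelihood deviance:
#' for each fold, dev(lambda) = -2 [ l_full(beta_-f) - l_-f(beta_-f) ],
#' where beta_-f is the path fit without the fold. Selects the lambda
#' minimizing the mean deviance across folds (`lambda_1se = TRUE` applies
#' the one-standard-error rule instead).
#'
#' @inheritParams fit_grlasso_path
#' @param k_folds number of folds (stratified by event status).
#' @param seed fold-assignment seed.
#' @param lambda_1se select the sparsest lambda within 1 SE of the minimum.
#' @param tol KKT tolerance for the reported full-data path.
#' @param cv_fold_tol KKT tolerance for the internal leave-fold-out path
#'   fits (looser than the reported full-data path).
#' @param ... passed to [fit_grlasso_path()].
#' @return A `grlasso_path` (full-data path) with components `cv`
#'   (data.frame: lambda, mean deviance, se), `lambda_selected`,
#'   `selected_index`, `selected_features`.
#' @export
cv_select_lambda <- function(X, y, gs, k_folds = 5L, seed = 1L,
                             lambda_1se = FALSE, tol = 1e-6,
                             cv_fold_tol = 1e-4, check_std = TRUE, ...) {
  stopifnot(k_folds >= 2)
  X <- as.matrix(X)
  y <- as_surv_outcome(y)
  folds <- make_outer_folds(y, k = k_folds, seed = seed)
  path <- fit_grlasso_path(X, y, gs, tol = tol, check_std = check_std,
                           on_divergence = "truncate", ...)
  L <- length(path$lambda)
  dev <- matrix(NA_real_, k_folds, L)
  prep_full <- cox_prep(y)
  Xs_full <- X[prep_full$ord, , drop = FALSE]
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    if (sum(y$event[tr]) == 0) {
      stop("fold ", f, " training set has zero events; re-stratify folds")
    }
    y_tr <- surv_outcome(y$time[tr], y$event[tr])
    prep_tr <- cox_prep(y_tr)
    X_tr <- X[tr, , drop = FALSE]
    path_f <- fit_grlasso_path(X_tr, y_tr, gs, lambda = path$lambda,
                               check_std = FALSE,
                               tol = max(cv_fold_tol, tol),
                               on_divergence = "truncate", ...)
    Xs_tr <- X_tr[prep_tr$ord, , drop = FALSE]
    for (l in seq_len(length(path_f$lambda))) {
      b <- path_f$beta[, l]
      l_full <- -cox_nll_prepped(Xs_full, prep_full, b)$value
      l_tr <- -cox_nll_prepped(Xs_tr, prep_tr, b)$value
      dev[f, l] <- -2 * (l_full - l_tr)
    }
  }
  # Restrict selection to lambdas fit in every fold (paths may truncate
  # where the unpenalized end diverges).
  complete_l <- colSums(is.na(dev)) == 0
  if (!any(complete_l)) stop("no lambda value was fit in every CV fold")
  cvm <- colMeans(dev)
  cvm[!complete_l] <- Inf
  cvse <- apply(dev, 2, stats::sd) / sqrt(k_folds)
  i_min <- which.min(cvm)
  i_sel <- if (lambda_1se) which(cvm <= cvm[i_min] + cvse[i_min])[1] else i_min
  path$cv <- data.frame(lambda = path$lambda, deviance = cvm, se = cvse)
  path$selected_index <- i_sel
  path$lambda_selected <- path$lambda[i_sel]
  path$selected_features <- path$gs$features[path$beta[, i_sel] != 0]
  path$folds <- folds
  path
}

#' Selection frequency across outer folds
#'
#' Per-feature count of outer folds in which the feature had a nonzero
#' coefficient at the fold's CV-selected penalty, and the mean per-fold
#' coefficient (zeros included), sorted by frequency then |mean|.
#'
#' @param fold_coefs list of named coefficient vectors, one per outer fold
#'   (e.g. the selected-lambda column of each fold's path).
#' @return data.frame: feature, coefficient (mean), selection_frequency.
#' @export
selection_frequency <- function(fold_coefs) {
  stopifnot(length(fold_coefs) >= 1)
  feats <- names(fold_coefs[[1]])
  M <- vapply(fold_coefs, function(b) b[feats], numeric(length(feats)))
  M <- matrix(M, nrow = length(feats),
              dimnames = list(feats, NULL))
  out <- data.frame(
    feature = feats,
    coefficient = rowMeans(M),
    selection_frequency = rowSums(M != 0),
    row.names = NULL)
  out[order(-out$selection_frequency, -abs(out$coefficient)), , drop = FALSE]
}
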