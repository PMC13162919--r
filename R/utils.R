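# Internal helpers shared across modules.

#' Survival outcome container
#'
#' Bundles follow-up time (years) and the event indicator (1 = death,
#' 0 = censored) after validation. All modelling and evaluation functions
#' in the package accept the returned object or any list/data.frame with
#' `time` and `event` components.
#'
#' @param time numeric vector of strictly positive follow-up times (years).
#' @param event integer/numeric vector of 0/1 event indicators.
#' @return An object of class `surv_outcome`: a data.frame with columns
#'   `time` and `event`.
#' @export
surv_outcome <- function(time, event) {
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("follow-up times must be finite and strictly positive")
  }
  if (!all(event %in% c(0, 1))) stop("event must be coded 0 (censored) / 1 (death)")
  structure(data.frame(time = time, event = event), class = c("surv_outcome", "data.frame"))
}

as_surv_outcome <- function(y) {
  if (inherits(y, "surv_outcome")) return(y)
  if (is.list(y) && all(c("time", "event") %in% names(y))) {
    return(surv_outcome(y$time, y$event))
  }
  stop("y must be a surv_outcome or have $time and $event components")
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from a base seed; stays below 2^31.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629
}

# Column standardization using supplied (training) statistics.
std_fit <- function(X) {
  ctr <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv < 1e-12)) {
    stop("constant column(s): ", paste(colnames(X)[sdv < 1e-12], collapse = ", "))
  }
  list(center = ctr, scale = sdv)
}

std_apply <- function(X, st) {
  sweep(sweep(X, 2, st$center, "-"), 2, st$scale, "/")
}

# Reverse cumulative sum (vector) / column-wise (matrix).
revcumsum <- function(x) {
  if (is.matrix(x)) {
    n <- nrow(x)
    if (n <= 1L) return(x)
    y <- apply(x[n:1L, , drop = FALSE], 2, cumsum)
    y <- matrix(y, nrow = n, dimnames = dimnames(x))
    y[n:1L, , drop = FALSE]
  } else {
    rev(cumsum(rev(x)))
  }
}

# Rank transform to [0, 1] learned on a training vector, applied to new values.
rank_transform <- function(train) {
  train <- sort(train)
  n <- length(train)
  function(x) findInterval(x, train) / n
}
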