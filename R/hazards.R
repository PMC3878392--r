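#' Fit a time-constant additive hazards model
#'
#' Fits the semiparametric additive hazards model
#' \eqn{\alpha(t \mid x) = \beta_0(t) + \lambda' x} with time-constant
#' covariate effects \eqn{\lambda}, leaving the baseline \eqn{\beta_0(t)}
#' unspecified (it is profiled out by risk-set centering and not returned).
#' The estimator is the closed-form solution of the counting-process
#' estimating equation
#' \deqn{\hat\lambda = A^{-1} b, \quad
#'   A = \sum_i \int Y_i(t)\{x_i - \bar x(t)\}^{\otimes 2}\, dt, \quad
#'   b = \sum_i \int \{x_i - \bar x(t)\}\, dN_i(t),}
#' where \eqn{Y_i(t)} is the at-risk indicator and \eqn{\bar x(t)} the at-risk
#' average of the covariates. The covariance is the sandwich
#' \eqn{A^{-1} B A^{-1}} with
#' \eqn{B = \sum_i \int \{x_i - \bar x(t)\}^{\otimes 2}\, dN_i(t)}.
#' All integrals are finite sums over the distinct observed times.
#'
#' Ties are handled by aggregating counting-process increments at distinct
#' times; subjects censored at a time t remain at risk through t (censoring
#' is ordered after events at the same time).
#'
#' @param data A data frame with one row per sample.
#' @param time,status Columns holding the nonnegative follow-up time and the
#'   event indicator (1 = event observed, 0 = censored). Tidy-eval: pass bare
#'   column names.
#' @param covariates Columns to use as hazard covariates (tidyselect). By
#'   default, every numeric column other than `time` and `status`.
#' @return An object of class `hazards_fit`: a list with `coefficients`
#'   (named vector), `vcov` (sandwich covariance matrix), `n_samples`,
#'   `n_events`.
#' @examples
#' d <- simulate_cohort(sim_config(seed = 1), n = 200)
#' fit_additive_hazards(d, time, status, c(mrna, dcna))
#' @export
fit_additive_hazards <- function(data, time = time, status = status,
                                 covariates = NULL) {
  stopifnot(is.data.frame(data))
  time_v <- dplyr::pull(data, {{ time }})
  status_v <- dplyr::pull(data, {{ status }})
  time_name <- names(tidyselect::eval_select(enquo(time), data))
  status_name <- names(tidyselect::eval_select(enquo(status), data))
  cov_quo <- enquo(covariates)
  if (rlang::quo_is_null(cov_quo)) {
    keep <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                    c(time_name, status_name))
    if (length(keep) == 0) {
      abort("no candidate covariate columns found", class = "medhaz_validation_error")
    }
    X <- as.matrix(data[keep])
  } else {
    X <- as.matrix(dplyr::select(data, !!cov_quo))
  }
  validate_survival_inputs(time_v, status_v, X)
  fit <- ly_fit(time_v, status_v, X, compute_vcov = TRUE)
  new_hazards_fit(fit$coef, fit$vcov, n_samples = length(time_v),
                  n_events = sum(status_v == 1))
}

new_hazards_fit <- function(coefficients, vcov, n_samples, n_events) {
  structure(
    list(coefficients = coefficients, vcov = vcov,
         n_samples = n_samples, n_events = n_events),
    class = "hazards_fit"
  )
}

validate_survival_inputs <- function(time, status, X) {
  if (anyNA(time) || anyNA(status) || anyNA(X)) {
    abort("survival data contain missing values", class = "medhaz_validation_error")
  }
  if (any(time < 0)) {
    abort("follow-up times must be nonnegative", class = "medhaz_validation_error")
  }
  if (!all(status %in% c(0, 1))) {
    abort("event status must be 0 (censored) or 1 (event)",
          class = "medhaz_validation_error")
  }
  if (sum(status == 1) == 0) {
    abort("at least one observed event is required", class = "medhaz_validation_error")
  }
  if (is.null(colnames(X)) || anyDuplicated(colnames(X))) {
    abort("covariates must have unique column names", class = "medhaz_validation_error")
  }
  n_distinct <- apply(X, 2, function(v) length(unique(v)))
  if (any(n_distinct < 2)) {
    abort(paste0("degenerate design: covariate '",
                 colnames(X)[which(n_distinct < 2)[1]],
                 "' is constant"),
          class = "medhaz_degenerate_design")
  }
  invisible(NULL)
}

# Core closed-form solver. Vectorised over distinct observed times:
# on each inter-event interval the risk set is constant, so the dt-integral
# in A is a weighted sum of centered cross-product matrices; b and B are sums
# of risk-set-centered covariates (and their outer products) over events.
ly_fit <- function(time, status, X, compute_vcov = TRUE) {
  n <- length(time)
  p <- ncol(X)
  o <- order(time)
  ts <- time[o]
  d <- status[o]
  Xs <- X[o, , drop = FALSE]

  # upper-triangle product columns (i <= j) represent symmetric matrices
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  pi_ <- pairs[, 1]
  pj_ <- pairs[, 2]
  P <- Xs[, pi_, drop = FALSE] * Xs[, pj_, drop = FALSE]

  # suffix (reverse cumulative) sums: row k holds the sum over subjects k..n,
  # i.e. the at-risk totals just before the k-th smallest time
  S1 <- suffix_cumsum(Xs)
  S2 <- suffix_cumsum(P)

  first <- which(!duplicated(ts))
  ut <- ts[first]
  S0 <- n - first + 1
  dt <- diff(c(0, ut))

  S1f <- S1[first, , drop = FALSE]
  S2f <- S2[first, , drop = FALSE]
  centered <- S2f - S1f[, pi_, drop = FALSE] * S1f[, pj_, drop = FALSE] / S0
  A <- sym_from_upper(colSums(dt * centered), p)

  if (rcond_safe(A) < 1e-12) {
    abort("degenerate design: at-risk covariate information matrix is singular",
          class = "medhaz_degenerate_design")
  }

  time_index <- cumsum(!duplicated(ts))
  ev <- which(d == 1)
  xbar_ev <- S1f[time_index[ev], , drop = FALSE] / S0[time_index[ev]]
  resid_ev <- Xs[ev, , drop = FALSE] - xbar_ev
  b <- colSums(resid_ev)

  coef <- drop(solve(A, b))
  names(coef) <- colnames(X)

  vcov <- NULL
  if (compute_vcov) {
    Bv <- colSums(resid_ev[, pi_, drop = FALSE] * resid_ev[, pj_, drop = FALSE])
    B <- sym_from_upper(Bv, p)
    Ai <- solve(A)
    vcov <- Ai %*% B %*% Ai
    dimnames(vcov) <- list(colnames(X), colnames(X))
  }
  list(coef = coef, vcov = vcov)
}

suffix_cumsum <- function(M) {
  n <- nrow(M)
  out <- M
  for (j in seq_len(ncol(M))) {
    out[, j] <- rev(cumsum(rev(M[, j])))
  }
  out
}

sym_from_upper <- function(v, p) {
  M <- matrix(0, p, p)
  M[upper.tri(M, diag = TRUE)] <- v
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}

rcond_safe <- function(A) {
  if (nrow(A) == 1) {
    if (A[1, 1] == 0) 0 else 1
  } else {
    tryCatch(rcond(A), error = function(e) 0)
  }
}

#' @export
print.hazards_fit <- function(x, ...) {
  cat("Time-constant additive hazards fit\n")
  cat(sprintf("  n = %d samples, %d events\n", x$n_samples, x$n_events))
  tab <- cbind(estimate = x$coefficients,
               std.error = sqrt(diag(x$vcov)))
  print(round(tab, 4))
  invisible(x)
}

#' @rdname fit_additive_hazards
#' @param x A `hazards_fit` object.
#' @param ... Unused.
#' @method tidy hazards_fit
#' @export
tidy.hazards_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(z),
    p.value = 2 * pnorm(-abs(unname(z)))
  )
}

#' @rdname fit_additive_hazards
#' @method glance hazards_fit
#' @export
glance.hazards_fit <- function(x, ...) {
  tibble::tibble(n_samples = x$n_samples, n_events = x$n_events,
                 n_covariates = length(x$coefficients))
}
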