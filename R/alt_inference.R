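#' Normal-product confidence interval for the mediated effect
#'
#' The product of the two (asymptotically normal, independent) path
#' estimates is not normal: it follows the normal-product distribution, a
#' leptokurtic distribution symmetric about its mean. This interval takes
#' empirical quantiles of a seeded Monte-Carlo sample of
#' \eqn{A \cdot L} with \eqn{A \sim N(\hat\alpha_m, se_\alpha^2)} and
#' \eqn{L \sim N(\hat\lambda_m, se_\lambda^2)} independent.
#'
#' @param alpha_hat,se_alpha Estimate and standard error of the
#'   exposure-to-mediator slope.
#' @param lambda_hat,se_lambda Estimate and standard error of the mediator
#'   hazard coefficient.
#' @param level Nominal confidence level.
#' @param draws Number of Monte-Carlo draws (>= 1e5).
#' @param seed Integer seed; the interval is deterministic given the seed.
#' @return A one-row tibble of class `interval_estimate` with columns
#'   `method`, `lower`, `upper`, `level`.
#' @examples
#' product_normal_ci(0.775, 0.18, 0.4, 0.36, seed = 1)
#' @export
product_normal_ci <- function(alpha_hat, se_alpha, lambda_hat, se_lambda,
                              level = 0.95, draws = 1e5, seed = 1) {
  if (se_alpha < 0 || se_lambda < 0) {
    abort("standard errors must be nonnegative", class = "medhaz_validation_error")
  }
  if (draws < 1e5) {
    abort("draws must be at least 1e5", class = "medhaz_validation_error")
  }
  if (level <= 0 || level >= 1) {
    abort("level must be in (0, 1)", class = "medhaz_validation_error")
  }
  if (se_alpha == 0 && se_lambda == 0) {
    m <- alpha_hat * lambda_hat
    return(new_interval("product_normal", m, m, level))
  }
  bounds <- with_seed(seed, {
    prod_draws <- rnorm(draws, alpha_hat, se_alpha) *
      rnorm(draws, lambda_hat, se_lambda)
    empirical_quantile(prod_draws, c((1 - level) / 2, 1 - (1 - level) / 2))
  })
  new_interval("product_normal", bounds[1], bounds[2], level)
}

new_interval <- function(method, lower, upper, level, extra = NULL) {
  out <- tibble::tibble(method = method, lower = lower, upper = upper,
                        level = level)
  structure(out, class = c("interval_estimate", class(out)), extra = extra)
}

#' Nonparametric bootstrap confidence intervals for the mediated effect
#'
#' Resamples whole individuals (exposure, mediator, time, status rows) with
#' replacement, recomputes the full two-regression mediated-effect estimate
#' on every resample, and forms one of four intervals: `boot_normal`
#' (bias-corrected normal approximation), `boot_basic` (reflected
#' percentiles), `boot_percentile` (empirical quantiles, rank interpolation
#' at (R+1)q), or `boot_bca` (bias-corrected and accelerated, with jackknife
#' acceleration). Resamples with a degenerate design (constant exposure or
#' no events) are redrawn and counted; more than 10\% degenerate resamples is
#' an error.
#'
#' @inheritParams mediate_survival
#' @param method One of `"boot_normal"`, `"boot_basic"`, `"boot_percentile"`,
#'   `"boot_bca"`.
#' @param replicates Number of bootstrap resamples (>= 199).
#' @param seed Integer seed; deterministic given the seed.
#' @return A one-row `interval_estimate` tibble. The replicate estimates are
#'   attached as `attr(, "replicates")` for audit.
#' @export
bootstrap_ci <- function(data, method = c("boot_percentile", "boot_basic",
                                          "boot_normal", "boot_bca"),
                         replicates = 999, level = 0.95, seed = 1,
                         exposure = dcna, mediator = mrna,
                         time = time, status = status) {
  method <- match.arg(method)
  if (replicates < 199) {
    abort("replicates must be at least 199", class = "medhaz_validation_error")
  }
  x <- dplyr::pull(data, {{ exposure }})
  y <- dplyr::pull(data, {{ mediator }})
  tv <- dplyr::pull(data, {{ time }})
  sv <- dplyr::pull(data, {{ status }})
  est <- mediated_estimate_xy(x, y, tv, sv)

  boots <- with_seed(seed, draw_boot_estimates(x, y, tv, sv, replicates))
  interval <- boot_interval(method, est, boots$estimates, level,
                            x = x, y = y, tv = tv, sv = sv)
  out <- new_interval(method, interval[1], interval[2], level)
  attr(out, "replicates") <- boots$estimates
  attr(out, "n_degenerate") <- boots$n_degenerate
  attr(out, "estimate") <- est
  out
}

# Point estimate of the mediated effect: OLS slope times the mediator's
# constant additive-hazard coefficient (no covariance needed -> fast path).
mediated_estimate_xy <- function(x, y, tv, sv) {
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) {
    abort("degenerate design: exposure is constant",
          class = "medhaz_degenerate_design")
  }
  am <- sum(xc * y) / sxx
  fit <- ly_fit(tv, sv, cbind(m = y, x = x), compute_vcov = FALSE)
  am * fit$coef[[1]]
}

draw_boot_estimates <- function(x, y, tv, sv, replicates) {
  n <- length(x)
  estimates <- numeric(replicates)
  n_degenerate <- 0L
  max_degenerate <- ceiling(0.1 * replicates)
  for (r in seq_len(replicates)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      ok <- sum(sv[idx]) > 0 && length(unique(x[idx])) > 1 &&
        length(unique(y[idx])) > 1
      if (ok) {
        est <- tryCatch(
          mediated_estimate_xy(x[idx], y[idx], tv[idx], sv[idx]),
          medhaz_degenerate_design = function(e) NULL
        )
        if (!is.null(est)) {
          estimates[r] <- est
          break
        }
      }
      n_degenerate <- n_degenerate + 1L
      if (n_degenerate > max_degenerate) {
        abort("more than 10% of bootstrap resamples had a degenerate design",
              class = "medhaz_degenerate_design")
      }
    }
  }
  list(estimates = estimates, n_degenerate = n_degenerate)
}

boot_interval <- function(method, est, boots, level, x = NULL, y = NULL,
                          tv = NULL, sv = NULL) {
  lo <- (1 - level) / 2
  hi <- 1 - lo
  switch(
    method,
    boot_normal = {
      bias <- mean(boots) - est
      (est - bias) + c(-1, 1) * qnorm(hi) * sd(boots)
    },
    boot_basic = {
      q <- empirical_quantile(boots, c(lo, hi))
      c(2 * est - q[2], 2 * est - q[1])
    },
    boot_percentile = empirical_quantile(boots, c(lo, hi)),
    boot_bca = bca_interval(est, boots, lo, hi, x, y, tv, sv)
  )
}

# BCa: bias correction z0 from the fraction of replicates below the point
# estimate; acceleration from the jackknife influence of each individual.
bca_interval <- function(est, boots, lo, hi, x, y, tv, sv) {
  prop <- mean(boots < est)
  if (prop == 0 || prop == 1) {
    warn("all bootstrap replicates on one side of the estimate; BCa falls back to percentile")
    return(empirical_quantile(boots, c(lo, hi)))
  }
  z0 <- qnorm(prop)
  n <- length(x)
  jack <- vapply(seq_len(n), function(i) {
    tryCatch(
      mediated_estimate_xy(x[-i], y[-i], tv[-i], sv[-i]),
      error = function(e) NA_real_
    )
  }, numeric(1))
  jack <- jack[is.finite(jack)]
  u <- mean(jack) - jack
  denom <- 6 * sum(u^2)^1.5
  a <- if (denom == 0) 0 else sum(u^3) / denom
  adj <- function(q) {
    zq <- qnorm(q)
    pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  }
  empirical_quantile(boots, c(adj(lo), adj(hi)))
}
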