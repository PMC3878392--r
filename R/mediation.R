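#' First-order (Delta-method) variance propagation
#'
#' Returns \eqn{g' \Sigma g}, the first-order approximation to the variance
#' of a smooth function of asymptotically normal estimators, where `gradient`
#' holds the partial derivatives evaluated at the point estimate and
#' `covariance` the joint covariance matrix of the estimators.
#'
#' @param gradient Numeric vector of partial derivatives.
#' @param covariance Symmetric covariance matrix of matching dimension.
#' @return A single nonnegative number (up to floating-point error).
#' @examples
#' delta_variance(c(3, 2), diag(c(0.04, 0.25)))
#' @export
delta_variance <- function(gradient, covariance) {
  if (!is.numeric(gradient) || !is.matrix(covariance)) {
    abort("gradient must be numeric and covariance a matrix",
          class = "medhaz_validation_error")
  }
  if (length(gradient) != nrow(covariance) ||
      nrow(covariance) != ncol(covariance)) {
    abort("gradient and covariance dimensions do not match",
          class = "medhaz_validation_error")
  }
  if (max(abs(covariance - t(covariance))) >
      1e-8 * max(1, max(abs(covariance)))) {
    abort("covariance matrix is not symmetric",
          class = "medhaz_validation_error")
  }
  drop(crossprod(gradient, covariance %*% gradient))
}

#' Combine mediator and hazards fits into mediation inference
#'
#' Forms the product-of-coefficients mediated effect
#' \eqn{\alpha_m \lambda_m}, the total effect
#' \eqn{\alpha_m \lambda_m + \lambda_c}, the direct effect \eqn{\lambda_c}
#' and the relative magnitude
#' \eqn{P_M = \alpha_m\lambda_m / (\alpha_m\lambda_m + \lambda_c)},
#' with Delta-method variances
#' \deqn{\sigma^2_{Med} = \alpha_m^2\sigma^2_{\lambda_m} +
#'       \lambda_m^2\sigma^2_{\alpha_m}}
#' \deqn{\sigma^2_{Tot} = \sigma^2_{\lambda_c} + \alpha_m^2\sigma^2_{\lambda_m}
#'       + \lambda_m^2\sigma^2_{\alpha_m} + 2\alpha_m\sigma_{\lambda_m\lambda_c}}
#' and, for \eqn{P_M}, generic gradient propagation over
#' \eqn{(\alpha_m, \lambda_m, \lambda_c)} with the full block covariance
#' (the OLS slope is independent of the hazards coefficients; the
#' \eqn{\lambda}'s carry their estimated covariance). Z statistics are
#' estimate / standard error with two-sided normal p-values, and Wald
#' confidence intervals are estimate \eqn{\pm z_{\alpha/2}} se.
#'
#' `var_total` can come out negative when a large negative
#' \eqn{\sigma_{\lambda_m\lambda_c}} dominates; it is then floored at zero
#' and flagged (`total_variance_floored`). A total effect of exactly zero
#' leaves `relative_magnitude` and its variance undefined (`NA`, flagged
#' `pm_undefined`). Relative-magnitude inference is always flagged
#' `pm_unstable`: its point and variance estimates require very large
#' samples to stabilise.
#'
#' @param med A `mediator_fit`.
#' @param haz A `hazards_fit` whose coefficients include `mediator_name` and
#'   `exposure_name`.
#' @param mediator_name,exposure_name Names of the mediator and exposure
#'   coefficients in `haz`.
#' @param level Nominal confidence level in (0, 1).
#' @return An object of class `mediation_result`.
#' @export
mediation_inference <- function(med, haz, mediator_name = "mrna",
                                exposure_name = "dcna", level = 0.95) {
  stopifnot(inherits(med, "mediator_fit"), inherits(haz, "hazards_fit"))
  if (!all(c(mediator_name, exposure_name) %in% names(haz$coefficients))) {
    abort("hazards fit does not contain the named mediator/exposure coefficients",
          class = "medhaz_validation_error")
  }
  if (level <= 0 || level >= 1) {
    abort("level must be in (0, 1)", class = "medhaz_validation_error")
  }
  am <- med$slope
  v_am <- med$slope_variance
  lm_ <- haz$coefficients[[mediator_name]]
  lc <- haz$coefficients[[exposure_name]]
  v_lm <- haz$vcov[mediator_name, mediator_name]
  v_lc <- haz$vcov[exposure_name, exposure_name]
  cov_lmlc <- haz$vcov[mediator_name, exposure_name]

  mediated <- am * lm_
  direct <- lc
  total <- mediated + direct

  var_mediated <- am^2 * v_lm + lm_^2 * v_am
  var_total_raw <- v_lc + am^2 * v_lm + lm_^2 * v_am + 2 * am * cov_lmlc
  total_floored <- var_total_raw < 0
  if (total_floored) {
    warn("Delta-method variance of the total effect is negative; floored at 0")
  }
  var_total <- max(var_total_raw, 0)

  pm_undefined <- total == 0
  if (pm_undefined) {
    pm <- NA_real_
    var_pm <- NA_real_
  } else {
    pm <- mediated / total
    # gradient of a*l / (a*l + c) over (a, l, c)
    grad <- c(lm_ * lc, am * lc, -mediated) / total^2
    sigma <- matrix(0, 3, 3)
    sigma[1, 1] <- v_am
    sigma[2, 2] <- v_lm
    sigma[3, 3] <- v_lc
    sigma[2, 3] <- sigma[3, 2] <- cov_lmlc
    var_pm <- delta_variance(grad, sigma)
  }

  zq <- qnorm(1 - (1 - level) / 2)
  zify <- function(est, v) if (v > 0) est / sqrt(v) else NA_real_
  z_mediated <- zify(mediated, var_mediated)
  z_total <- zify(total, var_total)
  z_direct <- zify(direct, v_lc)
  pval <- function(z) if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z))

  ci <- function(est, v) {
    if (is.na(v)) return(c(NA_real_, NA_real_))
    est + c(-1, 1) * zq * sqrt(v)
  }

  structure(
    list(
      mediated = mediated, total = total, direct = direct,
      relative_magnitude = pm,
      var_mediated = var_mediated, var_total = var_total,
      var_direct = v_lc, var_pm = var_pm,
      z_mediated = z_mediated, z_total = z_total, z_direct = z_direct,
      p_mediated = pval(z_mediated), p_total = pval(z_total),
      p_direct = pval(z_direct),
      ci_mediated = ci(mediated, var_mediated),
      ci_total = ci(total, var_total),
      ci_pm = if (pm_undefined) c(NA_real_, NA_real_) else ci(pm, var_pm),
      level = level,
      alpha_m = am, lambda_m = lm_, lambda_c = lc,
      var_alpha_m = v_am, var_lambda_m = v_lm, var_lambda_c = v_lc,
      cov_lambda = cov_lmlc,
      n_samples = haz$n_samples, n_events = haz$n_events,
      flags = list(total_variance_floored = total_floored,
                   pm_undefined = pm_undefined,
                   pm_unstable = TRUE)
    ),
    class = "mediation_result"
  )
}

#' Full mediation analysis of a survival cohort
#'
#' One-call pipeline: fits the mediator regression of `mediator` on
#' `exposure`, the additive hazards model with both `mediator` and
#' `exposure` as covariates, and combines them via [mediation_inference()].
#'
#' @inheritParams fit_additive_hazards
#' @param exposure,mediator Bare column names of the exposure and mediator.
#' @param level Nominal confidence level.
#' @return A `mediation_result`.
#' @examples
#' d <- simulate_cohort(sim_config(seed = 7), n = 300)
#' res <- mediate_survival(d)
#' tidy(res)
#' @export
mediate_survival <- function(data, exposure = dcna, mediator = mrna,
                             time = time, status = status, level = 0.95) {
  exp_name <- names(tidyselect::eval_select(enquo(exposure), data))
  med_name <- names(tidyselect::eval_select(enquo(mediator), data))
  med <- fit_mediator(data, {{ exposure }}, {{ mediator }})
  haz <- fit_additive_hazards(data, {{ time }}, {{ status }},
                              covariates = dplyr::all_of(c(med_name, exp_name)))
  mediation_inference(med, haz, mediator_name = med_name,
                      exposure_name = exp_name, level = level)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Survival mediation analysis (Delta-method inference)\n")
  cat(sprintf("  n = %d samples, %d events; level = %.2f\n",
              x$n_samples, x$n_events, x$level))
  print(as.data.frame(tidy(x)), row.names = FALSE, digits = 4)
  if (!is.na(x$relative_magnitude)) {
    cat("  note: relative-magnitude inference is unstable at moderate n\n")
  }
  invisible(x)
}

#' @rdname mediation_inference
#' @param x A `mediation_result` object.
#' @param ... Unused.
#' @method tidy mediation_result
#' @export
tidy.mediation_result <- function(x, ...) {
  tibble::tibble(
    term = c("mediated", "total", "direct", "relative_magnitude"),
    estimate = c(x$mediated, x$total, x$direct, x$relative_magnitude),
    std.error = sqrt(c(x$var_mediated, x$var_total, x$var_direct, x$var_pm)),
    statistic = c(x$z_mediated, x$z_total, x$z_direct, NA_real_),
    p.value = c(x$p_mediated, x$p_total, x$p_direct, NA_real_),
    conf.low = c(x$ci_mediated[1], x$ci_total[1], NA_real_, x$ci_pm[1]),
    conf.high = c(x$ci_mediated[2], x$ci_total[2], NA_real_, x$ci_pm[2])
  )
}

#' @rdname mediation_inference
#' @method glance mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(
    n_samples = x$n_samples, n_events = x$n_events, level = x$level,
    alpha_m = x$alpha_m, lambda_m = x$lambda_m, lambda_c = x$lambda_c,
    total_variance_floored = x$flags$total_variance_floored,
    pm_undefined = x$flags$pm_undefined,
    pm_unstable = x$flags$pm_unstable
  )
}
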