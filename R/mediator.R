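#' Fit the mediator regression (mRNA on DCNA)
#'
#' Ordinary least-squares regression of the mediator on the exposure. The
#' slope is the exposure-to-mediator path coefficient of the mediation model
#' (the change in mediator per unit exposure); its variance is the residual
#' variance (n - 2 denominator) divided by the centered sum of squares of the
#' exposure.
#'
#' @param data A data frame with one row per sample.
#' @param exposure,mediator Bare column names of the exposure (e.g. DCNA
#'   log2 ratio) and the mediator (e.g. mRNA log2 ratio).
#' @return An object of class `mediator_fit`: list with `slope`, `intercept`,
#'   `slope_variance`, `sigma2` (residual variance) and `n_samples`.
#' @examples
#' d <- simulate_cohort(sim_config(seed = 1), n = 100)
#' fit_mediator(d, dcna, mrna)
#' @export
fit_mediator <- function(data, exposure = dcna, mediator = mrna) {
  stopifnot(is.data.frame(data))
  x <- dplyr::pull(data, {{ exposure }})
  y <- dplyr::pull(data, {{ mediator }})
  fit_mediator_xy(x, y)
}

fit_mediator_xy <- function(x, y) {
  n <- length(x)
  if (length(y) != n) {
    abort("exposure and mediator must have equal length",
          class = "medhaz_validation_error")
  }
  if (n < 3) {
    abort("at least 3 samples are required for the mediator regression",
          class = "medhaz_validation_error")
  }
  if (anyNA(x) || anyNA(y)) {
    abort("mediator regression inputs contain missing values",
          class = "medhaz_validation_error")
  }
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0) {
    abort("degenerate design: exposure is constant",
          class = "medhaz_degenerate_design")
  }
  slope <- sum(xc * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  sigma2 <- sum(resid^2) / (n - 2)
  structure(
    list(slope = slope, intercept = intercept,
         slope_variance = sigma2 / sxx, sigma2 = sigma2, n_samples = n),
    class = "mediator_fit"
  )
}

#' @export
print.mediator_fit <- function(x, ...) {
  cat("Mediator regression (OLS)\n")
  cat(sprintf("  n = %d\n", x$n_samples))
  cat(sprintf("  slope = %.4f (se %.4f), intercept = %.4f\n",
              x$slope, sqrt(x$slope_variance), x$intercept))
  invisible(x)
}

#' @rdname fit_mediator
#' @param x A `mediator_fit` object.
#' @param ... Unused.
#' @method tidy mediator_fit
#' @export
tidy.mediator_fit <- function(x, ...) {
  se <- sqrt(x$slope_variance)
  z <- if (se > 0) x$slope / se else NA_real_
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, se),
    statistic = c(NA_real_, z),
    p.value = c(NA_real_, if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)))
  )
}

#' @rdname fit_mediator
#' @method glance mediator_fit
#' @export
glance.mediator_fit <- function(x, ...) {
  tibble::tibble(n_samples = x$n_samples, sigma2 = x$sigma2)
}
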