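#' Simulation configuration for the synthetic DCNA/mRNA/survival generator
#'
#' Bundles the generative parameters of the synthetic cohort model. The
#' defaults reproduce the design calibrated to breast-tumor log2-ratio data:
#' DCNA is Normal with mean 0.248 and variance 0.047; mRNA is
#' `-0.578 + 0.775 * DCNA` plus Normal noise with variance 0.158; event
#' times are exponential with per-subject additive hazard
#' `baseline + lambda_m * mRNA + lambda_c * DCNA` (baseline 1,
#' lambda_m 0.4, lambda_c 0.1); censoring is independent with scale
#' parameter 0.9, giving roughly 60\% censored observations under the
#' default exponential-mean mechanism.
#'
#' @param n_samples Cohort size per replicate.
#' @param n_replicates Number of Monte-Carlo replicates for [run_study()].
#' @param dcna_mean,dcna_var Mean and variance of the DCNA log2 ratios.
#' @param mrna_intercept,mrna_slope,mrna_noise_var Mediator regression truth:
#'   intercept, slope (the true exposure-to-mediator path) and Gaussian noise
#'   variance. `mrna_noise_var` is a variance, consistent with `dcna_var`.
#' @param baseline_hazard Baseline hazard rate (events per time unit).
#' @param lambda_m,lambda_c True additive-hazard coefficients of mRNA
#'   (mediator path) and DCNA (direct path).
#' @param censoring_scale Scale of the censoring distribution (time units).
#' @param censoring_mechanism `"exponential_mean"` (censoring times
#'   exponential with mean `censoring_scale`; the default),
#'   `"uniform"` (uniform on (0, `censoring_scale`)) or
#'   `"administrative"` (everyone censored at `censoring_scale`).
#' @param level Nominal confidence level used by the study engine.
#' @param seed Integer master seed; all randomness flows from it.
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(seed = 1)
#' true_effects(cfg)
#' @export
sim_config <- function(n_samples = 100, n_replicates = 1000,
                       dcna_mean = 0.248, dcna_var = 0.047,
                       mrna_intercept = -0.578, mrna_slope = 0.775,
                       mrna_noise_var = 0.158,
                       baseline_hazard = 1, lambda_m = 0.4, lambda_c = 0.1,
                       censoring_scale = 0.9,
                       censoring_mechanism = c("exponential_mean", "uniform",
                                               "administrative"),
                       level = 0.95, seed = 1) {
  censoring_mechanism <- match.arg(censoring_mechanism)
  if (dcna_var < 0 || mrna_noise_var < 0) {
    abort("variances must be nonnegative", class = "medhaz_validation_error")
  }
  if (n_samples < 5) {
    abort("n_samples must be at least 5", class = "medhaz_validation_error")
  }
  if (n_replicates < 1) {
    abort("n_replicates must be at least 1", class = "medhaz_validation_error")
  }
  if (baseline_hazard <= 0 || censoring_scale <= 0) {
    abort("baseline_hazard and censoring_scale must be positive",
          class = "medhaz_validation_error")
  }
  if (level <= 0 || level >= 1) {
    abort("level must be in (0, 1)", class = "medhaz_validation_error")
  }
  structure(
    list(n_samples = n_samples, n_replicates = n_replicates,
         dcna_mean = dcna_mean, dcna_var = dcna_var,
         mrna_intercept = mrna_intercept, mrna_slope = mrna_slope,
         mrna_noise_var = mrna_noise_var,
         baseline_hazard = baseline_hazard,
         lambda_m = lambda_m, lambda_c = lambda_c,
         censoring_scale = censoring_scale,
         censoring_mechanism = censoring_mechanism,
         level = level, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' True effects implied by a simulation configuration
#'
#' @param config A [sim_config()].
#' @return A one-row tibble with the true `mediated`
#'   (`mrna_slope * lambda_m`), `total` and `direct` effects.
#' @export
true_effects <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mediated <- config$mrna_slope * config$lambda_m
  tibble::tibble(mediated = mediated,
                 total = mediated + config$lambda_c,
                 direct = config$lambda_c)
}

#' Generate one synthetic cohort
#'
#' Draws a cohort under the generative model in [sim_config()]: exposure
#' DCNA, mediator mRNA linear in DCNA with Gaussian noise, exponential event
#' times from the additive hazard, independent censoring, observed time
#' `min(T, C)` and status `T <= C`. Subjects whose linear hazard is
#' nonpositive are redrawn (additive hazards admit negative rates; clipping
#' would bias the generator); the redraw count is attached as an attribute
#' and a warning is raised if it exceeds 1\% of the cohort.
#'
#' @param config A [sim_config()].
#' @param n Cohort size (defaults to `config$n_samples`).
#' @param replicate Replicate index; together with `config$seed` it fully
#'   determines the dataset.
#' @return A tibble with columns `sample_id`, `dcna`, `mrna`, `time`,
#'   `status`, with attributes `n_redraws` and `replicate`.
#' @export
simulate_cohort <- function(config, n = config$n_samples, replicate = 1) {
  stopifnot(inherits(config, "sim_config"))
  s <- derive_seeds(config$seed, replicate)[replicate]
  out <- with_seed(s, generate_cohort_raw(config, n))
  attr(out, "replicate") <- replicate
  out
}

# Draws from the generative model using the current RNG stream.
generate_cohort_raw <- function(config, n) {
  dcna <- rnorm(n, config$dcna_mean, sqrt(config$dcna_var))
  mrna <- config$mrna_intercept + config$mrna_slope * dcna +
    rnorm(n, 0, sqrt(config$mrna_noise_var))
  h <- config$baseline_hazard + config$lambda_m * mrna + config$lambda_c * dcna
  n_redraws <- 0L
  while (any(bad <- h <= 0)) {
    k <- sum(bad)
    n_redraws <- n_redraws + k
    dcna[bad] <- rnorm(k, config$dcna_mean, sqrt(config$dcna_var))
    mrna[bad] <- config$mrna_intercept + config$mrna_slope * dcna[bad] +
      rnorm(k, 0, sqrt(config$mrna_noise_var))
    h[bad] <- config$baseline_hazard + config$lambda_m * mrna[bad] +
      config$lambda_c * dcna[bad]
  }
  if (n_redraws > 0.01 * n) {
    warn(sprintf("%d subjects redrawn for nonpositive hazards (> 1%% of n)",
                 n_redraws))
  }
  event_time <- rexp(n, h)
  cens_time <- switch(config$censoring_mechanism,
    exponential_mean = rexp(n, 1 / config$censoring_scale),
    uniform = runif(n, 0, config$censoring_scale),
    administrative = rep(config$censoring_scale, n)
  )
  out <- tibble::tibble(
    sample_id = paste0("s", seq_len(n)),
    dcna = dcna, mrna = mrna,
    time = pmin(event_time, cens_time),
    status = as.integer(event_time <= cens_time)
  )
  attr(out, "n_redraws") <- n_redraws
  out
}

#' Binomial acceptance band for empirical coverage
#'
#' The band inside which the empirical coverage of a well-calibrated
#' interval is expected to fall, given the Monte-Carlo sample size:
#' `nominal +/- 1.96 * sqrt(nominal * (1 - nominal) / n_sims)`, reported to
#' three decimals.
#'
#' @param nominal Nominal coverage in (0, 1).
#' @param n_sims Number of simulation replicates.
#' @return Named numeric vector `c(low, high)`.
#' @examples
#' coverage_band(0.95, 1000)
#' @export
coverage_band <- function(nominal, n_sims) {
  if (nominal <= 0 || nominal >= 1) {
    abort("nominal must be in (0, 1)", class = "medhaz_validation_error")
  }
  if (n_sims < 1) {
    abort("n_sims must be at least 1", class = "medhaz_validation_error")
  }
  half <- 1.96 * sqrt(nominal * (1 - nominal) / n_sims)
  round(c(low = nominal - half, high = nominal + half), 3)
}

#' Monte-Carlo evaluation of mediated-effect inference
#'
#' Runs the full simulation study: for every replicate at every sample size,
#' generates a cohort, fits the mediator regression and the additive hazards
#' model, forms the requested confidence intervals for the mediated effect
#' (and, for the Delta method, also the total effect), and aggregates bias
#' (mean estimate minus truth), mean squared error (squared bias plus the
#' empirical variance of the estimates), coverage, mean interval width, and
#' lower/upper tail errors (intervals falling entirely below/above the
#' truth). All requested methods are evaluated on the same generated
#' datasets. Replicates whose fits fail are dropped, counted, and flagged
#' when they exceed 1\%.
#'
#' @param config A [sim_config()]; supplies the generative truth, the
#'   nominal level, the master seed and the default replicate count.
#' @param n_grid Integer vector of cohort sizes.
#' @param methods Subset of `"delta"`, `"product_normal"`, `"boot_normal"`,
#'   `"boot_basic"`, `"boot_percentile"`, `"boot_bca"`.
#' @param n_replicates Replicates per sample size.
#' @param boot_replicates Bootstrap resamples per dataset (when a bootstrap
#'   method is requested).
#' @param pn_draws Monte-Carlo draws for the normal-product interval.
#' @param keep_estimates Attach per-replicate estimates and intervals as a
#'   list-column for audit.
#' @return A tibble of class `medhaz_study`, one row per
#'   (sample size, method, estimand), with columns `n`, `method`, `estimand`,
#'   `truth`, `bias`, `mse`, `coverage`, `mean_width`, `lower_error`,
#'   `upper_error`, `band_low`, `band_high`, `empirical_censoring`,
#'   `n_replicates`, `n_failed`, `flagged`.
#' @examples
#' cfg <- sim_config(n_replicates = 50, seed = 42)
#' run_study(cfg, n_grid = c(50, 100))
#' @export
run_study <- function(config, n_grid = config$n_samples, methods = "delta",
                      n_replicates = config$n_replicates,
                      boot_replicates = 999, pn_draws = 1e5,
                      keep_estimates = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  all_methods <- c("delta", "product_normal", "boot_normal", "boot_basic",
                   "boot_percentile", "boot_bca")
  methods <- match.arg(methods, all_methods, several.ok = TRUE)
  boot_methods <- intersect(methods, all_methods[3:6])
  truth <- true_effects(config)
  level <- config$level
  lo <- (1 - level) / 2
  hi <- 1 - lo

  seeds <- matrix(derive_seeds(config$seed, length(n_grid) * n_replicates),
                  nrow = n_replicates)
  rows <- list()
  for (g in seq_along(n_grid)) {
    n <- n_grid[g]
    est_med <- est_tot <- cens <- rep(NA_real_, n_replicates)
    cis <- lapply(methods, function(m) matrix(NA_real_, n_replicates, 2))
    names(cis) <- methods
    ci_tot <- matrix(NA_real_, n_replicates, 2)
    n_failed <- 0L

    for (r in seq_len(n_replicates)) {
      res <- with_seed(seeds[r, g], {
        d <- generate_cohort_raw(config, n)
        fit <- tryCatch(
          {
            med <- fit_mediator_xy(d$dcna, d$mrna)
            X <- cbind(mrna = d$mrna, dcna = d$dcna)
            haz_raw <- ly_fit(d$time, d$status, X, compute_vcov = TRUE)
            haz <- new_hazards_fit(haz_raw$coef, haz_raw$vcov, n, sum(d$status))
            mediation_inference(med, haz, "mrna", "dcna", level = level)
          },
          error = function(e) NULL
        )
        if (is.null(fit)) {
          NULL
        } else {
          out <- list(mediated = fit$mediated, total = fit$total,
                      cens = mean(1 - d$status),
                      ci = list(delta = fit$ci_mediated),
                      ci_total = fit$ci_total)
          if ("product_normal" %in% methods) {
            pd <- rnorm(pn_draws, fit$alpha_m, sqrt(fit$var_alpha_m)) *
              rnorm(pn_draws, fit$lambda_m, sqrt(fit$var_lambda_m))
            out$ci$product_normal <- empirical_quantile(pd, c(lo, hi))
          }
          if (length(boot_methods) > 0) {
            boots <- draw_boot_estimates(d$dcna, d$mrna, d$time, d$status,
                                         boot_replicates)
            for (m in boot_methods) {
              out$ci[[m]] <- boot_interval(m, fit$mediated, boots$estimates,
                                           level, x = d$dcna, y = d$mrna,
                                           tv = d$time, sv = d$status)
            }
          }
          out
        }
      })
      if (is.null(res)) {
        n_failed <- n_failed + 1L
        next
      }
      est_med[r] <- res$mediated
      est_tot[r] <- res$total
      cens[r] <- res$cens
      ci_tot[r, ] <- res$ci_total
      for (m in methods) cis[[m]][r, ] <- res$ci[[m]]
    }

    ok <- !is.na(est_med)
    n_used <- sum(ok)
    band <- coverage_band(level, n_used)
    summarise_one <- function(method, estimand, est, ci) {
      est <- est[ok]
      ci <- ci[ok, , drop = FALSE]
      tr <- truth[[estimand]]
      bias <- mean(est) - tr
      row <- tibble::tibble(
        n = n, method = method, estimand = estimand, truth = tr,
        bias = bias, mse = bias^2 + sd(est)^2,
        coverage = mean(ci[, 1] <= tr & tr <= ci[, 2]),
        mean_width = mean(ci[, 2] - ci[, 1]),
        lower_error = mean(ci[, 2] < tr),
        upper_error = mean(ci[, 1] > tr),
        band_low = band[["low"]], band_high = band[["high"]],
        empirical_censoring = mean(cens[ok]),
        n_replicates = n_used, n_failed = n_failed,
        flagged = n_failed > 0.01 * n_replicates
      )
      if (keep_estimates) {
        row$replicates <- list(tibble::tibble(
          estimate = est, lower = ci[, 1], upper = ci[, 2]))
      }
      row
    }

    for (m in methods) {
      rows[[length(rows) + 1]] <- summarise_one(m, "mediated", est_med, cis[[m]])
      if (m == "delta") {
        rows[[length(rows) + 1]] <- summarise_one(m, "total", est_tot, ci_tot)
      }
    }
  }

  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  attr(out, "boot_replicates") <- boot_replicates
  attr(out, "pn_draws") <- pn_draws
  class(out) <- c("medhaz_study", class(out))
  out
}

#' @importFrom utils str
NULL
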