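test_that("delta_variance equals the explicit double-loop quadratic form", {
  set.seed(501)
  for (i in 1:50) {
    p <- sample(1:4, 1)
    g <- rnorm(p)
    S <- random_psd_matrix(p)
    expect_equal(delta_variance(g, S), oracle_quadratic_form(g, S),
                 tolerance = 1e-12)
  }
  expect_identical(delta_variance(c(0, 0, 0), random_psd_matrix(3)), 0)
  expect_error(delta_variance(c(1, 2), diag(3)),
               class = "medhaz_validation_error")
  expect_error(delta_variance(c(1, 2), matrix(c(1, 0.5, 0, 1), 2, 2)),
               class = "medhaz_validation_error")
})

test_that("mediated-effect variance is the gradient propagation identity", {
  # closed form alpha^2 var(lambda) + lambda^2 var(alpha) must equal
  # g' Sigma g with g = (lambda, alpha) for arbitrary inputs
  set.seed(502)
  for (i in 1:1000) {
    am <- rnorm(1)
    lm_ <- rnorm(1)
    v_am <- rexp(1)
    v_lm <- rexp(1)
    res <- mediation_inference(make_mediator_fit(am, v_am),
                               make_hazards_fit(lm_, 0.1, v_lm, 0.05))
    expect_equal(res$var_mediated,
                 delta_variance(c(lm_, am), diag(c(v_am, v_lm))),
                 tolerance = 1e-12)
  }
})

test_that("plug-in variance example evaluates exactly", {
  res <- mediation_inference(make_mediator_fit(2, 0.04),
                             make_hazards_fit(3, 0, 0.25, 0.01))
  expect_equal(res$var_mediated, 4 * 0.25 + 9 * 0.04, tolerance = 1e-12)
})

test_that("generative path coefficients imply mediated 0.31 and total 0.41", {
  res <- mediation_inference(make_mediator_fit(0.775, 0),
                             make_hazards_fit(0.4, 0.1, 0, 0))
  expect_equal(res$mediated, 0.31, tolerance = 1e-12)
  expect_equal(res$total, 0.41, tolerance = 1e-12)
  expect_equal(res$relative_magnitude, 0.31 / 0.41, tolerance = 1e-12)
})

test_that("total effect is exactly mediated plus direct, CIs are symmetric", {
  set.seed(503)
  for (i in 1:25) {
    res <- mediation_inference(
      make_mediator_fit(rnorm(1), rexp(1)),
      make_hazards_fit(rnorm(1), rnorm(1), rexp(1), rexp(1),
                       cov_lmlc = rnorm(1, 0, 0.05)))
    expect_identical(res$total, res$mediated + res$direct)
    expect_equal(mean(res$ci_mediated), res$mediated, tolerance = 1e-12)
    expect_equal(mean(res$ci_total), res$total, tolerance = 1e-12)
    expect_true(res$ci_mediated[1] <= res$mediated &&
                  res$mediated <= res$ci_mediated[2])
    expect_true(all(c(res$p_mediated, res$p_total) >= 0 &
                      c(res$p_mediated, res$p_total) <= 1))
  }
})

test_that("degenerate and boundary cases are flagged, not fatal", {
  # no mediator path at all: zero estimate, zero variance, undefined Z
  res0 <- mediation_inference(make_mediator_fit(0, 0),
                              make_hazards_fit(0.4, 0.1, 0, 0))
  expect_equal(res0$mediated, 0)
  expect_equal(res0$var_mediated, 0)
  expect_true(is.na(res0$z_mediated) && is.na(res0$p_mediated))

  # no direct path: complete mediation, P_M = 1
  res1 <- mediation_inference(make_mediator_fit(0.775, 0.01),
                              make_hazards_fit(0.4, 0, 0.01, 0.01))
  expect_equal(res1$relative_magnitude, 1, tolerance = 1e-12)

  # total effect exactly zero: relative magnitude undefined, rest returned
  res2 <- mediation_inference(make_mediator_fit(1, 0.01),
                              make_hazards_fit(0.4, -0.4, 0.01, 0.01))
  expect_true(is.na(res2$relative_magnitude) && is.na(res2$var_pm))
  expect_true(res2$flags$pm_undefined)
  expect_equal(res2$mediated, 0.4)

  # dominant negative covariance: total variance floored at zero and flagged
  expect_warning(
    res3 <- mediation_inference(make_mediator_fit(1, 0),
                                make_hazards_fit(0, 1, 0.01, 0.01,
                                                 cov_lmlc = -0.5)),
    "floored")
  expect_equal(res3$var_total, 0)
  expect_true(res3$flags$total_variance_floored)
})

test_that("relative-magnitude variance matches brute-force propagation", {
  set.seed(504)
  for (i in 1:200) {
    am <- rnorm(1, 1)
    lm_ <- rnorm(1, 0.5)
    lc <- rnorm(1, 0.3)
    if (abs(am * lm_ + lc) < 1e-3) next
    v <- rexp(3, 10)
    cv <- runif(1, -1, 1) * sqrt(v[2] * v[3])
    res <- mediation_inference(make_mediator_fit(am, v[1]),
                               make_hazards_fit(lm_, lc, v[2], v[3], cv))
    tot <- am * lm_ + lc
    g <- c(lm_ * lc, am * lc, -am * lm_) / tot^2
    S <- rbind(c(v[1], 0, 0), c(0, v[2], cv), c(0, cv, v[3]))
    expect_equal(res$var_pm, oracle_quadratic_form(g, S), tolerance = 1e-12)
  }
})

test_that("mediated and total effects are invariant to mediator rescaling", {
  d <- simulate_cohort(sim_config(seed = 505), n = 200)
  res1 <- mediate_survival(d)
  for (c_scale in c(3.7, -0.25)) {
    d2 <- dplyr::mutate(d, mrna = mrna * c_scale)
    res2 <- mediate_survival(d2)
    expect_equal(res2$mediated, res1$mediated, tolerance = 1e-10)
    expect_equal(res2$total, res1$total, tolerance = 1e-10)
    expect_equal(res2$var_mediated, res1$var_mediated, tolerance = 1e-10)
    expect_equal(res2$alpha_m, res1$alpha_m * c_scale, tolerance = 1e-10)
    expect_equal(res2$lambda_m, res1$lambda_m / c_scale, tolerance = 1e-10)
  }
})

test_that("Z-test keeps its size under the no-mediation null", {
  cfg <- sim_config(lambda_m = 0, seed = 506)
  reps <- 400
  seeds <- medhaz:::derive_seeds(cfg$seed, reps)
  reject <- logical(reps)
  for (r in seq_len(reps)) {
    d <- medhaz:::with_seed(seeds[r], medhaz:::generate_cohort_raw(cfg, 200))
    res <- mediate_survival(d)
    reject[r] <- res$p_mediated < 0.05
  }
  rate <- mean(reject)
  half <- 3 * sqrt(0.05 * 0.95 / reps)
  expect_gt(rate, 0.05 - half)
  expect_lt(rate, 0.05 + half)
})
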