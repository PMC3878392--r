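# Independent oracles used across the suite. These deliberately use naive
# explicit loops (not the package's vectorised code paths).

# Brute-force estimating-equation oracle for the time-constant additive
# hazards model: assembles A, b and B by looping over distinct observed
# times and at-risk subjects.
oracle_additive_hazards <- function(time, status, X) {
  p <- ncol(X)
  ut <- sort(unique(time))
  A <- matrix(0, p, p)
  B <- matrix(0, p, p)
  b <- rep(0, p)
  prev <- 0
  for (tk in ut) {
    risk <- which(time >= tk)
    xbar <- colMeans(X[risk, , drop = FALSE])
    Ck <- matrix(0, p, p)
    for (i in risk) Ck <- Ck + tcrossprod(X[i, ] - xbar)
    A <- A + (tk - prev) * Ck
    prev <- tk
    for (i in which(time == tk & status == 1)) {
      b <- b + (X[i, ] - xbar)
      B <- B + tcrossprod(X[i, ] - xbar)
    }
  }
  Ai <- solve(A)
  list(coef = drop(Ai %*% b), vcov = Ai %*% B %*% Ai)
}

# Double-loop quadratic form oracle for gradient variance propagation.
oracle_quadratic_form <- function(g, S) {
  total <- 0
  for (j in seq_along(g)) {
    for (k in seq_along(g)) {
      total <- total + g[j] * S[j, k] * g[k]
    }
  }
  total
}

# Sort-based type-6 ((R + 1) * q rank interpolation) quantile oracle.
oracle_quantile6 <- function(x, q) {
  xs <- sort(x)
  R <- length(xs)
  h <- (R + 1) * q
  lo <- floor(h)
  out <- numeric(length(q))
  for (i in seq_along(q)) {
    if (lo[i] < 1) {
      out[i] <- xs[1]
    } else if (lo[i] >= R) {
      out[i] <- xs[R]
    } else {
      out[i] <- xs[lo[i]] + (h[i] - lo[i]) * (xs[lo[i] + 1] - xs[lo[i]])
    }
  }
  out
}

# Hand step-up false-discovery-rate adjustment.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(n)
  running <- Inf
  for (idx in seq_along(o)) {
    i <- o[idx]
    rank_i <- n - idx + 1
    running <- min(running, p[i] * n / rank_i)
    adj[i] <- min(running, 1)
  }
  adj
}

# Small random survival datasets (with ties and censoring) for property
# tests against the brute-force oracle.
random_survival_dataset <- function(n, p) {
  time <- round(rexp(n, 1), 1) + 0.1
  status <- rbinom(n, 1, 0.7)
  status[sample.int(n, 1)] <- 1
  X <- matrix(rnorm(n * p), n, p)
  if (p > 1) X[, 2] <- rbinom(n, 1, 0.5) + rnorm(n, 0, 0.2)
  colnames(X) <- paste0("x", seq_len(p))
  list(time = time, status = status, X = X)
}

make_mediator_fit <- function(slope, slope_variance, intercept = 0,
                              sigma2 = 1, n = 100) {
  structure(list(slope = slope, intercept = intercept,
                 slope_variance = slope_variance, sigma2 = sigma2,
                 n_samples = n),
            class = "mediator_fit")
}

make_hazards_fit <- function(lambda_m, lambda_c, v_lm, v_lc, cov_lmlc = 0,
                             n = 100, n_events = 40) {
  vc <- matrix(c(v_lm, cov_lmlc, cov_lmlc, v_lc), 2, 2,
               dimnames = list(c("mrna", "dcna"), c("mrna", "dcna")))
  structure(list(coefficients = c(mrna = lambda_m, dcna = lambda_c),
                 vcov = vc, n_samples = n, n_events = n_events),
            class = "hazards_fit")
}

random_psd_matrix <- function(p) {
  M <- matrix(rnorm(p * p), p, p)
  crossprod(M) + diag(1e-6, p)
}
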