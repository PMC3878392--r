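#' Read and write omics matrices
#'
#' An omics matrix is stored as a tab-separated file with a header row: the
#' first column holds unique gene identifiers, the remaining columns one
#' numeric sample each (log2-ratio scale by convention; values are never
#' discretized). `read_omics_matrix()` validates identifiers and numeric
#' content and reports offending rows and columns; `write_omics_matrix()`
#' writes the complementary format so that a write/read cycle reproduces the
#' file byte for byte.
#'
#' @param path File path.
#' @return `read_omics_matrix()`: a tibble whose first column is `gene_id`.
#' @export
read_omics_matrix <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "medhaz_validation_error")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2) {
    abort("omics matrix needs a gene column and at least one sample column",
          class = "medhaz_validation_error")
  }
  names(raw)[1] <- "gene_id"
  if (anyDuplicated(raw$gene_id)) {
    dup <- raw$gene_id[duplicated(raw$gene_id)][1]
    abort(paste0("duplicate gene id: ", dup), class = "medhaz_validation_error")
  }
  for (j in names(raw)[-1]) {
    vals <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(vals) & !is.na(raw[[j]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value '%s' at gene %s, sample column %s",
                    raw[[j]][bad[1]], raw$gene_id[bad[1]], j),
            class = "medhaz_validation_error")
    }
    raw[[j]] <- vals
  }
  raw
}

#' @rdname read_omics_matrix
#' @param x An omics tibble (`gene_id` first column).
#' @export
write_omics_matrix <- function(x, path) {
  validate_omics(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a per-sample survival table
#'
#' Tab-separated with header `sample  time  status`; `status` must be 0
#' (censored) or 1 (event), times nonnegative.
#'
#' @param path File path.
#' @return A tibble with columns `sample`, `time`, `status`.
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "medhaz_validation_error")
  }
  surv <- readr::read_tsv(path, col_types = readr::cols(
    sample = "c", time = "d", status = "i"), progress = FALSE)
  if (!all(c("sample", "time", "status") %in% names(surv))) {
    abort("survival table must have columns sample, time, status",
          class = "medhaz_validation_error")
  }
  if (anyNA(surv$time) || any(surv$time < 0)) {
    abort("survival times must be nonnegative and complete",
          class = "medhaz_validation_error")
  }
  if (!all(surv$status %in% c(0L, 1L))) {
    abort("status must be 0 or 1", class = "medhaz_validation_error")
  }
  surv
}

#' Write a synthetic multi-gene screening fixture to disk
#'
#' Generates a cohort of `n_samples` patients with `n_genes` genes and one
#' shared survival outcome, and writes `dcna.tsv`, `mrna.tsv`,
#' `survival.tsv` and `truth.tsv` (ground-truth labels) into `dir`.
#'
#' The first `n_pathway_genes` genes form a co-amplified pathway module:
#' they share a single DCNA realization (one amplicon) and a single module
#' expression signal following the mediator model of [sim_config()]
#' (`mrna_intercept + mrna_slope * DCNA + noise`). The first pathway gene is
#' the designated driver and reports the module expression exactly; the
#' remaining pathway genes add independent gene-level measurement noise with
#' variance `gene_noise_var`. Survival follows the additive hazard
#' `baseline + lambda_m * module + lambda_c * DCNA`, so per-gene marginal
#' models see an attenuated but genuine mediated signal. The remaining genes
#' are null: independent DCNA, mRNA unrelated to DCNA (variance matched to
#' the marginal mediator variance), and no survival effect.
#'
#' @param dir Output directory (created if needed).
#' @param n_genes Total number of genes.
#' @param n_samples Number of patients.
#' @param n_pathway_genes Number of pathway genes (<= `n_genes`).
#' @param config A [sim_config()] supplying the generative parameters.
#' @param seed Integer seed; the files are byte-identical across runs with
#'   the same seed.
#' @param gene_noise_var Gene-level measurement-noise variance for
#'   non-driver pathway genes.
#' @return Invisibly, a list with the four file `paths`, the `truth` tibble
#'   and the generated `data` (dcna, mrna, survival tibbles).
#' @export
make_fixture <- function(dir, n_genes, n_samples, n_pathway_genes = 0,
                         config = sim_config(), seed = config$seed,
                         gene_noise_var = 0.2 * config$mrna_noise_var) {
  if (n_pathway_genes > n_genes) {
    abort("n_pathway_genes must not exceed n_genes",
          class = "medhaz_validation_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  sample_ids <- paste0("s", seq_len(n_samples))

  out <- with_seed(seed, {
    dcna <- matrix(NA_real_, n_genes, n_samples)
    mrna <- matrix(NA_real_, n_genes, n_samples)
    if (n_pathway_genes > 0) {
      # shared amplicon and module expression, redrawn while hazard <= 0
      dcna_p <- rnorm(n_samples, config$dcna_mean, sqrt(config$dcna_var))
      u <- rnorm(n_samples, 0, sqrt(config$mrna_noise_var))
      module <- config$mrna_intercept + config$mrna_slope * dcna_p + u
      h <- config$baseline_hazard + config$lambda_m * module +
        config$lambda_c * dcna_p
      while (any(bad <- h <= 0)) {
        k <- sum(bad)
        dcna_p[bad] <- rnorm(k, config$dcna_mean, sqrt(config$dcna_var))
        u[bad] <- rnorm(k, 0, sqrt(config$mrna_noise_var))
        module[bad] <- config$mrna_intercept +
          config$mrna_slope * dcna_p[bad] + u[bad]
        h[bad] <- config$baseline_hazard + config$lambda_m * module[bad] +
          config$lambda_c * dcna_p[bad]
      }
      for (g in seq_len(n_pathway_genes)) {
        dcna[g, ] <- dcna_p
        mrna[g, ] <- if (g == 1) module else
          module + rnorm(n_samples, 0, sqrt(gene_noise_var))
      }
    } else {
      h <- rep(config$baseline_hazard, n_samples)
    }
    if (n_genes > n_pathway_genes) {
      marg_var <- config$mrna_slope^2 * config$dcna_var + config$mrna_noise_var
      marg_mean <- config$mrna_intercept + config$mrna_slope * config$dcna_mean
      for (g in seq(n_pathway_genes + 1, n_genes)) {
        dcna[g, ] <- rnorm(n_samples, config$dcna_mean, sqrt(config$dcna_var))
        mrna[g, ] <- rnorm(n_samples, marg_mean, sqrt(marg_var))
      }
    }
    event_time <- rexp(n_samples, h)
    cens_time <- switch(config$censoring_mechanism,
      exponential_mean = rexp(n_samples, 1 / config$censoring_scale),
      uniform = runif(n_samples, 0, config$censoring_scale),
      administrative = rep(config$censoring_scale, n_samples)
    )
    list(dcna = dcna, mrna = mrna,
         time = pmin(event_time, cens_time),
         status = as.integer(event_time <= cens_time))
  })

  as_omics <- function(M) {
    df <- tibble::as_tibble(as.data.frame(M))
    names(df) <- sample_ids
    dplyr::bind_cols(tibble::tibble(gene_id = gene_ids), df)
  }
  dcna_tbl <- as_omics(out$dcna)
  mrna_tbl <- as_omics(out$mrna)
  surv_tbl <- tibble::tibble(sample = sample_ids, time = out$time,
                             status = out$status)
  truth <- tibble::tibble(
    gene_id = gene_ids,
    pathway = seq_len(n_genes) <= n_pathway_genes,
    driver = seq_len(n_genes) == 1 & n_pathway_genes > 0
  )

  paths <- list(
    dcna = file.path(dir, "dcna.tsv"),
    mrna = file.path(dir, "mrna.tsv"),
    survival = file.path(dir, "survival.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_omics_matrix(dcna_tbl, paths$dcna)
  write_omics_matrix(mrna_tbl, paths$mrna)
  readr::write_tsv(surv_tbl, paths$survival, progress = FALSE)
  readr::write_tsv(truth, paths$truth, progress = FALSE)
  invisible(list(paths = paths, truth = truth,
                 data = list(dcna = dcna_tbl, mrna = mrna_tbl,
                             survival = surv_tbl)))
}
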