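#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity,
#' capped at 1; input order is preserved. Thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03))
#' @export
adjust_bh <- function(pvalues) {
  if (!is.numeric(pvalues)) {
    abort("pvalues must be numeric", class = "medhaz_validation_error")
  }
  finite <- pvalues[!is.na(pvalues)]
  if (any(finite < 0 | finite > 1)) {
    abort("p-values must lie in [0, 1]", class = "medhaz_validation_error")
  }
  p.adjust(pvalues, method = "BH")
}

#' Align DCNA and mRNA matrices with a survival table
#'
#' Restricts both omics matrices to their common genes and restricts and
#' reorders the samples of all three inputs to the common sample set (in the
#' DCNA matrix's order). Counts of dropped genes and samples are reported.
#'
#' @param dcna,mrna Omics tibbles as returned by [read_omics_matrix()]:
#'   a `gene_id` column followed by one numeric column per sample.
#' @param survival A survival table with columns `sample`, `time`, `status`.
#' @return A list of class `omics_aligned` with elements `dcna`, `mrna`,
#'   `survival`, aligned on identical gene and sample sets, plus attributes
#'   `dropped_genes` and `dropped_samples`.
#' @export
match_platforms <- function(dcna, mrna, survival) {
  validate_omics(dcna)
  validate_omics(mrna)
  if (!all(c("sample", "time", "status") %in% names(survival))) {
    abort("survival table must have columns sample, time, status",
          class = "medhaz_validation_error")
  }
  genes <- intersect(dcna$gene_id, mrna$gene_id)
  samples <- intersect(intersect(names(dcna)[-1], names(mrna)[-1]),
                       survival$sample)
  if (length(genes) == 0 || length(samples) == 0) {
    abort("empty gene or sample intersection across platforms",
          class = "medhaz_validation_error")
  }
  dropped_genes <- length(union(dcna$gene_id, mrna$gene_id)) - length(genes)
  all_samples <- union(union(names(dcna)[-1], names(mrna)[-1]),
                       survival$sample)
  dropped_samples <- length(all_samples) - length(samples)
  if (dropped_genes > 0 || dropped_samples > 0) {
    rlang::inform(sprintf("alignment dropped %d gene(s) and %d sample(s)",
                          dropped_genes, dropped_samples))
  }
  take <- function(m) {
    m <- m[match(genes, m$gene_id), c("gene_id", samples)]
    m
  }
  surv <- survival[match(samples, survival$sample), , drop = FALSE]
  structure(
    list(dcna = take(dcna), mrna = take(mrna),
         survival = tibble::as_tibble(surv)),
    class = "omics_aligned",
    dropped_genes = dropped_genes, dropped_samples = dropped_samples
  )
}

validate_omics <- function(x) {
  if (!is.data.frame(x) || names(x)[1] != "gene_id") {
    abort("omics matrix must be a data frame whose first column is gene_id",
          class = "medhaz_validation_error")
  }
  if (anyDuplicated(x$gene_id)) {
    dup <- x$gene_id[duplicated(x$gene_id)][1]
    abort(paste0("duplicate gene id: ", dup), class = "medhaz_validation_error")
  }
  if (!all(vapply(x[-1], is.numeric, logical(1)))) {
    abort("omics matrix sample columns must be numeric",
          class = "medhaz_validation_error")
  }
  invisible(x)
}

#' Genome-wide mediation screening
#'
#' Runs the per-gene mediation analysis over aligned DCNA/mRNA matrices with
#' shared survival data: for every gene, the mediator regression of its mRNA
#' on its DCNA, the bivariate additive hazards fit (that gene's mRNA and
#' DCNA), and Delta-method mediation inference. Two testing families are
#' offered. `family = "all_genes"` applies Benjamini-Hochberg adjustment to
#' the mediated-effect p-values of every gene. `family = "prefiltered"`
#' first selects genes with a BH-significant DCNA-to-mRNA association AND a
#' BH-significant mRNA-to-survival association (both at `fdr`), then applies
#' BH to the mediated-effect p-values within the selection only.
#'
#' Genes with a significant mediated effect are classified
#' `complete_mediation` when the residual direct DCNA effect is not
#' significant and `partial_mediation` when it is; `direct_only` marks a
#' significant direct effect without mediation, `none` everything else
#' (including unselected genes in the prefiltered family). Direct-effect
#' significance uses BH-adjusted direct-path p-values over the same family.
#'
#' @param aligned An `omics_aligned` triple from [match_platforms()].
#' @param level Confidence level for per-gene intervals.
#' @param fdr False-discovery-rate threshold.
#' @param family `"all_genes"` or `"prefiltered"`.
#' @return A tibble with one row per gene: path coefficients, effect
#'   estimates, raw and adjusted p-values, selection flag and
#'   classification. Per-gene fit failures are flagged, not fatal.
#' @export
screen_genes <- function(aligned, level = 0.95, fdr = 0.05,
                         family = c("all_genes", "prefiltered")) {
  stopifnot(inherits(aligned, "omics_aligned"))
  family <- match.arg(family)
  samples <- names(aligned$dcna)[-1]
  Xd <- as.matrix(aligned$dcna[-1])
  Xm <- as.matrix(aligned$mrna[-1])
  surv <- aligned$survival
  stopifnot(identical(samples, surv$sample))
  tv <- surv$time
  sv <- surv$status

  one_gene <- function(i) {
    x <- Xd[i, ]
    y <- Xm[i, ]
    tryCatch({
      med <- fit_mediator_xy(x, y)
      raw <- ly_fit(tv, sv, cbind(mrna = y, dcna = x), compute_vcov = TRUE)
      haz <- new_hazards_fit(raw$coef, raw$vcov, length(tv), sum(sv))
      fit <- mediation_inference(med, haz, "mrna", "dcna", level = level)
      z_a <- med$slope / sqrt(med$slope_variance)
      z_lm <- raw$coef[["mrna"]] / sqrt(raw$vcov["mrna", "mrna"])
      tibble::tibble(
        alpha_m = med$slope, lambda_m = fit$lambda_m, lambda_c = fit$lambda_c,
        mediated = fit$mediated, total = fit$total,
        p_dcna_mrna = 2 * pnorm(-abs(z_a)),
        p_mrna_surv = 2 * pnorm(-abs(z_lm)),
        p_mediated = fit$p_mediated, p_total = fit$p_total,
        p_direct = fit$p_direct, failed = FALSE
      )
    }, error = function(e) {
      tibble::tibble(alpha_m = NA_real_, lambda_m = NA_real_,
                     lambda_c = NA_real_, mediated = NA_real_,
                     total = NA_real_, p_dcna_mrna = NA_real_,
                     p_mrna_surv = NA_real_, p_mediated = NA_real_,
                     p_total = NA_real_, p_direct = NA_real_, failed = TRUE)
    })
  }

  res <- dplyr::bind_rows(lapply(seq_len(nrow(Xd)), one_gene))
  res <- dplyr::bind_cols(tibble::tibble(gene_id = aligned$dcna$gene_id), res)

  if (family == "all_genes") {
    res$selected <- !res$failed
  } else {
    q_xm <- adjust_bh(res$p_dcna_mrna)
    q_ms <- adjust_bh(res$p_mrna_surv)
    res$selected <- !res$failed & !is.na(q_xm) & q_xm <= fdr &
      !is.na(q_ms) & q_ms <= fdr
  }
  res$q_mediated <- NA_real_
  res$q_direct <- NA_real_
  res$q_mediated[res$selected] <- adjust_bh(res$p_mediated[res$selected])
  res$q_direct[res$selected] <- adjust_bh(res$p_direct[res$selected])

  sig_med <- !is.na(res$q_mediated) & res$q_mediated <= fdr
  sig_dir <- !is.na(res$q_direct) & res$q_direct <= fdr
  res$classification <- dplyr::case_when(
    sig_med & !sig_dir ~ "complete_mediation",
    sig_med & sig_dir ~ "partial_mediation",
    !sig_med & sig_dir ~ "direct_only",
    .default = "none"
  )
  res$family <- family
  res
}
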