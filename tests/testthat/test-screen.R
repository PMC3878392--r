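test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 4)), rep(1, 4))
  expect_error(adjust_bh(c(0.5, 1.2)), class = "medhaz_validation_error")
  set.seed(801)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    adj <- adjust_bh(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("platform matching aligns genes and samples", {
  mk <- function(genes, samples, offset = 0) {
    vals <- matrix(seq_along(genes) %o% seq_along(samples) + offset,
                   length(genes), length(samples))
    df <- tibble::as_tibble(as.data.frame(vals))
    names(df) <- samples
    dplyr::bind_cols(tibble::tibble(gene_id = genes), df)
  }
  surv <- tibble::tibble(sample = c("s1", "s2", "s3"),
                         time = c(1, 2, 3), status = c(1L, 0L, 1L))
  # identical id sets: identity alignment
  a <- mk(c("A", "B"), c("s1", "s2", "s3"))
  al <- match_platforms(a, a, surv)
  expect_identical(al$dcna, a)
  expect_identical(al$survival$sample, surv$sample)
  # set intersection on genes
  b <- mk(c("B", "C", "D"), c("s1", "s2", "s3"))
  expect_message(al2 <- match_platforms(mk(c("A", "B", "C"), c("s1", "s2", "s3")),
                                        b, surv), "dropped")
  expect_identical(al2$dcna$gene_id, c("B", "C"))
  expect_identical(al2$mrna$gene_id, c("B", "C"))
  expect_error(match_platforms(mk("A", "s1"), mk("B", "s1"),
                               tibble::tibble(sample = "s1", time = 1,
                                              status = 1L)),
               class = "medhaz_validation_error")
})

test_that("scrambled sample orders are realigned to the reference order", {
  set.seed(802)
  fx <- make_fixture(withr::local_tempdir(), n_genes = 50, n_samples = 30,
                     n_pathway_genes = 5, config = sim_config(seed = 803))
  dcna <- fx$data$dcna
  mrna <- fx$data$mrna
  surv <- fx$data$survival
  for (i in 1:10) {
    perm <- sample(30)
    mrna_s <- mrna[c(1, perm + 1)]
    surv_s <- surv[sample(30), ]
    al <- match_platforms(dcna, mrna_s, surv_s)
    # permutation oracle: columns put back by name must equal the originals
    expect_identical(al$mrna, mrna)
    expect_identical(al$dcna, dcna)
    expect_equal(al$survival$time, surv$time)
  }
})

test_that("screening one pathway gene reproduces single-gene inference", {
  fx <- make_fixture(withr::local_tempdir(), n_genes = 1, n_samples = 300,
                     n_pathway_genes = 1, config = sim_config(seed = 804))
  al <- match_platforms(fx$data$dcna, fx$data$mrna, fx$data$survival)
  row <- screen_genes(al)
  d <- tibble::tibble(dcna = as.numeric(fx$data$dcna[1, -1]),
                      mrna = as.numeric(fx$data$mrna[1, -1]),
                      time = fx$data$survival$time,
                      status = fx$data$survival$status)
  res <- mediate_survival(d)
  expect_equal(row$alpha_m, res$alpha_m, tolerance = 1e-12)
  expect_equal(row$lambda_m, res$lambda_m, tolerance = 1e-12)
  expect_equal(row$lambda_c, res$lambda_c, tolerance = 1e-12)
  expect_equal(row$p_mediated, res$p_mediated, tolerance = 1e-12)
  expect_equal(row$q_mediated, res$p_mediated, tolerance = 1e-12)
})

test_that("no false mediation calls under the global null", {
  discoveries <- 0L
  for (s in c(805, 806, 807)) {
    fx <- make_fixture(withr::local_tempdir(), n_genes = 300,
                       n_samples = 100, n_pathway_genes = 0,
                       config = sim_config(seed = s))
    al <- match_platforms(fx$data$dcna, fx$data$mrna, fx$data$survival)
    res <- screen_genes(al, family = "all_genes")
    discoveries <- discoveries +
      sum(res$classification %in% c("complete_mediation", "partial_mediation"))
  }
  expect_lte(discoveries, 2L)
})

test_that("planted pathway genes are recovered with FDR control", {
  fx <- make_fixture(withr::local_tempdir(), n_genes = 200, n_samples = 300,
                     n_pathway_genes = 20, config = sim_config(seed = 808))
  al <- match_platforms(fx$data$dcna, fx$data$mrna, fx$data$survival)
  res <- screen_genes(al, family = "prefiltered")
  hits <- res$gene_id[res$classification %in%
                        c("complete_mediation", "partial_mediation")]
  pathway <- fx$truth$gene_id[fx$truth$pathway]
  expect_gt(length(intersect(hits, pathway)), length(pathway) / 2)
  fdp <- if (length(hits) == 0) 0 else
    length(setdiff(hits, pathway)) / length(hits)
  expect_lte(fdp, 0.1)
  # prefiltered candidates are a subset of the all-genes family
  res_all <- screen_genes(al, family = "all_genes")
  expect_true(all(res$selected <= res_all$selected))
})

test_that("direct-effect strength separates complete from partial mediation", {
  # classification is subject to per-gene type-I/II error, so check the
  # majority call over independent cohorts rather than a single draw
  classify <- function(lambda_c, seed) {
    fx <- make_fixture(withr::local_tempdir(), n_genes = 1, n_samples = 1000,
                       n_pathway_genes = 1,
                       config = sim_config(lambda_c = lambda_c, seed = seed))
    al <- match_platforms(fx$data$dcna, fx$data$mrna, fx$data$survival)
    screen_genes(al)$classification
  }
  no_direct <- vapply(809:813, function(s) classify(0, s), character(1))
  expect_gte(sum(no_direct == "complete_mediation"), 4)
  with_direct <- vapply(814:818, function(s) classify(0.4, s), character(1))
  expect_gte(sum(with_direct == "partial_mediation"), 4)
})

test_that("per-gene fit failures are flagged rows, not errors", {
  fx <- make_fixture(withr::local_tempdir(), n_genes = 5, n_samples = 40,
                     n_pathway_genes = 0, config = sim_config(seed = 811))
  dcna <- fx$data$dcna
  dcna[3, -1] <- as.list(rep(0.5, 40))  # constant exposure for one gene
  al <- match_platforms(dcna, fx$data$mrna, fx$data$survival)
  res <- screen_genes(al)
  expect_true(res$failed[3])
  expect_false(any(res$failed[-3]))
  expect_equal(res$classification[3], "none")
})
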