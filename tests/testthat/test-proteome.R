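test_that("protein ranking puts undetected at zero and is deterministic", {
  pr <- tibble::tibble(gene = c("A", "B", "C"),
                       log2fc = c(-2, 0, 1),
                       detected = TRUE)
  expect_equal(rank_proteins(pr)$gene, c("A", "B", "C"))

  # undetected D enters at 0, between negatives and positives
  with_d <- dplyr::bind_rows(pr, tibble::tibble(gene = "D", log2fc = NA_real_,
                                                detected = FALSE))
  ranked <- rank_proteins(with_d)
  expect_equal(ranked$gene, c("A", "B", "D", "C"))  # B before D: gene-id tie
  expect_equal(ranked$log2fc[ranked$gene == "D"], 0)

  # permuted rows rank identically
  expect_equal(rank_proteins(with_d[c(3, 1, 4, 2), ]), ranked)

  dup <- dplyr::bind_rows(pr, pr[1, ])
  expect_error(rank_proteins(dup), "duplicate",
               class = "gliosplice_validation_error")
})

test_that("enrichment reproduces closed-form hypergeometric examples", {
  # N=10, K=5, n=5, k=5: p = 1 / C(10,5) = 1/252
  ranked <- tibble::tibble(gene = sprintf("g%02d", 1:10))
  res <- enrich(ranked, sprintf("g%02d", 1:5), top_k = 5)
  expect_equal(res$k, 5)
  expect_equal(res$p_value, 1 / 252, tolerance = 1e-12)

  # zero overlap: fold 0, p = 1
  res0 <- enrich(ranked, sprintf("g%02d", 6:10), top_k = 3)
  # top 3 of the ranked list are g01..g03, none in the set
  expect_equal(res0$k, 0)
  expect_equal(res0$fold, 0)
  expect_equal(res0$p_value, 1)

  # fold * expected = k identically
  pr <- sim_proteome(200, 40, seed = 2)
  e <- enrich(rank_proteins(pr$proteins), pr$gene_set, 30)
  expect_equal(e$fold * e$expected, e$k)

  # p is non-increasing in k at fixed margins
  ps <- vapply(0:10, function(k) hyper_enrichment(100, 20, 10, k)$p_value,
               numeric(1))
  expect_true(all(diff(ps) <= 1e-15))

  expect_error(enrich(ranked, character(0), 5), "empty")
  expect_error(enrich(ranked, "not_there", 5), "subset")
})

test_that("enrichment p equals brute-force tail summation", {
  set.seed(12)
  for (i in 1:50) {
    N <- sample(20:2000, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hyper_enrichment(N, K, n, k)$p_value,
                 brute_force_tail(N, K, n, k), tolerance = 1e-9)
  }
})

test_that("bootstrap fold SE is seeded, sane, and degenerate when set = universe", {
  pr <- sim_proteome(300, 50, frac_depleted_in_set = 0.4, seed = 3)
  b1 <- bootstrap_fold_se(pr$proteins, pr$gene_set, 30, B = 50, seed = 9)
  b2 <- bootstrap_fold_se(pr$proteins, pr$gene_set, 30, B = 50, seed = 9)
  expect_equal(b1, b2)
  fold <- enrich(rank_proteins(pr$proteins), pr$gene_set, 30)$fold
  expect_gt(b1$se, 0)
  expect_lt(b1$se, fold)

  # the whole universe as gene set: fold is identically 1, SE = 0
  whole <- bootstrap_fold_se(pr$proteins, pr$proteins$gene, 30, B = 20,
                             seed = 1)
  expect_equal(whole$folds, rep(1, 20))
  expect_equal(whole$se, 0)
})

test_that("RNA-protein correlation matches the closed form and the zero rule", {
  rna <- tibble::tibble(gene = c("a", "b", "c", "d"), log2fc = c(0, 1, 2, 3))
  prot <- tibble::tibble(gene = c("a", "b", "c", "d"),
                         log2fc = c(0, 1, 1, 3), detected = TRUE)
  got <- rna_protein_correlation(rna, prot)
  # hand-computed Pearson r for {(0,0),(1,1),(2,1),(3,3)}
  expect_equal(got$r, 4.5 / sqrt(5 * 4.75), tolerance = 1e-12)
  expect_equal(got$df, 2)

  # affine transformation leaves r = 1
  aff <- dplyr::mutate(rna, gene = gene)
  prot_aff <- tibble::tibble(gene = rna$gene, log2fc = 2 * rna$log2fc + 1,
                             detected = TRUE)
  expect_equal(rna_protein_correlation(aff, prot_aff)$r, 1)

  # undetected proteins enter the correlation at 0
  prot_un <- dplyr::mutate(prot, detected = c(TRUE, TRUE, TRUE, FALSE),
                           log2fc = c(0, 1, 1, NA))
  got_un <- rna_protein_correlation(rna, prot_un)
  manual <- cor(c(0, 1, 2, 3), c(0, 1, 1, 0))
  expect_equal(got_un$r, manual)

  # restriction to a gene set narrows n
  sub <- rna_protein_correlation(rna, prot, restrict_to = c("a", "b", "c"))
  expect_equal(sub$n, 3)

  expect_error(rna_protein_correlation(rna[1:2, ], prot), "three")
})

test_that("the GSEA ranking statistic is signed -log10 with infinity handling", {
  g <- tibble::tibble(gene = c("up", "null", "down"),
                      lfc = c(2, -1, -3), padj = c(0.01, 1, 0.001))
  r <- gsea_rank_statistic(g, seed = 1)
  expect_equal(r$score[r$gene == "up"], 2)
  expect_equal(r$score[r$gene == "null"], 0)
  expect_equal(r$score[r$gene == "down"], -3)
  expect_equal(r$gene, c("up", "null", "down"))  # sorted descending

  # two zero p-values with positive LFC land in (max_finite, max_finite + 1],
  # distinct, above every finite score
  gz <- tibble::tibble(gene = c("a", "b", "c"),
                       lfc = c(1, 2, 1), padj = c(0, 0, 1e-5))
  rz <- gsea_rank_statistic(gz, seed = 42)
  finite_max <- 5  # -log10(1e-5)
  inf_scores <- rz$score[rz$gene %in% c("a", "b")]
  expect_true(all(inf_scores > finite_max & inf_scores <= finite_max + 1))
  expect_length(unique(inf_scores), 2)
  expect_true(all(inf_scores > rz$score[rz$gene == "c"]))

  # seeded: reproducible
  expect_equal(gsea_rank_statistic(gz, seed = 42),
               gsea_rank_statistic(gz, seed = 42))

  expect_error(gsea_rank_statistic(dplyr::mutate(g, padj = c(2, 1, 1))),
               "\\[0, 1\\]")
})
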