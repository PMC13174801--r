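test_that("null effect model realizes the configured prevalence", {
  cfg <- simulation_config(n_genes = 50, n_causal_genes = 0,
                           prevalence = 0.05,
                           studies = list(list(n_cases = 1000,
                                               n_referents = 19000)),
                           seed = 7)
  st <- simulate_cohort(cfg, 1)
  n <- length(st$phenotype)
  expect_equal(n, 20000)
  sd3 <- 3 * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(mean(st$phenotype) - 0.05), sd3)
})

test_that("annotation class proportions follow the configured mix", {
  cfg <- simulation_config(n_genes = 400, seed = 12,
                           studies = list(list(n_cases = 50,
                                               n_referents = 450)))
  vt <- simulate_variant_table(cfg)
  props <- prop.table(table(vt$sim_class))[names(cfg$annotation_mix)]
  m <- nrow(vt)
  for (cl in names(cfg$annotation_mix)) {
    tol <- 4 * sqrt(cfg$annotation_mix[[cl]] *
                      (1 - cfg$annotation_mix[[cl]]) / m)
    expect_lt(abs(props[[cl]] - cfg$annotation_mix[[cl]]), tol)
  }
  # qualitative composition: ~quarter synonymous, about half benign
  # missense, 10-15% damaging missense, under 5% PTV
  expect_lt(abs(props[["synonymous"]] - 0.25), 0.05)
  expect_lt(props[["PTV"]], 0.05)
})

test_that("identical seeds give identical datasets", {
  cfg <- small_config(seed = 31)
  a <- simulate_cohort(cfg, 1)
  b <- simulate_cohort(cfg, 1)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$covariates, b$covariates)
  expect_true(identical(as.matrix(a$genotypes), as.matrix(b$genotypes)))
  expect_identical(a$variant_table, b$variant_table)
})

test_that("multi-study cohorts share truth but draw independent noise", {
  cfg <- simulation_config(
    n_genes = 40, seed = 5,
    studies = list(list(n_cases = 200, n_referents = 800),
                   list(n_cases = 200, n_referents = 800)))
  ss <- simulate_multi_study(cfg)
  expect_length(ss, 2)
  vt_cols <- c("variant_id", "gene", "consequence", "true_freq",
               "liability_beta")
  expect_identical(ss[[1]]$variant_table[vt_cols],
                   ss[[2]]$variant_table[vt_cols])
  expect_false(identical(as.matrix(ss[[1]]$genotypes),
                         as.matrix(ss[[2]]$genotypes)))
})

test_that("eight configured studies yield eight datasets", {
  cfg <- simulation_config(
    n_genes = 10, n_causal_genes = 0, seed = 2,
    studies = rep(list(list(n_cases = 30, n_referents = 170)), 8))
  expect_length(simulate_multi_study(cfg), 8)
})

test_that("in-sample frequencies converge to configured frequencies", {
  cfg <- simulation_config(n_genes = 8, n_causal_genes = 0,
                           variants_per_gene = 3,
                           freq_range = c(1e-3, 1e-2), seed = 9,
                           studies = list(list(n_cases = 2500,
                                               n_referents = 47500)))
  st <- simulate_cohort(cfg, 1)
  vt <- st$variant_table
  n2 <- 2 * length(st$phenotype)
  se <- sqrt(vt$true_freq * (1 - vt$true_freq) / n2)
  expect_true(all(abs(vt$in_sample_freq - vt$true_freq) < 4 * se + 1e-12))
})

test_that("case ascertainment hits the target case count", {
  cfg <- simulation_config(
    n_genes = 20, n_causal_genes = 0, prevalence = 0.05, seed = 44,
    studies = list(list(n_cases = 400, n_referents = 600,
                        case_ascertainment = TRUE)))
  st <- simulate_cohort(cfg, 1)
  expect_equal(sum(st$phenotype == 1), 400)
  expect_equal(sum(st$phenotype == 0), 600)
})

test_that("degenerate configurations are rejected", {
  expect_error(simulation_config(prevalence = 0), "prevalence")
  expect_error(simulation_config(prevalence = 0.6), "prevalence")
  expect_error(simulation_config(n_genes = 0), "degenerate")
  expect_error(simulation_config(studies = list()), "at least one")
  expect_error(simulation_config(
    studies = list(list(n_cases = 0, n_referents = 10))), "positive")
  expect_error(simulation_config(
    annotation_mix = c(synonymous = 0.5, benign_missense = 0.5,
                       damaging_missense = 0.2, PTV = 0.1)), "sum to 1")
})

test_that("causal genes rank ahead of null genes in association", {
  cfg <- simulation_config(
    n_genes = 80, n_causal_genes = 15, variants_per_gene = 16,
    effect_model = c(PTV = 1.8, damaging_missense = 1.1),
    studies = list(list(n_cases = 500, n_referents = 4500),
                   list(n_cases = 500, n_referents = 2000)), seed = 77)
  ss <- simulate_multi_study(cfg)
  assoc <- do.call(rbind, lapply(ss, run_study_scan, cmac_min = 5))
  meta <- meta_filter(meta_analyze(assoc))
  genes <- layered_gene_pvalue(meta)
  truth <- attr(attr(ss, "variant_table"), "causal_genes")
  causal_p <- genes$p_final[genes$gene %in% truth]
  null_p <- genes$p_final[!genes$gene %in% truth]
  expect_gt(length(causal_p), 2)
  rs <- wilcox.test(causal_p, null_p, alternative = "less")
  expect_lt(rs$p.value, 0.05)
})

test_that("gwas annotation simulator respects its invariants", {
  truth <- data.frame(gene = sprintf("G%03d", 1:400),
                      causal = rep(c(TRUE, FALSE), c(40, 360)))
  g1 <- simulate_gwas_annotations(truth, enrichment = 1, seed = 3)
  expect_true(all(g1$geneprio_score[!g1$in_locus] == 0))
  # null enrichment: causal and null genes have equal locus probability
  tb <- table(truth$causal, g1$in_locus)
  expect_gt(fisher.test(tb)$p.value, 0.001)
  g10 <- simulate_gwas_annotations(truth, enrichment = 10, seed = 3)
  expect_gt(mean(g10$in_locus[truth$causal]),
            mean(g10$in_locus[!truth$causal]))
  expect_error(simulate_gwas_annotations(truth, enrichment = 0.5))
})

test_that("chromosome X males carry haploid dosages", {
  cfg <- simulation_config(n_genes = 30, n_causal_genes = 0,
                           frac_chrx = 1, seed = 15,
                           studies = list(list(n_cases = 150,
                                               n_referents = 850)))
  st <- simulate_cohort(cfg, 1)
  male <- st$covariates$sex == 1
  G <- as.matrix(st$genotypes)
  expect_true(all(G[male, ] <= 1))
  expect_true(all(G %in% 0:2))
})
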