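test_that("Cauchy combination basics hold exactly", {
  expect_equal(cauchy_combine(c(0.5, 0.5, 0.5)), 0.5)
  expect_equal(cauchy_combine(0.037), 0.037, tolerance = 1e-12)
  expect_equal(cauchy_combine(0.9), 0.9, tolerance = 1e-12)
  expect_error(cauchy_combine(numeric(0)), "empty")
  expect_error(cauchy_combine(c(0.5, 0)), "lie in")
  expect_error(cauchy_combine(c(0.5, 1.2)), "lie in")
  expect_error(cauchy_combine(c(0.2, 0.3), weights = c(1, -1)), "weights")
  # p = 1 is clipped, not rejected (penalized LRTs can return exactly 1)
  expect_lt(cauchy_combine(c(1, 1)), 1 + 1e-12)
})

test_that("fixed lists match an independent high-precision evaluation", {
  # independent oracle: the transform evaluated term by term with
  # arbitrary-precision-safe arithmetic, plus a Monte-Carlo check of the
  # equivalent Cauchy-mixture tail
  plist <- c(0.01, 0.2, 0.9)
  tstat <- mean(1 / tan(plist * pi))   # tan((0.5-p)pi) = cot(p pi)
  expected <- pcauchy(tstat, lower.tail = FALSE)
  expect_equal(cauchy_combine(plist), expected, tolerance = 1e-12)
  set.seed(5)
  draws <- matrix(rcauchy(3 * 2e6), ncol = 3)
  mc <- mean(rowMeans(draws) > tstat)
  expect_lt(abs(mc - expected) / expected, 0.05)
  # tiny p handled through the 1/(pi p) expansion
  expect_equal(cauchy_combine(c(1e-18, 0.5, 0.5)),
               pcauchy(mean(c(1 / (1e-18 * pi), 0, 0)),
                       lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("combination is permutation- and duplication-invariant", {
  set.seed(8)
  for (k in c(2, 5, 9)) {
    p <- runif(k)
    expect_equal(cauchy_combine(p), cauchy_combine(sample(p)))
    expect_equal(cauchy_combine(p), cauchy_combine(rep(p, 2)),
                 tolerance = 1e-12)
  }
})

test_that("decreasing any single p never increases the combined p", {
  set.seed(13)
  for (rep in 1:20) {
    p <- runif(5)
    i <- sample(5, 1)
    p2 <- p; p2[i] <- p[i] * runif(1)
    expect_lte(cauchy_combine(p2), cauchy_combine(p) + 1e-12)
  }
})

test_that("combined p of independent uniforms is uniform", {
  set.seed(99)
  n <- 20000
  for (k in c(3, 7)) {
    u <- matrix(runif(n * k), ncol = k)
    comb <- 0.5 - atan(rowMeans(tan((0.5 - u) * pi))) / pi
    ks <- ks.test(comb, "punif")
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("layered gene p-values equal two manual combination layers", {
  meta <- data.frame(
    gene = "G1", stratum = "autosomal",
    annotation_group = c("missREVEL", "miss3/4", "PTV", "PTVnf",
                         "PTV+missREVEL", "PTVnf+miss3/4"),
    freq_tier = "R",
    beta_meta = rnorm(6, 0.3, 0.1), se_meta = runif(6, 0.08, 0.2),
    p_ivw = c(0.02, 0.04, 0.3, 0.25, 0.01, 0.05),
    cmac_total = c(40, 30, 25, 22, 60, 45), n_studies = 2)
  g <- layered_gene_pvalue(meta)
  p_miss <- cauchy_combine(c(0.02, 0.04))
  p_ptv <- cauchy_combine(c(0.3, 0.25))
  p_pm <- cauchy_combine(c(0.01, 0.05))
  expect_equal(g$p_missense, p_miss)
  expect_equal(g$p_ptv, p_ptv)
  expect_equal(g$p_ptv_miss, p_pm)
  expect_equal(g$p_final, cauchy_combine(c(p_miss, p_ptv, p_pm)))
  expect_equal(g$n_masks, 6)
  # best mask: minimum p with ties broken by larger cMAC
  expect_equal(g$best_mask, "PTV+missREVEL_R")
})

test_that("single-layer genes pass their layer p through", {
  meta <- data.frame(
    gene = "G2", stratum = "autosomal",
    annotation_group = c("PTV", "PTVnf"), freq_tier = c("UR", "UR"),
    beta_meta = c(0.5, 0.4), se_meta = c(0.2, 0.2),
    p_ivw = c(0.01, 0.03), cmac_total = c(25, 22), n_studies = 2)
  g <- layered_gene_pvalue(meta)
  expect_equal(g$p_final, cauchy_combine(c(0.01, 0.03)))
  expect_true(is.na(g$p_missense))
  # all masks at p = 0.5 combine to 0.5
  meta$p_ivw <- c(0.5, 0.5)
  expect_equal(layered_gene_pvalue(meta)$p_final, 0.5)
})

test_that("lambda90 is calibrated, scales, and flags degenerate input", {
  n <- 1e5
  grid <- (1:n) / (n + 1)
  expect_equal(lambda90(grid), 1, tolerance = 1e-3)
  # chi-square statistics inflated by 1.2 convert back to lambda ~ 1.2
  chi <- qchisq(grid, df = 1, lower.tail = FALSE) * 1.2
  p_infl <- pchisq(chi, df = 1, lower.tail = FALSE)
  expect_equal(lambda90(p_infl), 1.2, tolerance = 1e-3)
  # degenerate: all p identical
  p0 <- rep(0.123, 200)
  expect_equal(lambda90(p0),
               qchisq(0.123, 1, lower.tail = FALSE) / qchisq(0.9, 1))
  expect_error(lambda90(runif(50)), "at least 100")
})

test_that("sensitivity recombination restricts and attenuates correctly", {
  # planted signal carried by a single low-frequency (RL) mask
  meta <- data.frame(
    gene = "G3", stratum = "autosomal",
    annotation_group = c("PTV", "PTV", "missREVEL"),
    freq_tier = c("UR", "RL", "RL"),
    beta_meta = c(0.1, 1.2, 0.9), se_meta = c(0.3, 0.2, 0.25),
    p_ivw = c(0.7, 1e-6, 1e-4), cmac_total = c(25, 300, 200),
    n_studies = 2)
  full <- layered_gene_pvalue(meta)
  ident <- sensitivity_recombine(meta)
  expect_equal(ident$p_final, full$p_final)
  ptv_only <- sensitivity_recombine(meta, layers = "PTV")
  expect_equal(ptv_only$p_final, cauchy_combine(c(0.7, 1e-6)))
  rare_only <- sensitivity_recombine(meta, freq_tiers = c("UR", "R"))
  expect_gt(rare_only$p_final, full$p_final)   # attenuated
  expect_error(sensitivity_recombine(meta, freq_tiers = character(0)),
               "nonempty")
  # restriction leaving no masks drops the gene
  none <- sensitivity_recombine(meta[meta$freq_tier == "RL", ],
                                freq_tiers = "UR")
  expect_equal(nrow(none), 0)
})

test_that("Bonferroni flag uses the supplied test count", {
  meta <- data.frame(
    gene = c("A", "B"), stratum = "autosomal",
    annotation_group = "PTV", freq_tier = "R",
    beta_meta = c(1, 0.1), se_meta = c(0.2, 0.3),
    p_ivw = c(1e-7, 0.4), cmac_total = c(50, 30), n_studies = 2)
  g <- layered_gene_pvalue(meta, n_tests = 19841)
  expect_equal(g$alpha[1], 0.05 / 19841)
  expect_equal(g$significant, c(TRUE, FALSE))
})
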