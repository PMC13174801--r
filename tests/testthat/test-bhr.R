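test_that("burden scores implement 2p(1-p) additively over bins", {
  vt <- data.frame(
    variant_id = c("v1", "v2", "v3", "v4"),
    gene = c("G1", "G1", "G1", "G2"),
    consequence = c("PTV", "PTV", "synonymous", "missense"),
    revel_damaging = c(FALSE, FALSE, FALSE, TRUE),
    am_damaging = FALSE, pai3d_damaging = FALSE, popeve_damaging = FALSE,
    true_freq = c(1e-5, 1e-5, 2e-6, 5e-5))
  sc <- burden_scores(vt)
  g1_ptv <- sc[sc$gene == "G1" & sc$annotation == "PTV", ]
  # two PTVs at the same frequency double the single-variant score
  expect_equal(g1_ptv$gamma, 2 * (2 * 1e-5 * (1 - 1e-5)))
  expect_equal(g1_ptv$freq_bin, "rare")
  syn <- sc[sc$annotation == "synonymous", ]
  expect_equal(syn$gamma, 2 * 2e-6 * (1 - 2e-6))
  expect_equal(syn$freq_bin, "ultrarare")
  expect_equal(sc$annotation[sc$gene == "G2"], "damaging_missense")
  # variants above the exclusion frequency are dropped
  vt2 <- vt; vt2$true_freq <- 1e-3
  expect_error(burden_scores(vt2), "no variants left")
})

test_that("gamma matches the empirical variance of a simulated burden", {
  set.seed(12)
  n <- 200000
  freqs <- c(2e-5, 5e-5, 8e-5)
  G <- sapply(freqs, function(p) rbinom(n, 2, p))
  burden <- rowSums(G)
  gamma <- sum(2 * freqs * (1 - freqs))
  emp <- var(burden)
  # SE of a sample variance: sqrt((m4 - s^4)/n), heavy-tailed here
  m4 <- mean((burden - mean(burden))^4)
  mc_se <- sqrt((m4 - emp^2) / n)
  expect_lt(abs(emp - gamma), 3 * mc_se)
})

test_that("null summary statistics recover zero heritability", {
  st <- simulate_bhr_sumstats(n_genes = 3000, h2 = 0, prop_causal = 0.05,
                              n = 4e5, seed = 3)
  fit <- bhr_regression(st)
  expect_lt(abs(fit$h2_obs), 2 * fit$se)
})

test_that("planted heritability is recovered within jackknife error", {
  st <- simulate_bhr_sumstats(n_genes = 5000, h2 = 0.02,
                              prop_causal = 0.05, n = 4e5, seed = 21)
  fit <- bhr_regression(st)
  expect_lt(abs(fit$h2_obs - 0.02), 2 * fit$se)
  expect_gt(fit$h2_obs, 0.005)
})

test_that("null and causal bins separate like synonymous versus PTV", {
  syn <- simulate_bhr_sumstats(n_genes = 4000, h2 = 0,
                               prop_causal = 0.05, n = 4e5, seed = 31)
  ptv <- simulate_bhr_sumstats(n_genes = 4000, h2 = 0.015,
                               prop_causal = 0.05, n = 4e5, seed = 32)
  f_syn <- bhr_regression(syn)
  f_ptv <- bhr_regression(ptv)
  expect_lt(abs(f_syn$h2_obs), 2 * f_syn$se)
  expect_gt(f_ptv$h2_obs, 2 * f_ptv$se)
})

test_that("scale equivariance: doubling effects quadruples h2", {
  base <- simulate_bhr_sumstats(n_genes = 5000, h2 = 0.01,
                                prop_causal = 0.1, n = 1e6, seed = 41)
  quad <- simulate_bhr_sumstats(n_genes = 5000, h2 = 0.04,
                                prop_causal = 0.1, n = 1e6, seed = 41)
  f1 <- bhr_regression(base)
  f4 <- bhr_regression(quad)
  expect_lt(abs(f4$h2_obs / f1$h2_obs - 4), 4 * 4 *
              sqrt((f1$se / f1$h2_obs)^2 + (f4$se / f4$h2_obs)^2))
})

test_that("fixed genes are counted directly and partition correctly", {
  st <- simulate_bhr_sumstats(n_genes = 5000, h2 = 0.02,
                              prop_causal = 0.05, n = 4e5,
                              concentrated_share = 0.5, seed = 51)
  conc <- attr(st, "concentrated_gene")
  fit <- bhr_regression(st, fixed_genes = conc)
  part <- partition_h2(fit, list(top = conc, all_fixed = conc))
  expect_lt(abs(part[["top"]] - 0.5), 0.17)
  # full-set partition: all genes fixed sums to 1
  st2 <- simulate_bhr_sumstats(n_genes = 120, h2 = 0.05,
                               prop_causal = 0.5, n = 1e7, seed = 52)
  fit2 <- bhr_regression(st2, fixed_genes = st2$gene[1:60],
                         min_genes = 50)
  pg <- attr(partition_h2(fit2, list(all = st2$gene[1:60])), "per_gene")
  expect_equal(sum(pg) * fit2$h2_obs,
               sum(fit2$fixed_contrib), tolerance = 1e-12)
  expect_equal(as.numeric(partition_h2(fit2, list(none = character(0)))), 0)
  expect_message(partition_h2(fit2, list(x = "NOT_A_GENE")), "omitting")
})

test_that("point estimate is invariant to gene order", {
  st <- simulate_bhr_sumstats(n_genes = 2000, h2 = 0.02,
                              prop_causal = 0.05, n = 4e5, seed = 61)
  f1 <- bhr_regression(st)
  set.seed(1)
  f2 <- bhr_regression(st[sample.int(nrow(st)), ])
  expect_equal(f1$h2_obs, f2$h2_obs, tolerance = 1e-10)
})

test_that("genome-wide correction leaves undirected architectures alone", {
  st <- simulate_bhr_sumstats(n_genes = 4000, h2 = 0.02,
                              prop_causal = 0.05, n = 4e5, seed = 71)
  f0 <- bhr_regression(st)
  f1 <- bhr_regression(st, genomewide_correction = TRUE)
  # signs are random, so the fitted directional component is small and
  # the estimate moves by much less than its SE
  expect_lt(abs(f1$h2_obs - f0$h2_obs), f0$se)
})

test_that("liability transform matches its closed form", {
  expect_equal(liability_transform(0, 0.1, 0.3), 0)
  K <- 0.05
  z <- dnorm(qnorm(1 - K))
  expect_equal(liability_transform(0.01, K),
               0.01 * K * (1 - K) / z^2, tolerance = 1e-12)
  # general formula reduces to the population-sample branch at P = K
  expect_equal(liability_transform(0.01, K, P = K),
               0.01 * K^2 * (1 - K)^2 / (z^2 * K * (1 - K)),
               tolerance = 1e-12)
  # monotone increasing in h2_obs, continuous in K
  h <- seq(0, 0.05, by = 0.01)
  out <- sapply(h, liability_transform, K = 0.053, P = 0.1)
  expect_true(all(diff(out) > 0))
  expect_lt(abs(liability_transform(0.01, 0.0530) -
                  liability_transform(0.01, 0.0530 + 1e-6)), 1e-6)
  expect_error(liability_transform(0.01, 0), "strictly inside")
  expect_error(liability_transform(0.01, 0.5, 1), "strictly inside")
})

test_that("jackknife error shrinks as gene count grows", {
  ses <- sapply(c(200, 1000, 5000), function(ng) {
    st <- simulate_bhr_sumstats(n_genes = ng, h2 = 0.02,
                                prop_causal = 0.1, n = 4e5, seed = 81)
    bhr_regression(st)$se
  })
  expect_true(all(diff(ses) < 0))
})

test_that("end-to-end scores from a simulated cohort feed the regression", {
  cfg <- simulation_config(
    n_genes = 400, n_causal_genes = 40, variants_per_gene = 12,
    freq_range = c(2e-6, 9e-5), prevalence = 0.1,
    effect_model = c(PTV = 0.8, damaging_missense = 0.4), seed = 93,
    studies = list(list(n_cases = 4000, n_referents = 36000)))
  st <- simulate_cohort(cfg, 1)
  sc <- suppressMessages(burden_scores(st$variant_table, st, cmac_min = 10))
  expect_true(all(c("gamma", "alpha_hat", "se", "cmac") %in% names(sc)))
  expect_true(all(sc$cmac >= 10))
  ptv <- sc[sc$annotation == "PTV", ]
  syn <- sc[sc$annotation == "synonymous", ]
  if (nrow(ptv) >= 50 && nrow(syn) >= 50) {
    f_ptv <- bhr_regression(ptv, n_blocks = 50)
    f_syn <- bhr_regression(syn, n_blocks = 50)
    expect_gt(f_ptv$h2_obs, f_syn$h2_obs)
  }
})
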