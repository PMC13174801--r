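test_that("Fisher exact p equals hypergeometric enumeration", {
  # independent oracle: sum of hypergeometric point masses at least as
  # extreme as observed, enumerated with dhyper
  hyper_p <- function(a, b, c, d) {
    m <- a + c; n <- b + d; k <- a + b
    x <- max(0, k - n):min(k, m)
    probs <- dhyper(x, m, n, k)
    sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  # the printed-scale fixture
  ft <- fisher.test(matrix(c(9, 3239, 6, 15228), 2))
  expect_equal(ft$p.value, hyper_p(9, 6, 3239, 15228), tolerance = 1e-12)
  # exhaustive check over tables with small margins
  set.seed(41)
  for (rep in 1:200) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    cc <- sample(0:25, 1); d <- sample(0:25, 1)
    if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0)
      next
    ft <- fisher.test(matrix(c(a, cc, b, d), 2))
    expect_equal(ft$p.value, hyper_p(a, b, cc, d), tolerance = 1e-12)
  }
})

test_that("the enrichment grid builds correct tables and flags", {
  gr <- data.frame(gene = sprintf("g%02d", 1:40),
                   p_final = c(rep(1e-8, 4), runif(36, 0.2, 1)))
  gw <- data.frame(gene = gr$gene,
                   in_locus = c(rep(TRUE, 3), rep(FALSE, 1),
                                rep(TRUE, 7), rep(FALSE, 29)),
                   geneprio_score = 0L)
  gw$geneprio_score[gw$in_locus] <- rep(c(3L, 0L), length.out = 10)
  grid <- fisher_enrichment(gr, gw, rvas_cutoffs = 1e-6,
                            geneprio_cutoffs = c(0, 3))
  cell0 <- grid[grid$geneprio_cutoff == 0, ]
  expect_equal(cell0$a, 3); expect_equal(cell0$b, 1)
  expect_equal(cell0$c, 7); expect_equal(cell0$d, 29)
  expect_equal(cell0$a + cell0$b + cell0$c + cell0$d, 40)
  expect_equal(cell0$or_sample, (3 * 29) / (1 * 7))
  ftref <- fisher.test(matrix(c(3, 7, 1, 29), 2))
  expect_equal(cell0$p_value, ftref$p.value)
  expect_equal(cell0$or, unname(ftref$estimate))
})

test_that("independent RVAS and GWAS sets show no enrichment", {
  set.seed(55)
  n <- 2000
  gr <- data.frame(gene = sprintf("g%04d", 1:n), p_final = runif(n))
  gw <- data.frame(gene = gr$gene,
                   in_locus = runif(n) < 0.15, geneprio_score = 0L)
  grid <- fisher_enrichment(gr, gw, rvas_cutoffs = 0.05,
                            geneprio_cutoffs = 0)
  expect_gt(grid$p_value, 0.001)
  expect_lt(abs(log(grid$or)), log(3))
})

test_that("simulated tenfold enrichment is recovered within its CI", {
  set.seed(66)
  truth <- data.frame(gene = sprintf("g%04d", 1:2000),
                      causal = rep(c(TRUE, FALSE), c(100, 1900)))
  gw <- simulate_gwas_annotations(truth, enrichment = 10, seed = 67)
  gr <- data.frame(gene = truth$gene,
                   p_final = ifelse(truth$causal, 1e-8, runif(2000)))
  grid <- fisher_enrichment(gr, gw, rvas_cutoffs = 1e-6,
                            geneprio_cutoffs = 0)
  expect_lt(grid$ci_lo, 10)
  expect_gt(grid$ci_hi, 10)
  expect_lt(grid$p_value, 1e-6)
})

test_that("degenerate margins are flagged, unbounded ORs survive", {
  gr <- data.frame(gene = c("a", "b", "c", "d"),
                   p_final = c(1e-9, 1e-9, 0.5, 0.6))
  gw <- data.frame(gene = gr$gene,
                   in_locus = c(TRUE, TRUE, TRUE, FALSE),
                   geneprio_score = 0L)
  grid <- fisher_enrichment(gr, gw, rvas_cutoffs = 1e-6,
                            geneprio_cutoffs = 0)
  # b = 0: all significant genes in loci; conditional OR unbounded above
  expect_equal(grid$b, 0)
  expect_false(grid$degenerate)
  expect_equal(grid$ci_hi, Inf)
  expect_true(is.finite(grid$ci_lo))
  # empty significant margin flags degenerate
  grid2 <- fisher_enrichment(gr[3:4, ], gw[3:4, ], rvas_cutoffs = 1e-6,
                             geneprio_cutoffs = 0)
  expect_true(grid2$degenerate)
})

test_that("monotonicity: tightening the RVAS cutoff cannot grow cell a", {
  set.seed(72)
  gr <- data.frame(gene = sprintf("g%03d", 1:500),
                   p_final = rbeta(500, 0.3, 4))
  gw <- data.frame(gene = gr$gene, in_locus = runif(500) < 0.3,
                   geneprio_score = 0L)
  grid <- fisher_enrichment(gr, gw,
                            rvas_cutoffs = c(1e-4, 1e-3, 1e-2),
                            geneprio_cutoffs = 0)
  a_by_cut <- grid$a[order(grid$rvas_cutoff)]
  expect_true(all(diff(a_by_cut) >= 0))
})

test_that("subset discovery applies the subset-sized threshold", {
  gr <- data.frame(gene = sprintf("g%04d", 1:4000),
                   p_final = 1)
  gr$p_final[1:3] <- c(1e-5, 2e-4, 3e-4)
  s207 <- subset_discovery(gr, gr$gene[1:207])
  expect_equal(s207$alpha, 0.05 / 207)
  expect_equal(s207$significant$gene, c("g0001", "g0002"))
  s3248 <- subset_discovery(gr, gr$gene[1:3248])
  expect_equal(s3248$alpha, 0.05 / 3248)
  expect_equal(s3248$significant$gene, "g0001")
  none <- subset_discovery(gr[10:19, ], gr$gene[10:19])
  expect_equal(nrow(none$significant), 0)
  expect_error(subset_discovery(gr, character(0)), "empty")
})

test_that("power-law fit recovers exact and noisy relationships", {
  maf <- 10^seq(-5, -1, length.out = 20)
  et <- data.frame(maf = maf, abs_beta = 2 * maf^(-0.3))
  fit <- fit_powerlaw(et)
  expect_equal(fit$slope, -0.3, tolerance = 1e-10)
  expect_equal(fit$intercept, log(2), tolerance = 1e-10)
  # constant effect: slope 0
  et2 <- data.frame(maf = maf, abs_beta = 0.7)
  expect_equal(fit_powerlaw(et2)$slope, 0, tolerance = 1e-10)
  # noisy recovery at known truth
  set.seed(91)
  maf3 <- 10^runif(300, -5, -1)
  et3 <- data.frame(maf = maf3,
                    abs_beta = 1.5 * maf3^(-0.25) *
                      exp(rnorm(300, 0, 0.2)))
  expect_lt(abs(fit_powerlaw(et3)$slope - (-0.25)), 0.05)
  expect_error(fit_powerlaw(data.frame(maf = c(0, 1e-3, 1e-2),
                                       abs_beta = c(1, 1, 1))),
               "positive")
})

test_that("CI band fits bracket the point fit", {
  set.seed(14)
  maf <- 10^runif(50, -4, -1)
  beta <- 2 * maf^(-0.2) * exp(rnorm(50, 0, 0.1))
  et <- data.frame(maf = maf, abs_beta = beta,
                   ci_lo = beta * 0.8, ci_hi = beta * 1.25)
  fit <- fit_powerlaw(et)
  grid <- seq(log(min(maf)), log(max(maf)), length.out = 20)
  pt <- fit$intercept + fit$slope * grid
  lo <- fit$band_lower[["intercept"]] + fit$band_lower[["slope"]] * grid
  hi <- fit$band_upper[["intercept"]] + fit$band_upper[["slope"]] * grid
  expect_true(all(lo <= pt + 1e-9))
  expect_true(all(hi >= pt - 1e-9))
})
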