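# Shared fixture builders. Everything is generated in code; no stored data.

# Small two-study configuration used across module tests.
small_config <- function(seed = 101, n_genes = 60, n_causal = 6,
                         effects = c(PTV = 0.9, damaging_missense = 0.5)) {
  simulation_config(
    n_genes = n_genes, n_causal_genes = n_causal,
    effect_model = effects,
    studies = list(list(n_cases = 300, n_referents = 2700),
                   list(n_cases = 400, n_referents = 1600)),
    seed = seed)
}

# A hand-built variant table for one gene covering every annotation group
# in every frequency tier: 1 flagged PTV, 1 unflagged PTV, 4 single-tool
# missense, 1 three-tool missense, 1 synonymous -- per tier.
full_gene_table <- function(gene = "G1") {
  tier_freqs <- c(UR = 5e-6, R = 5e-4, RL = 5e-3)
  rows <- list()
  for (tn in names(tier_freqs)) {
    f <- tier_freqs[[tn]]
    mk <- function(consequence, flagged = FALSE,
                   calls = c(FALSE, FALSE, FALSE, FALSE)) {
      data.frame(gene = gene, chrom = "1",
                 consequence = consequence, loftee_flagged = flagged,
                 revel_damaging = calls[1], am_damaging = calls[2],
                 pai3d_damaging = calls[3], popeve_damaging = calls[4],
                 maf_max = f, stringsAsFactors = FALSE)
    }
    rows <- c(rows, list(
      mk("PTV", flagged = TRUE),
      mk("PTV", flagged = FALSE),
      mk("missense", calls = c(TRUE, FALSE, FALSE, FALSE)),
      mk("missense", calls = c(FALSE, TRUE, FALSE, FALSE)),
      mk("missense", calls = c(FALSE, FALSE, TRUE, FALSE)),
      mk("missense", calls = c(FALSE, FALSE, FALSE, TRUE)),
      mk("missense", calls = c(TRUE, TRUE, TRUE, FALSE)),
      mk("synonymous")))
  }
  out <- do.call(rbind, rows)
  out$pos <- seq_len(nrow(out))
  out$variant_id <- paste0("1:", out$pos, ":A:T")
  out
}

# Independent grid-search maximizer of the Firth-penalized likelihood for
# a 2x2 table (carrier x case), used as the oracle for firth_logistic.
# Coarse-to-fine refinement of a 2-d grid; independent of the Newton path.
grid_firth_2x2 <- function(y, x, lim = 8, rounds = 6, pts = 41) {
  pll <- function(a, b) {
    eta <- a + b * x
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    s1 <- sum(w); sx <- sum(w * x); sxx <- sum(w * x^2)
    det <- s1 * sxx - sx^2
    if (det <= 0) return(-Inf)
    sum(y * eta - log1p(exp(pmin(eta, 500)))) + 0.5 * log(det)
  }
  ca <- 0; cb <- 0; ra <- lim; rb <- lim
  for (r in seq_len(rounds)) {
    as <- seq(ca - ra, ca + ra, length.out = pts)
    bs <- seq(cb - rb, cb + rb, length.out = pts)
    vals <- outer(as, bs, Vectorize(pll))
    ij <- arrayInd(which.max(vals), dim(vals))
    ca <- as[ij[1]]; cb <- bs[ij[2]]
    ra <- ra * 2.2 / (pts - 1); rb <- rb * 2.2 / (pts - 1)
  }
  c(intercept = ca, beta = cb)
}

# Exact two-sided mid-p tail of the weighted binomial meta score by full
# enumeration over the joint support (small studies only).
enum_spa_midp <- function(z, cmac, phi, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(cmac))
  zeta <- weights / sum(weights)
  lambda <- zeta / sqrt(cmac * phi * (1 - phi))
  grids <- lapply(seq_along(cmac), function(s) {
    x <- 0:cmac[s]
    list(v = lambda[s] * (x - cmac[s] * phi[s]),
         p = dbinom(x, cmac[s], phi[s]))
  })
  dist <- data.frame(v = 0, p = 1)
  for (g in grids) {
    v <- outer(dist$v, g$v, "+")
    p <- outer(dist$p, g$p)
    key <- round(as.numeric(v), 12)
    agg <- rowsum(as.numeric(p), key)
    dist <- data.frame(v = as.numeric(rownames(agg)), p = as.numeric(agg))
  }
  sdT <- sqrt(sum(zeta^2))
  t_abs <- abs(z) * sdT
  up <- sum(dist$p[dist$v > t_abs + 1e-12]) +
    0.5 * sum(dist$p[abs(dist$v - t_abs) < 1e-9])
  lo <- sum(dist$p[dist$v < -t_abs - 1e-12]) +
    0.5 * sum(dist$p[abs(dist$v + t_abs) < 1e-9])
  min(up + lo, 1)
}
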