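# Burden heritability regression.
#
# The estimand is the fraction of observed-scale phenotypic variance
# explained by gene-level rare-variant burdens within a frequency x
# annotation bin, assuming per-allele effects are homogeneous within a
# gene's bin mask. Writing gamma_g = sum_i 2 p_i (1 - p_i) for the burden
# score (the variance of the allele-sum burden genotype under
# Hardy-Weinberg and negligible LD, the regime of MAF < 1e-4 variation)
# and alpha_g for the effect of the standardized burden genotype on the
# standardized phenotype, E[alpha_hat^2 - se^2] = alpha^2 and, when
# squared per-allele effects are unrelated to gamma,
# E[alpha^2 | gamma] is linear in gamma. Regressing
# (alpha_hat^2 - se^2) on gamma with a free intercept (absorbing
# stratification and residual relatedness) therefore estimates the mean
# squared per-allele effect; h2 = slope * sum(gamma) plus the directly
# counted contributions of any fixed genes.

.BHR_FREQ_BINS <- c(ultrarare = 1e-5, rare = 1e-4)
.BHR_ANNOT <- c("PTV", "damaging_missense", "benign_missense", "synonymous")

.bhr_annotation <- function(vt) {
  damaging <- vt$revel_damaging | vt$am_damaging |
    vt$pai3d_damaging | vt$popeve_damaging
  ifelse(vt$consequence == "PTV", "PTV",
         ifelse(vt$consequence == "synonymous", "synonymous",
                ifelse(damaging, "damaging_missense", "benign_missense")))
}

#' Gene-level burden scores and standardized burden effects per bin
#'
#' Bins variants by frequency (`ultrarare`: AF < 1e-5; `rare`: 1e-5 to
#' 1e-4; variants above 1e-4 are excluded) and annotation (PTV, damaging
#' missense = called damaging by at least one prediction tool,
#' non-damaging missense, synonymous), computes the burden score
#' `gamma_g = sum(2 p (1-p))` per gene-bin, and -- when a study is
#' supplied -- the standardized burden effect `alpha_hat` (regression of
#' the standardized phenotype on the standardized allele-sum burden
#' genotype) with `se = 1/sqrt(n)`, plus the gene-bin cMAC. Gene-bin
#' masks with cMAC below `cmac_min` are excluded.
#'
#' @param variant_table Variant records with `gene`, `consequence`, the
#'   four `*_damaging` columns, and a frequency column (see `freq_col`).
#' @param study Optional `study_dataset` supplying genotypes and phenotype
#'   for `alpha_hat`; without it only `gamma` is computed and `cmac_min`
#'   is not applied.
#' @param cmac_min Minimum gene-bin cMAC (default 20).
#' @param freq_col Column holding the population allele frequency used
#'   for binning and exclusion; defaults to the first of `true_freq`,
#'   `af`, `maf_max`, `in_sample_freq` present.
#' @return Data frame: `gene`, `freq_bin`, `annotation`, `n_variants`,
#'   `gamma`, and with a study also `cmac`, `alpha_hat`, `se`.
#' @export
burden_scores <- function(variant_table, study = NULL, cmac_min = 20,
                          freq_col = NULL) {
  vt <- variant_table
  if (is.null(freq_col)) {
    # population allele frequency preferred over the coarse in-sample one
    freq_col <- intersect(c("true_freq", "af", "maf_max", "in_sample_freq"),
                          names(vt))[1]
    if (is.na(freq_col)) stop("no allele-frequency column found")
  }
  freq <- vt[[freq_col]]
  keep <- !is.na(freq) & freq > 0 & freq <= .BHR_FREQ_BINS[["rare"]]
  vt <- vt[keep, , drop = FALSE]; freq <- freq[keep]
  if (!nrow(vt)) stop("no variants left after the frequency exclusion rule")
  fbin <- ifelse(freq < .BHR_FREQ_BINS[["ultrarare"]], "ultrarare", "rare")
  annot <- .bhr_annotation(vt)
  gamma_i <- 2 * freq * (1 - freq)
  key <- paste(vt$gene, fbin, annot, sep = "\r")
  agg <- rowsum(cbind(gamma = gamma_i, n = 1), key)
  parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  out <- data.frame(gene = parts[, 1], freq_bin = parts[, 2],
                    annotation = parts[, 3],
                    n_variants = as.integer(agg[, "n"]),
                    gamma = agg[, "gamma"],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(study)) {
    G <- study$genotypes[, vt$variant_id, drop = FALSE]
    y <- as.numeric(study$phenotype)
    n <- length(y)
    groups <- split(seq_len(nrow(vt)), key)
    M <- Matrix::sparseMatrix(
      i = unlist(groups),
      j = rep.int(seq_along(groups), lengths(groups)),
      x = 1, dims = c(nrow(vt), length(groups)))
    B <- as.matrix(G %*% M)          # samples x gene-bins allele sums
    colnames(B) <- names(groups)
    cmac <- colSums(B)
    ys <- (y - mean(y)) / stats::sd(y)
    sdB <- apply(B, 2, stats::sd)
    ok <- sdB > 0
    alpha <- rep(NA_real_, ncol(B))
    alpha[ok] <- as.numeric(crossprod(B[, ok, drop = FALSE], ys)) /
      ((n - 1) * sdB[ok])
    idx <- match(paste(out$gene, out$freq_bin, out$annotation, sep = "\r"),
                 names(groups))
    out$cmac <- cmac[idx]
    out$alpha_hat <- alpha[idx]
    out$se <- 1 / sqrt(n)
    drop_n <- sum(out$cmac < cmac_min | is.na(out$alpha_hat))
    if (drop_n)
      message("burden_scores: excluding ", drop_n,
              " gene-bin masks with cMAC < ", cmac_min, " or no variation")
    out <- out[out$cmac >= cmac_min & !is.na(out$alpha_hat), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Burden heritability regression on a gene-bin summary table
#'
#' Weighted least-squares regression of `alpha_hat^2 - se^2` on the burden
#' score `gamma` with a free intercept. Weights come from a one-step
#' iteration: `1 / (2 (gamma * slope0 + se^2)^2)` with `slope0` the
#' unweighted slope (floored at 0), the variance of a squared-normal
#' response. `fixed_genes` are removed from the regression and their
#' contributions `alpha_hat^2 - se^2` counted directly (large-effect genes
#' violate the random-effect linearity and would dominate the slope).
#' With `genomewide_correction`, the fitted genome-wide mean directional
#' per-allele effect (WLS of `alpha_hat` on `sqrt(gamma)`) is removed from
#' the effects before squaring, conditioning the estimate on the
#' genome-wide burden (a guard against directional confounding such as
#' stratification); the removed directional component is not counted as
#' heritability. The standard error is a block jackknife over
#' `n_blocks` contiguous gene blocks.
#'
#' @param score_table Data frame with `gene`, `gamma`, `alpha_hat`, `se`
#'   (one frequency x annotation bin; run bins separately).
#' @param fixed_genes Character vector of genes entered as fixed effects.
#' @param genomewide_correction Logical.
#' @param n_blocks Number of jackknife blocks (capped at the number of
#'   regression genes).
#' @param min_genes Minimum rows required after filtering.
#' @return Object of class `bhr_fit`: `h2_obs`, `se`, `ci95`, `slope`,
#'   `intercept`, `fixed_contrib` (named per-gene contributions),
#'   `sum_gamma`, options used.
#' @export
bhr_regression <- function(score_table, fixed_genes = NULL,
                           genomewide_correction = FALSE,
                           n_blocks = 100, min_genes = 50) {
  st <- score_table
  need <- c("gene", "gamma", "alpha_hat", "se")
  if (!all(need %in% names(st)))
    stop("score_table must have columns: ", paste(need, collapse = ", "))
  if (any(st$gamma <= 0)) stop("burden scores must be positive")
  is_fixed <- st$gene %in% fixed_genes
  reg <- st[!is_fixed, , drop = FALSE]
  if (nrow(reg) < min_genes)
    stop("need at least ", min_genes, " gene-bins for the regression")

  estimate <- function(d) {
    a <- d$alpha_hat
    mu_gw <- 0
    if (genomewide_correction) {
      sg <- sqrt(d$gamma)
      mu_gw <- sum(a * sg / d$se^2) / sum(sg^2 / d$se^2)
      a <- a - mu_gw * sg
    }
    z <- a^2 - d$se^2
    f0 <- stats::lm.fit(cbind(1, d$gamma), z)
    slope0 <- max(f0$coefficients[2], 0)
    w <- 1 / (2 * (d$gamma * slope0 + d$se^2)^2)
    fw <- stats::lm.wfit(cbind(1, d$gamma), z, w)
    c(intercept = unname(fw$coefficients[1]),
      slope = unname(fw$coefficients[2]),
      mu_gw = mu_gw)
  }

  est <- estimate(reg)
  sum_gamma <- sum(reg$gamma)
  fixed_contrib <- if (any(is_fixed)) {
    fc <- st$alpha_hat[is_fixed]^2 - st$se[is_fixed]^2
    names(fc) <- st$gene[is_fixed]
    fc
  } else numeric(0)
  h2 <- est[["slope"]] * sum_gamma + sum(fixed_contrib)

  # block jackknife over contiguous gene blocks of the regression set
  nb <- min(n_blocks, nrow(reg))
  blocks <- split(seq_len(nrow(reg)),
                  ceiling(seq_len(nrow(reg)) / (nrow(reg) / nb)))
  theta <- vapply(blocks, function(ix) {
    e <- estimate(reg[-ix, , drop = FALSE])
    e[["slope"]] * sum_gamma + sum(fixed_contrib)
  }, numeric(1))
  nb <- length(blocks)
  se_jk <- sqrt((nb - 1) / nb * sum((theta - mean(theta))^2))
  # sampling variance of the directly counted fixed-gene squares
  if (length(fixed_contrib)) {
    v_fixed <- sum(4 * st$alpha_hat[is_fixed]^2 * st$se[is_fixed]^2 +
                     2 * st$se[is_fixed]^4)
    se_jk <- sqrt(se_jk^2 + v_fixed)
  }
  structure(list(
    h2_obs = unname(h2),
    se = se_jk,
    ci95 = unname(h2) + c(-1, 1) * .zcrit * se_jk,
    p_value = 2 * stats::pnorm(-abs(h2 / se_jk)),
    slope = est[["slope"]], intercept = est[["intercept"]],
    mu_genomewide = est[["mu_gw"]],
    sum_gamma = sum_gamma,
    fixed_contrib = fixed_contrib,
    n_genes = nrow(reg), n_blocks = nb,
    options = list(fixed_genes = fixed_genes,
                   genomewide_correction = genomewide_correction)
  ), class = "bhr_fit")
}

#' @export
print.bhr_fit <- function(x, ...) {
  cat(sprintf("Burden heritability (observed scale): %.4g (SE %.3g, 95%% CI [%.4g, %.4g])\n",
              x$h2_obs, x$se, x$ci95[1], x$ci95[2]))
  cat(sprintf("  slope %.3g over %d gene-bins (sum gamma %.3g), %d fixed genes\n",
              x$slope, x$n_genes, x$sum_gamma, length(x$fixed_contrib)))
  invisible(x)
}

#' Observed-scale to liability-scale heritability conversion
#'
#' Under the liability-threshold model with population prevalence `K` and
#' sample (case) proportion `P`,
#' `h2_liab = h2_obs * K^2 (1-K)^2 / (z^2 P (1-P))` with `z` the standard
#' normal density at the `1-K` quantile. For a population sample
#' (`P = K`) this reduces to `h2_obs * K (1-K) / z^2`.
#'
#' @param h2_obs Observed-scale estimate (or a `bhr_fit`).
#' @param K Population prevalence, in (0, 1).
#' @param P Sample case proportion, in (0, 1); defaults to `K`.
#' @return Numeric liability-scale value; for a `bhr_fit` input, the fit
#'   with `h2_liab`, `se_liab`, `ci95_liab` added.
#' @export
liability_transform <- function(h2_obs, K, P = K) {
  if (!(K > 0 && K < 1) || !(P > 0 && P < 1))
    stop("prevalences must lie strictly inside (0, 1)")
  z <- stats::dnorm(stats::qnorm(1 - K))
  fac <- K^2 * (1 - K)^2 / (z^2 * P * (1 - P))
  if (inherits(h2_obs, "bhr_fit")) {
    fit <- h2_obs
    fit$h2_liab <- fit$h2_obs * fac
    fit$se_liab <- fit$se * fac
    fit$ci95_liab <- fit$ci95 * fac
    fit$prevalence <- c(K = K, P = P)
    return(fit)
  }
  h2_obs * fac
}

#' Partition bin heritability across gene sets
#'
#' Attributes to each fixed gene the fraction
#' `(alpha_hat^2 - se^2) / h2_obs` of the bin's heritability, and to each
#' gene set the sum over its members present in the fit. Genes not among
#' the fit's fixed genes are omitted with a notice.
#'
#' @param fit A `bhr_fit` produced with `fixed_genes`.
#' @param gene_sets Named list of character vectors.
#' @return Named numeric vector of set fractions, with per-gene fractions
#'   in attribute `per_gene`.
#' @export
partition_h2 <- function(fit, gene_sets) {
  stopifnot(inherits(fit, "bhr_fit"))
  per_gene <- fit$fixed_contrib / fit$h2_obs
  out <- vapply(gene_sets, function(gs) {
    missing <- setdiff(gs, names(per_gene))
    if (length(missing))
      message("partition_h2: omitting genes without fixed-effect ",
              "estimates: ", paste(missing, collapse = ", "))
    sum(per_gene[intersect(gs, names(per_gene))])
  }, numeric(1))
  attr(out, "per_gene") <- per_gene
  out
}

#' Simulate a gene-bin summary-statistic table with known heritability
#'
#' Generates `(gamma, alpha_hat, se)` per gene for one frequency x
#' annotation bin under the generative model behind the regression:
#' burden scores lognormal, a fraction of genes causal with per-allele
#' effect sized so the planted observed-scale heritability is exactly
#' `h2`, `alpha_hat = alpha + N(0, 1/n)`. Optionally one gene carries a
#' stated share of the planted heritability, for partition checks.
#'
#' @param n_genes Number of genes.
#' @param h2 Planted observed-scale burden heritability.
#' @param prop_causal Fraction of genes with nonzero effects.
#' @param n Effective sample size (`se = 1/sqrt(n)`).
#' @param concentrated_share Optional share of `h2` assigned to the first
#'   causal gene.
#' @param seed Integer seed.
#' @return Data frame `gene`, `gamma`, `alpha_hat`, `se` with attributes
#'   `causal_genes` and `concentrated_gene`.
#' @export
simulate_bhr_sumstats <- function(n_genes = 5000, h2 = 0.02,
                                  prop_causal = 0.05, n = 4e5,
                                  concentrated_share = 0, seed = 1L) {
  set.seed(as.integer(seed))
  gene <- sprintf("GENE%05d", seq_len(n_genes))
  gamma <- exp(stats::rnorm(n_genes, log(2e-4), 0.8))
  causal <- sort(sample.int(n_genes, max(1, round(prop_causal * n_genes))))
  alpha2 <- numeric(n_genes)
  conc_gene <- NA_character_
  h2_spread <- h2
  if (concentrated_share > 0) {
    conc <- causal[1]
    conc_gene <- gene[conc]
    alpha2[conc] <- h2 * concentrated_share
    h2_spread <- h2 * (1 - concentrated_share)
    causal <- causal[-1]
  }
  b2 <- h2_spread / sum(gamma[causal])
  alpha2[causal] <- b2 * gamma[causal]
  se <- 1 / sqrt(n)
  alpha_hat <- sqrt(alpha2) * sample(c(-1, 1), n_genes, replace = TRUE) +
    stats::rnorm(n_genes, 0, se)
  out <- data.frame(gene = gene, gamma = gamma, alpha_hat = alpha_hat,
                    se = se)
  attr(out, "causal_genes") <- gene[sort(c(causal,
    if (!is.na(conc_gene)) which(gene == conc_gene)))]
  attr(out, "concentrated_gene") <- conc_gene
  out
}
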