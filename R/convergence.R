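# Integration of gene-level rare-variant results with common-variant GWAS
# inputs: enrichment grids over significance/prioritization cutoffs,
# subset (search-space-narrowed) discovery, and the power-law model of
# effect size against allele frequency.

#' Fisher exact enrichment grid of RVAS genes among GWAS-nominated genes
#'
#' For every pair of an RVAS significance cutoff and a prioritization-score
#' cutoff, builds the 2x2 table of (gene significant in RVAS) x (gene
#' GWAS-nominated) over the shared autosomal gene universe and runs the
#' exact conditional test. A score cutoff of 0 means any gene within a
#' GWAS locus (`in_locus`); higher cutoffs require `geneprio_score >=`
#' the cutoff. The reported OR is the conditional maximum-likelihood
#' estimate with exact CI (the exact-test convention); the sample
#' cross-product OR is also returned.
#'
#' @param gene_results Data frame with `gene` and `p_final` (from
#'   [layered_gene_pvalue()]).
#' @param gwas_table Data frame with `gene`, logical `in_locus`, integer
#'   `geneprio_score`.
#' @param rvas_cutoffs Numeric vector of p-value thresholds.
#' @param geneprio_cutoffs Integer vector of score thresholds (0 = locus
#'   membership only).
#' @return Data frame grid: cutoffs, counts `a` (both), `b` (RVAS only),
#'   `c` (GWAS only), `d` (neither), `or` (conditional MLE), `or_sample`,
#'   `ci_lo`, `ci_hi`, `p_value`, `degenerate` flag.
#' @export
fisher_enrichment <- function(gene_results, gwas_table,
                              rvas_cutoffs = c(2.5e-6, 1e-5, 1e-4, 1e-3),
                              geneprio_cutoffs = 0:3) {
  universe <- merge(gene_results[, c("gene", "p_final")], gwas_table,
                    by = "gene")
  if (!nrow(universe)) stop("gene universes of the two tables do not overlap")
  if (any(universe$geneprio_score > 0 & !universe$in_locus))
    stop("geneprio_score > 0 requires in_locus")
  grid <- expand.grid(rvas_cutoff = rvas_cutoffs,
                      geneprio_cutoff = geneprio_cutoffs)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    rv <- universe$p_final < grid$rvas_cutoff[i]
    gw <- if (grid$geneprio_cutoff[i] == 0) universe$in_locus
          else universe$in_locus &
            universe$geneprio_score >= grid$geneprio_cutoff[i]
    a <- sum(rv & gw); b <- sum(rv & !gw)
    cc <- sum(!rv & gw); d <- sum(!rv & !gw)
    degenerate <- (a + b) == 0 || (a + cc) == 0 ||
      (b + d) == 0 || (cc + d) == 0
    if (degenerate) {
      return(data.frame(grid[i, ], a = a, b = b, c = cc, d = d,
                        or = NA_real_, or_sample = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_,
                        p_value = NA_real_, degenerate = TRUE))
    }
    ft <- stats::fisher.test(matrix(c(a, cc, b, d), 2))
    data.frame(grid[i, ], a = a, b = b, c = cc, d = d,
               or = unname(ft$estimate),
               or_sample = (a * d) / (b * cc),
               ci_lo = ft$conf.int[1], ci_hi = ft$conf.int[2],
               p_value = ft$p.value, degenerate = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Subset discovery at a Bonferroni threshold sized to the subset
#'
#' Narrows the rare-variant search space to a GWAS-nominated gene subset
#' and declares significance at `alpha = 0.05 / |subset|`, the more
#' lenient threshold justified by the smaller test count.
#'
#' @param gene_results Data frame with `gene` and `p_final`.
#' @param gene_subset Character vector of genes to test.
#' @return List with `alpha`, `n_subset`, and `significant` (data frame of
#'   subset genes below the threshold, ordered by p).
#' @export
subset_discovery <- function(gene_results, gene_subset) {
  if (!length(gene_subset)) stop("gene subset is empty")
  alpha <- 0.05 / length(gene_subset)
  d <- gene_results[gene_results$gene %in% gene_subset, , drop = FALSE]
  sig <- d[!is.na(d$p_final) & d$p_final < alpha, , drop = FALSE]
  list(alpha = alpha, n_subset = length(gene_subset),
       significant = sig[order(sig$p_final), , drop = FALSE])
}

#' Power-law fit of absolute effect size against allele frequency
#'
#' Fits the logarithmic power-law model
#' `log|beta| = a + b log(MAF)` by ordinary least squares across single
#' variants and burden masks, then refits with `|beta|` replaced by the
#' lower and upper 95% CI bounds to obtain the confidence band of the
#' frequency-effect relationship.
#'
#' @param effect_table Data frame with columns `maf` (minor or cumulative
#'   minor allele frequency), `abs_beta`, and optionally `ci_lo`, `ci_hi`
#'   (absolute-scale CI bounds of `abs_beta`).
#' @return List of class `powerlaw_fit`: `intercept`, `slope`, `fit` (the
#'   `lm` object), and `band_lower`/`band_upper` coefficient pairs when CI
#'   columns are present.
#' @export
fit_powerlaw <- function(effect_table) {
  et <- effect_table
  if (nrow(et) < 3) stop("need at least 3 rows to fit the power law")
  if (any(et$maf <= 0) || any(et$abs_beta <= 0))
    stop("maf and abs_beta must be positive")
  fit <- stats::lm(log(abs_beta) ~ log(maf), data = et)
  out <- list(intercept = unname(stats::coef(fit)[1]),
              slope = unname(stats::coef(fit)[2]),
              fit = fit)
  for (side in c("lower", "upper")) {
    col <- if (side == "lower") "ci_lo" else "ci_hi"
    if (!is.null(et[[col]])) {
      if (any(et[[col]] <= 0))
        stop("CI bounds must be positive for the log-scale band fit")
      bf <- stats::lm(log(et[[col]]) ~ log(et$maf))
      out[[paste0("band_", side)]] <- c(intercept = unname(stats::coef(bf)[1]),
                                        slope = unname(stats::coef(bf)[2]))
    }
  }
  class(out) <- "powerlaw_fit"
  out
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("Power-law fit: log|beta| =", format(x$intercept, digits = 4), "+",
      format(x$slope, digits = 4), "* log(MAF)\n")
  invisible(x)
}
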