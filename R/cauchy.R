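# Layered Cauchy (ACAT) combination of mask p-values into gene-level
# statistics. The Cauchy combination is valid under arbitrary dependence
# between the combined p-values, which is what makes it usable over the
# heavily overlapping mask grid (tiers are nested and annotation groups
# share variants).

#' Cauchy (ACAT) combination of p-values
#'
#' Computes `T = sum(w_i tan((0.5 - p_i) pi)) / sum(w_i)` and returns
#' `0.5 - atan(T)/pi`. Terms with `p_i < 1e-15` are replaced by the
#' asymptotically equivalent `1/(p_i pi)` for numerical stability, and
#' `p_i = 1` is clipped to `1 - 1e-15` to avoid the tangent singularity
#' (penalized-likelihood-ratio tests can return exactly 1 on degenerate
#' data). With a single p-value the transform is the identity.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param weights Optional non-negative weights (equal by default).
#' @return Combined p-value.
#' @export
#' @examples
#' cauchy_combine(c(0.01, 0.2, 0.9))
cauchy_combine <- function(p, weights = NULL) {
  if (!length(p)) stop("empty p-value list")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  if (is.null(weights)) weights <- rep(1, length(p))
  if (length(weights) != length(p) || any(weights < 0))
    stop("weights must be non-negative and match p in length")
  p <- pmin(p, 1 - 1e-15)
  # tan((0.5 - p) pi) computed as cot(p pi) = 1/tanpi(p): accurate for
  # small p, where the direct form loses ~6 digits to cancellation
  # (tanpi(0.5) is NaN by definition; that term is exactly 0)
  term <- numeric(length(p))
  tiny <- p < 1e-15
  rest <- !tiny & p != 0.5
  term[tiny] <- 1 / (p[tiny] * pi)
  term[rest] <- 1 / tanpi(p[rest])
  t_stat <- sum(weights * term) / sum(weights)
  # 0.5 - atan(T)/pi, with the tail branches through atan(1/T) to avoid
  # cancellation near the +/- pi/2 asymptotes
  out <- if (!is.finite(t_stat)) {
    if (t_stat > 0) .PMIN else 1
  } else if (t_stat > 1) {
    atan(1 / t_stat) / pi
  } else if (t_stat < -1) {
    1 - atan(-1 / t_stat) / pi
  } else 0.5 - atan(t_stat) / pi
  min(max(out, .PMIN), 1)
}

# layer of an annotation group: masks of PTV-only groups, missense-only
# groups, or PTV+missense unions are combined within their own layer first
.mask_layer <- function(annotation_group) {
  ifelse(grepl("+", annotation_group, fixed = TRUE), "PTV+missense",
         ifelse(annotation_group %in% .PTV_GROUPS, "PTV", "missense"))
}

.gene_from_masks <- function(d, p_col) {
  layers <- split(d[[p_col]], .mask_layer(d$annotation_group))
  layer_p <- vapply(layers, cauchy_combine, numeric(1))
  p_final <- cauchy_combine(layer_p)
  pm <- d[[p_col]]
  ord <- order(pm, -d$cmac_total, d$annotation_group, d$freq_tier)
  best <- d[ord[1], , drop = FALSE]
  out <- data.frame(
    gene = d$gene[1], stratum = d$stratum[1],
    p_missense = if ("missense" %in% names(layer_p))
      layer_p[["missense"]] else NA_real_,
    p_ptv = if ("PTV" %in% names(layer_p)) layer_p[["PTV"]] else NA_real_,
    p_ptv_miss = if ("PTV+missense" %in% names(layer_p))
      layer_p[["PTV+missense"]] else NA_real_,
    p_final = p_final,
    n_masks = nrow(d),
    best_mask = paste0(best$annotation_group, "_", best$freq_tier),
    best_p = best[[p_col]],
    best_beta = best$beta_meta,
    best_or = exp(best$beta_meta),
    best_ci_lo = exp(best$beta_meta - .zcrit * best$se_meta),
    best_ci_hi = exp(best$beta_meta + .zcrit * best$se_meta),
    best_cmac = best$cmac_total,
    stringsAsFactors = FALSE)
  out
}

#' Layered gene-level Cauchy p-values from meta-analyzed mask results
#'
#' Masks of each gene (and sex stratum, for chromosome-X genes) are
#' partitioned into three layers by annotation group -- missense-only,
#' PTV-only, and PTV+missense unions -- and combined by [cauchy_combine()]
#' within layer; the 1-3 layer p-values are then combined in a second
#' layer into the gene's final p-value. Layers with no surviving masks are
#' dropped, not imputed. The best mask is the minimum-p mask
#' (saddlepoint-adjusted p where available), ties broken by larger
#' aggregate cMAC then mask name.
#'
#' @param meta Data frame of (typically filtered) [meta_analyze()] output.
#' @param n_tests Number of gene-stratum tests used for the Bonferroni
#'   exome-wide significance flag; defaults to the number of gene-stratum
#'   combinations in `meta`.
#' @return Data frame with one row per gene-stratum: layer p-values,
#'   `p_final`, best-mask statistics, and `significant` at
#'   `alpha = 0.05/n_tests`.
#' @export
layered_gene_pvalue <- function(meta, n_tests = NULL) {
  if (!nrow(meta)) return(.empty_gene())
  p_col <- if ("p_spa" %in% names(meta)) "p_eff" else "p_ivw"
  if (p_col == "p_eff") meta$p_eff <- ifelse(is.na(meta$p_spa),
                                             meta$p_ivw, meta$p_spa)
  key <- interaction(meta$gene, meta$stratum, drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(split(meta, key), .gene_from_masks,
                               p_col = p_col))
  rownames(out) <- NULL
  if (is.null(n_tests)) n_tests <- nrow(out)
  out$alpha <- 0.05 / n_tests
  out$significant <- out$p_final < out$alpha
  out[order(out$p_final), ]
}

.empty_gene <- function() {
  data.frame(gene = character(0), stratum = character(0),
             p_missense = numeric(0), p_ptv = numeric(0),
             p_ptv_miss = numeric(0), p_final = numeric(0),
             n_masks = integer(0), best_mask = character(0),
             best_p = numeric(0), best_beta = numeric(0),
             best_or = numeric(0), best_ci_lo = numeric(0),
             best_ci_hi = numeric(0), best_cmac = numeric(0))
}

#' Genomic inflation factor at the 90th percentile
#'
#' Transforms p-values to upper-tail chi-square(1 df) statistics and
#' returns the ratio of their 90th percentile to the 90th percentile of
#' the chi-square(1) distribution (about 2.70554). Values near 1 indicate
#' calibrated tests; the 90th percentile (rather than the median) makes
#' the diagnostic sensitive to the tail relevant for discovery.
#'
#' @param p Numeric vector of at least 100 p-values.
#' @return The inflation factor (scalar).
#' @export
lambda90 <- function(p) {
  if (length(p) < 100)
    stop("lambda90 needs at least 100 p-values")
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  as.numeric(stats::quantile(chi, 0.9, type = 7) /
               stats::qchisq(0.9, df = 1))
}

#' Sensitivity re-combination over a restricted mask set
#'
#' Applies the identical layering logic of [layered_gene_pvalue()] after
#' restricting the mask results to chosen frequency tiers and/or layers
#' (rare-only, PTV-only, missense-only, and similar sensitivity analyses).
#' Genes left with no masks under the restriction are omitted (untestable
#' under the restriction).
#'
#' @param meta Data frame of [meta_analyze()] output.
#' @param freq_tiers Frequency tiers to keep (subset of
#'   `names(mask_freq_tiers())`).
#' @param layers Layers to keep (subset of
#'   `c("missense", "PTV", "PTV+missense")`).
#' @param n_tests Bonferroni denominator passed through.
#' @return As [layered_gene_pvalue()], for the restricted set.
#' @export
sensitivity_recombine <- function(meta,
                                  freq_tiers = names(mask_freq_tiers()),
                                  layers = c("missense", "PTV",
                                             "PTV+missense"),
                                  n_tests = NULL) {
  if (!length(freq_tiers) || !length(layers))
    stop("subset specification must be nonempty")
  keep <- meta$freq_tier %in% freq_tiers &
    .mask_layer(meta$annotation_group) %in% layers
  layered_gene_pvalue(meta[keep, , drop = FALSE], n_tests = n_tests)
}
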