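# Fixed-effects meta-analysis and the genotype-count saddlepoint
# adjustment.
#
# Even with Firth correction within each study, normal-theory
# meta-analysis p-values for rare burdens become anti-conservative when
# carrier counts are low and case:control ratios are unbalanced. The
# adjustment models the meta score under the null as a weighted sum of
# centered binomial counts -- each of a study's cMAC carrier alleles falls
# in a case independently with probability equal to the study case
# fraction -- and evaluates the tail by saddlepoint approximation
# (Lugannani-Rice), with weights chosen so the normal approximation of
# the saddlepoint statistic reproduces the IVW Z exactly. The adjustment
# is therefore a pure tail correction.

#' Inverse-variance-weighted fixed-effects meta-analysis of one mask
#'
#' Combines per-study burden association results with weights
#' `w_s = 1/SE_s^2`: `beta_meta = sum(w beta)/sum(w)`,
#' `SE_meta = 1/sqrt(sum(w))`, two-sided normal p from
#' `Z = beta_meta/SE_meta`, and Cochran heterogeneity
#' `Q = sum(w (beta - beta_meta)^2)` on `n_studies - 1` df (undefined for
#' a single study).
#'
#' @param results Data frame of per-study results for one mask, with
#'   columns `beta`, `se`, `cmac`, `n_cases`, `n_referents` (and
#'   optionally `study_id`).
#' @return One-row data frame: `beta_meta`, `se_meta`, `p_ivw`, `q_stat`,
#'   `q_df`, `q_p`, `n_studies`, `cmac_total`, plus a `per_study` list
#'   column holding `(study_id, cmac, phi, weight)` for the saddlepoint
#'   adjustment.
#' @export
ivw_meta <- function(results) {
  if (nrow(results) < 1) stop("need at least one study result")
  if (any(!is.finite(results$se)) || any(results$se <= 0))
    stop("all standard errors must be finite and positive")
  w <- 1 / results$se^2
  beta <- sum(w * results$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- beta / se
  p <- max(2 * stats::pnorm(-abs(z)), .PMIN)
  k <- nrow(results)
  q <- if (k > 1) sum(w * (results$beta - beta)^2) else NA_real_
  qp <- if (k > 1) stats::pchisq(q, df = k - 1, lower.tail = FALSE)
        else NA_real_
  per <- data.frame(
    study_id = if (!is.null(results$study_id)) results$study_id
               else paste0("study", seq_len(k)),
    cmac = results$cmac,
    phi = results$n_cases / (results$n_cases + results$n_referents),
    weight = w / sum(w))
  out <- data.frame(beta_meta = beta, se_meta = se, p_ivw = p,
                    q_stat = q, q_df = if (k > 1) k - 1L else NA_integer_,
                    q_p = qp, n_studies = k,
                    cmac_total = sum(results$cmac))
  out$per_study <- list(per)
  out
}

# CGF of T = sum_s lambda_s (X_s - cmac_s phi_s), X_s ~ Bin(cmac_s, phi_s),
# and its first two derivatives. Vectorized over t.
.spa_cgf <- function(t, cmac, phi, lambda, deriv = 0) {
  E <- exp(outer(t, lambda))                     # |t| x S
  denom <- sweep(E, 2, phi, `*`)
  denom <- sweep(denom, 2, 1 - phi, `+`)         # 1 - phi + phi e^{l t}
  if (deriv == 0) {
    drop(log(denom) %*% cmac) - t * sum(lambda * cmac * phi)
  } else if (deriv == 1) {
    num <- sweep(E, 2, phi * lambda, `*`)
    drop((num / denom) %*% cmac) - sum(lambda * cmac * phi)
  } else {
    num <- sweep(E, 2, phi * lambda^2, `*`)
    ratio <- num / denom
    extra <- sweep(E, 2, phi, `*`) / denom
    drop((ratio * (1 - extra)) %*% cmac)
  }
}

# K' and K'' from one shared exponential evaluation (the solver's inner
# loop cost is dominated by these)
.spa_cgf12 <- function(t, cmac, phi, lambda) {
  E <- exp(outer(t, lambda))
  pe <- sweep(E, 2, phi, `*`)
  denom <- sweep(pe, 2, 1 - phi, `+`)
  r <- pe / denom
  k1 <- drop(sweep(r, 2, lambda, `*`) %*% cmac) -
    sum(lambda * cmac * phi)
  k2 <- drop(sweep(r * (1 - r), 2, lambda^2, `*`) %*% cmac)
  list(k1 = k1, k2 = k2)
}

#' Saddlepoint-adjusted meta-analysis p-value from genotype counts
#'
#' Evaluates the two-sided tail probability of the meta-analysis Z score
#' under the count-based null: each study contributes a centered
#' `Binomial(cmac_s, phi_s)` case-allele count, weighted so the combined
#' score has unit variance and matches Z under the normal approximation.
#' Tails are computed by the Lugannani-Rice saddlepoint formula with the
#' Daniels lattice continuity correction (the score is a sum of weighted
#' binomial lattices; the variance-weighted mean lattice span is used, so
#' the single-study case reduces to the exact lattice formula and the
#' large-count limit to the continuous one), reported in the mid-p
#' convention -- the average of the inclusive tails one lattice span
#' apart -- which keeps the adjusted p-values calibrated on the discrete
#' support and agreeing with the normal p in the symmetric large-count
#' limit. When per-study lattice spans are strongly heterogeneous (one
#' study's per-allele step much coarser than the rest, as for a tiny
#' study among large ones), the coarsest studies' counts are enumerated
#' exactly and the saddlepoint is applied to the remainder, conditioning
#' on each enumerated configuration. When the saddlepoint is within
#' `1e-6` of the origin the normal tail is used (the two agree there),
#' and tails are floored at the boundary atoms of the discrete support.
#'
#' @param z IVW meta-analysis Z score(s); vectorized.
#' @param cmac Per-study cumulative minor allele counts.
#' @param phi Per-study case fractions.
#' @param weights Optional per-study IVW weights (normalized internally);
#'   equal weights by default.
#' @param alternative `"two.sided"` (default): `P(T >= |t|) + P(T <= -|t|)`;
#'   `"greater"` / `"less"`: the corresponding one-sided mid-p tail (as
#'   used for one-sided replication tests).
#' @return p-value(s) under the requested alternative, with mid-p tails.
#' @export
spa_pvalue <- function(z, cmac, phi, weights = NULL,
                       alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(cmac) == length(phi), all(cmac > 0),
            all(phi > 0 & phi < 1))
  if (is.null(weights)) weights <- rep(1, length(cmac))
  zeta <- weights / sum(weights)
  lambda <- zeta / sqrt(cmac * phi * (1 - phi))
  sdT <- sqrt(sum(lambda^2 * cmac * phi * (1 - phi)))  # = sqrt(sum zeta^2)
  t_obs <- z * sdT

  # split off studies whose lattice span dwarfs the remainder's: their
  # counts are enumerated exactly (they carry the discreteness the
  # smooth approximation cannot follow), the rest stays on the SPA
  en <- integer(0)
  keep <- seq_along(cmac)
  budget <- 256
  while (length(keep) > 1) {
    s <- keep[which.max(lambda[keep])]
    rest <- setdiff(keep, s)
    varc_r <- lambda[rest]^2 * cmac[rest] * phi[rest] * (1 - phi[rest])
    delta_r <- sum(lambda[rest] * varc_r) / sum(varc_r)
    if (lambda[s] <= 2 * delta_r) break
    if (budget %/% (cmac[s] + 1) < 1) break
    budget <- budget %/% (cmac[s] + 1)
    en <- c(en, s); keep <- rest
  }

  # two-sided p = P(T >= |t|) + P(T <= -|t|), each tail in the mid-p
  # convention; the symmetric tail sum stays calibrated on skewed
  # discrete supports, where doubling the minimum tail is conservative
  # because the short tail is bounded away from 0 by its boundary atom
  if (alternative == "greater") {
    p <- .spa_compound_tail(t_obs, cmac, phi, lambda, en, keep, "upper")
  } else if (alternative == "less") {
    p <- .spa_compound_tail(t_obs, cmac, phi, lambda, en, keep, "lower")
  } else {
    t_abs <- abs(t_obs)
    p <- .spa_compound_tail(t_abs, cmac, phi, lambda, en, keep, "upper") +
      .spa_compound_tail(-t_abs, cmac, phi, lambda, en, keep, "lower")
    p[t_abs == 0] <- 1
  }
  pmin(pmax(p, .PMIN), 1)
}

# Mid-p tail of the compound score: exact enumeration over the counts of
# studies `en`, mid-p saddlepoint over the remaining studies `keep`.
.spa_compound_tail <- function(t, cmac, phi, lambda, en, keep, side) {
  if (!length(en)) return(.spa_mid_tail(t, cmac, phi, lambda, side))
  combos <- expand.grid(lapply(en, function(s) 0:cmac[s]))
  offs <- as.matrix(combos) %*% lambda[en] -
    sum(lambda[en] * cmac[en] * phi[en])
  prs <- rep(1, nrow(combos))
  for (j in seq_along(en))
    prs <- prs * stats::dbinom(combos[[j]], cmac[en[j]], phi[en[j]])
  out <- 0
  for (k in seq_len(nrow(combos)))
    out <- out + prs[k] * .spa_mid_tail(t - offs[k], cmac[keep],
                                        phi[keep], lambda[keep], side)
  out
}

# Mid-p tail of one weighted-binomial sum: average of the inclusive
# Daniels tails one mean lattice span apart.
.spa_mid_tail <- function(t, cmac, phi, lambda, side) {
  t_max <- sum(lambda * cmac * (1 - phi))
  t_min <- -sum(lambda * cmac * phi)
  varc <- lambda^2 * cmac * phi * (1 - phi)
  delta <- sum(lambda * varc) / sum(varc)
  if (side == "upper") {
    (.spa_tails_incl(t, cmac, phi, lambda, delta, t_min, t_max)$upper +
     .spa_tails_incl(t + delta, cmac, phi, lambda, delta,
                     t_min, t_max)$upper) / 2
  } else {
    (.spa_tails_incl(t, cmac, phi, lambda, delta, t_min, t_max)$lower +
     .spa_tails_incl(t - delta, cmac, phi, lambda, delta,
                     t_min, t_max)$lower) / 2
  }
}

# Inclusive upper/lower tails of one weighted-binomial score by the
# Lugannani-Rice formula with the Daniels lattice continuity correction.
# Falls back to the normal tail near the origin and where the correction
# degenerates (observations clamped to the support boundary).
.spa_tails_incl <- function(t_obs, cmac, phi, lambda, delta,
                            t_min, t_max) {
  z <- t_obs / sqrt(sum(lambda^2 * cmac * phi * (1 - phi)))
  eps <- 1e-9 * (t_max - t_min)
  below <- t_obs < t_min - eps   # strictly outside the support
  above <- t_obs > t_max + eps
  at_bottom <- !below & t_obs <= t_min + eps   # exactly the boundary atom
  at_top <- !above & t_obs >= t_max - eps
  t_obs <- pmin(pmax(t_obs, t_min + eps), t_max - eps)

  # solve K'(that) = t_obs: K' is strictly increasing and maps R onto
  # (t_min, t_max), so a bracketed Newton/bisection hybrid always
  # converges; iterate only the not-yet-converged subset
  lo <- rep(-1, length(t_obs)); hi <- rep(1, length(t_obs))
  bad <- which(.spa_cgf(lo, cmac, phi, lambda, deriv = 1) > t_obs)
  for (it in 1:60) {
    if (!length(bad)) break
    lo[bad] <- lo[bad] * 2
    bad <- bad[.spa_cgf(lo[bad], cmac, phi, lambda, deriv = 1) >
                 t_obs[bad]]
  }
  bad <- which(.spa_cgf(hi, cmac, phi, lambda, deriv = 1) < t_obs)
  for (it in 1:60) {
    if (!length(bad)) break
    hi[bad] <- hi[bad] * 2
    bad <- bad[.spa_cgf(hi[bad], cmac, phi, lambda, deriv = 1) <
                 t_obs[bad]]
  }
  that <- (lo + hi) / 2
  act <- seq_along(t_obs)
  gtol <- 1e-12 * max(1, max(abs(t_obs)))
  for (it in 1:80) {
    kk <- .spa_cgf12(that[act], cmac, phi, lambda)
    g <- kk$k1 - t_obs[act]
    neg <- act[g < 0]; pos <- act[g > 0]
    lo[neg] <- that[neg]; hi[pos] <- that[pos]
    live <- abs(g) >= gtol
    if (!any(live)) break
    cand <- that[act][live] - g[live] / kk$k2[live]
    act <- act[live]
    outside <- !is.finite(cand) | cand <= lo[act] | cand >= hi[act]
    cand[outside] <- (lo[act][outside] + hi[act][outside]) / 2
    that[act] <- cand
  }
  K <- .spa_cgf(that, cmac, phi, lambda, deriv = 0)
  k2 <- .spa_cgf(that, cmac, phi, lambda, deriv = 2)
  w <- sign(that) * sqrt(pmax(2 * (that * t_obs - K), 0))
  sk2 <- sqrt(k2)
  v_up <- -expm1(-delta * that) / delta * sk2   # (1 - e^{-d that})/d
  v_lo <- -expm1(delta * that) / delta * sk2    # mirrored: (1 - e^{d that})/d
  upper <- stats::pnorm(w, lower.tail = FALSE) -
    stats::dnorm(w) * (1 / w - 1 / v_up)
  lower <- stats::pnorm(-w, lower.tail = FALSE) -
    stats::dnorm(w) * (-1 / w - 1 / v_lo)
  bad_u <- abs(that) < 1e-6 | !is.finite(upper) | upper <= 0 | upper >= 1
  bad_l <- abs(that) < 1e-6 | !is.finite(lower) | lower <= 0 | lower >= 1
  upper[bad_u] <- stats::pnorm(z[bad_u], lower.tail = FALSE)
  lower[bad_l] <- stats::pnorm(z[bad_l])
  # floor each tail at the boundary atom of the discrete support
  # (all carrier alleles in referents, resp. all in cases); outside the
  # support the tails are exactly 0 or 1
  p_bottom <- exp(sum(cmac * log1p(-phi)))
  p_top <- exp(sum(cmac * log(phi)))
  upper <- pmin(pmax(upper, p_top), 1)
  lower <- pmin(pmax(lower, p_bottom), 1)
  upper[at_top] <- p_top; lower[at_top] <- 1
  lower[at_bottom] <- p_bottom; upper[at_bottom] <- 1
  upper[below] <- 1; lower[below] <- 0
  upper[above] <- 0; lower[above] <- 1
  list(upper = upper, lower = lower)
}

#' Apply the saddlepoint adjustment to a meta-analysis result table
#'
#' Adds a `p_spa` column to [ivw_meta()] output rows whose `p_ivw` falls
#' below `alpha` (the adjustment is a tail correction and is only applied
#' to nominally significant masks). Rows where root finding fails keep
#' `p_spa = NA` and are flagged in `spa_failed`.
#'
#' @param meta Data frame from [meta_analyze()]/[ivw_meta()] with a
#'   `per_study` list column.
#' @param alpha Nominal threshold for applying the adjustment.
#' @return `meta` with `p_spa` (and `spa_failed`) columns.
#' @export
spa_adjust <- function(meta, alpha = 0.05) {
  meta$p_spa <- NA_real_
  meta$spa_failed <- FALSE
  todo <- which(meta$p_ivw < alpha)
  for (i in todo) {
    per <- meta$per_study[[i]]
    z <- meta$beta_meta[i] / meta$se_meta[i]
    p <- tryCatch(
      spa_pvalue(z, per$cmac, per$phi, per$weight),
      error = function(e) NA_real_)
    if (is.na(p)) {
      meta$p_spa[i] <- meta$p_ivw[i]
      meta$spa_failed[i] <- TRUE
    } else meta$p_spa[i] <- p
  }
  meta
}

#' Meta-analyze a table of per-study burden results
#'
#' Groups association results by mask key (gene, annotation group,
#' frequency tier, stratum), runs [ivw_meta()] per mask, and optionally
#' applies the saddlepoint adjustment.
#'
#' @param assoc Data frame of [run_study_scan()] results pooled across
#'   studies.
#' @param spa Apply [spa_adjust()] to nominally significant masks.
#' @param alpha_spa Nominal threshold for the adjustment.
#' @return Data frame with one row per mask.
#' @export
meta_analyze <- function(assoc, spa = TRUE, alpha_spa = 0.05) {
  if (!nrow(assoc)) return(.empty_meta())
  if (any(!is.finite(assoc$se)) || any(assoc$se <= 0))
    stop("all standard errors must be finite and positive")
  key <- factor(paste(assoc$gene, assoc$annotation_group, assoc$freq_tier,
                      assoc$stratum, sep = "\r"))
  # grouped closed forms (identical to ivw_meta, vectorized over masks)
  w <- 1 / assoc$se^2
  sw <- rowsum(w, key)
  swb <- rowsum(w * assoc$beta, key)
  swb2 <- rowsum(w * assoc$beta^2, key)
  k <- as.vector(rowsum(rep(1L, nrow(assoc)), key))
  beta_meta <- as.vector(swb / sw)
  se_meta <- as.vector(1 / sqrt(sw))
  z <- beta_meta / se_meta
  q <- pmax(as.vector(swb2) - beta_meta^2 * as.vector(sw), 0)
  first <- !duplicated(key)
  ord <- match(levels(key), key[first])
  out <- data.frame(
    gene = assoc$gene[first][ord],
    annotation_group = assoc$annotation_group[first][ord],
    freq_tier = assoc$freq_tier[first][ord],
    stratum = assoc$stratum[first][ord],
    beta_meta = beta_meta, se_meta = se_meta,
    p_ivw = pmax(2 * stats::pnorm(-abs(z)), .PMIN),
    q_stat = ifelse(k > 1, q, NA_real_),
    q_df = ifelse(k > 1, k - 1L, NA_integer_),
    q_p = ifelse(k > 1, stats::pchisq(q, df = pmax(k - 1, 1),
                                      lower.tail = FALSE), NA_real_),
    n_studies = k,
    cmac_total = as.vector(rowsum(assoc$cmac, key)),
    stringsAsFactors = FALSE)
  idx_by_key <- split(seq_len(nrow(assoc)), key)
  out$per_study <- lapply(idx_by_key, function(ix)
    data.frame(study_id = assoc$study_id[ix],
               cmac = assoc$cmac[ix],
               phi = assoc$n_cases[ix] /
                 (assoc$n_cases[ix] + assoc$n_referents[ix]),
               weight = w[ix] / sum(w[ix])))
  rownames(out) <- NULL
  if (spa) out <- spa_adjust(out, alpha_spa)
  out
}

#' Post-meta-analysis count filters
#'
#' Keeps masks with aggregate cMAC of at least `cmac_min` and
#' contributions from at least `min_studies` datasets, dropping results
#' that could be driven by very low counts or by a single dataset.
#'
#' @param meta Data frame from [meta_analyze()].
#' @param cmac_min Minimum aggregate cMAC (default 20).
#' @param min_studies Minimum number of contributing studies (default 2).
#' @return Filtered data frame.
#' @export
meta_filter <- function(meta, cmac_min = 20, min_studies = 2) {
  if (!nrow(meta)) return(meta)
  meta[meta$cmac_total >= cmac_min & meta$n_studies >= min_studies, ,
       drop = FALSE]
}

.empty_meta <- function() {
  data.frame(gene = character(0), annotation_group = character(0),
             freq_tier = character(0), stratum = character(0),
             beta_meta = numeric(0), se_meta = numeric(0),
             p_ivw = numeric(0), q_stat = numeric(0), q_df = integer(0),
             q_p = numeric(0), n_studies = integer(0),
             cmac_total = numeric(0))
}
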