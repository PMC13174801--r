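# Exome-wide per-study burden scan.
#
# The scan uses the approximate-Firth factorization: one ordinary-ML
# covariate-only null fit per stratum supplies a fixed linear-predictor
# offset, after which every mask needs only a two-parameter
# (intercept + burden) Firth fit with a binary burden predictor. For that
# special case the information matrix, hat values and Jeffreys penalty
# have closed forms in three scalar sums, so each fit is a handful of
# vectorized Newton iterations.

.softplus <- function(eta) pmax(eta, 0) + log1p(exp(-abs(eta)))

# Two-parameter Firth fit (intercept a, burden b) with offset, x = carrier
# indicator given by index set. Returns estimate and penalized loglik.
.firth_fit_burden <- function(y, carrier_idx, offset,
                              max_iter = 50, tol = 1e-8) {
  n <- length(y)
  yc_sum <- sum(y[carrier_idx])
  nc <- length(carrier_idx)
  a <- 0; b <- 0
  pll_ab <- function(a, b) {
    eta <- offset + a
    eta[carrier_idx] <- eta[carrier_idx] + b
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    S1 <- sum(w); Sx <- sum(w[carrier_idx])
    det <- Sx * (S1 - Sx)
    ll <- sum(y * eta - .softplus(eta))
    list(value = if (det > 0) ll + 0.5 * log(det) else -Inf,
         mu = mu, w = w, S1 = S1, Sx = Sx, det = det)
  }
  cur <- pll_ab(a, b)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (cur$det <= 0) break
    S0 <- cur$S1 - cur$Sx           # non-carrier weight sum
    h <- cur$w / S0                 # hat values, non-carriers
    h[carrier_idx] <- cur$w[carrier_idx] / cur$Sx
    adj <- y - cur$mu + h * (0.5 - cur$mu)
    U1 <- sum(adj); U2 <- sum(adj[carrier_idx])
    # solve [[S1,Sx],[Sx,Sx]] step = U
    step_b <- (U2 * cur$S1 - U1 * cur$Sx) / cur$det
    step_a <- (U1 - cur$Sx * step_b) / cur$S1
    lam <- 1
    repeat {
      na <- a + lam * step_a; nb <- b + lam * step_b
      new <- pll_ab(na, nb)
      if (is.finite(new$value) && new$value >= cur$value - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { na <- a; nb <- b; new <- cur; break }
    }
    moved <- max(abs(c(na - a, nb - b)))
    a <- na; b <- nb; cur <- new
    if (moved < tol) { converged <- TRUE; break }
  }
  var_beta <- if (cur$det > 0) cur$S1 / cur$det else NA_real_
  list(intercept = a, beta = b, pll = cur$value, converged = converged,
       var_beta = var_beta)
}

# Intercept-only Firth fit with offset (used to center the score-test
# residuals for a stratum).
.firth_fit_null <- function(y, offset, max_iter = 50, tol = 1e-8) {
  a <- 0
  pll_a <- function(a) {
    eta <- offset + a
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    S1 <- sum(w)
    list(value = sum(y * eta - .softplus(eta)) + 0.5 * log(S1),
         mu = mu, w = w, S1 = S1)
  }
  cur <- pll_a(a)
  for (it in seq_len(max_iter)) {
    adj <- y - cur$mu + (cur$w / cur$S1) * (0.5 - cur$mu)
    step <- sum(adj) / cur$S1
    lam <- 1
    repeat {
      na <- a + lam * step
      new <- pll_a(na)
      if (is.finite(new$value) && new$value >= cur$value - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { na <- a; new <- cur; break }
    }
    moved <- abs(na - a); a <- na; cur <- new
    if (moved < tol) break
  }
  list(intercept = a, pll = cur$value)
}

# Restricted fit for the penalized LRT of one mask: burden coefficient
# fixed at 0 but kept in the Jeffreys penalty (full 2x2 information
# determinant), the logistf convention. Maximizes over the intercept.
.firth_fit_burden0 <- function(y, carrier_idx, offset,
                               max_iter = 50, tol = 1e-8) {
  a <- 0
  pll_a <- function(a) {
    eta <- offset + a
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    S1 <- sum(w); Sx <- sum(w[carrier_idx])
    det <- Sx * (S1 - Sx)
    list(value = if (det > 0)
      sum(y * eta - .softplus(eta)) + 0.5 * log(det) else -Inf,
      mu = mu, w = w, S1 = S1, Sx = Sx)
  }
  cur <- pll_a(a)
  for (it in seq_len(max_iter)) {
    S0 <- cur$S1 - cur$Sx
    h <- cur$w / S0
    h[carrier_idx] <- cur$w[carrier_idx] / cur$Sx
    adj <- y - cur$mu + h * (0.5 - cur$mu)
    step <- sum(adj) / cur$S1
    lam <- 1
    repeat {
      na <- a + lam * step
      new <- pll_a(na)
      if (is.finite(new$value) && new$value >= cur$value - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { na <- a; new <- cur; break }
    }
    moved <- abs(na - a); a <- na; cur <- new
    if (moved < tol) break
  }
  list(intercept = a, pll = cur$value)
}

.zcrit <- 1.959963984540054

# Smallest p reported: keeps downstream log/tangent transforms finite.
.PMIN <- 1e-300

#' Run the burden scan of one study across a set of masks
#'
#' Fits a Firth-corrected logistic burden test for every mask with at
#' least one carrier, adjusting for the study covariates (at minimum age,
#' sex and ancestry PCs), and applies the per-study post-test count
#' filter. Autosomal masks are tested in the combined sample; masks of
#' chromosome-X genes are tested in males and females separately.
#'
#' @param study A `study_dataset` from [simulate_cohort()] or assembled
#'   from [read_genotypes()] inputs.
#' @param masks Mask table from [enumerate_masks()]; by default enumerated
#'   from the study's variant table (so frequency tiers use the study's
#'   in-sample frequencies together with any reference frequencies).
#' @param covariates Character vector of covariate column names in
#'   `study$covariates`.
#' @param mode `"approximate"` (offset factorization, the scan default) or
#'   `"exact"` (joint Firth over all coefficients; for small problems).
#' @param cmac_min Post-test filter: drop results with mask cMAC below
#'   this (5 for well-balanced studies, 10 otherwise).
#' @param carrier_min Optional additional minimum carrier count (some
#'   cohorts require carrier count >= 20).
#' @param coding Burden coding, `"carrier"` or `"sum"`.
#' @param firth_p_threshold In approximate mode, masks are first evaluated
#'   with the covariate-adjusted score test (one-step beta `U/V`,
#'   `se = 1/sqrt(V)`); the Firth refit with penalized-LRT p and
#'   back-corrected SE is applied to masks whose score p falls below this
#'   threshold. This score-then-Firth fallback is the standard behavior of
#'   the whole-exome burden-testing tool family; set to 1 to force the
#'   Firth fit on every mask.
#' @return Data frame of association results, one row per surviving mask
#'   (and per sex stratum for chromosome-X masks): mask key columns,
#'   `stratum`, `beta`, `se`, `p`, `or`, `ci_lo`, `ci_hi`, `cmac`,
#'   `n_carriers`, `n_cases`, `n_referents`, `converged`.
#' @export
run_study_scan <- function(study, masks = NULL,
                           covariates = NULL,
                           mode = c("approximate", "exact"),
                           cmac_min = 10, carrier_min = 0,
                           coding = c("carrier", "sum"),
                           firth_p_threshold = 0.05) {
  mode <- match.arg(mode)
  coding <- match.arg(coding)
  stopifnot(inherits(study, "study_dataset"))
  if (is.null(study$phenotype)) stop("study has no phenotype column")
  vt <- study$variant_table
  if (is.null(masks)) masks <- enumerate_masks(vt)
  if (!nrow(masks)) return(.empty_scan())
  if (is.null(covariates)) {
    cand <- c("age", "sex", grep("^PC", names(study$covariates), value = TRUE))
    covariates <- intersect(cand, names(study$covariates))
  }
  y_all <- as.numeric(study$phenotype)
  G <- study$genotypes
  n <- nrow(G)
  C_all <- if (length(covariates))
    as.matrix(study$covariates[, covariates, drop = FALSE]) else NULL

  gene_chrom <- vt$chrom[!duplicated(vt$gene)]
  names(gene_chrom) <- vt$gene[!duplicated(vt$gene)]
  mask_chrx <- gene_chrom[masks$gene] == "X"

  strata <- list(list(name = "autosomal", rows = seq_len(n),
                      masks = which(!mask_chrx)))
  if (any(mask_chrx)) {
    sex <- study$covariates$sex
    strata <- c(strata,
      list(list(name = "chrX_male", rows = which(sex == 1),
                masks = which(mask_chrx)),
           list(name = "chrX_female", rows = which(sex == 0),
                masks = which(mask_chrx))))
  }

  out <- vector("list", length(strata))
  for (si in seq_along(strata)) {
    st <- strata[[si]]
    if (!length(st$masks)) next
    rows <- st$rows
    y <- y_all[rows]
    if (length(unique(y)) < 2) next
    C <- C_all
    if (!is.null(C)) {
      C <- C[rows, , drop = FALSE]
      C <- C[, apply(C, 2, function(v) stats::var(v) > 0), drop = FALSE]
      if (!ncol(C)) C <- NULL
    }
    if (mode == "approximate") {
      offset <- if (!is.null(C)) {
        fit0 <- stats::glm.fit(cbind(1, C), y, family = stats::binomial())
        drop(cbind(1, C) %*% fit0$coefficients)
      } else numeric(length(y))
      null_fit <- .firth_fit_null(y, offset)
      # score-test machinery under the Firth null: residuals and weights
      mu0 <- stats::plogis(offset + null_fit$intercept)
      w0 <- mu0 * (1 - mu0)
      S1w <- sum(w0)
      yres <- y - mu0
    }
    mk <- masks[st$masks, , drop = FALSE]
    nm <- nrow(mk)
    Gr <- G[rows, , drop = FALSE]
    keep <- logical(nm)
    beta_v <- se_v <- p_v <- cmac_v <- rep(NA_real_, nm)
    ncarr_v <- integer(nm); conv_v <- rep(TRUE, nm)
    method_v <- rep("score", nm)
    # burden construction, vectorized per (group, tier): sparse product of
    # the genotype block with a variants-by-mask membership indicator
    combos <- unique(mk[, c("annotation_group", "freq_tier")])
    for (ci in seq_len(nrow(combos))) {
      sel <- which(mk$annotation_group == combos$annotation_group[ci] &
                   mk$freq_tier == combos$freq_tier[ci])
      memb <- mk$members[sel]
      vidx <- unlist(memb)
      M <- Matrix::sparseMatrix(i = vidx,
                                j = rep.int(seq_along(sel), lengths(memb)),
                                x = 1, dims = c(ncol(G), length(sel)))
      AC <- methods::as(Gr %*% M, "CsparseMatrix")
      pvec <- AC@p; iv <- AC@i; xv <- AC@x
      for (k in seq_along(sel)) {
        lo <- pvec[k] + 1L; hi <- pvec[k + 1L]
        if (hi < lo) next
        idx <- iv[lo:hi] + 1L
        counts <- xv[lo:hi]
        cmac <- sum(counts)
        n_carr <- length(idx)
        if (n_carr < 1 || n_carr >= length(y)) next
        if (cmac < cmac_min || n_carr < carrier_min) next
        j <- sel[k]
        b <- NA_real_; se <- NA_real_; p <- NA_real_
        conv <- TRUE; se_wald <- NA_real_; lrt <- NA_real_
        p_exact <- NA_real_
        if (coding == "carrier" && mode == "approximate") {
          # one-step score statistic with the intercept profiled out
          Sxw <- sum(w0[idx])
          V <- Sxw - Sxw^2 / S1w
          if (V <= 0) next
          U <- sum(yres[idx])
          z0 <- U / sqrt(V)
          p_score <- 2 * stats::pnorm(-abs(z0))
          if (p_score >= firth_p_threshold) {
            b <- U / V; se <- 1 / sqrt(V); p <- p_score
          } else {
            fit <- .firth_fit_burden(y, idx, offset)
            fit0 <- .firth_fit_burden0(y, idx, offset)
            b <- fit$beta
            lrt <- max(0, 2 * (fit$pll - fit0$pll))
            conv <- fit$converged
            se_wald <- sqrt(fit$var_beta)
            method_v[j] <- "firth"
          }
        } else if (coding == "carrier") {
          x <- numeric(length(y)); x[idx] <- 1
          r <- firth_logistic(x, y, covariates = C, mode = "exact")
          b <- r$beta; conv <- r$converged
          p_exact <- r$p; se_wald <- r$se
          method_v[j] <- "firth"
        } else {
          x <- numeric(length(y)); x[idx] <- counts
          r <- firth_logistic(x, y, covariates = C,
                              mode = if (mode == "exact") "exact"
                                     else "approximate")
          b <- r$beta; conv <- r$converged
          p_exact <- r$p; se_wald <- r$se
          method_v[j] <- "firth"
        }
        if (is.na(p)) {
          p <- if (!is.na(lrt))
            stats::pchisq(lrt, df = 1, lower.tail = FALSE) else p_exact
          p <- max(p, .PMIN)
          z <- stats::qnorm(1 - p / 2)
          se <- if (is.finite(z) && z > 0 && abs(b) > 0) abs(b) / z
                else if (is.finite(se_wald)) se_wald
                else NA_real_
        }
        keep[j] <- TRUE
        beta_v[j] <- b; se_v[j] <- se; p_v[j] <- max(p, .PMIN)
        cmac_v[j] <- cmac; ncarr_v[j] <- n_carr; conv_v[j] <- conv
      }
    }
    if (!any(keep)) next
    out[[si]] <- data.frame(
      gene = mk$gene[keep],
      annotation_group = mk$annotation_group[keep],
      freq_tier = mk$freq_tier[keep],
      stratum = st$name,
      study_id = study$study_id,
      beta = beta_v[keep], se = se_v[keep], p = p_v[keep],
      or = exp(beta_v[keep]),
      ci_lo = exp(beta_v[keep] - .zcrit * se_v[keep]),
      ci_hi = exp(beta_v[keep] + .zcrit * se_v[keep]),
      cmac = cmac_v[keep], n_carriers = ncarr_v[keep],
      n_cases = sum(y == 1), n_referents = sum(y == 0),
      converged = conv_v[keep], method = method_v[keep],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(.empty_scan())
  rownames(res) <- NULL
  res
}

.empty_scan <- function() {
  data.frame(gene = character(0), annotation_group = character(0),
             freq_tier = character(0), stratum = character(0),
             study_id = character(0), beta = numeric(0), se = numeric(0),
             p = numeric(0), or = numeric(0), ci_lo = numeric(0),
             ci_hi = numeric(0), cmac = numeric(0), n_carriers = integer(0),
             n_cases = integer(0), n_referents = integer(0),
             converged = logical(0), method = character(0))
}
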