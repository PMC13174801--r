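#' Configure a synthetic multi-study case-control simulation
#'
#' Builds and validates the configuration object consumed by
#' [simulate_cohort()] and [simulate_multi_study()]. The generator emulates
#' the data structure a multi-cohort rare-variant association study of a
#' binary trait assumes: a shared panel of rare coding variants with a
#' log-uniform allele-frequency spectrum, an annotation composition of
#' roughly one quarter synonymous, half benign missense, 10-15% damaging
#' missense and <5% protein-truncating variants, and a liability-threshold
#' disease model in which per-allele effects are constant within annotation
#' class and concentrated in a small set of causal genes.
#'
#' @param n_genes Number of genes in the simulated exome.
#' @param n_causal_genes Number of genes carrying nonzero liability effects.
#' @param variants_per_gene Mean number of rare variants per gene (Poisson,
#'   truncated at 1).
#' @param freq_range Numeric length-2; allele frequencies are drawn
#'   log-uniformly on this interval. The default spans all three mask
#'   frequency tiers and both heritability frequency bins.
#' @param annotation_mix Named proportions over
#'   `synonymous`, `benign_missense`, `damaging_missense`, `PTV`;
#'   must sum to 1.
#' @param effect_model Named per-allele liability effects (standard-normal
#'   liability units) for `PTV` and `damaging_missense` in causal genes.
#'   Benign missense and synonymous variants always have effect 0.
#' @param prevalence Population prevalence K of the binary trait, in (0, 0.5).
#' @param studies List of studies, each a list with `n_cases`, `n_referents`
#'   and optional `case_ascertainment` flag (oversample cases to the target
#'   count, emulating case-control assemblies rather than population cohorts).
#' @param covariate_model Named effects of covariates on liability:
#'   `age` (per SD of age), `sex` (male vs female) and `pc` (per SD of each
#'   ancestry PC).
#' @param n_pcs Number of simulated ancestry principal components.
#' @param frac_chrx Fraction of genes placed on chromosome X (males carry
#'   0/1 dosages there and are analyzed in a separate stratum).
#' @param between_study_effect_sd Optional SD of per-study multiplicative
#'   jitter on causal effects (defaults to 0: homogeneous effects).
#' @param seed Integer seed; all randomness in the simulator derives from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 50, studies = list(
#'   list(n_cases = 100, n_referents = 900)), seed = 1)
simulation_config <- function(n_genes = 200,
                              n_causal_genes = 10,
                              variants_per_gene = 8,
                              freq_range = c(1e-6, 1e-2),
                              annotation_mix = c(synonymous = 0.25,
                                                 benign_missense = 0.555,
                                                 damaging_missense = 0.15,
                                                 PTV = 0.045),
                              effect_model = c(PTV = 0.5,
                                               damaging_missense = 0.25),
                              prevalence = 0.05,
                              studies = list(list(n_cases = 500,
                                                  n_referents = 9500)),
                              covariate_model = c(age = 0.2, sex = 0.25,
                                                  pc = 0),
                              n_pcs = 4,
                              frac_chrx = 0,
                              between_study_effect_sd = 0,
                              seed = 1L) {
  # accept named lists (e.g. from YAML configs) as well as named vectors
  annotation_mix <- unlist(annotation_mix)
  effect_model <- unlist(effect_model)
  covariate_model <- unlist(covariate_model)
  classes <- c("synonymous", "benign_missense", "damaging_missense", "PTV")
  if (!all(classes %in% names(annotation_mix)))
    stop("annotation_mix must name all of: ", paste(classes, collapse = ", "))
  annotation_mix <- annotation_mix[classes]
  if (abs(sum(annotation_mix) - 1) > 1e-8)
    stop("annotation_mix must sum to 1")
  if (any(annotation_mix < 0)) stop("annotation_mix proportions must be >= 0")
  if (!(prevalence > 0 && prevalence < 0.5))
    stop("prevalence must lie in (0, 0.5)")
  if (n_genes < 1 || variants_per_gene <= 0)
    stop("degenerate configuration: need >= 1 gene and > 0 variants per gene")
  if (n_causal_genes > n_genes) stop("n_causal_genes exceeds n_genes")
  if (length(freq_range) != 2 || any(freq_range <= 0) ||
      any(freq_range > 0.5) || freq_range[1] >= freq_range[2])
    stop("freq_range must be increasing within (0, 0.5]")
  if (length(studies) < 1) stop("at least one study must be specified")
  for (s in studies) {
    if (is.null(s$n_cases) || is.null(s$n_referents) ||
        s$n_cases <= 0 || s$n_referents <= 0)
      stop("every study needs positive n_cases and n_referents")
  }
  if (!all(c("PTV", "damaging_missense") %in% names(effect_model)))
    stop("effect_model must name PTV and damaging_missense")
  if (frac_chrx < 0 || frac_chrx > 1) stop("frac_chrx must be in [0, 1]")
  structure(list(
    n_genes = as.integer(n_genes),
    n_causal_genes = as.integer(n_causal_genes),
    variants_per_gene = variants_per_gene,
    freq_range = freq_range,
    annotation_mix = annotation_mix,
    effect_model = effect_model,
    prevalence = prevalence,
    studies = lapply(studies, function(s) {
      list(n_cases = as.integer(s$n_cases),
           n_referents = as.integer(s$n_referents),
           case_ascertainment = isTRUE(s$case_ascertainment))
    }),
    covariate_model = covariate_model,
    n_pcs = as.integer(n_pcs),
    frac_chrx = frac_chrx,
    between_study_effect_sd = between_study_effect_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Probability a simulated tool calls a missense variant damaging, by truth
# class. Four tools at 0.8 give P(>=3/4 agree) ~ 0.82 for truly damaging
# variants and rare spurious calls on benign ones.
.TOOL_SENS <- 0.8
.TOOL_FPR <- 0.05
.LOFTEE_FLAG_RATE <- 0.15

#' Simulate the shared variant panel (gene truth) for a configuration
#'
#' All studies generated from one configuration share this panel: gene
#' assignments, annotation classes, tool calls, population allele
#' frequencies and the causal-gene truth. Only genotype and phenotype draws
#' differ between studies.
#'
#' @param config A [simulation_config()] object.
#' @return A data frame of variant records with simulation truth columns
#'   (`true_freq`, `sim_class`, `liability_beta`, `causal_gene`).
#' @export
simulate_variant_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  genes <- sprintf("GENE%04d", seq_len(ng))
  causal <- sort(sample.int(ng, config$n_causal_genes))
  n_chrx <- round(config$frac_chrx * ng)
  chrx_genes <- if (n_chrx > 0) sample.int(ng, n_chrx) else integer(0)
  gene_chrom <- as.character(sample(1:22, ng, replace = TRUE))
  gene_chrom[chrx_genes] <- "X"
  gene_start <- sample.int(1e8, ng)

  nv <- pmax(1L, stats::rpois(ng, config$variants_per_gene))
  gene_idx <- rep(seq_len(ng), nv)
  m <- length(gene_idx)
  pos <- gene_start[gene_idx] + unlist(lapply(nv, function(k)
    sort(sample.int(5e4, k))))
  sim_class <- sample(names(config$annotation_mix), m, replace = TRUE,
                      prob = config$annotation_mix)
  consequence <- c(synonymous = "synonymous", benign_missense = "missense",
                   damaging_missense = "missense", PTV = "PTV")[sim_class]
  lo <- log(config$freq_range[1]); hi <- log(config$freq_range[2])
  p <- exp(stats::runif(m, lo, hi))

  is_miss <- consequence == "missense"
  call_prob <- ifelse(sim_class == "damaging_missense", .TOOL_SENS, .TOOL_FPR)
  tool <- function() is_miss & (stats::runif(m) < call_prob)
  revel <- tool(); am <- tool(); pai3d <- tool(); popeve <- tool()
  loftee_flagged <- consequence == "PTV" &
    stats::runif(m) < .LOFTEE_FLAG_RATE

  # gnomAD-style super-population frequencies: lognormal jitter around the
  # generating frequency, folded at 0.5
  pops <- c("nfe", "afr", "sas", "eas", "amr")
  pf <- vapply(pops, function(x)
    pmin(p * exp(stats::rnorm(m, 0, 0.3)), 0.5), numeric(m))
  colnames(pf) <- paste0("freq_", pops)

  beta <- numeric(m)
  in_causal <- gene_idx %in% causal
  beta[in_causal & sim_class == "PTV"] <- config$effect_model[["PTV"]]
  beta[in_causal & sim_class == "damaging_missense"] <-
    config$effect_model[["damaging_missense"]]

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  chrom <- gene_chrom[gene_idx]
  out <- data.frame(
    variant_id = paste(chrom, pos, ref, alt, sep = ":"),
    gene = genes[gene_idx],
    chrom = chrom,
    pos = pos,
    ref = ref,
    alt = alt,
    consequence = consequence,
    loftee_hc = consequence == "PTV",
    loftee_flagged = loftee_flagged,
    revel_damaging = revel,
    am_damaging = am,
    pai3d_damaging = pai3d,
    popeve_damaging = popeve,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(pf))
  out$true_freq <- p
  out$sim_class <- sim_class
  out$liability_beta <- beta
  out$causal_gene <- in_causal
  attr(out, "causal_genes") <- genes[causal]
  out
}

# Draw a sparse dosage block for n samples: per variant, total alt alleles
# ~ Binomial(2n, p) assigned to random haplotypes (males on chrX are
# haploid, dosage 0/1). Variants are treated as independent (no LD), which
# matches the independent pooling of mask variants in burden testing and
# the negligible-LD regime of ultra-rare variation.
.draw_genotypes <- function(n, vt, male) {
  m <- nrow(vt)
  ii <- vector("list", m); xx <- vector("list", m)
  is_x <- vt$chrom == "X"
  for (j in seq_len(m)) {
    p <- vt$true_freq[j]
    if (is_x[j]) {
      # haploid males, diploid females
      nh_m <- sum(male); nh_f <- 2L * (n - sum(male))
      a <- stats::rbinom(1, nh_m + nh_f, p)
      if (a == 0) { ii[[j]] <- integer(0); xx[[j]] <- numeric(0); next }
      hap <- sample.int(nh_m + nh_f, a)
      midx <- which(male); fidx <- which(!male)
      fem_hap <- hap[hap > nh_m] - nh_m
      samp <- c(midx[hap[hap <= nh_m]], fidx[(fem_hap + 1L) %/% 2L])
      tb <- table(samp)
      ii[[j]] <- as.integer(names(tb))
      xx[[j]] <- as.numeric(tb)
    } else {
      a <- stats::rbinom(1, 2L * n, p)
      if (a == 0) { ii[[j]] <- integer(0); xx[[j]] <- numeric(0); next }
      hap <- sample.int(2L * n, a)
      samp <- (hap + 1L) %/% 2L
      tb <- table(samp)
      ii[[j]] <- as.integer(names(tb))
      xx[[j]] <- as.numeric(tb)
    }
  }
  lens <- lengths(ii)
  Matrix::sparseMatrix(i = unlist(ii), j = rep.int(seq_len(m), lens),
                       x = unlist(xx), dims = c(n, m))
}

.sim_covariates <- function(n, n_pcs) {
  data.frame(age = stats::rnorm(n, 60, 10),
             sex = stats::rbinom(n, 1, 0.5),  # 1 = male
             matrix(stats::rnorm(n * n_pcs), n, n_pcs,
                    dimnames = list(NULL, paste0("PC", seq_len(n_pcs)))))
}

.liability_threshold <- function(config, vt) {
  cm <- config$covariate_model
  g_var <- sum(2 * vt$true_freq * (1 - vt$true_freq) * vt$liability_beta^2)
  g_mean <- sum(2 * vt$true_freq * vt$liability_beta)
  tot <- 1 + cm[["age"]]^2 + cm[["sex"]]^2 * 0.25 +
    config$n_pcs * cm[["pc"]]^2 + g_var
  # liability mean is nonzero (sex indicator and risk alleles shift it)
  g_mean + cm[["sex"]] * 0.5 +
    stats::qnorm(1 - config$prevalence) * sqrt(tot)
}

#' Simulate one study cohort under the liability-threshold model
#'
#' Draws genotypes, covariates and disease status for one study of the
#' configuration. Liability is the sum of per-allele genetic effects,
#' covariate effects and standard normal noise; a sample is a case iff its
#' liability exceeds the threshold putting population prevalence at K.
#' With `case_ascertainment`, population batches are drawn until the target
#' case count is reached (rejection sampling), emulating case-control
#' assemblies; otherwise the cohort is a population draw of
#' `n_cases + n_referents` samples and the realized case count is binomial.
#'
#' @param config A [simulation_config()].
#' @param study_index Which study of `config$studies` to generate (1-based).
#' @param variant_table Optional pre-generated [simulate_variant_table()]
#'   output, so multiple studies share one panel.
#' @return A `study_dataset`: list with `study_id`, sparse `genotypes`
#'   (samples x variants dosage matrix), `phenotype` (0/1), `covariates`,
#'   and `variant_table` with the study's `in_sample_freq` appended.
#' @export
simulate_cohort <- function(config, study_index = 1L, variant_table = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (study_index < 1 || study_index > length(config$studies))
    stop("study_index out of range")
  if (is.null(variant_table)) variant_table <- simulate_variant_table(config)
  vt <- variant_table
  st <- config$studies[[study_index]]
  set.seed(config$seed + 7919L * as.integer(study_index))

  beta <- vt$liability_beta
  if (config$between_study_effect_sd > 0) {
    jit <- exp(stats::rnorm(1, 0, config$between_study_effect_sd))
    beta <- beta * jit
  }
  thr <- .liability_threshold(config, vt)
  cm <- config$covariate_model

  draw_batch <- function(nb) {
    cov <- .sim_covariates(nb, config$n_pcs)
    G <- .draw_genotypes(nb, vt, male = cov$sex == 1)
    lin <- as.numeric(G %*% beta) +
      cm[["age"]] * (cov$age - 60) / 10 + cm[["sex"]] * cov$sex
    if (config$n_pcs > 0 && cm[["pc"]] != 0)
      lin <- lin + as.matrix(cov[paste0("PC", seq_len(config$n_pcs))]) %*%
        rep(cm[["pc"]], config$n_pcs)
    liab <- lin + stats::rnorm(nb)
    list(G = G, cov = cov, y = as.integer(liab > thr))
  }

  if (st$case_ascertainment) {
    need_ca <- st$n_cases; need_re <- st$n_referents
    Gs <- list(); covs <- list(); ys <- list()
    got_ca <- 0L; got_re <- 0L; guard <- 0L
    while ((got_ca < need_ca || got_re < need_re) && guard < 60L) {
      guard <- guard + 1L
      nb <- max(2000L, ceiling((need_ca - got_ca) / config$prevalence * 1.2))
      b <- draw_batch(nb)
      keep_ca <- which(b$y == 1)[seq_len(min(sum(b$y == 1), need_ca - got_ca))]
      keep_re <- which(b$y == 0)[seq_len(min(sum(b$y == 0), need_re - got_re))]
      keep <- c(keep_ca, keep_re)
      Gs[[guard]] <- b$G[keep, , drop = FALSE]
      covs[[guard]] <- b$cov[keep, , drop = FALSE]
      ys[[guard]] <- b$y[keep]
      got_ca <- got_ca + length(keep_ca); got_re <- got_re + length(keep_re)
    }
    G <- do.call(rbind, Gs)
    cov <- do.call(rbind, covs); rownames(cov) <- NULL
    y <- unlist(ys)
  } else {
    b <- draw_batch(st$n_cases + st$n_referents)
    G <- b$G; cov <- b$cov; y <- b$y
  }

  n <- nrow(G)
  ploidy <- ifelse(vt$chrom == "X",
                   sum(cov$sex == 1) + 2 * sum(cov$sex == 0), 2 * n)
  vt$in_sample_freq <- as.numeric(Matrix::colSums(G)) / ploidy
  sample_id <- sprintf("S%d_%06d", study_index, seq_len(n))
  rownames(G) <- sample_id
  colnames(G) <- vt$variant_id
  structure(list(study_id = paste0("study", study_index),
                 genotypes = G,
                 phenotype = y,
                 covariates = cbind(sample_id = sample_id, cov),
                 variant_table = vt),
            class = "study_dataset")
}

#' Simulate all configured studies from a shared variant panel
#'
#' Studies share the variant panel (allele frequencies, annotations and
#' causal-gene truth) but have independent genotype/phenotype draws and can
#' have different case:referent ratios and ascertainment modes.
#'
#' @param config A [simulation_config()].
#' @return List of `study_dataset` objects, with the shared panel attached
#'   as attribute `variant_table`.
#' @export
simulate_multi_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  vt <- simulate_variant_table(config)
  out <- lapply(seq_along(config$studies), function(i)
    simulate_cohort(config, i, variant_table = vt))
  attr(out, "variant_table") <- vt
  out
}

#' Simulate a GWAS gene table with tunable causal-gene enrichment
#'
#' Produces the common-variant side of the convergence analyses: per gene,
#' whether it lies within 500 kb of a genome-wide significant locus
#' (`in_locus`) and an integer 0-5 prioritization score, with causal genes'
#' odds of locus membership and of high scores multiplied by `enrichment`.
#'
#' @param gene_truth Data frame with columns `gene` and logical `causal`.
#' @param enrichment Odds multiplier (>= 1) applied to causal genes.
#' @param base_locus_rate Locus-membership probability for null genes.
#' @param base_score_rate Per-point score probability for null in-locus genes
#'   (scores are Binomial(5, rate), odds-tilted for causal genes).
#' @param seed Integer seed.
#' @return Data frame `gene`, `in_locus`, `geneprio_score`; scores are > 0
#'   only for in-locus genes.
#' @export
simulate_gwas_annotations <- function(gene_truth, enrichment = 1,
                                      base_locus_rate = 0.15,
                                      base_score_rate = 0.1,
                                      seed = 1L) {
  stopifnot(enrichment >= 1, all(c("gene", "causal") %in% names(gene_truth)))
  set.seed(as.integer(seed))
  tilt <- function(p, odds_mult) {
    o <- p / (1 - p) * odds_mult
    o / (1 + o)
  }
  p_locus <- ifelse(gene_truth$causal,
                    tilt(base_locus_rate, enrichment), base_locus_rate)
  in_locus <- stats::runif(nrow(gene_truth)) < p_locus
  q <- ifelse(gene_truth$causal,
              tilt(base_score_rate, enrichment), base_score_rate)
  score <- ifelse(in_locus, stats::rbinom(nrow(gene_truth), 5, q), 0L)
  data.frame(gene = gene_truth$gene,
             in_locus = in_locus,
             geneprio_score = as.integer(score))
}
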