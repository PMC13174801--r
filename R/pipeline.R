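#' Run the full burden-testing pipeline
#'
#' Executes the end-to-end analysis: (optional) multi-study simulation ->
#' mask enumeration -> per-study Firth burden scans -> fixed-effects
#' meta-analysis with saddlepoint adjustment -> post-meta count filters ->
#' layered Cauchy gene-level combination -> sensitivity re-combinations ->
#' (optional) GWAS convergence analyses -> (optional) burden heritability.
#' All randomness derives from the single `seed`. When `outdir` is given,
#' each stage's table is written as TSV together with a JSON run manifest
#' (configuration echo, seed, package version, and row counts before and
#' after every filter, so no rows are dropped silently).
#'
#' @param config Either a list or a YAML file path. Recognized entries:
#'   `seed`; `simulation` (arguments to [simulation_config()]) or
#'   `studies` (a pre-built list of `study_dataset`s); `scan` (arguments
#'   `mode`, `cmac_min`, `carrier_min`, `coding`, `covariates` for
#'   [run_study_scan()]; `cmac_min` may be a per-study vector); `meta`
#'   (`spa`, `alpha_spa`, `cmac_min`, `min_studies`); `cauchy`
#'   (`n_tests`); `sensitivity` (named list of
#'   `list(freq_tiers=, layers=)` subset specs, or `FALSE`);
#'   `convergence` (`enrichment` for a simulated GWAS table, or
#'   `gwas_table` path, or `FALSE`); `bhr` (`prevalence`, `cmac_min`,
#'   `study` index, or `FALSE`); `outdir`.
#' @return List of class `rareburden_run`: `studies`, `masks` (per
#'   study), `assoc`, `meta`, `meta_filtered`, `genes`, `sensitivity`,
#'   `enrichment`, `bhr`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  manifest <- list(seed = seed,
                   package_version = as.character(
                     utils::packageVersion("rareburden")),
                   config = config, counts = list())
  note <- function(...) message("[pipeline] ", ...)

  # --- studies ---------------------------------------------------------
  if (!is.null(config$studies)) {
    studies <- config$studies
    note("using ", length(studies), " supplied studies")
  } else {
    sim_args <- if (!is.null(config$simulation)) config$simulation else list()
    sim_args$seed <- seed
    cfg <- do.call(simulation_config, sim_args)
    note("simulating ", length(cfg$studies), " studies")
    studies <- simulate_multi_study(cfg)
    manifest$counts$n_variants <- nrow(attr(studies, "variant_table"))
  }
  n_studies <- length(studies)

  # --- masks + per-study scans ----------------------------------------
  scan_cfg <- config$scan
  cmac_min <- scan_cfg$cmac_min
  if (is.null(cmac_min)) cmac_min <- 10
  cmac_min <- rep_len(cmac_min, n_studies)
  assoc <- vector("list", n_studies)
  n_masks <- integer(n_studies)
  for (i in seq_len(n_studies)) {
    masks <- enumerate_masks(studies[[i]]$variant_table)
    n_masks[i] <- nrow(masks)
    assoc[[i]] <- run_study_scan(
      studies[[i]], masks,
      covariates = scan_cfg$covariates,
      mode = if (!is.null(scan_cfg$mode)) scan_cfg$mode else "approximate",
      cmac_min = cmac_min[i],
      carrier_min = if (!is.null(scan_cfg$carrier_min))
        scan_cfg$carrier_min else 0,
      coding = if (!is.null(scan_cfg$coding)) scan_cfg$coding else "carrier")
    note("study ", i, ": ", n_masks[i], " masks enumerated, ",
         nrow(assoc[[i]]), " results after per-study filters")
  }
  manifest$counts$masks_enumerated <- n_masks
  manifest$counts$assoc_per_study <- vapply(assoc, nrow, integer(1))
  assoc <- do.call(rbind, assoc)

  # --- meta-analysis ---------------------------------------------------
  meta_cfg <- config$meta
  meta <- meta_analyze(
    assoc,
    spa = if (!is.null(meta_cfg$spa)) meta_cfg$spa else TRUE,
    alpha_spa = if (!is.null(meta_cfg$alpha_spa))
      meta_cfg$alpha_spa else 0.05)
  meta_f <- meta_filter(
    meta,
    cmac_min = if (!is.null(meta_cfg$cmac_min)) meta_cfg$cmac_min else 20,
    min_studies = if (!is.null(meta_cfg$min_studies))
      meta_cfg$min_studies else 2)
  manifest$counts$meta_masks <- nrow(meta)
  manifest$counts$meta_masks_filtered <- nrow(meta_f)
  note("meta-analysis: ", nrow(meta), " masks, ", nrow(meta_f),
       " after cMAC/study-count filters")

  # --- gene-level combination -----------------------------------------
  genes <- layered_gene_pvalue(meta_f, n_tests = config$cauchy$n_tests)
  manifest$counts$genes_tested <- nrow(genes)
  note(nrow(genes), " gene-stratum tests; ",
       sum(genes$significant), " significant at alpha = ",
       format(genes$alpha[1], digits = 3))

  # --- sensitivity re-combinations ------------------------------------
  sens_cfg <- config$sensitivity
  sens <- NULL
  if (!isFALSE(sens_cfg)) {
    if (is.null(sens_cfg) || isTRUE(sens_cfg))
      sens_cfg <- list(
        rare_only = list(freq_tiers = c("UR", "R")),
        ultrarare_only = list(freq_tiers = "UR"),
        ptv_only = list(layers = "PTV"),
        missense_only = list(layers = "missense"))
    sens <- lapply(sens_cfg, function(sp) {
      sensitivity_recombine(
        meta_f,
        freq_tiers = if (!is.null(sp$freq_tiers)) sp$freq_tiers
          else names(mask_freq_tiers()),
        layers = if (!is.null(sp$layers)) sp$layers
          else c("missense", "PTV", "PTV+missense"),
        n_tests = nrow(genes))
    })
  }

  # --- GWAS convergence (optional) ------------------------------------
  enrich <- NULL
  conv_cfg <- config$convergence
  if (!is.null(conv_cfg) && !isFALSE(conv_cfg)) {
    gwas <- if (!is.null(conv_cfg$gwas_table)) {
      utils::read.delim(conv_cfg$gwas_table, stringsAsFactors = FALSE)
    } else {
      vt <- studies[[1]]$variant_table
      truth <- data.frame(gene = unique(vt$gene))
      truth$causal <- truth$gene %in% attr(vt, "causal_genes")
      simulate_gwas_annotations(
        truth,
        enrichment = if (!is.null(conv_cfg$enrichment))
          conv_cfg$enrichment else 1,
        seed = seed + 101L)
    }
    auto <- genes[genes$stratum == "autosomal", , drop = FALSE]
    enrich <- fisher_enrichment(auto, gwas)
  }

  # --- burden heritability (optional) ---------------------------------
  bhr <- NULL
  bhr_cfg <- config$bhr
  if (!is.null(bhr_cfg) && !isFALSE(bhr_cfg)) {
    sidx <- if (!is.null(bhr_cfg$study)) bhr_cfg$study else 1L
    st <- studies[[sidx]]
    sc <- tryCatch(
      burden_scores(st$variant_table, st,
                    cmac_min = if (!is.null(bhr_cfg$cmac_min))
                      bhr_cfg$cmac_min else 20),
      error = function(e) {
        note("burden heritability skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(sc)) {
    K <- if (!is.null(bhr_cfg$prevalence)) bhr_cfg$prevalence
         else mean(st$phenotype)
    bhr <- lapply(split(sc, paste(sc$freq_bin, sc$annotation, sep = ".")),
                  function(d) {
      if (nrow(d) < 50) return(NULL)
      liability_transform(
        bhr_regression(d, fixed_genes = bhr_cfg$fixed_genes,
                       genomewide_correction =
                         isTRUE(bhr_cfg$genomewide_correction)),
        K = K, P = mean(st$phenotype))
    })
    bhr <- Filter(Negate(is.null), bhr)
    }
  }

  out <- structure(list(studies = studies, assoc = assoc, meta = meta,
                        meta_filtered = meta_f, genes = genes,
                        sensitivity = sens, enrichment = enrich,
                        bhr = bhr, manifest = manifest),
                   class = "rareburden_run")

  # --- outputs ---------------------------------------------------------
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    wp <- function(x, f) if (!is.null(x))
      write_results_tsv(x, file.path(config$outdir, f))
    wp(assoc, "association_results.tsv")
    wp(meta, "meta_results.tsv")
    wp(meta_f, "meta_results_filtered.tsv")
    wp(genes, "gene_results.tsv")
    if (!is.null(sens))
      for (nm in names(sens)) wp(sens[[nm]],
                                 paste0("gene_results_", nm, ".tsv"))
    wp(enrich, "enrichment_grid.tsv")
    if (!is.null(bhr) && length(bhr)) {
      bh <- do.call(rbind, lapply(names(bhr), function(nm)
        data.frame(bin = nm, h2_obs = bhr[[nm]]$h2_obs,
                   se = bhr[[nm]]$se, h2_liab = bhr[[nm]]$h2_liab,
                   ci_lo = bhr[[nm]]$ci95_liab[1],
                   ci_hi = bhr[[nm]]$ci95_liab[2])))
      wp(bh, "burden_heritability.tsv")
    }
    jsonlite::write_json(manifest,
                         file.path(config$outdir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         null = "null")
  }
  out
}

#' @export
print.rareburden_run <- function(x, ...) {
  cat("rareburden pipeline run\n")
  cat("  studies:            ", length(x$studies), "\n")
  cat("  association results:", nrow(x$assoc), "\n")
  cat("  meta-analyzed masks:", nrow(x$meta), " (",
      nrow(x$meta_filtered), " after filters)\n", sep = "")
  cat("  gene-stratum tests: ", nrow(x$genes), "\n")
  if (nrow(x$genes))
    cat("  significant genes:  ", sum(x$genes$significant),
        " at alpha=", format(x$genes$alpha[1], digits = 3), "\n", sep = "")
  invisible(x)
}
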