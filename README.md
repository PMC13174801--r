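# rareburden

Gene-based rare-variant burden association for binary traits across
multiple sequencing cohorts, in R.

Rare coding variants can carry large effects on common-disease risk, but
single-variant tests are hopeless at allele frequencies of 10⁻⁵: power
comes from pooling a gene's qualifying variants into *masks* and testing
the pooled burden. Which variants to pool is itself uncertain, so modern
studies test many masks per gene — here up to 60, from 20 annotation
schemes (protein-truncating variants with/without quality flags, missense
variants called damaging by each of four in-silico tools, by ≥1 or ≥3 of
them, and every PTV×missense union) crossed with three nested
maximum-population-allele-frequency tiers (MAF_max < 10⁻⁵, < 10⁻³,
< 10⁻²) — and then collapse the mask p-values into one statistic per
gene. `rareburden` implements that full pipeline for case-control
phenotypes, plus the integrative analyses that accompany it:

* **Per-study tests**: Firth-penalized logistic regression
  (Jeffreys-prior penalty, finite under complete separation) of case
  status on the mask carrier indicator, covariate-adjusted, with
  penalized-LRT p-values and back-corrected SEs
  (`firth_logistic`, `run_study_scan`).
* **Meta-analysis**: inverse-variance-weighted fixed effects with
  Cochran's Q, count-based filters (aggregate cMAC ≥ 20, ≥ 2 studies),
  and a genotype-count saddlepoint adjustment of nominally significant
  p-values that corrects the anti-conservatism of normal-theory
  meta-analysis under case-control imbalance
  (`ivw_meta`, `spa_pvalue`, `meta_analyze`, `meta_filter`).
* **Gene-level statistic**: layered Cauchy (ACAT) combination — masks
  combine within missense / PTV / PTV+missense layers, layers combine
  into the final gene p-value — with sensitivity re-combinations
  (rare-only, PTV-only, missense-only) and the λ₉₀ inflation diagnostic
  (`cauchy_combine`, `layered_gene_pvalue`, `sensitivity_recombine`,
  `lambda90`).
* **GWAS integration**: Fisher-exact enrichment grids of RVAS genes
  among GWAS-nominated genes, subset discovery at subset-sized
  Bonferroni thresholds, and the log-log power-law fit of absolute
  effect size against allele frequency
  (`fisher_enrichment`, `subset_discovery`, `fit_powerlaw`).
* **Burden heritability**: regression of squared standardized burden
  effects on gene burden scores γ = Σ 2p(1−p) per frequency × annotation
  bin, with fixed-gene effects, genome-wide correction, block-jackknife
  SEs, liability-scale conversion and gene-set partitioning
  (`burden_scores`, `bhr_regression`, `liability_transform`,
  `partition_h2`).
* **A synthetic multi-study generator** (liability-threshold disease
  model, shared variant panel, per-study genotype draws, case
  ascertainment, chromosome X) so the whole pipeline is testable without
  restricted cohort access (`simulation_config`, `simulate_multi_study`,
  `simulate_gwas_annotations`, `simulate_bhr_sumstats`).

File formats: VCF 4.2 or dense TSV genotypes, TSV annotation and
phenotype tables, YAML configs, TSV/JSON outputs
(`read_genotypes`, `read_annotations`, `run_pipeline`).

## Worked example

Simulate two cohorts with six causal genes, scan, meta-analyze and
combine:

```r
library(rareburden)

run <- run_pipeline(list(
  seed = 5,
  simulation = list(
    n_genes = 60, n_causal_genes = 6, variants_per_gene = 12,
    effect_model = list(PTV = 1.5, damaging_missense = 0.9),
    studies = list(list(n_cases = 400, n_referents = 3600),
                   list(n_cases = 300, n_referents = 1200))),
  scan = list(cmac_min = 5),
  convergence = list(enrichment = 5)))
run
#> rareburden pipeline run
#>   studies:             2
#>   association results: 548
#>   meta-analyzed masks:309 (217 after filters)
#>   gene-stratum tests:  25
#>   significant genes:  1 at alpha=0.002

head(run$genes[, c("gene", "p_final", "best_mask", "best_or",
                   "best_cmac", "significant")], 3)
#>        gene      p_final     best_mask  best_or best_cmac significant
#> 2  GENE0002 2.459322e-09 missPopEVE_RL 9.591077        95        TRUE
#> 24 GENE0054 2.680874e-02    miss3/4_RL 5.227379        52       FALSE
#> 17 GENE0038 4.146882e-02    miss1/4_RL 2.937086        46       FALSE
```

One of the six causal genes reaches Bonferroni significance at this
deliberately small demo scale (2,000 + 3,600 + 300 + 1,200 samples); its
best mask — popEVE-called damaging missense variants at MAF_max < 1% —
carries 95 minor alleles and an odds ratio near 9.6, and the layered
Cauchy p-value combines all of the gene's surviving masks.

(Your exact numbers depend only on the seed; rerunning the same config
is bit-reproducible.) `run$genes` holds the layered Cauchy p-values per
gene with the best mask's odds ratio and cMAC; `run$sensitivity` holds
the rare-only / PTV-only / missense-only re-combinations;
`run$enrichment` holds the Fisher grid against the simulated GWAS gene
table. With an `outdir` entry, every table is written as TSV together
with a JSON run manifest that echoes the config, the seed and the row
counts at every filtering stage.

See the methods vignette (`vignettes/rareburden-methods.Rmd`) for the
statistical models, the numerical choices, and what the simulations do
and do not demonstrate.

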