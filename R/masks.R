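#' @importFrom Matrix colSums rowSums t sparseMatrix
NULL

# The 20 annotation schemes: two PTV groups, six missense groups, and the
# 12 PTV x missense products.
.MISS_GROUPS <- c("missREVEL", "missAM", "missPAI3D", "missPopEVE",
                  "miss1/4", "miss3/4")
.PTV_GROUPS <- c("PTV", "PTVnf")

#' Annotation groups and frequency tiers of the mask grid
#'
#' The grid crosses 20 annotation schemes (PTV with and without flagged
#' calls; missense predicted damaging by each of four tools, by any one
#' tool, or by at least three; and every PTV x missense union) with three
#' nested maximum-frequency tiers, giving up to 60 masks per gene.
#'
#' @return `mask_annotation_groups()`: character vector of the 20 group
#'   names. `mask_freq_tiers()`: named numeric vector of the tier
#'   frequency cutoffs (`UR` < 1e-5, `R` < 1e-3, `RL` < 1e-2).
#' @export
mask_annotation_groups <- function() {
  c(.PTV_GROUPS, .MISS_GROUPS,
    as.vector(outer(.PTV_GROUPS, .MISS_GROUPS, paste, sep = "+")))
}

#' @rdname mask_annotation_groups
#' @export
mask_freq_tiers <- function() c(UR = 1e-5, R = 1e-3, RL = 1e-2)

#' Fold allele frequencies to the minor allele
#'
#' @param freq Numeric vector of allele frequencies in \[0, 1\].
#' @return Frequencies folded into \[0, 0.5\].
#' @export
fold_maf <- function(freq) {
  if (any(freq < 0 | freq > 1, na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]")
  pmin(freq, 1 - freq)
}

#' Maximum population minor allele frequency
#'
#' Returns, per variant, the maximum over the supplied reference
#' super-population frequencies and (optionally) the study's in-sample
#' frequency, after minor-allele folding. When no reference frequencies are
#' available the in-sample frequency alone is used, which is how cohorts
#' without external frequency annotation are handled.
#'
#' @param pop_freqs Numeric matrix or data frame (variants x populations),
#'   may have zero columns; NAs are treated as absent.
#' @param in_sample_freq Numeric vector of in-sample allele frequencies.
#' @param use_insample Include the in-sample frequency in the maximum.
#' @return Numeric vector of MAF_max values.
#' @export
compute_maf_max <- function(pop_freqs, in_sample_freq = NULL,
                            use_insample = TRUE) {
  pf <- as.matrix(pop_freqs)
  if (use_insample && !is.null(in_sample_freq))
    pf <- cbind(pf, in_sample = in_sample_freq)
  if (ncol(pf) == 0)
    stop("no frequency source available: supply population or in-sample ",
         "frequencies")
  pf[] <- fold_maf(as.numeric(pf))
  out <- apply(pf, 1, function(r) if (all(is.na(r))) NA_real_ else
    max(r, na.rm = TRUE))
  if (anyNA(out)) stop("variants with every frequency source missing")
  out
}

# variants x 20 logical membership matrix over annotation groups
.group_membership <- function(vt) {
  miss <- vt$consequence == "missense"
  ptv <- vt$consequence == "PTV"
  calls <- cbind(vt$revel_damaging, vt$am_damaging,
                 vt$pai3d_damaging, vt$popeve_damaging)
  if (any(rowSums(calls, na.rm = TRUE) > 0 & !miss))
    stop("damaging tool calls set on non-missense variants")
  ncalls <- rowSums(calls)
  g <- cbind(
    "PTV" = ptv,
    "PTVnf" = ptv & !vt$loftee_flagged,
    "missREVEL" = miss & vt$revel_damaging,
    "missAM" = miss & vt$am_damaging,
    "missPAI3D" = miss & vt$pai3d_damaging,
    "missPopEVE" = miss & vt$popeve_damaging,
    "miss1/4" = miss & ncalls >= 1,
    "miss3/4" = miss & ncalls >= 3
  )
  combos <- setdiff(mask_annotation_groups(), colnames(g))
  for (nm in combos) {
    parts <- strsplit(nm, "+", fixed = TRUE)[[1]]
    g <- cbind(g, g[, parts[1]] | g[, parts[2]])
    colnames(g)[ncol(g)] <- nm
  }
  g[, mask_annotation_groups(), drop = FALSE]
}

#' Enumerate annotation-by-frequency masks for a variant table
#'
#' Crosses the 20 annotation groups with the three nested frequency tiers
#' and emits one mask per (gene, group, tier) combination that has at least
#' one qualifying variant. Tiers are nested, so a variant below the
#' ultra-rare cutoff is a member of all three tiers' masks.
#'
#' @param variant_table Data frame of variant records (see
#'   [read_annotations()] for the schema); must contain `gene`,
#'   `consequence`, `loftee_flagged`, the four `*_damaging` calls and
#'   either a `maf_max` column or the columns needed by
#'   [compute_maf_max()].
#' @param maf_max Optional per-variant MAF_max overriding the table column.
#' @return Data frame with one row per mask: `gene`, `annotation_group`,
#'   `freq_tier`, `n_variants`, `variant_ids` (semicolon-separated), and a
#'   `members` list column of integer row indices into `variant_table`.
#' @export
enumerate_masks <- function(variant_table, maf_max = NULL) {
  vt <- variant_table
  if (is.null(maf_max)) {
    if (!is.null(vt$maf_max)) maf_max <- vt$maf_max
    else {
      pf <- vt[, grep("^freq_", names(vt)), drop = FALSE]
      maf_max <- compute_maf_max(pf, vt$in_sample_freq)
    }
  }
  memb <- .group_membership(vt)
  tiers <- mask_freq_tiers()
  rows <- vector("list", 3L * ncol(memb))
  k <- 0L
  for (tier in names(tiers)) {
    in_tier <- maf_max < tiers[[tier]]
    for (grp in colnames(memb)) {
      sel <- which(memb[, grp] & in_tier)
      if (!length(sel)) next
      by_gene <- split(sel, vt$gene[sel])
      if (grepl("+", grp, fixed = TRUE)) {
        # a PTV x missense union exists only where both component masks
        # exist in the gene and tier (otherwise it duplicates one of them)
        parts <- strsplit(grp, "+", fixed = TRUE)[[1]]
        both <- vapply(by_gene, function(i)
          any(memb[i, parts[1]]) && any(memb[i, parts[2]]), logical(1))
        by_gene <- by_gene[both]
        if (!length(by_gene)) next
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        gene = names(by_gene),
        annotation_group = grp,
        freq_tier = tier,
        n_variants = lengths(by_gene),
        variant_ids = vapply(by_gene, function(i)
          paste(vt$variant_id[i], collapse = ";"), character(1)),
        stringsAsFactors = FALSE, row.names = NULL
      )
      rows[[k]]$members <- unname(by_gene)
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  if (is.null(out))
    return(data.frame(gene = character(0), annotation_group = character(0),
                      freq_tier = character(0), n_variants = integer(0),
                      variant_ids = character(0)))
  out <- out[order(out$gene, out$annotation_group,
                   match(out$freq_tier, names(tiers))), ]
  rownames(out) <- NULL
  out
}

#' Build the burden genotype of one mask in one study
#'
#' Default coding is the carrier indicator: a sample scores 1 iff it
#' carries at least one minor allele across the mask's member variants
#' (maximum dosage thresholded at 1), which makes the burden odds ratio
#' interpretable as carrier risk. `coding = "sum"` uses the allele count
#' instead. The cumulative minor allele count (cMAC) always sums all minor
#' alleles over members and samples, independent of coding.
#'
#' @param mask One row of [enumerate_masks()] output (data frame or list
#'   with `variant_ids` or `members`).
#' @param study A `study_dataset` or a samples x variants dosage matrix
#'   with variant ids as column names.
#' @param coding `"carrier"` (default) or `"sum"`.
#' @return List with `burden` (per-sample numeric), `cmac`, `n_carriers`.
#' @export
build_burden_genotype <- function(mask, study, coding = c("carrier", "sum")) {
  coding <- match.arg(coding)
  G <- if (inherits(study, "study_dataset")) study$genotypes else study
  ids <- if (!is.null(mask$variant_ids))
    strsplit(mask$variant_ids[[1]], ";", fixed = TRUE)[[1]]
  else colnames(G)[mask$members[[1]]]
  missing <- setdiff(ids, colnames(G))
  if (length(missing))
    stop("mask member variants absent from genotype matrix: ",
         paste(missing, collapse = ", "))
  sub <- G[, ids, drop = FALSE]
  counts <- as.numeric(Matrix::rowSums(sub))
  burden <- if (coding == "carrier") as.numeric(counts > 0) else counts
  list(burden = burden,
       cmac = sum(counts),
       n_carriers = sum(counts > 0))
}
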