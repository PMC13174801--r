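# File formats: genotypes (VCF 4.2 or dense TSV), annotation tables,
# phenotype/covariate tables, and the tab-separated result writers.
# Interchange dialect is TSV with a header row, UTF-8, '.' decimal.

.gt_to_dosage <- function(gt) {
  # "0/0", "0|1", "1/1", haploid "1"; missing "./." or "." -> NA
  out <- rep(NA_real_, length(gt))
  ok <- !is.na(gt) & gt != "." & gt != "./." & gt != ".|."
  alleles <- strsplit(gt[ok], "[/|]")
  out[ok] <- vapply(alleles, function(a) {
    a <- suppressWarnings(as.numeric(a))
    if (anyNA(a)) NA_real_ else sum(a > 0)
  }, numeric(1))
  out
}

#' Read a genotype dosage matrix from VCF or TSV
#'
#' VCF input (4.x, GT field required) is parsed with vcfR; genotypes are
#' converted to 0/1/2 alternate-allele dosages (haploid calls count as
#' 0/1). TSV input is a dense matrix: first column `sample_id`, remaining
#' columns one variant each, named by `chrom:pos:ref:alt` key. Missing
#' genotypes are excluded (set to 0) with the excluded pair count
#' reported.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return List with `genotypes` (samples x variants matrix, variant keys
#'   as column names) and `variants` (data frame `variant_id`, `chrom`,
#'   `pos`, `ref`, `alt`).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    if (nrow(fix) == 0) {
      warning("empty VCF body: returning 0-variant matrix")
      return(list(genotypes = matrix(0, 0, 0),
                  variants = data.frame(variant_id = character(0),
                                        chrom = character(0),
                                        pos = integer(0),
                                        ref = character(0),
                                        alt = character(0))))
    }
    keys <- paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":")
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, 2, .gt_to_dosage)
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1)
    dos <- t(dos)                      # samples x variants
    colnames(dos) <- keys
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(tab))
      stop("TSV genotype matrix needs a sample_id column")
    dos <- as.matrix(tab[, setdiff(names(tab), "sample_id"),
                         drop = FALSE])
    rownames(dos) <- tab$sample_id
    keys <- colnames(dos)
    parts <- strsplit(keys, ":", fixed = TRUE)
    bad <- which(lengths(parts) != 4)
    if (length(bad))
      stop("malformed variant keys (need chrom:pos:ref:alt) in columns: ",
           paste(bad, collapse = ", "))
  }
  n_missing <- sum(is.na(dos))
  if (n_missing > 0) {
    message("read_genotypes: excluded ", n_missing,
            " missing sample-variant pairs (set to 0)")
    dos[is.na(dos)] <- 0
  }
  parts <- strsplit(colnames(dos), ":", fixed = TRUE)
  variants <- data.frame(
    variant_id = colnames(dos),
    chrom = vapply(parts, `[`, character(1), 1),
    pos = as.integer(vapply(parts, `[`, character(1), 2)),
    ref = vapply(parts, `[`, character(1), 3),
    alt = vapply(parts, `[`, character(1), 4),
    stringsAsFactors = FALSE)
  list(genotypes = dos, variants = variants)
}

#' Write a study's genotypes as a minimal GT-only VCF 4.2
#'
#' Positions are 1-based; dosage 1 on diploid records is written `0/1`,
#' dosage 2 `1/1`. The seed (when recorded on the study) is echoed in a
#' header line for provenance.
#'
#' @param study A `study_dataset` (or list with `genotypes` and
#'   `variant_table`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(study, path) {
  G <- as.matrix(study$genotypes)
  vt <- study$variant_table
  samples <- rownames(G)
  if (is.null(samples)) samples <- sprintf("S%06d", seq_len(nrow(G)))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=rareburden",
           if (!is.null(attr(study, "seed")))
             paste0("##rareburden_seed=", attr(study, "seed")),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(G)), function(j) {
    paste(c(vt$chrom[j], vt$pos[j], vt$variant_id[j], vt$ref[j], vt$alt[j],
            ".", "PASS", ".", "GT", code[G[, j] + 1]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read and validate a variant annotation table
#'
#' Expects the tab-separated schema: `variant_id`, `gene`, `chrom`, `pos`,
#' `ref`, `alt`, `consequence` (synonymous/missense/PTV), logical
#' `loftee_hc`, `loftee_flagged`, `revel_damaging`, `am_damaging`,
#' `pai3d_damaging`, `popeve_damaging`, and the population frequency
#' columns `freq_nfe`, `freq_afr`, `freq_sas`, `freq_eas`, `freq_amr`.
#' Booleans are parsed strictly (TRUE/FALSE/0/1); frequencies above 0.5
#' are folded to the minor allele with a notice; damaging calls on
#' non-missense rows are rejected with their row indices.
#'
#' @param path TSV path.
#' @return Data frame of validated variant records.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("variant_id", "gene", "chrom", "pos", "ref", "alt",
           "consequence", "loftee_hc", "loftee_flagged", "revel_damaging",
           "am_damaging", "pai3d_damaging", "popeve_damaging")
  missing <- setdiff(req, names(tab))
  if (length(missing))
    stop("annotation table missing columns: ",
         paste(missing, collapse = ", "))
  boolcols <- req[8:13]
  parse_bool <- function(x, col) {
    if (is.logical(x)) return(x)
    v <- rep(NA, length(x))
    v[x %in% c("TRUE", "True", "true", "1", 1)] <- TRUE
    v[x %in% c("FALSE", "False", "false", "0", 0)] <- FALSE
    if (anyNA(v))
      stop("unparseable boolean values in column ", col, ", rows: ",
           paste(utils::head(which(is.na(v)), 10), collapse = ", "))
    v
  }
  for (cl in boolcols) tab[[cl]] <- parse_bool(tab[[cl]], cl)
  if (!all(tab$consequence %in% c("synonymous", "missense", "PTV")))
    stop("consequence must be one of synonymous, missense, PTV")
  calls <- tab$revel_damaging | tab$am_damaging | tab$pai3d_damaging |
    tab$popeve_damaging
  bad <- which(calls & tab$consequence != "missense")
  if (length(bad))
    stop("damaging tool calls on non-missense variants at rows: ",
         paste(bad, collapse = ", "))
  fcols <- grep("^freq_", names(tab), value = TRUE)
  for (cl in c(fcols, intersect("in_sample_freq", names(tab)))) {
    x <- tab[[cl]]
    if (any(x < 0 | x > 1, na.rm = TRUE))
      stop("frequencies in ", cl, " outside [0, 1]")
    n_fold <- sum(x > 0.5, na.rm = TRUE)
    if (n_fold > 0) {
      message("read_annotations: folded ", n_fold,
              " frequencies in ", cl, " to the minor allele")
      tab[[cl]] <- fold_maf(x)
    }
  }
  tab
}

#' Read a phenotype/covariate table
#'
#' Tab-separated, one row per sample: `sample_id`, a binary status column
#' (`af_status` by default), and covariates (`age`, `sex`, `PC1`..).
#'
#' @param path TSV path.
#' @param status_col Name of the binary phenotype column.
#' @return Data frame with a `phenotype` column appended.
#' @export
read_phenotypes <- function(path, status_col = "af_status") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab)) stop("phenotype table needs sample_id")
  if (!status_col %in% names(tab))
    stop("phenotype table missing status column ", status_col)
  y <- tab[[status_col]]
  if (!all(y %in% c(0, 1))) stop(status_col, " must be binary 0/1")
  tab$phenotype <- as.integer(y)
  tab
}

#' Write a result table as TSV
#'
#' @param x Data frame (list columns are dropped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(x, path) {
  keep <- !vapply(x, is.list, logical(1))
  utils::write.table(x[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
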