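#' Construct an expression matrix container
#'
#' Light S3 container for a genes x samples abundance matrix with a tracked
#' unit and optional gene coordinates (chromosome and 1-based TSS position).
#'
#' @param values numeric matrix, genes in rows, samples in columns; rownames
#'   are gene ids, colnames are sample ids.
#' @param unit one of `"rpkm"`, `"tpm"`, `"log2tpm"`, `"zscore"`.
#' @param gene_coords optional data.frame with columns `gene_id`, `chr`,
#'   `tss` (1-based position).
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, unit, gene_coords = NULL) {
  unit <- match.arg(unit, c("rpkm", "tpm", "log2tpm", "zscore"))
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression values must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (!all(is.finite(values)))
    stop("expression values must be finite")
  if (!is.null(gene_coords)) {
    stopifnot(all(c("gene_id", "chr", "tss") %in% names(gene_coords)))
    gene_coords <- gene_coords[gene_coords$gene_id %in% rownames(values), ,
                               drop = FALSE]
  }
  structure(list(values = values, unit = unit, gene_coords = gene_coords),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' Construct a genotype matrix container
#'
#' @param dosages numeric matrix, variants in rows (rownames = variant ids),
#'   samples in columns; values are alt-allele dosages in \[0, 2\].
#' @param chr character vector of chromosome names, one per variant.
#' @param pos integer vector of 1-based positions, one per variant.
#' @return an object of class `genotype_matrix` with per-variant minor
#'   allele frequency in `$maf`.
#' @export
genotype_matrix <- function(dosages, chr, pos) {
  dosages <- as.matrix(dosages)
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop("dosage matrix must carry variant rownames and sample colnames")
  if (anyDuplicated(rownames(dosages))) stop("duplicate variant ids")
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  if (length(chr) != nrow(dosages) || length(pos) != nrow(dosages))
    stop("coordinate vectors must match the number of variants")
  if (any(pos < 1)) stop("positions must be positive 1-based integers")
  af <- rowMeans(dosages, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  structure(list(dosages = dosages, chr = as.character(chr),
                 pos = as.integer(pos), maf = maf),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d variants x %d samples\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Convert RPKM to TPM
#'
#' Per sample, rescales RPKM values to transcripts per million:
#' `tpm[g, s] = rpkm[g, s] / sum_g'(rpkm[g', s]) * 1e6`, so every column of
#' the result sums to one million.
#'
#' @param expr an [expression_matrix] with unit `"rpkm"`.
#' @return an [expression_matrix] with unit `"tpm"`.
#' @export
rpkm_to_tpm <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$unit != "rpkm") stop("input unit must be rpkm")
  if (any(expr$values < 0)) stop("rpkm values must be nonnegative")
  cs <- colSums(expr$values)
  if (any(cs == 0)) {
    bad <- colnames(expr$values)[cs == 0]
    stop(sprintf("sample(s) with all-zero RPKM: %s",
                 paste(bad, collapse = ", ")))
  }
  tpm <- sweep(expr$values, 2, cs, "/") * 1e6
  expression_matrix(tpm, "tpm", expr$gene_coords)
}

#' Per-sample TPM/RPKM scaling factors
#'
#' The scaling factor of a sample is the ratio of its mean TPM to its mean
#' RPKM over all genes. The minimum factor over samples is used as the
#' detection threshold by [filter_low_expression()].
#'
#' @param expr_rpkm,expr_tpm matched [expression_matrix] objects in RPKM and
#'   TPM units, aligned on genes and samples.
#' @return named numeric vector of per-sample factors.
#' @export
scaling_factors <- function(expr_rpkm, expr_tpm) {
  stopifnot(inherits(expr_rpkm, "expression_matrix"),
            inherits(expr_tpm, "expression_matrix"))
  if (!identical(rownames(expr_rpkm$values), rownames(expr_tpm$values)) ||
      !identical(colnames(expr_rpkm$values), colnames(expr_tpm$values)))
    stop("rpkm and tpm matrices must be aligned on genes and samples")
  f <- colMeans(expr_tpm$values) / colMeans(expr_rpkm$values)
  if (any(!is.finite(f) | f <= 0)) stop("scaling factors must be positive")
  f
}

#' Filter genes with low expression
#'
#' A gene is retained when it exceeds the minimum per-sample scaling factor
#' in at least `frac` of samples; genes with strictly fewer such samples are
#' excluded. Gene order is preserved.
#'
#' @param expr_tpm an [expression_matrix] with unit `"tpm"`.
#' @param factors per-sample scaling factors from [scaling_factors()].
#' @param frac minimum fraction of samples above threshold (default 0.05).
#' @return filtered [expression_matrix].
#' @export
filter_low_expression <- function(expr_tpm, factors, frac = 0.05) {
  stopifnot(inherits(expr_tpm, "expression_matrix"))
  if (expr_tpm$unit != "tpm") stop("input unit must be tpm")
  if (frac <= 0 || frac > 1) stop("frac must lie in (0, 1]")
  thr <- min(factors)
  n <- ncol(expr_tpm$values)
  need <- ceiling(frac * n - 1e-9)
  keep <- rowSums(expr_tpm$values > thr) >= need
  expression_matrix(expr_tpm$values[keep, , drop = FALSE], "tpm",
                    expr_tpm$gene_coords)
}

#' Log2-transform TPM values
#'
#' @param expr_tpm an [expression_matrix] with nonnegative values.
#' @param pseudocount added before the log to keep zeros finite
#'   (default 1e-3 TPM).
#' @return an [expression_matrix] with unit `"log2tpm"`.
#' @export
log2_transform <- function(expr_tpm, pseudocount = 1e-3) {
  stopifnot(inherits(expr_tpm, "expression_matrix"))
  if (any(expr_tpm$values < 0)) stop("values must be nonnegative")
  expression_matrix(log2(expr_tpm$values + pseudocount), "log2tpm",
                    expr_tpm$gene_coords)
}

#' Read genotypes from a VCF file
#'
#' Reads a VCF v4.2 file into a [genotype_matrix]. The `DS` (dosage) FORMAT
#' field is used when present; otherwise dosage is the alt-allele count from
#' `GT`. Multi-allelic records are skipped with a message.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @return a [genotype_matrix].
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("package 'vcfR' is required to read VCF files")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  biallelic <- !grepl(",", alt) & alt != "."
  n_skip <- sum(!biallelic)
  if (n_skip > 0)
    message(sprintf("skipping %d non-biallelic record(s)", n_skip))
  if (!any(biallelic)) stop("no biallelic records in VCF")
  ids <- unname(fix[biallelic, "ID"])
  if (any(is.na(ids) | ids == "."))
    ids <- ifelse(is.na(ids) | ids == ".",
                  paste0(fix[biallelic, "CHROM"], ":", fix[biallelic, "POS"]),
                  ids)
  fmt <- v@gt[, 1]
  has_ds <- all(grepl("DS", fmt))
  if (has_ds) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    dos <- ds[biallelic, , drop = FALSE]
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[biallelic, , drop = FALSE]
    cnt <- function(g) {
      if (is.na(g)) return(NA_real_)
      sum(strsplit(gsub("\\|", "/", g), "/")[[1]] == "1")
    }
    dos <- matrix(vapply(gt, cnt, numeric(1)), nrow = nrow(gt),
                  dimnames = dimnames(gt))
  }
  rownames(dos) <- ids
  genotype_matrix(dos, chr = fix[biallelic, "CHROM"],
                  pos = as.integer(fix[biallelic, "POS"]))
}

#' Read / write a feature x sample TSV matrix
#'
#' Tab-separated, UTF-8; header row holds sample ids, first column holds
#' feature ids; missing values are written as `.`.
#'
#' @param path file path.
#' @param x numeric matrix with rownames and colnames.
#' @param digits significant digits used when writing (default 10), so that
#'   write/read round-trips are stable at the printed precision.
#' @return `read_matrix_tsv` returns a numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   na.strings = ".", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(x, path, digits = 10) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  out <- format(signif(x, digits), trim = TRUE, scientific = FALSE,
                digits = 15)
  out[is.na(x)] <- "."
  df <- data.frame(id = rownames(x), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("id", colnames(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' Requires columns `variant_id`, `chr`, `pos`, `beta`, `se`, `p`. When both
#' effect size and p-value are present, rows where `p` disagrees with
#' `2 * pnorm(-|beta / se|)` by more than `tol` are flagged in the logical
#' column `p_inconsistent`.
#'
#' @param path TSV file path.
#' @param tol numerical tolerance on the p/z consistency check.
#' @return data.frame of class `gwas_summary`.
#' @export
read_gwas_tsv <- function(path, tol = 1e-6) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  req <- c("variant_id", "chr", "pos", "beta", "se", "p")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("GWAS TSV missing column(s): %s", paste(miss, collapse = ", ")))
  if (any(df$se <= 0, na.rm = TRUE)) stop("GWAS se must be positive")
  if (any(df$p <= 0 | df$p > 1, na.rm = TRUE)) stop("GWAS p must lie in (0, 1]")
  p_theory <- 2 * pnorm(-abs(df$beta / df$se))
  df$p_inconsistent <- is.finite(p_theory) & abs(df$p - p_theory) > tol
  class(df) <- c("gwas_summary", "data.frame")
  df
}

#' Read an expression-regulator gene list
#'
#' One gene id per line (or the first column of a TSV); comment lines
#' starting with `#` are ignored.
#'
#' @param path file path.
#' @return character vector of unique gene ids.
#' @export
read_regulator_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  ids <- vapply(strsplit(lines, "\t"), `[[`, character(1), 1)
  unique(ids)
}

#' Assemble a QTL covariate matrix
#'
#' Combines age (from a phenotype table) with the top genotype principal
#' components into a samples x covariates matrix aligned on shared samples.
#'
#' @param pheno data.frame with columns `sample_id` and `age`.
#' @param pcs matrix of genotype PC scores (samples x PCs) from
#'   [genotype_pcs()].
#' @return numeric matrix with rownames = sample ids.
#' @export
assemble_covariates <- function(pheno, pcs) {
  stopifnot("sample_id" %in% names(pheno), "age" %in% names(pheno))
  shared <- intersect(pheno$sample_id, rownames(pcs))
  if (!length(shared)) stop("no shared samples between phenotype table and PCs")
  age <- pheno$age[match(shared, pheno$sample_id)]
  cbind(age = age, pcs[shared, , drop = FALSE])
}
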