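# LD matrices: validation, file loading, and computation from a VCF
# reference panel. An LD matrix is a plain numeric matrix of pairwise
# genotype correlations r in [-1, 1] with SNP ids as dimnames.

#' Validate an LD matrix
#'
#' Checks squareness, dimension against the SNP list, symmetry and unit
#' diagonal (within `tol`), and attaches SNP ids as dimnames.
#'
#' @param r Square numeric matrix of genotype correlations.
#' @param snp_ids Character vector, one id per row/column.
#' @param tol Tolerance for symmetry and the unit diagonal.
#' @return The validated matrix with dimnames set.
#' @export
as_ld_matrix <- function(r, snp_ids = rownames(r), tol = 1e-6) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square")
  if (is.null(snp_ids) || length(snp_ids) != nrow(r))
    stop("SNP list length (", length(snp_ids),
         ") does not match LD dimension (", nrow(r), ")")
  if (any(abs(r - t(r)) > tol)) stop("LD matrix asymmetric beyond tolerance ", tol)
  if (any(abs(diag(r) - 1) > tol)) stop("LD diagonal differs from 1 beyond tolerance ", tol)
  if (any(abs(r) > 1 + tol)) stop("LD entries outside [-1, 1]")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(snp_ids, snp_ids)
  r
}

#' Load an LD matrix from files
#'
#' @param matrix_file Whitespace-delimited square matrix, no header.
#' @param snp_file One SNP id per line, ordered as the matrix rows.
#' @param tol Validation tolerance.
#' @return Validated LD matrix.
#' @export
load_ld <- function(matrix_file, snp_file, tol = 1e-6) {
  r <- as.matrix(data.table::fread(matrix_file, header = FALSE,
                                   data.table = FALSE, showProgress = FALSE))
  snps <- readLines(snp_file)
  snps <- snps[nzchar(snps)]
  as_ld_matrix(unname(r), snps, tol = tol)
}

#' Compute LD from a VCF reference panel
#'
#' Reads biallelic genotypes from a VCF (v4.x), converts GT fields to
#' ALT-allele dosages, and returns the Pearson correlation matrix of
#' dosages. Multiallelic and monomorphic sites are skipped with a warning;
#' requested SNPs absent from the VCF are reported via the
#' `"missing_snps"` attribute.
#'
#' @param vcf_path Path to a VCF file.
#' @param snp_ids Optional ids to restrict to (in this order where present).
#' @return LD matrix with attribute `"missing_snps"`.
#' @export
ld_from_genotypes <- function(vcf_path, snp_ids = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  ids <- v@fix[, "ID"]
  alt <- v@fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    warning(sum(multi), " multiallelic site(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt)) || ncol(gt) < 2) stop("need at least 2 samples to compute LD")
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  ids <- ids[keep]
  # dosage = number of ALT alleles in the GT string
  dos <- matrix(0L, nrow(gt), ncol(gt))
  for (j in seq_len(ncol(gt))) {
    g <- gt[, j]
    dos[, j] <- vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), integer(1))
    dos[is.na(g), j] <- NA_integer_
  }
  rownames(dos) <- ids
  missing <- character(0)
  if (!is.null(snp_ids)) {
    missing <- setdiff(snp_ids, ids)
    dos <- dos[ids %in% snp_ids, , drop = FALSE]
    dos <- dos[match(intersect(snp_ids, rownames(dos)), rownames(dos)), , drop = FALSE]
  }
  vars <- apply(dos, 1, stats::var, na.rm = TRUE)
  mono <- !is.finite(vars) | vars == 0
  if (any(mono)) {
    warning("dropping ", sum(mono), " monomorphic site(s): ",
            paste(rownames(dos)[mono], collapse = ", "))
    dos <- dos[!mono, , drop = FALSE]
  }
  if (nrow(dos) == 0L) stop("no usable sites left for LD computation")
  r <- stats::cor(t(dos), use = "pairwise.complete.obs")
  diag(r) <- 1
  r <- as_ld_matrix(r, rownames(dos))
  attr(r, "missing_snps") <- missing
  r
}

# Submatrix for a set of SNPs, in the given order; ids absent from the
# matrix are silently dropped.
ld_submatrix <- function(ld, snps) {
  snps <- intersect(snps, rownames(ld))
  ld[snps, snps, drop = FALSE]
}
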