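# Reading, validation and genomic subsetting of GWAS / eQTL summary statistics.
#
# Canonical column set used everywhere downstream:
#   snp, chr, pos, ea, oa, eaf, beta, se, p, n  [, gene, context]
# Coordinates are 1-based GRCh37; alleles are upper-case A/C/G/T; beta is the
# effect per copy of the effect allele (ea).

CANONICAL_FIELDS <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "p", "n")

#' Column mapping for summary-statistics files
#'
#' Describes how the columns of an input file map onto the canonical field
#' names, which strings denote missing values, and the p-value underflow
#' floor. Required fields for a GWAS table are snp, chr, pos, ea, oa, beta,
#' se, p, n; an eQTL table additionally requires gene and context. `eaf` is
#' optional at read time, but a palindromic variant without an allele
#' frequency cannot be resolved during harmonization and will be dropped
#' there.
#'
#' @param snp,chr,pos,ea,oa,eaf,beta,se,p,n Input column headers for the
#'   canonical fields.
#' @param gene,context Input headers for the eQTL-only fields.
#' @param na_strings Strings treated as missing values.
#' @param p_floor P-values below this (including underflow to 0) are floored
#'   here so that downstream log transforms stay finite.
#' @return A list of class `"colmap"`.
#' @export
colmap <- function(snp = "snp", chr = "chr", pos = "pos", ea = "ea", oa = "oa",
                   eaf = "eaf", beta = "beta", se = "se", p = "p", n = "n",
                   gene = "gene", context = "context",
                   na_strings = c("NA", "", ".", "nan", "NaN"),
                   p_floor = 1e-300) {
  structure(list(snp = snp, chr = chr, pos = pos, ea = ea, oa = oa, eaf = eaf,
                 beta = beta, se = se, p = p, n = n, gene = gene,
                 context = context, na_strings = na_strings,
                 p_floor = p_floor),
            class = "colmap")
}

strip_chr_prefix <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))

#' Read and validate a summary-statistics table
#'
#' Reads a delimited (tab or comma, gzip-transparent) summary-statistics file,
#' renames columns through a [colmap()], upper-cases alleles, floors
#' underflowed p-values, and drops rows violating the record invariants
#' (non-ACGT or identical alleles, `se <= 0`, `p` outside (0,1], `pos < 1`,
#' `eaf` outside [0,1], `n <= 0`, or missing required values). Duplicate SNP
#' ids keep the record with the smallest p-value. Drop counts by reason are
#' attached as attribute `"drop_log"`.
#'
#' @param path File path (plain or gzipped, with header).
#' @param map A [colmap()].
#' @param kind `"gwas"` or `"eqtl"`; an eQTL table must also carry gene and
#'   context columns.
#' @return A `data.frame` in canonical column order.
#' @export
read_sumstats <- function(path, map = colmap(), kind = c("gwas", "eqtl")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- data.table::fread(path, na.strings = map$na_strings,
                           data.table = FALSE, showProgress = FALSE)
  required <- c("snp", "chr", "pos", "ea", "oa", "beta", "se", "p", "n")
  if (kind == "eqtl") required <- c(required, "gene", "context")
  for (f in required) {
    if (!(map[[f]] %in% names(raw)))
      stop("column '", map[[f]], "' (canonical field '", f,
           "') not found in ", path)
  }
  fields <- c(CANONICAL_FIELDS, if (kind == "eqtl") c("gene", "context"))
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (f in fields) {
    out[[f]] <- if (map[[f]] %in% names(raw)) raw[[map[[f]]]] else NA
  }
  validate_sumstats(out, kind = kind, p_floor = map$p_floor)
}

# Validation shared by the reader and the simulator round-trip. Returns the
# cleaned data frame with a "drop_log" attribute of counts per reason.
validate_sumstats <- function(x, kind = c("gwas", "eqtl"), p_floor = 1e-300) {
  kind <- match.arg(kind)
  x$snp <- as.character(x$snp)
  x$chr <- strip_chr_prefix(x$chr)
  x$pos <- suppressWarnings(as.integer(x$pos))
  x$ea <- toupper(as.character(x$ea))
  x$oa <- toupper(as.character(x$oa))
  for (f in c("eaf", "beta", "se", "p")) x[[f]] <- suppressWarnings(as.numeric(x[[f]]))
  x$n <- suppressWarnings(as.numeric(x$n))
  # p-value underflow: "0" or "1e-320" style entries are floored, not dropped
  x$p[!is.na(x$p) & x$p >= 0 & x$p < p_floor] <- p_floor

  drop <- list(
    missing_core = is.na(x$snp) | is.na(x$chr) | is.na(x$pos) | is.na(x$ea) |
      is.na(x$oa) | is.na(x$beta) | is.na(x$se) | is.na(x$p) | is.na(x$n),
    bad_alleles = !grepl("^[ACGT]+$", x$ea) | !grepl("^[ACGT]+$", x$oa) |
      x$ea == x$oa,
    nonpositive_se = !is.na(x$se) & x$se <= 0,
    bad_p = !is.na(x$p) & (x$p <= 0 | x$p > 1),
    bad_pos = !is.na(x$pos) & x$pos < 1,
    bad_eaf = !is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1),
    nonpositive_n = !is.na(x$n) & x$n <= 0
  )
  if (kind == "eqtl") {
    drop$missing_gene <- is.na(x$gene) | is.na(x$context)
  }
  bad <- Reduce(`|`, lapply(drop, function(v) v & !is.na(v)))
  bad[is.na(bad)] <- TRUE
  log <- vapply(drop, function(v) sum(v & !is.na(v)), integer(1))
  x <- x[!bad, , drop = FALSE]

  # duplicate snp ids (within gene/context for eQTL): keep smallest p
  if (nrow(x)) {
    key <- if (kind == "eqtl") paste(x$snp, x$gene, x$context) else x$snp
    ord <- order(x$p, x$snp)
    x <- x[ord, , drop = FALSE]
    dup <- duplicated(key[ord])
    log <- c(log, duplicate_snp = sum(dup))
    x <- x[!dup, , drop = FALSE]
    x <- x[order(x$chr, x$pos, x$snp), , drop = FALSE]
  } else {
    log <- c(log, duplicate_snp = 0L)
  }
  if (nrow(x) == 0L) stop("no valid summary-statistic rows after validation")
  rownames(x) <- NULL
  attr(x, "drop_log") <- log
  x
}

#' Write a canonical summary-statistics TSV
#'
#' @param x A canonical summary-statistics data frame.
#' @param path Output path.
#' @export
write_sumstats <- function(x, path) {
  cols <- intersect(c(CANONICAL_FIELDS, "gene", "context"), names(x))
  utils::write.table(format(x[cols], digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genomic region
#'
#' Constructs a region from 1-based inclusive coordinates (the GWAS
#' convention); internally the region is half-open `[start, end)`. An
#' optional symmetric flank widens the region on both sides, clamped at
#' position 1.
#'
#' @param chrom Chromosome (with or without "chr" prefix).
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @param flank Bases added to both sides (e.g. 1e5 for the cis window).
#' @param anchor_gene Optional gene id the region is anchored on.
#' @return A list of class `"region"` with half-open `start`/`end`.
#' @export
region <- function(chrom, start, end, flank = 0, anchor_gene = NULL) {
  stopifnot(length(chrom) == 1, start <= end, start >= 1, flank >= 0)
  structure(list(chrom = strip_chr_prefix(chrom),
                 start = max(1, start - flank),
                 end = end + 1 + flank,        # half-open
                 anchor_gene = anchor_gene),
            class = "region")
}

#' Subset records to a region
#'
#' Keeps exactly the records on the region's chromosome with
#' `start <= pos < end` under the half-open internal convention.
#'
#' @param x Canonical summary-statistics data frame.
#' @param reg A [region()].
#' @return The subset, possibly empty.
#' @export
extract_region <- function(x, reg) {
  stopifnot(inherits(reg, "region"))
  keep <- strip_chr_prefix(x$chr) == reg$chrom & x$pos >= reg$start & x$pos < reg$end
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude the MHC region
#'
#' Removes variants in the extended MHC, chr6:28477797-33448354 (GRCh37,
#' closed interval), where extreme LD makes fine-mapping and colocalization
#' unreliable.
#'
#' @param x Canonical summary-statistics data frame.
#' @param start,end Closed-interval bounds on chromosome 6.
#' @return `x` without MHC variants.
#' @export
exclude_mhc <- function(x, start = 28477797, end = 33448354) {
  drop <- strip_chr_prefix(x$chr) == "6" & x$pos >= start & x$pos <= end
  out <- x[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
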