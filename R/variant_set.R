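#' Multi-sample variant set
#'
#' In-memory representation of a multi-sample SNP matrix: per-site fields
#' (`chrom`, `pos` 1-based, `id`, `ref`, `alt`, `qual`) and three
#' site-by-sample matrices: `gt` (genotype strings such as `"0/0"`,
#' `"0/1"`; `NA` = missing/masked), `dp` (read depth) and `gq`
#' (phred-scaled genotype quality). Built from a vcfR object or by the
#' simulator.
#'
#' @param chrom,pos,ref,alt,qual per-site vectors (`alt` may hold
#'   comma-separated alternates).
#' @param gt,dp,gq site-by-sample matrices; columns named by sample.
#' @param id optional site identifiers.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(chrom, pos, ref, alt, qual, gt, dp = NULL, gq = NULL,
                        id = NULL) {
  n <- length(chrom)
  gt <- as.matrix(gt)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n,
            length(qual) == n, nrow(gt) == n)
  if (is.null(colnames(gt))) stop("gt matrix needs sample column names")
  if (is.null(dp)) dp <- matrix(NA_integer_, n, ncol(gt),
                                dimnames = dimnames(gt))
  if (is.null(gq)) gq <- matrix(NA_integer_, n, ncol(gt),
                                dimnames = dimnames(gt))
  if (is.null(id)) id <- rep(".", n)
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 id = as.character(id), ref = as.character(ref),
                 alt = as.character(alt), qual = as.numeric(qual),
                 gt = gt, dp = as.matrix(dp), gq = as.matrix(gq)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", n_sites(x), "sites x", length(samples(x)),
      "samples\n")
  invisible(x)
}

#' @rdname variant_set
#' @param x a `variant_set`.
#' @export
n_sites <- function(x) length(x$chrom)

#' @rdname variant_set
#' @export
samples <- function(x) colnames(x$gt)

#' Subset a variant set by site or sample
#'
#' @param x a `variant_set`.
#' @param sites logical or integer site index.
#' @param keep_samples character vector of sample names to keep.
#' @return A `variant_set`.
#' @export
subset_sites <- function(x, sites) {
  variant_set(x$chrom[sites], x$pos[sites], x$ref[sites], x$alt[sites],
              x$qual[sites], x$gt[sites, , drop = FALSE],
              x$dp[sites, , drop = FALSE], x$gq[sites, , drop = FALSE],
              id = x$id[sites])
}

#' @rdname subset_sites
#' @export
subset_samples <- function(x, keep_samples) {
  variant_set(x$chrom, x$pos, x$ref, x$alt, x$qual,
              x$gt[, keep_samples, drop = FALSE],
              x$dp[, keep_samples, drop = FALSE],
              x$gq[, keep_samples, drop = FALSE], id = x$id)
}

#' Convert between variant_set and vcfR
#'
#' `as_variant_set()` extracts GT/DP/GQ from a [vcfR::vcfR] object;
#' `as_vcfR()` builds a vcfR object (FORMAT `GT:DP:GQ`, missing genotypes
#' written `./.`) suitable for [vcfR::write.vcf()].
#'
#' @param v a `vcfR` object.
#' @return `as_variant_set()`: a `variant_set`; `as_vcfR()`: a `vcfR`.
#' @export
as_variant_set <- function(v) {
  fix <- v@fix
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  gt[gt %in% c("./.", ".", ".|.")] <- NA_character_
  gt <- gsub("|", "/", gt, fixed = TRUE)
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  qual[is.na(qual)] <- 0
  rownames(gt) <- rownames(dp) <- rownames(gq) <- NULL
  variant_set(fix[, "CHROM"], as.integer(fix[, "POS"]), fix[, "REF"],
              fix[, "ALT"], qual, gt, dp, gq, id = fix[, "ID"])
}

#' @rdname as_variant_set
#' @param x a `variant_set`.
#' @param contig_lengths optional named vector for `##contig` header lines.
#' @importClassesFrom vcfR vcfR
#' @export
as_vcfR <- function(x, contig_lengths = NULL) {
  n <- n_sites(x)
  fix <- cbind(CHROM = x$chrom, POS = as.character(x$pos), ID = x$id,
               REF = x$ref, ALT = x$alt,
               QUAL = trimws(formatC(x$qual, format = "g", digits = 8)),
               FILTER = rep(".", n), INFO = rep(".", n))
  gt_chr <- x$gt
  gt_chr[is.na(gt_chr)] <- "./."
  fmt <- function(m) {
    m <- format(m, trim = TRUE)
    m[grepl("NA", m)] <- "."
    m
  }
  cells <- matrix(paste(gt_chr, fmt(x$dp), fmt(x$gq), sep = ":"),
                  nrow = n, ncol = ncol(x$gt))
  dimnames(cells) <- dimnames(x$gt)
  gt <- cbind(FORMAT = rep("GT:DP:GQ", n), cells)
  meta <- c("##fileformat=VCFv4.2",
            "##source=capcore",
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
            '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
            '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">')
  if (!is.null(contig_lengths))
    meta <- c(meta, sprintf("##contig=<ID=%s,length=%d>",
                            names(contig_lengths),
                            as.integer(contig_lengths)))
  methods::new("vcfR", meta = meta, fix = fix, gt = gt)
}

#' Read / write a variant set as VCF
#'
#' Thin wrappers over vcfR; `write_variant_vcf()` emits a gzip-compressed
#' VCF 4.2 with FORMAT `GT:DP:GQ`.
#'
#' @param path VCF path (plain or gzipped for reading; `.vcf.gz` written).
#' @return `read_variant_vcf()` returns a `variant_set`.
#' @export
read_variant_vcf <- function(path) {
  as_variant_set(vcfR::read.vcfR(path, verbose = FALSE))
}

#' @rdname read_variant_vcf
#' @param x a `variant_set`.
#' @param contig_lengths optional named vector for `##contig` lines.
#' @export
write_variant_vcf <- function(x, path, contig_lengths = NULL) {
  vcfR::write.vcf(as_vcfR(x, contig_lengths), file = path)
  invisible(path)
}
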