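# SAM flag bits
FLAG_PAIRED <- 0x1L
FLAG_PROPER_PAIR <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_MATE_UNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_MATE_REVERSE <- 0x20L
FLAG_FIRST <- 0x40L
FLAG_SECOND <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_DUP <- 0x400L
FLAG_SUPPLEMENTARY <- 0x800L

has_flag <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

#' Reference span consumed by a CIGAR string
#'
#' Sums the lengths of the operations that consume reference bases
#' (M, =, X, D, N); insertions, clips and padding do not advance the
#' reference coordinate.
#'
#' @param cigar character vector of CIGAR strings ("*" allowed, width 0).
#' @return Integer vector of reference widths.
#' @export
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
    if (!length(ops) || sum(nchar(ops)) != nchar(cg))
      stop("malformed CIGAR: ", cg)
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- substr(ops, nchar(ops), nchar(ops))
    sum(n[op %in% c("M", "=", "X", "D", "N")])
  }, 1L, USE.NAMES = FALSE)
}

#' Read alignment records from SAM text
#'
#' Parses the eleven mandatory SAM columns into an alignment-record table.
#' Positions are converted to the package-wide 0-based half-open
#' convention: `pos` is the leftmost aligned base (0-based) and `aln_end`
#' the exclusive end of the reference span implied by the CIGAR. Flag bits
#' are unpacked into logical columns.
#'
#' @param path path to a SAM text file (header lines are skipped).
#' @return A data.frame with columns `read_id`, `flag`, `chrom`, `pos`,
#'   `aln_end`, `mapq`, `cigar`, `mate_chrom`, `mate_pos`, `seq`, `qual`
#'   and logicals `is_paired`, `is_proper_pair`, `is_unmapped`,
#'   `is_reverse`, `is_first`, `is_secondary`, `is_supplementary`,
#'   `is_duplicate`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 11L
  if (any(short))
    stop("SAM record with fewer than 11 fields at line ", which(short)[1])
  col <- function(i) vapply(fields, `[[`, "", i)
  flag <- as.integer(col(2))
  pos1 <- as.integer(col(4))
  cigar <- col(6)
  alignments(
    read_id = col(1), flag = flag, chrom = col(3), pos = pos1 - 1L,
    aln_end = pos1 - 1L + cigar_ref_width(cigar),
    mapq = as.integer(col(5)), cigar = cigar,
    mate_chrom = col(7), mate_pos = as.integer(col(8)) - 1L,
    seq = col(10), qual = col(11))
}

alignments <- function(read_id, flag, chrom, pos, aln_end, mapq, cigar,
                       mate_chrom, mate_pos, seq, qual) {
  data.frame(
    read_id = read_id, flag = flag, chrom = chrom, pos = pos,
    aln_end = aln_end, mapq = mapq, cigar = cigar,
    mate_chrom = mate_chrom, mate_pos = mate_pos, seq = seq, qual = qual,
    is_paired = has_flag(flag, FLAG_PAIRED),
    is_proper_pair = has_flag(flag, FLAG_PROPER_PAIR),
    is_unmapped = has_flag(flag, FLAG_UNMAPPED),
    is_reverse = has_flag(flag, FLAG_REVERSE),
    is_first = has_flag(flag, FLAG_FIRST),
    is_secondary = has_flag(flag, FLAG_SECONDARY),
    is_supplementary = has_flag(flag, FLAG_SUPPLEMENTARY),
    is_duplicate = has_flag(flag, FLAG_DUP),
    stringsAsFactors = FALSE)
}

empty_alignments <- function() {
  alignments(character(), integer(), character(), integer(), integer(),
             integer(), character(), character(), integer(), character(),
             character())
}

#' Record-level alignment filters
#'
#' Applies the predicates used before zone extraction: duplicate removal,
#' proper-pair requirement, exclusion of secondary/supplementary
#' alignments, and a mapping-quality floor (records with MAPQ strictly
#' below `min_mapq` are removed). Unmapped records are always removed when
#' any predicate is enabled with `drop_unmapped = TRUE` (the default).
#' Counts removed by each predicate are attached as attribute
#' `"filter_counts"` for the per-sample read report.
#'
#' @param records alignment table from [read_sam()].
#' @param drop_duplicates remove duplicate-flagged records.
#' @param require_proper_pair keep only properly paired records.
#' @param drop_secondary_supplementary remove non-primary alignments.
#' @param min_mapq MAPQ floor, or `NULL` to disable.
#' @param drop_unmapped remove unmapped records.
#' @return Filtered alignment table; attribute `filter_counts` is a named
#'   integer vector of records removed per predicate (applied in order).
#' @export
filter_alignments <- function(records, drop_duplicates = FALSE,
                              require_proper_pair = FALSE,
                              drop_secondary_supplementary = FALSE,
                              min_mapq = NULL, drop_unmapped = TRUE) {
  counts <- c(raw = nrow(records))
  if (drop_unmapped) {
    keep <- !records$is_unmapped
    counts <- c(counts, unmapped = sum(!keep))
    records <- records[keep, , drop = FALSE]
  }
  if (drop_duplicates) {
    keep <- !records$is_duplicate
    counts <- c(counts, duplicate = sum(!keep))
    records <- records[keep, , drop = FALSE]
  }
  if (require_proper_pair) {
    keep <- records$is_proper_pair
    counts <- c(counts, improper_pair = sum(!keep))
    records <- records[keep, , drop = FALSE]
  }
  if (drop_secondary_supplementary) {
    keep <- !(records$is_secondary | records$is_supplementary)
    counts <- c(counts, secondary_supplementary = sum(!keep))
    records <- records[keep, , drop = FALSE]
  }
  if (!is.null(min_mapq)) {
    keep <- records$mapq >= min_mapq
    counts <- c(counts, low_mapq = sum(!keep))
    records <- records[keep, , drop = FALSE]
  }
  counts <- c(counts, retained = nrow(records))
  attr(records, "filter_counts") <- counts
  records
}
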