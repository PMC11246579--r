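#' Assign each alignment to the zone it best overlaps
#'
#' A record is assigned to the zone whose interval overlaps its aligned
#' span `[pos, aln_end)` by the largest number of bases; ties go to the
#' leftmost zone. Records overlapping no zone get `NA`.
#'
#' @param records alignment table ([read_sam()]).
#' @param zone_df zone data.frame (sorted, disjoint per chromosome).
#' @return Character vector of zone names (or `NA`) parallel to `records`.
#' @export
assign_zones <- function(records, zone_df) {
  out <- rep(NA_character_, nrow(records))
  if (!nrow(records) || !nrow(zone_df)) return(out)
  for (ch in unique(records$chrom)) {
    ri <- which(records$chrom == ch)
    zi <- which(zone_df$chrom == ch)
    if (!length(zi)) next
    reads <- IRanges::IRanges(start = records$pos[ri] + 1L,
                              end = records$aln_end[ri])
    zr <- IRanges::IRanges(start = zone_df$start[zi] + 1L,
                           end = zone_df$end[zi])
    hits <- IRanges::findOverlaps(reads, zr)
    if (!length(hits)) next
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(reads[q], zr[s]))
    # largest overlap wins; zones are position-sorted so on a tie the
    # smaller subject index is the leftmost zone
    o <- order(q, -ov, s)
    first <- !duplicated(q[o])
    out[ri[q[o][first]]] <- zone_df$name[zi[s[o][first]]]
  }
  out
}

#' Zone-by-zone extraction of reads with single-end demotion
#'
#' Mate pairs whose two records land in the same zone stay paired; pairs
#' split across two zones are demoted to single-end reads so that the
#' targeted remapping never sees an improperly paired mate. A record whose
#' mate overlaps no zone (or has no mate) is emitted single-end; records
#' overlapping no zone are dropped.
#'
#' @param records alignment table, pre-filtered to primary mapped records
#'   (pairs are identified by shared `read_id`).
#' @param zone_df zone data.frame.
#' @return A list with elements `paired` (data.frame of R1/R2 row indices
#'   into `records` plus the shared zone), `singles` (integer row
#'   indices), `dropped` (count of records in no zone), and
#'   `per_zone_counts` (named integer vector: retained records per zone).
#' @export
extract_reads <- function(records, zone_df) {
  if (any(records$is_secondary | records$is_supplementary))
    stop("secondary/supplementary records must be filtered out before extraction")
  zone <- assign_zones(records, zone_df)
  n_per_id <- table(records$read_id)
  if (any(n_per_id > 2L))
    stop("more than two primary records for read ",
         names(n_per_id)[which(n_per_id > 2L)[1]])
  idx <- split(seq_len(nrow(records)), records$read_id)
  r1 <- integer(); r2 <- integer(); pz <- character()
  singles <- integer(); dropped <- 0L
  for (ii in idx) {
    if (length(ii) == 2L) {
      # order mates first/second for synchronized R1/R2 output
      if (!records$is_first[ii[1]] && records$is_first[ii[2]]) ii <- rev(ii)
      za <- zone[ii[1]]; zb <- zone[ii[2]]
      if (!is.na(za) && !is.na(zb) && za == zb) {
        r1 <- c(r1, ii[1]); r2 <- c(r2, ii[2]); pz <- c(pz, za)
      } else {
        for (k in 1:2) {
          if (is.na(zone[ii[k]])) dropped <- dropped + 1L
          else singles <- c(singles, ii[k])
        }
      }
    } else {
      if (is.na(zone[ii])) dropped <- dropped + 1L
      else singles <- c(singles, ii)
    }
  }
  retained_zones <- c(zone[r1], zone[r2], zone[singles])
  per_zone <- stats::setNames(integer(nrow(zone_df)), zone_df$name)
  tab <- table(retained_zones)
  per_zone[names(tab)] <- as.integer(tab)
  list(paired = data.frame(r1 = r1, r2 = r2, zone = pz,
                           stringsAsFactors = FALSE),
       singles = singles, dropped = dropped, per_zone_counts = per_zone,
       zone_of = zone, records = records)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

reverse_string <- function(x) {
  vapply(strsplit(x, ""), function(s) paste(rev(s), collapse = ""), "")
}

fastq_block <- function(records, rows) {
  if (!length(rows)) return(character())
  seq <- records$seq[rows]
  qual <- records$qual[rows]
  rev <- records$is_reverse[rows]
  if (any(rev)) {
    seq[rev] <- revcomp(seq[rev])
    qual[rev] <- reverse_string(qual[rev])
  }
  as.vector(rbind(paste0("@", records$read_id[rows]), seq, "+", qual))
}

#' Write extracted reads as FASTQ
#'
#' Emits synchronized R1/R2 files for same-zone pairs and a third file for
#' single-end (demoted or unpaired) reads. Reads aligned on the reverse
#' strand are restored to their original orientation (sequence
#' reverse-complemented, quality string reversed). Files are
#' gzip-compressed.
#'
#' @param extraction result of [extract_reads()].
#' @param out_paired_r1,out_paired_r2,out_single output paths (.gz).
#' @return Invisibly, the three paths.
#' @export
write_fastq <- function(extraction, out_paired_r1, out_paired_r2,
                        out_single) {
  rec <- extraction$records
  write_gz <- function(lines, path) {
    con <- gzfile(path, "w")
    on.exit(close(con))
    if (length(lines)) writeLines(lines, con)
  }
  write_gz(fastq_block(rec, extraction$paired$r1), out_paired_r1)
  write_gz(fastq_block(rec, extraction$paired$r2), out_paired_r2)
  write_gz(fastq_block(rec, extraction$singles), out_single)
  invisible(c(out_paired_r1, out_paired_r2, out_single))
}
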