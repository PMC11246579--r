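#' Zone index for coordinate lift-over
#'
#' Bundles the zone table with full-reference chromosome lengths and
#' validates that every zone fits its chromosome and that names are
#' unique.
#'
#' @param zone_df zone data.frame.
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @return An object of class `zone_index`.
#' @export
zone_index <- function(zone_df, chrom_lengths) {
  if (anyDuplicated(zone_df$name))
    stop("duplicate zone name: ", zone_df$name[duplicated(zone_df$name)][1])
  missing_len <- setdiff(zone_df$chrom, names(chrom_lengths))
  if (length(missing_len))
    stop("no chromosome length for ", missing_len[1])
  over <- zone_df$end > chrom_lengths[zone_df$chrom]
  if (any(over))
    stop("zone ", zone_df$name[which(over)[1]], " exceeds chromosome length")
  structure(list(zones = zone_df, chrom_lengths = chrom_lengths),
            class = "zone_index")
}

#' Lift a sub-reference position to the full reference
#'
#' A sub-reference contig named `"{chrom}_{start}_{end}"` (0-based
#' half-open) carries its own offset: 1-based position `sub_pos` on the
#' contig corresponds to 1-based `start + sub_pos` on `chrom`.
#'
#' @param sub_contig sub-reference contig name(s).
#' @param sub_pos 1-based position(s) on the contig.
#' @param index a [zone_index()].
#' @return A data.frame with columns `chrom` and `pos` (1-based).
#' @export
lift_position <- function(sub_contig, sub_pos, index) {
  z <- index$zones
  i <- match(sub_contig, z$name)
  if (anyNA(i))
    stop("unknown sub-reference contig: ", sub_contig[which(is.na(i))[1]])
  sub_pos <- as.integer(sub_pos)
  len <- z$end[i] - z$start[i]
  bad <- sub_pos < 1L | sub_pos > len
  if (any(bad))
    stop("position ", sub_pos[which(bad)[1]], " outside contig ",
         sub_contig[which(bad)[1]], " (length ", len[which(bad)[1]], ")")
  data.frame(chrom = z$chrom[i], pos = z$start[i] + sub_pos,
             stringsAsFactors = FALSE)
}

#' Lift a VCF from sub-reference to full-reference coordinates
#'
#' Rewrites CHROM and POS of every record through [lift_position()],
#' replaces the `##contig` header lines with the full-reference
#' chromosomes (lengths from the index), and re-sorts records by lifted
#' (chrom, pos). All other fields are preserved byte-for-byte.
#'
#' @param v a [vcfR::vcfR] object called against the sub-reference.
#' @param index a [zone_index()].
#' @return A `vcfR` object in full-reference coordinates.
#' @export
lift_vcf <- function(v, index) {
  fix <- v@fix
  if (nrow(fix)) {
    lifted <- lift_position(fix[, "CHROM"], as.integer(fix[, "POS"]), index)
    over <- lifted$pos > index$chrom_lengths[lifted$chrom]
    if (any(over))
      stop("lifted position exceeds chromosome length for record ",
           fix[which(over)[1], "CHROM"], ":", fix[which(over)[1], "POS"])
    fix[, "CHROM"] <- lifted$chrom
    fix[, "POS"] <- as.character(lifted$pos)
    o <- order(fix[, "CHROM"], as.integer(fix[, "POS"]))
    fix <- fix[o, , drop = FALSE]
    v@gt <- v@gt[o, , drop = FALSE]
  }
  v@fix <- fix
  meta <- v@meta[!grepl("^##contig=", v@meta)]
  contig <- sprintf("##contig=<ID=%s,length=%d>",
                    names(index$chrom_lengths),
                    as.integer(index$chrom_lengths))
  # keep contig lines ahead of any trailing header content
  v@meta <- c(meta, contig)
  v
}

#' @rdname lift_vcf
#' @param in_vcf,out_vcf VCF file paths (`out_vcf` written gzipped).
#' @export
lift_vcf_file <- function(in_vcf, out_vcf, index) {
  v <- vcfR::read.vcfR(in_vcf, verbose = FALSE)
  vcfR::write.vcf(lift_vcf(v, index), file = out_vcf)
  invisible(out_vcf)
}
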