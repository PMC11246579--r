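#' Zone tables
#'
#' A zone is a contiguous interval of the full reference that becomes one
#' sub-reference contig. Zones are represented as a data.frame with columns
#' `chrom` (character), `start`/`end` (0-based half-open integers) and
#' `name` (the sub-contig identifier, `"{chrom}_{start}_{end}"`).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open (`end > start`).
#' @param name optional character vector of zone names; derived from the
#'   coordinates when missing.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`.
#' @export
zones <- function(chrom, start, end, name = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(chrom) != length(start) || length(start) != length(end))
    stop("chrom, start and end must have equal length")
  if (any(start < 0L)) stop("zone start must be >= 0")
  bad <- which(end <= start)
  if (length(bad))
    stop("zone end must exceed start (offending interval ", chrom[bad[1]], ":",
         start[bad[1]], "-", end[bad[1]], ")")
  if (is.null(name)) name <- zone_name(chrom, start, end)
  z <- data.frame(chrom = as.character(chrom), start = start, end = end,
                  name = as.character(name), stringsAsFactors = FALSE)
  z <- z[order(z$chrom, z$start), , drop = FALSE]
  rownames(z) <- NULL
  z
}

#' Zone naming convention
#'
#' Sub-reference contigs are named `"{chrom}_{start}_{end}"` using full
#' reference 0-based half-open coordinates, so that a contig name alone
#' carries enough information to lift coordinates back.
#'
#' @param chrom,start,end zone coordinates.
#' @return Character vector of names.
#' @export
zone_name <- function(chrom, start, end) {
  paste(chrom, as.integer(start), as.integer(end), sep = "_")
}

#' Parse a zone name back into coordinates
#'
#' Inverse of [zone_name()]. Chromosome names may themselves contain
#' underscores; the final two underscore-separated fields are taken as the
#' coordinates.
#'
#' @param name character vector of zone names.
#' @return A data.frame with columns `chrom`, `start`, `end`.
#' @export
parse_zone_name <- function(name) {
  m <- regmatches(name, regexec("^(.+)_([0-9]+)_([0-9]+)$", name))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("not a valid zone name: ", name[which(bad)[1]])
  chrom <- vapply(m, `[[`, "", 2L)
  start <- as.integer(vapply(m, `[[`, "", 3L))
  end <- as.integer(vapply(m, `[[`, "", 4L))
  if (any(end <= start))
    stop("zone name with end <= start: ", name[which(end <= start)[1]])
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

#' Mean per-sample depth profile
#'
#' Collapses per-sample per-base depth vectors for one chromosome into the
#' mean coverage per sample at every base, the quantity thresholded during
#' coverage-driven zone calling. The mean is taken over all samples,
#' including samples with zero coverage at the base.
#'
#' @param per_sample_depths named list mapping sample to a non-negative
#'   integer (or numeric) vector of per-base depth, all of one length.
#' @param chrom chromosome name attached to the profile.
#' @return A list with elements `chrom`, `depth` (numeric vector of mean
#'   depth per sample) and `length`.
#' @export
mean_depth_profile <- function(per_sample_depths, chrom = "chr") {
  if (!is.list(per_sample_depths) || length(per_sample_depths) == 0L)
    stop("need at least one sample depth vector")
  lens <- vapply(per_sample_depths, length, 1L)
  if (length(unique(lens)) != 1L)
    stop("depth vectors differ in length: ", paste(unique(lens), collapse = ", "))
  if (any(vapply(per_sample_depths, function(d) any(d < 0), TRUE)))
    stop("depth values must be non-negative")
  depth <- Reduce(`+`, lapply(per_sample_depths, as.numeric)) /
    length(per_sample_depths)
  list(chrom = chrom, depth = depth, length = lens[[1]])
}

#' Call zones from a coverage profile
#'
#' Three-step coverage-driven interval calling: (1) mark every base whose
#' mean depth per sample is at least `min_mean_cov`; (2) merge consecutive
#' marked runs separated by a gap strictly smaller than `min_dist` bp (a gap
#' of exactly `min_dist` does not merge); (3) discard merged regions shorter
#' than `min_length` bp. Bases in the gaps bridged at step 2 become part of
#' the zone, so each zone is one contiguous interval.
#'
#' @param profile a depth profile from [mean_depth_profile()].
#' @param min_mean_cov minimum mean reads per sample per base (default 1).
#' @param min_dist merge runs closer than this many bp (default 100).
#' @param min_length drop merged regions shorter than this (default 100).
#' @return A zone data.frame (possibly zero rows), sorted and disjoint.
#' @export
call_zones <- function(profile, min_mean_cov = 1, min_dist = 100L,
                       min_length = 100L) {
  stopifnot(min_mean_cov >= 0, min_dist >= 0, min_length >= 1)
  marked <- profile$depth >= min_mean_cov
  if (!any(marked))
    return(zones(character(), integer(), integer()))
  r <- rle(marked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths       # 0-based half-open run coordinates
  run_start <- starts[r$values]
  run_end <- ends[r$values]
  # merge runs whose separating gap is strictly below min_dist
  mstart <- run_start[1]
  mend <- run_end[1]
  out_start <- integer()
  out_end <- integer()
  for (i in seq_along(run_start)[-1]) {
    if (run_start[i] - mend < min_dist) {
      mend <- run_end[i]
    } else {
      out_start <- c(out_start, mstart)
      out_end <- c(out_end, mend)
      mstart <- run_start[i]
      mend <- run_end[i]
    }
  }
  out_start <- c(out_start, mstart)
  out_end <- c(out_end, mend)
  keep <- (out_end - out_start) >= min_length
  zones(rep(profile$chrom, sum(keep)), out_start[keep], out_end[keep])
}

#' Merge user-supplied target intervals
#'
#' Unites overlapping or touching intervals on the same chromosome, the
#' normalisation applied to a user BED of targeted regions before
#' sub-reference extraction. Touching half-open intervals (one's end equal
#' to the next's start) are merged.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return A zone data.frame, sorted and disjoint.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L)
    return(zones(character(), integer(), integer()))
  bad <- which(intervals$end <= intervals$start)
  if (length(bad))
    stop("interval with end <= start at input line ", bad[1], ": ",
         intervals$chrom[bad[1]], ":", intervals$start[bad[1]], "-",
         intervals$end[bad[1]])
  merged <- lapply(split(intervals, intervals$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, merged)
  zones(m$chrom, m$start, m$end)
}

#' Extract the sub-reference sequences for a set of zones
#'
#' Slices each zone out of the full reference and names the resulting
#' record after the zone, producing the contigs of the sub-reference used
#' for targeted remapping.
#'
#' @param reference a [Biostrings::DNAStringSet] (or named character vector)
#'   of full-reference chromosomes.
#' @param zone_df a zone data.frame.
#' @return A `DNAStringSet` with one record per zone, in zone order.
#' @export
extract_subreference <- function(reference, zone_df) {
  if (!methods::is(reference, "DNAStringSet"))
    reference <- Biostrings::DNAStringSet(reference)
  missing_chrom <- setdiff(zone_df$chrom, names(reference))
  if (length(missing_chrom))
    stop("reference lacks chromosome ", missing_chrom[1])
  lens <- Biostrings::width(reference)[match(zone_df$chrom, names(reference))]
  over <- which(zone_df$end > lens)
  if (length(over))
    stop("zone ", zone_df$name[over[1]], " extends beyond chromosome end (",
         lens[over[1]], " bp)")
  if (nrow(zone_df) == 0L)
    return(Biostrings::DNAStringSet())
  sub <- Biostrings::subseq(reference[zone_df$chrom],
                            start = zone_df$start + 1L, end = zone_df$end)
  names(sub) <- zone_df$name
  sub
}

#' @rdname read_bed
#' @param zone_df zone data.frame to write; column 4 carries the zone name.
#' @export
write_bed <- function(zone_df, path) {
  utils::write.table(zone_df[, c("chrom", "start", "end", "name")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read and write zone BED files
#'
#' BED is tab-separated, 0-based half-open, with at least three columns;
#' a fourth column, when present, is used as the zone name.
#'
#' @param path file path.
#' @return `read_bed()` returns a zone data.frame.
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(d) < 3L) stop("BED file needs at least 3 columns: ", path)
  name <- if (ncol(d) >= 4L) d[[4]] else NULL
  zones(d[[1]], as.integer(d[[2]]), as.integer(d[[3]]), name = name)
}

#' Read a per-base depth table
#'
#' Three tab-separated columns: chromosome, 0-based position, depth. Returns
#' a full-length depth vector per chromosome (positions absent from the
#' table get depth 0), given the chromosome lengths.
#'
#' @param path TSV file path.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return Named list mapping chromosome to a numeric depth vector.
#' @export
read_depth_tsv <- function(path, chrom_lengths) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "pos0", "depth"))
  lapply(stats::setNames(names(chrom_lengths), names(chrom_lengths)),
         function(ch) {
           v <- numeric(chrom_lengths[[ch]])
           rows <- d[d$chrom == ch, ]
           if (any(rows$pos0 >= chrom_lengths[[ch]] | rows$pos0 < 0))
             stop("depth position outside chromosome ", ch)
           v[rows$pos0 + 1L] <- rows$depth
           v
         })
}
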