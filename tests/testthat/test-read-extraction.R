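mk_rec <- function(read_id, chrom, pos, len = 100L, flag = 0L, mapq = 60L,
                   seq = NULL, qual = NULL) {
  if (is.null(seq)) seq <- strrep("A", len)
  if (is.null(qual)) qual <- strrep("I", len)
  capcore:::alignments(read_id, flag, chrom, pos, pos + len, mapq,
                       paste0(len, "M"), chrom, pos, seq, qual)
}

test_that("CIGAR reference width counts M/=/X/D/N only", {
  expect_equal(cigar_ref_width("100M"), 100L)
  expect_equal(cigar_ref_width(c("50M10D50M", "10S90M", "30M5I30M")),
               c(110L, 90L, 60L))
  expect_equal(cigar_ref_width("*"), 0L)
  expect_error(cigar_ref_width("12Q"), "malformed CIGAR")
})

test_that("record filters apply their predicates and log counts", {
  recs <- rbind(mk_rec("a", "c1", 0, flag = 0x400L + 0x1L + 0x2L),
                mk_rec("b", "c1", 10, mapq = 29L, flag = 0x1L + 0x2L),
                mk_rec("c", "c1", 20, mapq = 30L, flag = 0x1L + 0x2L),
                mk_rec("d", "c1", 30, flag = 0x100L + 0x1L + 0x2L),
                mk_rec("e", "c1", 40, flag = 0x1L))
  dup <- filter_alignments(recs, drop_duplicates = TRUE)
  expect_false("a" %in% dup$read_id)
  mq <- filter_alignments(recs, min_mapq = 30L)
  expect_false("b" %in% mq$read_id)
  expect_true("c" %in% mq$read_id)
  # identity when everything is disabled
  off <- filter_alignments(recs, drop_unmapped = FALSE)
  expect_equal(off$read_id, recs$read_id)
  expect_true("d" %in% off$read_id)
  all_on <- filter_alignments(recs, drop_duplicates = TRUE,
                              require_proper_pair = TRUE,
                              drop_secondary_supplementary = TRUE,
                              min_mapq = 30L)
  counts <- attr(all_on, "filter_counts")
  expect_equal(unname(counts[c("raw", "duplicate", "improper_pair",
                               "secondary_supplementary", "low_mapq",
                               "retained")]),
               c(5, 1, 1, 1, 1, 1))
})

test_that("reads are assigned to the zone with the largest overlap", {
  z <- zones(c("c1", "c1"), c(0, 255), c(250, 400))
  contained <- mk_rec("r", "c1", 100, 150)
  expect_equal(assign_zones(contained, z), "c1_0_250")
  spanning <- mk_rec("r", "c1", 240, 20)   # overlap 10 vs 5
  expect_equal(assign_zones(spanning, z), "c1_0_250")
  outside <- mk_rec("r", "c1", 500, 100)
  expect_true(is.na(assign_zones(outside, z)))
})

test_that("extraction keeps same-zone pairs and demotes split pairs", {
  z <- zones(c("c1", "c1"), c(0, 500), c(300, 800))
  pair_flags <- function(first) {
    0x1L + 0x2L + (if (first) 0x40L else 0x80L)
  }
  recs <- rbind(
    mk_rec("both", "c1", 10, flag = pair_flags(TRUE)),
    mk_rec("both", "c1", 150, flag = pair_flags(FALSE)),
    mk_rec("split", "c1", 20, flag = pair_flags(TRUE)),
    mk_rec("split", "c1", 600, flag = pair_flags(FALSE)),
    mk_rec("lost", "c1", 30, flag = pair_flags(TRUE)),
    mk_rec("lost", "c1", 400, flag = pair_flags(FALSE)))
  ex <- extract_reads(recs, z)
  expect_equal(nrow(ex$paired), 1L)
  expect_equal(recs$read_id[ex$paired$r1], "both")
  expect_equal(ex$paired$zone, "c1_0_300")
  # split pair -> two singles; lost mate -> one single + one dropped
  expect_setequal(recs$read_id[ex$singles], c("split", "split", "lost"))
  expect_equal(ex$dropped, 1L)
  # read conservation
  expect_equal(2 * nrow(ex$paired) + length(ex$singles) + ex$dropped,
               nrow(recs))
  expect_error(extract_reads(rbind(recs, mk_rec("both", "c1", 5,
                                                flag = pair_flags(TRUE))),
                             z),
               "more than two primary records")
})

test_that("FASTQ output restores original read orientation", {
  z <- zones("c1", 0, 300)
  fwd <- mk_rec("f", "c1", 10, 4, seq = "ACGT", qual = "IJKL")
  rev <- mk_rec("r", "c1", 20, 4, flag = 0x10L, seq = "AACC", qual = "IJKL")
  ex <- extract_reads(rbind(fwd, rev), z)
  paths <- c(withr::local_tempfile(fileext = ".fastq.gz"),
             withr::local_tempfile(fileext = ".fastq.gz"),
             withr::local_tempfile(fileext = ".fastq.gz"))
  write_fastq(ex, paths[1], paths[2], paths[3])
  single <- readLines(paths[3])
  i <- which(single == "@f")
  expect_equal(single[i + 1], "ACGT")       # forward strand untouched
  i <- which(single == "@r")
  expect_equal(single[i + 1], "GGTT")       # reverse complement
  expect_equal(single[i + 3], "LKJI")       # reversed qualities
  # empty extraction writes empty files
  ex0 <- extract_reads(capcore:::empty_alignments(), z)
  write_fastq(ex0, paths[1], paths[2], paths[3])
  expect_length(readLines(paths[1]), 0)
})

test_that("SAM text round-trips through write_sam/read_sam", {
  cfg <- sim_config(seed = 5, n_read_pairs = 100L)
  ref <- simulate_reference(cfg)
  aln <- simulate_alignments(cfg, ref$reference, ref$zones)
  path <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln$records, path,
            stats::setNames(Biostrings::width(ref$reference),
                            names(ref$reference)))
  back <- read_sam(path)
  for (col in c("read_id", "flag", "chrom", "pos", "aln_end", "mapq",
                "seq", "qual", "is_reverse", "is_duplicate"))
    expect_identical(back[[col]], aln$records[[col]])
})

test_that("extraction recall is exact on simulated capture reads", {
  cfg <- sim_config(seed = 21, n_read_pairs = 600L, n_straddle_pairs = 8L)
  ref <- simulate_reference(cfg)
  aln <- simulate_alignments(cfg, ref$reference, ref$zones)
  rec <- filter_alignments(aln$records, drop_duplicates = TRUE,
                           require_proper_pair = TRUE,
                           drop_secondary_supplementary = TRUE,
                           min_mapq = 30L)
  ex <- extract_reads(rec, ref$zones)
  truth <- aln$truth[!aln$truth$is_duplicate & !aln$truth$low_mapq, ]
  expect_equal(nrow(ex$paired), sum(truth$category == "in_zone"))
  expect_equal(length(ex$singles), 2 * sum(truth$category == "straddle"))
  expect_equal(ex$dropped, 2 * sum(truth$category == "off_target"))
  # paired entries share one zone; retained records all have a zone
  expect_true(all(!is.na(ex$zone_of[c(ex$paired$r1, ex$paired$r2,
                                      ex$singles)])))
  expect_identical(ex$zone_of[ex$paired$r1], ex$zone_of[ex$paired$r2])
})
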