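#' Simulation configuration
#'
#' One configuration object drives the three fixture generators. Defaults
#' emulate a desk-scale capture experiment on a large selfing-crop genome:
#' sparse zones (a fraction of a percent of the sequence), a high PCR
#' duplicate rate (capture libraries commonly exceed 80 %), four
#' populations of 30 diploid individuals, strong inbreeding near the
#' selfing equilibrium (FIS about 0.92) and moderate divergence.
#'
#' @param seed integer seed; identical config + seed gives identical
#'   output.
#' @param n_chrom,chrom_length reference shape.
#' @param n_zones,zone_length,zone_spacing zone layout; spacing is the
#'   minimum gap between zones (kept at least twice the default merge
#'   distance so simulated zones never merge).
#' @param n_read_pairs,read_length,mean_depth read simulation scale.
#' @param duplicate_rate fraction of pairs flagged as PCR duplicates.
#' @param off_target_rate fraction of pairs placed outside every zone.
#' @param low_mapq_rate fraction of in-zone pairs given MAPQ below 30.
#' @param n_straddle_pairs pairs placed with their two mates in two
#'   different zones (demoted to single-end at extraction).
#' @param populations named integer vector, population label -> number of
#'   diploid individuals.
#' @param target_fst Balding-Nichols divergence among populations.
#' @param inbreeding_f within-population inbreeding coefficient F.
#' @param n_sites number of simulated SNP sites.
#' @param ancestral_maf_range range of the ancestral ALT frequency.
#' @param depth_model mean of the Poisson read depth per genotype.
#' @param gq_slope,gq_sd GQ is `round(gq_slope * DP + noise)` truncated to
#'   `[0, 99]` — only its monotone relation to depth matters.
#' @param n_planted_low_qual,n_planted_excess_het,n_planted_no_minor_hom,n_planted_multiallelic
#'   numbers of sites deliberately violating one filtering rule each.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chrom = 2L, chrom_length = 50000L,
                       n_zones = 20L, zone_length = 300L,
                       zone_spacing = 400L, n_read_pairs = 2000L,
                       read_length = 100L, mean_depth = 5,
                       duplicate_rate = 0.8, off_target_rate = 0.1,
                       low_mapq_rate = 0.05, n_straddle_pairs = 5L,
                       populations = c(DD = 30L, DC = 30L, DP = 30L,
                                       DE = 30L),
                       target_fst = 0.2, inbreeding_f = 0.92,
                       n_sites = 500L, ancestral_maf_range = c(0.1, 0.5),
                       depth_model = 20, gq_slope = 4, gq_sd = 3,
                       n_planted_low_qual = 0L, n_planted_excess_het = 0L,
                       n_planted_no_minor_hom = 0L,
                       n_planted_multiallelic = 0L) {
  cfg <- as.list(environment())
  stopifnot(cfg$seed < 2^31, cfg$duplicate_rate >= 0,
            cfg$duplicate_rate <= 1, cfg$off_target_rate >= 0,
            cfg$off_target_rate <= 1, cfg$inbreeding_f >= 0,
            cfg$inbreeding_f <= 1, cfg$target_fst >= 0, cfg$target_fst < 1,
            cfg$zone_length > 0, cfg$chrom_length > 0,
            !is.null(names(cfg$populations)))
  structure(cfg, class = "sim_config")
}

#' Simulate a reference genome with target zones
#'
#' Random A/C/G/T chromosomes with `n_zones` non-overlapping zones placed
#' at least `zone_spacing` bp apart (round-robin across chromosomes).
#'
#' @param cfg a [sim_config()].
#' @return A list with `reference` (a `DNAStringSet`) and `zones` (zone
#'   data.frame).
#' @export
simulate_reference <- function(cfg) {
  set.seed(cfg$seed)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chrom))
  reference <- Biostrings::DNAStringSet(vapply(chroms, function(ch) {
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE),
          collapse = "")
  }, ""))
  names(reference) <- chroms
  per_chrom <- table(factor(chroms[(seq_len(cfg$n_zones) - 1L) %%
                                     cfg$n_chrom + 1L], levels = chroms))
  zl <- list()
  for (ch in chroms) {
    k <- per_chrom[[ch]]
    if (k == 0L) next
    stride <- cfg$zone_length + cfg$zone_spacing
    if (k * stride > cfg$chrom_length)
      stop("zones do not fit on ", ch, ": need ", k * stride,
           " bp, have ", cfg$chrom_length)
    jitter_max <- cfg$chrom_length - k * stride
    # non-decreasing jitter keeps inter-zone gaps at >= zone_spacing
    starts <- (seq_len(k) - 1L) * stride +
      sort(sample.int(jitter_max + 1L, k, replace = TRUE) - 1L)
    zl[[ch]] <- data.frame(chrom = ch, start = starts,
                           end = starts + cfg$zone_length,
                           stringsAsFactors = FALSE)
  }
  z <- do.call(rbind, zl)
  list(reference = reference, zones = zones(z$chrom, z$start, z$end))
}

sam_flag <- function(paired = TRUE, proper = TRUE, unmapped = FALSE,
                     reverse = FALSE, mate_reverse = FALSE, first = TRUE,
                     duplicate = FALSE) {
  f <- 0L
  if (paired) f <- f + 0x1L
  if (proper) f <- f + 0x2L
  if (unmapped) f <- f + 0x4L
  if (reverse) f <- f + 0x10L
  if (mate_reverse) f <- f + 0x20L
  f <- f + (if (first) 0x40L else 0x80L)
  if (duplicate) f <- f + 0x400L
  f
}

slice_seq <- function(reference, chrom, start0, len) {
  as.character(Biostrings::subseq(reference[[chrom]], start0 + 1L,
                                  start0 + len))
}

#' Simulate capture-like paired-end alignments
#'
#' Emulates enrichment sequencing against the full reference: most pairs
#' fall entirely inside one zone, an `off_target_rate` fraction lands
#' outside every zone, `n_straddle_pairs` pairs have their mates in two
#' different zones (these exercise single-end demotion), a
#' `duplicate_rate` fraction of pairs are exact flagged copies of another
#' pair, and a `low_mapq_rate` fraction of in-zone pairs get MAPQ 10.
#'
#' @param cfg a [sim_config()].
#' @param reference,zone_df from [simulate_reference()].
#' @return A list with `records` (alignment table as from [read_sam()])
#'   and `truth` (per-pair data.frame: `qname`, `category` in
#'   `in_zone`/`straddle`/`off_target`, `zone_r1`, `zone_r2`,
#'   `is_duplicate`, `low_mapq`).
#' @export
simulate_alignments <- function(cfg, reference, zone_df) {
  set.seed(cfg$seed + 1L)
  rl <- cfg$read_length
  stopifnot(cfg$zone_length >= 2L * rl)
  chrom_len <- stats::setNames(Biostrings::width(reference),
                               names(reference))
  chrom_seq <- stats::setNames(as.character(reference), names(reference))
  n_base <- cfg$n_read_pairs
  off <- stats::runif(n_base) < cfg$off_target_rate
  n_in <- sum(!off)

  # one fragment per pair: chrom, start, length, R2 start
  chrom <- character(n_base); fs <- integer(n_base)
  frag <- integer(n_base); mapq <- integer(n_base)
  zone_of_pair <- rep(NA_character_, n_base)
  low <- logical(n_base)

  j <- sample.int(nrow(zone_df), n_in, replace = TRUE)
  zlen <- zone_df$end[j] - zone_df$start[j]
  fmax <- pmin(zlen, 2L * rl + 100L)
  flen <- 2L * rl + as.integer(floor(stats::runif(n_in) * (fmax - 2L * rl + 1L)))
  chrom[!off] <- zone_df$chrom[j]
  frag[!off] <- flen
  fs[!off] <- zone_df$start[j] +
    as.integer(floor(stats::runif(n_in) * (zlen - flen + 1L)))
  low[!off] <- stats::runif(n_in) < cfg$low_mapq_rate
  mapq[!off] <- ifelse(low[!off], 10L, 60L)
  zone_of_pair[!off] <- zone_df$name[j]

  # off-target fragments: rejection-sample until no zone overlap
  todo <- which(off)
  while (length(todo)) {
    ch <- sample(names(chrom_len), length(todo), replace = TRUE)
    fl <- rl * 2L + sample.int(50L, length(todo), replace = TRUE)
    st <- as.integer(floor(stats::runif(length(todo)) *
                             (chrom_len[ch] - fl))) # 0-based start
    ok <- vapply(seq_along(todo), function(i) {
      zch <- zone_df[zone_df$chrom == ch[i], ]
      !nrow(zch) || !any(st[i] < zch$end & st[i] + fl[i] > zch$start)
    }, TRUE)
    idx <- todo[ok]
    chrom[idx] <- ch[ok]; frag[idx] <- fl[ok]; fs[idx] <- st[ok]
    mapq[idx] <- 60L
    todo <- todo[!ok]
  }
  r2_start <- fs + frag - rl
  chrom2 <- chrom
  category <- ifelse(off, "off_target", "in_zone")
  zone_r1 <- zone_of_pair; zone_r2 <- zone_of_pair

  # straddling pairs: mates in two different zones of one chromosome
  multi <- unique(zone_df$chrom[duplicated(zone_df$chrom)])
  for (s in seq_len(cfg$n_straddle_pairs)) {
    ch <- sample(multi, 1L)
    zch <- which(zone_df$chrom == ch)
    j1 <- zch[1L + (s - 1L) %% (length(zch) - 1L)]
    j2 <- zch[which(zch == j1) + 1L]
    s1 <- zone_df$start[j1] +
      sample.int(zone_df$end[j1] - zone_df$start[j1] - rl, 1L) - 1L
    s2 <- zone_df$start[j2] +
      sample.int(zone_df$end[j2] - zone_df$start[j2] - rl, 1L) - 1L
    chrom <- c(chrom, ch); chrom2 <- c(chrom2, ch)
    fs <- c(fs, s1); r2_start <- c(r2_start, s2); frag <- c(frag, NA)
    mapq <- c(mapq, 60L); low <- c(low, FALSE)
    category <- c(category, "straddle")
    zone_r1 <- c(zone_r1, zone_df$name[j1])
    zone_r2 <- c(zone_r2, zone_df$name[j2])
  }
  k <- length(chrom)
  dup <- rep(FALSE, k)

  # PCR duplicates: flagged exact copies of existing non-duplicate pairs;
  # duplicate_rate is the duplicate fraction of the FINAL read set, so
  # k unique pairs need k * rate / (1 - rate) flagged copies
  if (cfg$duplicate_rate >= 1) stop("duplicate_rate must be < 1")
  n_dup <- as.integer(round(k * cfg$duplicate_rate /
                              (1 - cfg$duplicate_rate)))
  src <- sample.int(k, n_dup, replace = TRUE)
  chrom <- c(chrom, chrom[src]); chrom2 <- c(chrom2, chrom2[src])
  fs <- c(fs, fs[src]); r2_start <- c(r2_start, r2_start[src])
  mapq <- c(mapq, mapq[src]); low <- c(low, low[src])
  category <- c(category, category[src])
  zone_r1 <- c(zone_r1, zone_r1[src]); zone_r2 <- c(zone_r2, zone_r2[src])
  dup <- c(dup, rep(TRUE, n_dup))
  k <- k + n_dup
  qname <- sprintf("read%06d", seq_len(k))

  flag1 <- sam_flag(first = TRUE, mate_reverse = TRUE) +
    ifelse(dup, 0x400L, 0L)
  flag2 <- sam_flag(first = FALSE, reverse = TRUE) +
    ifelse(dup, 0x400L, 0L)
  seq1 <- substring(chrom_seq[chrom], fs + 1L, fs + rl)
  seq2 <- substring(chrom_seq[chrom2], r2_start + 1L, r2_start + rl)
  interleave <- function(a, b) as.vector(rbind(a, b))
  records <- alignments(
    read_id = interleave(qname, qname),
    flag = interleave(flag1, flag2),
    chrom = interleave(chrom, chrom2),
    pos = interleave(fs, r2_start),
    aln_end = interleave(fs + rl, r2_start + rl),
    mapq = interleave(mapq, mapq),
    cigar = rep(paste0(rl, "M"), 2L * k),
    mate_chrom = interleave(chrom2, chrom),
    mate_pos = interleave(r2_start, fs),
    seq = interleave(seq1, seq2),
    qual = rep(strrep("I", rl), 2L * k))
  truth <- data.frame(qname = qname, category = category,
                      zone_r1 = zone_r1, zone_r2 = zone_r2,
                      is_duplicate = dup, low_mapq = low,
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Write alignment records as SAM text
#'
#' @param records alignment table.
#' @param path output path.
#' @param chrom_lengths named vector for the `@SQ` header lines.
#' @export
write_sam <- function(records, path, chrom_lengths) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
                  records$read_id, records$flag, records$chrom,
                  records$pos + 1L, records$mapq, records$cigar,
                  ifelse(records$mate_chrom == records$chrom, "=",
                         records$mate_chrom),
                  records$mate_pos + 1L, records$seq, records$qual)
  writeLines(c(header, body), path)
  invisible(path)
}

# Balding-Nichols population frequency given ancestral p and Fst
bn_freq <- function(p_anc, fst, n) {
  if (fst <= 0) return(rep(p_anc, n))
  shape <- (1 - fst) / fst
  stats::rbeta(n, p_anc * shape, (1 - p_anc) * shape)
}

# diploid genotypes (ALT allele count 0/1/2) with inbreeding F
draw_genotypes <- function(p, f, n) {
  probs <- c((1 - p)^2 + f * p * (1 - p),
             2 * p * (1 - p) * (1 - f),
             p^2 + f * p * (1 - p))
  sample(0:2, n, replace = TRUE, prob = probs)
}

gt_string <- function(alt_count) c("0/0", "0/1", "1/1")[alt_count + 1L]

#' Simulate a multi-population genotype matrix with known truth
#'
#' Per site, an ancestral ALT frequency is drawn uniformly from
#' `ancestral_maf_range`, population frequencies diverge under a
#' Balding-Nichols model at `target_fst`, and diploid genotypes are drawn
#' with inbreeding coefficient `inbreeding_f` (probabilities
#' `p^2 + Fpq`, `2pq(1-F)`, `q^2 + Fpq`). DP is Poisson around
#' `depth_model` and GQ increases monotonically with DP. Sites violating
#' individual filtering rules can be planted (low QUAL, all-heterozygous,
#' minor allele never homozygous, a second ALT allele) for cascade
#' bookkeeping tests.
#'
#' @param cfg a [sim_config()].
#' @return A list with `sites` (a `variant_set`), `pop_map` (named
#'   vector), and `truth` (list: per-site `category`, `p_anc`,
#'   `pop_freqs` matrix, plus the configured `inbreeding_f` and
#'   `target_fst`).
#' @export
simulate_genotypes <- function(cfg) {
  set.seed(cfg$seed + 2L)
  pops <- cfg$populations
  sample_names <- unlist(lapply(names(pops), function(lb)
    sprintf("%s_%02d", lb, seq_len(pops[[lb]]))))
  pop_map <- stats::setNames(rep(names(pops), pops), sample_names)
  n_ind <- length(sample_names)
  n_planted <- cfg$n_planted_low_qual + cfg$n_planted_excess_het +
    cfg$n_planted_no_minor_hom + cfg$n_planted_multiallelic
  stopifnot(n_planted <= cfg$n_sites)
  category <- rep("normal", cfg$n_sites)
  if (n_planted > 0L) {
    planted_idx <- sample.int(cfg$n_sites, n_planted)
    category[planted_idx] <- rep(
      c("low_qual", "excess_het", "no_minor_hom", "multiallelic"),
      c(cfg$n_planted_low_qual, cfg$n_planted_excess_het,
        cfg$n_planted_no_minor_hom, cfg$n_planted_multiallelic))
  }
  p_anc <- stats::runif(cfg$n_sites, cfg$ancestral_maf_range[1],
                        cfg$ancestral_maf_range[2])
  pop_freqs <- matrix(unlist(lapply(p_anc, function(p)
    bn_freq(p, cfg$target_fst, length(pops)))), ncol = length(pops),
    byrow = TRUE, dimnames = list(NULL, names(pops)))
  gt <- matrix(NA_character_, cfg$n_sites, n_ind,
               dimnames = list(NULL, sample_names))
  # REF/ALT drawn uniformly over the 6 substitution classes (no Ts/Tv
  # enrichment is modelled; random pairs sit at Ts/Tv = 0.5)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, cfg$n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "",
                USE.NAMES = FALSE)
  qual <- round(stats::runif(cfg$n_sites, 60, 900), 2)
  for (i in seq_len(cfg$n_sites)) {
    g <- unlist(lapply(names(pops), function(lb)
      draw_genotypes(pop_freqs[i, lb], cfg$inbreeding_f, pops[[lb]])))
    if (category[i] == "excess_het") {
      g <- rep(1L, n_ind)                       # every call heterozygous
    } else if (category[i] == "no_minor_hom") {
      g <- rep(0L, n_ind)                       # minor allele only in hets
      g[sample.int(n_ind, max(2L, n_ind %/% 10L))] <- 1L
    }
    row <- gt_string(g)
    if (category[i] == "multiallelic") {        # introduce a second ALT
      row[sample.int(n_ind, max(2L, n_ind %/% 10L))] <- "2/2"
      alt[i] <- paste(alt[i], sample(setdiff(bases, c(ref[i], alt[i])), 1L),
                      sep = ",")
    }
    if (category[i] == "low_qual")
      qual[i] <- round(stats::runif(1, 2, 29), 2)
    gt[i, ] <- row
  }
  dp <- matrix(stats::rpois(cfg$n_sites * n_ind, cfg$depth_model),
               cfg$n_sites, n_ind, dimnames = list(NULL, sample_names))
  gq <- matrix(pmin(99L, pmax(0L, round(cfg$gq_slope * dp +
                                          stats::rnorm(length(dp), 0,
                                                       cfg$gq_sd)))),
               cfg$n_sites, n_ind, dimnames = list(NULL, sample_names))
  vs <- variant_set(chrom = rep("chr1", cfg$n_sites),
                    pos = sort(sample.int(cfg$chrom_length, cfg$n_sites)),
                    ref = ref, alt = alt, qual = qual,
                    gt = gt, dp = dp, gq = gq)
  list(sites = vs, pop_map = pop_map,
       truth = list(category = category, p_anc = p_anc,
                    pop_freqs = pop_freqs,
                    inbreeding_f = cfg$inbreeding_f,
                    target_fst = cfg$target_fst))
}
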