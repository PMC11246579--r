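# Brute-force per-base zone-calling oracle: enumerates marked bases and
# joins them by pairwise distance checks, independent of the rle-based
# implementation.
oracle_call_zones <- function(depth, min_cov, min_dist, min_length,
                              chrom = "chr") {
  marked <- which(depth >= min_cov) - 1L   # 0-based marked positions
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (!length(marked)) return(empty)
  starts <- integer(); ends <- integer()
  s <- marked[1]; e <- marked[1] + 1L
  for (p in marked[-1]) {
    joined <- (p == e) || (p - e < min_dist)   # adjacent, or gap < min_dist
    if (joined) {
      e <- p + 1L
    } else {
      starts <- c(starts, s); ends <- c(ends, e)
      s <- p; e <- p + 1L
    }
  }
  starts <- c(starts, s); ends <- c(ends, e)
  keep <- (ends - starts) >= min_length
  data.frame(chrom = rep(chrom, sum(keep)), start = starts[keep],
             end = ends[keep], stringsAsFactors = FALSE)
}

# depth profile with given marked runs (0-based half-open) at depth 2
profile_from_runs <- function(len, runs, chrom = "chr") {
  d <- numeric(len)
  for (r in runs) d[(r[1] + 1):r[2]] <- 2
  list(chrom = chrom, depth = d, length = len)
}

# small variant_set builder: rows = list of genotype-string vectors
make_vs <- function(rows, qual = NULL, ref = NULL, alt = NULL,
                    dp = 30L, gq = 90L) {
  n <- length(rows)
  ns <- length(rows[[1]])
  gt <- do.call(rbind, rows)
  colnames(gt) <- sprintf("s%02d", seq_len(ns))
  if (is.null(qual)) qual <- rep(100, n)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  variant_set(chrom = rep("chr1", n), pos = seq_len(n) * 10L, ref = ref,
              alt = alt, qual = qual, gt = gt,
              dp = matrix(dp, n, ns, dimnames = dimnames(gt)),
              gq = matrix(gq, n, ns, dimnames = dimnames(gt)))
}
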