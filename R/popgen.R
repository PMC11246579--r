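# Split "a/b" genotype strings into two integer allele columns.
# Missing genotypes give NA rows.
gt_alleles <- function(g) {
  a1 <- suppressWarnings(as.integer(sub("/.*$", "", g)))
  a2 <- suppressWarnings(as.integer(sub("^.*/", "", g)))
  cbind(a1, a2)
}

#' Per-site genotype statistics
#'
#' Computes, from the genotypes observed at one site, the quantities the
#' population-genetic filter needs: number of genotyped diploids `n`, ALT
#' allele frequency `p`, expected heterozygosity `he` (Nei's gene
#' diversity, `2p(1-p)` at a biallelic site, `1 - sum(p_k^2)` in general),
#' observed heterozygosity `ho`, the inbreeding coefficient
#' `fis = 1 - ho/he` clipped to `[-1, 1]` (undefined when `he = 0`), the
#' minor-allele frequency, the number of genotypes homozygous for the
#' minor allele, and the number of distinct alleles observed. The minor
#' allele is the least frequent observed allele; on an exact tie the ALT
#' (higher allele index) is treated as minor.
#'
#' @param g character vector of genotype strings (`"0/0"`, `"0/1"`, ...;
#'   `NA` = missing) for one site, one entry per sample.
#' @return A list with elements `n`, `p`, `he`, `ho`, `fis`, `maf`,
#'   `minor_allele`, `minor_hom_count`, `n_alleles`.
#' @export
site_stats <- function(g) {
  al <- gt_alleles(g)
  ok <- stats::complete.cases(al)
  if (!any(ok)) stop("no non-missing genotype at site")
  al <- al[ok, , drop = FALSE]
  n <- nrow(al)
  freqs <- table(factor(c(al[, 1], al[, 2]))) / (2 * n)
  alleles <- as.integer(names(freqs))
  p <- if ("1" %in% names(freqs)) unname(freqs[["1"]]) else 0
  he <- 1 - sum(freqs^2)
  ho <- mean(al[, 1] != al[, 2])
  fis <- if (he > 0) min(1, max(-1, 1 - ho / he)) else NA_real_
  # minor allele: least frequent; tie broken toward the higher index (ALT)
  o <- order(freqs, -alleles)
  minor <- alleles[o[1]]
  maf <- unname(freqs[o[1]])
  minor_hom <- sum(al[, 1] == minor & al[, 2] == minor)
  list(n = n, p = p, he = he, ho = ho, fis = fis, maf = maf,
       minor_allele = minor, minor_hom_count = minor_hom,
       n_alleles = length(alleles))
}

#' Per-site statistics for every site of a variant set
#'
#' @param x a `variant_set`.
#' @return A data.frame with one row per site (columns as in
#'   [site_stats()], `NA` rows for sites with no genotyped sample).
#' @export
site_stats_table <- function(x) {
  rows <- lapply(seq_len(n_sites(x)), function(i) {
    g <- x$gt[i, ]
    if (all(is.na(gt_alleles(g)[, 1])))
      return(data.frame(n = 0L, p = NA_real_, he = NA_real_, ho = NA_real_,
                        fis = NA_real_, maf = NA_real_,
                        minor_allele = NA_integer_, minor_hom_count = 0L,
                        n_alleles = 0L))
    as.data.frame(site_stats(g))
  })
  cbind(data.frame(chrom = x$chrom, pos = x$pos, stringsAsFactors = FALSE),
        do.call(rbind, rows))
}

#' Equilibrium inbreeding coefficient under partial selfing
#'
#' Weir's selfing-equilibrium formula: with outcrossing rate `t`, the
#' inbreeding coefficient settles at `(1 - t) / (1 + t)`. For a
#' predominantly selfing crop with `t = 0.04` this predicts FIS near 0.92,
#' the basis of the excess-heterozygosity SNP filter.
#'
#' @param t outcrossing rate in `[0, 1]`.
#' @return Expected FIS.
#' @export
expected_fis_selfing <- function(t) {
  if (any(t < 0 | t > 1)) stop("outcrossing rate must lie in [0, 1]")
  (1 - t) / (1 + t)
}

#' Transition/transversion classification and ratio
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine exchanges
#' (A<->G, C<->T); the other four substitution classes are transversions.
#' Random sequencing errors hit the six classes uniformly, giving
#' Ts/Tv = 2/4 = 0.5, whereas genuine SNP sets typically exceed 2 — the
#' ratio is therefore a standard SNP-quality control.
#'
#' @param ref,alt single-base REF and ALT alleles (vectors of equal
#'   length).
#' @return `is_transition()`: logical vector; `tstv_ratio()`: Ts/Tv, or
#'   `NA` with a warning when no transversion is present.
#' @export
is_transition <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
  if (!all(ok)) stop("REF/ALT must be distinct single bases")
  (ref %in% c("A", "G") & alt %in% c("A", "G")) |
    (ref %in% c("C", "T") & alt %in% c("C", "T"))
}

#' @rdname is_transition
#' @export
tstv_ratio <- function(ref, alt) {
  ts <- is_transition(ref, alt)
  n_tv <- sum(!ts)
  if (n_tv == 0L) {
    warning("no transversions: Ts/Tv undefined")
    return(NA_real_)
  }
  sum(ts) / n_tv
}

# Ts/Tv over a variant_set: every single-base REF/ALT allele pair counts
# (comma-separated ALTs expanded); NA when no pair or no transversion.
tstv_of_set <- function(x) {
  if (n_sites(x) == 0L) return(NA_real_)
  alt_list <- strsplit(x$alt, ",", fixed = TRUE)
  ref <- rep(x$ref, lengths(alt_list))
  alt <- unlist(alt_list)
  keep <- nchar(ref) == 1L & nchar(alt) == 1L &
    toupper(ref) %in% c("A", "C", "G", "T") &
    toupper(alt) %in% c("A", "C", "G", "T") & ref != alt
  if (!any(keep)) return(NA_real_)
  ts <- is_transition(ref[keep], alt[keep])
  if (all(ts)) return(NA_real_)
  sum(ts) / sum(!ts)
}

#' Read a sample-to-population assignment table
#'
#' Two tab-separated columns: sample, population. No header.
#'
#' @param path TSV file path.
#' @return Named character vector mapping sample to population.
#' @export
read_pop_map <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("sample", "population"))
  stats::setNames(d$population, d$sample)
}

#' Nucleotide diversity of one population
#'
#' Mean per-site unbiased heterozygosity over the sites with at least
#' `min_per_pop` genotyped individuals in the population:
#' `pi_i = 2 n_i / (2 n_i - 1) * 2 p_i (1 - p_i)` at a biallelic site
#' (general multi-allele form `2n/(2n-1) * (1 - sum p_k^2)`).
#'
#' @param x a `variant_set`.
#' @param pop_map named vector mapping sample to population label.
#' @param population population to summarise.
#' @param min_per_pop minimum genotyped individuals per site (default 10).
#' @return A list with `pi`, `n_sites` (sites entering the mean) and
#'   `population`.
#' @export
nucleotide_diversity <- function(x, pop_map, population, min_per_pop = 10L) {
  members <- names(pop_map)[pop_map == population]
  members <- intersect(members, samples(x))
  if (!length(members)) stop("no samples in population ", population)
  gt <- x$gt[, members, drop = FALSE]
  pis <- apply(gt, 1, function(g) {
    al <- gt_alleles(g)
    al <- al[stats::complete.cases(al), , drop = FALSE]
    n <- nrow(al)
    if (n < min_per_pop) return(NA_real_)
    freqs <- table(c(al[, 1], al[, 2])) / (2 * n)
    (2 * n / (2 * n - 1)) * (1 - sum(freqs^2))
  })
  if (all(is.na(pis)))
    stop("no site with >= ", min_per_pop, " genotyped individuals in ",
         population)
  list(pi = mean(pis, na.rm = TRUE), n_sites = sum(!is.na(pis)),
       population = population)
}

#' Diversity Reduction Index
#'
#' Ratio of nucleotide diversity between the two populations framing a
#' domestication transition, ancestral over derived: values above 1
#' indicate a loss of diversity through the transition, and the larger the
#' value the stronger the loss.
#'
#' @param pi_ancestral,pi_derived nucleotide diversities (`pi_derived`
#'   must be positive).
#' @return The ratio `pi_ancestral / pi_derived`.
#' @export
dri <- function(pi_ancestral, pi_derived) {
  if (any(pi_derived <= 0)) stop("derived-population diversity must be > 0")
  pi_ancestral / pi_derived
}

# Per-site Weir & Cockerham (1984) variance components for two
# populations at a biallelic site. Returns c(a, b, c) or NULL if the
# site is unusable.
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  n_bar <- (n1 + n2) / r
  if (n_bar <= 1) return(NULL)
  nc <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  if (nc <= 0) return(NULL)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / nc) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  c(a = a, b = b, c = h_bar / 2)
}

# allele frequency / heterozygosity / sample size of allele-1 at one site
pop_site_summary <- function(g) {
  al <- gt_alleles(g)
  al <- al[stats::complete.cases(al), , drop = FALSE]
  n <- nrow(al)
  if (n == 0L) return(c(n = 0, p = NA, h = NA, multi = 0))
  obs <- unique(c(al[, 1], al[, 2]))
  c(n = n, p = mean(c(al[, 1], al[, 2]) == 1L),
    h = mean(al[, 1] != al[, 2]), multi = as.numeric(any(obs > 1L)))
}

#' Pairwise Fst between two populations
#'
#' Weir & Cockerham's (1984) theta for two populations, aggregated over
#' sites as the ratio of summed variance components (sum of `a` over sum
#' of `a + b + c`), not the mean of per-site ratios. Only biallelic
#' (REF/ALT-1) sites with at least `min_per_pop` genotyped individuals in
#' each population enter the sums; negative estimates are reported as-is.
#'
#' @param x a `variant_set`.
#' @param pop_map named vector mapping sample to population label.
#' @param pop_a,pop_b the two population labels.
#' @param min_per_pop minimum genotyped individuals per population per
#'   site (default 10).
#' @return The multi-site Fst estimate.
#' @export
pairwise_fst <- function(x, pop_map, pop_a, pop_b, min_per_pop = 10L) {
  mem_a <- intersect(names(pop_map)[pop_map == pop_a], samples(x))
  mem_b <- intersect(names(pop_map)[pop_map == pop_b], samples(x))
  if (!length(mem_a) || !length(mem_b))
    stop("both populations need samples in the variant set")
  num <- 0; den <- 0; used <- 0L
  for (i in seq_len(n_sites(x))) {
    sa <- pop_site_summary(x$gt[i, mem_a])
    sb <- pop_site_summary(x$gt[i, mem_b])
    if (sa[["n"]] < min_per_pop || sb[["n"]] < min_per_pop) next
    if (sa[["multi"]] > 0 || sb[["multi"]] > 0) next
    comp <- wc_components(sa[["n"]], sa[["p"]], sa[["h"]],
                          sb[["n"]], sb[["p"]], sb[["h"]])
    if (is.null(comp)) next
    num <- num + comp[["a"]]
    den <- den + sum(comp)
    used <- used + 1L
  }
  if (used == 0L)
    stop("no site with >= ", min_per_pop,
         " genotyped individuals in both populations")
  if (den == 0)
    stop("all usable sites are monomorphic: Fst undefined")
  structure(num / den, n_sites = used)
}

#' Per-zone Fst for a scan
#'
#' Computes the Weir & Cockerham Fst separately within every zone
#' (ratio-of-sums over the sites falling in the zone), the granularity at
#' which selection scans are read.
#'
#' @inheritParams pairwise_fst
#' @param zone_df zone data.frame; sites are assigned to the zone whose
#'   half-open interval contains their position.
#' @return A data.frame with columns `chrom`, `zone`, `n_sites`, `fst`
#'   (`NA` where no usable site).
#' @export
fst_per_zone <- function(x, pop_map, pop_a, pop_b, zone_df,
                         min_per_pop = 10L) {
  rows <- lapply(seq_len(nrow(zone_df)), function(j) {
    inz <- x$chrom == zone_df$chrom[j] &
      x$pos > zone_df$start[j] & x$pos <= zone_df$end[j]
    fst <- NA_real_; n_used <- 0L
    if (any(inz)) {
      est <- tryCatch(pairwise_fst(subset_sites(x, inz), pop_map, pop_a,
                                   pop_b, min_per_pop),
                      error = function(e) NULL)
      if (!is.null(est)) {
        fst <- as.numeric(est)
        n_used <- attr(est, "n_sites")
      }
    }
    data.frame(chrom = zone_df$chrom[j], zone = zone_df$name[j],
               n_sites = n_used, fst = fst, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fst-scan outlier detection
#'
#' Flags, per chromosome, the zones whose Fst lies strictly above the
#' empirical `q`-quantile (linear interpolation between order statistics)
#' of the chromosome-wide distribution of per-zone Fst values — the
#' classic scan for candidate selection footprints. Chromosomes with
#' fewer than two defined Fst values are skipped with a warning.
#'
#' @param zone_fst data.frame with columns `chrom`, `zone`, `fst`
#'   (e.g. from [fst_per_zone()]).
#' @param q quantile defining the threshold (default 0.95).
#' @return A list with `thresholds` (data.frame `chrom`, `threshold`,
#'   `n_zones`) and `outliers` (rows of `zone_fst` above their
#'   chromosome's threshold).
#' @export
fst_scan <- function(zone_fst, q = 0.95) {
  thr <- list(); out <- list()
  for (ch in unique(zone_fst$chrom)) {
    d <- zone_fst[zone_fst$chrom == ch & !is.na(zone_fst$fst), , drop = FALSE]
    if (nrow(d) < 2L) {
      warning("chromosome ", ch, " has < 2 zones with defined Fst; skipped")
      next
    }
    t_ch <- unname(stats::quantile(d$fst, q, type = 7))
    thr[[ch]] <- data.frame(chrom = ch, threshold = t_ch,
                            n_zones = nrow(d), stringsAsFactors = FALSE)
    out[[ch]] <- d[d$fst > t_ch, , drop = FALSE]
  }
  list(thresholds = do.call(rbind, c(thr, list(NULL))),
       outliers = do.call(rbind, c(out, list(NULL))))
}

#' Mean depth per zone per sample
#'
#' Capture-efficiency summary: for every (zone, sample) pair, the mean
#' per-base depth of that sample within the zone.
#'
#' @param per_sample_depths named list mapping sample to a named list
#'   mapping chromosome to a per-base depth vector.
#' @param zone_df zone data.frame.
#' @return Numeric matrix, rows = zones, columns = samples.
#' @export
mean_depth_per_zone_per_sample <- function(per_sample_depths, zone_df) {
  m <- matrix(NA_real_, nrow(zone_df), length(per_sample_depths),
              dimnames = list(zone_df$name, names(per_sample_depths)))
  for (s in names(per_sample_depths)) {
    depths <- per_sample_depths[[s]]
    for (j in seq_len(nrow(zone_df))) {
      ch <- zone_df$chrom[j]
      if (is.null(depths[[ch]]) || zone_df$end[j] > length(depths[[ch]]))
        stop("depth vector for sample ", s, " does not cover zone ",
             zone_df$name[j])
      m[j, s] <- mean(depths[[ch]][(zone_df$start[j] + 1L):zone_df$end[j]])
    }
  }
  m
}
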