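#' Filtering-cascade configuration
#'
#' Defaults follow a stringent capture-genotyping parameterisation for a
#' predominantly selfing crop: genotypes kept only when supported by at
#' least `min_dp = 5` reads with GQ strictly above `min_gq = 15` (step 01);
#' loci kept when QUAL is at least `min_qual = 30` (step 02); no sample
#' filtering (step 03 disabled, `max_sample_missing = NULL`); step 04
#' keeps biallelic SNPs with `FIS >= 0.8` whose minor allele is observed
#' at least once in the homozygous state.
#'
#' @param min_dp minimum read depth per genotype (kept when `DP >= min_dp`).
#' @param min_gq exclusive GQ bound (kept when `GQ > min_gq`).
#' @param min_qual minimum site QUAL (kept when `QUAL >= min_qual`).
#' @param max_f_missing maximum fraction of missing calls per site, or
#'   `NULL` to disable.
#' @param max_sample_missing maximum per-sample missing fraction, or
#'   `NULL` to disable (the default).
#' @param biallelic_only keep only sites with exactly two observed alleles.
#' @param min_fis minimum site FIS, or `NULL` to disable.
#' @param require_minor_homozygote require at least one genotype
#'   homozygous for the minor allele.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_dp = 5L, min_gq = 15L, min_qual = 30,
                          max_f_missing = NULL, max_sample_missing = NULL,
                          biallelic_only = TRUE, min_fis = 0.8,
                          require_minor_homozygote = TRUE) {
  frac_ok <- function(v) is.null(v) || (is.finite(v) && v >= 0 && v <= 1)
  stopifnot(min_dp >= 0, min_gq >= 0, is.finite(min_qual),
            frac_ok(max_f_missing), frac_ok(max_sample_missing),
            is.null(min_fis) || is.finite(min_fis))
  structure(list(min_dp = min_dp, min_gq = min_gq, min_qual = min_qual,
                 max_f_missing = max_f_missing,
                 max_sample_missing = max_sample_missing,
                 biallelic_only = biallelic_only, min_fis = min_fis,
                 require_minor_homozygote = require_minor_homozygote),
            class = "filter_config")
}

#' Step 01: mask unreliable genotypes
#'
#' A genotype call is kept only when its depth is at least `min_dp` AND
#' its GQ is strictly greater than `min_gq`; all other calls — including
#' calls lacking a DP or GQ value — are masked to missing. DP/GQ values
#' are retained on masked calls; only the genotype is blanked.
#'
#' @param x a `variant_set`.
#' @param cfg a [filter_config()].
#' @return The masked `variant_set` (site count unchanged).
#' @export
mask_genotypes <- function(x, cfg = filter_config()) {
  keep <- !is.na(x$dp) & !is.na(x$gq) & x$dp >= cfg$min_dp & x$gq > cfg$min_gq
  x$gt[!keep] <- NA_character_
  x
}

#' Step 02: drop unreliable loci
#'
#' Removes sites with `QUAL < min_qual` and, when `max_f_missing` is set,
#' sites whose fraction of missing genotype calls exceeds it.
#'
#' @inheritParams mask_genotypes
#' @return A `variant_set` with offending sites removed.
#' @export
filter_loci <- function(x, cfg = filter_config()) {
  keep <- x$qual >= cfg$min_qual
  if (!is.null(cfg$max_f_missing)) {
    f_missing <- rowMeans(is.na(x$gt))
    keep <- keep & f_missing <= cfg$max_f_missing
  }
  subset_sites(x, keep)
}

#' Step 03: drop samples with excess missingness
#'
#' Computes each sample's missing-call fraction over the current sites and
#' removes samples exceeding `max_sample_missing` from every site. When
#' the threshold is `NULL` (the default) the step is the identity.
#'
#' @inheritParams mask_genotypes
#' @return A list with `sites` (the `variant_set`) and `removed_samples`.
#' @export
filter_samples <- function(x, cfg = filter_config()) {
  if (is.null(cfg$max_sample_missing) || n_sites(x) == 0L)
    return(list(sites = x, removed_samples = character()))
  miss <- colMeans(is.na(x$gt))
  removed <- samples(x)[miss > cfg$max_sample_missing]
  if (length(removed) == length(samples(x)))
    stop("sample filter would remove every sample")
  list(sites = subset_samples(x, setdiff(samples(x), removed)),
       removed_samples = removed)
}

#' Step 04: population-genetic SNP filter
#'
#' Annotates every site with its genotype statistics ([site_stats()]) and
#' keeps the sites that look like genuine variation in the study system:
#' monomorphic-after-masking sites are dropped (FIS undefined); with
#' `biallelic_only`, sites with more than two observed alleles are
#' dropped; sites with `FIS < min_fis` (excess heterozygosity, the
#' signature of collapsed paralogs in a selfer) are dropped; with
#' `require_minor_homozygote`, sites whose minor allele is never seen
#' homozygous are dropped.
#'
#' @inheritParams mask_genotypes
#' @return A `variant_set` of surviving sites; their statistics are
#'   attached as attribute `"site_stats"` (a data.frame).
#' @export
popgen_filter <- function(x, cfg = filter_config()) {
  if (n_sites(x) == 0L) {
    out <- x
    attr(out, "site_stats") <- site_stats_table(x)
    return(out)
  }
  st <- site_stats_table(x)
  keep <- st$n_alleles >= 2L          # drops monomorphic and all-missing
  if (cfg$biallelic_only) keep <- keep & st$n_alleles == 2L
  if (!is.null(cfg$min_fis))
    keep <- keep & !is.na(st$fis) & st$fis >= cfg$min_fis
  if (cfg$require_minor_homozygote) keep <- keep & st$minor_hom_count >= 1L
  out <- subset_sites(x, keep)
  attr(out, "site_stats") <- st[keep, , drop = FALSE]
  out
}

#' Run the full four-step filtering cascade
#'
#' Applies, in order: 01 genotype masking, 02 locus filtering, 03 sample
#' filtering, 04 population-genetic filtering, and records after each
#' step the SNP count, the Ts/Tv ratio of the surviving sites and the
#' sample count — the per-step summary used to judge each filter's effect
#' (random-error SNPs pull Ts/Tv toward 0.5; a clean set rises above 2).
#'
#' @inheritParams mask_genotypes
#' @return A list with `sites` (the final `variant_set`, with site
#'   statistics attached), `report` (data.frame: `step`, `label`,
#'   `n_snps`, `tstv`, `n_samples`) and `removed_samples`.
#' @export
run_cascade <- function(x, cfg = filter_config()) {
  report <- data.frame(step = character(), label = character(),
                       n_snps = integer(), tstv = numeric(),
                       n_samples = integer(), stringsAsFactors = FALSE)
  note <- function(step, label, x) {
    rbind(report, data.frame(step = step, label = label,
                             n_snps = n_sites(x), tstv = tstv_of_set(x),
                             n_samples = length(samples(x)),
                             stringsAsFactors = FALSE))
  }
  x <- mask_genotypes(x, cfg)
  report <- note("01", "genotype masking (DP/GQ)", x)
  x <- filter_loci(x, cfg)
  report <- note("02", "locus filtering (QUAL/F_missing)", x)
  fs <- filter_samples(x, cfg)
  x <- fs$sites
  report <- note("03", "sample filtering", x)
  x <- popgen_filter(x, cfg)
  report <- note("04", "population-genetic filtering", x)
  list(sites = x, report = report, removed_samples = fs$removed_samples)
}

#' Write the per-step cascade summary
#'
#' @param report the `report` data.frame from [run_cascade()].
#' @param path output TSV path.
#' @export
write_cascade_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
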