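test_that("genotype masking uses DP >= 5 and GQ > 15 boundaries", {
  gt <- matrix("0/1", 1, 4, dimnames = list(NULL, paste0("s", 1:4)))
  dp <- matrix(c(5L, 4L, 10L, 10L), 1, dimnames = dimnames(gt))
  gq <- matrix(c(16L, 99L, 15L, NA), 1, dimnames = dimnames(gt))
  x <- variant_set("c1", 1L, "A", "G", 50, gt, dp, gq)
  m <- mask_genotypes(x, filter_config())
  expect_equal(unname(m$gt[1, ]), c("0/1", NA, NA, NA))
  # dp/gq values survive masking
  expect_equal(unname(m$dp[1, 2]), 4L)
  expect_equal(n_sites(m), 1L)
})

test_that("locus filter applies QUAL and missingness thresholds", {
  rows <- rep(list(rep("0/1", 10)), 3)
  rows[[3]][1:6] <- NA
  x <- make_vs(rows, qual = c(29.9, 30, 100))
  kept <- filter_loci(x, filter_config())
  expect_equal(kept$qual, c(30, 100))
  withmiss <- filter_loci(x, filter_config(max_f_missing = 0.5))
  expect_equal(withmiss$qual, 30)          # 6/10 missing site dropped
  # disabled missingness keeps any missing fraction
  expect_equal(n_sites(filter_loci(x, filter_config(min_qual = 0))), 3L)
})

test_that("sample filter removes high-missingness samples only when enabled", {
  rows <- rep(list(c("0/1", "0/1", "0/1")), 10)
  for (i in 1:6) rows[[i]][2] <- NA        # sample 2 missing at 60 %
  x <- make_vs(rows)
  res <- filter_samples(x, filter_config(max_sample_missing = 0.5))
  expect_equal(res$removed_samples, "s02")
  expect_equal(samples(res$sites), c("s01", "s03"))
  expect_equal(filter_samples(x, filter_config())$removed_samples,
               character())
  expect_equal(
    filter_samples(x, filter_config(max_sample_missing = 1))$removed_samples,
    character())
  all_missing <- make_vs(rep(list(c(NA, NA)), 4))
  expect_error(filter_samples(all_missing,
                              filter_config(max_sample_missing = 0.1)),
               "every sample")
})

test_that("population-genetic filter enforces FIS and minor-homozygote rules", {
  x <- make_vs(list(
    c(rep("0/0", 8), rep("0/1", 2)),        # no minor homozygote
    c(rep("0/0", 5), rep("1/1", 5)),        # FIS = 1, minor hom present
    rep("0/1", 10),                         # FIS = -1
    rep("0/0", 10)))                        # monomorphic
  kept <- popgen_filter(x, filter_config())
  expect_equal(n_sites(kept), 1L)
  expect_equal(kept$pos, x$pos[2])
  st <- attr(kept, "site_stats")
  expect_equal(st$fis, 1)
  expect_equal(st$ho, 0)
  # multi-allelic sites drop under biallelic_only
  multi <- make_vs(list(c(rep("0/0", 4), rep("1/1", 4), rep("2/2", 2))),
                   alt = "G,T")
  expect_equal(n_sites(popgen_filter(multi, filter_config())), 0L)
  expect_equal(n_sites(popgen_filter(
    multi, filter_config(biallelic_only = FALSE, min_fis = NULL,
                         require_minor_homozygote = FALSE))), 1L)
})

test_that("surviving sites have two homozygote classes under the minor rule", {
  cfg <- sim_config(seed = 17, n_sites = 200L, inbreeding_f = 0.9,
                    target_fst = 0)
  x <- simulate_genotypes(cfg)$sites
  kept <- popgen_filter(mask_genotypes(x), filter_config())
  for (i in seq_len(n_sites(kept))) {
    g <- kept$gt[i, ]
    g <- g[!is.na(g)]
    expect_true(all(c("0/0", "1/1") %in% g))
  }
})

test_that("the cascade is monotone and reports per-step counts", {
  cfg <- sim_config(seed = 3, inbreeding_f = 1, target_fst = 0,
                    ancestral_maf_range = c(0.2, 0.5),
                    n_planted_low_qual = 10L, n_planted_excess_het = 8L,
                    n_planted_no_minor_hom = 6L,
                    n_planted_multiallelic = 4L)
  gen <- simulate_genotypes(cfg)
  res <- run_cascade(gen$sites, filter_config())
  tab <- table(gen$truth$category)
  expect_equal(res$report$n_snps,
               c(500L, 500L - 10L, 500L - 10L, 500L - 28L))
  expect_true(all(diff(res$report$n_snps) <= 0))
  expect_equal(res$report$step, c("01", "02", "03", "04"))
  # the sites removed at step 02 are exactly the planted low-QUAL sites
  masked <- mask_genotypes(gen$sites, filter_config())
  gone02 <- setdiff(masked$pos, filter_loci(masked, filter_config())$pos)
  expect_setequal(gone02,
                  gen$sites$pos[gen$truth$category == "low_qual"])
  # survivors of step 04 are exactly the unplanted sites
  expect_setequal(res$sites$pos,
                  gen$sites$pos[gen$truth$category == "normal"])
})

test_that("empty input and disabled filters are handled", {
  empty <- subset_sites(make_vs(list(rep("0/1", 4))), integer(0))
  res <- run_cascade(empty, filter_config())
  expect_equal(res$report$n_snps, rep(0L, 4))
  expect_true(all(is.na(res$report$tstv)))
  x <- make_vs(list(c("0/0", "0/1", "1/1"), rep("0/1", 3)))
  off <- filter_config(min_dp = 0L, min_gq = 0L, min_qual = 0,
                       biallelic_only = FALSE, min_fis = NULL,
                       require_minor_homozygote = FALSE)
  # GQ bound is exclusive, so disable via gq > 0 with gq matrix at 90
  res2 <- run_cascade(x, off)
  expect_equal(res2$report$n_snps, rep(2L, 4))
})

test_that("the QUAL predicate commutes with genotype masking", {
  cfg <- sim_config(seed = 29, n_sites = 300L, n_planted_low_qual = 30L)
  x <- simulate_genotypes(cfg)$sites
  cf <- filter_config()
  after_mask <- filter_loci(mask_genotypes(x, cf), cf)$pos
  before_mask <- mask_genotypes(filter_loci(x, cf), cf)$pos
  expect_identical(after_mask, before_mask)
})
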