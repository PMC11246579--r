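test_that("site statistics recover textbook values", {
  s <- site_stats(c(rep("0/0", 9), "1/1"))
  expect_equal(s[c("n", "p", "he", "ho", "fis", "maf", "minor_hom_count")],
               list(n = 10L, p = 0.1, he = 0.18, ho = 0, fis = 1,
                    maf = 0.1, minor_hom_count = 1L))
  h <- site_stats(rep("0/1", 10))
  expect_equal(h$p, 0.5)
  expect_equal(h$he, 0.5)
  expect_equal(h$ho, 1)
  expect_equal(h$fis, -1)                   # clipped at -1
  mono <- site_stats(rep("0/0", 10))
  expect_equal(mono$he, 0)
  expect_true(is.na(mono$fis))
  expect_error(site_stats(c(NA, NA)), "no non-missing genotype")
  # 50/50 tie: ALT treated as minor
  tie <- site_stats(c(rep("0/0", 5), rep("1/1", 5)))
  expect_equal(tie$minor_allele, 1L)
  expect_equal(tie$minor_hom_count, 5L)
})

test_that("selfing-equilibrium FIS follows (1-t)/(1+t)", {
  expect_equal(round(expected_fis_selfing(0.04), 4), 0.9231)
  expect_equal(round(expected_fis_selfing(0.04), 2), 0.92)
  expect_equal(expected_fis_selfing(0), 1)
  expect_equal(expected_fis_selfing(1), 0)
  expect_error(expected_fis_selfing(1.2), "\\[0, 1\\]")
  t <- seq(0, 1, by = 0.01)
  expect_true(all(diff(expected_fis_selfing(t)) < 0))   # strictly decreasing
})

test_that("transition/transversion classification and ratio", {
  expect_equal(tstv_ratio(c("A", "C", "A"), c("G", "T", "C")), 2)
  six_ref <- c("A", "C", "A", "A", "C", "G")
  six_alt <- c("G", "T", "C", "T", "G", "T")
  expect_equal(tstv_ratio(six_ref, six_alt), 0.5)
  expect_warning(out <- tstv_ratio("A", "G"), "undefined")
  expect_true(is.na(out))
  expect_error(is_transition("A", "A"), "distinct single bases")
  # uniform draws over the six classes converge to 0.5
  set.seed(13)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 10000, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  expect_lt(abs(tstv_ratio(ref, alt) - 0.5), 0.05)
})

test_that("nucleotide diversity uses the small-sample correction", {
  x <- make_vs(list(c(rep("0/0", 5), rep("1/1", 5))))
  pops <- stats::setNames(rep("P", 10), samples(x))
  d <- nucleotide_diversity(x, pops, "P", min_per_pop = 10)
  expect_equal(d$pi, (20 / 19) * 0.5)
  expect_equal(d$n_sites, 1L)
  mono <- make_vs(list(rep("0/0", 10), rep("0/0", 10)))
  expect_equal(nucleotide_diversity(mono, pops, "P", 10)$pi, 0)
  # doubling the sample moves pi toward 2p(1-p)
  x2 <- make_vs(list(c(rep("0/0", 10), rep("1/1", 10))))
  pops2 <- stats::setNames(rep("P", 20), samples(x2))
  d2 <- nucleotide_diversity(x2, pops2, "P", 10)
  expect_lt(abs(d2$pi - 0.5), abs(d$pi - 0.5))
  # sites below min_per_pop are excluded entirely
  expect_error(nucleotide_diversity(x, pops, "P", min_per_pop = 11),
               ">= 11")
})

test_that("diversity reduction index is a reciprocal ratio", {
  expect_equal(dri(0.012, 0.010), 1.2)
  expect_equal(dri(0.5, 0.5), 1)
  expect_equal(round(dri(0.010, 0.012), 4), 0.8333)
  expect_error(dri(0.1, 0), "must be > 0")
  set.seed(2)
  x <- runif(20, 0.001, 1); y <- runif(20, 0.001, 1)
  expect_equal(dri(x, y) * dri(y, x), rep(1, 20))
})

test_that("Weir-Cockerham Fst is 1 for a fixed difference and ~0 under the null", {
  gt <- rbind(c(rep("0/0", 10), rep("1/1", 10)))
  colnames(gt) <- sprintf("s%02d", 1:20)
  x <- variant_set("c1", 1L, "A", "G", 50, gt)
  pops <- stats::setNames(rep(c("A", "B"), each = 10), colnames(gt))
  expect_equal(as.numeric(pairwise_fst(x, pops, "A", "B", 10)), 1)
  # two samples from one panmictic population
  cfg <- sim_config(seed = 19, populations = c(A = 50L, B = 50L),
                    target_fst = 0, inbreeding_f = 0, n_sites = 500L)
  gen <- simulate_genotypes(cfg)
  null_fst <- pairwise_fst(gen$sites, gen$pop_map, "A", "B", 10)
  expect_lt(abs(as.numeric(null_fst)), 0.02)
  mono <- make_vs(list(rep("0/0", 20), rep("0/0", 20)))
  pops2 <- stats::setNames(rep(c("A", "B"), each = 10), samples(mono))
  expect_error(pairwise_fst(mono, pops2, "A", "B", 10), "monomorphic")
})

test_that("FIS recovery: estimator mean tracks the simulated F", {
  for (f in c(0, 0.5, 0.92)) {
    cfg <- sim_config(seed = 100 + round(100 * f),
                      populations = c(P = 200L), target_fst = 0,
                      inbreeding_f = f, n_sites = 500L)
    st <- site_stats_table(simulate_genotypes(cfg)$sites)
    expect_lt(abs(mean(st$fis, na.rm = TRUE) - f), 0.05)
  }
})

test_that("Fst recovery under the Balding-Nichols model", {
  for (target in c(0.1, 0.3)) {
    cfg <- sim_config(seed = 200 + round(100 * target),
                      populations = c(A = 50L, B = 50L),
                      target_fst = target, inbreeding_f = 0,
                      n_sites = 1000L)
    gen <- simulate_genotypes(cfg)
    est <- as.numeric(pairwise_fst(gen$sites, gen$pop_map, "A", "B", 10))
    expect_lt(abs(est - target), 0.03)
  }
})

test_that("the Fst scan thresholds at the type-7 quantile, strictly above", {
  zf <- data.frame(chrom = "c1", zone = paste0("z", 1:20), fst = 1:20)
  sc <- fst_scan(zf, 0.95)
  expect_equal(sc$thresholds$threshold, 19.05)
  expect_equal(sc$outliers$zone, "z20")
  flat <- data.frame(chrom = "c1", zone = paste0("z", 1:10), fst = 0.2)
  expect_equal(nrow(fst_scan(flat)$outliers), 0L)
  expect_warning(fst_scan(data.frame(chrom = "c2", zone = "z", fst = 0.1)),
                 "skipped")
  # never flags more than ceiling(5 %) of zones
  set.seed(23)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    zf <- data.frame(chrom = "c", zone = seq_len(n), fst = runif(n))
    expect_lte(nrow(fst_scan(zf)$outliers), ceiling(0.05 * n))
  }
})

test_that("per-zone per-sample depth means match brute force", {
  z <- zones(c("c1", "c1"), c(0, 6), c(4, 10))
  depths <- list(
    sampleA = list(c1 = c(2, 2, 4, 4, 0, 0, 1, 1, 1, 1)),
    sampleB = list(c1 = rep(0, 10)))
  m <- mean_depth_per_zone_per_sample(depths, z)
  expect_equal(m["c1_0_4", "sampleA"], 3)
  expect_equal(m["c1_6_10", "sampleA"], 1)
  expect_equal(unname(m[, "sampleB"]), c(0, 0))
  # brute-force per-base cross-check on random data
  set.seed(3)
  depths2 <- list(s1 = list(c1 = rpois(100, 3)), s2 = list(c1 = rpois(100, 1)))
  z2 <- zones(c("c1", "c1"), c(5, 50), c(25, 90))
  m2 <- mean_depth_per_zone_per_sample(depths2, z2)
  for (s in names(depths2))
    for (j in 1:2) {
      acc <- 0
      for (b in (z2$start[j] + 1):z2$end[j]) acc <- acc + depths2[[s]]$c1[b]
      expect_equal(m2[j, s], acc / (z2$end[j] - z2$start[j]))
    }
  expect_error(mean_depth_per_zone_per_sample(depths2, zones("c1", 90, 120)),
               "does not cover")
})
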