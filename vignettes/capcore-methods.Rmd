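---
title: "Methods: targeted remapping, SNP filtering, and diversity statistics in capcore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: targeted remapping, SNP filtering, and diversity statistics in capcore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capcore)
```

# Scope and rationale

Target enrichment capture sequences a chosen fraction of a genome — often
well under 1 % — at many individuals. On very large genomes (wheat-scale,
around 10 Gb) two practical problems follow: most of the reference is dead
weight for every downstream step, and some variant callers cannot even
index chromosomes that large. `capcore` implements the computational
stages that make capture genotyping tractable in that setting:

1. build a **sub-reference** from the covered or targeted regions
   ("zones"), so remapping and calling run against megabases instead of
   gigabases;
2. extract the reads belonging to each zone, **pair-aware**, and emit
   FASTQ for remapping;
3. **lift** the resulting variant coordinates back to the full reference;
4. filter the multi-sample VCF through a **four-step cascade** that ends
   with population-genetic criteria suited to a predominantly selfing
   organism;
5. compute the **QC and diversity statistics** used to judge the result:
   Ts/Tv, FIS, nucleotide diversity, the diversity reduction index, and
   Weir & Cockerham Fst with a per-zone selection scan.

External aligners and variant callers are out of scope by design: the
package starts from aligned records (SAM text) and from multi-sample
VCFs, and ends at FASTQ, VCF, and tabular reports.

# Coordinate conventions

All internal coordinates are BED-style 0-based half-open. Conversion to
1-based happens only at VCF boundaries. Sub-reference contigs are named
`{chrom}_{start}_{end}` in full-reference coordinates, so a contig name
alone determines the lift-over offset; `parse_zone_name()` rejects names
not matching the pattern. Chromosome names may themselves contain
underscores — the final two numeric fields are taken as coordinates.

# Zone calling

`call_zones()` takes a per-base *mean coverage per sample* profile and
three parameters:

* `min_mean_cov` (default 1 read/sample/base): bases at or above this
  mean are marked. The threshold is inclusive (`>=`): the default asks
  for "an average of one read per sample", and a strict `>` would drop
  bases at exactly 1.
* `min_dist` (default 100 bp): marked runs separated by a gap strictly
  smaller than this merge into one region. A gap of exactly `min_dist`
  does **not** merge — "closer than" is read strictly, and the tie-break
  is fixed by test. Bases in a bridged gap become part of the zone, so
  every zone is one contiguous interval.
* `min_length` (default 100 bp): merged regions shorter than this are
  discarded. The length filter runs **after** merging, so two short runs
  can jointly survive through their merged length.

The mean is taken over *all* samples, including samples with zero
coverage at the base; using only covered samples would make the
threshold depend on capture breadth in a way the parameter's name does
not suggest. The implementation is run-length based; the test suite
checks it against an independent per-base brute-force scan on hundreds
of random profiles, and checks monotonicity (raising `min_mean_cov`
never enlarges total zone length; raising `min_length` never increases
zone count).

When the user supplies their own targeted BED instead,
`merge_intervals()` normalises it: overlapping *or touching* half-open
intervals merge (at base resolution, touching is indistinguishable from
overlap), and the operation is idempotent and order-independent.

# Pair-aware read extraction

Before extraction, `filter_alignments()` applies the record-level
predicates used in practice on capture data: duplicate removal
(capture libraries are heavily amplified; duplicate *detection* is left
to the usual tools, only the flag is honoured), proper-pair and
primary-only requirements, and a MAPQ floor (strictly-below removal, so
`min_mapq = 30` keeps Q30 exactly).

`extract_reads()` then assigns each primary record to the zone its
aligned span overlaps most (ties to the leftmost zone — the overlap rule
is a package decision, documented so results are reproducible). The
pairing logic protects the remapping step:

* both mates in the same zone → the pair stays paired;
* mates in two different zones → **both demoted to single-end**, so the
  remapping never sees a pair whose mates lie on different sub-contigs;
* mate without any zone → the surviving mate goes single-end, the other
  is dropped (the conservative extension of the two-zones rule);
* no zone at all → dropped.

Reads are emitted in their original orientation (reverse-strand records
are reverse-complemented back, qualities reversed), R1/R2 files stay
synchronized, and read conservation
(`2·pairs + singles + dropped = input`) is asserted in tests.

# Coordinate lift-over

`lift_position()` is pure offset arithmetic: 1-based `sub_pos` on
contig `{chrom}_{start}_{end}` maps to `start + sub_pos` on `chrom`,
valid exactly for `1 <= sub_pos <= end - start`. `lift_vcf()` rewrites
CHROM/POS, replaces the `##contig` header lines with full-reference
chromosomes and their lengths, re-sorts records by lifted coordinate
(downstream indexing requires a sorted VCF, so re-sorting is the
package's choice), and leaves every other field
byte-identical. The round trip `pos − start` is tested for every
position of every zone in a 50-zone fixture.

# The filtering cascade

The four steps run in a fixed order, and a per-step summary (SNP count,
Ts/Tv, sample count) is recorded after each:

* **01 — genotype masking.** A call survives only with `DP >= 5` *and*
  `GQ > 15` (defaults). The DP bound is inclusive and the GQ bound
  exclusive, read literally from the usual parameterisation; both are
  configurable. Calls lacking DP or GQ are masked — the conservative
  choice for a filter whose purpose is distrust.
* **02 — locus filtering.** `QUAL >= 30` (inclusive; "lower than 30" is
  removed), plus an optional per-site missing-call fraction cap. The
  QUAL predicate is independent of step 01 and commutes with it; the
  suite asserts this on fixtures.
* **03 — sample filtering.** Per-sample missingness over the current
  sites; disabled by default (matching an analysis that keeps every
  accession), and erroring rather than silently removing all samples.
* **04 — population-genetic filtering.** Sites monomorphic after
  masking are dropped first (FIS undefined there). With the defaults the
  step keeps sites that are biallelic *on observed alleles* (not the ALT
  column — masking can remove an allele), have `FIS >= 0.8`, and show
  the minor allele at least once in the homozygous state. Multiallelic
  sites are dropped, not split. The minor allele is the least frequent
  observed allele, ALT on an exact 50/50 tie.

The FIS threshold is motivated by mating system: at selfing equilibrium
with outcrossing rate $t$, Weir's formula gives
$F_{IS} = (1-t)/(1+t)$, i.e. about 0.92 at $t = 0.04$
(`expected_fis_selfing()`). Excess heterozygosity (low FIS) in a strong
selfer is the signature of collapsed paralogs or homeologs, not of real
variation. The minor-homozygote rule targets the same artefact class
from another angle: an allele seen only in heterozygotes is suspect.

Ts/Tv is the cascade's quality dial: transitions are A↔G and C↔T, the
other four classes transversions, so random errors sit at
$2/4 = 0.5$ while genuine SNP sets typically exceed 2. The per-step
report computes it over all single-base REF/ALT pairs present.

# Estimators

* **Per-site statistics** (`site_stats()`): $\hat p$ from allele counts,
  $H_e = 1 - \sum_k p_k^2$ (equal to $2p(1-p)$ when biallelic),
  $H_o$ the heterozygote fraction, and $F_{IS} = 1 - H_o/H_e$ clipped to
  $[-1, 1]$, undefined when $H_e = 0$. This is the Nei-style per-site
  estimator; numerical agreement with any particular external library's
  estimator is not claimed.
* **Nucleotide diversity** (`nucleotide_diversity()`): per-site
  $\frac{2n}{2n-1}\,2p(1-p)$ (unbiased for sample size $n$ diploids),
  averaged over sites with at least `min_per_pop` genotyped individuals
  in the population; under-covered sites are excluded per statistic, not
  globally.
* **DRI** (`dri()`): $\pi_\text{ancestral} / \pi_\text{derived}$, so a
  diversity loss through a domestication transition gives DRI > 1 and
  `dri(x, y) * dri(y, x) = 1`.
* **Fst** (`pairwise_fst()`): Weir & Cockerham's (1984) two-population
  θ, aggregated across sites as the **ratio of summed variance
  components** — not the mean of per-site ratios, which is biased at low
  per-site information. Negative estimates are reported as-is. Only
  biallelic sites with `min_per_pop` genotyped individuals in each
  population enter the sums.
* **Fst scan** (`fst_per_zone()`, `fst_scan()`): Fst is computed per
  zone (ratio-of-sums within the zone), and per chromosome the zones
  strictly above the empirical 95 % quantile (type-7, linear
  interpolation) are flagged as candidate selection footprints.
  Chromosomes with fewer than two defined values are skipped with a
  warning rather than producing a degenerate threshold.

# The simulator: what it emulates, and what it does not

The fixture generators exist so every stage can be validated against
known truth without any external dataset.

* `simulate_reference()` draws uniform-random chromosomes and places
  non-overlapping zones with a guaranteed minimum gap (kept at twice the
  default merge distance so simulated zones never merge away).
* `simulate_alignments()` emulates enrichment: pairs fall inside a
  random zone, an `off_target_rate` fraction is placed wholly outside
  every zone (rejection-sampled, so truth labels are unambiguous),
  `n_straddle_pairs` pairs have their mates in two different zones to
  exercise single-end demotion, and a `duplicate_rate` fraction of the
  final read set are exact flagged copies — the default 0.8 mirrors the
  very high duplicate levels of amplified capture libraries.
* `simulate_genotypes()` draws ancestral ALT frequencies uniformly from
  `ancestral_maf_range`, diverges populations under a Balding–Nichols
  model at `target_fst` (chosen because it has a tunable true Fst),
  and draws genotypes with inbreeding coefficient $F$ via
  $p^2 + Fpq,\; 2pq(1-F),\; q^2 + Fpq$. The default $F = 0.92$ matches
  the selfing-equilibrium expectation; the default four populations of
  30 individuals mirror a domestication-series design. DP is Poisson
  (mean 20 by default, high enough that masking is rare unless a test
  lowers it) and GQ is a noisy monotone function of DP — only its
  ordering relative to the threshold matters. Sites violating a single
  filtering rule can be planted in known numbers for cascade
  bookkeeping.

Deliberately *not* modelled: sequencing error profiles, indels, bait
hybridisation thermodynamics, linkage between sites, and any Ts/Tv
enrichment (REF/ALT pairs are uniform over the six substitution classes,
so simulated data sit at Ts/Tv ≈ 0.5). Passing tests therefore
demonstrate the correctness of the algorithms and estimators under the
stated models, not the biological realism of any particular dataset.

# Problem sizes and numerical choices

The test suite runs at desk scale, chosen to keep each recovery check
well inside its tolerance at a fixed seed: zone-calling equivalence on
200 random profiles up to 10 kb; extraction on a few thousand pairs;
FIS recovery on 200 individuals × 500 sites for
$F \in \{0, 0.5, 0.92\}$ (tolerance ±0.05); Fst recovery on 2 × 50
individuals × 1 000 sites at targets 0.1 and 0.3 (±0.03); the scan on
100 zones × 20 sites with one planted zone at Fst 0.6 over a 0.05
background. Degenerate inputs are defined rather than accidental:
empty profiles yield empty zone sets, header-only VCFs lift to
header-only VCFs, a Ts/Tv with zero transversions is `NA` with a
warning (never a silent `Inf`), monomorphic-only Fst input errors, and
a sample filter that would remove every sample errors.

# Known limitations

* The SAM reader supports the eleven mandatory columns and consumes
  CIGAR only for the reference span; BAM and optional tags are outside
  the toolkit's scope.
* FIS here is the per-site $1 - H_o/H_e$; other estimators (e.g.
  method-of-moments multi-locus estimators) will differ numerically on
  real data.
* Per-zone Fst uses ratio-of-sums within the zone; zones with very few
  informative sites have noisy estimates, which the scan's quantile
  threshold only partially absorbs.
* The simulator's independence between sites means multi-site
  aggregation tests say nothing about linkage effects.
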