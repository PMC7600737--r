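---
title: "Methods: pooled-heterozygosity and di selection scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-heterozygosity and di selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pooled whole-genome sequencing (Pool-seq) estimates population allele
frequencies cheaply: DNA from ~10 individuals per population is sequenced
as one library, so each variant site carries only reference/alternate read
counts per pool, never individual genotypes. Selective sweeps — beneficial
alleles dragged to fixation together with linked variation — leave two
signatures such data can still see: locally depressed heterozygosity in
the selected population, and locally elevated differentiation between that
population and the others. `poolsweep` implements a genome scan that calls
a region selected only when both signatures are extreme, then annotates
the called loci with overlapping genes and screens the selected genes'
breed-specific variants against multi-species conserved sites.

## Statistics

**Pooled heterozygosity.** For each sliding window and pool,

$$H_p = \frac{2\,\Sigma n_{maj}\,\Sigma n_{min}}{(\Sigma n_{maj}+\Sigma n_{min})^2},$$

where $\Sigma n_{maj}$ and $\Sigma n_{min}$ sum, over the window's SNVs,
the read counts of each site's major and minor allele in that pool (the
major allele is the one with more reads; a 50/50 tie resolves to the
reference allele, deterministically). $H_p \in [0, 0.5]$, maximal when the
summed counts balance. Per population the window values are Z-transformed,
$ZH_p = (H_p - \mu_{H_p})/\sigma_{H_p}$, with $\mu$ and $\sigma$ taken
over that population's retained windows. $\sigma$ uses the $1/n$
(population) denominator so the resulting scores have sd exactly 1; the
$1/(n-1)$ convention is available via `sd_type = "sample"`.

**Fst from read counts.** Every read is treated as one sampled allele
(the standard Pool-seq convention), and each SNV is a one-way ANOVA of the
allele indicator on the two pools:

$$F_{st} = \frac{MSP - MSG}{MSP + (n_c - 1)\,MSG},$$

with $MSP$/$MSG$ the among/within-population mean squares and
$n_c = \left(\sum a_i - \sum a_i^2 / \sum a_i\right)/(r-1)$ the
unequal-sample-size coefficient for pool depths $a_i$ and $r = 2$ pools.
Window estimates are ratio-of-sums (summed numerators over summed
denominators), the standard multi-locus estimator, which is stable at
low-information SNVs; per-SNV-then-average is deliberately not used.
Negative raw estimates are clamped to 0 (and >1 to 1) before any
downstream use.

**The di statistic.** For population $i$ and window $w$,

$$d_i(w) = \sum_{j \ne i} \frac{F_{st}^{ij}(w) - \mathbb{E}[F_{st}^{ij}]}{\mathrm{sd}[F_{st}^{ij}]},$$

standardising each pairwise window Fst by its genome-wide mean and sd
(sample sd, over retained windows). Because the standardisation baseline
is computed from the same clamped window values, the genome-wide mean of
$d_i$ is exactly 0 whenever no window is missing, clamping or not.

**Calling.** A window is called for a population iff $ZH_p$ is strictly
below the cutoff (default −7) *and* $d_i$ is strictly above the top-1%
empirical quantile (type-7, linear interpolation; ties therefore pass
fewer windows, never more). Overlapping or bookended called windows merge
into loci; a gene is reported for a locus if it overlaps it by ≥1 bp
(containment is not required — candidate tables report genes *in* regions).
An absolute `di_cutoff` can replace the quantile rule: published analyses
sometimes quote absolute values (e.g. di > 7 or joint ZHp < −9, di > 9),
but those are data-dependent summaries of the same top-tail rule, so the
quantile form is the default and the absolute form a configuration preset.

## Windowing and retention

Windows are 50 kb by default and slide by 25 kb (half a window). The
source method says only "overlapping" windows; a half-window step is
standard ZHp practice, guarantees overlap, and makes a contiguous sweep
signal merge into one locus. Window starts tile every step until the
contig end, with terminal windows truncated, so every bp is covered.
Windows with ≤ 10 SNVs (strictly: a window needs *more than* 10) are
treated as missing, not zero — they are excluded from $\mu_{H_p}$,
$\sigma_{H_p}$, the pair statistics and calling. The SNV count of a window
is population-independent (sites, not covered sites), so every population
track and every pairwise Fst track shares a single retained-window set;
this is what lets the conjunction rule join tracks without reconciliation.

## SNV filters

Sites enter the scan only if they are biallelic SNVs with QUAL ≥ 30,
summed read depth across pools ≥ 68 and ≥ 3 alternate-supporting reads.
All thresholds are inclusive, and a dropped record is attributed to the
first rule it fails (biallelic, qual, coverage, alt-reads) so rejection
counts are auditable. Two interpretation notes:

* *Coverage 68, summed.* With six pools at ~11× each, 68 is approximately
  the expected total depth, so the threshold is read as a sum over pools;
  a per-pool reading is available (`coverage_per_pool = TRUE`).
* *Alt-read start sites.* Callers sometimes additionally require the ≥3
  alternate reads to have distinct start positions; that needs alignments
  (BAMs), not a VCF, so it is documented as unenforceable here and the
  rule is a plain count.
* *Pool zygosity.* For pooled data "heterozygous" is defined on read
  counts: a pool is homozygous at a site when one allele has zero reads.
  This is an interpretation — no individual-genotype definition exists
  for pools.

## The synthetic generator: what it emulates, and what not

`sim_config()` defaults state the emulated design: 6 populations, a 20-Mb
genome (2 × 10 Mb contigs), SNV density 0.005/bp (~100,000 sites), mean
pool depth 12 (the study's 10–13×), ancestral frequencies uniform on
(0.05, 0.95) — rare alleles are omitted because real call sets of this
kind have them removed during calling — and Balding–Nichols
differentiation with one shared `drift_F = 0.05`, i.e. per-population
frequencies Beta$(p(1-F)/F,\,(1-p)(1-F)/F)$ around ancestral $p$, whose
expected pairwise Fst is $F$ (background differentiation of a few
percent). Read counts are Poisson total depth and binomial alternate
counts; sites with no alternate read in any pool are dropped (a caller
would never emit them), while sites fixed for the alternate allele
everywhere are kept — they are variants relative to the reference. A
configurable 5% of sites get QUAL < 30 so the quality filter has work.

Sweeps are planted by moving target-population frequencies a fraction
`fixation_push` toward the nearer of 0/1 ($f = 0.5$ resolves to 0 via
round-half-to-even). This creates exactly the joint signal the scan
detects — zero within-pool variation plus elevated divergence — without
simulating linkage, recombination, sequencing error or indels
(deliberately out of scope). Consequently a green sweep-recovery test
establishes that the statistics and calling logic recover a planted joint
signal at realistic depth and differentiation; it does *not* establish
power against realistic sweep haplotype structure, demography, or
reference bias.

**Sweep length and the reachability of ZHp < −7.** If a fraction $q$ of
retained windows sit at $H_p \approx 0$ and the rest near $\mu_0$, then
$\sigma^2_{H_p} \ge q(1-q)\mu_0^2$, so the sweep windows' score is bounded:
$|ZH_p| \le \sqrt{(1-q)/q}$. Reaching −7 requires $q < 1/50$. With 5
sweeps over a 20-Mb genome (800 window positions), 150-kb sweeps would put
~35 windows at zero ($q \approx 0.044$, bound ≈ 4.7) and make the stated
cutoff mathematically unattainable; 75-kb sweeps aligned to the 25-kb grid
put 2 fully-contained windows each at zero ($q \approx 0.0125$, bound
≈ 8.9), leaving headroom for background variance. The recovery fixture
therefore uses 75-kb sweeps; this was derived a priori from the bound, not
tuned against test outcomes.

Fixture gene annotations place one 2-kb gene (with a 600-bp CDS) at each
sweep's centre plus background genes away from sweeps; per-gene 12-species
alignments plant conserved columns only at positions carrying no simulated
variant (plus the planted breed-specific sites), which makes the
conservation-screen truth exact by construction rather than probabilistic.

## Conservation screen

Breed-specific SNVs are sites where one allele has frequency ≥ 0.9 in the
focal pool and ≤ 0.1 in every other pool (either allele may play the
role; both thresholds configurable). The source analysis never quantifies
"breed-specific", so 0.9/0.1 are this package's defaults. Conserved
alignment columns require all non-gap rows identical (case-insensitive)
with at most `max_gap_rows = 0` gap rows — the strictest reading of
"conserved by sequence alignment"; sites are mapped to genome coordinates
through the reference row and intersected with specific SNVs inside gene
± 1000 bp regions, each hit labelled coding/non-coding by CDS overlap.
Alignments are consumed pre-aligned; computing them is out of scope.

## Numerical choices and degenerate inputs

* Per-SNV Fst is undefined (NA, excluded) when either pool has zero depth
  or the denominator is zero (site monomorphic in both pools); a window
  with no usable SNV has missing Fst, and a window missing any pairwise
  Fst gets missing di.
* $MSG$ is defined as 0 when both pools have a single read (0/0 case).
* `z_transform` and `compute_pair_stats` refuse degenerate inputs
  (σ = 0, or fewer than 2 windows) rather than emitting infinities.
* `di_threshold` warns below 100 windows, where an empirical 1% quantile
  is unstable.
* Windowed sums are exact integer arithmetic until the final ratios, so
  brute-force per-window recomputation matches bitwise on integer counts.

## Known limitations

Sites, not haplotypes: no iHS/EHH-type statistics; no per-chromosome
normalisation; no hierarchical F-statistics or bootstrap intervals; VCF
round-trip preserves QUAL to ~15 significant digits; multi-allelic sites
are skipped (with counts), not decomposed. The read-as-allele ANOVA
ignores that reads may sample the same chromosome twice at high
depth-to-pool-size ratios; a cap on effective per-pool sample size is the
natural extension but is not enabled by default at the ~12× depths this
package targets.
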