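# poolsweep

Selection-signature scans from multi-population pooled whole-genome
sequencing (Pool-seq).

Pool-seq experiments sequence DNA pooled from many individuals of a
population as one library, so every variant site carries only per-pool
reference/alternate read counts. For breeders and population geneticists
this is a cheap way to map selective sweeps — regions where artificial or
natural selection fixed an allele and flattened linked variation. A sweep
leaves two read-count signatures at once: depressed pooled heterozygosity
in the selected population and elevated differentiation against all other
populations. `poolsweep` calls a locus selected only when both are
extreme, then annotates it with overlapping genes and screens
breed-specific variants in those genes against multi-species conserved
sites.

## The statistics

Per sliding window (default 50 kb, 25-kb step, windows with > 10 SNVs) and
pool:

- **Pooled heterozygosity**
  `Hp = 2 ΣnMaj ΣnMin / (ΣnMaj + ΣnMin)²`, where ΣnMaj/ΣnMin sum the
  major/minor allele read counts over the window's SNVs, Z-transformed per
  population: `ZHp = (Hp − μHp) / σHp`.
- **Pairwise Fst** by among/within mean squares, treating each read as a
  sampled allele: `Fst = (MSP − MSG) / (MSP + (nc − 1) MSG)` with the
  unequal-sample-size coefficient `nc`; window values are ratio-of-sums
  over SNVs, clamped to [0, 1].
- **di statistic** for population *i*:
  `di = Σ_{j≠i} (Fst_ij − E[Fst_ij]) / sd(Fst_ij)`, standardised by
  genome-wide pair means/sds.

Calling: `ZHp < −7` (strict) **and** `di` above the top-1% empirical
quantile (strict); flagged windows merge into loci; genes overlap loci by
≥ 1 bp. SNVs enter the scan only with QUAL ≥ 30, summed depth ≥ 68 and
≥ 3 alternate reads (all inclusive).

A synthetic generator (Balding–Nichols differentiation, Poisson/binomial
read sampling, planted sweeps, toy GFF3 + 12-species alignments) makes the
whole pipeline testable without sequencing data; see
`vignettes/methods.Rmd` for the model, defaults and their rationale.

## Worked example

Simulate a 6-population, 20-Mb Pool-seq experiment at 12× with two planted
sweeps in population 1, then scan it with default settings:

```r
library(poolsweep)

cfg <- sim_config(
  n_populations = 6,
  contig_lengths = c(ctg1 = 1e7, ctg2 = 1e7),
  snv_density = 0.005, drift_F = 0.05, mean_depth = 12,
  sweep_specs = list(
    sweep_spec("ctg1", 2.0e6, 2.075e6, target_populations = 1L, fixation_push = 1),
    sweep_spec("ctg2", 6.5e6, 6.575e6, target_populations = 1L, fixation_push = 1)
  ),
  seed = 1
)
bundle <- write_fixture_bundle(cfg, "demo")          # VCF + GFF3 + alignments + truth BED

manifest <- run_full_scan(run_config(
  vcf = bundle$paths$vcf, gff = bundle$paths$gff, out_dir = "demo/scan",
  alignments_dir = bundle$paths$alignments_dir, seed = 1
))
str(manifest$counts)
```

```
List of 10
 $ variants_read          : int 99868
 $ variants_kept          : int 65655
 $ rejections             : qual 4968, coverage 28703, alt_reads 542
 $ windows                : int 800
 $ retained_windows       : int 800
 $ flagged_windows        : int 4
 $ loci                   : int 2
 $ candidate_genes        : int 2
 $ conserved_specific_snvs: int 2
```

~100k simulated SNVs; the QUAL ≥ 30 and summed-coverage ≥ 68 filters drop
about a third at 12× (expected total depth 72). All 800 windows hold > 10
SNVs. Exactly the 4 windows fully inside the two sweeps pass the joint
rule and merge into 2 loci:

```r
manifest$tables$loci
#>    population contig   start     end n_windows   min_zhp   max_di
#> 1:       pop1   ctg1 2000000 2075000         2 -11.89463 57.43113
#> 2:       pop1   ctg2 6500000 6575000         2 -11.89463 58.91485

manifest$tables$report[, c("population", "gene_id", "contig", "min_zhp", "max_di")]
#>    population       gene_id contig   min_zhp   max_di
#> 1:       pop1 gene_sweep_01   ctg1 -11.89463 57.43113
#> 2:       pop1 gene_sweep_02   ctg2 -11.89463 58.91485
```

Both loci coincide with the planted sweep intervals and recover the genes
planted at their centres, with the candidate-gene table's columns (gene,
scaffold, annotation, ZHp, di). ZHp ≈ −11.9 is the sweep windows' Hp = 0
against the genome background; di ≈ 58 sums five strongly standardised
pairwise Fst values. The conservation screen then reports the planted
breed-specific SNVs that sit at conserved alignment columns, labelled by
CDS overlap (at 12× a site can drop out of the screen when the coverage
filter removes it — the screen runs on filtered variants):

```r
manifest$tables$conservation[, c("gene_id", "pos", "population", "coding")]
#>          gene_id     pos population coding
#> 1: gene_sweep_01 2036712       pop1  FALSE
#> 2: gene_sweep_02 6537304       pop1   TRUE
```

A command-line wrapper with `simulate` and `scan` subcommands is installed
at `system.file("cli/poolsweep", package = "poolsweep")`.

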