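test_that("config validation rejects bad parameter combinations", {
  expect_error(sim_config(n_populations = 1), "n_populations")
  expect_error(sim_config(drift_F = 0), "drift_F")
  expect_error(sim_config(drift_F = 1), "drift_F")
  expect_error(sim_config(mean_depth = 0.5), "mean_depth")
  expect_error(sim_config(contig_lengths = numeric(0)), "contig_lengths")
  expect_error(
    sim_config(contig_lengths = c(c1 = 1000),
               sweep_specs = list(sweep_spec("c1", 500, 2000, 1L))),
    "exceeds contig"
  )
  expect_error(sweep_spec("c1", 10, 10, 1L), "end must exceed")
  expect_error(sweep_spec("c1", 0, 10, integer(0)), "non-empty")
  expect_error(sweep_spec("c1", 0, 10, 1L, fixation_push = 1.2), "fixation_push")
})

test_that("Balding-Nichols frequencies concentrate at the ancestral value as F -> 0", {
  cfg <- sim_config(n_populations = 3, contig_lengths = c(c1 = 1e6),
                    snv_density = 0.002, drift_F = 1e-6, seed = 11)
  ft <- simulate_population_frequencies(cfg)
  for (p in cfg$population_names) {
    expect_gte(mean(abs(ft[[p]] - ft$ancestral) < 0.01), 0.99)
  }
  expect_true(all(ft$ancestral >= 0.05 & ft$ancestral <= 0.95))
})

test_that("the generator is deterministic in the seed", {
  cfg <- sim_config(n_populations = 2, contig_lengths = c(c1 = 5e5),
                    snv_density = 0.001, seed = 3)
  ft1 <- simulate_population_frequencies(cfg)
  ft2 <- simulate_population_frequencies(cfg)
  expect_identical(ft1, ft2)
  v1 <- sample_pooled_reads(ft1, 12, seed = 4)
  v2 <- sample_pooled_reads(ft2, 12, seed = 4)
  expect_identical(as.data.frame(v1), as.data.frame(v2))
})

test_that("plant_sweeps moves frequencies toward the nearer boundary", {
  cfg <- sim_config(n_populations = 3, contig_lengths = c(c1 = 1e5),
                    snv_density = 0.002, seed = 5)
  ft <- simulate_population_frequencies(cfg)
  sw0 <- list(sweep_spec("c1", 0, 5e4, 2L, fixation_push = 0))
  expect_equal(plant_sweeps(ft, sw0), ft)

  sw1 <- list(sweep_spec("c1", 0, 1e5, 2L, fixation_push = 1))
  out <- plant_sweeps(ft, sw1)
  expect_true(all(out$pop2 %in% c(0, 1)))
  expect_identical(out$pop1, ft$pop1)  # non-target populations untouched
  expect_identical(out$pop3, ft$pop3)
  # 0.3 -> 0 under full push
  ft2 <- data.table::copy(ft)
  data.table::set(ft2, 1L, "pop2", 0.3)
  expect_identical(plant_sweeps(ft2, sw1)$pop2[1], 0)

  expect_error(
    plant_sweeps(ft, list(sweep_spec("c1", 0, 5e4, 1L),
                          sweep_spec("c1", 4e4, 9e4, 2L))),
    "conflicting"
  )
})

test_that("a 0.9 push collapses expected heterozygosity by at least 70%", {
  set.seed(8)
  n <- 100
  ft <- data.table::data.table(contig = "c1", pos = seq_len(n) * 10L,
                               ancestral = runif(n, 0.05, 0.95))
  for (p in c("pop1", "pop2")) ft[, (p) := runif(n, 0.2, 0.8)]
  data.table::setattr(ft, "populations", c("pop1", "pop2"))
  out <- plant_sweeps(ft, list(sweep_spec("c1", 0, 1001, 1L, fixation_push = 0.9)))
  het <- function(f) mean(2 * f * (1 - f))
  expect_lte(het(out$pop1), 0.3 * het(ft$pop1))
  expect_equal(het(out$pop2), het(ft$pop2))
})

test_that("read sampling honours the monomorphic-drop and fixed-allele limits", {
  n <- 200
  ft <- data.table::data.table(contig = "c1", pos = seq_len(n) * 10L,
                               ancestral = 0.5, pop1 = 0, pop2 = 0)
  data.table::setattr(ft, "populations", c("pop1", "pop2"))
  expect_length(sample_pooled_reads(ft, 20, seed = 1), 0)

  ft[, c("pop1", "pop2") := list(1, 1)]
  v <- sample_pooled_reads(ft, 20, seed = 1)
  expect_gt(length(v), 0)
  expect_true(all(v$ref_counts == 0))
  expect_true(all(pool_depth(v) == v$alt_counts))
})

test_that("observed mean pool depth matches the Poisson mean", {
  n <- 10000
  set.seed(2)
  ft <- data.table::data.table(contig = "c1", pos = seq_len(n) * 10L,
                               ancestral = 0.5,
                               pop1 = runif(n, 0.2, 0.8), pop2 = runif(n, 0.2, 0.8))
  data.table::setattr(ft, "populations", c("pop1", "pop2"))
  v <- sample_pooled_reads(ft, 12, seed = 3)
  expect_lt(abs(mean(pool_depth(v)) - 12), 0.5)
})

test_that("fixture bundle files are complete, deterministic and truth-consistent", {
  fx <- fixture_bundle()
  b <- fx$bundle
  expect_true(all(file.exists(unlist(b$paths[c("vcf", "gff", "truth_bed")]))))

  # VCF record count equals the generator's polymorphic-site count
  body <- grep("^#", readLines(b$paths$vcf), invert = TRUE, value = TRUE)
  expect_identical(length(body), length(b$variants))

  # conservation of reads: AD pair sums to DP in every pool of every record
  gt <- strsplit(sub("^([^\t]*\t){9}", "", body[1:50]), "\t")
  for (rec in gt) {
    for (cell in rec) {
      ad <- as.integer(strsplit(strsplit(cell, ":")[[1]][1], ",")[[1]])
      dp <- as.integer(strsplit(cell, ":")[[1]][2])
      expect_identical(sum(ad), dp)
    }
  }

  # truth BED matches the sweep specs
  bed <- read.table(b$paths$truth_bed, sep = "\t")
  expect_identical(nrow(bed), length(fx$config$sweep_specs))
  expect_identical(bed$V2, vapply(fx$config$sweep_specs, function(s) as.integer(s$start), 1L))

  # re-running the generator reproduces byte-identical files
  b2 <- write_fixture_bundle(fx$config, tempfile("bundle_rerun"))
  for (f in c("vcf", "gff", "truth_bed", "truth_specific", "truth_conserved")) {
    expect_identical(readLines(b2$paths[[f]]), readLines(b$paths[[f]]))
  }
  a1 <- list.files(b$paths$alignments_dir, full.names = TRUE)
  a2 <- list.files(b2$paths$alignments_dir, full.names = TRUE)
  expect_identical(basename(a1), basename(a2))
  expect_identical(lapply(a1, readLines), lapply(a2, readLines))
})

test_that("no sweeps means an empty truth BED", {
  cfg <- sim_config(n_populations = 2, contig_lengths = c(c1 = 3e5),
                    snv_density = 0.001, seed = 9)
  b <- write_fixture_bundle(cfg, tempfile("nosweep"))
  expect_identical(nrow(b$truth$sweeps), 0L)
  expect_identical(length(readLines(b$paths$truth_bed)), 0L)
})

test_that("planted sweeps depress windowed Hp below the genome-wide 1st percentile", {
  # averaged over 5 seeds: mean Hp of windows fully inside a full-push sweep
  # sits below the 1st percentile of all retained windows
  ratios <- vapply(1:5, function(seed) {
    sw <- list(sweep_spec("c1", 1.0e6, 1.075e6, 1L, 1))
    cfg <- sim_config(n_populations = 3, contig_lengths = c(c1 = 4e6),
                      snv_density = 0.004, mean_depth = 12,
                      sweep_specs = sw, seed = seed)
    ft <- plant_sweeps(simulate_population_frequencies(cfg), sw)
    v <- sample_pooled_reads(ft, cfg$mean_depth, seed + 100)
    w <- make_windows(cfg$contig_lengths)
    hp <- retain_windows(windowed_hp(v, w))
    keep <- hp$population == "pop1"
    hp1 <- hp[keep, ]
    inside <- hp1$start >= 1.0e6 & hp1$end <= 1.075e6
    mean(hp1$hp[inside]) - quantile(hp1$hp, 0.01, names = FALSE)
  }, numeric(1))
  expect_lt(mean(ratios), 0)
})
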