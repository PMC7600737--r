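write_alignment <- function(rows, gene_id = "gX") {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(rows), function(n) c(paste0(">", n), rows[[n]]))),
             path)
  path
}

test_that("breed-specific SNVs require presence in focal and absence elsewhere", {
  v <- toy_variants(list(
    c(0, 20, 20, 0, 18, 0),    # alt fixed in pop1, absent elsewhere -> specific
    c(10, 10, 20, 0, 20, 0),   # alt at 0.5 in pop1 -> not specific
    c(20, 0, 0, 20, 0, 20),    # ref specific to pop1 (mirrored condition)
    c(0, 20, 16, 4, 20, 0),    # alt at 0.2 in pop2 -> not specific
    c(1, 19, 20, 1, 19, 0)     # 0.95 focal / 0.048 elsewhere -> specific
  ))
  sp <- breed_specific_snvs(v, "pop1")
  expect_identical(sp$pos, c(100L, 300L, 500L))
  expect_identical(attr(sp, "which_allele"), c("alt", "ref", "alt"))

  # zero depth anywhere skips the site with a warning
  v2 <- toy_variants(list(c(0, 20, 0, 0, 18, 0)))
  expect_warning(sp2 <- breed_specific_snvs(v2, "pop1"), "zero depth")
  expect_length(sp2, 0)
})

test_that("tightening specificity thresholds never adds SNVs", {
  v <- random_variants(400, n_pops = 3, seed = 67)
  base <- length(breed_specific_snvs(v, "pop1", 0.8, 0.2))
  expect_lte(length(breed_specific_snvs(v, "pop1", 0.9, 0.2)), base)
  expect_lte(length(breed_specific_snvs(v, "pop1", 0.8, 0.1)), base)
  expect_lte(length(breed_specific_snvs(v, "pop1", 0.95, 0.05)), base)
})

test_that("gene flanks extend and clip correctly", {
  genes <- data.table::data.table(
    gene_id = c("g1", "g2"), contig = "c1",
    start = c(5001L, 300L), end = c(6000L, 1200L),
    strand = "+", name = NA_character_
  )
  fl <- gene_flank_regions(genes, 1000)
  expect_identical(fl$start, c(4001L, 1L))    # g2 clipped at contig start
  expect_identical(fl$end, c(7000L, 2200L))
  fl0 <- gene_flank_regions(genes, 0)
  expect_identical(fl0$start, genes$start)
  expect_identical(fl0$end, genes$end)
  flc <- gene_flank_regions(genes, 1000, contig_lengths = c(c1 = 6500))
  expect_identical(flc$end, c(6500L, 2200L))
})

test_that("conserved columns are identical non-gap columns mapped to the genome", {
  rows <- list(
    "reference|gX" = "ACGTAC",
    sp1            = "ACTTAC",
    sp2            = "ACGT-C",
    sp3            = "acgTAg"   # case must not matter
  )
  aln <- read_species_alignment(write_alignment(rows), "gX", gene_start = 1001)
  cons <- find_conserved_sites(aln, max_gap_rows = 0)
  # col1 A identical; col2 C identical; col3 G/T mismatch; col4 T identical;
  # col5 gap in sp2; col6 C/C/C/G mismatch
  expect_identical(cons$column, c(1L, 2L, 4L))
  expect_identical(cons$pos, c(1001L, 1002L, 1004L))
  expect_identical(cons$base, c("A", "C", "T"))

  # relaxing the gap allowance admits the gapped-but-identical column 5
  cons1 <- find_conserved_sites(aln, max_gap_rows = 1)
  expect_true(5L %in% cons1$column)

  # row order invariance
  aln_r <- read_species_alignment(write_alignment(rows[c(3, 1, 4, 2)]), "gX", 1001)
  expect_identical(find_conserved_sites(aln_r)$column, cons$column)
})

test_that("reference gaps shift the coordinate map and drop genomic positions", {
  rows <- list("reference|gY" = "AC-TA", sp1 = "ACGTA", sp2 = "ACGTA")
  aln <- read_species_alignment(write_alignment(rows, "gY"), "gY", gene_start = 501)
  expect_identical(aln$coord_map, c(501L, 502L, NA_integer_, 503L, 504L))
  cons <- find_conserved_sites(aln, max_gap_rows = 1)
  expect_true(is.na(cons$pos[cons$column == 3]))  # conserved col, no ref coordinate
  expect_identical(cons$pos[cons$column == 4], 503L)
})

test_that("alignment reader validates shape and reference row", {
  rows <- list("reference|gZ" = "ACGT", sp1 = "ACG")
  expect_error(read_species_alignment(write_alignment(rows, "gZ"), "gZ", 1),
               ">= 3 rows")
  rows3 <- list("reference|gZ" = "ACGT", sp1 = "ACGT", sp2 = "ACG")
  expect_error(read_species_alignment(write_alignment(rows3, "gZ"), "gZ", 1),
               "differ in length")
  rows4 <- list(refX = "ACGT", sp1 = "ACGT", sp2 = "ACGT")
  expect_error(read_species_alignment(write_alignment(rows4, "gZ"), "gZ", 1),
               "reference\\|gZ")
})

test_that("intersection keeps only conserved positions and labels coding state", {
  genes <- data.table::data.table(gene_id = "g1", contig = "c1",
                                  start = 1000L, end = 1999L,
                                  strand = "+", name = NA_character_)
  cds <- data.table::data.table(gene_id = "g1", contig = "c1",
                                start = 1400L, end = 1599L, strand = "+")
  cons <- data.table::data.table(gene_id = "g1", column = c(101L, 451L, 901L),
                                 pos = c(1100L, 1450L, 1900L), base = "A")
  sp <- toy_variants(list(c(0, 20, 20, 0), c(0, 20, 20, 0), c(0, 20, 20, 0)),
                     pos = c(1100L, 1450L, 1200L), contig = "c1")
  out <- intersect_and_classify(sp, cons, genes, cds, population = "pop1")
  expect_identical(out$pos, c(1100L, 1450L))  # 1200 is not conserved
  expect_identical(out$coding, c(FALSE, TRUE))
  expect_identical(unique(out$population), "pop1")

  none <- intersect_and_classify(sp[integer(0)], cons, genes, cds)
  expect_identical(nrow(none), 0L)
})

test_that("fixture truth: planted conserved columns and specific SNVs recover exactly", {
  fx <- fixture_bundle()
  b <- fx$bundle
  models <- read_gene_models(b$paths$gff)
  for (gid in c("gene_sweep_01", "gene_sweep_02")) {
    g <- models$genes[models$genes$gene_id == gid, ]
    aln <- read_species_alignment(
      file.path(b$paths$alignments_dir, paste0(gid, ".fa")), gid, g$start)
    cons <- find_conserved_sites(aln)
    truth_rows <- b$truth$conserved_sites$gene_id == gid
    expect_identical(cons$pos, b$truth$conserved_sites$pos[truth_rows])
  }
})
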