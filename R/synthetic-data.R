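#' Simulation configuration for synthetic Pool-seq data
#'
#' Describes a synthetic multi-population pooled-sequencing experiment:
#' a genome of one or more contigs, SNVs at a given density with ancestral
#' allele frequencies drawn uniformly, per-population frequencies drawn from
#' the Balding-Nichols model around the ancestral value, pooled read counts
#' at a given mean depth, and optional planted selective sweeps.
#'
#' Defaults emulate the study design this package targets: six pooled breed
#' libraries at 10-13x coverage over a multi-megabase genome with background
#' differentiation of a few percent.
#'
#' @param n_populations number of pooled populations (>= 2).
#' @param contig_lengths named integer vector of contig lengths in bp.
#' @param snv_density expected SNVs per bp (sites are placed uniformly).
#' @param ancestral_freq_range ancestral allele frequencies are drawn
#'   uniformly on this interval; the default (0.05, 0.95) avoids an excess
#'   of rare alleles, mirroring call sets from which rare alleles have
#'   already been removed.
#' @param drift_F Balding-Nichols differentiation parameter in (0,1); the
#'   expected pairwise Fst between populations.
#' @param mean_depth mean per-pool read depth (Poisson).
#' @param sweep_specs list of [sweep_spec()] objects.
#' @param qual_fail_fraction fraction of sites assigned a synthetic QUAL
#'   below 30, to exercise quality filtering.
#' @param population_names optional character vector of population ids.
#' @param seed integer seed; all outputs are pure functions of the config.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_populations = 6,
                       contig_lengths = c(ctg1 = 1e7, ctg2 = 1e7),
                       snv_density = 0.005,
                       ancestral_freq_range = c(0.05, 0.95),
                       drift_F = 0.05,
                       mean_depth = 12,
                       sweep_specs = list(),
                       qual_fail_fraction = 0.05,
                       population_names = NULL,
                       seed = 1L) {
  if (n_populations < 2) stop("n_populations must be >= 2")
  if (length(contig_lengths) == 0 || any(contig_lengths <= 0)) {
    stop("contig_lengths must be a non-empty vector of positive lengths")
  }
  if (is.null(names(contig_lengths))) {
    names(contig_lengths) <- paste0("ctg", seq_along(contig_lengths))
  }
  if (!(drift_F > 0 && drift_F < 1)) stop("drift_F must lie in (0, 1)")
  if (mean_depth < 1) stop("mean_depth must be >= 1")
  if (length(ancestral_freq_range) != 2 ||
      ancestral_freq_range[1] >= ancestral_freq_range[2] ||
      ancestral_freq_range[1] < 0 || ancestral_freq_range[2] > 1) {
    stop("ancestral_freq_range must be an increasing pair within [0, 1]")
  }
  if (is.null(population_names)) {
    population_names <- paste0("pop", seq_len(n_populations))
  }
  stopifnot(length(population_names) == n_populations)
  for (sw in sweep_specs) {
    if (!inherits(sw, "sweep_spec")) stop("sweep_specs must be sweep_spec objects")
    if (!sw$contig %in% names(contig_lengths)) {
      stop("sweep contig '", sw$contig, "' not in contig_lengths")
    }
    if (sw$end > contig_lengths[[sw$contig]]) {
      stop("sweep [", sw$start, ",", sw$end, ") exceeds contig '", sw$contig, "'")
    }
    if (any(sw$target_populations > n_populations | sw$target_populations < 1)) {
      stop("sweep target population index out of range")
    }
  }
  structure(
    list(
      n_populations = as.integer(n_populations),
      contig_lengths = contig_lengths,
      snv_density = snv_density,
      ancestral_freq_range = ancestral_freq_range,
      drift_F = drift_F,
      mean_depth = mean_depth,
      sweep_specs = sweep_specs,
      qual_fail_fraction = qual_fail_fraction,
      population_names = population_names,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Planted selective sweep
#'
#' A genomic interval in which target-population allele frequencies are
#' pushed toward fixation, jointly depressing pooled heterozygosity and
#' elevating differentiation - the signal a ZHp/di scan detects.
#'
#' @param contig contig id.
#' @param start,end 0-based half-open interval in bp.
#' @param target_populations integer indices of affected populations.
#' @param fixation_push fraction in [0, 1] by which each target-population
#'   frequency f moves toward the nearer of 0/1: f + push * (round(f) - f).
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(contig, start, end, target_populations, fixation_push = 1) {
  if (end <= start) stop("sweep end must exceed start")
  if (fixation_push < 0 || fixation_push > 1) stop("fixation_push must lie in [0, 1]")
  if (length(target_populations) == 0) stop("target_populations must be non-empty")
  structure(
    list(
      contig = as.character(contig), start = as.numeric(start),
      end = as.numeric(end),
      target_populations = as.integer(target_populations),
      fixation_push = fixation_push
    ),
    class = "sweep_spec"
  )
}

#' Simulate per-population allele frequencies
#'
#' Places SNVs uniformly along each contig, draws each site's ancestral
#' frequency p uniformly from the configured range, and draws each
#' population's frequency from the Balding-Nichols model,
#' Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean p and variance F p(1-p).
#'
#' @param config a [sim_config()].
#' @return A [data.table::data.table] with columns `contig`, `pos` (1-based),
#'   `ancestral`, and one frequency column per population.
#' @export
simulate_population_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tabs <- lapply(names(config$contig_lengths), function(ctg) {
    L <- config$contig_lengths[[ctg]]
    n <- max(1L, as.integer(round(L * config$snv_density)))
    pos <- sort(sample.int(L, n, replace = FALSE))
    data.table::data.table(contig = ctg, pos = pos)
  })
  ft <- data.table::rbindlist(tabs)
  n <- nrow(ft)
  rng <- config$ancestral_freq_range
  ft[, "ancestral" := stats::runif(n, rng[1], rng[2])]
  F <- config$drift_F
  scale <- (1 - F) / F
  for (pn in config$population_names) {
    ft[, (pn) := stats::rbeta(n, ft$ancestral * scale, (1 - ft$ancestral) * scale)]
  }
  data.table::setattr(ft, "populations", config$population_names)
  ft[]
}

#' Push allele frequencies toward fixation inside planted sweeps
#'
#' Inside each sweep, for target populations only, each frequency f becomes
#' f + fixation_push * (round(f) - f), i.e. it moves the given fraction of
#' the way toward the nearer of 0 and 1 (f = 0.5 resolves to 0). Frequencies
#' outside sweeps and in non-target populations are unchanged.
#'
#' @param freq_table output of [simulate_population_frequencies()].
#' @param sweep_specs list of [sweep_spec()] objects; overlapping sweeps
#'   with different target populations are an error.
#' @return A modified copy of `freq_table`.
#' @export
plant_sweeps <- function(freq_table, sweep_specs) {
  pops <- attr(freq_table, "populations")
  stopifnot(!is.null(pops))
  if (length(sweep_specs) > 1) {
    for (i in seq_along(sweep_specs)) {
      for (j in seq_len(i - 1L)) {
        a <- sweep_specs[[i]]; b <- sweep_specs[[j]]
        if (a$contig == b$contig && a$start < b$end && b$start < a$end &&
            !setequal(a$target_populations, b$target_populations)) {
          stop("overlapping sweeps with conflicting target populations")
        }
      }
    }
  }
  out <- data.table::copy(freq_table)
  for (sw in sweep_specs) {
    # sweep interval is 0-based half-open; pos is 1-based
    in_sweep <- out$contig == sw$contig & out$pos > sw$start & out$pos <= sw$end
    for (pi in sw$target_populations) {
      pn <- pops[pi]
      f <- out[[pn]][in_sweep]
      data.table::set(out, which(in_sweep), pn, f + sw$fixation_push * (round(f) - f))
    }
  }
  data.table::setattr(out, "populations", pops)
  out[]
}

#' Sample pooled read counts from simulated frequencies
#'
#' Per site and pool, total depth ~ Poisson(mean_depth) and the alternate
#' read count ~ Binomial(depth, f). Sites with no alternate read in any pool
#' (reference-monomorphic in the sample) are dropped, mirroring the fact
#' that a caller only emits sites with alternate-allele evidence; sites
#' fixed for the alternate allele in every pool are kept. Each
#' record receives a synthetic QUAL; a configurable fraction falls below 30
#' so that quality filtering has something to remove.
#'
#' @param freq_table frequency table (possibly after [plant_sweeps()]).
#' @param mean_depth mean per-pool depth.
#' @param seed integer seed for the read-sampling RNG.
#' @param qual_fail_fraction fraction of sites with QUAL below 30.
#' @return A [pooled_variants] object.
#' @export
sample_pooled_reads <- function(freq_table, mean_depth, seed,
                                qual_fail_fraction = 0.05) {
  stopifnot(mean_depth >= 1)
  pops <- attr(freq_table, "populations")
  stopifnot(!is.null(pops))
  set.seed(seed)
  n <- nrow(freq_table)
  P <- length(pops)
  depth <- matrix(stats::rpois(n * P, mean_depth), nrow = n, ncol = P)
  freqs <- as.matrix(freq_table[, pops, with = FALSE])
  altc <- matrix(stats::rbinom(n * P, as.vector(depth), as.vector(freqs)),
                 nrow = n, ncol = P)
  refc <- depth - altc
  colnames(refc) <- colnames(altc) <- pops

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- bases[(match(ref, bases) + sample.int(3, n, replace = TRUE) - 1L) %% 4L + 1L]
  fail <- stats::runif(n) < qual_fail_fraction
  qual <- round(ifelse(fail, stats::runif(n, 10, 29.9), stats::runif(n, 30, 60)), 2)

  # a site enters a call set only with alternate-allele evidence; sites
  # fixed for alt in every pool are still variants relative to the reference
  poly <- rowSums(altc) > 0 & rowSums(depth) > 0
  pooled_variants(
    freq_table$contig[poly], freq_table$pos[poly], ref[poly], alt[poly],
    qual[poly], refc[poly, , drop = FALSE], altc[poly, , drop = FALSE]
  )
}

base_mutate <- function(b, shift) {
  bases <- c("A", "C", "G", "T")
  bases[(match(b, bases) + shift - 1L) %% 4L + 1L]
}

#' Write a complete synthetic fixture bundle
#'
#' Runs the full generator (frequencies, planted sweeps, planted
#' breed-specific variants, pooled read sampling) and writes a
#' standards-compliant set of files: a VCF 4.2 with per-pool AD fields, a
#' GFF3 with genes placed inside and outside sweeps (each with a CDS), one
#' multi-FASTA 12-species alignment per gene with planted conserved columns,
#' and a BED6 truth file of sweep intervals.
#'
#' Each sweep carries one 2-kb gene at its centre; two additional background
#' genes are placed per contig away from any sweep. For every sweep gene,
#' breed-specific SNVs (alternate allele fixed in the sweep's first target
#' population, absent elsewhere) are planted at conserved alignment columns,
#' one inside the gene's CDS and one outside it. Alignment columns that
#' coincide with any other VCF variant are forced non-conserved, so the
#' truth tables are exact by construction.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return A list with `paths` (vcf, gff, alignments_dir, truth_bed,
#'   truth_specific, truth_conserved), `truth` (data.tables: `sweeps`,
#'   `specific_snvs`, `conserved_sites`), and the `variants` object written
#'   to the VCF.
#' @export
write_fixture_bundle <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pops <- config$population_names

  ft <- simulate_population_frequencies(config)

  # gene placement: one gene centred in each sweep, two background genes per contig
  gene_len <- 2000L
  cds_off <- 700L; cds_len <- 600L
  genes <- list()
  gi <- 0L
  for (si in seq_along(config$sweep_specs)) {
    sw <- config$sweep_specs[[si]]
    gi <- gi + 1L
    mid <- floor((sw$start + sw$end) / 2)
    gstart <- as.integer(mid - gene_len / 2 + 1L)  # 1-based inclusive
    genes[[gi]] <- list(
      gene_id = sprintf("gene_sweep_%02d", si), contig = sw$contig,
      start = gstart, end = gstart + gene_len - 1L,
      sweep = si, focal = pops[sw$target_populations[1]]
    )
  }
  for (ctg in names(config$contig_lengths)) {
    L <- config$contig_lengths[[ctg]]
    anchors <- as.integer(c(floor(L * 0.1), floor(L * 0.8)))
    for (a in anchors) {
      cand <- c(a, as.integer(floor(L * 0.45)), as.integer(floor(L * 0.62)))
      placed <- FALSE
      for (gstart in cand) {
        gend <- gstart + gene_len - 1L
        clash <- any(vapply(config$sweep_specs, function(sw) {
          sw$contig == ctg && gstart <= sw$end + gene_len && gend >= sw$start - gene_len
        }, logical(1)))
        if (!clash && gend <= L) {
          gi <- gi + 1L
          genes[[gi]] <- list(
            gene_id = sprintf("gene_bg_%s_%d", ctg, gstart), contig = ctg,
            start = gstart, end = gend, sweep = NA_integer_, focal = NA_character_
          )
          placed <- TRUE
          break
        }
      }
      if (!placed) next
    }
  }

  # plant breed-specific variants in sweep genes: fixed alt in the focal
  # pool, absent elsewhere; one in the CDS, one outside it
  specific <- data.table::data.table(
    gene_id = character(), contig = character(), pos = integer(),
    population = character(), coding = logical()
  )
  for (g in genes) {
    if (is.na(g$sweep)) next
    pos_cds <- g$start + cds_off + 103L
    pos_non <- g$start + 211L
    for (row in list(list(pos_cds, TRUE), list(pos_non, FALSE))) {
      p <- row[[1]]
      ft <- ft[!(contig == g$contig & pos == p)]
      newrow <- data.table::data.table(contig = g$contig, pos = p, ancestral = 0.5)
      for (pn in pops) newrow[, (pn) := if (pn == g$focal) 1 else 0]
      ft <- data.table::rbindlist(list(ft, newrow), use.names = TRUE)
      specific <- data.table::rbindlist(list(specific, data.table::data.table(
        gene_id = g$gene_id, contig = g$contig, pos = p,
        population = g$focal, coding = row[[2]]
      )))
    }
  }
  data.table::setorder(ft, contig, pos)
  data.table::setattr(ft, "populations", pops)

  ft <- plant_sweeps(ft, config$sweep_specs)
  variants <- sample_pooled_reads(ft, config$mean_depth, config$seed + 1L,
                                  config$qual_fail_fraction)

  vcf_path <- file.path(out_dir, "variants.vcf")
  write_pooled_vcf(variants, vcf_path, contig_lengths = config$contig_lengths)

  gff_path <- file.path(out_dir, "genes.gff3")
  write_fixture_gff3(genes, config$contig_lengths, cds_off, cds_len, gff_path)

  # alignments: conserved columns avoid all non-planted variant positions
  aln_dir <- file.path(out_dir, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  set.seed(config$seed + 2L)
  conserved <- list()
  vpos <- split(variants$pos, variants$contig)
  planted_key <- paste(specific$contig, specific$pos)
  for (g in genes) {
    gpos <- g$start:g$end
    has_variant <- gpos %in% vpos[[g$contig]]
    is_planted <- paste(g$contig, gpos) %in% planted_key
    candidate <- which(!has_variant | is_planted)
    cons_cols <- sort(unique(c(which(is_planted), candidate[seq(1, length(candidate), by = 7)])))
    gap_pool <- setdiff(candidate, cons_cols)
    gap_cols <- gap_pool[seq_len(min(3L, length(gap_pool)))]
    write_fixture_alignment(g, cons_cols, gap_cols, aln_dir)
    conserved[[g$gene_id]] <- data.table::data.table(
      gene_id = g$gene_id, contig = g$contig, pos = g$start + cons_cols - 1L,
      column = cons_cols
    )
  }
  conserved <- data.table::rbindlist(conserved)

  bed_path <- file.path(out_dir, "truth_sweeps.bed")
  sweeps <- data.table::rbindlist(lapply(seq_along(config$sweep_specs), function(si) {
    sw <- config$sweep_specs[[si]]
    data.table::data.table(
      contig = sw$contig, start = as.integer(sw$start), end = as.integer(sw$end),
      name = sprintf("sweep_%02d|%s", si,
                     paste(pops[sw$target_populations], collapse = ",")),
      score = 0L, strand = "."
    )
  }))
  if (nrow(sweeps) == 0) {
    sweeps <- data.table::data.table(
      contig = character(), start = integer(), end = integer(),
      name = character(), score = integer(), strand = character()
    )
  }
  utils::write.table(sweeps, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  spec_path <- file.path(out_dir, "truth_specific_snvs.tsv")
  utils::write.table(specific, spec_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cons_path <- file.path(out_dir, "truth_conserved_sites.tsv")
  utils::write.table(conserved, cons_path, sep = "\t", quote = FALSE, row.names = FALSE)

  list(
    paths = list(
      vcf = vcf_path, gff = gff_path, alignments_dir = aln_dir,
      truth_bed = bed_path, truth_specific = spec_path, truth_conserved = cons_path
    ),
    truth = list(sweeps = sweeps, specific_snvs = specific, conserved_sites = conserved),
    variants = variants
  )
}

write_fixture_gff3 <- function(genes, contig_lengths, cds_off, cds_len, path) {
  lines <- c("##gff-version 3")
  for (ctg in names(contig_lengths)) {
    lines <- c(lines, sprintf("##sequence-region %s 1 %d", ctg,
                              as.integer(contig_lengths[[ctg]])))
  }
  for (g in genes) {
    cs <- g$start + cds_off
    ce <- cs + cds_len - 1L
    lines <- c(
      lines,
      sprintf("%s\tpoolsweep\tgene\t%d\t%d\t.\t+\t.\tID=%s;Name=%s",
              g$contig, g$start, g$end, g$gene_id, g$gene_id),
      sprintf("%s\tpoolsweep\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.t1;Parent=%s",
              g$contig, g$start, g$end, g$gene_id, g$gene_id),
      sprintf("%s\tpoolsweep\tCDS\t%d\t%d\t.\t+\t0\tID=%s.cds;Parent=%s.t1",
              g$contig, cs, ce, g$gene_id, g$gene_id)
    )
  }
  writeLines(lines, path)
}

write_fixture_alignment <- function(g, cons_cols, gap_cols, aln_dir) {
  n_species <- 11L
  glen <- g$end - g$start + 1L
  bases <- c("A", "C", "G", "T")
  refseq <- sample(bases, glen, replace = TRUE)
  rows <- matrix(rep(refseq, each = n_species + 1L), nrow = n_species + 1L)
  variable <- setdiff(seq_len(glen), c(cons_cols, gap_cols))
  # every variable column gets at least one mismatching species
  for (col in variable) {
    k <- 1L + (col %% 3L)                      # 2-4 mismatching species
    sp <- 1L + ((col + seq_len(k)) %% n_species)
    rows[1L + sp, col] <- base_mutate(refseq[col], 1L + (col + sp) %% 3L)
  }
  for (col in gap_cols) {
    sp <- 1L + (col %% n_species)
    rows[1L + sp, col] <- "-"
  }
  seqs <- apply(rows, 1, paste, collapse = "")
  names(seqs) <- c(paste0("reference|", g$gene_id),
                   sprintf("species_%02d", seq_len(n_species)))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs),
    file.path(aln_dir, paste0(g$gene_id, ".fa"))
  )
  invisible(NULL)
}
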