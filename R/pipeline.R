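#' Run configuration for a full selection scan
#'
#' Bundles every tunable of the pipeline. The defaults mirror the scan this
#' package implements: 50-kb windows with a 25-kb step, windows used only
#' when they hold more than 10 SNVs, QUAL >= 30, summed coverage >= 68,
#' >= 3 alternate reads, calling at ZHp < -7 together with di in the top 1%,
#' and a 1000-bp flank for the conservation screen.
#'
#' @param vcf path to the pooled VCF.
#' @param gff path to the GFF3 gene annotation.
#' @param out_dir output directory.
#' @param alignments_dir optional directory of per-gene multi-FASTA
#'   alignments (`<gene_id>.fa`) for the conservation screen.
#' @param window_size,window_step window geometry in bp.
#' @param min_snvs strict minimum SNV count per retained window.
#' @param min_qual,min_coverage,min_alt_reads SNV filter thresholds.
#' @param coverage_per_pool apply the coverage threshold per pool instead of
#'   to the summed depth.
#' @param zhp_cutoff ZHp calling cutoff (windows below it qualify).
#' @param di_top_fraction di calling cutoff as an upper-tail fraction.
#' @param di_cutoff absolute di cutoff; overrides `di_top_fraction`.
#' @param presence_min,absence_max breed-specificity thresholds.
#' @param flank bp around genes for the conservation screen.
#' @param seed integer seed recorded in the manifest.
#' @return An object of class `run_config`.
#' @export
run_config <- function(vcf, gff, out_dir,
                       alignments_dir = NULL,
                       window_size = 50000L, window_step = 25000L,
                       min_snvs = 10L,
                       min_qual = 30, min_coverage = 68, min_alt_reads = 3,
                       coverage_per_pool = FALSE,
                       zhp_cutoff = -7,
                       di_top_fraction = 0.01, di_cutoff = NULL,
                       presence_min = 0.9, absence_max = 0.1,
                       flank = 1000L, seed = 1L) {
  structure(
    list(
      vcf = vcf, gff = gff, out_dir = out_dir,
      alignments_dir = alignments_dir,
      window_size = as.integer(window_size),
      window_step = as.integer(window_step),
      min_snvs = as.integer(min_snvs),
      min_qual = min_qual, min_coverage = min_coverage,
      min_alt_reads = min_alt_reads, coverage_per_pool = coverage_per_pool,
      zhp_cutoff = zhp_cutoff, di_top_fraction = di_top_fraction,
      di_cutoff = di_cutoff,
      presence_min = presence_min, absence_max = absence_max,
      flank = as.integer(flank), seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Validate a run configuration
#'
#' @param config a [run_config()].
#' @return character vector of problems, each naming the offending field;
#'   empty iff the configuration is runnable.
#' @export
validate_config <- function(config) {
  p <- character()
  if (is.null(config$vcf) || !file.exists(config$vcf)) {
    p <- c(p, "vcf: file missing or not found")
  }
  if (is.null(config$gff) || !file.exists(config$gff)) {
    p <- c(p, "gff: file missing or not found")
  }
  if (!is.null(config$alignments_dir) && !dir.exists(config$alignments_dir)) {
    p <- c(p, "alignments_dir: directory not found")
  }
  if (config$window_step <= 0 || config$window_step > config$window_size) {
    p <- c(p, "window_step: must satisfy 0 < step <= window_size")
  }
  if (config$min_qual < 0) p <- c(p, "min_qual: must be >= 0")
  if (config$min_coverage < 0) p <- c(p, "min_coverage: must be >= 0")
  if (config$min_alt_reads < 0) p <- c(p, "min_alt_reads: must be >= 0")
  if (config$min_snvs < 0) p <- c(p, "min_snvs: must be >= 0")
  if (config$di_top_fraction <= 0 || config$di_top_fraction >= 1) {
    p <- c(p, "di_top_fraction: must lie in (0, 1)")
  }
  if (config$presence_min <= 0 || config$presence_min > 1) {
    p <- c(p, "presence_min: must lie in (0, 1]")
  }
  if (config$absence_max < 0 || config$absence_max >= 1) {
    p <- c(p, "absence_max: must lie in [0, 1)")
  }
  if (config$flank < 0) p <- c(p, "flank: must be >= 0")
  p
}

write_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t")
  path
}

#' Run the full selection scan
#'
#' Executes filter -> windows/Hp/ZHp -> Fst/di -> calling -> gene
#' annotation -> conservation screen, writes every stage's table under
#' `out_dir`, and returns (and writes) a JSON manifest with the config
#' echo, per-stage record counts and output paths. A stage failure aborts
#' with the stage name prefixed to the error.
#'
#' @param config a [run_config()].
#' @return The manifest, invisibly a list (also written as
#'   `manifest.json`). Stage tables are additionally returned in the
#'   `tables` element for programmatic use.
#' @export
run_full_scan <- function(config) {
  problems <- validate_config(config)
  if (length(problems) > 0) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  variants <- stage("read_vcf", read_pooled_vcf(config$vcf))
  fc <- filter_config(config$min_qual, config$min_coverage, config$min_alt_reads,
                      coverage_per_pool = config$coverage_per_pool)
  filt <- stage("filter", filter_variants(variants, fc))
  kept <- filt$kept
  if (length(kept) == 0) stop("stage 'filter' failed: no variants pass the filters")

  contig_lengths <- attr(variants, "contig_lengths")
  if (is.null(contig_lengths) || anyNA(contig_lengths)) {
    contig_lengths <- tapply(kept$pos, kept$contig, max)
  }
  windows <- stage("windows", make_windows(contig_lengths, config$window_size,
                                           config$window_step))
  hp <- stage("hp", windowed_hp(kept, windows))
  retained <- stage("retain", retain_windows(hp, config$min_snvs))
  zhp <- stage("zhp", z_transform(retained))

  retained_ids <- sort(unique(retained$window_id))
  fst <- stage("fst", pairwise_window_fst(kept, windows, retained_ids))
  pair_stats <- stage("pair_stats", compute_pair_stats(fst))
  di <- stage("di", compute_di(fst, pair_stats))

  pops <- populations(kept)
  cutoffs <- data.table::data.table(population = pops, di_cutoff = NA_real_)
  flagged <- data.table::rbindlist(lapply(pops, function(p) {
    di_rows <- di$population == p
    dp <- di[di_rows, ]
    cut <- if (!is.null(config$di_cutoff)) config$di_cutoff else {
      suppressWarnings(di_threshold(dp$di, config$di_top_fraction))
    }
    cut_row <- which(cutoffs$population == p)
    data.table::set(cutoffs, cut_row, "di_cutoff", cut)
    zhp_rows <- zhp$population == p
    flag_selected_windows(zhp[zhp_rows, ], dp,
                          zhp_cutoff = config$zhp_cutoff, di_cutoff = cut)
  }))
  loci <- stage("loci", merge_windows_to_loci(flagged))

  models <- stage("gff", read_gene_models(config$gff))
  report <- if (nrow(loci) > 0) {
    stage("annotate", annotate_loci(loci, models$genes))
  } else {
    annotate_loci(loci, models$genes)
  }

  conservation <- data.table::data.table()
  if (!is.null(config$alignments_dir) && nrow(report) > 0) {
    conservation <- stage("conservation", {
      data.table::rbindlist(lapply(unique(report$population), function(p) {
        specific <- suppressWarnings(
          breed_specific_snvs(kept, p, config$presence_min, config$absence_max)
        )
        gene_ids <- unique(report$gene_id[report$population == p])
        gm <- models$genes[models$genes$gene_id %in% gene_ids, ]
        cons <- data.table::rbindlist(lapply(seq_len(nrow(gm)), function(k) {
          fa <- file.path(config$alignments_dir, paste0(gm$gene_id[k], ".fa"))
          if (!file.exists(fa)) return(NULL)
          find_conserved_sites(read_species_alignment(fa, gm$gene_id[k],
                                                      gm$start[k]))
        }))
        if (nrow(cons) == 0) return(NULL)
        intersect_and_classify(specific, cons, gm, models$cds,
                               flank = config$flank, population = p)
      }), use.names = TRUE)
    })
  }

  paths <- list(
    filter_summary = write_tsv(
      data.table::data.table(rule = names(filt$rejections),
                             rejected = as.integer(filt$rejections)),
      file.path(config$out_dir, "filter_summary.tsv")),
    zhp = write_tsv(zhp, file.path(config$out_dir, "zhp.tsv")),
    window_fst = write_tsv(fst, file.path(config$out_dir, "window_fst.tsv")),
    pair_stats = write_tsv(pair_stats, file.path(config$out_dir, "pair_stats.tsv")),
    di = write_tsv(di, file.path(config$out_dir, "di.tsv")),
    flagged = write_tsv(flagged, file.path(config$out_dir, "flagged_windows.tsv")),
    loci_tsv = write_tsv(loci, file.path(config$out_dir, "loci.tsv")),
    candidate_genes = write_tsv(report, file.path(config$out_dir,
                                                  "candidate_genes.tsv"))
  )
  bed <- if (nrow(loci) > 0) {
    data.table::data.table(
      contig = loci$contig, start = loci$start, end = loci$end,
      name = sprintf("%s|zhp=%.3f|di=%.3f", loci$population, loci$min_zhp,
                     loci$max_di),
      score = 0L, strand = "."
    )
  } else {
    data.table::data.table(contig = character(), start = integer(),
                           end = integer(), name = character(),
                           score = integer(), strand = character())
  }
  utils::write.table(bed, file.path(config$out_dir, "loci.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths$loci_bed <- file.path(config$out_dir, "loci.bed")
  if (nrow(conservation) > 0 || !is.null(config$alignments_dir)) {
    paths$conservation <- write_tsv(
      if (nrow(conservation) > 0) conservation else data.table::data.table(
        gene_id = character(), contig = character(), pos = integer(),
        population = character(), ref = character(), alt = character(),
        conserved = logical(), coding = logical()),
      file.path(config$out_dir, "conservation_report.tsv"))
  }

  manifest <- list(
    tool = "poolsweep",
    version = as.character(utils::packageVersion("poolsweep")),
    seed = config$seed,
    config = config[setdiff(names(config), "di_cutoff")],
    di_cutoffs = stats::setNames(as.list(cutoffs$di_cutoff), cutoffs$population),
    counts = list(
      variants_read = length(variants),
      variants_skipped = as.list(attr(variants, "skipped")),
      variants_kept = length(kept),
      rejections = as.list(filt$rejections),
      windows = nrow(windows),
      retained_windows = length(retained_ids),
      flagged_windows = sum(flagged$flagged),
      loci = nrow(loci),
      candidate_genes = length(unique(report$gene_id)),
      conserved_specific_snvs = nrow(conservation)
    ),
    outputs = paths
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE, pretty = TRUE)
  manifest$tables <- list(
    zhp = zhp, fst = fst, pair_stats = pair_stats, di = di,
    flagged = flagged, loci = loci, report = report,
    conservation = conservation, cutoffs = cutoffs
  )
  invisible(manifest)
}
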