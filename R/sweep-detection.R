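#' Flag windows jointly extreme in ZHp and di
#'
#' The calling rule: a retained window is flagged for a population iff
#' ZHp < `zhp_cutoff` (strictly; default -7) AND di > `di_cutoff`
#' (strictly). Both tracks must have been computed on the same
#' retained-window set; a mismatch is an error rather than a silent join.
#'
#' @param zhp_dt output of [z_transform()] (one population or several).
#' @param di_dt output of [compute_di()].
#' @param zhp_cutoff upper bound on ZHp (default -7).
#' @param di_cutoff lower bound on di, e.g. from [di_threshold()].
#' @return The joined table with a logical `flagged` column.
#' @export
flag_selected_windows <- function(zhp_dt, di_dt, zhp_cutoff = -7, di_cutoff) {
  pops <- intersect(unique(zhp_dt$population), unique(di_dt$population))
  if (length(pops) == 0) stop("no common population between ZHp and di tracks")
  z <- zhp_dt[zhp_dt$population %in% pops, ]
  d <- di_dt[di_dt$population %in% pops, ]
  for (p in pops) {
    wz <- sort(z$window_id[z$population == p])
    wd <- sort(d$window_id[d$population == p])
    if (!identical(wz, wd)) {
      stop("ZHp and di tracks cover different window sets for population ", p,
           " (", length(wz), " vs ", length(wd), " windows)")
    }
  }
  out <- merge(z, d[, c("window_id", "population", "di")],
               by = c("window_id", "population"), sort = FALSE)
  out[, "flagged" := !is.na(zhp) & !is.na(di) & zhp < zhp_cutoff & di > di_cutoff]
  data.table::setorder(out, population, window_id)
  out[]
}

#' Merge flagged windows into selection loci
#'
#' Overlapping or bookended (touching) flagged windows on one contig merge
#' into a single locus per population, carrying the most negative ZHp and
#' the largest di among the merged windows. Windows on different contigs
#' never merge.
#'
#' @param flagged output of [flag_selected_windows()] (only rows with
#'   `flagged == TRUE` are used).
#' @return A [data.table::data.table] of loci: `population`, `contig`,
#'   `start`, `end` (0-based half-open), `n_windows`, `min_zhp`, `max_di`.
#' @export
merge_windows_to_loci <- function(flagged) {
  keep_rows <- flagged$flagged == TRUE      # plain vector first: a column
  fw <- flagged[keep_rows, ]                # named 'flagged' shadows the table

  empty <- data.table::data.table(
    population = character(), contig = character(), start = integer(),
    end = integer(), n_windows = integer(), min_zhp = numeric(),
    max_di = numeric()
  )
  if (nrow(fw) == 0) return(empty)
  fw <- data.table::copy(fw)
  data.table::setorder(fw, population, contig, start, end)
  fw[, "grp" := cumsum(c(TRUE, start[-1] > cummax(as.numeric(end))[-.N])),
     by = c("population", "contig")]
  out <- fw[, list(start = min(start), end = max(end), n_windows = .N,
                   min_zhp = min(zhp), max_di = max(di)),
            by = c("population", "contig", "grp")]
  out[, "grp" := NULL]
  data.table::setorder(out, population, contig, start)
  out[]
}

#' Read gene models from a GFF3 file
#'
#' Extracts `gene` features (id from the `ID` attribute, display name from
#' `Name` when present) and `CDS` features. Coordinates keep the GFF3
#' 1-based inclusive convention.
#'
#' @param path GFF3 file.
#' @return list with `genes` and `cds` data.tables (`gene_id`, `contig`,
#'   `start`, `end`, `strand`, and `name` for genes).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", ]
  cds <- df[df$type == "CDS", ]
  gene_dt <- data.table::data.table(
    gene_id = as.character(genes$ID),
    contig = as.character(genes$seqnames),
    start = as.integer(genes$start), end = as.integer(genes$end),
    strand = as.character(genes$strand),
    name = if ("Name" %in% names(genes)) as.character(genes$Name) else NA_character_
  )
  cds_parent <- if (nrow(cds) > 0 && "Parent" %in% names(cds)) {
    vapply(cds$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
           character(1))
  } else rep(NA_character_, nrow(cds))
  cds_dt <- data.table::data.table(
    gene_id = sub("\\.t[0-9]+$", "", cds_parent),
    contig = as.character(cds$seqnames),
    start = as.integer(cds$start), end = as.integer(cds$end),
    strand = as.character(cds$strand)
  )
  list(genes = gene_dt, cds = cds_dt)
}

#' Annotate selection loci with overlapping genes
#'
#' A gene is reported for a locus when its span overlaps the locus by at
#' least 1 bp (genes need not be contained). The report row carries the
#' locus extremes (`min_zhp`, `max_di`), matching the shape of a
#' candidate-gene table: gene, scaffold, annotation, ZHp, di.
#'
#' @param loci output of [merge_windows_to_loci()].
#' @param gene_models `genes` table from [read_gene_models()].
#' @return A [data.table::data.table] with one row per (locus, gene):
#'   `population`, `gene_id`, `name`, `contig`, `gene_start`, `gene_end`,
#'   `locus_start`, `locus_end`, `min_zhp`, `max_di`.
#' @export
annotate_loci <- function(loci, gene_models) {
  empty <- data.table::data.table(
    population = character(), gene_id = character(), name = character(),
    contig = character(), gene_start = integer(), gene_end = integer(),
    locus_start = integer(), locus_end = integer(),
    min_zhp = numeric(), max_di = numeric()
  )
  if (nrow(loci) == 0) return(empty)
  offenders <- setdiff(unique(loci$contig), unique(gene_models$contig))
  if (length(offenders) == length(unique(loci$contig))) {
    stop("no locus contig matches the gene annotation; offending contig(s): ",
         paste(offenders, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    lc <- loci[i, ]
    g <- gene_models[gene_models$contig == lc$contig &
                       (gene_models$start - 1L) < lc$end &   # gene as 0-based half-open
                       gene_models$end > lc$start, ]
    if (nrow(g) == 0) return(NULL)
    data.table::data.table(
      population = lc$population, gene_id = g$gene_id, name = g$name,
      contig = lc$contig, gene_start = g$start, gene_end = g$end,
      locus_start = lc$start, locus_end = lc$end,
      min_zhp = lc$min_zhp, max_di = lc$max_di
    )
  })
  out <- data.table::rbindlist(Filter(Negate(is.null), rows))
  if (nrow(out) == 0) return(empty)
  data.table::setorder(out, population, contig, locus_start, gene_start)
  out[]
}
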