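#' Breed-specific SNVs
#'
#' A variant is specific to the focal population when one of its alleles is
#' at high frequency there and near-absent everywhere else: alt frequency
#' >= `presence_min` in the focal pool and <= `absence_max` in every other
#' pool, or the mirrored condition for the reference allele. Frequencies
#' come from pooled read counts; sites with zero depth in any population
#' are skipped with a warning (their frequencies are uncomputable).
#'
#' @param x a [pooled_variants] object.
#' @param population focal population id.
#' @param presence_min minimum focal allele frequency (default 0.9).
#' @param absence_max maximum frequency of that allele elsewhere (default 0.1).
#' @return The specific subset of `x`, with attribute `which_allele`
#'   (`"alt"` or `"ref"` per returned record).
#' @export
breed_specific_snvs <- function(x, population, presence_min = 0.9,
                                absence_max = 0.1) {
  stopifnot(population %in% populations(x))
  d <- pool_depth(x)
  usable <- rowSums(d == 0) == 0
  if (any(!usable)) {
    warning(sum(!usable), " site(s) with zero depth in some population skipped")
  }
  f <- x$alt_counts / d
  others <- setdiff(populations(x), population)
  fo <- f[, others, drop = FALSE]
  alt_specific <- usable & f[, population] >= presence_min &
    rowSums(fo > absence_max) == 0
  ref_specific <- usable & (1 - f[, population]) >= presence_min &
    rowSums((1 - fo) > absence_max) == 0
  keep <- which(alt_specific | ref_specific)
  out <- x[keep]
  attr(out, "which_allele") <- ifelse(alt_specific[keep], "alt", "ref")
  out
}

#' Gene spans extended by a flank
#'
#' @param gene_models `genes` table from [read_gene_models()] (1-based
#'   inclusive coordinates).
#' @param flank bp added on both sides (default 1000).
#' @param contig_lengths optional named vector used to clip at contig ends.
#' @return A [data.table::data.table] with `gene_id`, `contig`, `start`,
#'   `end` (1-based inclusive, clipped to `[1, contig length]`).
#' @export
gene_flank_regions <- function(gene_models, flank = 1000L, contig_lengths = NULL) {
  out <- data.table::data.table(
    gene_id = gene_models$gene_id, contig = gene_models$contig,
    start = pmax(1L, gene_models$start - as.integer(flank)),
    end = gene_models$end + as.integer(flank)
  )
  if (!is.null(contig_lengths)) {
    lim <- as.integer(contig_lengths[out$contig])
    out[, "end" := pmin(end, lim)]
  }
  out[]
}

#' Read one gene's multi-species alignment
#'
#' Expects a multi-FASTA of aligned sequences (gap character `-` allowed),
#' one row per species, with the reference-genome row named
#' `reference|<gene_id>`. The reference row's non-gap columns are mapped to
#' consecutive genomic positions starting at `gene_start`.
#'
#' @param path multi-FASTA alignment file.
#' @param gene_id gene identifier (used to find the reference row).
#' @param gene_start 1-based genomic start of the aligned reference region.
#' @return An object of class `species_alignment`: list with `gene_id`,
#'   `rows` (character matrix, species x columns, upper case), `ref_row`
#'   (row index), `coord_map` (genomic position per column, NA at
#'   reference-gap columns).
#' @export
read_species_alignment <- function(path, gene_id, gene_start) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) < 3) stop("alignment needs >= 3 rows: ", path)
  if (length(unique(Biostrings::width(seqs))) != 1) {
    stop("alignment rows differ in length: ", path)
  }
  rows <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(rows) <- names(seqs)
  ref_name <- paste0("reference|", gene_id)
  ref_row <- match(ref_name, names(seqs))
  if (is.na(ref_row)) stop("no row named '", ref_name, "' in ", path)
  is_base <- rows[ref_row, ] != "-"
  coord_map <- rep(NA_integer_, ncol(rows))
  coord_map[is_base] <- as.integer(gene_start) + seq_len(sum(is_base)) - 1L
  structure(
    list(gene_id = gene_id, rows = rows, ref_row = ref_row,
         coord_map = coord_map),
    class = "species_alignment"
  )
}

#' Find conserved alignment columns
#'
#' A column is conserved when all non-gap rows carry the same base and at
#' most `max_gap_rows` rows are gaps. The default (0) is the strictest
#' reading of cross-species conservation: every species present and
#' identical. Conserved columns are mapped to genomic coordinates through
#' the reference row; a conserved column where the reference itself is
#' gapped is reported with `pos = NA`.
#'
#' @param aln a `species_alignment` from [read_species_alignment()].
#' @param max_gap_rows maximum gap rows tolerated in a conserved column.
#' @return A [data.table::data.table] with `gene_id`, `column`, `pos`,
#'   `base`.
#' @export
find_conserved_sites <- function(aln, max_gap_rows = 0L) {
  stopifnot(inherits(aln, "species_alignment"))
  m <- aln$rows
  gaps <- colSums(m == "-")
  n_distinct <- apply(m, 2, function(col) length(unique(col[col != "-"])))
  conserved <- gaps <= max_gap_rows & n_distinct == 1 & gaps < nrow(m)
  cols <- which(conserved)
  base <- vapply(cols, function(j) m[m[, j] != "-", j][1], character(1))
  data.table::data.table(
    gene_id = aln$gene_id, column = cols, pos = aln$coord_map[cols], base = base
  )
}

#' Intersect breed-specific SNVs with conserved sites
#'
#' Produces the conservation-screen report: breed-specific SNVs whose
#' position is a conserved column of the gene's multi-species alignment,
#' each labelled coding or non-coding by overlap with CDS features.
#'
#' @param specific output of [breed_specific_snvs()].
#' @param conserved_sites rbind of [find_conserved_sites()] results.
#' @param gene_models `genes` table from [read_gene_models()].
#' @param cds_models `cds` table from [read_gene_models()].
#' @param flank bp around genes within which SNVs are considered
#'   (default 1000).
#' @param population focal population id recorded in the report.
#' @return A [data.table::data.table]: `gene_id`, `contig`, `pos`,
#'   `population`, `ref`, `alt`, `conserved` (always TRUE here), `coding`.
#' @export
intersect_and_classify <- function(specific, conserved_sites, gene_models,
                                   cds_models, flank = 1000L,
                                   population = NA_character_) {
  regions <- gene_flank_regions(gene_models, flank)
  rows <- list()
  for (k in seq_len(nrow(regions))) {
    rg <- regions[k, ]
    in_region <- which(specific$contig == rg$contig &
                         specific$pos >= rg$start & specific$pos <= rg$end)
    if (length(in_region) == 0) next
    cons_pos <- conserved_sites$pos[conserved_sites$gene_id == rg$gene_id]
    hit <- in_region[specific$pos[in_region] %in% cons_pos]
    if (length(hit) == 0) next
    cds <- cds_models[cds_models$gene_id == rg$gene_id, ]
    coding <- vapply(specific$pos[hit], function(p) {
      nrow(cds) > 0 && any(p >= cds$start & p <= cds$end)
    }, logical(1))
    rows[[length(rows) + 1L]] <- data.table::data.table(
      gene_id = rg$gene_id, contig = rg$contig, pos = specific$pos[hit],
      population = population, ref = specific$ref[hit], alt = specific$alt[hit],
      conserved = TRUE, coding = coding
    )
  }
  if (length(rows) == 0) {
    return(data.table::data.table(
      gene_id = character(), contig = character(), pos = integer(),
      population = character(), ref = character(), alt = character(),
      conserved = logical(), coding = logical()
    ))
  }
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, gene_id, pos)
  out[]
}
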