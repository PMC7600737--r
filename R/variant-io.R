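#' Read a pooled VCF into a pooled_variants object
#'
#' Parses a multi-sample VCF in which each sample is one pooled population
#' library carrying AD-style allele depths. Only biallelic SNV lines are
#' kept; multi-allelic and non-SNV lines are counted and skipped (counts are
#' attached as the `"skipped"` attribute and reported via a message).
#'
#' @param path path to a VCF (4.x) file.
#' @param population_names samples to read, in order; default all samples.
#' @return A [pooled_variants] object with attribute `skipped`, a named
#'   integer vector with elements `multiallelic` and `non_snv`.
#' @export
read_pooled_vcf <- function(path, population_names = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  samp <- colnames(vcf)
  if (is.null(population_names)) population_names <- samp
  missing <- setdiff(population_names, samp)
  if (length(missing) > 0) {
    stop("population(s) not present as VCF samples: ", paste(missing, collapse = ", "))
  }
  if (!"AD" %in% rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf)))) {
    stop("VCF lacks a FORMAT AD field: ", path)
  }

  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  ref_chr <- as.character(VariantAnnotation::ref(vcf))
  alt_chr <- rep(NA_character_, length(vcf))
  alt_chr[n_alt == 1] <- as.character(unlist(alt_list[n_alt == 1]))

  multi <- n_alt != 1
  snv <- !multi & nchar(ref_chr) == 1 & nchar(alt_chr) == 1 &
    ref_chr %in% c("A", "C", "G", "T") & alt_chr %in% c("A", "C", "G", "T")
  skipped <- c(multiallelic = sum(multi), non_snv = sum(!multi & !snv))
  if (sum(skipped) > 0) {
    message(sprintf("read_pooled_vcf: skipped %d multi-allelic and %d non-SNV line(s)",
                    skipped[["multiallelic"]], skipped[["non_snv"]]))
  }

  keep <- which(snv)
  n <- length(keep)
  P <- length(population_names)
  ad <- VariantAnnotation::geno(vcf)$AD[keep, population_names, drop = FALSE]
  refc <- matrix(0L, n, P, dimnames = list(NULL, population_names))
  altc <- refc
  if (n > 0) {
    lens <- lengths(ad)
    if (any(lens != 2)) {
      bad <- which(matrixStats_rowAnys(matrix(lens != 2, n, P)))[1]
      stop("malformed AD (expected ref,alt pair) at record ", keep[bad])
    }
    flat <- unlist(ad, use.names = FALSE)      # column-major, pairs
    refc[] <- as.integer(flat[seq(1, length(flat), by = 2)])
    altc[] <- as.integer(flat[seq(2, length(flat), by = 2)])
    if (anyNA(refc) || anyNA(altc)) stop("missing AD values in ", path)
  }

  gr <- as.data.frame(SummarizedExperiment::rowRanges(vcf)[keep])
  out <- pooled_variants(
    as.character(gr$seqnames), gr$start,
    ref_chr[keep], alt_chr[keep],
    as.numeric(VariantAnnotation::qual(vcf))[keep], refc, altc
  )
  attr(out, "skipped") <- skipped
  sl <- GenomeInfoDb::seqlengths(vcf)
  if (length(sl) > 0 && !anyNA(sl)) attr(out, "contig_lengths") <- sl
  out
}

matrixStats_rowAnys <- function(m) rowSums(m) > 0

#' Write pooled variants to a VCF 4.2 file
#'
#' Serialises a [pooled_variants] object as a minimal VCF with one pooled
#' sample per population and per-sample `AD` (ref,alt depths) and `DP`
#' fields. Round-trips through [read_pooled_vcf()] to identical records.
#'
#' @param x a [pooled_variants] object.
#' @param path output path.
#' @param contig_lengths optional named vector for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_pooled_vcf <- function(x, path, contig_lengths = NULL) {
  pops <- populations(x)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=poolsweep",
    if (!is.null(contig_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
              as.integer(contig_lengths))
    },
    "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Number of pools\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depth per allele (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", pops), collapse = "\t")
  )
  n <- length(x)
  if (n > 0) {
    dp <- pool_depth(x)
    geno_cols <- vapply(seq_along(pops), function(j) {
      sprintf("%d,%d:%d", x$ref_counts[, j], x$alt_counts[, j], dp[, j])
    }, character(n))
    if (n == 1) geno_cols <- matrix(geno_cols, nrow = 1)
    body <- paste(
      x$contig, x$pos, ".", x$ref, x$alt, sprintf("%.15g", x$qual), "PASS",
      sprintf("NS=%d", length(pops)), "AD:DP",
      apply(geno_cols, 1, paste, collapse = "\t"),
      sep = "\t"
    )
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' SNV filter thresholds
#'
#' The call-set hygiene filters applied before any selection scan: a site is
#' kept iff it is a biallelic SNV, QUAL >= `min_qual`, the read depth summed
#' over all pools >= `min_total_coverage`, and the alternate-supporting read
#' count summed over pools >= `min_alt_reads`. All thresholds are inclusive.
#' The defaults (30 / 68 / 3) target a six-pool experiment at ~11x per pool,
#' where 68 is roughly the expected total depth. Set `coverage_per_pool =
#' TRUE` to require `min_total_coverage` in every pool instead of the sum.
#'
#' Note: callers sometimes additionally require the alternate reads to have
#' distinct start sites; that check needs alignments (BAMs) and cannot be
#' enforced from a VCF, so the alt-read rule here is a plain count.
#'
#' @param min_qual minimum QUAL (phred-scaled).
#' @param min_total_coverage minimum summed (or per-pool) depth.
#' @param min_alt_reads minimum summed alternate read count.
#' @param biallelic_only keep only biallelic SNVs (always true post-read;
#'   kept for completeness of the rejection accounting).
#' @param coverage_per_pool apply the coverage threshold per pool.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_qual = 30, min_total_coverage = 68,
                          min_alt_reads = 3, biallelic_only = TRUE,
                          coverage_per_pool = FALSE) {
  stopifnot(min_qual >= 0, min_total_coverage >= 0, min_alt_reads >= 0)
  structure(
    list(
      min_qual = min_qual, min_total_coverage = min_total_coverage,
      min_alt_reads = min_alt_reads, biallelic_only = biallelic_only,
      coverage_per_pool = coverage_per_pool
    ),
    class = "filter_config"
  )
}

#' Apply SNV filters
#'
#' Applies the [filter_config()] rules. Each dropped record is attributed to
#' the first rule it fails, in the fixed order biallelic, qual, coverage,
#' alt-reads, so the rejection counts always sum to the number dropped.
#'
#' @param x a [pooled_variants] object.
#' @param config a [filter_config()].
#' @return list with `kept` (a [pooled_variants]) and `rejections` (named
#'   integer vector: biallelic, qual, coverage, alt_reads).
#' @export
filter_variants <- function(x, config = filter_config()) {
  stopifnot(inherits(x, "pooled_variants"), inherits(config, "filter_config"))
  dp <- pool_depth(x)
  ok_bi <- rep(TRUE, length(x))  # the reader only emits biallelic SNVs
  ok_qual <- x$qual >= config$min_qual
  cov <- if (config$coverage_per_pool) {
    apply(dp, 1, min) >= config$min_total_coverage
  } else {
    rowSums(dp) >= config$min_total_coverage
  }
  ok_alt <- rowSums(x$alt_counts) >= config$min_alt_reads

  first_fail <- rep(NA_character_, length(x))
  first_fail[!ok_alt] <- "alt_reads"
  first_fail[!cov] <- "coverage"
  first_fail[!ok_qual] <- "qual"
  first_fail[!ok_bi] <- "biallelic"
  keep <- is.na(first_fail)
  rej <- c(
    biallelic = sum(first_fail == "biallelic", na.rm = TRUE),
    qual = sum(first_fail == "qual", na.rm = TRUE),
    coverage = sum(first_fail == "coverage", na.rm = TRUE),
    alt_reads = sum(first_fail == "alt_reads", na.rm = TRUE)
  )
  list(kept = x[keep], rejections = rej)
}

#' Minor-allele-frequency spectrum of one pool
#'
#' Per SNV, MAF = min(ref, alt) / (ref + alt) from the pool's read counts,
#' binned into the ten classes [0,0.05), [0.05,0.10), ..., [0.45,0.50]
#' (the last bin closed). Zero-depth sites are excluded with a warning.
#'
#' @param x a [pooled_variants] object.
#' @param population population id.
#' @return numeric vector of 10 bin proportions summing to 1, named by bin.
#' @export
maf_spectrum <- function(x, population) {
  stopifnot(population %in% populations(x))
  r <- x$ref_counts[, population]
  a <- x$alt_counts[, population]
  d <- r + a
  if (any(d == 0)) {
    warning(sum(d == 0), " zero-depth site(s) excluded from MAF spectrum")
    r <- r[d > 0]; a <- a[d > 0]; d <- d[d > 0]
  }
  if (length(d) == 0) stop("no sites with non-zero depth in population ", population)
  maf <- pmin(r, a) / d
  br <- seq(0, 0.5, by = 0.05)
  bin <- pmin(findInterval(maf, br, rightmost.closed = TRUE), 10L)
  counts <- tabulate(bin, nbins = 10L)
  prop <- counts / sum(counts)
  names(prop) <- sprintf("[%.2f,%.2f%s", br[-11], br[-1],
                         c(rep(")", 9), "]"))
  prop
}

#' Pool-level zygosity summary
#'
#' For pooled data, a site is counted as "homozygote" in a pool when one of
#' the two alleles has zero reads there (the pool looks fixed), and
#' "heterozygote" otherwise. Sites with zero depth in the pool are excluded;
#' the two counts partition the remaining sites.
#'
#' @param x a [pooled_variants] object.
#' @param population population id.
#' @return named integer vector `c(homozygote=, heterozygote=)`.
#' @export
zygosity_summary <- function(x, population) {
  stopifnot(population %in% populations(x))
  r <- x$ref_counts[, population]
  a <- x$alt_counts[, population]
  nonzero <- (r + a) > 0
  hom <- sum(nonzero & (r == 0 | a == 0))
  c(homozygote = hom, heterozygote = sum(nonzero) - hom)
}
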