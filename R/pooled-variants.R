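#' Pooled variant container
#'
#' The central in-memory representation of a Pool-seq call set: one row per
#' biallelic SNV, with per-population reference/alternate read counts held as
#' integer matrices (sites x populations). Read counts are the only
#' allele-frequency information a pooled library provides, so every
#' downstream statistic (Hp, Fst, di, MAF) is computed from these matrices.
#'
#' @param contig character vector of contig/scaffold names.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-base reference and alternate alleles.
#' @param qual numeric phred-scaled site qualities.
#' @param ref_counts,alt_counts integer matrices (sites x populations) of
#'   reference / alternate read counts; column names are population ids.
#'
#' @return An object of class `pooled_variants`.
#' @export
pooled_variants <- function(contig, pos, ref, alt, qual, ref_counts, alt_counts) {
  n <- length(contig)
  stopifnot(
    length(pos) == n, length(ref) == n, length(alt) == n, length(qual) == n,
    is.matrix(ref_counts), is.matrix(alt_counts),
    nrow(ref_counts) == n, nrow(alt_counts) == n,
    identical(dim(ref_counts), dim(alt_counts))
  )
  if (is.null(colnames(ref_counts))) {
    colnames(ref_counts) <- paste0("pop", seq_len(ncol(ref_counts)))
  }
  colnames(alt_counts) <- colnames(ref_counts)
  if (n > 0 && (any(pos < 1) || any(ref_counts < 0) || any(alt_counts < 0))) {
    stop("positions must be >= 1 and read counts non-negative")
  }
  structure(
    list(
      contig = as.character(contig),
      pos = as.integer(pos),
      ref = as.character(ref),
      alt = as.character(alt),
      qual = as.numeric(qual),
      ref_counts = ref_counts,
      alt_counts = alt_counts
    ),
    class = "pooled_variants"
  )
}

#' @export
length.pooled_variants <- function(x) length(x$pos)

#' Population ids of a pooled variant set
#' @param x a `pooled_variants` object.
#' @return character vector of population ids.
#' @export
populations <- function(x) colnames(x$ref_counts)

#' @export
`[.pooled_variants` <- function(x, i) {
  pooled_variants(
    x$contig[i], x$pos[i], x$ref[i], x$alt[i], x$qual[i],
    x$ref_counts[i, , drop = FALSE], x$alt_counts[i, , drop = FALSE]
  )
}

#' @export
print.pooled_variants <- function(x, ...) {
  cat(sprintf(
    "<pooled_variants> %d SNVs, %d populations (%s)\n",
    length(x), ncol(x$ref_counts), paste(populations(x), collapse = ", ")
  ))
  invisible(x)
}

#' @method as.data.frame pooled_variants
#' @export
as.data.frame.pooled_variants <- function(x, ...) {
  d <- data.frame(
    contig = x$contig, pos = x$pos, ref = x$ref, alt = x$alt, qual = x$qual,
    stringsAsFactors = FALSE
  )
  for (p in populations(x)) {
    d[[paste0("ref_", p)]] <- x$ref_counts[, p]
    d[[paste0("alt_", p)]] <- x$alt_counts[, p]
  }
  d
}

#' Per-population total read depth
#' @param x a `pooled_variants` object.
#' @return integer matrix (sites x populations).
#' @export
pool_depth <- function(x) x$ref_counts + x$alt_counts

#' Per-population alternate allele frequency
#'
#' @param x a `pooled_variants` object.
#' @return numeric matrix (sites x populations); `NaN` where depth is zero.
#' @export
alt_frequency <- function(x) {
  d <- pool_depth(x)
  x$alt_counts / d
}
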