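#' Per-SNV pairwise Fst by among/within mean squares
#'
#' Treats every read as one sampled allele and performs, per SNV, a one-way
#' ANOVA of the allele indicator (alt = 1, ref = 0) on the two pools:
#' MSP is the among-population mean square, MSG the within-population mean
#' square, and nc the unequal-sample-size coefficient
#' nc = (sum(a) - sum(a^2)/sum(a)) / (r - 1) for pool depths a and r = 2.
#' The estimate is Fst = (MSP - MSG) / (MSP + (nc - 1) MSG), clamped into
#' [0, 1]; it is NA when either pool has zero depth or when the site is
#' monomorphic in both pools (zero denominator).
#'
#' All arguments are vectorised over sites.
#'
#' @param ref_i,alt_i reference/alternate read counts in pool i.
#' @param ref_j,alt_j reference/alternate read counts in pool j.
#' @return A [data.table::data.table] with columns `msp`, `msg`, `nc`,
#'   `num`, `den` (the Fst numerator/denominator, reused by the multi-locus
#'   ratio-of-sums estimator) and `fst` (clamped).
#' @export
per_snv_fst <- function(ref_i, alt_i, ref_j, alt_j) {
  d1 <- ref_i + alt_i
  d2 <- ref_j + alt_j
  usable <- d1 > 0 & d2 > 0
  p1 <- alt_i / d1
  p2 <- alt_j / d2
  pbar <- (alt_i + alt_j) / (d1 + d2)
  msp <- d1 * (p1 - pbar)^2 + d2 * (p2 - pbar)^2          # r - 1 = 1
  ssg <- d1 * p1 * (1 - p1) + d2 * p2 * (1 - p2)
  msg <- ifelse(d1 + d2 > 2, ssg / (d1 + d2 - 2), 0)
  nc <- d1 + d2 - (d1^2 + d2^2) / (d1 + d2)               # / (r - 1) = 1
  num <- msp - msg
  den <- msp + (nc - 1) * msg
  fst <- ifelse(usable & den != 0, pmin(pmax(num / den, 0), 1), NA_real_)
  num[!usable] <- NA_real_
  den[!usable] <- NA_real_
  data.table::data.table(msp = msp, msg = msg, nc = nc,
                         num = num, den = den, fst = fst)
}

#' Multi-locus window Fst for one SNV set
#'
#' Ratio-of-sums estimator: sum of per-SNV Fst numerators over the window
#' divided by the sum of denominators, then clamped to [0, 1]. SNVs with
#' zero depth in either pool are excluded; a window with no usable SNV is
#' NA.
#'
#' @param x a [pooled_variants] object holding the window's SNVs.
#' @param pop_i,pop_j population ids.
#' @return list with `fst`, `n_used`, `num`, `den`.
#' @export
window_fst <- function(x, pop_i, pop_j) {
  comp <- per_snv_fst(x$ref_counts[, pop_i], x$alt_counts[, pop_i],
                      x$ref_counts[, pop_j], x$alt_counts[, pop_j])
  ok <- !is.na(comp$num)
  num <- sum(comp$num[ok])
  den <- sum(comp$den[ok])
  fst <- if (sum(ok) == 0 || den == 0) NA_real_ else min(max(num / den, 0), 1)
  list(fst = fst, n_used = sum(ok), num = num, den = den)
}

#' Window Fst for every population pair
#'
#' @param x a [pooled_variants] object.
#' @param windows output of [make_windows()].
#' @param window_ids optional subset of window ids (e.g. retained windows).
#' @return A [data.table::data.table] with `window_id`, `pop_i`, `pop_j`
#'   (ordered as in `populations(x)`, i before j), `n_used`, `fst`.
#' @export
pairwise_window_fst <- function(x, windows, window_ids = NULL) {
  map <- snv_window_map(x, windows)
  if (!is.null(window_ids)) map <- map[map$window_id %in% window_ids, ]
  pops <- populations(x)
  pairs <- utils::combn(pops, 2, simplify = FALSE)
  out <- data.table::rbindlist(lapply(pairs, function(pr) {
    comp <- per_snv_fst(x$ref_counts[, pr[1]], x$alt_counts[, pr[1]],
                        x$ref_counts[, pr[2]], x$alt_counts[, pr[2]])
    dt <- data.table::data.table(
      window_id = map$window_id,
      num = comp$num[map$snv], den = comp$den[map$snv]
    )
    agg <- dt[, list(n_used = sum(!is.na(num)),
                     num = sum(num, na.rm = TRUE),
                     den = sum(den, na.rm = TRUE)), by = "window_id"]
    agg[, "fst" := ifelse(n_used == 0 | den == 0, NA_real_,
                          pmin(pmax(num / den, 0), 1))]
    agg[, c("pop_i", "pop_j") := list(pr[1], pr[2])]
    agg[, c("num", "den") := NULL]
    agg
  }))
  data.table::setorder(out, pop_i, pop_j, window_id)
  data.table::setcolorder(out, c("window_id", "pop_i", "pop_j", "n_used", "fst"))
  out[]
}

#' Genome-wide mean and sd of window Fst per pair
#'
#' The standardisation baseline for the di statistic: for every population
#' pair, the mean and (sample) standard deviation of window Fst over all
#' retained windows.
#'
#' @param fst_dt output of [pairwise_window_fst()] (retained windows only).
#' @return A [data.table::data.table] with `pop_i`, `pop_j`, `mean_fst`,
#'   `sd_fst`, `n_windows`.
#' @export
compute_pair_stats <- function(fst_dt) {
  ps <- fst_dt[!is.na(fst_dt$fst),
               list(mean_fst = mean(fst), sd_fst = stats::sd(fst), n_windows = .N),
               by = c("pop_i", "pop_j")]
  if (any(ps$n_windows < 2)) stop("compute_pair_stats needs >= 2 windows per pair")
  if (any(ps$sd_fst == 0)) {
    stop("degenerate input: sd(Fst) = 0 for pair(s) ",
         paste(ps$pop_i[ps$sd_fst == 0], ps$pop_j[ps$sd_fst == 0],
               sep = "-", collapse = ", "))
  }
  ps[]
}

#' Population-specific di statistic per window
#'
#' For population i and window w, di = sum over all other populations j of
#' (Fst_ij(w) - mean(Fst_ij)) / sd(Fst_ij), where mean and sd are the
#' genome-wide pair statistics. A window missing any pairwise Fst gets a
#' missing di. Its genome-wide mean is 0 by construction (up to clamping).
#'
#' @param fst_dt output of [pairwise_window_fst()].
#' @param pair_stats output of [compute_pair_stats()].
#' @param population one population id, or NULL for all.
#' @return A [data.table::data.table] with `window_id`, `population`, `di`.
#' @export
compute_di <- function(fst_dt, pair_stats, population = NULL) {
  std <- merge(fst_dt, pair_stats, by = c("pop_i", "pop_j"), sort = FALSE)
  std[, "z" := (fst - mean_fst) / sd_fst]
  pops <- if (is.null(population)) {
    sort(unique(c(fst_dt$pop_i, fst_dt$pop_j)))
  } else population
  out <- data.table::rbindlist(lapply(pops, function(p) {
    sub <- std[std$pop_i == p | std$pop_j == p, ]
    agg <- sub[, list(di = if (anyNA(z)) NA_real_ else sum(z), n_pairs = .N),
               by = "window_id"]
    agg[, "population" := p]
    agg
  }))
  data.table::setorder(out, population, window_id)
  data.table::setcolorder(out, c("window_id", "population", "n_pairs", "di"))
  out[]
}

#' Empirical top-fraction cutoff for di
#'
#' The calling threshold "top 1%" is the empirical (1 - top_fraction)
#' quantile (linear-interpolation quantile, R type 7) of di over retained
#' windows; a window passes only if its di is strictly greater than the
#' cutoff, so with heavy ties fewer windows pass, never more.
#'
#' @param di numeric vector of di values (NAs ignored).
#' @param top_fraction upper tail mass (default 0.01).
#' @return The cutoff value.
#' @export
di_threshold <- function(di, top_fraction = 0.01) {
  di <- di[!is.na(di)]
  if (length(di) < 100) {
    warning("di_threshold on fewer than 100 windows; the empirical ",
            "quantile is unstable")
  }
  stats::quantile(di, probs = 1 - top_fraction, type = 7, names = FALSE)
}
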