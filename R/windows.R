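#' Build sliding windows over a genome
#'
#' Windows start at 0, step_bp, 2*step_bp, ... on every contig; each window
#' spans `size_bp` bp (0-based half-open) and the terminal windows are
#' truncated at the contig end, so every bp is covered. With the default
#' half-window step, consecutive windows overlap by 50%.
#'
#' @param contig_lengths named vector of contig lengths in bp.
#' @param size_bp window size (default 50 kb).
#' @param step_bp step between window starts; must be in (0, size_bp].
#' @return A [data.table::data.table] with columns `window_id`, `contig`,
#'   `start`, `end`, sorted by contig then start.
#' @export
make_windows <- function(contig_lengths, size_bp = 50000L, step_bp = 25000L) {
  if (step_bp <= 0 || step_bp > size_bp) {
    stop("step_bp must satisfy 0 < step_bp <= size_bp (larger steps leave gaps)")
  }
  if (is.null(names(contig_lengths))) stop("contig_lengths must be named")
  out <- data.table::rbindlist(lapply(names(contig_lengths), function(ctg) {
    L <- as.numeric(contig_lengths[[ctg]])
    starts <- seq(0, L - 1, by = step_bp)
    data.table::data.table(
      contig = ctg, start = as.integer(starts),
      end = as.integer(pmin(starts + size_bp, L))
    )
  }))
  out[, "window_id" := seq_len(.N)]
  data.table::setcolorder(out, c("window_id", "contig", "start", "end"))
  data.table::setattr(out, "window_size", as.integer(size_bp))
  data.table::setattr(out, "window_step", as.integer(step_bp))
  out[]
}

# map each SNV to every window containing it (overlapping windows -> several)
snv_window_map <- function(x, windows) {
  size <- attr(windows, "window_size")
  step <- attr(windows, "window_step")
  stopifnot(!is.null(size), !is.null(step))
  first_id <- windows[, list(first_id = min(window_id), n_win = .N), by = "contig"]
  dt <- data.table::data.table(snv = seq_along(x$pos), contig = x$contig,
                               p0 = x$pos - 1L)
  dt <- merge(dt, first_id, by = "contig", sort = FALSE)
  k_min <- pmax(0L, as.integer(floor((dt$p0 - size) / step)) + 1L)
  k_max <- pmin(as.integer(floor(dt$p0 / step)), dt$n_win - 1L)
  reps <- k_max - k_min + 1L
  data.table::data.table(
    snv = rep(dt$snv, reps),
    window_id = rep(dt$first_id + k_min, reps) +
      unlist(lapply(reps, seq_len), use.names = FALSE) - 1L
  )
}

#' Pooled heterozygosity of one SNV set in one pool
#'
#' The single-window primitive: per SNV the major allele is the one with
#' more reads in the pool (ties resolved to the reference allele), and
#' Hp = 2 * S_maj * S_min / (S_maj + S_min)^2 where S_maj, S_min sum the
#' major/minor read counts over the SNVs. Hp lies in [0, 0.5]; it is NA for
#' an empty SNV set or zero total depth.
#'
#' @param x a [pooled_variants] object holding the window's SNVs.
#' @param population population id.
#' @return list with `sum_major`, `sum_minor`, `n_snvs`, `hp`.
#' @export
hp_record <- function(x, population) {
  stopifnot(population %in% populations(x))
  r <- x$ref_counts[, population]
  a <- x$alt_counts[, population]
  maj <- ifelse(a > r, a, r)       # tie -> reference
  min_ <- ifelse(a > r, r, a)
  sm <- sum(maj); sn <- sum(min_)
  hp <- if (length(r) == 0 || sm + sn == 0) NA_real_ else 2 * sm * sn / (sm + sn)^2
  list(sum_major = sm, sum_minor = sn, n_snvs = length(r), hp = hp)
}

#' Windowed pooled heterozygosity for all populations
#'
#' Vectorised Hp over a window set: every SNV contributes its major/minor
#' read counts to each window containing it. `n_snvs` counts the SNVs
#' falling in the window (the same for every population, so that all
#' population tracks and all pairwise Fst tracks share one retained-window
#' set).
#'
#' @param x a [pooled_variants] object.
#' @param windows output of [make_windows()].
#' @return A [data.table::data.table] with one row per (window, population):
#'   `window_id`, `contig`, `start`, `end`, `population`, `n_snvs`,
#'   `sum_major`, `sum_minor`, `hp`. Windows with no SNV are omitted.
#' @export
windowed_hp <- function(x, windows) {
  map <- snv_window_map(x, windows)
  pops <- populations(x)
  per_pop <- lapply(pops, function(p) {
    r <- x$ref_counts[map$snv, p]
    a <- x$alt_counts[map$snv, p]
    dt <- data.table::data.table(
      window_id = map$window_id,
      maj = ifelse(a > r, a, r), min_ = ifelse(a > r, r, a)
    )
    agg <- dt[, list(sum_major = sum(maj), sum_minor = sum(min_), n_snvs = .N),
              by = "window_id"]
    agg[, "population" := p]
    agg
  })
  out <- data.table::rbindlist(per_pop)
  out[, "hp" := ifelse(sum_major + sum_minor == 0, NA_real_,
                       2 * sum_major * sum_minor / (sum_major + sum_minor)^2)]
  out <- merge(windows, out, by = "window_id", sort = TRUE)
  data.table::setorder(out, population, window_id)
  data.table::setcolorder(out, c("window_id", "contig", "start", "end",
                                 "population", "n_snvs", "sum_major",
                                 "sum_minor", "hp"))
  out[]
}

#' Drop windows with too few SNVs
#'
#' Only windows with strictly more than `min_snvs` SNVs are used in any
#' scan statistic; sparser windows are treated as missing, not as zero, and
#' are excluded from the Z-score baseline as well as from calling.
#'
#' @param hp_dt output of [windowed_hp()] (or any table with `n_snvs`).
#' @param min_snvs strict lower bound (default 10: a window needs > 10 SNVs).
#' @return The retained subset.
#' @export
retain_windows <- function(hp_dt, min_snvs = 10L) {
  out <- hp_dt[hp_dt$n_snvs > min_snvs & !is.na(hp_dt$hp), ]
  if (nrow(out) == 0) warning("no windows retained (all at or below ", min_snvs, " SNVs)")
  out
}

pop_sd <- function(v, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (sd_type == "population") sqrt(mean((v - mean(v))^2)) else stats::sd(v)
}

#' Z-transform windowed heterozygosity
#'
#' Per population, ZHp = (Hp - mean(Hp)) / sd(Hp), with the mean and sd
#' taken over that population's retained windows only. By default the sd
#' uses the population (1/n) denominator so the resulting Z-scores have
#' sd exactly 1.
#'
#' @param hp_dt retained windows from [retain_windows()].
#' @param sd_type `"population"` (1/n, default) or `"sample"` (1/(n-1)).
#' @return `hp_dt` with a `zhp` column added; attribute `hp_stats` is a
#'   data.table of per-population `mu_hp`, `sigma_hp`, `n_windows`.
#' @export
z_transform <- function(hp_dt, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  out <- data.table::copy(hp_dt)
  stats_dt <- out[, list(mu_hp = mean(hp), sigma_hp = pop_sd(hp, sd_type),
                         n_windows = .N), by = "population"]
  if (any(stats_dt$n_windows < 2)) {
    stop("z_transform needs >= 2 retained windows per population")
  }
  if (any(stats_dt$sigma_hp == 0)) {
    stop("degenerate input: sigma(Hp) = 0 for population(s) ",
         paste(stats_dt$population[stats_dt$sigma_hp == 0], collapse = ", "))
  }
  out <- merge(out, stats_dt, by = "population", sort = FALSE)
  out[, "zhp" := (hp - mu_hp) / sigma_hp]
  out[, c("mu_hp", "sigma_hp", "n_windows") := NULL]
  data.table::setorder(out, population, window_id)
  data.table::setattr(out, "hp_stats", stats_dt)
  out[]
}
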