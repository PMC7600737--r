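# Independent brute-force oracles, written before the implementations they
# check, plus small fixture builders shared across test files.

# one-way ANOVA on expanded allele indicator vectors (alt = 1, ref = 0);
# mean squares straight from sums of squares, never via per_snv_fst
oracle_fst_anova <- function(ref_i, alt_i, ref_j, alt_j) {
  x <- c(rep(1, alt_i), rep(0, ref_i), rep(1, alt_j), rep(0, ref_j))
  g <- c(rep("i", ref_i + alt_i), rep("j", ref_j + alt_j))
  a <- tapply(x, g, length)
  means <- tapply(x, g, mean)
  grand <- mean(x)
  ssp <- sum(a * (means - grand)^2)
  ssg <- sum((x - means[g])^2)
  r <- 2
  msp <- ssp / (r - 1)
  msg <- if (length(x) - r > 0) ssg / (length(x) - r) else 0
  nc <- (sum(a) - sum(a^2) / sum(a)) / (r - 1)
  num <- msp - msg
  den <- msp + (nc - 1) * msg
  list(msp = msp, msg = msg, nc = nc, num = num, den = den,
       fst = if (den == 0) NA_real_ else min(max(num / den, 0), 1))
}

# naive per-pool Hp over an explicit SNV loop
oracle_hp <- function(ref_counts, alt_counts) {
  sm <- 0; sn <- 0
  for (k in seq_along(ref_counts)) {
    r <- ref_counts[k]; a <- alt_counts[k]
    if (a > r) { sm <- sm + a; sn <- sn + r } else { sm <- sm + r; sn <- sn + a }
  }
  if (length(ref_counts) == 0 || sm + sn == 0) return(NA_real_)
  unname(2 * sm * sn / (sm + sn)^2)
}

# random pooled_variants on one or more contigs
random_variants <- function(n, n_pops = 3, contigs = "ctg1", max_pos = 1e6,
                            depth = 30, seed = 1) {
  set.seed(seed)
  ctg <- sample(contigs, n, replace = TRUE)
  pos <- integer(n)
  for (c in unique(ctg)) {
    idx <- ctg == c
    pos[idx] <- sort(sample.int(max_pos, sum(idx)))
  }
  o <- order(ctg, pos)
  d <- matrix(rpois(n * n_pops, depth), n, n_pops)
  f <- matrix(runif(n * n_pops), n, n_pops)
  altc <- matrix(rbinom(n * n_pops, as.vector(d), as.vector(f)), n, n_pops)
  refc <- d - altc
  colnames(refc) <- colnames(altc) <- paste0("pop", seq_len(n_pops))
  pooled_variants(ctg[o], pos[o], rep("A", n), rep("T", n),
                  round(runif(n, 30, 60), 2), refc[o, , drop = FALSE],
                  altc[o, , drop = FALSE])
}

# handcrafted variants from a counts spec: list of c(ref1, alt1, ref2, alt2, ...)
toy_variants <- function(counts, pos = NULL, contig = "ctg1", qual = 50) {
  m <- do.call(rbind, counts)
  P <- ncol(m) / 2
  refc <- m[, seq(1, ncol(m), by = 2), drop = FALSE]
  altc <- m[, seq(2, ncol(m), by = 2), drop = FALSE]
  colnames(refc) <- colnames(altc) <- paste0("pop", seq_len(P))
  n <- nrow(m)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  pooled_variants(rep(contig, n), pos, rep("A", n), rep("G", n),
                  rep_len(qual, n), refc, altc)
}

# one small fixture bundle per session, reused by several test files
fixture_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_populations = 4, contig_lengths = c(ctgA = 2e6, ctgB = 2e6),
        snv_density = 0.002, mean_depth = 40,
        sweep_specs = list(sweep_spec("ctgA", 500000, 575000, 1L, 1),
                           sweep_spec("ctgB", 1000000, 1075000, 2L, 1)),
        seed = 42
      )
      cache <<- list(config = cfg,
                     bundle = write_fixture_bundle(cfg, tempfile("bundle")))
    }
    cache
  }
})
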