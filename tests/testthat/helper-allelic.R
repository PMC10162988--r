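# Fixture builders and independent oracles used across the test files.

# Build a genotype_dataset from a bare dosage matrix.
make_ds <- function(dosages, positions = NULL, scaffold = NULL,
                    localities = NULL, replicate_of = NULL) {
  dosages <- as.matrix(dosages)
  L <- nrow(dosages)
  n <- ncol(dosages)
  if (is.null(positions)) positions <- seq_len(L) * 10000L
  if (is.null(scaffold)) scaffold <- rep("s1", L)
  if (is.null(localities)) localities <- rep("popA", n)
  cn <- colnames(dosages)
  if (!is.null(cn) && anyDuplicated(cn)) cn <- NULL
  rn <- rownames(dosages)
  if (!is.null(rn) && anyDuplicated(rn)) rn <- NULL
  samples <- tibble::tibble(
    sample_id = if (!is.null(cn)) cn else sprintf("ind%02d", seq_len(n)),
    locality = localities
  )
  if (!is.null(replicate_of)) samples$replicate_of <- replicate_of
  loci <- tibble::tibble(
    locus_id = if (!is.null(rn)) rn else sprintf("loc%04d", seq_len(L)),
    scaffold = scaffold, position = as.integer(positions),
    ref = "A", alt = "T"
  )
  colnames(dosages) <- NULL
  rownames(dosages) <- NULL
  genotype_dataset(dosages, loci, samples)
}

# Panmictic single- or multi-locality configuration (no differentiation).
flat_config <- function(n_loci, localities, n_samples, f = 1e-12,
                        seed = 1, missing_rate = 0, freq_range = c(0.05, 0.95)) {
  k <- length(localities)
  sim_config(
    n_loci = n_loci,
    lineages = tibble::tibble(lineage_id = "l1", f_lineage = 1e-12),
    localities = tibble::tibble(
      locality = localities, lineage_id = "l1",
      f_local = rep(f, length.out = k),
      n_samples = as.integer(rep(n_samples, length.out = k))
    ),
    ancestral_freq_range = freq_range,
    missing_rate = missing_rate, n_relative_pairs = 0,
    n_replicate_pairs = 0, seed = seed
  )
}

# Independent transcription of the Weir-Cockerham (1984) variance
# components, written as literal per-population sums over genotype counts
# (distinct from the package's vectorised frequency/heterozygosity path).
wc_theta_oracle <- function(geno_by_pop) {
  # geno_by_pop: list of integer dosage matrices (loci x samples), one per
  # population, NA allowed
  L <- nrow(geno_by_pop[[1]])
  num <- 0
  den <- 0
  for (l in seq_len(L)) {
    gl <- lapply(geno_by_pop, function(m) m[l, !is.na(m[l, ])])
    ni <- vapply(gl, length, numeric(1))
    if (any(ni < 1)) next
    r <- length(gl)
    pi <- vapply(gl, function(g) sum(g) / (2 * length(g)), numeric(1))
    hi <- vapply(gl, function(g) mean(g == 1), numeric(1))
    nbar <- sum(ni) / r
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    pbar <- sum(ni * pi) / sum(ni)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / sum(ni)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                  ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    if (!is.finite(a + b + cc)) next
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Brute-force rarefaction: mean number of distinct alleles over every
# possible subsample of g copies (exhaustive enumeration).
brute_force_ar <- function(alt, n, g) {
  copies <- c(rep(1L, alt), rep(0L, n - alt))
  subs <- utils::combn(n, g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}

# Greedy forward max-coverage (lower bound on the exhaustive optimum).
greedy_coverage <- function(incidence, budget) {
  chosen <- integer(0)
  covered <- rep(FALSE, nrow(incidence))
  for (b in seq_len(budget)) {
    gain <- vapply(seq_len(ncol(incidence)), function(j) {
      if (j %in% chosen) return(-1L)
      sum(incidence[!covered, j])
    }, numeric(1))
    chosen <- c(chosen, which.max(gain))
    covered <- covered | rowSums(incidence[, chosen, drop = FALSE]) > 0
  }
  sum(covered)
}
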