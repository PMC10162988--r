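#' Configuration for the hierarchical genotype simulator
#'
#' Describes a two-level island model: localities nested within divergent
#' lineages, with Balding-Nichols drift at each level.  The defaults emulate
#' a range-wide rodent sampling design: an isolated island lineage that
#' split first, and a continental lineage holding a strongly drifted
#' low-diversity peripheral locality plus two weakly differentiated, diverse
#' central localities; sample sizes 5/14/8/14, ~2.5% missing data, one pair
#' of close relatives inside the island locality and two technical-replicate
#' pairs.  The per-branch drift parameters were calibrated so that expected
#' pairwise differentiation between localities (approximately the mean of
#' the two branches' divergence below their common ancestor) spans
#' ~0.12-0.4, the range typical of strongly structured
#' northern-Australian mammals.  See [study_config()] for the fixture that
#' additionally uses the rare-skewed allele-frequency spectrum.
#'
#' @param n_loci Number of biallelic loci.
#' @param lineages Data frame with columns `lineage_id`, `f_lineage` (the
#'   Balding-Nichols divergence of the lineage from the species ancestor,
#'   in (0,1); values below 1e-9 mean "no drift").
#' @param localities Data frame with columns `locality`, `lineage_id`,
#'   `f_local` (drift of the locality from its lineage) and `n_samples`.
#' @param ancestral_freq_range Range of the ancestral allele frequency draw;
#'   the default (0.05, 0.95) keeps Beta parameters away from degeneracy
#'   while still allowing monomorphic realised loci.
#' @param ancestral_sfs Shape of the ancestral frequency spectrum:
#'   `"uniform"` draws p uniformly over `ancestral_freq_range`;
#'   `"rare_skewed"` draws the minor allele frequency log-uniformly (density
#'   proportional to 1/x) between the lower range bound and 0.5, emulating
#'   the rare-allele-heavy spectrum of real SNP panels.
#' @param missing_rate Independent per-genotype missingness probability.
#' @param n_relative_pairs Number of parent-offspring trios to inject (the
#'   offspring is appended as a new sample in `relative_locality`).
#' @param n_replicate_pairs Number of technical-replicate copies to append.
#' @param replicate_error_rate Per-genotype probability that a replicate call
#'   disagrees with its source sample (genotyping error).
#' @param relative_locality Locality receiving the relative pairs; defaults
#'   to the largest locality.
#' @param scaffold_spacing Base pairs between adjacent simulated loci.
#' @param loci_per_scaffold Loci placed on each synthetic scaffold.
#' @param seed Integer seed making the whole dataset reproducible.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 5000,
                       lineages = tibble::tibble(
                         lineage_id = c("island", "continent"),
                         f_lineage = c(0.30, 0.12)
                       ),
                       localities = tibble::tibble(
                         locality = c("weipa", "melville", "cobourg", "darwin"),
                         lineage_id = c("continent", "island", "continent",
                                        "continent"),
                         f_local = c(0.46, 0.02, 0.13, 0.10),
                         n_samples = c(5L, 14L, 8L, 14L)
                       ),
                       ancestral_freq_range = c(0.05, 0.95),
                       ancestral_sfs = c("uniform", "rare_skewed"),
                       missing_rate = 0.025,
                       n_relative_pairs = 1,
                       n_replicate_pairs = 2,
                       replicate_error_rate = 0.01,
                       relative_locality = NULL,
                       scaffold_spacing = 20000,
                       loci_per_scaffold = 100,
                       seed = 1L) {
  ancestral_sfs <- match.arg(ancestral_sfs)
  lineages <- tibble::as_tibble(lineages)
  localities <- tibble::as_tibble(localities)
  stopifnot(
    n_loci >= 1,
    all(c("lineage_id", "f_lineage") %in% names(lineages)),
    all(c("locality", "lineage_id", "f_local", "n_samples") %in%
          names(localities)),
    all(localities$lineage_id %in% lineages$lineage_id),
    all(localities$n_samples >= 1)
  )
  if (any(lineages$f_lineage <= 0 | lineages$f_lineage >= 1) ||
      any(localities$f_local <= 0 | localities$f_local >= 1)) {
    stop("all drift parameters must lie strictly in (0, 1); ",
         "use values below 1e-9 for 'no drift'")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (length(ancestral_freq_range) != 2 ||
      ancestral_freq_range[1] <= 0 || ancestral_freq_range[2] >= 1 ||
      diff(ancestral_freq_range) < 0) {
    stop("ancestral_freq_range must be an increasing pair inside (0, 1)")
  }
  if (is.null(relative_locality)) {
    relative_locality <-
      localities$locality[which.max(localities$n_samples)]
  }
  structure(
    list(
      n_loci = as.integer(n_loci), lineages = lineages,
      localities = localities, ancestral_freq_range = ancestral_freq_range,
      ancestral_sfs = ancestral_sfs, missing_rate = missing_rate,
      n_relative_pairs = as.integer(n_relative_pairs),
      n_replicate_pairs = as.integer(n_replicate_pairs),
      replicate_error_rate = replicate_error_rate,
      relative_locality = relative_locality,
      scaffold_spacing = scaffold_spacing,
      loci_per_scaffold = as.integer(loci_per_scaffold),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' The bundled range-wide study fixture
#'
#' The [sim_config()] topology combined with the rare-skewed ancestral
#' spectrum reaching down to 0.5% frequency.  Shared drift along the
#' continental branch loses very rare alleles across all three continental
#' localities at once, so the isolated island locality accumulates
#' private alleles at appreciable frequency - the configuration that
#' reproduces the qualitative range-wide pattern this package's
#' prioritisation analyses are designed to detect: the island population
#' contributes most to pooled allelic richness even though a central
#' population is the single best unit to conserve, and two central
#' populations jointly retain >90% of observed alleles.
#'
#' @param seed Integer seed.
#' @param n_loci Number of loci (default 5000).
#' @return A `sim_config`.
#' @export
study_config <- function(seed = 1L, n_loci = 5000) {
  sim_config(n_loci = n_loci,
             ancestral_freq_range = c(0.005, 0.995),
             ancestral_sfs = "rare_skewed",
             seed = seed)
}

#' Read a simulator configuration from YAML or JSON
#'
#' Scalar fields override the [sim_config()] defaults; `lineages` and
#' `localities` are given as lists of records.
#'
#' @param path YAML (or JSON; YAML is a superset) file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (fld in c("lineages", "localities")) {
    if (!is.null(raw[[fld]])) {
      raw[[fld]] <- dplyr::bind_rows(lapply(raw[[fld]], tibble::as_tibble))
    }
  }
  do.call(sim_config, raw)
}

# Balding-Nichols draw around frequency p with divergence f
rbn <- function(p, f) {
  if (f < 1e-9) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate a hierarchically structured genotype dataset
#'
#' Per locus, an ancestral frequency is drawn uniformly; each lineage
#' frequency is a Balding-Nichols draw around it, each locality frequency a
#' Balding-Nichols draw around its lineage, and genotypes are binomial(2, p)
#' within localities (Hardy-Weinberg within populations).  Relative pairs,
#' technical replicates and missingness are then layered on per the
#' configuration.  Loci are placed on uniformly spaced synthetic scaffolds so
#' that window-based operations (LD pruning, LD-Ne distance bins) are
#' exercised.
#'
#' @param config A [sim_config()].
#' @return A list with elements `dataset` (a [genotype_dataset()]) and
#'   `truth` (a `sim_truth`: ancestral/lineage/locality allele frequencies,
#'   injected pair lists, and the drift parameters used).
#' @export
simulate_hierarchical_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_loci
  if (config$ancestral_sfs == "uniform") {
    p_anc <- stats::runif(L, config$ancestral_freq_range[1],
                          config$ancestral_freq_range[2])
  } else {
    # rare-skewed spectrum (density ~ 1/x): log-uniform minor allele
    # frequency between the lower range bound and 0.5, randomly folded -
    # emulates the ascertainment profile of reduced-representation panels
    p_min <- config$ancestral_freq_range[1]
    maf <- p_min * (0.5 / p_min)^stats::runif(L)
    p_anc <- ifelse(stats::runif(L) < 0.5, maf, 1 - maf)
  }
  p_lin <- vapply(seq_len(nrow(config$lineages)), function(i) {
    rbn(p_anc, config$lineages$f_lineage[i])
  }, numeric(L))
  colnames(p_lin) <- config$lineages$lineage_id

  locs <- config$localities
  p_loc <- vapply(seq_len(nrow(locs)), function(i) {
    rbn(p_lin[, locs$lineage_id[i]], locs$f_local[i])
  }, numeric(L))
  colnames(p_loc) <- locs$locality

  dosage_cols <- list()
  sample_rows <- list()
  for (i in seq_len(nrow(locs))) {
    n <- locs$n_samples[i]
    g <- matrix(stats::rbinom(L * n, 2, p_loc[, i]), nrow = L)
    ids <- sprintf("%s_%02d", locs$locality[i], seq_len(n))
    dosage_cols[[i]] <- g
    sample_rows[[i]] <- tibble::tibble(
      sample_id = ids, locality = locs$locality[i],
      latitude = -12 - i, longitude = 130 + 3 * i,
      replicate_of = NA_character_
    )
  }
  dosages <- do.call(cbind, dosage_cols)
  samples <- dplyr::bind_rows(sample_rows)

  n_scaffold <- ceiling(L / config$loci_per_scaffold)
  scaffold_idx <- rep(seq_len(n_scaffold),
                      each = config$loci_per_scaffold)[seq_len(L)]
  within <- stats::ave(seq_len(L), scaffold_idx, FUN = seq_along)
  loci <- tibble::tibble(
    locus_id = sprintf("L%05d", seq_len(L)),
    scaffold = sprintf("scaffold_%03d", scaffold_idx),
    position = as.integer(within * config$scaffold_spacing),
    ref = "A", alt = "T"
  )
  ds <- genotype_dataset(dosages, loci, samples)

  truth <- structure(
    list(
      ancestral_freq = p_anc, lineage_freq = p_lin, locality_freq = p_loc,
      localities = locs, lineages = config$lineages,
      relative_pairs = tibble::tibble(parent_a = character(),
                                      parent_b = character(),
                                      offspring = character(),
                                      locality = character()),
      replicate_pairs = tibble::tibble(source = character(),
                                       replicate = character())
    ),
    class = "sim_truth"
  )

  if (config$n_relative_pairs > 0) {
    loc <- config$relative_locality
    members <- samples$sample_id[samples$locality == loc]
    if (length(members) < 2 * config$n_relative_pairs) {
      stop("locality ", loc, " too small for requested relative pairs")
    }
    pairs <- tibble::tibble(
      parent_a = members[seq(1, by = 2,
                             length.out = config$n_relative_pairs)],
      parent_b = members[seq(2, by = 2,
                             length.out = config$n_relative_pairs)],
      locality = loc
    )
    res <- inject_relatives(ds, truth, pairs)
    ds <- res$dataset
    truth <- res$truth
  }

  if (config$n_replicate_pairs > 0) {
    src_loc <- locs$locality[order(-locs$n_samples)]
    src_loc <- rep(src_loc, length.out = config$n_replicate_pairs)
    sources <- vapply(seq_len(config$n_replicate_pairs), function(k) {
      ds$samples$sample_id[ds$samples$locality == src_loc[k]][k]
    }, character(1))
    res <- inject_replicates(ds, truth, sources,
                             error_rate = config$replicate_error_rate)
    ds <- res$dataset
    truth <- res$truth
  }

  if (config$missing_rate > 0) {
    ds <- add_missingness(ds, config$missing_rate)
  }
  list(dataset = ds, truth = truth)
}

#' Append Mendelian offspring of in-locality parent pairs
#'
#' For each pair, one new sample is appended whose genotype at every locus is
#' one allele drawn from each parent; a missing parent genotype propagates a
#' missing offspring genotype.  Used to exercise kinship-based relative
#' filtering (expected kinship ~0.25 for parent-offspring).
#'
#' @param ds A `genotype_dataset`.
#' @param truth A `sim_truth` (updated pair list is returned).
#' @param pairs Data frame with columns `parent_a`, `parent_b`, `locality`.
#' @return List with updated `dataset` and `truth`.
#' @export
inject_relatives <- function(ds, truth, pairs) {
  pairs <- tibble::as_tibble(pairs)
  for (k in seq_len(nrow(pairs))) {
    pa <- pairs$parent_a[k]
    pb <- pairs$parent_b[k]
    for (p in c(pa, pb)) {
      if (!p %in% ds$samples$sample_id) stop("unknown parent: ", p)
      loc <- ds$samples$locality[ds$samples$sample_id == p]
      if (loc != pairs$locality[k]) {
        stop("parent ", p, " is not in locality ", pairs$locality[k])
      }
    }
    xa <- ds$dosages[, pa]
    xb <- ds$dosages[, pb]
    off <- stats::rbinom(n_loci(ds), 1, ifelse(is.na(xa), 0, xa / 2)) +
      stats::rbinom(n_loci(ds), 1, ifelse(is.na(xb), 0, xb / 2))
    off[is.na(xa) | is.na(xb)] <- NA_integer_
    off_id <- sprintf("%s_off%02d", pairs$locality[k], k)
    ds <- append_sample(ds, off_id, pairs$locality[k], off)
    truth$relative_pairs <- dplyr::bind_rows(
      truth$relative_pairs,
      tibble::tibble(parent_a = pa, parent_b = pb, offspring = off_id,
                     locality = pairs$locality[k])
    )
  }
  list(dataset = ds, truth = truth)
}

#' Append technical-replicate copies of existing samples
#'
#' @param ds A `genotype_dataset`.
#' @param truth A `sim_truth`, or `NULL`.
#' @param sample_ids Samples to duplicate.
#' @param error_rate Per-genotype probability that the replicate call is
#'   perturbed to a different dosage (genotyping error).
#' @return List with updated `dataset` and `truth`.
#' @export
inject_replicates <- function(ds, truth = NULL, sample_ids,
                              error_rate = 0) {
  for (k in seq_along(sample_ids)) {
    src <- sample_ids[k]
    if (!src %in% ds$samples$sample_id) stop("unknown sample: ", src)
    x <- ds$dosages[, src]
    if (error_rate > 0) {
      flip <- !is.na(x) & stats::runif(length(x)) < error_rate
      x[flip] <- (x[flip] + sample(1:2, sum(flip), replace = TRUE)) %% 3L
    }
    rep_id <- paste0(src, "_rep")
    loc <- ds$samples$locality[ds$samples$sample_id == src]
    ds <- append_sample(ds, rep_id, loc, x, replicate_of = src)
    if (!is.null(truth)) {
      truth$replicate_pairs <- dplyr::bind_rows(
        truth$replicate_pairs,
        tibble::tibble(source = src, replicate = rep_id)
      )
    }
  }
  list(dataset = ds, truth = truth)
}

append_sample <- function(ds, sample_id, locality, dosage,
                          replicate_of = NA_character_) {
  new_row <- ds$samples[ds$samples$locality == locality, ][1, ]
  new_row$sample_id <- sample_id
  new_row$replicate_of <- replicate_of
  genotype_dataset(cbind(ds$dosages, dosage),
                   ds$loci, dplyr::bind_rows(ds$samples, new_row))
}

#' Set called genotypes to missing at random
#'
#' @param ds A `genotype_dataset`.
#' @param rate Independent per-genotype missingness probability in `[0, 1)`.
#' @param seed Optional seed for reproducibility of the mask alone.
#' @return The dataset with additional missing entries.
#' @export
add_missingness <- function(ds, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(ds)
  if (!is.null(seed)) set.seed(seed)
  mask <- matrix(stats::runif(length(ds$dosages)) < rate,
                 nrow = nrow(ds$dosages))
  ds$dosages[mask] <- NA_integer_
  ds
}

#' Forward Wright-Fisher simulation of recombining chromosomes
#'
#' A discrete-generation, non-overlapping Wright-Fisher population of
#' `2 * Ne` haplotypes per chromosome.  Each gamete derives from a randomly
#' chosen parent with a Poisson number of crossovers placed uniformly along
#' the chromosome; loci start at frequency 0.5 (i.i.d.).  After
#' `n_generations`, `sample_n` diploids are drawn without replacement and
#' returned unphased, giving a dataset whose linkage-disequilibrium decay
#' with recombination distance reflects the known constant `Ne` - the oracle
#' for the LD-based Ne estimator.
#'
#' @param Ne Constant diploid effective population size (>= 2).
#' @param n_generations Generations to evolve.
#' @param chrom_length Chromosome length in base pairs.
#' @param recomb_rate Per-base-pair, per-generation crossover rate (Morgans
#'   per bp); the default 1e-8 is the conventional 1 cM/Mb.
#' @param n_chromosomes Independent chromosomes to simulate.
#' @param sample_n Diploid individuals sampled from the final generation.
#' @param n_loci_per_chrom Evenly spaced loci tracked per chromosome.
#' @param seed Integer seed.
#' @return A [genotype_dataset()] with one scaffold per chromosome; all
#'   samples share locality `"wf"`.
#' @export
simulate_wright_fisher_ld <- function(Ne, n_generations,
                                      chrom_length = 5e6,
                                      recomb_rate = 1e-8,
                                      n_chromosomes = 5,
                                      sample_n = Ne,
                                      n_loci_per_chrom = 100,
                                      seed = 1L) {
  if (Ne < 2) stop("Ne must be >= 2")
  if (n_generations < 1) stop("n_generations must be >= 1")
  if (sample_n > Ne) stop("sample_n cannot exceed Ne")
  set.seed(seed)
  pos <- round(seq(1, chrom_length, length.out = n_loci_per_chrom))
  morgans <- chrom_length * recomb_rate
  n_hap <- 2L * as.integer(Ne)

  chrom_result <- lapply(seq_len(n_chromosomes), function(chrom) {
    H <- matrix(stats::rbinom(n_hap * n_loci_per_chrom, 1, 0.5),
                nrow = n_hap)
    for (g in seq_len(n_generations)) {
      parent <- sample.int(Ne, n_hap, replace = TRUE)
      start <- sample.int(2L, n_hap, replace = TRUE) - 1L
      ncross <- stats::rpois(n_hap, morgans)
      plain <- ncross == 0
      Hn <- matrix(0L, n_hap, n_loci_per_chrom)
      Hn[plain, ] <- H[2L * parent[plain] - 1L + start[plain], ,
                       drop = FALSE]
      for (i in which(!plain)) {
        bp <- sort(stats::runif(ncross[i], 0, chrom_length))
        seg <- findInterval(pos, bp)
        choice <- (start[i] + seg) %% 2L
        h1 <- H[2L * parent[i] - 1L, ]
        h2 <- H[2L * parent[i], ]
        Hn[i, ] <- ifelse(choice == 0L, h1, h2)
      }
      H <- Hn
    }
    ind <- sample.int(Ne, sample_n)
    H[2L * ind - 1L, , drop = FALSE] + H[2L * ind, , drop = FALSE]
  })

  dosages <- do.call(rbind, lapply(chrom_result, t))
  loci <- tibble::tibble(
    locus_id = sprintf("chr%02d_%09d", rep(seq_len(n_chromosomes),
                                           each = n_loci_per_chrom),
                       rep(pos, n_chromosomes)),
    scaffold = sprintf("chr%02d", rep(seq_len(n_chromosomes),
                                      each = n_loci_per_chrom)),
    position = rep(as.integer(pos), n_chromosomes),
    ref = "A", alt = "T"
  )
  samples <- tibble::tibble(
    sample_id = sprintf("wf_%03d", seq_len(sample_n)), locality = "wf"
  )
  genotype_dataset(dosages, loci, samples)
}
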