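#' @title Post-genotyping quality-control filters
#' @description Each filter takes a `genotype_dataset` first and returns a
#'   list with the filtered `dataset` and a one-row `report` tibble; the full
#'   cascade is [qc_cascade()].  Boundary conventions follow the removal
#'   conditions as usually stated for such pipelines: loci are removed when
#'   call rate is strictly below the threshold, when observed heterozygosity
#'   strictly exceeds the cap, samples when missingness strictly exceeds the
#'   cap, and relatives when kinship strictly exceeds the threshold.
#' @name qc_filters
NULL

filter_report_row <- function(name, before, after, params, removed) {
  tibble::tibble(
    filter = name,
    n_loci_before = n_loci(before), n_loci_after = n_loci(after),
    n_samples_before = n_samples(before), n_samples_after = n_samples(after),
    parameters = paste(names(params), unlist(params), sep = "=",
                       collapse = ", "),
    removed_ids = list(removed)
  )
}

locus_callrate <- function(ds) rowMeans(!is.na(ds$dosages))

#' @rdname qc_filters
#' @param ds A `genotype_dataset`.
#' @param min_prop Minimum proportion of samples in which a locus must be
#'   genotyped (loci strictly below are removed).
#' @return For each filter, a list with elements `dataset` and `report`.
#' @export
filter_locus_callrate <- function(ds, min_prop = 0.90) {
  stopifnot(min_prop > 0, min_prop <= 1)
  keep <- locus_callrate(ds) >= min_prop
  if (!any(keep)) stop("all loci fail the call-rate filter")
  out <- subset_loci(ds, keep)
  list(dataset = out,
       report = filter_report_row("locus_callrate", ds, out,
                                  list(min_prop = min_prop),
                                  ds$loci$locus_id[!keep]))
}

minor_allele_count <- function(ds) {
  alt <- rowSums(ds$dosages, na.rm = TRUE)
  copies <- 2 * rowSums(!is.na(ds$dosages))
  pmin(alt, copies - alt)
}

#' @rdname qc_filters
#' @param min_mac Minimum minor-allele copy count over called genotypes.
#' @export
filter_mac <- function(ds, min_mac = 3) {
  stopifnot(min_mac >= 0)
  keep <- minor_allele_count(ds) >= min_mac
  if (!any(keep)) stop("all loci fail the minor-allele-count filter")
  out <- subset_loci(ds, keep)
  list(dataset = out,
       report = filter_report_row("minor_allele_count", ds, out,
                                  list(min_mac = min_mac),
                                  ds$loci$locus_id[!keep]))
}

observed_het <- function(ds) {
  rowSums(ds$dosages == 1, na.rm = TRUE) / rowSums(!is.na(ds$dosages))
}

#' @rdname qc_filters
#' @param max_ho Observed-heterozygosity cap; loci strictly above are removed
#'   (guards against erroneously merged paralogous reads).
#' @export
filter_excess_het <- function(ds, max_ho = 0.6) {
  stopifnot(max_ho > 0, max_ho <= 1)
  ho <- observed_het(ds)
  keep <- is.nan(ho) | ho <= max_ho
  out <- subset_loci(ds, keep)
  list(dataset = out,
       report = filter_report_row("excess_heterozygosity", ds, out,
                                  list(max_ho = max_ho),
                                  ds$loci$locus_id[!keep]))
}

#' @rdname qc_filters
#' @param max_miss Maximum tolerated per-sample missing fraction; samples
#'   strictly above are removed.
#' @export
filter_sample_missingness <- function(ds, max_miss = 0.25) {
  stopifnot(max_miss > 0, max_miss < 1)
  miss <- colMeans(is.na(ds$dosages))
  keep <- miss <= max_miss
  if (!any(keep)) stop("all samples fail the missingness filter")
  out <- subset_samples(ds, keep)
  list(dataset = out,
       report = filter_report_row("sample_missingness", ds, out,
                                  list(max_miss = max_miss),
                                  ds$samples$sample_id[!keep]))
}

#' Allele-matching (Weir-Goudet) kinship matrix
#'
#' Method-of-moments kinship from allele matching: for samples i and j,
#' `M_ij` is the mean over co-called loci of the probability that an allele
#' drawn at random from i matches one drawn from j (in dosage form
#' `(x_i x_j + (2 - x_i)(2 - x_j)) / 4`), and the kinship estimate is
#' `beta_ij = (M_ij - M_B) / (1 - M_B)` where `M_B` is the average matching
#' over all distinct pairs.  The diagonal holds within-individual matching
#' scaled the same way.  Estimates are relative to the average pair, so the
#' mean off-diagonal beta is ~0 in a panmictic sample.
#'
#' @param ds A `genotype_dataset` with at least two samples.
#' @return A symmetric matrix of class `kinship_matrix` with sample ids as
#'   dimnames; pairs sharing no co-called locus are `NA`.
#' @export
kinship_matrix <- function(ds) {
  if (n_samples(ds) < 2) stop("kinship requires at least two samples")
  X <- ds$dosages
  A <- X; A[is.na(A)] <- 0L
  B <- 2L - X; B[is.na(B)] <- 0L
  C <- !is.na(X)
  S <- (crossprod(A) + crossprod(B)) / 4
  N <- crossprod(C)
  M <- S / N
  if (any(N == 0)) {
    warning(sum(N == 0 & upper.tri(N)), " sample pair(s) share no ",
            "co-called locus; kinship undefined (NA)")
  }
  off <- M[upper.tri(M)]
  m_b <- mean(off, na.rm = TRUE)
  beta <- (M - m_b) / (1 - m_b)
  structure(beta, class = c("kinship_matrix", "matrix"))
}

#' Tidy a kinship matrix into a pair table
#'
#' @param x A `kinship_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `sample_a`, `sample_b`, `kinship` (one row
#'   per unordered distinct pair).
#' @export
tidy.kinship_matrix <- function(x, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble::tibble(
    sample_a = rownames(m)[idx[, 1]],
    sample_b = colnames(m)[idx[, 2]],
    kinship = m[idx]
  )
}

#' @rdname qc_filters
#' @param threshold Kinship value above which a pair counts as close
#'   relatives.
#' @param scope `"within-locality"` (default) only considers pairs sampled at
#'   the same locality; `"global"` considers all pairs.
#' @details `remove_related` estimates relatedness at each locality: the
#'   allele-matching kinship matrix is computed on each locality's samples
#'   alone, so the reference mean `M_B` is locality-local and population
#'   structure does not masquerade as relatedness (with `scope = "global"`
#'   a single matrix over all samples is used instead).  From the pair with
#'   the highest kinship above the threshold it iteratively drops the member
#'   with more missing data (ties broken towards the later sample).
#'   Technical replicates (`replicate_of` set) are exempt - they are handled
#'   by [replicate_concordance()].
#' @export
remove_related <- function(ds, threshold = 0.25,
                           scope = c("within-locality", "global")) {
  scope <- match.arg(scope)
  miss <- colMeans(is.na(ds$dosages))
  is_rep <- !is.na(ds$samples$replicate_of)
  removed <- character(0)
  groups <- if (scope == "within-locality") {
    split(seq_len(n_samples(ds)), ds$samples$locality)
  } else {
    list(seq_len(n_samples(ds)))
  }
  for (idx in groups) {
    if (length(idx) < 2) next
    k <- unclass(kinship_matrix(subset_samples(ds, idx)))
    eligible <- upper.tri(k) & !outer(is_rep[idx], is_rep[idx], `|`)
    gmiss <- miss[idx]
    active <- rep(TRUE, length(idx))
    repeat {
      kk <- k
      kk[!eligible] <- NA
      kk[!active, ] <- NA
      kk[, !active] <- NA
      mx <- suppressWarnings(max(kk, na.rm = TRUE))
      if (!is.finite(mx) || mx <= threshold) break
      at <- which(kk == mx, arr.ind = TRUE)[1, ]
      i <- at[1]; j <- at[2]
      drop <- if (gmiss[i] > gmiss[j]) i else
        if (gmiss[j] > gmiss[i]) j else max(i, j)
      active[drop] <- FALSE
      removed <- c(removed, colnames(k)[drop])
    }
  }
  out <- subset_samples(ds, !ds$samples$sample_id %in% removed)
  list(dataset = out,
       report = filter_report_row("kinship_removal", ds, out,
                                  list(threshold = threshold, scope = scope),
                                  removed))
}

#' @rdname qc_filters
#' @param max_corr Absolute Pearson correlation of dosages above which the
#'   later locus of a pair is removed.
#' @param window_bp Sliding-window width in base pairs (pairs farther apart
#'   are never compared).
#' @details `ld_prune` sweeps loci in genomic order per scaffold; when a
#'   retained locus and a later locus within `window_bp` have `|r|` strictly
#'   above `max_corr`, the later locus is removed and takes no further part
#'   in comparisons.
#' @export
ld_prune <- function(ds, max_corr = 0.5, window_bp = 100000) {
  ord <- order(ds$loci$scaffold, ds$loci$position)
  X <- ds$dosages
  keep <- rep(TRUE, n_loci(ds))
  scaffolds <- ds$loci$scaffold[ord]
  positions <- ds$loci$position[ord]
  for (sc in unique(scaffolds)) {
    rows <- ord[scaffolds == sc]
    pos <- positions[scaffolds == sc]
    m <- length(rows)
    alive <- rep(TRUE, m)
    for (a in seq_len(m)) {
      if (!alive[a]) next
      b <- a + 1L
      while (b <= m && pos[b] - pos[a] <= window_bp) {
        if (alive[b]) {
          r <- suppressWarnings(
            stats::cor(X[rows[a], ], X[rows[b], ],
                       use = "pairwise.complete.obs")
          )
          if (!is.na(r) && abs(r) > max_corr) alive[b] <- FALSE
        }
        b <- b + 1L
      }
    }
    keep[rows] <- alive
  }
  out <- subset_loci(ds, keep)
  list(dataset = out,
       report = filter_report_row("ld_prune", ds, out,
                                  list(max_corr = max_corr,
                                       window_bp = window_bp),
                                  ds$loci$locus_id[!keep]))
}

#' Technical-replicate concordance check
#'
#' For every sample whose `replicate_of` points at its source, reports the
#' fraction of co-called loci with identical dosage and whether the
#' replicate's nearest neighbour under Prevosti distance is its partner (the
#' dendrogram criterion: replicates must pair together before they are
#' removed from analysis).
#'
#' @param ds A `genotype_dataset` containing at least one replicate pair.
#' @return Tibble with columns `sample_id`, `replicate_of`, `concordance`,
#'   `nearest_neighbour`, `pass`.
#' @export
replicate_concordance <- function(ds) {
  reps <- which(!is.na(ds$samples$replicate_of))
  if (length(reps) == 0) stop("dataset contains no replicate pairs")
  d <- unclass(prevosti_distance(ds))
  purrr::map_dfr(reps, function(i) {
    src <- ds$samples$replicate_of[i]
    j <- match(src, ds$samples$sample_id)
    xi <- ds$dosages[, i]
    xj <- ds$dosages[, j]
    cc <- !is.na(xi) & !is.na(xj)
    conc <- mean(xi[cc] == xj[cc])
    dist_i <- d[i, ]
    dist_i[i] <- NA
    nn <- colnames(d)[which.min(dist_i)]
    tibble::tibble(
      sample_id = ds$samples$sample_id[i], replicate_of = src,
      concordance = conc, nearest_neighbour = nn, pass = nn == src
    )
  })
}

#' Remove technical replicates
#'
#' Drops every sample whose `replicate_of` is set, keeping the source.
#'
#' @param ds A `genotype_dataset`.
#' @return List with `dataset` and `report` as for the other filters.
#' @export
remove_replicates <- function(ds) {
  keep <- is.na(ds$samples$replicate_of)
  out <- subset_samples(ds, keep)
  list(dataset = out,
       report = filter_report_row("replicate_removal", ds, out, list(),
                                  ds$samples$sample_id[!keep]))
}

#' Run the full quality-control cascade
#'
#' Applies, in order: locus call rate, minor allele count, excess
#' heterozygosity, kinship-based relative removal, LD pruning, sample
#' missingness, and (when replicate pairs are present) replicate concordance
#' checking followed by replicate removal.  Because removing samples changes
#' per-locus call rates and allele counts, the six-stage pass is repeated
#' until the dataset stops changing (removals are monotone, so this
#' converges, almost always in two passes).  The combined filter report has
#' monotonically non-increasing locus and sample counts, and the returned
#' dataset passes every filter: re-running the cascade changes nothing.
#'
#' @param ds A `genotype_dataset`.
#' @param min_prop,min_mac,max_ho,kin_threshold,max_corr,window_bp,max_miss
#'   Stage thresholds; defaults follow a conventional conservative ddRAD
#'   filtering protocol (call rate 0.90, MAC 3, H_O cap 0.6, kinship 0.25,
#'   |r| 0.5 in 100-kb windows, sample missingness 0.25).
#' @param check_replicates Run the replicate concordance check and drop
#'   replicates at the end (only if any `replicate_of` is set).
#' @param max_passes Safety cap on refinement passes.
#' @return List with `dataset` (filtered), `report` (tibble, one row per
#'   stage and pass) and `replicates` (concordance table or `NULL`).
#' @export
qc_cascade <- function(ds, min_prop = 0.90, min_mac = 3, max_ho = 0.6,
                       kin_threshold = 0.25, max_corr = 0.5,
                       window_bp = 100000, max_miss = 0.25,
                       check_replicates = TRUE, max_passes = 10) {
  steps <- list()
  current <- ds
  for (pass in seq_len(max_passes)) {
    shape_before <- c(n_loci(current), n_samples(current))
    s <- filter_locus_callrate(current, min_prop)
    steps <- c(steps, list(s$report))
    s <- filter_mac(s$dataset, min_mac)
    steps <- c(steps, list(s$report))
    s <- filter_excess_het(s$dataset, max_ho)
    steps <- c(steps, list(s$report))
    s <- remove_related(s$dataset, kin_threshold)
    steps <- c(steps, list(s$report))
    s <- ld_prune(s$dataset, max_corr, window_bp)
    steps <- c(steps, list(s$report))
    s <- filter_sample_missingness(s$dataset, max_miss)
    steps <- c(steps, list(s$report))
    current <- s$dataset
    if (all(c(n_loci(current), n_samples(current)) == shape_before)) break
  }
  rep_table <- NULL
  if (check_replicates && any(!is.na(current$samples$replicate_of))) {
    rep_table <- replicate_concordance(current)
    s <- remove_replicates(current)
    steps <- c(steps, list(s$report))
    current <- s$dataset
    # dropping replicate columns shifts call rates: refine to the fixpoint
    for (pass in seq_len(max_passes)) {
      shape_before <- c(n_loci(current), n_samples(current))
      s <- filter_locus_callrate(current, min_prop)
      steps <- c(steps, list(s$report))
      s <- filter_mac(s$dataset, min_mac)
      steps <- c(steps, list(s$report))
      s <- filter_excess_het(s$dataset, max_ho)
      steps <- c(steps, list(s$report))
      s <- remove_related(s$dataset, kin_threshold)
      steps <- c(steps, list(s$report))
      s <- ld_prune(s$dataset, max_corr, window_bp)
      steps <- c(steps, list(s$report))
      s <- filter_sample_missingness(s$dataset, max_miss)
      steps <- c(steps, list(s$report))
      current <- s$dataset
      if (all(c(n_loci(current), n_samples(current)) == shape_before)) break
    }
  }
  list(dataset = current, report = dplyr::bind_rows(steps),
       replicates = rep_table)
}
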