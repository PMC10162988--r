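#' Per-population allele frequencies
#'
#' Alternate-allele frequencies computed over called gene copies, with the
#' copy counts returned alongside.  Loci with no called genotype in a
#' population get `NA` frequency.
#'
#' @param ds A `genotype_dataset`.
#' @param populations Named assignment of samples to populations; defaults to
#'   the `locality` column.
#' @return Tibble with columns `population`, `locus_id`, `p_alt`, `n_copies`.
#' @export
allele_frequencies <- function(ds, populations = NULL) {
  pops <- resolve_populations(ds, populations)
  purrr::map_dfr(unique(pops), function(pop) {
    X <- ds$dosages[, pops == pop, drop = FALSE]
    copies <- unname(2 * rowSums(!is.na(X)))
    p <- unname(rowSums(X, na.rm = TRUE)) / copies
    p[copies == 0] <- NA_real_
    tibble::tibble(population = pop, locus_id = ds$loci$locus_id,
                   p_alt = p, n_copies = copies)
  })
}

resolve_populations <- function(ds, populations) {
  if (is.null(populations)) return(ds$samples$locality)
  if (length(populations) != n_samples(ds)) {
    stop("populations must have one entry per sample")
  }
  as.character(populations)
}

#' Per-locus diversity statistics within populations
#'
#' For each locus and population with allele frequency `p` over `2 n_c`
#' called gene copies: observed allele count `A`, effective allele count
#' `A_E = 1 / (p^2 + (1 - p)^2)`, observed heterozygosity `H_O`, unbiased
#' expected heterozygosity `H_E = 2 n_c / (2 n_c - 1) * 2 p (1 - p)` (Nei's
#' small-sample correction; disable with `correct = FALSE`), and the
#' fixation index `F_IS = 1 - H_O / H_E` on polymorphic loci.
#'
#' @inheritParams allele_frequencies
#' @param correct Apply the small-sample correction to `H_E`.
#' @return Tibble with one row per population x locus: `population`,
#'   `locus_id`, `n_called`, `A`, `A_E`, `H_O`, `H_E`, `F_IS`.
#' @export
per_locus_diversity <- function(ds, populations = NULL, correct = TRUE) {
  pops <- resolve_populations(ds, populations)
  purrr::map_dfr(unique(pops), function(pop) {
    X <- ds$dosages[, pops == pop, drop = FALSE]
    n_called <- unname(rowSums(!is.na(X)))
    copies <- 2 * n_called
    p <- unname(rowSums(X, na.rm = TRUE)) / copies
    p[copies == 0] <- NA_real_
    a <- 1L + as.integer(p > 0 & p < 1)
    a_e <- 1 / (p^2 + (1 - p)^2)
    h_o <- unname(rowSums(X == 1, na.rm = TRUE)) / n_called
    h_e <- 2 * p * (1 - p)
    if (correct) h_e <- h_e * copies / (copies - 1)
    f_is <- ifelse(h_e > 0, 1 - h_o / h_e, NA_real_)
    tibble::tibble(population = pop, locus_id = ds$loci$locus_id,
                   n_called = n_called, A = a, A_E = a_e,
                   H_O = h_o, H_E = h_e, F_IS = f_is)
  })
}

se_mean <- function(x) {
  x <- x[!is.na(x)]
  stats::sd(x) / sqrt(length(x))
}

#' Population diversity table
#'
#' Means (and standard errors over loci) of the per-locus statistics of
#' [per_locus_diversity()] for every population: sample size `n`, mean
#' alleles per locus `A`, effective alleles `A_E`, SNP expected and observed
#' heterozygosity `H_E`/`H_O`, and mean `F_IS` over polymorphic loci.
#'
#' @inheritParams per_locus_diversity
#' @param min_n Populations with fewer samples are dropped from the table.
#' @return Tibble with one row per population and paired `*_se` columns.
#' @export
per_population_diversity <- function(ds, populations = NULL, min_n = 2,
                                     correct = TRUE) {
  pops <- resolve_populations(ds, populations)
  sizes <- table(pops)
  keep <- names(sizes)[sizes >= min_n]
  if (length(keep) == 0) stop("no population has at least ", min_n,
                              " samples")
  per_locus <- per_locus_diversity(ds, pops, correct = correct)
  per_locus <- per_locus[per_locus$population %in% keep &
                           per_locus$n_called >= 2, ]
  if (nrow(per_locus) == 0) {
    stop("no locus has at least two called samples in any population")
  }
  out <- per_locus |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(
      A_se = se_mean(.data$A), A = mean(.data$A, na.rm = TRUE),
      A_E_se = se_mean(.data$A_E), A_E = mean(.data$A_E, na.rm = TRUE),
      H_E_se = se_mean(.data$H_E), H_E = mean(.data$H_E, na.rm = TRUE),
      H_O_se = se_mean(.data$H_O), H_O = mean(.data$H_O, na.rm = TRUE),
      F_IS_se = se_mean(.data$F_IS), F_IS = mean(.data$F_IS, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::select("population", "A", "A_se", "A_E", "A_E_se", "H_E",
                  "H_E_se", "H_O", "H_O_se", "F_IS", "F_IS_se")
  n_tbl <- tibble::tibble(population = pops) |>
    dplyr::count(.data$population, name = "n")
  dplyr::left_join(n_tbl, out, by = "population") |>
    dplyr::filter(.data$population %in% keep)
}

#' Autosomal heterozygosity over variant plus invariant sites
#'
#' SNP-panel heterozygosities are inflated by ascertainment (only variable
#' sites are kept); dividing by the number of genuinely callable sites
#' (variant plus invariant) gives per-site autosomal heterozygosity.
#' `H_O_auto` is total heterozygous calls over total called genotype-site
#' observations (invariant sites are assumed called wherever the sample was
#' genotyped); `H_E_auto` is the mean unbiased expected heterozygosity over
#' all callable sites, invariant sites contributing zero.  Values are
#' reported per thousand sites (`x 1000`) for readability.
#'
#' @inheritParams per_population_diversity
#' @param callable_sites Total callable sites per population: a single
#'   number used for all populations, or a named vector.
#' @return Tibble with columns `population`, `n`, `H_O_auto`, `H_E_auto`
#'   (and SEs), all multiplied by 1000.
#' @export
autosomal_heterozygosity <- function(ds, populations = NULL, callable_sites,
                                     min_n = 2) {
  pops <- resolve_populations(ds, populations)
  sizes <- table(pops)
  keep <- names(sizes)[sizes >= min_n]
  purrr::map_dfr(keep, function(pop) {
    X <- ds$dosages[, pops == pop, drop = FALSE]
    cs <- if (length(callable_sites) == 1) callable_sites else
      callable_sites[[pop]]
    if (cs < nrow(X)) {
      stop("callable_sites (", cs, ") is below the number of variant loci (",
           nrow(X), ")")
    }
    n_ind <- ncol(X)
    called_variant <- sum(!is.na(X))
    het <- sum(X == 1, na.rm = TRUE)
    invariant_obs <- (cs - nrow(X)) * n_ind
    h_o_auto <- het / (called_variant + invariant_obs)
    n_called <- rowSums(!is.na(X))
    copies <- 2 * n_called
    p <- rowSums(X, na.rm = TRUE) / copies
    he <- ifelse(copies > 1, 2 * p * (1 - p) * copies / (copies - 1), 0)
    he[copies == 0] <- 0
    h_e_auto <- sum(he) / cs
    # per-sample SE for H_O; site-level SE for H_E with invariant sites as 0
    per_sample_ho <- colSums(X == 1, na.rm = TRUE) /
      (colSums(!is.na(X)) + (cs - nrow(X)))
    var_all <- (sum(he^2) - cs * h_e_auto^2) / (cs - 1)
    tibble::tibble(
      population = pop, n = n_ind,
      H_O_auto = 1000 * h_o_auto,
      H_O_auto_se = 1000 * se_mean(per_sample_ho),
      H_E_auto = 1000 * h_e_auto,
      H_E_auto_se = 1000 * sqrt(max(var_all, 0) / cs)
    )
  })
}
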