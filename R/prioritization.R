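#' @title Rarefied allelic richness and conservation prioritisation
#' @description Allelic richness rarefied to a fixed number of gene copies,
#'   leave-one-out population contributions to the pooled richness, and
#'   exact maximum-coverage selection of populations over allele incidence.
#' @name prioritization
NULL

# expected alleles observed in g copies drawn without replacement from a
# biallelic locus with alt copies among n total: hypergeometric rarefaction
rarefy_biallelic <- function(alt, n, g) {
  2 - (exp(lchoose(n - alt, g) - lchoose(n, g)) +
         exp(lchoose(alt, g) - lchoose(n, g)))
}

pop_allele_counts <- function(ds, pops) {
  lapply(stats::setNames(unique(pops), unique(pops)), function(pop) {
    X <- ds$dosages[, pops == pop, drop = FALSE]
    alt <- rowSums(X, na.rm = TRUE)
    n <- 2 * rowSums(!is.na(X))
    cbind(alt = alt, n = n)
  })
}

#' Rarefied allelic richness per population
#'
#' The expected number of distinct alleles observed in a random subsample of
#' `g` gene copies (hypergeometric rarefaction), which makes allele counts
#' comparable across unequal sample sizes.  Loci with fewer than `g` called
#' copies in any retained population are excluded (count reported in the
#' `n_loci_excluded` attribute).
#'
#' @param ds A `genotype_dataset`.
#' @param populations Optional assignment of samples to populations
#'   (defaults to locality).
#' @param g Rarefaction size in gene copies (10 copies = 5 diploids).
#' @param min_n Populations with fewer samples are excluded.
#' @return Tibble with columns `population`, `mean_AR`, `sd_AR`, `n_loci`.
#' @export
rarefied_allelic_richness <- function(ds, populations = NULL, g = 10,
                                      min_n = 1) {
  stopifnot(g >= 2)
  pops <- resolve_populations(ds, populations)
  sizes <- table(pops)
  keep_pop <- names(sizes)[sizes >= min_n]
  pops_keep <- pops[pops %in% keep_pop]
  counts <- pop_allele_counts(subset_samples(ds, pops %in% keep_pop),
                              pops_keep)
  enough <- Reduce(`&`, lapply(counts, function(m) m[, "n"] >= g))
  if (!any(enough)) stop("no locus has at least ", g,
                         " called gene copies in every population")
  out <- purrr::map_dfr(names(counts), function(pop) {
    m <- counts[[pop]][enough, , drop = FALSE]
    ar <- rarefy_biallelic(m[, "alt"], m[, "n"], g)
    tibble::tibble(population = pop, mean_AR = mean(ar),
                   sd_AR = stats::sd(ar), n_loci = sum(enough))
  })
  attr(out, "n_loci_excluded") <- sum(!enough)
  out
}

pooled_ar <- function(ds, keep_samples, g) {
  X <- ds$dosages[, keep_samples, drop = FALSE]
  alt <- rowSums(X, na.rm = TRUE)
  n <- 2 * rowSums(!is.na(X))
  ok <- n >= g
  if (!any(ok)) return(NA_real_)
  mean(rarefy_biallelic(alt[ok], n[ok], g))
}

#' Leave-one-out contribution of each population to pooled allelic richness
#'
#' All samples are pooled into one collection and rarefied allelic richness
#' `AR(t)` computed; removing population `i` gives `AR(-i)`, and its
#' contribution is `(AR(t) - AR(-i)) / (AR(t) - 1)` - the proportional loss
#' of above-monomorphic richness were that population to go extinct.
#' Populations with divergent allele frequencies (or private alleles) raise
#' the pooled richness most and score highest; a population whose
#' composition matches the pool contributes ~0, and negative values are
#' possible.  Set `normalisation = "petit"` for the alternative
#' `(AR(t) - AR(-i)) / AR(t)` scaling.
#'
#' @inheritParams rarefied_allelic_richness
#' @param normalisation `"floor"` (default; divides by `AR(t) - 1`) or
#'   `"petit"` (divides by `AR(t)`).
#' @return An `ar_result`: list with `per_population` (tibble: `population`,
#'   `mean_AR`, `sd_AR`, `AR_minus`, `contribution`), `AR_total`, `g`.
#' @export
loo_contribution <- function(ds, populations = NULL, g = 10, min_n = 1,
                             normalisation = c("floor", "petit")) {
  normalisation <- match.arg(normalisation)
  pops <- resolve_populations(ds, populations)
  sizes <- table(pops)
  keep_pop <- names(sizes)[sizes >= min_n]
  if (length(keep_pop) < 2) stop("need at least two populations")
  in_pool <- pops %in% keep_pop
  ar_t <- pooled_ar(ds, in_pool, g)
  if (is.na(ar_t) || ar_t <= 1 + 1e-12) {
    stop("pooled allelic richness is at the monomorphic floor; ",
         "contributions are undefined")
  }
  per_pop <- rarefied_allelic_richness(ds, pops, g = g, min_n = min_n)
  denom <- if (normalisation == "floor") ar_t - 1 else ar_t
  per_pop$AR_minus <- vapply(per_pop$population, function(pop) {
    pooled_ar(ds, in_pool & pops != pop, g)
  }, numeric(1))
  per_pop$contribution <- (ar_t - per_pop$AR_minus) / denom
  structure(
    list(per_population = per_pop, AR_total = ar_t, g = g,
         normalisation = normalisation),
    class = "ar_result"
  )
}

#' @export
print.ar_result <- function(x, ...) {
  cat(sprintf("<ar_result> pooled AR(t) = %.3f at g = %d\n", x$AR_total,
              x$g))
  print(x$per_population)
  invisible(x)
}

#' @rdname loo_contribution
#' @param x An `ar_result`.
#' @param ... Unused.
#' @export
tidy.ar_result <- function(x, ...) x$per_population

#' @rdname loo_contribution
#' @export
glance.ar_result <- function(x, ...) {
  tibble::tibble(AR_total = x$AR_total, g = x$g,
                 n_populations = nrow(x$per_population),
                 normalisation = x$normalisation)
}

#' Exact maximum-coverage selection over an allele incidence matrix
#'
#' Enumerates every subset of `budget` populations and returns those
#' covering the largest number of alleles (rows with at least one `TRUE`
#' among chosen columns).  All tied optima are returned.  Beyond 20
#' populations exhaustive enumeration is replaced by greedy forward
#' selection with a message (the greedy value is a lower bound).
#'
#' @param incidence Logical matrix, alleles in rows, populations in columns.
#' @param budget Number of populations to choose.
#' @return A list with `budget`, `chosen_sets` (list of character vectors),
#'   `alleles_covered`, `total_alleles` (alleles present in any population),
#'   `proportion_of_total`.
#' @export
max_coverage_exact <- function(incidence, budget) {
  if (is.null(dim(incidence)) || nrow(incidence) == 0 ||
      ncol(incidence) == 0) {
    stop("incidence matrix is empty")
  }
  n_pop <- ncol(incidence)
  stopifnot(budget >= 1, budget <= n_pop)
  pop_names <- colnames(incidence)
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(n_pop))
  total <- sum(rowSums(incidence) > 0)
  if (n_pop <= 20) {
    sets <- utils::combn(n_pop, budget, simplify = FALSE)
    covered <- vapply(sets, function(s) {
      sum(rowSums(incidence[, s, drop = FALSE]) > 0)
    }, numeric(1))
    best <- max(covered)
    chosen <- lapply(sets[covered == best], function(s) pop_names[s])
  } else {
    message("more than 20 planning units: using greedy forward selection")
    remaining <- rep(TRUE, nrow(incidence))
    sel <- integer(0)
    for (b in seq_len(budget)) {
      gain <- vapply(seq_len(n_pop), function(j) {
        if (j %in% sel) return(-1)
        sum(incidence[remaining, j])
      }, numeric(1))
      sel <- c(sel, which.max(gain))
      remaining <- remaining & rowSums(incidence[, sel, drop = FALSE]) == 0
    }
    best <- sum(rowSums(incidence[, sel, drop = FALSE]) > 0)
    chosen <- list(pop_names[sort(sel)])
  }
  list(budget = budget, chosen_sets = chosen, alleles_covered = best,
       total_alleles = total, proportion_of_total = best / total)
}

subset_label <- function(set) paste(sort(set), collapse = "+")

#' Resampled maximum-coverage prioritisation of populations
#'
#' Repeats, `reps` times: draw `n_per_pop` individuals per population
#' without replacement; mark each of the two alleles of every locus present
#' in a population iff its observed copy count among the drawn individuals
#' is positive; solve the exact maximum-coverage problem for every budget;
#' record the optimal subsets (ties tallied fractionally so per-budget
#' tallies sum to `reps`), the covered-allele proportion of that iteration's
#' total, and the rarefied allelic richness of the union of the chosen
#' populations' drawn samples.
#'
#' @inheritParams rarefied_allelic_richness
#' @param n_per_pop Individuals drawn per population each iteration.
#' @param reps Number of resampling iterations.
#' @param budgets Budgets (numbers of populations) to solve for.
#' @param seed Optional seed.
#' @return A `prioritization` object: list with `tallies` (tibble: `budget`,
#'   `subset`, `tally`, `mean_proportion`, `mean_AR_union`), `by_budget`
#'   (tibble: `budget`, `mean_alleles_covered`, `mean_proportion`,
#'   `mean_AR_union`), plus `reps`, `budgets`, `g`, `n_per_pop`.
#' @export
prioritize_resampled <- function(ds, populations = NULL, n_per_pop = 4,
                                 reps = 100, budgets = 1:4, g = 10,
                                 seed = NULL, min_n = 1) {
  pops <- resolve_populations(ds, populations)
  sizes <- table(pops)
  keep_pop <- names(sizes)[sizes >= min_n]
  small <- keep_pop[sizes[keep_pop] < n_per_pop]
  if (length(small) > 0) {
    stop("population(s) smaller than n_per_pop: ",
         paste(small, collapse = ", "))
  }
  if (any(budgets > length(keep_pop))) {
    stop("budget exceeds the number of usable populations (",
         length(keep_pop), ")")
  }
  if (!is.null(seed)) set.seed(seed)
  pop_idx <- lapply(stats::setNames(keep_pop, keep_pop),
                    function(p) which(pops == p))
  records <- list()
  for (it in seq_len(reps)) {
    drawn <- lapply(pop_idx, function(ix) sort(sample(ix, n_per_pop)))
    counts <- lapply(drawn, function(ix) {
      X <- ds$dosages[, ix, drop = FALSE]
      alt <- rowSums(X, na.rm = TRUE)
      n <- 2 * rowSums(!is.na(X))
      cbind(alt = alt, ref = n - alt)
    })
    incidence <- do.call(cbind, lapply(counts, function(m) {
      c(m[, "alt"] > 0, m[, "ref"] > 0)
    }))
    colnames(incidence) <- keep_pop
    for (budget in budgets) {
      sol <- max_coverage_exact(incidence, budget)
      n_tie <- length(sol$chosen_sets)
      for (set in sol$chosen_sets) {
        union_idx <- unlist(drawn[set], use.names = FALSE)
        # small unions cannot supply g copies: rarefy at what they can hold
        g_union <- min(g, 2 * n_per_pop * budget)
        ar_union <- pooled_ar(ds, union_idx, g_union)
        records[[length(records) + 1]] <- tibble::tibble(
          iteration = it, budget = budget,
          subset = subset_label(set), weight = 1 / n_tie,
          alleles_covered = sol$alleles_covered,
          total_alleles = sol$total_alleles,
          proportion = sol$proportion_of_total,
          AR_union = ar_union
        )
      }
    }
  }
  rec <- dplyr::bind_rows(records)
  tallies <- rec |>
    dplyr::group_by(.data$budget, .data$subset) |>
    dplyr::summarise(
      tally = sum(.data$weight),
      mean_proportion = stats::weighted.mean(.data$proportion, .data$weight),
      mean_AR_union = stats::weighted.mean(.data$AR_union, .data$weight),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$budget, dplyr::desc(.data$tally))
  by_budget <- rec |>
    dplyr::group_by(.data$budget) |>
    dplyr::summarise(
      mean_alleles_covered = stats::weighted.mean(.data$alleles_covered,
                                                  .data$weight),
      mean_proportion = stats::weighted.mean(.data$proportion, .data$weight),
      mean_AR_union = stats::weighted.mean(.data$AR_union, .data$weight),
      .groups = "drop"
    )
  structure(
    list(tallies = tallies, by_budget = by_budget, records = rec,
         reps = reps, budgets = budgets, g = g, n_per_pop = n_per_pop),
    class = "prioritization"
  )
}

#' @export
print.prioritization <- function(x, ...) {
  cat("<prioritization>", x$reps, "iterations,", x$n_per_pop,
      "individuals/population\n")
  print(x$tallies)
  invisible(x)
}

#' Tidy prioritisation results
#'
#' @param x A `prioritization`.
#' @param ... Unused.
#' @return The per-budget subset tally tibble.
#' @export
tidy.prioritization <- function(x, ...) x$tallies

#' @rdname tidy.prioritization
#' @export
glance.prioritization <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(reps = x$reps, g = x$g,
                                  n_per_pop = x$n_per_pop),
                   tidyr::pivot_wider(
                     x$by_budget[, c("budget", "mean_proportion")],
                     names_from = "budget", values_from = "mean_proportion",
                     names_prefix = "prop_budget_"
                   ))
}

#' Plot prioritisation coverage against budget
#'
#' @param object A `prioritization`.
#' @param ... Unused.
#' @return A ggplot object: per-subset covered-allele proportion by budget,
#'   point size showing how often each subset was optimal.
#' @export
autoplot.prioritization <- function(object, ...) {
  ggplot2::ggplot(object$tallies,
                  ggplot2::aes(factor(.data$budget), .data$mean_proportion,
                               size = .data$tally,
                               label = .data$subset)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%",
                                                             100 * v)) +
    ggplot2::labs(x = "populations conserved (budget)",
                  y = "alleles retained", size = "iterations") +
    ggplot2::theme_minimal()
}
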