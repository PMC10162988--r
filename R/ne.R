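#' Pairwise linkage disequilibrium against recombination distance
#'
#' Within one population, loci are filtered to a minor-allele-frequency
#' threshold and call rate >= 0.5, and every same-scaffold locus pair with
#' recombination fraction `c = bp_distance * recomb_rate_per_bp` up to
#' `c_max` contributes one observation: the squared Pearson correlation of
#' dosages over co-called individuals, corrected for unphased finite samples
#' as `r2_adj = r2 - 1/n` with `n` the co-called individual count.
#'
#' @param ds_pop A `genotype_dataset` for a single population.
#' @param maf Minor-allele-frequency threshold.
#' @param recomb_rate_per_bp Morgans per base pair (default 1e-8 = 1 cM/Mb,
#'   a uniform map in the absence of a species-specific one).
#' @param c_max Largest recombination fraction retained.
#' @return Tibble with columns `c`, `r2`, `r2_adj`, `n_pair`.
#' @export
pairwise_ld <- function(ds_pop, maf = 0.05, recomb_rate_per_bp = 1e-8,
                        c_max = 0.25) {
  X <- ds_pop$dosages
  copies <- 2 * rowSums(!is.na(X))
  p <- rowSums(X, na.rm = TRUE) / copies
  mafs <- pmin(p, 1 - p)
  keep <- !is.na(mafs) & mafs >= maf &
    rowMeans(!is.na(X)) >= 0.5
  if (sum(keep) < 2) stop("fewer than two loci pass the MAF/call-rate filter")
  X <- X[keep, , drop = FALSE]
  info <- ds_pop$loci[keep, ]
  out <- lapply(unique(info$scaffold), function(sc) {
    rows <- which(info$scaffold == sc)
    if (length(rows) < 2) return(NULL)
    pos <- info$position[rows]
    M <- t(X[rows, , drop = FALSE])
    R <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
    called <- (!is.na(M)) * 1
    N <- crossprod(called)
    idx <- which(upper.tri(R), arr.ind = TRUE)
    cval <- abs(pos[idx[, 2]] - pos[idx[, 1]]) * recomb_rate_per_bp
    ok <- cval <= c_max & cval > 0 & !is.na(R[idx]) & N[idx] >= 2
    tibble::tibble(
      c = cval[ok],
      r2 = R[idx][ok]^2,
      n_pair = N[idx][ok]
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) stop("no locus pair within c_max on a shared scaffold")
  out$r2_adj <- out$r2 - 1 / out$n_pair
  out[, c("c", "r2", "r2_adj", "n_pair")]
}

default_ld_bins <- function(c_min = 5e-4, c_max = 0.25, n_bins = 8) {
  exp(seq(log(c_min), log(c_max), length.out = n_bins + 1))
}

#' Effective population size trajectory from binned LD
#'
#' Bins LD observations by recombination fraction and inverts the drift
#' expectation `E[r2_adj] = 1 / (alpha + 4 Ne c)` within each bin:
#' `Ne = (1 / mean_r2_adj - alpha) / (4 c_mean)`, dated to
#' `t = 1 / (2 c_mean)` generations in the past (pairs at recombination
#' fraction c reflect drift roughly that many generations ago).  Bins with
#' too few pairs are merged into their left neighbour; bins whose inverted
#' `Ne` is non-positive (mean r2 at or below `1/alpha`) are dropped with a
#' warning.
#'
#' @param pairs Tibble from [pairwise_ld()].
#' @param bins Numeric vector of bin edges on the recombination-fraction
#'   scale (default: 8 logarithmic bins over 5e-4 to 0.25).
#' @param alpha Constant absorbing sampling and mutation effects in the
#'   drift expectation; 2.2 is the usual choice for unphased data with
#'   mutation correction.
#' @param min_pairs Minimum pair count a bin must retain.
#' @param population Label stored in the result.
#' @param generation_time Years per generation used by [scale_to_years()];
#'   stored in the parameters.
#' @return An `ne_trajectory`: list with `estimates` (tibble: `c_mean`,
#'   `mean_r2_adj`, `n_pairs`, `t_generations`, `t_years`, `Ne`),
#'   `replicates` (empty here; see [bootstrap_trajectory()]) and `params`.
#' @export
estimate_trajectory <- function(pairs, bins = default_ld_bins(),
                                alpha = 2.2, min_pairs = 50,
                                population = "pop",
                                generation_time = 1.95) {
  if (nrow(pairs) == 0) stop("no LD observations supplied")
  bin_id <- cut(pairs$c, bins, labels = FALSE, include.lowest = TRUE)
  keep <- !is.na(bin_id)
  pairs <- pairs[keep, ]
  bin_id <- bin_id[keep]
  if (nrow(pairs) == 0) stop("no LD observations fall inside the bins")
  est <- pairs |>
    dplyr::mutate(bin = bin_id) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      c_mean = mean(.data$c),
      mean_r2_adj = mean(.data$r2_adj),
      n_pairs = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$c_mean)
  # merge thin bins leftwards so every retained bin meets min_pairs
  merged <- list()
  pending <- NULL
  for (i in seq_len(nrow(est))) {
    row <- est[i, ]
    if (!is.null(pending)) {
      w <- c(pending$n_pairs, row$n_pairs)
      row <- tibble::tibble(
        bin = row$bin,
        c_mean = stats::weighted.mean(c(pending$c_mean, row$c_mean), w),
        mean_r2_adj = stats::weighted.mean(
          c(pending$mean_r2_adj, row$mean_r2_adj), w),
        n_pairs = sum(w)
      )
      pending <- NULL
    }
    if (row$n_pairs < min_pairs) pending <- row else
      merged <- c(merged, list(row))
  }
  if (!is.null(pending) && length(merged) > 0) {
    last <- merged[[length(merged)]]
    w <- c(last$n_pairs, pending$n_pairs)
    merged[[length(merged)]] <- tibble::tibble(
      bin = last$bin,
      c_mean = stats::weighted.mean(c(last$c_mean, pending$c_mean), w),
      mean_r2_adj = stats::weighted.mean(
        c(last$mean_r2_adj, pending$mean_r2_adj), w),
      n_pairs = sum(w)
    )
  }
  est <- dplyr::bind_rows(merged)
  if (nrow(est) == 0) stop("no bin reaches min_pairs = ", min_pairs)
  est$Ne <- (1 / est$mean_r2_adj - alpha) / (4 * est$c_mean)
  bad <- est$Ne <= 0
  if (any(bad)) {
    warning(sum(bad), " bin(s) dropped: mean adjusted r2 at or below 1/alpha")
    est <- est[!bad, ]
  }
  if (nrow(est) == 0) stop("all bins yielded non-positive Ne")
  est$t_generations <- 1 / (2 * est$c_mean)
  est$t_years <- est$t_generations * generation_time
  est <- est[, c("c_mean", "mean_r2_adj", "n_pairs", "t_generations",
                 "t_years", "Ne")]
  structure(
    list(
      population = population, estimates = est,
      replicates = tibble::tibble(),
      params = list(alpha = alpha, min_pairs = min_pairs,
                    generation_time = generation_time, bins = bins)
    ),
    class = "ne_trajectory"
  )
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat("<ne_trajectory>", x$population, "-", nrow(x$estimates), "bins",
      if (nrow(x$replicates) > 0)
        paste0("(", length(unique(x$replicates$replicate)), " bootstrap reps)",
               collapse = ""),
      "\n")
  print(x$estimates)
  invisible(x)
}

#' Tidy an Ne trajectory
#'
#' @param x An `ne_trajectory`.
#' @param ... Unused.
#' @return The per-bin estimate tibble with a `population` column; bootstrap
#'   envelope columns (`Ne_lo`, `Ne_med`, `Ne_hi`) are joined when replicates
#'   are present.
#' @export
tidy.ne_trajectory <- function(x, ...) {
  out <- dplyr::bind_cols(tibble::tibble(population = x$population),
                          x$estimates)
  if (nrow(x$replicates) > 0) {
    env <- x$replicates |>
      dplyr::group_by(.data$t_generations) |>
      dplyr::summarise(Ne_lo = min(.data$Ne), Ne_med = stats::median(.data$Ne),
                       Ne_hi = max(.data$Ne), .groups = "drop")
    out <- dplyr::left_join(out, env, by = "t_generations")
  }
  out
}

#' Estimate an Ne trajectory for one population's dataset
#'
#' Convenience wrapper: [pairwise_ld()] then [estimate_trajectory()].
#'
#' @inheritParams pairwise_ld
#' @inheritParams estimate_trajectory
#' @export
ne_trajectory <- function(ds_pop, maf = 0.05, recomb_rate_per_bp = 1e-8,
                          c_max = 0.25, bins = default_ld_bins(),
                          alpha = 2.2, min_pairs = 50,
                          population = "pop", generation_time = 1.95) {
  pairs <- pairwise_ld(ds_pop, maf, recomb_rate_per_bp, c_max)
  estimate_trajectory(pairs, bins, alpha, min_pairs, population,
                      generation_time)
}

#' Individual-dropout bootstrap of an Ne trajectory
#'
#' Repeatedly removes a fraction of individuals (at least one) at random and
#' re-estimates the trajectory, returning the point estimate augmented with
#' all replicate trajectories; summarise the envelope with
#' [tidy.ne_trajectory()].
#'
#' @inheritParams ne_trajectory
#' @param drop_frac Fraction of individuals removed per replicate.
#' @param reps Number of replicates (reduce for very small populations).
#' @param seed Optional seed.
#' @return An `ne_trajectory` whose `replicates` tibble has one row per
#'   replicate x bin.
#' @export
bootstrap_trajectory <- function(ds_pop, drop_frac = 0.1, reps = 10,
                                 seed = NULL, maf = 0.05,
                                 recomb_rate_per_bp = 1e-8, c_max = 0.25,
                                 bins = default_ld_bins(), alpha = 2.2,
                                 min_pairs = 50, population = "pop",
                                 generation_time = 1.95) {
  n <- n_samples(ds_pop)
  n_keep <- ceiling((1 - drop_frac) * n)
  n_drop <- if (drop_frac > 0) max(1L, n - n_keep) else 0L
  if (ceiling((1 - drop_frac) * n) < 5) {
    stop("population too small: need at least ",
         ceiling(5 / (1 - drop_frac)),
         " individuals for drop_frac = ", drop_frac)
  }
  if (!is.null(seed)) set.seed(seed)
  point <- ne_trajectory(ds_pop, maf, recomb_rate_per_bp, c_max, bins,
                         alpha, min_pairs, population, generation_time)
  rep_rows <- purrr::map_dfr(seq_len(reps), function(b) {
    keep <- if (n_drop == 0) seq_len(n) else
      sort(sample.int(n, n - n_drop))
    traj <- tryCatch(
      ne_trajectory(subset_samples(ds_pop, keep), maf, recomb_rate_per_bp,
                    c_max, bins, alpha, min_pairs, population,
                    generation_time),
      error = function(e) NULL
    )
    if (is.null(traj)) return(tibble::tibble())
    dplyr::bind_cols(tibble::tibble(replicate = b), traj$estimates)
  })
  point$replicates <- rep_rows
  point$params$drop_frac <- drop_frac
  point$params$reps <- reps
  point
}

#' Rescale a trajectory's time axis
#'
#' @param traj An `ne_trajectory`.
#' @param generation_time Years per generation (must be positive).
#' @return The trajectory with `t_years` recomputed.
#' @export
scale_to_years <- function(traj, generation_time = 1.95) {
  if (!is.numeric(generation_time) || generation_time <= 0) {
    stop("generation_time must be positive")
  }
  traj$estimates$t_years <- traj$estimates$t_generations * generation_time
  if (nrow(traj$replicates) > 0) {
    traj$replicates$t_years <- traj$replicates$t_generations * generation_time
  }
  traj$params$generation_time <- generation_time
  traj
}

#' Plot effective-population-size trajectories
#'
#' @param object An `ne_trajectory` (or list of them).
#' @param max_years Restrict the view to the most recent `max_years` years
#'   (`Inf` keeps everything).
#' @param ... Unused.
#' @return A ggplot object: Ne against years before present, with a
#'   min-max bootstrap ribbon when replicates are available.
#' @export
autoplot.ne_trajectory <- function(object, max_years = Inf, ...) {
  df <- tidy(object)
  df <- df[df$t_years <= max_years, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$t_years, .data$Ne)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "years before present", y = "Ne") +
    ggplot2::theme_minimal()
  if (!is.null(df$Ne_lo)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$Ne_lo, ymax = .data$Ne_hi), alpha = 0.2
    )
  }
  p
}
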