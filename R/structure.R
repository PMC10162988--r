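#' Prevosti genetic distance between individuals
#'
#' At a biallelic locus the within-individual allele frequencies are
#' (1, 0), (1/2, 1/2) or (0, 1) for dosages 0, 1, 2, and the per-locus
#' distance is half the sum of absolute frequency differences - i.e.
#' `|x_i - x_j| / 2` in dosage form.  The overall distance is the mean over
#' co-called loci and lies between 0 and 1.
#'
#' @param ds A `genotype_dataset` with at least two samples.
#' @return A symmetric `dist_matrix` (matrix subclass) with zero diagonal;
#'   pairs with no co-called locus are `NA` with a warning.
#' @export
prevosti_distance <- function(ds) {
  if (n_samples(ds) < 2) stop("need at least two samples")
  X <- ds$dosages / 2
  A <- X; A[is.na(A)] <- 0
  C <- (!is.na(X)) * 1
  # mean |x_i - x_j| over co-called loci via E|a-b| = a + b - 2ab for the
  # homozygote part plus heterozygote corrections is messy; loop over pairs
  n <- ncol(X)
  d <- matrix(0, n, n, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(n - 1)) {
    xi <- X[, i]
    for (j in (i + 1):n) {
      cc <- !is.na(xi) & !is.na(X[, j])
      if (!any(cc)) {
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- mean(abs(xi[cc] - X[cc, j]))
      }
    }
  }
  if (anyNA(d)) warning("some sample pairs share no co-called locus")
  structure(d, class = c("dist_matrix", "matrix"))
}

#' Principal coordinates analysis of a genetic distance matrix
#'
#' Classical metric ordination (Gower): double-centre `-D^2/2`,
#' eigendecompose, scale eigenvectors by the square root of their
#' eigenvalues.  Percent variance explained is each positive eigenvalue over
#' the sum of positive eigenvalues.
#'
#' @param dist A symmetric distance matrix (e.g. from
#'   [prevosti_distance()]).
#' @param n_axes Number of axes to return.
#' @return A `pcoa_result`: list with `coordinates` (tibble: `sample_id`,
#'   `axis1`, `axis2`, ...) and `percent_variance` (numeric per axis).
#' @export
pcoa <- function(dist, n_axes = 2) {
  d <- unclass(dist)
  if (all(d == 0)) stop("distance matrix is all zero")
  if (anyNA(d)) stop("distance matrix contains undefined entries")
  fit <- stats::cmdscale(stats::as.dist(d), k = min(n_axes, nrow(d) - 1),
                         eig = TRUE)
  pos <- fit$eig[fit$eig > 1e-12]
  pct <- 100 * fit$eig[seq_len(ncol(fit$points))] / sum(pos)
  coords <- tibble::as_tibble(fit$points, .name_repair = "minimal")
  names(coords) <- paste0("axis", seq_len(ncol(coords)))
  coords <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(d)), coords
  )
  structure(list(coordinates = coords, percent_variance = pct),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("<pcoa_result>", nrow(x$coordinates), "samples;",
      paste0(sprintf("axis%d %.1f%%", seq_along(x$percent_variance),
                     x$percent_variance), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname pcoa
#' @param x A `pcoa_result`.
#' @param ... Unused.
#' @export
tidy.pcoa_result <- function(x, ...) x$coordinates

#' Plot a principal coordinates ordination
#'
#' @param object A `pcoa_result`.
#' @param colour_by Optional vector (e.g. locality per sample) used to colour
#'   points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcoa_result <- function(object, colour_by = NULL, ...) {
  df <- object$coordinates
  df$group <- if (is.null(colour_by)) "all" else as.character(colour_by)
  ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PCo 1 (%.1f%%)", object$percent_variance[1]),
      y = sprintf("PCo 2 (%.1f%%)", object$percent_variance[2]),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

# Weir-Cockerham variance components for one locus across r populations.
# n: called sample sizes, p: alt frequencies, h: observed het proportions.
# Returns c(a, b, c): among-population, among-individual, within-individual.
wc_components <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

pair_theta_components <- function(X1, X2) {
  n1 <- rowSums(!is.na(X1)); n2 <- rowSums(!is.na(X2))
  ok <- n1 >= 1 & n2 >= 1
  p1 <- rowSums(X1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(X2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(X1 == 1, na.rm = TRUE) / n1
  h2 <- rowSums(X2 == 1, na.rm = TRUE) / n2
  comp <- matrix(NA_real_, nrow(X1), 2,
                 dimnames = list(rownames(X1), c("a", "total")))
  for (l in which(ok)) {
    abc <- wc_components(c(n1[l], n2[l]), c(p1[l], p2[l]), c(h1[l], h2[l]))
    comp[l, ] <- c(abc[1], sum(abc))
  }
  comp[ok & !is.finite(comp[, 2]), ] <- NA_real_
  comp
}

#' Pairwise Weir-Cockerham F_ST with locus bootstrap
#'
#' For every pair of populations, the multi-locus theta is the ratio of sums
#' over loci of the among-population variance component to the total
#' (ratio-of-sums aggregation, unequal sample sizes, computed from genotype
#' counts including observed heterozygosity).  Significance of theta > 0 is
#' assessed by resampling loci with replacement `n_bootstrap` times and
#' reporting the fraction of replicate thetas <= 0.  Negative point
#' estimates are reported as computed.
#'
#' @param ds A `genotype_dataset`.
#' @param populations Optional sample-to-population assignment (defaults to
#'   locality).
#' @param min_n Populations with fewer samples are excluded.
#' @param n_bootstrap Locus-bootstrap replicates for p-values.
#' @param seed Optional seed for the bootstrap.
#' @return An `fst_result`: list with `theta` and `p_value` matrices and
#'   `n_bootstrap`.
#' @export
pairwise_fst <- function(ds, populations = NULL, min_n = 2,
                         n_bootstrap = 1000, seed = NULL) {
  pops <- resolve_populations(ds, populations)
  sizes <- table(pops)
  keep <- names(sizes)[sizes >= max(2, min_n)]
  if (length(keep) < 2) stop("need at least two populations with >= ",
                             max(2, min_n), " samples")
  if (!is.null(seed)) set.seed(seed)
  k <- length(keep)
  theta <- matrix(0, k, k, dimnames = list(keep, keep))
  pval <- matrix(NA_real_, k, k, dimnames = list(keep, keep))
  diag(pval) <- NA_real_
  for (i in seq_len(k - 1)) {
    Xi <- ds$dosages[, pops == keep[i], drop = FALSE]
    for (j in (i + 1):k) {
      Xj <- ds$dosages[, pops == keep[j], drop = FALSE]
      comp <- pair_theta_components(Xi, Xj)
      use <- stats::complete.cases(comp) & comp[, 2] != 0
      a <- comp[use, 1]; tot <- comp[use, 2]
      th <- sum(a) / sum(tot)
      theta[i, j] <- theta[j, i] <- th
      if (n_bootstrap > 0) {
        L <- length(a)
        reps <- vapply(seq_len(n_bootstrap), function(b) {
          idx <- sample.int(L, L, replace = TRUE)
          sum(a[idx]) / sum(tot[idx])
        }, numeric(1))
        p <- mean(reps <= 0)
        pval[i, j] <- pval[j, i] <- p
      }
    }
  }
  structure(list(theta = theta, p_value = pval, n_bootstrap = n_bootstrap),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("<fst_result>", nrow(x$theta), "populations,", x$n_bootstrap,
      "bootstraps\n")
  m <- round(x$theta, 2)
  m[upper.tri(m)] <- x$p_value[upper.tri(x$p_value)]
  print(m)
  invisible(x)
}

#' Tidy pairwise differentiation results
#'
#' @param x An `fst_result`.
#' @param ... Unused.
#' @return Tibble with one row per population pair: `pop_a`, `pop_b`,
#'   `theta`, `p_value`.
#' @export
tidy.fst_result <- function(x, ...) {
  idx <- which(upper.tri(x$theta), arr.ind = TRUE)
  tibble::tibble(
    pop_a = rownames(x$theta)[idx[, 1]],
    pop_b = colnames(x$theta)[idx[, 2]],
    theta = x$theta[idx],
    p_value = x$p_value[idx]
  )
}

#' @rdname tidy.fst_result
#' @return For `glance`: a one-row tibble with the number of populations,
#'   bootstrap count, and the range of pairwise theta.
#' @export
glance.fst_result <- function(x, ...) {
  th <- x$theta[upper.tri(x$theta)]
  tibble::tibble(n_populations = nrow(x$theta),
                 n_bootstrap = x$n_bootstrap,
                 min_theta = min(th), max_theta = max(th))
}

#' UPGMA dendrogram from a genetic distance matrix
#'
#' Average-linkage agglomerative clustering, returned as an `ape` phylo tree
#' whose leaves are sample ids; use it to confirm technical replicates pair
#' together before removal.
#'
#' @param dist A symmetric distance matrix.
#' @param file Optional path; when given the tree is also written as Newick.
#' @return An object of class `phylo`.
#' @export
upgma_dendrogram <- function(dist, file = NULL) {
  d <- unclass(dist)
  if (anyNA(d)) stop("distance matrix contains undefined entries")
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  tree <- ape::as.phylo(hc)
  if (!is.null(file)) ape::write.tree(tree, file)
  tree
}
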