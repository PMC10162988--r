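#' Construct a genotype dataset
#'
#' The central container of the package: a biallelic locus-by-sample dosage
#' matrix together with locus and sample metadata.  Dosages count copies of
#' the alternate allele (0, 1, 2); missing genotypes are `NA`.  All
#' downstream statistics are symmetric in the allele labels, so the choice of
#' counted allele is arbitrary but fixed.
#'
#' @param dosages Integer matrix, loci in rows and samples in columns, with
#'   entries in `{0, 1, 2, NA}`.
#' @param loci Data frame with one row per locus and columns `locus_id`,
#'   `scaffold`, `position` (1-based base pairs), `ref`, `alt`.
#' @param samples Data frame with one row per sample and columns `sample_id`,
#'   `locality`, and optionally `latitude`, `longitude`, `replicate_of`.
#'
#' @return An object of class `genotype_dataset`: a list with elements
#'   `dosages` (named matrix), `loci` and `samples` (tibbles).
#' @export
genotype_dataset <- function(dosages, loci, samples) {
  loci <- tibble::as_tibble(loci)
  samples <- tibble::as_tibble(samples)
  required_locus <- c("locus_id", "scaffold", "position", "ref", "alt")
  missing_cols <- setdiff(required_locus, names(loci))
  if (length(missing_cols) > 0) {
    stop("loci is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(c("sample_id", "locality") %in% names(samples))) {
    stop("samples must have columns sample_id and locality")
  }
  for (opt in c("latitude", "longitude")) {
    if (!opt %in% names(samples)) samples[[opt]] <- NA_real_
  }
  if (!"replicate_of" %in% names(samples)) samples$replicate_of <- NA_character_
  samples$replicate_of[!is.na(samples$replicate_of) &
                         samples$replicate_of == ""] <- NA_character_

  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (nrow(dosages) != nrow(loci) || ncol(dosages) != nrow(samples)) {
    stop(sprintf(
      "dosage matrix is %d x %d but there are %d loci and %d samples",
      nrow(dosages), ncol(dosages), nrow(loci), nrow(samples)
    ))
  }
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "invalid dosage %s at locus %d, sample %d (must be 0, 1, 2 or NA)",
      dosages[bad][1], idx[1], idx[2]
    ))
  }
  if (anyDuplicated(loci$locus_id)) stop("locus_id values must be unique")
  if (anyDuplicated(samples$sample_id)) stop("sample_id values must be unique")
  if (any(!is.na(loci$position) & loci$position < 1)) {
    stop("positions must be >= 1 (1-based coordinates)")
  }
  if (any(loci$ref == loci$alt)) stop("ref and alt alleles must differ")
  known <- samples$replicate_of[!is.na(samples$replicate_of)]
  unknown <- setdiff(known, samples$sample_id)
  if (length(unknown) > 0) {
    stop("replicate_of refers to unknown sample(s): ",
         paste(unknown, collapse = ", "))
  }
  dimnames(dosages) <- list(loci$locus_id, samples$sample_id)
  structure(
    list(dosages = dosages, loci = loci, samples = samples),
    class = "genotype_dataset"
  )
}

#' @export
print.genotype_dataset <- function(x, ...) {
  miss <- mean(is.na(x$dosages))
  cat(sprintf(
    "<genotype_dataset> %d loci x %d samples (%.1f%% missing)\n",
    n_loci(x), n_samples(x), 100 * miss
  ))
  tab <- table(x$samples$locality)
  cat("localities:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of loci / samples in a genotype dataset
#' @param ds A `genotype_dataset`.
#' @return Integer count.
#' @export
n_loci <- function(ds) nrow(ds$dosages)

#' @rdname n_loci
#' @export
n_samples <- function(ds) ncol(ds$dosages)

#' Subset a genotype dataset
#'
#' @param ds A `genotype_dataset`.
#' @param keep Logical, integer, or character index of loci (samples) to keep.
#' @return A new `genotype_dataset` restricted to the selection; order follows
#'   `keep`.
#' @export
subset_loci <- function(ds, keep) {
  if (is.character(keep)) keep <- match(keep, ds$loci$locus_id)
  if (is.logical(keep)) keep <- which(keep)
  genotype_dataset(ds$dosages[keep, , drop = FALSE],
                   ds$loci[keep, , drop = FALSE], ds$samples)
}

#' @rdname subset_loci
#' @export
subset_samples <- function(ds, keep) {
  if (is.character(keep)) keep <- match(keep, ds$samples$sample_id)
  if (is.logical(keep)) keep <- which(keep)
  samples <- ds$samples[keep, , drop = FALSE]
  # drop dangling replicate pointers so the invariant holds on subsets
  samples$replicate_of[!samples$replicate_of %in% samples$sample_id] <-
    NA_character_
  genotype_dataset(ds$dosages[, keep, drop = FALSE], ds$loci, samples)
}

#' Split a dataset into per-locality views
#'
#' Localities with fewer than `min_n` samples are dropped, mirroring analyses
#' restricted to localities with adequate sample sizes.  All views share the
#' full locus table.
#'
#' @param ds A `genotype_dataset`.
#' @param min_n Minimum number of samples a locality must have to be returned.
#' @return Named list of `genotype_dataset`, one per retained locality.
#' @export
split_by_locality <- function(ds, min_n = 1L) {
  stopifnot(min_n >= 1)
  tab <- table(ds$samples$locality)
  keep <- names(tab)[tab >= min_n]
  if (length(keep) == 0) {
    warning("no locality has at least ", min_n, " samples")
    return(structure(list(), names = character(0)))
  }
  out <- lapply(keep, function(loc) {
    subset_samples(ds, ds$samples$locality == loc)
  })
  names(out) <- keep
  out
}

#' Tabulate sample counts per locality
#'
#' @param ds A `genotype_dataset`.
#' @return Tibble with columns `locality` and `n`.
#' @export
locality_sizes <- function(ds) {
  dplyr::count(ds$samples, .data$locality, name = "n")
}
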