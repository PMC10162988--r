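#' Read a VCF file into a genotype dataset
#'
#' Only biallelic SNP records are retained (multiallelic and indel records are
#' dropped with a message reporting the count).  Diploid GT fields are mapped
#' to alternate-allele dosages 0/1/2; any GT containing a missing allele
#' (`./.`, `.|.`, `.`) becomes `NA`.
#'
#' @param path Path to a VCF (optionally bgzip/gzip compressed).
#' @param metadata Optional data frame of sample metadata (`sample_id`,
#'   `locality`, ...).  When absent every sample is placed in locality
#'   `"unknown"`.
#' @return A [genotype_dataset()].
#' @export
read_vcf <- function(path, metadata = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no records: ", path)
  is_snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE) & fix$ALT != "."
  n_drop <- sum(!is_snp)
  if (n_drop > 0) {
    message(n_drop, " non-biallelic-SNP record(s) dropped")
  }
  if (!any(is_snp)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  dos <- apply(gt, 2, gt_to_dosage)
  dim(dos) <- dim(gt)
  ids <- fix$ID
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix$CHROM[no_id], "_", fix$POS[no_id])
  loci <- tibble::tibble(
    locus_id = make.unique(ids),
    scaffold = fix$CHROM,
    position = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  sample_ids <- colnames(gt)
  if (is.null(metadata)) {
    samples <- tibble::tibble(sample_id = sample_ids, locality = "unknown")
  } else {
    samples <- match_metadata(sample_ids, metadata)
  }
  genotype_dataset(dos, loci, samples)
}

gt_to_dosage <- function(gt) {
  alleles <- strsplit(sub(":.*", "", gt), "[/|]")
  vapply(alleles, function(a) {
    if (length(a) == 0 || any(a == "." | a == "" | is.na(a))) {
      return(NA_integer_)
    }
    sum(as.integer(a))
  }, integer(1))
}

match_metadata <- function(sample_ids, metadata) {
  metadata <- tibble::as_tibble(metadata)
  missing <- setdiff(sample_ids, metadata$sample_id)
  if (length(missing) > 0) {
    stop("sample(s) present in genotypes but absent from metadata: ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(metadata$sample_id, sample_ids)
  if (length(extra) > 0) {
    warning(length(extra), " metadata sample(s) absent from the genotype ",
            "matrix were ignored: ", paste(extra, collapse = ", "))
  }
  metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
}

#' Write a genotype dataset to VCF
#'
#' Emits a minimal VCF v4.2 with a GT-only FORMAT so that
#' `read_vcf(write_vcf(ds))` round-trips dosages, alleles and positions.
#'
#' @param ds A `genotype_dataset`.
#' @param path Output path; a `.gz` suffix writes bgzip-compressed output.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(ds, path) {
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", n_loci(ds), n_samples(ds))
  called <- !is.na(ds$dosages)
  gt[called] <- gt_codes[as.character(ds$dosages[called])]
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ds$samples$sample_id), collapse = "\t")
  )
  body <- paste(
    ds$loci$scaffold, ds$loci$position, ds$loci$locus_id,
    ds$loci$ref, ds$loci$alt, ".", "PASS", ".", "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a delimited genotype table plus sample metadata
#'
#' The genotype table holds columns `locus_id`, `scaffold`, `position`,
#' `ref`, `alt` followed by one dosage column per sample (codes 0/1/2, empty
#' or NA for missing).  Metadata holds `sample_id`, `locality` and optionally
#' `latitude`, `longitude`, `replicate_of`.  Samples listed in the metadata
#' but absent from the matrix are ignored with a warning; the reverse is an
#' error.  Delimiter is inferred from the file extension (`.csv` vs
#' `.tsv`/`.txt`).
#'
#' @param path Genotype table path.
#' @param metadata_path Metadata table path.
#' @return A [genotype_dataset()].
#' @export
read_genotype_table <- function(path, metadata_path) {
  geno <- read_delim_auto(path)
  meta <- read_delim_auto(metadata_path)
  fixed <- c("locus_id", "scaffold", "position", "ref", "alt")
  missing_cols <- setdiff(fixed, names(geno))
  if (length(missing_cols) > 0) {
    stop("genotype table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  sample_cols <- setdiff(names(geno), fixed)
  if (length(sample_cols) == 0) stop("genotype table has no sample columns")
  dos <- as.matrix(geno[, sample_cols, drop = FALSE])
  suppressWarnings(storage.mode(dos) <- "integer")
  raw <- as.matrix(geno[, sample_cols, drop = FALSE])
  bad <- is.na(dos) & !is.na(raw) & raw != "" & toupper(raw) != "NA"
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("unparseable dosage '%s' at locus %s, sample %s",
                 raw[bad][1], geno$locus_id[idx[1]], sample_cols[idx[2]]))
  }
  samples <- match_metadata(sample_cols, meta)
  genotype_dataset(dos, geno[, fixed], samples)
}

read_delim_auto <- function(path) {
  if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}

#' Write a genotype dataset as delimited tables
#'
#' Inverse of [read_genotype_table()]; writes the genotype matrix and the
#' sample metadata as two TSV (or CSV) files.
#'
#' @param ds A `genotype_dataset`.
#' @param path,metadata_path Output paths (extension selects the delimiter).
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(ds, path, metadata_path) {
  geno <- dplyr::bind_cols(
    ds$loci[, c("locus_id", "scaffold", "position", "ref", "alt")],
    tibble::as_tibble(ds$dosages)
  )
  write_delim_auto(geno, path)
  write_delim_auto(ds$samples, metadata_path)
  invisible(path)
}

write_delim_auto <- function(x, path) {
  if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) {
    readr::write_csv(x, path, progress = FALSE)
  } else {
    readr::write_tsv(x, path, progress = FALSE)
  }
}
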