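#' Pipeline configuration
#'
#' Collects every stage threshold with conventional ddRAD-conservation
#' defaults, plus a master seed from which per-stage seeds are derived
#' deterministically (`stage_seed = master_seed * 131 + stage_index`,
#' kept within 32-bit integer range), so each stage is independently
#' reproducible.
#'
#' @param min_prop,min_mac,max_ho,kin_threshold,max_corr,window_bp,max_miss
#'   QC thresholds (see [qc_cascade()]).
#' @param min_locality_n Minimum samples a locality needs to enter
#'   per-population analyses (ordination and the dendrogram always use all
#'   surviving samples).
#' @param g Rarefaction size in gene copies.
#' @param n_bootstrap Locus bootstraps for pairwise differentiation.
#' @param reps,n_per_pop,budgets Resampled prioritisation settings.
#' @param maf,recomb_rate_per_bp,c_max,alpha,ld_min_pairs LD-Ne settings.
#' @param generation_time Years per generation for the Ne time axis.
#' @param ne_drop_frac,ne_reps Individual-dropout bootstrap settings.
#' @param run_ne Estimate Ne trajectories (the slowest stage; disable for a
#'   quick pass).
#' @param callable_sites Optional callable-site total for autosomal
#'   heterozygosity (skipped when `NULL`).
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_prop = 0.90, min_mac = 3, max_ho = 0.6,
                            kin_threshold = 0.25, max_corr = 0.5,
                            window_bp = 100000, max_miss = 0.25,
                            min_locality_n = 5, g = 10, n_bootstrap = 1000,
                            reps = 100, n_per_pop = 4, budgets = 1:4,
                            maf = 0.05, recomb_rate_per_bp = 1e-8,
                            c_max = 0.25, alpha = 2.2, ld_min_pairs = 50,
                            generation_time = 1.95, ne_drop_frac = 0.1,
                            ne_reps = 10, run_ne = TRUE,
                            callable_sites = NULL, seed = 1L) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File whose top-level keys override [pipeline_config()]
#'   defaults.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, raw)
}

stage_seed <- function(config, index) {
  as.integer((as.numeric(config$seed) * 131 + index) %% .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Executes quality control, per-population diversity, structure
#' (ordination, dendrogram, pairwise differentiation), LD-based Ne
#' trajectories and allele-based prioritisation on a genotype dataset, and
#' optionally writes every result table as TSV into `output_dir`.
#' Ordination and the dendrogram use all samples surviving QC; diversity,
#' differentiation, Ne and prioritisation use only localities with at least
#' `min_locality_n` samples.
#'
#' @param ds A `genotype_dataset` (e.g. from [read_vcf()],
#'   [read_genotype_table()] or the simulator).
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for TSV reports (created if absent).
#' @return A list of stage results: `qc` (dataset + report), `diversity`,
#'   `autosomal` (or `NULL`), `pcoa`, `dendrogram`, `fst`, `ne` (list per
#'   population, or `NULL`), `ar`, `prioritization`, and `log` (tibble of
#'   stage timings, seeds, and parameters).
#' @export
run_pipeline <- function(ds, config = pipeline_config(),
                         output_dir = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"),
            inherits(config, "pipeline_config"))
  log_rows <- list()
  note <- function(stage, detail) {
    log_rows[[length(log_rows) + 1]] <<- tibble::tibble(
      stage = stage, detail = detail
    )
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  qc <- run_stage("qc", qc_cascade(
    ds, config$min_prop, config$min_mac, config$max_ho,
    config$kin_threshold, config$max_corr, config$window_bp, config$max_miss
  ))
  filtered <- qc$dataset
  note("qc", sprintf("%d loci x %d samples retained", n_loci(filtered),
                     n_samples(filtered)))

  pop_views <- split_by_locality(filtered, config$min_locality_n)
  analysed <- filtered$samples$locality %in% names(pop_views)
  pop_ds <- subset_samples(filtered, analysed)
  note("populations", paste(names(pop_views), collapse = ", "))

  diversity <- run_stage("diversity", per_population_diversity(pop_ds))
  autosomal <- NULL
  if (!is.null(config$callable_sites)) {
    autosomal <- run_stage("diversity", autosomal_heterozygosity(
      pop_ds, callable_sites = config$callable_sites
    ))
  }

  dist_all <- run_stage("structure", prevosti_distance(filtered))
  ordination <- run_stage("structure", pcoa(dist_all))
  dendro <- run_stage("structure", upgma_dendrogram(dist_all))
  set.seed(stage_seed(config, 3L))
  fst <- run_stage("structure", pairwise_fst(
    pop_ds, min_n = config$min_locality_n, n_bootstrap = config$n_bootstrap
  ))
  note("structure", sprintf("axis1 %.1f%%, axis2 %.1f%%",
                            ordination$percent_variance[1],
                            ordination$percent_variance[2]))

  ne <- NULL
  if (isTRUE(config$run_ne)) {
    ne <- lapply(names(pop_views), function(pop) {
      run_stage("ne", bootstrap_trajectory(
        pop_views[[pop]], drop_frac = config$ne_drop_frac,
        reps = config$ne_reps, seed = stage_seed(config, 4L),
        maf = config$maf, recomb_rate_per_bp = config$recomb_rate_per_bp,
        c_max = config$c_max, alpha = config$alpha,
        min_pairs = config$ld_min_pairs, population = pop,
        generation_time = config$generation_time
      ))
    })
    names(ne) <- names(pop_views)
    note("ne", paste(names(pop_views), collapse = ", "))
  }

  ar <- run_stage("prioritization", loo_contribution(pop_ds, g = config$g))
  prior <- run_stage("prioritization", prioritize_resampled(
    pop_ds, n_per_pop = config$n_per_pop, reps = config$reps,
    budgets = config$budgets, g = config$g, seed = stage_seed(config, 5L)
  ))
  note("prioritization",
       sprintf("AR(t) = %.3f; best budget-1 subset %s", ar$AR_total,
               prior$tallies$subset[prior$tallies$budget ==
                                      min(config$budgets)][1]))

  result <- list(
    qc = qc, diversity = diversity, autosomal = autosomal,
    pcoa = ordination, dendrogram = dendro, fst = fst, ne = ne, ar = ar,
    prioritization = prior, log = dplyr::bind_rows(log_rows),
    config = config
  )
  if (!is.null(output_dir)) write_pipeline_reports(result, output_dir)
  result
}

write_pipeline_reports <- function(result, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(x, name) {
    readr::write_tsv(x, file.path(output_dir, name), progress = FALSE)
  }
  rep_tbl <- result$qc$report
  rep_tbl$removed_ids <- vapply(rep_tbl$removed_ids, paste,
                                character(1), collapse = ",")
  out(rep_tbl, "filter_report.tsv")
  out(result$diversity, "diversity.tsv")
  if (!is.null(result$autosomal)) out(result$autosomal, "autosomal.tsv")
  out(tidy(result$pcoa), "pcoa_coordinates.tsv")
  out(tibble::tibble(axis = seq_along(result$pcoa$percent_variance),
                     percent_variance = result$pcoa$percent_variance),
      "pcoa_variance.tsv")
  ape::write.tree(result$dendrogram, file.path(output_dir, "dendrogram.nwk"))
  out(tidy(result$fst), "fst.tsv")
  if (!is.null(result$ne)) {
    out(dplyr::bind_rows(lapply(result$ne, tidy)), "ne_trajectories.tsv")
  }
  out(tidy(result$ar), "ar_contributions.tsv")
  out(tidy(result$prioritization), "prioritization.tsv")
  out(result$log, "run_log.tsv")
  invisible(output_dir)
}

#' Compare package results against a deposited filtered genotype matrix
#'
#' Given a directory containing the published filtered genotype matrix and
#' sample metadata of a range-wide study (downloaded separately; this
#' package ships no third-party data), recomputes the headline statistics -
#' realised missingness, per-population diversity, pairwise differentiation,
#' ordination variance, rarefied allelic richness with leave-one-out
#' contributions, and resampled maximum-coverage prioritisation - and
#' returns them for comparison with the published tables.
#'
#' @param genotype_path Filtered genotype table (see
#'   [read_genotype_table()]) or VCF.
#' @param metadata_path Sample metadata table.
#' @param config A [pipeline_config()]; QC is assumed already applied to a
#'   deposited *filtered* matrix, so only the analysis stages run.
#' @return List with `missingness`, `diversity`, `fst`, `pcoa_variance`,
#'   `ar`, `prioritization`.
#' @export
validate_published_genotypes <- function(genotype_path, metadata_path,
                                         config = pipeline_config()) {
  ds <- if (grepl("\\.vcf(\\.gz)?$", genotype_path)) {
    read_vcf(genotype_path,
             readr::read_tsv(metadata_path, show_col_types = FALSE))
  } else {
    read_genotype_table(genotype_path, metadata_path)
  }
  pop_views <- split_by_locality(ds, config$min_locality_n)
  pop_ds <- subset_samples(ds, ds$samples$locality %in% names(pop_views))
  set.seed(stage_seed(config, 3L))
  list(
    missingness = mean(is.na(ds$dosages)),
    diversity = per_population_diversity(pop_ds),
    fst = pairwise_fst(pop_ds, min_n = config$min_locality_n,
                       n_bootstrap = config$n_bootstrap),
    pcoa_variance = pcoa(prevosti_distance(ds))$percent_variance,
    ar = loo_contribution(pop_ds, g = config$g),
    prioritization = prioritize_resampled(
      pop_ds, n_per_pop = config$n_per_pop, reps = config$reps,
      budgets = config$budgets, g = config$g,
      seed = stage_seed(config, 5L)
    )
  )
}
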