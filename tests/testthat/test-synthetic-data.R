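test_that("simulator is deterministic and honours the requested design", {
  cfg <- sim_config(n_loci = 400, seed = 99)
  a <- simulate_hierarchical_dataset(cfg)
  b <- simulate_hierarchical_dataset(cfg)
  expect_identical(a$dataset$dosages, b$dataset$dosages)
  expect_identical(a$truth$locality_freq, b$truth$locality_freq)

  sizes <- locality_sizes(a$dataset)
  base <- cfg$localities$n_samples
  names(base) <- cfg$localities$locality
  # one relative offspring goes to the largest locality, replicates to the
  # two largest
  expect_equal(sizes$n[sizes$locality == "weipa"], base[["weipa"]])
  expect_equal(sum(sizes$n),
               sum(base) + cfg$n_relative_pairs + cfg$n_replicate_pairs)
  expect_equal(nrow(a$truth$relative_pairs), 1)
  expect_equal(nrow(a$truth$replicate_pairs), 2)
  # uniform scaffold spacing supports window arithmetic
  expect_true(all(diff(a$dataset$loci$position[1:50]) ==
                    cfg$scaffold_spacing))
})

test_that("realised locality allele frequencies track simulated truth", {
  cfg <- flat_config(3000, c("a", "b"), 30, f = 0.15, seed = 31)
  sim <- simulate_hierarchical_dataset(cfg)
  fr <- allele_frequencies(sim$dataset)
  for (i in 1:2) {
    pop <- c("a", "b")[i]
    realised <- fr$p_alt[fr$population == pop]
    expect_gt(stats::cor(realised, sim$truth$locality_freq[, i]), 0.95)
  }
})

test_that("differentiation of simulated localities matches the drift model", {
  # no-differentiation limit
  for (s in 1:3) {
    sim <- simulate_hierarchical_dataset(
      flat_config(5000, c("a", "b"), 30, f = 1e-12, seed = s)
    )
    th <- pairwise_fst(sim$dataset, n_bootstrap = 0)$theta["a", "b"]
    expect_gt(th, -0.01)
    expect_lt(th, 0.01)
  }
  # Balding-Nichols expectation: theta ~ F (module-level spot check; the
  # 20-seed version runs in the acceptance suite)
  for (s in 1:5) {
    sim <- simulate_hierarchical_dataset(
      flat_config(5000, c("a", "b"), 30, f = 0.2, seed = 100 + s)
    )
    th <- pairwise_fst(sim$dataset, n_bootstrap = 0)$theta["a", "b"]
    expect_gt(th, 0.15)
    expect_lt(th, 0.25)
  }
})

test_that("missingness injection hits the requested rate", {
  cfg <- flat_config(4764, c("a", "b"), 24, f = 0.05, seed = 8)
  ds <- simulate_hierarchical_dataset(cfg)$dataset
  expect_identical(add_missingness(ds, 0)$dosages, ds$dosages)
  withmiss <- add_missingness(ds, 0.025, seed = 4)
  frac <- mean(is.na(withmiss$dosages))
  expect_gt(frac, 0.020)
  expect_lt(frac, 0.030)
  # extreme missingness leaves no sample below the missingness cap
  drowned <- add_missingness(ds, 0.9, seed = 4)
  expect_error(filter_sample_missingness(drowned, 0.25), "all samples")
})

test_that("injected relatives are Mendelian and recoverable by kinship", {
  # homozygous parents give deterministic offspring
  dos <- cbind(p1 = c(0L, 2L, 0L, NA), p2 = c(0L, 2L, 2L, 0L))
  ds <- make_ds(dos)
  truth <- structure(list(relative_pairs = tibble::tibble()),
                     class = "sim_truth")
  res <- inject_relatives(ds, truth,
                          tibble::tibble(parent_a = "p1", parent_b = "p2",
                                         locality = "popA"))
  off <- res$dataset$dosages[, 3]
  expect_equal(unname(off[1:2]), c(0L, 2L))  # AA x AA -> AA
  expect_equal(unname(off[3]), 1L)           # AA x BB -> AB
  expect_true(is.na(off[4]))                 # missing parent propagates

  expect_error(
    inject_relatives(ds, truth,
                     tibble::tibble(parent_a = "p1", parent_b = "p2",
                                    locality = "elsewhere")),
    "not in locality"
  )

  # parent-offspring kinship ~0.25 on an unrelated background
  betas <- vapply(1:5, function(s) {
    sim <- simulate_hierarchical_dataset(
      flat_config(2000, "a", 20, seed = 300 + s)
    )
    res <- inject_relatives(
      sim$dataset, sim$truth,
      tibble::tibble(parent_a = "a_01", parent_b = "a_02", locality = "a")
    )
    unclass(kinship_matrix(res$dataset))["a_01", "a_off01"]
  }, numeric(1))
  expect_true(all(betas > 0.20 & betas < 0.30))
})

test_that("technical replicates show duplicate-grade kinship", {
  sim <- simulate_hierarchical_dataset(flat_config(2000, "a", 20, seed = 17))
  res <- inject_replicates(sim$dataset, NULL, "a_05")
  k <- unclass(kinship_matrix(res$dataset))
  expect_gt(k["a_05", "a_05_rep"], 0.45)
  expect_lt(k["a_05", "a_05_rep"], 0.55)
})

test_that("Wright-Fisher simulator is reproducible and drifts into LD", {
  a <- simulate_wright_fisher_ld(Ne = 30, n_generations = 20,
                                 n_chromosomes = 2, sample_n = 20,
                                 n_loci_per_chrom = 30, seed = 3)
  b <- simulate_wright_fisher_ld(Ne = 30, n_generations = 20,
                                 n_chromosomes = 2, sample_n = 20,
                                 n_loci_per_chrom = 30, seed = 3)
  expect_identical(a$dosages, b$dosages)
  expect_error(simulate_wright_fisher_ld(Ne = 10, n_generations = 5,
                                         sample_n = 11),
               "cannot exceed")

  # without recombination drift leaves segregating loci in strong mutual LD
  frozen <- simulate_wright_fisher_ld(Ne = 40, n_generations = 80,
                                      chrom_length = 1e6, recomb_rate = 0,
                                      n_chromosomes = 1, sample_n = 40,
                                      n_loci_per_chrom = 40, seed = 9)
  X <- t(frozen$dosages)
  seg <- apply(X, 2, stats::var) > 0
  R2 <- suppressWarnings(stats::cor(X[, seg]))^2
  expect_gte(stats::median(R2[upper.tri(R2)], na.rm = TRUE), 0.8)
})
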