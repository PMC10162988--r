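test_that("locus call-rate filter removes loci strictly below threshold", {
  dos <- rbind(
    c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L, 0L),   # fully called
    c(NA, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L, 0L),   # 9/10 -> kept at >= 0.9
    c(NA, NA, 2L, 0L, 1L, 2L, 0L, 1L, 2L, 0L)    # 8/10 -> removed
  )
  res <- filter_locus_callrate(make_ds(dos), 0.90)
  expect_equal(n_loci(res$dataset), 2)
  expect_equal(res$report$removed_ids[[1]], "loc0003")
  full <- make_ds(dos[1, , drop = FALSE])
  expect_equal(n_loci(filter_locus_callrate(full)$dataset), 1)
})

test_that("minor allele count filter uses copy counts over called genotypes", {
  dos <- rbind(
    c(0L, 0L, 0L, 1L, 1L, 1L),  # minor = 3 -> kept
    c(0L, 0L, 0L, 0L, 0L, 2L),  # minor = 2 -> removed
    c(0L, 0L, 0L, 0L, 0L, 0L)   # monomorphic -> removed
  )
  res <- filter_mac(make_ds(dos), 3)
  expect_equal(n_loci(res$dataset), 1)
  expect_setequal(res$report$removed_ids[[1]], c("loc0002", "loc0003"))
})

test_that("excess-heterozygosity filter is strict at the boundary", {
  het7 <- c(rep(1L, 7), rep(0L, 3))   # H_O = 0.7 -> removed
  het6 <- c(rep(1L, 6), rep(0L, 4))   # H_O = 0.6 -> kept
  hom <- rep(c(0L, 2L), 5)            # H_O = 0  -> kept
  res <- filter_excess_het(make_ds(rbind(het7, het6, hom)), 0.6)
  expect_equal(n_loci(res$dataset), 2)
})

test_that("sample-missingness filter is strict at the boundary", {
  dos <- matrix(0:2, nrow = 20, ncol = 3)
  dos[1:6, 1] <- NA   # 30% missing -> removed
  dos[1:5, 2] <- NA   # exactly 25% -> retained
  res <- filter_sample_missingness(make_ds(dos), 0.25)
  expect_equal(n_samples(res$dataset), 2)
  expect_equal(res$report$removed_ids[[1]], "ind01")
})

test_that("allele-matching kinship has its documented fixed points", {
  # identical all-homozygous samples force beta = 1 whatever the background
  set.seed(1)
  bg <- matrix(sample(0:2, 40 * 6, TRUE), nrow = 40)
  twin <- sample(c(0L, 2L), 40, TRUE)
  k <- unclass(kinship_matrix(make_ds(cbind(twin, twin, bg))))
  expect_equal(k[1, 2], 1)

  # exchangeable panmictic samples centre the mean off-diagonal at zero
  sim <- simulate_hierarchical_dataset(flat_config(2000, "a", 25, seed = 21))
  k <- unclass(kinship_matrix(sim$dataset))
  expect_lt(abs(mean(k[upper.tri(k)])), 0.01)
})

test_that("relative removal drops the more-missing member and resolves triangles", {
  sim <- simulate_hierarchical_dataset(flat_config(800, "a", 12, seed = 77))
  ds <- sim$dataset
  # duplicate a sample, then punch extra missingness into the copy
  dup <- ds$dosages[, "a_03"]
  dup[1:60] <- NA
  ds2 <- make_ds(unname(cbind(ds$dosages, dup)),
                 positions = ds$loci$position,
                 localities = c(ds$samples$locality, "a"))
  res <- remove_related(ds2, threshold = 0.25)
  expect_equal(res$report$removed_ids[[1]], "ind13")  # the missing-heavy copy
  expect_equal(n_samples(res$dataset), 12)

  # nothing removed when all pairs are unrelated
  res0 <- remove_related(ds, threshold = 0.25)
  expect_length(res0$report$removed_ids[[1]], 0)

  # a triangle of three mutual duplicates loses two members (tie broken
  # towards later sample order)
  tri <- ds$dosages[, "a_05"]
  ds3 <- make_ds(unname(cbind(ds$dosages, tri, tri)),
                 positions = ds$loci$position,
                 localities = c(ds$samples$locality, "a", "a"))
  res3 <- remove_related(ds3, threshold = 0.25)
  expect_setequal(res3$report$removed_ids[[1]], c("ind13", "ind14"))
  expect_true("ind05" %in% res3$dataset$samples$sample_id)
})

test_that("LD pruning sweeps genomic order and keeps the earlier locus", {
  # perfect duplicates 10 kb apart: later removed; 200 kb apart: both kept
  v <- c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L, 2L, 1L, 0L)
  near <- make_ds(rbind(v, v), positions = c(1L, 10001L))
  expect_equal(ld_prune(near)$dataset$loci$locus_id, "loc0001")
  far <- make_ds(rbind(v, v), positions = c(1L, 200001L))
  expect_equal(n_loci(ld_prune(far)$dataset), 2)

  # chain A~B, B~C strong, A~C at the boundary: B removed, C survives
  A <- c(2L,0L,2L,1L,2L,0L,2L,2L,2L,0L,1L,2L,0L,0L)
  B <- c(2L,0L,2L,2L,2L,0L,2L,2L,0L,0L,1L,2L,0L,0L)
  C <- c(2L,0L,0L,2L,2L,0L,0L,2L,0L,1L,1L,2L,0L,0L)
  stopifnot(cor(A, B) > 0.5, cor(B, C) > 0.5, abs(cor(A, C)) <= 0.5)
  chain <- make_ds(rbind(A, B, C), positions = c(1L, 50001L, 100001L))
  pruned <- ld_prune(chain, max_corr = 0.5, window_bp = 100000)
  expect_equal(pruned$dataset$loci$locus_id, c("A", "C"))

  # post-scan invariant: no surviving pair within the window above threshold
  sim <- simulate_hierarchical_dataset(sim_config(n_loci = 600, seed = 12))
  out <- ld_prune(sim$dataset)$dataset
  for (sc in unique(out$loci$scaffold)) {
    rows <- which(out$loci$scaffold == sc)
    pos <- out$loci$position[rows]
    for (a in seq_along(rows)) {
      b <- a + 1
      while (b <= length(rows) && pos[b] - pos[a] <= 100000) {
        r <- suppressWarnings(cor(out$dosages[rows[a], ],
                                  out$dosages[rows[b], ],
                                  use = "pairwise.complete.obs"))
        if (!is.na(r)) expect_lte(abs(r), 0.5)
        b <- b + 1
      }
    }
  }
})

test_that("replicate concordance identifies partners as nearest neighbours", {
  sim <- simulate_hierarchical_dataset(
    sim_config(n_loci = 600, n_relative_pairs = 0, n_replicate_pairs = 0,
               missing_rate = 0, seed = 41)
  )
  ds <- sim$dataset
  # identical copy: concordance exactly 1
  res <- inject_replicates(ds, NULL, "darwin_01", error_rate = 0)
  tab <- replicate_concordance(res$dataset)
  expect_equal(tab$concordance, 1)
  expect_true(tab$pass)

  # 5% genotyping error still pairs with the source in a structured dataset
  set.seed(6)
  res2 <- inject_replicates(ds, NULL, "melville_02", error_rate = 0.05)
  tab2 <- replicate_concordance(res2$dataset)
  expect_true(tab2$pass)
  expect_gt(tab2$concordance, 0.9)

  # replicate_of pointing nowhere is rejected by the container itself
  expect_error(
    make_ds(matrix(0:2, 3, 2), replicate_of = c(NA, "ghost")),
    "unknown sample"
  )
  expect_error(replicate_concordance(ds), "no replicate pairs")
})

test_that("the full cascade is monotone, consistent and idempotent", {
  cfg <- study_config(seed = 5, n_loci = 1500)
  cfg$n_relative_pairs <- 0L
  sim <- simulate_hierarchical_dataset(cfg)
  # plant a duplicate-grade related pair as ordinary samples
  set.seed(1)
  res <- inject_replicates(sim$dataset, NULL, "darwin_01",
                           error_rate = 0.02)
  ds <- res$dataset
  ds$samples$replicate_of[ds$samples$sample_id == "darwin_01_rep"] <-
    NA_character_
  qc <- qc_cascade(ds)
  kin_removed <- unlist(
    qc$report$removed_ids[qc$report$filter == "kinship_removal"])
  expect_length(kin_removed, 1)
  expect_true(kin_removed %in% c("darwin_01", "darwin_01_rep"))
  rep <- qc$report
  expect_true(all(rep$n_loci_after <= rep$n_loci_before))
  expect_true(all(rep$n_samples_after <= rep$n_samples_before))
  # removed id counts match the count deltas
  expect_equal(lengths(rep$removed_ids),
               (rep$n_loci_before - rep$n_loci_after) +
                 (rep$n_samples_before - rep$n_samples_after))
  # chaining: each stage starts where the previous ended
  expect_equal(rep$n_loci_before[-1], rep$n_loci_after[-nrow(rep)])

  again <- qc_cascade(qc$dataset)
  expect_identical(again$dataset$dosages, qc$dataset$dosages)
  expect_true(all(lengths(again$report$removed_ids) == 0))
})
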