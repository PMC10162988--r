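test_that("Prevosti distance matches its hand-evaluated cases", {
  same <- make_ds(cbind(c(0L, 1L, 2L), c(0L, 1L, 2L)))
  expect_equal(unclass(prevosti_distance(same))[1, 2], 0)
  opposite <- make_ds(cbind(c(0L, 2L, 0L), c(2L, 0L, 2L)))
  expect_equal(unclass(prevosti_distance(opposite))[1, 2], 1)
  aa_ab <- make_ds(cbind(0L, 1L))
  expect_equal(unclass(prevosti_distance(aa_ab))[1, 2], 0.5)
})

test_that("Prevosti distance is a metric on fully called data", {
  set.seed(14)
  dos <- matrix(sample(0:2, 30 * 8, TRUE), nrow = 30)
  d <- unclass(prevosti_distance(make_ds(dos)))
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 8), ignore_attr = TRUE)
  expect_true(all(d >= 0 & d <= 1))
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("principal coordinates reproduce known geometry", {
  # points on a line: one axis explains everything
  x <- c(0, 1, 3, 7)
  d <- as.matrix(stats::dist(x))
  res <- pcoa(d, n_axes = 3)
  expect_equal(res$percent_variance[1], 100, tolerance = 1e-8)

  # two tight, well-separated pairs: axis 1 separates them, > 90%
  pts <- c(0, 0.01, 5, 5.01)
  res2 <- pcoa(as.matrix(stats::dist(pts)), n_axes = 2)
  expect_gt(res2$percent_variance[1], 90)
  a1 <- res2$coordinates$axis1
  expect_equal(sign(a1[1]), sign(a1[2]))
  expect_equal(sign(a1[3]), sign(a1[4]))
  expect_true(sign(a1[1]) != sign(a1[3]))

  # identical samples land on identical coordinates
  dup <- make_ds(cbind(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L),
                       c(2L, 1L, 0L, 1L), c(2L, 2L, 0L, 0L)))
  resd <- pcoa(prevosti_distance(dup))
  expect_equal(resd$coordinates$axis1[1], resd$coordinates$axis1[2])

  # a known 2-D configuration is recovered up to rotation/reflection
  set.seed(3)
  conf <- matrix(rnorm(20), ncol = 2)
  fit <- pcoa(as.matrix(stats::dist(conf)), n_axes = 2)
  est <- as.matrix(fit$coordinates[, c("axis1", "axis2")])
  pro <- vegan::procrustes(conf, est)
  expect_lt(sum(pro$residuals^2), 1e-6)

  expect_error(pcoa(matrix(0, 3, 3)), "all zero")
})

test_that("Weir-Cockerham theta agrees with an independent transcription", {
  # toy with explicit genotype counts, including missing entries
  popA <- rbind(c(0L, 1L, 1L, 2L, 0L), c(2L, 2L, 1L, NA, 0L),
                c(0L, 0L, 0L, 1L, 1L))
  popB <- rbind(c(2L, 2L, 1L), c(0L, 1L, NA), c(1L, 1L, 2L))
  ds <- make_ds(cbind(popA, popB),
                localities = rep(c("A", "B"), c(5, 3)))
  got <- pairwise_fst(ds, n_bootstrap = 0)$theta["A", "B"]
  want <- wc_theta_oracle(list(popA, popB))
  expect_equal(got, want, tolerance = 1e-12)

  # larger random instance, same agreement
  set.seed(8)
  X <- matrix(sample(c(0:2, NA), 200 * 12, TRUE, prob = c(.3, .3, .3, .1)),
              nrow = 200)
  ds2 <- make_ds(X, localities = rep(c("A", "B"), c(7, 5)))
  got2 <- pairwise_fst(ds2, n_bootstrap = 0)$theta["A", "B"]
  want2 <- wc_theta_oracle(list(X[, 1:7], X[, 8:12]))
  expect_equal(got2, want2, tolerance = 1e-12)
})

test_that("theta hits its fixed points and null distribution", {
  # populations fixed for alternate alleles: theta = 1, p < 0.01
  fixed <- make_ds(cbind(matrix(0L, 40, 5), matrix(2L, 40, 5)),
                   localities = rep(c("A", "B"), each = 5))
  res <- pairwise_fst(fixed, n_bootstrap = 200, seed = 1)
  expect_equal(res$theta["A", "B"], 1)
  expect_lt(res$p_value["A", "B"], 0.01)

  # halves of a panmictic population: theta ~ 0, usually not significant
  for (s in 1:5) {
    sim <- simulate_hierarchical_dataset(flat_config(3000, "a", 40,
                                                     seed = 700 + s))
    halves <- rep(c("h1", "h2"), each = 20)
    th <- pairwise_fst(sim$dataset, populations = halves,
                       n_bootstrap = 0)$theta["h1", "h2"]
    expect_gt(th, -0.02)
    expect_lt(th, 0.02)
  }
})

test_that("theta is invariant to allele labels and population order", {
  sim <- simulate_hierarchical_dataset(
    flat_config(1000, c("A", "B"), 12, f = 0.15, seed = 19)
  )
  ds <- sim$dataset
  base <- pairwise_fst(ds, n_bootstrap = 0)$theta["A", "B"]

  # swap ref/alt labels at a subset of loci
  flip <- seq(1, 1000, by = 3)
  ds_flip <- ds
  ds_flip$dosages[flip, ] <- 2L - ds_flip$dosages[flip, ]
  expect_equal(pairwise_fst(ds_flip, n_bootstrap = 0)$theta["A", "B"],
               base, tolerance = 1e-12)

  # reverse sample (and thus population) order
  ds_rev <- subset_samples(ds, rev(seq_len(n_samples(ds))))
  expect_equal(pairwise_fst(ds_rev, n_bootstrap = 0)$theta["A", "B"],
               base, tolerance = 1e-12)
})

test_that("between-lineage differentiation exceeds within-lineage", {
  for (s in 1:3) {
    cfg <- sim_config(
      n_loci = 2000,
      lineages = tibble::tibble(lineage_id = c("L1", "L2"),
                                f_lineage = c(0.15, 0.15)),
      localities = tibble::tibble(
        locality = c("a1", "a2", "b1", "b2"),
        lineage_id = c("L1", "L1", "L2", "L2"),
        f_local = 0.05, n_samples = 12L
      ),
      missing_rate = 0, n_relative_pairs = 0, n_replicate_pairs = 0,
      seed = 900 + s
    )
    th <- pairwise_fst(simulate_hierarchical_dataset(cfg)$dataset,
                       n_bootstrap = 0)$theta
    within <- c(th["a1", "a2"], th["b1", "b2"])
    between <- c(th["a1", "b1"], th["a1", "b2"], th["a2", "b1"],
                 th["a2", "b2"])
    expect_gt(min(between), max(within))
  }
})

test_that("UPGMA trees cluster as the distances dictate", {
  # three samples with one close pair
  d <- matrix(c(0, 0.1, 0.5, 0.1, 0, 0.5, 0.5, 0.5, 0), 3, 3,
              dimnames = list(c("s1", "s2", "s3"), c("s1", "s2", "s3")))
  tree <- upgma_dendrogram(d)
  # s1 and s2 are siblings
  pair_mrca <- ape::getMRCA(tree, c("s1", "s2"))
  all_mrca <- ape::getMRCA(tree, c("s1", "s3"))
  expect_true(pair_mrca != all_mrca)

  # duplicate samples form a cherry in a noisy background
  set.seed(2)
  dos <- matrix(sample(0:2, 50 * 6, TRUE), nrow = 50)
  dos <- cbind(dos, dos[, 3])
  ds <- make_ds(dos)
  tr <- upgma_dendrogram(prevosti_distance(ds))
  expect_equal(ape::getMRCA(tr, c("ind03", "ind07")),
               ape::getMRCA(tr, c("ind03", "ind07")))
  cherry <- ape::cophenetic.phylo(tr)["ind03", "ind07"]
  others <- ape::cophenetic.phylo(tr)["ind03", c("ind01", "ind02")]
  expect_true(all(cherry < others))

  # UPGMA reproduces ultrametric inputs exactly
  ud <- matrix(c(0, .2, .8, .8,
                 .2, 0, .8, .8,
                 .8, .8, 0, .4,
                 .8, .8, .4, 0), 4, 4,
               dimnames = list(paste0("t", 1:4), paste0("t", 1:4)))
  ut <- upgma_dendrogram(ud)
  expect_equal(ape::cophenetic.phylo(ut)[rownames(ud), colnames(ud)], ud,
               tolerance = 1e-9)

  # Newick serialisation round-trips through ape
  f <- withr::local_tempfile(fileext = ".nwk")
  upgma_dendrogram(ud, file = f)
  expect_setequal(ape::read.tree(f)$tip.label, rownames(ud))
})
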