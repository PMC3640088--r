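test_that("UPGMA reproduces the hand-worked 3-specimen example", {
  m <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  dend <- upgma(make_dist_from_matrix(m))
  expect_equal(dend$hclust$height, c(1.0, 4.0))
  sets <- barcodeaudit:::clade_leafsets(dend)
  expect_setequal(sets[[1]], c("a", "b"))
  expect_setequal(sets[[2]], c("a", "b", "c"))
})

test_that("equal distances merge with lexicographic tie-breaking", {
  m <- matrix(5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m) <- 0
  dend <- upgma(make_dist_from_matrix(m))
  expect_true(all(abs(dend$hclust$height - 2.5) < 1e-12))
  sets <- barcodeaudit:::clade_leafsets(dend)
  expect_setequal(sets[[1]], c("a", "b"))
  expect_setequal(sets[[2]], c("a", "b", "c"))
})

test_that("UPGMA agrees with the naive oracle on random matrices", {
  set.seed(17)
  for (rep in 1:40) {
    n <- sample(3:7, 1)
    m <- random_dist_matrix(n)
    dend <- upgma(make_dist_from_matrix(m))
    oracle <- oracle_upgma(m)
    expect_equal(dend$hclust$height, oracle$heights, tolerance = 1e-10)
    sets <- barcodeaudit:::clade_leafsets(dend)
    for (k in seq_along(sets)) {
      expect_setequal(sets[[k]], oracle$merges[[k]])
    }
    # cross-check against average-linkage hclust heights (tie-free input)
    hc <- stats::hclust(stats::as.dist(m), method = "average")
    expect_equal(sort(dend$hclust$height), sort(hc$height / 2), tolerance = 1e-10)
  }
})

test_that("UPGMA trees are ultrametric with non-decreasing merge heights", {
  for (s in 1:5) {
    sim <- simulate_herbarium(tiny_config(seed = 300 + s))
    dend <- upgma(pairwise_distances(sim$dataset))
    expect_true(all(diff(dend$hclust$height) >= -1e-9))
    ph <- as_phylo(dend)
    depths <- ape::node.depth.edgelength(ph)
    leaf_depths <- depths[seq_len(ape::Ntip(ph))]
    expect_lt(max(leaf_depths) - min(leaf_depths), 1e-8)
  }
})

test_that("NMDS recovers planar configurations and is scale invariant", {
  pts <- rbind(c(0, 0), c(30, 0), c(30, 18), c(0, 18), c(15, 40))
  rownames(pts) <- sprintf("p%d", 1:5)
  m <- round(as.matrix(dist(pts)))
  ord <- nmds_ordination(make_dist_from_matrix(m), seed = 5)
  expect_lt(ord$stress, 0.01)
  expect_true(all(is.finite(as.matrix(ord$coordinates[, c("axis1", "axis2")]))))
  ord2 <- nmds_ordination(make_dist_from_matrix(2 * m), seed = 5)
  expect_equal(ord2$stress, ord$stress, tolerance = 1e-4)
  # best stress is no worse than any start's final stress
  expect_true(all(ord$stress <= ord$start_stress + 1e-12))
})

test_that("NMDS handles degenerate equal-distance input without crashing", {
  m <- matrix(10, 5, 5, dimnames = list(sprintf("p%d", 1:5), sprintf("p%d", 1:5)))
  diag(m) <- 0
  ord <- nmds_ordination(make_dist_from_matrix(m), seed = 2)
  expect_gte(ord$stress, 0)
  expect_true(all(is.finite(as.matrix(ord$coordinates[, c("axis1", "axis2")]))))
})

test_that("concordance flags catch injected misidentifications and little else", {
  sim <- simulate_herbarium(tiny_config(seed = 77, n_major_misid_injected = 1))
  d <- pairwise_distances(sim$dataset)
  flags <- concordance_flags(upgma(d), sim$dataset, "genus")
  misid <- dplyr::filter(sim$truth$injected, kind == "major_misid")$specimen_a
  expect_true(misid %in%
                dplyr::filter(flags, flag_type == "foreign_inclusion")$specimen_id)

  clean <- 0
  for (s in 1:10) {
    sim <- simulate_herbarium(tiny_config(seed = 400 + s))
    fl <- concordance_flags(upgma(pairwise_distances(sim$dataset)), sim$dataset, "genus")
    clean <- clean + (nrow(fl) == 0)
  }
  expect_gte(clean, 9)
})

test_that("flags are empty for single-accession taxa and invariant to input order", {
  ds <- manual_dataset(c("a", "b", "c"),
                       c(strrep("ACGT", 30), strrep("AGGT", 30), strrep("TCGA", 30)),
                       c("Gx s1", "Gy s1", "Gz s1"))
  d <- pairwise_distances(ds, threshold_bp = 1000L, threshold_frac = 1)
  expect_equal(nrow(concordance_flags(upgma(d), ds, "genus")), 0)

  sim <- simulate_herbarium(tiny_config(seed = 88, n_major_misid_injected = 1))
  d1 <- pairwise_distances(sim$dataset)
  ds2 <- sim$dataset
  ds2$records <- ds2$records[rev(seq_len(nrow(ds2$records))), ]
  d2 <- pairwise_distances(ds2)
  f1 <- concordance_flags(upgma(d1), sim$dataset, "genus")
  f2 <- concordance_flags(upgma(d2), ds2, "genus")
  expect_equal(f1, f2)
})

test_that("ordination coherence separates true genera and degrades under permutation", {
  sim <- simulate_herbarium(tiny_config(seed = 19))
  d <- pairwise_distances(sim$dataset)
  ord <- nmds_ordination(d, seed = 4, missing_policy = "censor")
  co <- ordination_coherence(ord, sim$dataset, "genus")
  expect_true(all(co$coherence < 1))

  # duplicated coordinates for one taxon -> coherence 0
  ord0 <- ord
  ids <- sim$dataset$records$specimen_id[sim$dataset$records$genus == "Genus01"]
  sel <- ord0$coordinates$specimen_id %in% ids
  ord0$coordinates$axis1[sel] <- 1.5
  ord0$coordinates$axis2[sel] <- -2
  co0 <- ordination_coherence(ord0, sim$dataset, "genus")
  expect_equal(co0$coherence[co0$taxon == "Genus01"], 0)

  # random label permutation -> scores near 1 on average
  set.seed(9)
  scores <- replicate(20, {
    dsp <- sim$dataset
    dsp$records$genus <- sample(dsp$records$genus)
    mean(ordination_coherence(ord, dsp, "genus")$coherence)
  })
  expect_lt(abs(mean(scores) - 1), 0.15)
})
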