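test_that("divergence profile assigns every retained pair to one bin and curve", {
  ds <- manual_dataset(c("a", "b", "c"), rep("ACGTACGTAC", 3), rep("Gx s1", 3))
  p <- divergence_profile(pairwise_distances(ds))
  expect_equal(p$intra_count[p$bp_diff == 0], 3L)
  expect_true(all(p$inter_count == 0))

  seq2 <- paste0(strrep("A", 100), strrep("C", 10))
  seq2b <- paste0(strrep("A", 100), strrep("G", 10))
  ds2 <- manual_dataset(c("a", "b"), c(seq2, seq2b), c("Gx s1", "Gx s2"))
  p2 <- divergence_profile(pairwise_distances(ds2))
  expect_equal(p2$inter_count[p2$bp_diff == 10], 1L)
  expect_equal(sum(p2$intra_count), 0L)

  d <- pairwise_distances(simulate_herbarium(tiny_config(seed = 31))$dataset)
  prof <- divergence_profile(d)
  expect_equal(sum(prof$intra_count) + sum(prof$inter_count), nrow(d$entries))
  # brute-force recomputation of both curves
  e <- d$entries
  expect_equal(sum(prof$intra_count * prof$bp_diff), sum(e$bp_diff[e$same_species]))
  expect_equal(sum(prof$inter_count * prof$bp_diff), sum(e$bp_diff[!e$same_species]))
})

test_that("false negatives are unique species pairs with zero-distance witnesses", {
  # no zero cross-species distances -> empty
  ds0 <- manual_dataset(c("a", "b"), c("AAAAAAAAAA", "CCCCCCCCCC"),
                        c("Gx s1", "Gx s2"))
  expect_equal(nrow(find_false_negatives(pairwise_distances(ds0))), 0)

  # injected false negative recovered exactly
  sim <- simulate_herbarium(tiny_config(seed = 23, n_false_neg_injected = 1))
  d <- pairwise_distances(sim$dataset)
  fn <- find_false_negatives(d)
  inj <- dplyr::filter(sim$truth$injected, kind == "false_neg")
  recs <- sim$dataset$records
  sp <- setNames(recs$species, recs$specimen_id)
  want <- sort(c(sp[[inj$specimen_a]], sp[[inj$specimen_b]]))
  expect_true(any(fn$species_a == want[1] & fn$species_b == want[2]))
  expect_equal(fn$severity[fn$species_a == want[1] & fn$species_b == want[2]],
               "congeneric")

  # one sequence shared by 3 species -> all 3 choose 2 pairs reported
  ds3 <- manual_dataset(c("a", "b", "c"), rep("ACGTACGTAC", 3),
                        c("Gx s1", "Gx s2", "Gx s3"))
  fn3 <- find_false_negatives(pairwise_distances(ds3))
  expect_equal(nrow(fn3), 3)
})

test_that("false negative detection is invariant under specimen relabeling", {
  sim <- simulate_herbarium(tiny_config(seed = 23, n_false_neg_injected = 2))
  d1 <- pairwise_distances(sim$dataset)
  ds2 <- sim$dataset
  perm <- sample(nrow(ds2$records))
  ds2$records <- ds2$records[perm, ]
  d2 <- pairwise_distances(ds2)
  f1 <- find_false_negatives(d1)[, c("species_a", "species_b", "severity")]
  f2 <- find_false_negatives(d2)[, c("species_a", "species_b", "severity")]
  expect_equal(f1, f2)
})

test_that("false positives respect the cutoff and non-retained pairs", {
  ds <- manual_dataset(c("a", "b"), rep("ACGTACGTAC", 2), rep("Gx s1", 2))
  expect_equal(nrow(find_false_positives(pairwise_distances(ds), 0)), 0)

  set.seed(3)
  base <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  ch <- strsplit(base, "")[[1]]
  pos <- sample(200, 18)
  ch[pos] <- vapply(ch[pos], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  ds2 <- manual_dataset(c("a", "b"), c(base, paste(ch, collapse = "")),
                        rep("Gx s1", 2))
  d2 <- pairwise_distances(ds2)   # 18 bp apart, within the 20 bp cap
  expect_equal(nrow(find_false_positives(d2, 14)), 1)
  expect_equal(nrow(find_false_positives(d2, 40)), 0)
  # a within-species pair beyond the retention cap exceeds every cutoff
  ch2 <- strsplit(base, "")[[1]]
  pos2 <- sample(200, 40)
  ch2[pos2] <- vapply(ch2[pos2], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  ds3 <- manual_dataset(c("a", "b"), c(base, paste(ch2, collapse = "")),
                        rep("Gx s1", 2))
  d3 <- pairwise_distances(ds3)
  fp3 <- find_false_positives(d3, 60)
  expect_equal(nrow(fp3), 1)
  expect_true(fp3$has_nonretained_pair)

  # injected false positive flagged at a 2%-of-length cutoff
  sim <- simulate_herbarium(tiny_config(seed = 41, n_false_pos_injected = 1))
  d <- pairwise_distances(sim$dataset)
  cutoff <- round(0.02 * mean(d$specimens$seq_length))
  fp <- find_false_positives(d, cutoff)
  inj <- dplyr::filter(sim$truth$injected, kind == "false_pos")
  sp <- setNames(sim$dataset$records$species, sim$dataset$records$specimen_id)
  expect_true(sp[[inj$specimen_a]] %in% fp$species)
})

test_that("severity ladder follows shared taxonomic rank", {
  taxo <- tibble::tibble(
    genus = c("Russula", "Leucoagaricus", "Endoptychum", "Boletus", "Inocybe"),
    family = c("Russulaceae", "Agaricaceae", "Agaricaceae", "Boletaceae", "Inocybaceae"),
    order = c("Russulales", "Agaricales", "Agaricales", "Boletales", "Agaricales"))
  expect_equal(classify_severity("Russula a", "Russula b", taxo), "congeneric")
  expect_equal(classify_severity("Leucoagaricus x", "Endoptychum y", taxo), "confamilial")
  expect_equal(classify_severity("Inocybe x", "Endoptychum y", taxo), "moderate")
  expect_equal(classify_severity("Boletus x", "Inocybe y", taxo), "major")
  expect_equal(classify_severity("Boletus x", "Unknownus y", taxo), "unknown")
})

test_that("threshold sweep counts are monotone and match a brute-force scan", {
  sim <- simulate_herbarium(tiny_config(seed = 51))
  d <- pairwise_distances(sim$dataset)
  cutoffs <- c(0, 7, 14, 35, 70)
  sw <- threshold_sweep(d, cutoffs)
  expect_true(all(diff(sw$lumping) >= 0))
  expect_true(all(diff(sw$splitting) <= 0))
  # independent pair scan
  e <- d$entries
  n_nonret_within <- nrow(d$not_retained_within_species)
  for (i in seq_along(cutoffs)) {
    expect_equal(sw$lumping[i], sum(!e$same_species & e$bp_diff <= cutoffs[i]))
    expect_equal(sw$splitting[i],
                 sum(e$same_species & e$bp_diff > cutoffs[i]) + n_nonret_within)
  }
  # boundary cases
  expect_equal(sw$splitting[cutoffs == 70], n_nonret_within)
  expect_error(threshold_sweep(d, c(10, 5)), "ascending")
})

test_that("clean synthetic data yields no barcode errors at a 2% cutoff", {
  hits_fn <- 0; hits_fp <- 0
  for (s in 1:10) {
    sim <- simulate_herbarium(tiny_config(seed = 100 + s))
    d <- pairwise_distances(sim$dataset)
    cutoff <- round(0.02 * mean(d$specimens$seq_length))
    hits_fn <- hits_fn + (nrow(find_false_negatives(d)) == 0)
    hits_fp <- hits_fp + (nrow(find_false_positives(d, cutoff)) == 0)
  }
  expect_gte(hits_fn, 9)
  expect_gte(hits_fp, 9)
})

test_that("error report collects near misses with severity", {
  base <- strrep("ACGT", 30)
  one_off <- sub("^A", "C", base)
  ds <- manual_dataset(c("a", "b"), c(base, one_off), c("Gx s1", "Gy s1"),
                       family = c("Fam1", "Fam1"))
  rep <- error_report(pairwise_distances(ds))
  expect_equal(nrow(rep$near_misses), 1)
  expect_equal(rep$near_misses$bp_diff, 1L)
  expect_equal(rep$near_misses$severity, "confamilial")
  collapsed <- error_report(pairwise_distances(ds), collapse_near_misses = TRUE)
  expect_equal(collapsed$near_misses$n_specimen_pairs, 1L)
})
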