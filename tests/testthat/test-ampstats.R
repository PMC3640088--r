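test_that("contingency tables tally records and partition across strata", {
  recs <- tibble::tibble(
    specimen_id = sprintf("v%d", 1:4),
    genus = "Gx",
    collection_year = c(1985L, 1985L, 2003L, 2003L),
    pcr_positive = c(TRUE, FALSE, TRUE, TRUE))
  tab <- build_contingency(recs, "decade", "pcr_positive")
  expect_equal(unclass(tab)[, ],
               matrix(c(1L, 2L, 1L, 0L), 2,
                      dimnames = list(c("1980", "2000"), c("positive", "negative")))[, ])

  expect_error(build_contingency(dplyr::filter(recs, collection_year < 1990),
                                 "decade", "pcr_positive"),
               "at least 2 non-empty rows")

  recs2 <- tibble::tibble(
    specimen_id = sprintf("v%d", 1:60), genus = rep(c("Ga", "Gb"), 30),
    collection_year = rep(c(1984L, 1995L, 2004L), 20),
    pcr_positive = rep(c(TRUE, FALSE), 30))
  strata <- list("1980s-1990s" = c(1980, 1999), "2000s" = c(2000, 2009))
  tabs <- build_contingency(recs2, "genus", "pcr_positive", strata = strata)
  expect_equal(sum(purrr::map_dbl(tabs, sum)),
               sum(build_contingency(recs2, "genus", "pcr_positive")))
})

test_that("chi-square post-hoc matches closed forms", {
  indep <- chi_square_posthoc(matrix(c(10, 10, 10, 10), 2))
  expect_equal(indep$chi2, 0)
  expect_equal(indep$p_value, 1)
  expect_true(all(abs(indep$adjusted_residuals) < 1e-12))

  res <- chi_square_posthoc(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
  expect_equal(res$chi2, 20)
  expect_equal(res$df, 1)
  expect_equal(abs(res$adjusted_residuals), matrix(sqrt(20), 2, 2), ignore_attr = TRUE)
  # 2x2 identity: omnibus chi2 equals any squared adjusted residual
  expect_equal(res$adjusted_residuals[1, 1]^2, res$chi2)
  expect_equal(sum(res$cell_contribution), 1, tolerance = 1e-12)
  expect_true(all(abs(rowSums(res$observed - res$expected)) < 1e-9))
})

test_that("Bonferroni correction divides alpha by the cell count", {
  tab <- matrix(c(40, 20, 35, 25, 10, 45), 3, 2, byrow = TRUE,
                dimnames = list(c("1980", "1990", "2000"), c("positive", "negative")))
  res <- chi_square_posthoc(tab, alpha = 0.05)
  expect_equal(res$n_contrasts, 6)
  expect_equal(res$alpha_corrected, 0.05 / 6)
  expect_equal(round(res$alpha_corrected, 3), 0.008)
  expect_equal(sum(res$cell_contribution), 1, tolerance = 1e-12)
  td <- tidy(res)
  expect_equal(nrow(td), 6)
  expect_equal(sum(td$cell_contribution), 1, tolerance = 1e-12)
})

test_that("omnibus type-I error is close to nominal under the null", {
  set.seed(2024)
  nrep <- 2000
  rejections <- 0
  for (r in seq_len(nrep)) {
    k <- rbinom(3, size = 60, prob = 0.5)
    tab <- cbind(positive = k, negative = 60 - k)
    res <- chi_square_posthoc(tab)
    rejections <- rejections + (res$p_value < 0.05)
  }
  rate <- rejections / nrep
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("chi-square p-value agrees with a Monte-Carlo permutation p-value", {
  tab <- matrix(c(110, 90, 90, 110), 2, byrow = TRUE)
  res <- chi_square_posthoc(tab)
  set.seed(7)
  nrep <- 4000
  stat <- function(m) {
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  sims <- r2dtable(nrep, rowSums(tab), colSums(tab))
  mc_p <- mean(vapply(sims, stat, numeric(1)) >= res$chi2 - 1e-9)
  se <- sqrt(mc_p * (1 - mc_p) / nrep)
  expect_lt(abs(mc_p - res$p_value), 3 * se + 0.005)
})

test_that("detected age effect matches the simulated direction", {
  cfg <- generator_config(n_genera = 4, species_per_genus = 4,
                          accessions_per_species = 12, seed = 33,
                          success_model = list(intercept = 1.5, per_decade = -1.2,
                                               genus_offsets = NULL))
  sim <- simulate_herbarium(cfg)
  tab <- build_contingency(sim$dataset$records, "decade", "pcr_positive")
  res <- chi_square_posthoc(tab)
  adj <- res$adjusted_residuals
  oldest <- 1; newest <- nrow(adj)
  expect_lt(adj[oldest, "positive"], 0)
  expect_gt(adj[newest, "positive"], 0)
  expect_true(res$significant[oldest, "positive"])
})

test_that("stratified report marks significance at raw and corrected alpha", {
  cfg <- generator_config(n_genera = 6, species_per_genus = 4,
                          accessions_per_species = 10, seed = 44,
                          success_model = list(
                            intercept = 1.0, per_decade = -0.4,
                            genus_offsets = list(Genus01 = -2)))
  sim <- simulate_herbarium(cfg)
  rep <- stratified_report(sim$dataset$records)
  expect_s3_class(rep$summary, "tbl_df")
  expect_setequal(unique(rep$summary$stratum), c("1980s-1990s", "2000s"))
  g1 <- dplyr::filter(rep$summary, genus == "Genus01")
  expect_true(all(g1$adjusted_residual < 0))
  expect_true(any(g1$significant_raw))
  # corrected flags are a subset of raw flags
  expect_true(all(rep$summary$significant_raw | !rep$summary$significant_bonferroni))
})

test_that("genus-level type-I rate under a null generator is near alpha", {
  set.seed(1)
  sig <- c(); total <- 0
  for (s in 1:8) {
    cfg <- generator_config(n_genera = 5, species_per_genus = 4,
                            accessions_per_species = 8, seed = 500 + s,
                            success_model = list(intercept = 0.4, per_decade = 0,
                                                 genus_offsets = NULL))
    sim <- simulate_herbarium(cfg)
    tab <- build_contingency(sim$dataset$records, "genus", "pcr_positive")
    res <- chi_square_posthoc(tab)
    crit <- qnorm(1 - 0.05 / 2)
    sig <- c(sig, abs(res$adjusted_residuals[, "positive"]) > crit)
  }
  rate <- mean(sig)
  se <- sqrt(0.05 * 0.95 / length(sig))
  expect_lt(abs(rate - 0.05), 3 * se + 0.02)
})
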