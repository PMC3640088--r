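#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Assemble a run configuration
#'
#' A run is fully determined by its inputs plus this configuration; it is
#' serialised alongside the outputs.
#'
#' @param fasta,metadata,taxonomy Input paths (ignored when `simulate` is
#'   given).
#' @param simulate Optional [generator_config()]: generate inputs instead
#'   of reading them.
#' @param out_dir Output directory.
#' @param threshold_bp,threshold_frac Distance retention parameters.
#' @param sweep_cutoffs Cutoff grid for [threshold_sweep()].
#' @param fp_cutoff_bp Cutoff for [find_false_positives()].
#' @param nmds_starts NMDS random starts.
#' @param alpha Significance level for contingency analyses.
#' @param seed Run seed; all stage seeds derive from it.
#' @return An `audit_config` list.
#' @export
audit_config <- function(fasta = NULL, metadata = NULL, taxonomy = NULL,
                         simulate = NULL, out_dir = "audit_run",
                         threshold_bp = 70L, threshold_frac = 0.10,
                         sweep_cutoffs = c(0, 7, 14, 35, 70),
                         fp_cutoff_bp = 14L, nmds_starts = 8, alpha = 0.05,
                         seed = 1L) {
  structure(list(fasta = fasta, metadata = metadata, taxonomy = taxonomy,
                 simulate = simulate, out_dir = out_dir,
                 threshold_bp = threshold_bp, threshold_frac = threshold_frac,
                 sweep_cutoffs = sweep_cutoffs, fp_cutoff_bp = fp_cutoff_bp,
                 nmds_starts = nmds_starts, alpha = alpha, seed = seed),
            class = "audit_config")
}

#' Run the full barcode audit pipeline
#'
#' Orchestrates ingest, pairwise distances, barcode-gap and error
#' analysis, mini-barcode evaluation, UPGMA/NMDS concordance and (when
#' collection years and PCR outcomes are present) contingency analysis of
#' amplification success. All artifacts are written as plain text into
#' `config$out_dir`; a stage failure aborts with the stage name.
#'
#' @param config An [audit_config()].
#' @return The run summary (also written as `summary.json`), invisibly.
#' @export
run_audit <- function(config) {
  stopifnot(inherits(config, "audit_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  out <- function(...) file.path(config$out_dir, ...)

  dataset <- stage("ingest", {
    if (!is.null(config$simulate)) {
      sim <- simulate_herbarium(config$simulate)
      write_simulated_inputs(sim, out("inputs"))
      sim$dataset
    } else {
      seqs <- read_barcode_fasta(config$fasta)
      meta <- read_specimen_metadata(config$metadata)
      taxo <- if (!is.null(config$taxonomy)) read_taxonomy(config$taxonomy) else NULL
      audit_dataset(seqs, meta, taxo)
    }
  })
  stage("feature_table", write_feature_table(dataset, out("feature_table.txt")))

  dmat <- stage("distances", pairwise_distances(dataset, config$threshold_bp,
                                                config$threshold_frac))
  write_distances(dmat, out("distances.tsv"))

  profile <- stage("gap", divergence_profile(dmat))
  readr::write_tsv(tibble::as_tibble(profile), out("divergence_profile.tsv"),
                   progress = FALSE)
  errors <- stage("gap", error_report(dmat, fp_cutoff_bp = config$fp_cutoff_bp))
  readr::write_tsv(errors$false_negatives, out("false_negatives.tsv"), progress = FALSE)
  readr::write_tsv(errors$false_positives, out("false_positives.tsv"), progress = FALSE)
  readr::write_tsv(errors$near_misses, out("near_misses.tsv"), progress = FALSE)
  sweep <- stage("gap", threshold_sweep(dmat, config$sweep_cutoffs))
  readr::write_tsv(tibble::as_tibble(sweep), out("threshold_sweep.tsv"), progress = FALSE)

  mini <- stage("minibarcode", minibarcode_report(dataset))
  jsonlite::write_json(mini[!vapply(mini, is.list, logical(1))],
                       out("minibarcode_report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  dend <- stage("concordance", upgma(dmat))
  write_newick(dend, out("upgma.nwk"))
  flags <- stage("concordance", dplyr::bind_rows(
    concordance_flags(dend, dataset, "genus"),
    if (!all(is.na(dataset$records$family))) concordance_flags(dend, dataset, "family")
  ))
  readr::write_tsv(flags, out("concordance_flags.tsv"), progress = FALSE)
  ord <- stage("concordance", nmds_ordination(dmat, n_starts = config$nmds_starts,
                                              seed = derive_seed(config$seed, 11)))
  readr::write_tsv(dplyr::mutate(ord$coordinates, stress = ord$stress),
                   out("nmds_coordinates.tsv"), progress = FALSE)

  stats_done <- FALSE
  recs <- dataset$records
  if (any(!is.na(recs$collection_year)) && any(!is.na(recs$pcr_positive)) &&
      dplyr::n_distinct(decade_of(recs$collection_year), na.rm = TRUE) >= 2) {
    decade_tab <- stage("pcrstats", build_contingency(recs, "decade", "pcr_positive"))
    decade_res <- stage("pcrstats", chi_square_posthoc(decade_tab, config$alpha))
    readr::write_tsv(tidy(decade_res), out("pcr_by_decade_posthoc.tsv"), progress = FALSE)
    stats_done <- TRUE
  }

  summary <- list(
    n_specimens = nrow(recs),
    n_sequenced = sum(!is.na(recs$sequence)),
    n_unique_taxa = dplyr::n_distinct(recs$species),
    n_genera = dplyr::n_distinct(recs$genus),
    n_pairs_retained = nrow(dmat$entries),
    n_pairs_not_retained = dmat$n_not_retained,
    n_false_negative_species_pairs = nrow(errors$false_negatives),
    n_false_positive_species = nrow(errors$false_positives),
    n_flags = nrow(flags),
    flags_by_type = as.list(table(flags$flag_type)),
    false_negatives_by_severity = as.list(table(errors$false_negatives$severity)),
    nmds_stress = ord$stress,
    pcr_stats_computed = stats_done,
    config = config[setdiff(names(config), "simulate")],
    seed = config$seed
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(summary)
}
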