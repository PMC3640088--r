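#' Within- versus among-species divergence profile
#'
#' Bins every retained pair by its bp difference and by whether the two
#' specimens share a morphological species, producing the two curves of a
#' barcode-gap plot.
#'
#' @param matrix A `barcode_dist` from [pairwise_distances()].
#' @return A `divergence_profile` tibble with columns `bp_diff`,
#'   `intra_count`, `inter_count`.
#' @export
divergence_profile <- function(matrix) {
  e <- matrix$entries
  if (nrow(e) == 0) stop("distance matrix has no retained pairs", call. = FALSE)
  bins <- 0:max(e$bp_diff)
  out <- tibble::tibble(
    bp_diff = bins,
    intra_count = as.integer(tabulate(e$bp_diff[e$same_species] + 1L, length(bins))),
    inter_count = as.integer(tabulate(e$bp_diff[!e$same_species] + 1L, length(bins)))
  )
  class(out) <- c("divergence_profile", class(out))
  out
}

#' @export
#' @rdname divergence_profile
#' @param object A `divergence_profile`.
#' @param ... Unused.
autoplot.divergence_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"bp_diff",
                              names_to = "class", values_to = "count")
  long$class <- ifelse(long$class == "intra_count", "within species", "among species")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bp_diff, y = .data$count,
                                     colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "nucleotide divergence (bp)", y = "pairs",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Detect false-negative barcode errors
#'
#' A false negative is a pair of distinct morphological species connected
#' by at least one retained specimen pair with identical sequences
#' (bp difference 0 under the ambiguity-tolerant alignment; set
#' `exact = TRUE` to require exact string identity). Results are
#' deduplicated to unique unordered species pairs and annotated with a
#' taxonomic severity class.
#'
#' @param matrix A `barcode_dist`.
#' @param exact Require byte-identical sequences instead of bp_diff == 0.
#' @param dataset Required when `exact = TRUE`: the originating
#'   [audit_dataset()] holding the sequences.
#' @return Tibble with columns `species_a`, `species_b`, `witness_a`,
#'   `witness_b`, `n_specimen_pairs`, `severity`.
#' @export
find_false_negatives <- function(matrix, exact = FALSE, dataset = NULL) {
  e <- dplyr::filter(matrix$entries, .data$bp_diff == 0, !.data$same_species)
  if (exact) {
    if (is.null(dataset)) stop("exact = TRUE requires the dataset", call. = FALSE)
    seqs <- stats::setNames(dataset$records$sequence, dataset$records$specimen_id)
    e <- dplyr::filter(e, seqs[.data$id_a] == seqs[.data$id_b])
  }
  sp <- stats::setNames(matrix$specimens$species, matrix$specimens$specimen_id)
  if (nrow(e) == 0) {
    return(tibble::tibble(species_a = character(), species_b = character(),
                          witness_a = character(), witness_b = character(),
                          n_specimen_pairs = integer(), severity = character()))
  }
  e |>
    dplyr::mutate(
      sp_a = pmin(sp[.data$id_a], sp[.data$id_b]),
      sp_b = pmax(sp[.data$id_a], sp[.data$id_b])
    ) |>
    dplyr::group_by(.data$sp_a, .data$sp_b) |>
    dplyr::summarise(witness_a = .data$id_a[1], witness_b = .data$id_b[1],
                     n_specimen_pairs = dplyr::n(), .groups = "drop") |>
    dplyr::rename(species_a = "sp_a", species_b = "sp_b") |>
    dplyr::mutate(severity = classify_severity(.data$species_a, .data$species_b,
                                               specimen_taxonomy(matrix))) |>
    dplyr::arrange(.data$species_a, .data$species_b)
}

specimen_taxonomy <- function(matrix) {
  dplyr::distinct(matrix$specimens[, c("species", "genus", "family", "order")])
}

#' Detect false-positive barcode errors
#'
#' A false positive is a morphological species whose collections carry
#' more than one barcode sequence: with two or more accessions, the
#' maximum within-species bp difference exceeds `cutoff_bp`. Within-species
#' pairs that fell outside the retention cap count as exceeding any cutoff.
#'
#' @param matrix A `barcode_dist`.
#' @param cutoff_bp Non-negative divergence cutoff in bp (0 flags any
#'   non-identical pair).
#' @return Tibble with columns `species`, `max_intra_bp`, `witness_a`,
#'   `witness_b`, `has_nonretained_pair`.
#' @export
find_false_positives <- function(matrix, cutoff_bp = 0L) {
  stopifnot(cutoff_bp >= 0)
  sp <- stats::setNames(matrix$specimens$species, matrix$specimens$specimen_id)
  intra_entries <- dplyr::filter(matrix$entries, .data$same_species)
  intra <- if (nrow(intra_entries) == 0) {
    tibble::tibble(species = character(), max_intra_bp = integer(),
                   witness_a = character(), witness_b = character())
  } else {
    intra_entries |>
      dplyr::mutate(species = unname(sp[.data$id_a])) |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(max_intra_bp = max(.data$bp_diff),
                       witness_a = .data$id_a[which.max(.data$bp_diff)],
                       witness_b = .data$id_b[which.max(.data$bp_diff)],
                       .groups = "drop")
  }
  nonret <- matrix$not_retained_within_species
  nonret_species <- unique(sp[nonret$id_a])
  out <- intra |>
    dplyr::mutate(has_nonretained_pair = .data$species %in% nonret_species) |>
    dplyr::filter(.data$max_intra_bp > cutoff_bp | .data$has_nonretained_pair)
  # species whose only divergent pairs were all non-retained
  only_nonret <- setdiff(nonret_species, intra$species)
  if (length(only_nonret) > 0) {
    extra <- nonret |>
      dplyr::mutate(species = sp[.data$id_a]) |>
      dplyr::filter(.data$species %in% only_nonret) |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(max_intra_bp = NA_integer_, witness_a = .data$id_a[1],
                       witness_b = .data$id_b[1], .groups = "drop") |>
      dplyr::mutate(has_nonretained_pair = TRUE)
    out <- dplyr::bind_rows(out, extra)
  }
  dplyr::arrange(out, .data$species)
}

#' Classify the taxonomic severity of a species pair
#'
#' Severity ladder keyed to the lowest shared rank: same genus is
#' `congeneric`; different genus but same family `confamilial`; different
#' family but same order `moderate`; different order `major`. Species whose
#' genus cannot be resolved yield `unknown`.
#'
#' @param species_a,species_b Character vectors of binomials (recycled).
#' @param taxonomy Tibble with columns `species` or `genus`, plus `family`
#'   and `order` (as produced inside a `barcode_dist`, or a genus-level
#'   index from [read_taxonomy()]).
#' @return Character vector of severity classes.
#' @export
classify_severity <- function(species_a, species_b, taxonomy) {
  look <- function(sp) {
    genus <- parse_genus(sp)
    if ("species" %in% names(taxonomy)) {
      i <- match(sp, taxonomy$species)
      fam <- taxonomy$family[i]; ord <- taxonomy$order[i]
      g <- dplyr::coalesce(taxonomy$genus[i] %||% NA_character_, genus)
    } else {
      i <- match(genus, taxonomy$genus)
      fam <- taxonomy$family[i]; ord <- taxonomy$order[i]
      g <- genus
    }
    list(genus = g, family = fam, order = ord)
  }
  a <- look(species_a); b <- look(species_b)
  dplyr::case_when(
    is.na(a$genus) | is.na(b$genus) ~ "unknown",
    a$genus == b$genus ~ "congeneric",
    !is.na(a$family) & !is.na(b$family) & a$family == b$family ~ "confamilial",
    !is.na(a$order) & !is.na(b$order) & a$order == b$order ~ "moderate",
    is.na(a$family) | is.na(b$family) ~ "unknown",
    TRUE ~ "major"
  )
}

#' Sweep species-delimitation cutoffs and count both error types
#'
#' For each cutoff: lumping errors are interspecific pairs at or below the
#' cutoff (distinct species that a similarity rule would merge); splitting
#' errors are intraspecific pairs above it (conspecifics it would separate,
#' including within-species pairs beyond the retention cap).
#'
#' @param matrix A `barcode_dist`.
#' @param cutoffs Ascending bp cutoffs.
#' @return A `threshold_sweep` tibble with columns `cutoff_bp`,
#'   `lumping`, `splitting`.
#' @export
threshold_sweep <- function(matrix, cutoffs = c(0, 7, 14, 35, 70)) {
  if (is.unsorted(cutoffs)) stop("cutoffs must be ascending", call. = FALSE)
  e <- matrix$entries
  n_nonret_within <- nrow(matrix$not_retained_within_species)
  out <- tibble::tibble(
    cutoff_bp = as.integer(cutoffs),
    lumping = vapply(cutoffs, function(ct) sum(!e$same_species & e$bp_diff <= ct), integer(1)),
    splitting = vapply(cutoffs, function(ct) {
      sum(e$same_species & e$bp_diff > ct) + n_nonret_within
    }, integer(1))
  )
  class(out) <- c("threshold_sweep", class(out))
  out
}

#' @export
#' @rdname threshold_sweep
#' @param object A `threshold_sweep`.
#' @param ... Unused.
autoplot.threshold_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"cutoff_bp",
                              names_to = "error", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(.data$cutoff_bp, .data$count,
                                     colour = .data$error)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "cutoff (bp)", y = "errors", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Full barcode error report
#'
#' Combines false negatives, false positives at a cutoff, and near-miss
#' interspecific pairs at small divergence.
#'
#' @param matrix A `barcode_dist`.
#' @param fp_cutoff_bp Cutoff for [find_false_positives()].
#' @param near_miss_bp Interspecific pairs with `0 < bp_diff <=` this value
#'   are reported as near misses (default 1 bp).
#' @param collapse_near_misses Report near misses as unique species pairs
#'   instead of specimen pairs.
#' @return A list with `false_negatives`, `false_positives`, `near_misses`.
#' @export
error_report <- function(matrix, fp_cutoff_bp = 0L, near_miss_bp = 1L,
                         collapse_near_misses = FALSE) {
  sp <- stats::setNames(matrix$specimens$species, matrix$specimens$specimen_id)
  near <- matrix$entries |>
    dplyr::filter(!.data$same_species, .data$bp_diff > 0,
                  .data$bp_diff <= near_miss_bp) |>
    dplyr::mutate(species_a = pmin(sp[.data$id_a], sp[.data$id_b]),
                  species_b = pmax(sp[.data$id_a], sp[.data$id_b]))
  if (collapse_near_misses) {
    near <- near |>
      dplyr::group_by(.data$species_a, .data$species_b) |>
      dplyr::summarise(bp_diff = min(.data$bp_diff), n_specimen_pairs = dplyr::n(),
                       .groups = "drop")
  } else {
    near <- near[, c("id_a", "id_b", "bp_diff", "species_a", "species_b")]
  }
  if (nrow(near) > 0) {
    near$severity <- classify_severity(near$species_a, near$species_b,
                                       specimen_taxonomy(matrix))
  } else {
    near$severity <- character(0)
  }
  list(
    false_negatives = find_false_negatives(matrix),
    false_positives = find_false_positives(matrix, fp_cutoff_bp),
    near_misses = near
  )
}
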