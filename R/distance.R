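#' Count base-pair differences between two sequences
#'
#' Aligns two sequences with a free-end-gap (dovetail) global alignment
#' under affine gap costs and counts substitution columns plus internal
#' gap columns; terminal overhangs are excluded. IUPAC ambiguity codes
#' count as a match whenever their base sets intersect. With
#' `indel_mode = "per_gap"` a multi-column gap counts once instead of
#' once per column.
#'
#' @param seq_a,seq_b Non-empty IUPAC DNA strings.
#' @param match,mismatch,gap_opening,gap_extension Alignment scoring; a gap
#'   of length k costs `gap_opening + k * gap_extension`.
#' @param indel_mode `"per_column"` (default) or `"per_gap"`.
#' @return Integer bp difference.
#' @export
align_count_diffs <- function(seq_a, seq_b, match = 1, mismatch = -1,
                              gap_opening = 5, gap_extension = 2,
                              indel_mode = c("per_column", "per_gap")) {
  indel_mode <- match.arg(indel_mode)
  if (is.na(seq_a) || is.na(seq_b) || nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  if (seq_a == seq_b) return(0L)
  aln <- align_pair_cpp(seq_a, seq_b, match, mismatch, gap_opening, gap_extension)
  gaps <- if (indel_mode == "per_column") aln$n_gap_cols else aln$n_gap_runs
  as.integer(aln$n_sub + gaps)
}

#' Build the sparse pairwise distance matrix for a dataset
#'
#' Evaluates every unordered pair of sequenced specimens, counts bp
#' differences with [align_count_diffs()], and applies the retention rule:
#' a pair is kept when its bp difference is at most
#' `min(threshold_bp, floor(threshold_frac * mean(length_a, length_b)))`
#' (default 70 bp or 10% of a ~700 bp amplicon). Non-retained pairs are
#' recorded only as a count. Pairs are canonicalised with
#' `id_a < id_b` lexicographically.
#'
#' @param dataset An [audit_dataset()] with at least two sequenced records.
#' @param threshold_bp Fixed retention cap in bp.
#' @param threshold_frac Fractional retention cap applied to the mean pair
#'   length.
#' @param ... Passed to [align_count_diffs()].
#' @return A `barcode_dist` object: retained pair entries (with
#'   `same_species`/`same_genus`/`same_family` flags), specimen table,
#'   thresholds and the non-retained pair count.
#' @export
pairwise_distances <- function(dataset, threshold_bp = 70L, threshold_frac = 0.10, ...) {
  recs <- dplyr::filter(dataset$records, !is.na(.data$sequence))
  if (nrow(recs) < 2) stop("need at least two sequenced records", call. = FALSE)
  recs <- dplyr::arrange(recs, .data$specimen_id)
  n <- nrow(recs)
  idx <- utils::combn(n, 2)
  seqs <- recs$sequence
  lens <- nchar(seqs)
  ia <- idx[1, ]; ib <- idx[2, ]
  bp <- integer(ncol(idx))
  for (k in seq_len(ncol(idx))) {
    bp[k] <- align_count_diffs(seqs[ia[k]], seqs[ib[k]], ...)
  }
  cap <- pmin(threshold_bp, floor(threshold_frac * (lens[ia] + lens[ib]) / 2))
  retained <- bp <= cap
  entries <- tibble::tibble(
    id_a = recs$specimen_id[ia], id_b = recs$specimen_id[ib],
    bp_diff = bp, retained = retained,
    same_species = recs$species[ia] == recs$species[ib],
    same_genus = recs$genus[ia] == recs$genus[ib],
    same_family = recs$family[ia] == recs$family[ib]
  )
  specimens <- dplyr::select(recs, "specimen_id", "species", "genus", "family",
                             "order", "taxon_name") |>
    dplyr::mutate(seq_length = lens)
  structure(list(
    entries = dplyr::filter(entries, .data$retained),
    n = n,
    n_pairs_evaluated = ncol(idx),
    n_not_retained = sum(!retained),
    not_retained_within_species = dplyr::filter(
      entries, !.data$retained, .data$same_species)[, c("id_a", "id_b")],
    threshold_bp = threshold_bp,
    threshold_frac = threshold_frac,
    specimens = specimens
  ), class = "barcode_dist")
}

#' @export
print.barcode_dist <- function(x, ...) {
  cat("<barcode_dist>\n")
  cat(sprintf("  %d specimens, %d pairs evaluated, %d retained (cap %d bp / %.0f%%)\n",
              x$n, x$n_pairs_evaluated, nrow(x$entries), x$threshold_bp,
              100 * x$threshold_frac))
  invisible(x)
}

#' @rdname pairwise_distances
#' @param x A `barcode_dist` object.
#' @export
tidy.barcode_dist <- function(x, ...) {
  x$entries
}

#' Restrict a distance matrix to a subset of specimens
#'
#' @param matrix A `barcode_dist`.
#' @param ids Specimen IDs to keep (must all be present).
#' @return A `barcode_dist` over the subset; thresholds unchanged.
#' @export
dist_subset <- function(matrix, ids) {
  unknown <- setdiff(ids, matrix$specimens$specimen_id)
  if (length(unknown) > 0) {
    stop("unknown specimen id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep_entry <- matrix$entries$id_a %in% ids & matrix$entries$id_b %in% ids
  out <- matrix
  out$entries <- matrix$entries[keep_entry, ]
  out$specimens <- dplyr::filter(matrix$specimens, .data$specimen_id %in% ids)
  out$n <- nrow(out$specimens)
  out$n_pairs_evaluated <- choose(out$n, 2)
  keep_nr <- matrix$not_retained_within_species$id_a %in% ids &
    matrix$not_retained_within_species$id_b %in% ids
  out$not_retained_within_species <- matrix$not_retained_within_species[keep_nr, ]
  out$n_not_retained <- out$n_pairs_evaluated - nrow(out$entries)
  out
}

#' Serialise a distance matrix as long-format text
#'
#' @param matrix A `barcode_dist`.
#' @param path Output path for a TSV with columns
#'   `id_a, id_b, bp_diff, retained`.
#' @return `path`, invisibly.
#' @export
write_distances <- function(matrix, path) {
  readr::write_tsv(matrix$entries[, c("id_a", "id_b", "bp_diff", "retained")],
                   path, progress = FALSE)
  invisible(path)
}

# Full symmetric numeric matrix with a censoring policy for pairs that were
# not retained: "censor" -> threshold_bp + 1, "na" -> NA.
dense_distance_matrix <- function(matrix, missing_policy = c("censor", "na")) {
  missing_policy <- match.arg(missing_policy)
  ids <- sort(matrix$specimens$specimen_id)
  n <- length(ids)
  fill <- if (missing_policy == "censor") matrix$threshold_bp + 1 else NA_real_
  m <- base::matrix(fill, n, n, dimnames = list(ids, ids))
  diag(m) <- 0
  ia <- match(matrix$entries$id_a, ids)
  ib <- match(matrix$entries$id_b, ids)
  m[cbind(ia, ib)] <- matrix$entries$bp_diff
  m[cbind(ib, ia)] <- matrix$entries$bp_diff
  m
}
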