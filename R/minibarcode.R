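#' Default 5.8S anchor sequence
#'
#' The conserved anchor used to locate the 5.8S region when no annotation
#' coordinates are available. This is a synthetic fixed sequence (it is
#' also the invariant 5.8S used by [simulate_herbarium()]); replace it
#' with a curated fungal 5.8S consensus for real data via the `anchor`
#' argument of [split_its_regions()].
#'
#' @param len Anchor length in bp.
#' @return A DNA string.
#' @export
anchor_58s <- function(len = 160L) {
  default_58s_anchor(len)
}

#' Split ITS sequences into ITS1 / 5.8S / ITS2 regions
#'
#' Records with annotated region coordinates are split directly. Otherwise
#' the 5.8S is located by best local alignment of the anchor against the
#' sequence, accepted when identity over the aligned span is at least
#' `min_anchor_identity` and the span covers at least `min_anchor_coverage`
#' of the anchor. Failures are recorded per specimen with a reason, never
#' fatal. Splits are lossless: `its1 + s58 + its2` reproduces the input.
#'
#' @param dataset An [audit_dataset()].
#' @param anchor Anchor DNA string; defaults to [anchor_58s()].
#' @param min_anchor_identity Minimum identity over the aligned span.
#' @param min_anchor_coverage Minimum fraction of the anchor aligned.
#' @return A `region_set` tibble: `specimen_id`, `its1`, `s58`, `its2`,
#'   `split_method` (`annotation`/`anchor`), `anchor_score`, `ok`, `reason`.
#' @export
split_its_regions <- function(dataset, anchor = anchor_58s(),
                              min_anchor_identity = 0.75,
                              min_anchor_coverage = 0.80) {
  if (is.null(anchor) || nchar(anchor) == 0) stop("anchor must be non-empty", call. = FALSE)
  recs <- dplyr::filter(dataset$records, !is.na(.data$sequence))
  anchor_set <- Biostrings::DNAString(anchor)
  split_one <- function(specimen_id, sequence, its1_end, s58_start, s58_end, ...) {
    if (!is.na(its1_end)) {
      return(tibble::tibble(
        specimen_id = specimen_id,
        its1 = substr(sequence, 1, its1_end),
        s58 = substr(sequence, s58_start + 1, s58_end),
        its2 = substr(sequence, s58_end + 1, nchar(sequence)),
        split_method = "annotation", anchor_score = NA_real_,
        ok = TRUE, reason = NA_character_))
    }
    aln <- Biostrings::pairwiseAlignment(
      anchor_set, Biostrings::DNAString(sequence), type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 5, gapExtension = 2)
    span <- Biostrings::width(Biostrings::pattern(aln))
    ident <- Biostrings::nmatch(aln) / max(span, 1)
    cover <- span / nchar(anchor)
    fail <- function(reason) tibble::tibble(
      specimen_id = specimen_id, its1 = NA_character_, s58 = NA_character_,
      its2 = NA_character_, split_method = "anchor",
      anchor_score = Biostrings::score(aln), ok = FALSE, reason = reason)
    if (cover < min_anchor_coverage) return(fail("anchor coverage below threshold"))
    if (ident < min_anchor_identity) return(fail("anchor identity below threshold"))
    s <- Biostrings::start(Biostrings::subject(aln))
    e <- Biostrings::end(Biostrings::subject(aln))
    tibble::tibble(
      specimen_id = specimen_id,
      its1 = substr(sequence, 1, s - 1),
      s58 = substr(sequence, s, e),
      its2 = substr(sequence, e + 1, nchar(sequence)),
      split_method = "anchor", anchor_score = Biostrings::score(aln),
      ok = TRUE, reason = NA_character_)
  }
  out <- purrr::pmap(recs, split_one) |> dplyr::bind_rows()
  class(out) <- c("region_set", class(out))
  out
}

#' Pearson correlation between two distance matrices
#'
#' Computed over the intersection of retained pairs of both matrices,
#' using bp differences (or percent divergence with `percent = TRUE`).
#'
#' @param m1,m2 `barcode_dist` objects.
#' @param percent Correlate percent divergence (bp / mean pair length)
#'   instead of raw bp.
#' @return A list with `r`, `n_shared_pairs`.
#' @export
matrix_correlation <- function(m1, m2, percent = FALSE) {
  val <- function(m) {
    v <- m$entries$bp_diff
    if (percent) {
      len <- stats::setNames(m$specimens$seq_length, m$specimens$specimen_id)
      v <- v / ((len[m$entries$id_a] + len[m$entries$id_b]) / 2)
    }
    tibble::tibble(id_a = m$entries$id_a, id_b = m$entries$id_b, v = unname(v))
  }
  shared <- dplyr::inner_join(val(m1), val(m2), by = c("id_a", "id_b"),
                              suffix = c("_1", "_2"))
  if (nrow(shared) < 3) {
    stop("need at least 3 shared retained pairs (got ", nrow(shared), ")", call. = FALSE)
  }
  if (stats::sd(shared$v_1) == 0 || stats::sd(shared$v_2) == 0) {
    stop("correlation undefined: zero variance in one matrix over shared pairs",
         call. = FALSE)
  }
  list(r = stats::cor(shared$v_1, shared$v_2), n_shared_pairs = nrow(shared))
}

#' Evaluate ITS1/ITS2 mini-barcode discriminating power
#'
#' Splits every sequence into regions, builds region-wise distance
#' matrices with the same parameters as the full-length matrix, and
#' reports Pearson correlations between ITS1, ITS2 and full-length
#' distances. Undefined correlations (zero variance, too few shared
#' pairs) are reported as `NA` with the reason.
#'
#' @param dataset An [audit_dataset()].
#' @param regions Optional precomputed [split_its_regions()] result.
#' @param threshold_bp,threshold_frac Retention parameters for the three
#'   matrices. The defaults retain every pair: the retention cap guards the
#'   barcode-gap analysis, whereas the correlation compares complete
#'   distance matrices; set these to the gap-analysis values to censor
#'   distant pairs here too.
#' @param ... Alignment parameters passed to [pairwise_distances()].
#' @return A `minibarcode_report` list: `r_its1_full`, `r_its2_full`,
#'   `r_its1_its2`, shared-pair counts, split failure count, and any
#'   undefined-correlation reasons.
#' @export
minibarcode_report <- function(dataset, regions = NULL, threshold_bp = Inf,
                               threshold_frac = 1, ...) {
  regions <- regions %||% split_its_regions(dataset)
  ok <- dplyr::filter(regions, .data$ok)
  region_dataset <- function(col) {
    recs <- dataset$records |>
      dplyr::filter(.data$specimen_id %in% ok$specimen_id) |>
      dplyr::mutate(sequence = ok[[col]][match(.data$specimen_id, ok$specimen_id)],
                    its1_end = NA_integer_, s58_start = NA_integer_,
                    s58_end = NA_integer_)
    ds <- dataset
    ds$records <- recs
    ds
  }
  full_ds <- dataset
  full_ds$records <- dplyr::filter(dataset$records, .data$specimen_id %in% ok$specimen_id)
  full <- pairwise_distances(full_ds, threshold_bp, threshold_frac, ...)
  m1 <- pairwise_distances(region_dataset("its1"), threshold_bp, threshold_frac, ...)
  m2 <- pairwise_distances(region_dataset("its2"), threshold_bp, threshold_frac, ...)
  corr <- function(a, b) {
    tryCatch(matrix_correlation(a, b),
             error = function(e) list(r = NA_real_, n_shared_pairs = NA_integer_,
                                      reason = conditionMessage(e)))
  }
  c12 <- corr(m1, m2); c1f <- corr(m1, full); c2f <- corr(m2, full)
  structure(list(
    r_its1_full = c1f$r, r_its2_full = c2f$r, r_its1_its2 = c12$r,
    n_shared_its1_full = c1f$n_shared_pairs,
    n_shared_its2_full = c2f$n_shared_pairs,
    n_shared_its1_its2 = c12$n_shared_pairs,
    n_split_failures = sum(!regions$ok),
    undefined = purrr::compact(list(its1_full = c1f$reason,
                                    its2_full = c2f$reason,
                                    its1_its2 = c12$reason))
  ), class = "minibarcode_report")
}

#' @export
print.minibarcode_report <- function(x, ...) {
  cat("<minibarcode_report>\n")
  cat(sprintf("  r(ITS1, full) = %.4f over %d pairs\n", x$r_its1_full, x$n_shared_its1_full))
  cat(sprintf("  r(ITS2, full) = %.4f over %d pairs\n", x$r_its2_full, x$n_shared_its2_full))
  cat(sprintf("  r(ITS1, ITS2) = %.4f over %d pairs\n", x$r_its1_its2, x$n_shared_its1_its2))
  if (x$n_split_failures > 0) cat("  split failures:", x$n_split_failures, "\n")
  invisible(x)
}

#' Write per-region FASTA files
#'
#' @param regions A [split_its_regions()] result.
#' @param stem Output path stem; writes `<stem>.ITS1.fasta` and
#'   `<stem>.ITS2.fasta` for successfully split records.
#' @return Paths, invisibly.
#' @export
write_region_fasta <- function(regions, stem) {
  ok <- dplyr::filter(regions, .data$ok)
  paths <- c(its1 = paste0(stem, ".ITS1.fasta"), its2 = paste0(stem, ".ITS2.fasta"))
  write_barcode_fasta(tibble::tibble(specimen_id = ok$specimen_id, sequence = ok$its1),
                      paths[["its1"]])
  write_barcode_fasta(tibble::tibble(specimen_id = ok$specimen_id, sequence = ok$its2),
                      paths[["its2"]])
  invisible(paths)
}
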