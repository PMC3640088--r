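#' Read barcode sequences from a FASTA file
#'
#' Sequences are uppercased and RNA `U` is normalised to `T`; IUPAC
#' ambiguity codes are preserved. Duplicate record identifiers and
#' non-IUPAC characters are hard errors.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `specimen_id` and `sequence`.
#' @export
read_barcode_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  ids <- stringr::str_split_i(names(set), "\\s+", 1)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate FASTA ID(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  seqs <- stringr::str_replace_all(toupper(as.character(set)), "U", "T")
  purrr::walk2(seqs, ids, check_iupac)
  tibble::tibble(specimen_id = ids, sequence = unname(seqs))
}

#' Write sequences of a dataset to FASTA
#'
#' @param x A tibble with `specimen_id` and `sequence` columns, or an
#'   [audit_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_barcode_fasta <- function(x, path) {
  recs <- if (inherits(x, "audit_dataset")) x$records else x
  recs <- dplyr::filter(recs, !is.na(.data$sequence))
  set <- Biostrings::DNAStringSet(recs$sequence)
  names(set) <- recs$specimen_id
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read a specimen metadata table
#'
#' Reads a delimited table of vouchered collections. The delimiter is
#' sniffed among tab, comma and semicolon unless given. Mandatory columns
#' are `specimen_id` and `taxon_name`; `genus`, `family`, `order`,
#' `collection_year`, `pcr_positive`, `sequence_positive` and region
#' coordinate columns (`its1_end`, `s58_start`, `s58_end`; 0-based
#' half-open) are used when present. Genus falls back to parsing
#' `taxon_name`; missing optional fields stay `NA`, never imputed.
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter; `NULL` (default) sniffs it.
#' @return A tibble of sequence-less specimen records.
#' @export
read_specimen_metadata <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  delim <- delim %||% sniff_delim(path)
  raw <- readr::read_delim(path, delim = delim, trim_ws = TRUE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  names(raw) <- tolower(names(raw))
  mandatory <- c("specimen_id", "taxon_name")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing) > 0) {
    stop("metadata is missing mandatory column(s) ", paste(missing, collapse = ", "),
         "; available headers: ", paste(names(raw), collapse = ", "), call. = FALSE)
  }
  year_col <- intersect(c("collection_year", "year", "date"), names(raw))
  tibble::tibble(
    specimen_id = raw$specimen_id,
    taxon_name = stringr::str_squish(raw$taxon_name),
    genus = if ("genus" %in% names(raw)) dplyr::coalesce(raw$genus, parse_genus(raw$taxon_name))
            else parse_genus(raw$taxon_name),
    family = raw[["family"]] %||% NA_character_,
    order = raw[["order"]] %||% NA_character_,
    collection_year = if (length(year_col) > 0) parse_year(raw[[year_col[1]]]) else NA_integer_,
    pcr_positive = parse_flag(raw[["pcr_positive"]]),
    sequence_positive = parse_flag(raw[["sequence_positive"]]),
    its1_end = parse_int(raw[["its1_end"]]),
    s58_start = parse_int(raw[["s58_start"]]),
    s58_end = parse_int(raw[["s58_end"]])
  )
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- vapply(c("\t", ",", ";"), function(d) stringr::str_count(header, stringr::fixed(d)), numeric(1))
  if (all(counts == 0)) stop("cannot sniff delimiter in ", path, call. = FALSE)
  names(counts)[which.max(counts)]
}

parse_year <- function(x) {
  if (is.null(x)) return(NA_integer_)
  y <- stringr::str_extract(x, "\\b(1[0-9]{3}|2[0-9]{3})\\b")
  as.integer(y)
}

parse_flag <- function(x) {
  if (is.null(x)) return(NA)
  out <- tolower(x) %in% c("true", "t", "1", "yes", "y", "positive")
  out[is.na(x) | x == ""] <- NA
  out
}

parse_int <- function(x) {
  if (is.null(x)) return(NA_integer_)
  suppressWarnings(as.integer(x))
}

#' Read a taxonomy index
#'
#' A 3-column delimited file mapping genus to family and order.
#'
#' @inheritParams read_specimen_metadata
#' @return A tibble with columns `genus`, `family`, `order`.
#' @export
read_taxonomy <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path, call. = FALSE)
  delim <- delim %||% sniff_delim(path)
  raw <- readr::read_delim(path, delim = delim, trim_ws = TRUE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  names(raw) <- tolower(names(raw))
  need <- c("genus", "family", "order")
  if (!all(need %in% names(raw))) {
    stop("taxonomy file needs columns genus, family, order; found: ",
         paste(names(raw), collapse = ", "), call. = FALSE)
  }
  dplyr::distinct(tibble::tibble(genus = raw$genus, family = raw$family, order = raw$order))
}

#' Assemble a validated audit dataset
#'
#' Joins sequences onto metadata records, resolves genus to family and
#' order through the taxonomy index, and collapses taxon names to
#' morphological species. Mismatches between the sequence and metadata
#' sides are reported, never fatal; genera absent from the taxonomy index
#' are collected into `unresolved_genera` rather than dropped.
#'
#' @param seqs Tibble from [read_barcode_fasta()] (may have zero rows).
#' @param metadata Tibble from [read_specimen_metadata()].
#' @param taxonomy Tibble from [read_taxonomy()], or `NULL` to rely on
#'   family/order columns already present in the metadata.
#' @param collapse_infraspecific Passed to [collapse_species()].
#' @return An `audit_dataset`: a list with `records` (tibble), `taxonomy`,
#'   `join` (counts of joined / metadata-only / sequence-only records and
#'   sequence-only IDs) and `unresolved_genera`.
#' @export
audit_dataset <- function(seqs, metadata, taxonomy = NULL,
                          collapse_infraspecific = TRUE) {
  stopifnot(is.data.frame(metadata))
  if (anyDuplicated(metadata$specimen_id)) {
    stop("duplicate specimen_id in metadata: ",
         paste(unique(metadata$specimen_id[duplicated(metadata$specimen_id)]), collapse = ", "),
         call. = FALSE)
  }
  seqs <- seqs %||% tibble::tibble(specimen_id = character(), sequence = character())
  records <- dplyr::left_join(metadata, seqs, by = "specimen_id")
  if (is.null(records[["genus"]])) records$genus <- parse_genus(records$taxon_name)
  if (!is.null(taxonomy)) {
    records <- records |>
      dplyr::select(-dplyr::any_of(c("family", "order"))) |>
      dplyr::left_join(taxonomy, by = "genus")
  }
  records <- dplyr::mutate(
    records,
    species = collapse_species(.data$taxon_name, collapse_infraspecific),
    .after = "taxon_name"
  )
  for (col in c("family", "order")) {
    if (is.null(records[[col]])) records[[col]] <- NA_character_
  }
  if (is.null(records[["collection_year"]])) records[["collection_year"]] <- NA_integer_
  for (col in c("pcr_positive", "sequence_positive")) {
    if (is.null(records[[col]])) records[[col]] <- NA
  }
  for (col in c("its1_end", "s58_start", "s58_end")) {
    if (is.null(records[[col]])) records[[col]] <- NA_integer_
  }
  check_region_coords(records)
  seq_only <- setdiff(seqs$specimen_id, metadata$specimen_id)
  unresolved <- sort(unique(records$genus[is.na(records$family)]))
  structure(list(
    records = tibble::as_tibble(records),
    taxonomy = taxonomy,
    join = list(
      n_joined = sum(!is.na(records$sequence)),
      n_metadata_only = sum(is.na(records$sequence)),
      n_sequence_only = length(seq_only),
      sequence_only_ids = seq_only
    ),
    unresolved_genera = unresolved
  ), class = "audit_dataset")
}

check_region_coords <- function(records) {
  has <- !is.na(records$its1_end)
  if (!any(has)) return(invisible(TRUE))
  r <- records[has, ]
  len <- nchar(r$sequence)
  bad <- is.na(r$s58_start) | is.na(r$s58_end) |
    !(r$its1_end > 0 & r$its1_end <= r$s58_start & r$s58_start < r$s58_end) |
    (!is.na(len) & r$s58_end > len)
  if (any(bad, na.rm = TRUE)) {
    stop("invalid region coordinates for specimen(s): ",
         paste(r$specimen_id[which(bad)], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.audit_dataset <- function(x, ...) {
  cat("<audit_dataset>\n")
  cat(sprintf("  records: %d (%d with sequence, %d metadata-only)\n",
              nrow(x$records), x$join$n_joined, x$join$n_metadata_only))
  cat(sprintf("  unique taxa: %d; genera: %d\n",
              dplyr::n_distinct(x$records$species), dplyr::n_distinct(x$records$genus)))
  if (x$join$n_sequence_only > 0) {
    cat(sprintf("  sequence-only IDs (no metadata): %d\n", x$join$n_sequence_only))
  }
  if (length(x$unresolved_genera) > 0) {
    cat("  unresolved genera:", paste(x$unresolved_genera, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write an NCBI 5-column feature annotation table
#'
#' One `>Feature` block per sequenced record. When region coordinates are
#' present the ITS1, 5.8S and ITS2 intervals are annotated; otherwise a
#' single misc_RNA feature spans the whole sequence. Internal coordinates
#' are 0-based half-open; the emitted table is 1-based inclusive.
#'
#' @param dataset An [audit_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(dataset, path) {
  recs <- dataset$records
  skipped <- recs$specimen_id[is.na(recs$sequence)]
  if (length(skipped) > 0) {
    warning("skipping record(s) without sequence: ", paste(skipped, collapse = ", "),
            call. = FALSE)
  }
  recs <- dplyr::filter(recs, !is.na(.data$sequence))
  lines <- purrr::pmap(recs, function(specimen_id, sequence, its1_end, s58_start, s58_end, ...) {
    len <- nchar(sequence)
    head <- sprintf(">Feature %s", specimen_id)
    if (!is.na(its1_end)) {
      c(head,
        feature_lines(1L, its1_end, "misc_RNA", "internal transcribed spacer 1"),
        feature_lines(s58_start + 1L, s58_end, "rRNA", "5.8S ribosomal RNA"),
        feature_lines(s58_end + 1L, len, "misc_RNA", "internal transcribed spacer 2"))
    } else {
      c(head, feature_lines(1L, len, "misc_RNA",
                            "internal transcribed spacer region"))
    }
  })
  writeLines(as.character(unlist(lines)), path)
  invisible(path)
}

feature_lines <- function(start, end, key, product) {
  c(paste(start, end, key, sep = "\t"),
    paste("", "", "", "product", product, sep = "\t"))
}
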