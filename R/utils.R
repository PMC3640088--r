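#' @importFrom rlang %||% .data
#' @importFrom Rcpp sourceCpp
#' @useDynLib barcodeaudit, .registration = TRUE
NULL

# Rank markers that may sit between genus and epithet in herbarium names.
RANK_MARKERS <- c("cf.", "aff.", "cf", "aff")
INFRA_MARKERS <- c("var.", "f.", "fo.", "subsp.", "ssp.", "var", "subsp", "ssp")

#' Parse the genus from a taxon name
#'
#' The genus is the first whitespace-delimited token after stripping
#' qualifier markers such as `cf.` and `aff.`.
#'
#' @param taxon_name Character vector of binomials, optionally with
#'   infraspecific epithets or qualifiers.
#' @return Character vector of genus names.
#' @export
parse_genus <- function(taxon_name) {
  purrr::map_chr(taxon_tokens(taxon_name), function(tok) {
    if (length(tok) == 0) NA_character_ else tok[[1]]
  })
}

#' Collapse a taxon name to its binomial
#'
#' Drops infraspecific rank markers (`var.`, `f.`, `subsp.`) and their
#' epithets, and identification qualifiers (`cf.`, `aff.`), keeping
#' genus + specific epithet. Used to define the morphological species
#' underlying intra/interspecific pair classification.
#'
#' @inheritParams parse_genus
#' @param collapse_infraspecific If `FALSE`, the full cleaned name (including
#'   infraspecific epithets) defines the species instead of the binomial.
#' @return Character vector of species names.
#' @export
collapse_species <- function(taxon_name, collapse_infraspecific = TRUE) {
  purrr::map_chr(taxon_tokens(taxon_name), function(tok) {
    if (length(tok) == 0) return(NA_character_)
    if (collapse_infraspecific) {
      cut <- match(tolower(tok), INFRA_MARKERS)
      if (any(!is.na(cut))) tok <- tok[seq_len(min(which(!is.na(cut))) - 1L)]
      tok <- utils::head(tok, 2L)
    }
    paste(tok, collapse = " ")
  })
}

taxon_tokens <- function(taxon_name) {
  purrr::map(stringr::str_split(stringr::str_squish(taxon_name %||% ""), " "), function(tok) {
    tok[!tolower(tok) %in% RANK_MARKERS & tok != ""]
  })
}

#' Bin a collection year into its decade
#'
#' @param year Integer vector of calendar years.
#' @return Integer vector of decades (e.g. 1987 -> 1980).
#' @export
decade_of <- function(year) {
  as.integer(floor(year / 10) * 10)
}

iupac_match <- function(a, b) {
  iupac_compatible_cpp(a, b)
}

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

check_iupac <- function(seq, id = "sequence") {
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% IUPAC_CHARS)
  if (length(bad) > 0) {
    stop(sprintf("non-IUPAC character '%s' at position %d in %s",
                 chars[bad[1]], bad[1], id), call. = FALSE)
  }
  invisible(TRUE)
}

# Deterministic child seed derived from a run seed; kept below 2^31.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}
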