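# Small dataset builders shared across tests.

tiny_config <- function(seed = 1L, ...) {
  generator_config(n_genera = 4, species_per_genus = 3, accessions_per_species = 2,
                   seed = seed, ...)
}

# build an audit_dataset straight from sequence/taxon vectors
manual_dataset <- function(ids, seqs, species, genus = parse_genus(species),
                           family = NULL, order = NULL, year = NULL, pcr = NULL) {
  meta <- tibble::tibble(specimen_id = ids, taxon_name = species, genus = genus)
  if (!is.null(year)) meta$collection_year <- year
  if (!is.null(pcr)) meta$pcr_positive <- pcr
  taxo <- if (!is.null(family)) {
    tibble::tibble(genus = unique(genus),
                   family = family[match(unique(genus), genus)],
                   order = if (is.null(order)) "OrderX" else order[match(unique(genus), genus)])
  }
  audit_dataset(tibble::tibble(specimen_id = ids, sequence = seqs), meta, taxo)
}

make_dist_from_matrix <- function(m) {
  # wrap a dense symmetric bp matrix as a barcode_dist over one species
  ids <- rownames(m)
  idx <- utils::combn(length(ids), 2)
  entries <- tibble::tibble(
    id_a = ids[idx[1, ]], id_b = ids[idx[2, ]],
    bp_diff = m[cbind(idx[1, ], idx[2, ])],
    retained = TRUE, same_species = TRUE, same_genus = TRUE, same_family = TRUE)
  structure(list(
    entries = entries, n = length(ids), n_pairs_evaluated = ncol(idx),
    n_not_retained = 0,
    not_retained_within_species = entries[0, c("id_a", "id_b")],
    threshold_bp = 70L, threshold_frac = 0.10,
    specimens = tibble::tibble(specimen_id = ids, species = "Gx s1",
                               genus = "Gx", family = "FamX", order = "OrdX",
                               taxon_name = "Gx s1", seq_length = 700L)
  ), class = "barcode_dist")
}

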