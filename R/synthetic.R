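#' Configuration for the synthetic herbarium generator
#'
#' Defines a star-shaped genealogy: per-genus ancestral spacers descend
#' from a single root by per-site substitution at `p_genus`, species
#' ancestors from their genus ancestor at `p_inter`, and accessions from
#' their species ancestor at `p_intra`. The 5.8S region is shared and
#' invariant by default, giving the region splitter a perfect anchor.
#' Defaults emulate a multi-genus macrofungal collection with a ~660 bp
#' ITS amplicon and a clear intra/interspecific divergence contrast.
#'
#' @param n_genera,species_per_genus,accessions_per_species Collection shape.
#' @param len_its1,len_58s,len_its2 Region lengths in bp.
#' @param p_intra Per-site substitution probability from species ancestor to
#'   accession (within-species divergence scale).
#' @param p_inter Species-ancestor substitution probability within a genus.
#' @param p_genus Genus-ancestor substitution probability from the root.
#' @param p_58s Substitution probability inside 5.8S (0 keeps it invariant).
#' @param spacer_bias Fraction of spacer mutation pressure routed to ITS1;
#'   0.5 is symmetric, 0.8 concentrates mutations in ITS1.
#' @param n_false_neg_injected Number of false-negative barcode errors to
#'   inject (an accession's sequence duplicated under a different congeneric
#'   species name).
#' @param n_false_pos_injected Number of false-positive errors (one species
#'   given an accession re-drawn from the genus ancestor at `p_inter`).
#' @param n_major_misid_injected Number of accessions relabelled with a
#'   genus from a different family.
#' @param year_range Inclusive range of collection years.
#' @param success_model Logistic model for PCR success: list with
#'   `intercept` (log-odds at the newest decade), `per_decade` (log-odds
#'   change per decade of specimen age) and optional named `genus_offsets`.
#' @param seed Integer seed; the dataset is fully determined by the config.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_genera = 8, species_per_genus = 4,
                             accessions_per_species = 3,
                             len_its1 = 250, len_58s = 160, len_its2 = 250,
                             p_intra = 0.005, p_inter = 0.05, p_genus = 0.20,
                             p_58s = 0, spacer_bias = 0.5,
                             n_false_neg_injected = 0,
                             n_false_pos_injected = 0,
                             n_major_misid_injected = 0,
                             year_range = c(1980, 2009),
                             success_model = list(intercept = 1.2,
                                                  per_decade = -0.9,
                                                  genus_offsets = NULL),
                             seed = 1L) {
  probs <- c(p_intra = p_intra, p_inter = p_inter, p_genus = p_genus,
             p_58s = p_58s, spacer_bias = spacer_bias)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(c(len_its1, len_58s, len_its2) <= 0)) stop("region lengths must be positive", call. = FALSE)
  structure(list(
    n_genera = n_genera, species_per_genus = species_per_genus,
    accessions_per_species = accessions_per_species,
    len_its1 = len_its1, len_58s = len_58s, len_its2 = len_its2,
    p_intra = p_intra, p_inter = p_inter, p_genus = p_genus, p_58s = p_58s,
    spacer_bias = spacer_bias,
    n_false_neg_injected = n_false_neg_injected,
    n_false_pos_injected = n_false_pos_injected,
    n_major_misid_injected = n_major_misid_injected,
    year_range = year_range, success_model = success_model, seed = seed
  ), class = "generator_config")
}

BASES <- c("A", "C", "G", "T")

mutate_sites <- function(seq_chars, p) {
  if (p <= 0) return(seq_chars)
  hit <- stats::runif(length(seq_chars)) < p
  if (any(hit)) {
    seq_chars[hit] <- vapply(seq_chars[hit], function(b) {
      sample(setdiff(BASES, b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  seq_chars
}

# Mutation pressure per spacer given the routing bias: the average rate over
# both spacers stays p, ITS1 sees 2*bias*p and ITS2 sees 2*(1-bias)*p.
spacer_rates <- function(p, bias) {
  pmin(c(its1 = 2 * bias * p, its2 = 2 * (1 - bias) * p), 1)
}

#' Generate a synthetic herbarium dataset with known ground truth
#'
#' Simulates a multi-genus, multi-species vouchered collection: conserved
#' 5.8S, variable ITS1/ITS2 spacers with controlled intra- and
#' interspecific divergence, optional injected barcode errors and
#' misidentifications, and age/taxon-dependent PCR success drawn from a
#' logistic model. Genera are grouped two per family and families two per
#' order so that the full taxonomic severity ladder is exercisable.
#'
#' @param config A [generator_config()].
#' @return A list with `dataset` (an [audit_dataset()]) and `truth`
#'   (true species per specimen, injected error pairs, region sequences,
#'   and per-specimen true PCR success probabilities).
#' @export
simulate_herbarium <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  set.seed(cfg$seed)

  genera <- sprintf("Genus%02d", seq_len(cfg$n_genera))
  families <- sprintf("Family%02d", ceiling(seq_len(cfg$n_genera) / 2))
  orders <- sprintf("Order%02d", ceiling(seq_len(cfg$n_genera) / 4))
  taxonomy <- tibble::tibble(genus = genera, family = families, order = orders)

  s58 <- strsplit(default_58s_anchor(cfg$len_58s), "")[[1]]
  r_intra <- spacer_rates(cfg$p_intra, cfg$spacer_bias)
  r_inter <- spacer_rates(cfg$p_inter, cfg$spacer_bias)
  r_genus <- spacer_rates(cfg$p_genus, cfg$spacer_bias)

  root1 <- sample(BASES, cfg$len_its1, replace = TRUE)
  root2 <- sample(BASES, cfg$len_its2, replace = TRUE)

  rows <- list(); truth_rows <- list(); k <- 0L
  for (g in seq_len(cfg$n_genera)) {
    g1 <- mutate_sites(root1, r_genus[["its1"]])
    g2 <- mutate_sites(root2, r_genus[["its2"]])
    for (s in seq_len(cfg$species_per_genus)) {
      sp1 <- mutate_sites(g1, r_inter[["its1"]])
      sp2 <- mutate_sites(g2, r_inter[["its2"]])
      species <- sprintf("%s species%02d", genera[g], s)
      for (a in seq_len(cfg$accessions_per_species)) {
        k <- k + 1L
        a1 <- mutate_sites(sp1, r_intra[["its1"]])
        a2 <- mutate_sites(sp2, r_intra[["its2"]])
        a58 <- mutate_sites(s58, cfg$p_58s)
        rows[[k]] <- tibble::tibble(
          specimen_id = sprintf("SYN%04d", k),
          taxon_name = species, genus = genera[g],
          its1 = paste(a1, collapse = ""),
          s58 = paste(a58, collapse = ""),
          its2 = paste(a2, collapse = "")
        )
      }
    }
  }
  recs <- dplyr::bind_rows(rows)
  n <- nrow(recs)

  # --- injections ------------------------------------------------------
  n_inject <- cfg$n_false_neg_injected + cfg$n_false_pos_injected +
    cfg$n_major_misid_injected
  if (n_inject > 0 && cfg$species_per_genus < 2) {
    stop("injections require at least 2 species per genus", call. = FALSE)
  }
  if (n_inject > n) stop("injection counts exceed available specimens", call. = FALSE)
  avail <- seq_len(n)
  pick <- function(m) {
    if (length(avail) < m) stop("injection counts exceed available specimens", call. = FALSE)
    idx <- if (length(avail) == 1) avail else sample(avail, m)
    avail <<- setdiff(avail, idx)
    idx
  }
  injected <- tibble::tibble(kind = character(), specimen_a = character(),
                             specimen_b = character())

  if (cfg$n_false_neg_injected > 0) {
    for (i in seq_len(cfg$n_false_neg_injected)) {
      src <- pick(1)
      # overwrite a congeneric, different-species accession with src's sequence
      cand <- which(recs$genus == recs$genus[src] &
                      recs$taxon_name != recs$taxon_name[src] &
                      seq_len(n) %in% avail)
      if (length(cand) == 0) stop("no congeneric target available for false-negative injection", call. = FALSE)
      dst <- if (length(cand) == 1) cand else sample(cand, 1)
      avail <- setdiff(avail, dst)
      recs$its1[dst] <- recs$its1[src]
      recs$s58[dst] <- recs$s58[src]
      recs$its2[dst] <- recs$its2[src]
      injected <- dplyr::add_row(injected, kind = "false_neg",
                                 specimen_a = recs$specimen_id[src],
                                 specimen_b = recs$specimen_id[dst])
    }
  }
  if (cfg$n_false_pos_injected > 0) {
    for (i in seq_len(cfg$n_false_pos_injected)) {
      dst <- pick(1)
      # re-draw this accession from its genus ancestor at the interspecific rate
      sib <- which(recs$taxon_name == recs$taxon_name[dst] & seq_len(n) != dst)
      if (length(sib) == 0) stop("false-positive injection needs >=2 accessions per species", call. = FALSE)
      base1 <- strsplit(recs$its1[sib[1]], "")[[1]]
      base2 <- strsplit(recs$its2[sib[1]], "")[[1]]
      recs$its1[dst] <- paste(mutate_sites(base1, r_inter[["its1"]]), collapse = "")
      recs$its2[dst] <- paste(mutate_sites(base2, r_inter[["its2"]]), collapse = "")
      injected <- dplyr::add_row(injected, kind = "false_pos",
                                 specimen_a = recs$specimen_id[dst],
                                 specimen_b = recs$specimen_id[sib[1]])
    }
  }
  true_species <- recs$taxon_name
  if (cfg$n_major_misid_injected > 0) {
    for (i in seq_len(cfg$n_major_misid_injected)) {
      dst <- pick(1)
      other <- taxonomy$genus[taxonomy$family != families[match(recs$genus[dst], genera)]]
      if (length(other) == 0) stop("major misidentification injection needs >1 family", call. = FALSE)
      new_genus <- if (length(other) == 1) other else sample(other, 1)
      recs$genus[dst] <- new_genus
      recs$taxon_name[dst] <- sprintf("%s species%02d", new_genus, 1L)
      injected <- dplyr::add_row(injected, kind = "major_misid",
                                 specimen_a = recs$specimen_id[dst],
                                 specimen_b = NA_character_)
    }
  }

  # --- metadata: years and PCR success ---------------------------------
  years <- sample(seq(cfg$year_range[1], cfg$year_range[2]), n, replace = TRUE)
  sm <- cfg$success_model
  ref_decade <- decade_of(cfg$year_range[2])
  age_decades <- (ref_decade - decade_of(years)) / 10
  offsets <- rep(0, n)
  if (!is.null(sm$genus_offsets)) {
    hit <- recs$genus %in% names(sm$genus_offsets)
    offsets[hit] <- unlist(sm$genus_offsets)[recs$genus[hit]]
  }
  eta <- sm$intercept + sm$per_decade * age_decades + offsets
  p_success <- stats::plogis(eta)
  pcr <- stats::runif(n) < p_success

  metadata <- tibble::tibble(
    specimen_id = recs$specimen_id,
    taxon_name = recs$taxon_name,
    genus = recs$genus,
    collection_year = years,
    pcr_positive = pcr,
    sequence_positive = pcr,
    its1_end = cfg$len_its1,
    s58_start = cfg$len_its1,
    s58_end = cfg$len_its1 + cfg$len_58s
  )
  seqs <- tibble::tibble(specimen_id = recs$specimen_id,
                         sequence = paste0(recs$its1, recs$s58, recs$its2))
  dataset <- audit_dataset(seqs, metadata, taxonomy)

  truth <- list(
    true_species = tibble::tibble(specimen_id = recs$specimen_id,
                                  true_species = true_species),
    injected = injected,
    regions = tibble::tibble(specimen_id = recs$specimen_id,
                             its1 = recs$its1, s58 = recs$s58, its2 = recs$its2),
    p_success = tibble::tibble(specimen_id = recs$specimen_id,
                               genus = recs$genus,
                               decade = decade_of(years),
                               p_success = p_success)
  )
  list(dataset = dataset, truth = truth)
}

#' Expected pairwise bp difference under the generator model
#'
#' Closed-form companion to [simulate_herbarium()]. Each lineage step with
#' per-site substitution probability p (uniform over the three alternative
#' bases) is a Jukes-Cantor-type channel with eigenvalue 1 - 4p/3; for a
#' path of steps p1..pk between two sequences the per-site mismatch
#' probability is (3/4) (1 - prod(1 - 4 pi / 3)). Intraspecific pairs are
#' separated by two `p_intra` steps, congeneric interspecific pairs by
#' (p_intra, p_inter, p_inter, p_intra), and cross-genus pairs additionally
#' by two `p_genus` steps. Spacer routing (`spacer_bias`) is applied per
#' region and the two spacer expectations summed.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `class` (`intra`, `inter_congeneric`,
#'   `inter_genus`) and `expected_bp`.
#' @export
expected_pair_divergence <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  mismatch_p <- function(steps) 0.75 * (1 - prod(1 - 4 * steps / 3))
  per_region <- function(rate_of) {
    r_intra <- spacer_rates(config$p_intra, config$spacer_bias)
    r_inter <- spacer_rates(config$p_inter, config$spacer_bias)
    r_genus <- spacer_rates(config$p_genus, config$spacer_bias)
    lens <- c(its1 = config$len_its1, its2 = config$len_its2)
    vapply(c("its1", "its2"), function(reg) {
      steps <- rate_of(r_intra[[reg]], r_inter[[reg]], r_genus[[reg]])
      lens[[reg]] * mismatch_p(steps)
    }, numeric(1))
  }
  intra <- sum(per_region(function(a, e, g) c(a, a)))
  inter <- sum(per_region(function(a, e, g) c(a, e, e, a)))
  genus <- sum(per_region(function(a, e, g) c(a, e, g, g, e, a)))
  tibble::tibble(
    class = c("intra", "inter_congeneric", "inter_genus"),
    expected_bp = c(intra, inter, genus)
  )
}

#' Write simulated inputs as plain-text files
#'
#' Emits FASTA, metadata and taxonomy files consumable by
#' [read_barcode_fasta()], [read_specimen_metadata()] and [read_taxonomy()].
#'
#' @param sim Result of [simulate_herbarium()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_simulated_inputs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "sequences.fasta"),
             metadata = file.path(dir, "metadata.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"))
  write_barcode_fasta(sim$dataset, paths[["fasta"]])
  meta <- dplyr::select(sim$dataset$records, "specimen_id", "taxon_name", "genus",
                        "collection_year", "pcr_positive", "sequence_positive",
                        "its1_end", "s58_start", "s58_end")
  readr::write_tsv(meta, paths[["metadata"]], progress = FALSE)
  readr::write_tsv(sim$dataset$taxonomy, paths[["taxonomy"]], progress = FALSE)
  invisible(paths)
}

# Fixed conserved 5.8S-like anchor used both as the generator's shared 5.8S
# and as the default splitting anchor. Synthetic: generated once from a
# fixed RNG stream, not a biological consensus.
default_58s_anchor <- function(len = 160L) {
  rng <- 104729
  out <- character(len)
  for (i in seq_len(len)) {
    rng <- (rng * 48271) %% 2147483647
    out[i] <- BASES[(rng %% 4) + 1]
  }
  paste(out, collapse = "")
}
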