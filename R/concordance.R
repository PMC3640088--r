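#' UPGMA dendrogram of a distance matrix
#'
#' Unweighted pair-group average clustering over the retained distances.
#' Pairs beyond the retention cap are censored at `threshold_bp + 1` by
#' default ("far, magnitude unknown"), or excluded from cluster averages
#' with `missing_policy = "exclude"`. Ties are broken deterministically by
#' the lexicographically smallest member id of the candidate pair. Merge
#' heights are half the merge distance, so the tree is ultrametric with
#' leaf-to-root heights in bp/2 units.
#'
#' @param matrix A `barcode_dist` with at least 2 specimens.
#' @param missing_policy `"censor"` (default) or `"exclude"`.
#' @return An `audit_dendrogram`: list with `merges` (tibble of member
#'   sets), `hclust` (a [stats::hclust] object) and `labels`.
#' @export
upgma <- function(matrix, missing_policy = c("censor", "exclude")) {
  missing_policy <- match.arg(missing_policy)
  policy <- if (missing_policy == "censor") "censor" else "na"
  d <- dense_distance_matrix(matrix, policy)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 specimens", call. = FALSE)
  labels <- rownames(d)

  # active clusters: membership (leaf indices), hclust codes, sizes
  members <- as.list(seq_len(n))
  codes <- as.integer(-seq_len(n))
  sizes <- rep(1L, n)
  smallest <- labels  # lexicographically smallest leaf label per cluster
  cd <- d             # pairwise cluster distances (NA allowed under "exclude")
  np <- base::matrix(1, n, n)  # number of observed leaf pairs behind each entry
  np[is.na(cd)] <- 0
  merge <- base::matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    m <- length(members)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        dij <- cd[i, j]
        if (is.na(dij)) next
        key <- sort(c(smallest[i], smallest[j]))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (key[1] < best$key[1] || (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = dij, key = key)
        }
      }
    }
    if (is.null(best)) stop("distance matrix is disconnected under missing_policy = 'exclude'",
                            call. = FALSE)
    i <- best$i; j <- best$j
    merge[step, ] <- c(codes[i], codes[j])
    height[step] <- best$d / 2

    # unweighted average update over observed leaf pairs
    others <- setdiff(seq_len(m), c(i, j))
    new_d <- rep(NA_real_, m); new_np <- rep(0, m)
    for (k in others) {
      w <- np[i, k] + np[j, k]
      if (w > 0) {
        s <- sum(cd[i, k] * np[i, k], cd[j, k] * np[j, k], na.rm = TRUE)
        new_d[k] <- s / w
      }
      new_np[k] <- w
    }
    members[[i]] <- c(members[[i]], members[[j]])
    codes[i] <- as.integer(step)
    sizes[i] <- sizes[i] + sizes[j]
    smallest[i] <- min(smallest[i], smallest[j])
    cd[i, ] <- new_d; cd[, i] <- new_d
    np[i, ] <- new_np; np[, i] <- new_np
    keep <- setdiff(seq_len(m), j)
    members <- members[keep]; codes <- codes[keep]; sizes <- sizes[keep]
    smallest <- smallest[keep]
    cd <- cd[keep, keep, drop = FALSE]; np <- np[keep, keep, drop = FALSE]
  }

  hc <- structure(list(merge = merge, height = height,
                       order = hclust_order(merge, n), labels = labels,
                       method = "upgma", call = match.call(),
                       dist.method = "bp_diff"), class = "hclust")
  structure(list(hclust = hc, labels = labels), class = "audit_dendrogram")
}

# leaf ordering consistent with the merge matrix (left-to-right traversal)
hclust_order <- function(merge, n) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  as.integer(expand(nrow(merge)))
}

#' @export
print.audit_dendrogram <- function(x, ...) {
  cat("<audit_dendrogram> UPGMA over", length(x$labels), "specimens\n")
  invisible(x)
}

#' Convert an audit dendrogram to an ape phylogeny
#'
#' @param x An `audit_dendrogram`.
#' @return An [ape::as.phylo] tree with branch lengths from merge heights.
#' @export
as_phylo <- function(x) {
  ape::as.phylo(x$hclust)
}

#' Write a dendrogram as Newick
#'
#' @param x An `audit_dendrogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  ape::write.tree(as_phylo(x), file = path)
  invisible(path)
}

# leaf label sets of every internal node, in merge order
clade_leafsets <- function(dend) {
  merge <- dend$hclust$merge
  labels <- dend$labels
  sets <- vector("list", nrow(merge))
  for (k in seq_len(nrow(merge))) {
    grab <- function(code) if (code < 0) labels[-code] else sets[[code]]
    sets[[k]] <- c(grab(merge[k, 1]), grab(merge[k, 2]))
  }
  sets
}

#' Nonmetric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 NMDS via [vegan::monoMDS()] from several seeded random
#' starts; the lowest-stress solution is returned. Pairs beyond the
#' retention cap are excluded from the stress computation by default
#' (treated as missing), or censored at `threshold_bp + 1`.
#'
#' @param matrix A `barcode_dist` with at least 4 specimens.
#' @param dims Embedding dimension.
#' @param n_starts Number of random starts.
#' @param max_iter,tol Iteration cap and convergence tolerance per start.
#' @param seed Integer seed controlling all starts.
#' @param missing_policy `"exclude"` (default) or `"censor"`.
#' @return An `audit_nmds`: list with `coordinates` tibble, `stress`,
#'   `n_iter`, `converged`, and `start_stress` (final stress per start).
#' @export
nmds_ordination <- function(matrix, dims = 2, n_starts = 8, max_iter = 300,
                            tol = 1e-6, seed = 1L,
                            missing_policy = c("exclude", "censor")) {
  missing_policy <- match.arg(missing_policy)
  policy <- if (missing_policy == "exclude") "na" else "censor"
  d <- dense_distance_matrix(matrix, policy)
  if (nrow(d) < 4) stop("need at least 4 specimens", call. = FALSE)
  dd <- stats::as.dist(d)
  best <- NULL
  finals <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    set.seed(derive_seed(seed, s))
    fit <- vegan::monoMDS(dd, k = dims, model = "global", maxit = max_iter,
                          smin = tol, sfgrmin = tol)
    finals[s] <- fit$stress
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- tibble::as_tibble(best$points, .name_repair = ~ paste0("axis", seq_along(.x)))
  coords <- dplyr::bind_cols(tibble::tibble(specimen_id = rownames(d)), coords)
  structure(list(
    coordinates = coords, stress = best$stress, n_iter = best$iters,
    converged = best$icause %in% c(2L, 3L, 4L), start_stress = finals
  ), class = "audit_nmds")
}

#' @export
print.audit_nmds <- function(x, ...) {
  cat(sprintf("<audit_nmds> stress = %.4f (%s after %d iterations)\n",
              x$stress, if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' @rdname nmds_ordination
#' @param x An `audit_nmds`.
#' @export
glance.audit_nmds <- function(x, ...) {
  tibble::tibble(stress = x$stress, n_iter = x$n_iter, converged = x$converged,
                 n_starts = length(x$start_stress))
}

#' @rdname nmds_ordination
#' @export
tidy.audit_nmds <- function(x, ...) {
  x$coordinates
}

#' Plot an NMDS ordination coloured by a taxonomic level
#'
#' @param object An `audit_nmds`.
#' @param dataset Optional [audit_dataset()] supplying taxon labels.
#' @param level `"genus"` or `"family"`.
#' @param ... Unused.
#' @export
autoplot.audit_nmds <- function(object, dataset = NULL, level = "genus", ...) {
  df <- object$coordinates
  if (!is.null(dataset)) {
    df[[level]] <- dataset$records[[level]][match(df$specimen_id,
                                                  dataset$records$specimen_id)]
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2,
                                          colour = .data[[level]]))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = "NMDS1", y = "NMDS2",
                  subtitle = sprintf("stress = %.3f", object$stress)) +
    ggplot2::theme_minimal()
}

#' Flag discordance between dendrogram clustering and taxonomy
#'
#' For each taxon at the chosen level with at least two accessions, finds
#' the smallest dendrogram clade containing all of them. Specimens of
#' other taxa inside that clade are flagged `foreign_inclusion`; when the
#' clade holds more than `dilation_factor` times the taxon's own accession
#' count, all the taxon's members are flagged `split_group` (the taxon
#' scatters over multiple clusters).
#'
#' @param dendrogram An `audit_dendrogram` from [upgma()].
#' @param dataset The [audit_dataset()] the distances came from.
#' @param level `"genus"` or `"family"`.
#' @param dilation_factor Clade-size multiple that triggers `split_group`.
#' @return Tibble with columns `specimen_id`, `level`, `taxon`,
#'   `flag_type`, `context`.
#' @export
concordance_flags <- function(dendrogram, dataset, level = c("genus", "family"),
                              dilation_factor = 3) {
  level <- match.arg(level)
  recs <- dataset$records
  taxon_of <- stats::setNames(recs[[level]], recs$specimen_id)
  sets <- clade_leafsets(dendrogram)
  leaves <- dendrogram$labels
  taxa <- table(taxon_of[leaves])
  taxa <- names(taxa[taxa >= 2])
  flags <- list()
  for (tx in sort(taxa)) {
    own <- leaves[!is.na(taxon_of[leaves]) & taxon_of[leaves] == tx]
    sizes <- vapply(sets, length, integer(1))
    holds <- vapply(sets, function(s) all(own %in% s), logical(1))
    k <- which(holds)[which.min(sizes[which(holds)])]
    clade <- sets[[k]]
    foreign <- setdiff(clade, own)
    ctx <- sprintf("smallest clade with all %d %s accessions spans %d specimens",
                   length(own), tx, length(clade))
    if (length(foreign) > 0) {
      flags[[length(flags) + 1]] <- tibble::tibble(
        specimen_id = sort(foreign), level = level, taxon = tx,
        flag_type = "foreign_inclusion", context = ctx)
    }
    if (length(clade) > dilation_factor * length(own)) {
      flags[[length(flags) + 1]] <- tibble::tibble(
        specimen_id = sort(own), level = level, taxon = tx,
        flag_type = "split_group", context = ctx)
    }
  }
  if (length(flags) == 0) {
    return(tibble::tibble(specimen_id = character(), level = character(),
                          taxon = character(), flag_type = character(),
                          context = character()))
  }
  dplyr::arrange(dplyr::bind_rows(flags), .data$taxon, .data$flag_type,
                 .data$specimen_id)
}

#' Per-taxon coherence of an ordination
#'
#' For each taxon with at least two accessions: mean within-taxon point
#' distance divided by the mean distance from the taxon's points to all
#' other points. Lower is tighter; values near 1 indicate no clustering.
#'
#' @param ordination An `audit_nmds`.
#' @param dataset The originating [audit_dataset()].
#' @param level `"genus"` or `"family"`.
#' @return Tibble with `taxon`, `n`, `coherence`, ranked ascending.
#' @export
ordination_coherence <- function(ordination, dataset, level = c("genus", "family")) {
  level <- match.arg(level)
  co <- ordination$coordinates
  taxon <- dataset$records[[level]][match(co$specimen_id,
                                          dataset$records$specimen_id)]
  pts <- as.matrix(co[, grep("^axis", names(co))])
  dmat <- as.matrix(stats::dist(pts))
  out <- purrr::map(unique(taxon[!is.na(taxon)]), function(tx) {
    inside <- which(taxon == tx)
    if (length(inside) < 2) return(NULL)
    outside <- which(taxon != tx | is.na(taxon))
    within <- mean(dmat[inside, inside][upper.tri(diag(length(inside)))])
    between <- if (length(outside) > 0) mean(dmat[inside, outside, drop = FALSE]) else NA_real_
    tibble::tibble(taxon = tx, n = length(inside), coherence = within / between)
  })
  dplyr::arrange(dplyr::bind_rows(purrr::compact(out)), .data$coherence)
}
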