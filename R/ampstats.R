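#' Build a contingency table of amplification outcomes
#'
#' Tallies specimens into a factor-by-outcome table, with rows defined by
#' collection decade or genus and columns `positive`/`negative`. Records
#' missing the factor or the outcome are excluded with a reported count.
#' An optional stratification yields one table per stratum.
#'
#' @param records Specimen records tibble (or an [audit_dataset()]).
#' @param row_factor `"decade"` or `"genus"`.
#' @param outcome `"pcr_positive"` or `"sequence_positive"`.
#' @param strata Optional named list of inclusive year ranges, e.g.
#'   `list("1980s-1990s" = c(1980, 1999), "2000s" = c(2000, 2009))`.
#' @return A `contingency_table` (observed count matrix with attributes),
#'   or a named list of them when `strata` is given.
#' @export
build_contingency <- function(records, row_factor = c("decade", "genus"),
                              outcome = c("pcr_positive", "sequence_positive"),
                              strata = NULL) {
  if (inherits(records, "audit_dataset")) records <- records$records
  row_factor <- match.arg(row_factor)
  outcome <- match.arg(outcome)
  if (!is.null(strata)) {
    out <- purrr::imap(strata, function(rng, nm) {
      sub <- dplyr::filter(records, !is.na(.data$collection_year),
                           .data$collection_year >= rng[1],
                           .data$collection_year <= rng[2])
      build_contingency(sub, row_factor, outcome)
    })
    return(out)
  }
  fac <- switch(row_factor,
                decade = decade_of(records$collection_year),
                genus = records$genus)
  oc <- records[[outcome]]
  keep <- !is.na(fac) & !is.na(oc)
  n_excluded <- sum(!keep)
  fac <- fac[keep]; oc <- oc[keep]
  levels_row <- sort(unique(fac))
  if (length(levels_row) < 2) {
    stop("need at least 2 non-empty rows for factor '", row_factor, "'", call. = FALSE)
  }
  obs <- base::matrix(0L, length(levels_row), 2,
                      dimnames = list(as.character(levels_row),
                                      c("positive", "negative")))
  tab <- table(factor(fac, levels = levels_row), factor(oc, levels = c(TRUE, FALSE)))
  obs[, ] <- as.integer(tab)
  structure(obs, class = c("contingency_table", "matrix"),
            row_factor = row_factor, outcome = outcome,
            n_excluded = n_excluded)
}

#' Pearson chi-square test with Haberman adjusted-residual post-hoc
#'
#' Computes the omnibus Pearson chi-square (no continuity correction by
#' default), cell-wise standardized adjusted residuals
#' \eqn{r_{ij} = (O_{ij}-E_{ij}) / \sqrt{E_{ij}(1-n_{i.}/n)(1-n_{.j}/n)}},
#' each cell's relative contribution \eqn{((O-E)^2/E)/\chi^2} to the
#' omnibus statistic, and flags cells whose adjusted residual exceeds the
#' standard-normal critical value at a Bonferroni-corrected alpha. The
#' Bonferroni denominator is the number of cells (rows x columns), so a
#' 3x2 table tests each cell at `alpha / 6`.
#'
#' @param table A `contingency_table` or plain count matrix (>= 2x2).
#' @param alpha Family-wise significance level.
#' @param correct Apply the Yates continuity correction to the omnibus
#'   statistic (2x2 only).
#' @return A `posthoc_result` list: `observed`, `expected`, `chi2`, `df`,
#'   `p_value`, `adjusted_residuals`, `cell_contribution`,
#'   `alpha_corrected`, `significant`.
#' @export
chi_square_posthoc <- function(table, alpha = 0.05, correct = FALSE) {
  obs <- unclass(table)
  if (nrow(obs) < 2 || ncol(obs) < 2) stop("table must be at least 2x2", call. = FALSE)
  n <- sum(obs)
  rows <- rowSums(obs); cols <- colSums(obs)
  if (any(rows == 0) || any(cols == 0)) stop("zero marginal in contingency table", call. = FALSE)
  expected <- outer(rows, cols) / n
  if (any(expected <= 1)) {
    warning("expected count <= 1 in cell(s): ",
            paste(which(expected <= 1), collapse = ", "), call. = FALSE)
  }
  suppressWarnings(
    ct <- stats::chisq.test(obs, correct = correct)
  )
  chi2 <- unname(ct$statistic)
  contrib <- (obs - expected)^2 / expected / chi2
  adj <- (obs - expected) / sqrt(expected * outer(1 - rows / n, 1 - cols / n))
  n_contrasts <- length(obs)
  alpha_corrected <- alpha / n_contrasts
  crit <- stats::qnorm(1 - alpha_corrected / 2)
  structure(list(
    observed = obs, expected = expected,
    chi2 = chi2, df = unname(ct$parameter), p_value = unname(ct$p.value),
    adjusted_residuals = adj,
    cell_contribution = contrib,
    alpha = alpha, alpha_corrected = alpha_corrected,
    n_contrasts = n_contrasts,
    significant = abs(adj) > crit
  ), class = "posthoc_result")
}

#' @export
print.posthoc_result <- function(x, ...) {
  cat(sprintf("<posthoc_result> chi2 = %.4g, df = %d, p = %.3g\n",
              x$chi2, x$df, x$p_value))
  cat(sprintf("  Bonferroni: alpha %.3g / %d contrasts = %.3g\n",
              x$alpha, x$n_contrasts, x$alpha_corrected))
  invisible(x)
}

#' @rdname chi_square_posthoc
#' @param x A `posthoc_result`.
#' @param ... Unused.
#' @export
tidy.posthoc_result <- function(x, ...) {
  grid <- expand.grid(row = rownames(x$observed), col = colnames(x$observed),
                      stringsAsFactors = FALSE)
  tibble::tibble(
    row = grid$row, col = grid$col,
    observed = as.vector(x$observed), expected = as.vector(x$expected),
    adjusted_residual = as.vector(x$adjusted_residuals),
    cell_contribution = as.vector(x$cell_contribution),
    significant = as.vector(x$significant)
  )
}

#' @rdname chi_square_posthoc
#' @export
glance.posthoc_result <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, df = x$df, p_value = x$p_value,
                 n = sum(x$observed), alpha_corrected = x$alpha_corrected)
}

#' Age-stratified taxon analysis of amplification success
#'
#' Builds one genus-by-outcome table per age stratum and reports, per
#' genus and stratum, the positive/negative counts and adjusted residual
#' of the positive cell, with significance marked at both the raw alpha
#' and the Bonferroni-corrected alpha.
#'
#' @param records Specimen records tibble (or an [audit_dataset()]).
#' @param strata Named list of inclusive year ranges; default splits
#'   1980s-1990s versus 2000s collections.
#' @param outcome Outcome column.
#' @param alpha Family-wise significance level.
#' @return A `stratified_report`: list with `tables` (per-stratum
#'   `posthoc_result`s) and `summary` (tidy per-genus rows).
#' @export
stratified_report <- function(records,
                              strata = list("1980s-1990s" = c(1980, 1999),
                                            "2000s" = c(2000, 2009)),
                              outcome = "pcr_positive", alpha = 0.05) {
  tabs <- build_contingency(records, "genus", outcome, strata = strata)
  results <- purrr::map(tabs, chi_square_posthoc, alpha = alpha)
  crit_raw <- stats::qnorm(1 - alpha / 2)
  summary <- purrr::imap(results, function(res, nm) {
    tidy(res) |>
      dplyr::filter(.data$col == "positive") |>
      dplyr::transmute(
        stratum = nm, genus = .data$row,
        positive = .data$observed,
        negative = res$observed[cbind(.data$row, "negative")],
        adjusted_residual = .data$adjusted_residual,
        significant_raw = abs(.data$adjusted_residual) > crit_raw,
        significant_bonferroni = .data$significant
      )
  }) |> dplyr::bind_rows()
  structure(list(tables = results, summary = summary, alpha = alpha),
            class = "stratified_report")
}

#' @export
print.stratified_report <- function(x, ...) {
  cat("<stratified_report>\n")
  for (nm in names(x$tables)) {
    r <- x$tables[[nm]]
    cat(sprintf("  %s: chi2 = %.3g (df %d, p = %.3g), corrected alpha = %.3g\n",
                nm, r$chi2, r$df, r$p_value, r$alpha_corrected))
  }
  invisible(x)
}
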