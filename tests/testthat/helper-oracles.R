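# Independent oracles used to freeze expected values. These deliberately do
# not share code with the package implementation.

# --- exhaustive global alignment enumeration --------------------------------
# Enumerates every global alignment (full monotone path); every gap run of
# length k, terminal or not, costs open + k * ext in the score. Differences
# = substitution columns + internal gap columns; terminal gap runs are
# excluded from the count only. Returns the optimal score and the set of
# difference counts achieved by score-optimal alignments.
oracle_align <- function(a, b, match = 1, mismatch = -1, open = 5, ext = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  la <- length(A); lb <- length(B)
  best <- -Inf; diffs <- integer()
  # cols: 0 match, 1 substitution, 2 gap in b, 3 gap in a
  finish <- function(score, cols) {
    if (score < best - 1e-9) return(invisible())
    lo <- 1; hi <- length(cols)
    while (lo <= hi && cols[lo] >= 2) lo <- lo + 1
    while (hi >= lo && cols[hi] >= 2) hi <- hi - 1
    core <- if (lo > hi) integer() else cols[lo:hi]
    nd <- sum(core >= 1)  # substitutions + internal gap columns
    if (score > best + 1e-9) { best <<- score; diffs <<- nd }
    else diffs <<- unique(c(diffs, nd))
  }
  rec <- function(i, j, score, cols, last) {
    if (i > la && j > lb) return(finish(score, cols))
    if (i <= la && j <= lb) {
      hit <- A[i] == B[j]
      rec(i + 1, j + 1, score + if (hit) match else mismatch,
          c(cols, if (hit) 0L else 1L), "pair")
    }
    if (i <= la) {
      pen <- if (last == "gap_b") ext else open + ext
      rec(i + 1, j, score - pen, c(cols, 2L), "gap_b")
    }
    if (j <= lb) {
      pen <- if (last == "gap_a") ext else open + ext
      rec(i, j + 1, score - pen, c(cols, 3L), "gap_a")
    }
  }
  rec(1, 1, 0, integer(), "start")
  list(score = best, diffs = sort(diffs))
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# --- naive UPGMA -----------------------------------------------------------
# Cluster distances recomputed each round as the mean over all ORIGINAL leaf
# pairs (the defining property of unweighted average linkage), ties broken by
# the lexicographically smallest pair of cluster-minimum labels. Returns
# merge heights and the leaf partition at each merge.
oracle_upgma <- function(d) {
  labels <- rownames(d)
  clusters <- as.list(labels)
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
      if (is.null(best) || dd < best$d - 1e-12 ||
          (abs(dd - best$d) <= 1e-12 &&
           (key[1] < best$key[1] || (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, d = dd, key = key)
      }
    }
    heights <- c(heights, best$d / 2)
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1]] <- merged
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# random symmetric distance matrix with labelled rows
random_dist_matrix <- function(n, max_d = 50) {
  ids <- sprintf("S%02d", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  v <- runif(n * (n - 1) / 2, 0, max_d)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  m
}

# Pearson r by the raw sum formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# score + per-column diff of the package aligner (internal entry point)
align_pair_score <- function(a, b) {
  r <- barcodeaudit:::align_pair_cpp(a, b, 1, -1, 5, 2)
  list(score = r$score, diff = r$n_sub + r$n_gap_cols)
}
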