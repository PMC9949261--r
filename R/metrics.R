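#' Convert counts to relative frequencies
#'
#' @param counts Non-negative vector with a positive sum.
#' @return Probability vector `counts / sum(counts)`.
#' @examples
#' to_frequencies(c(30, 70))
#' @export
to_frequencies <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  s <- sum(counts)
  if (s <= 0) stop("counts sum to zero", call. = FALSE)
  counts / s
}

check_probs <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("not a probability vector (must be non-negative, sum to 1 within ",
         "1e-9)", call. = FALSE)
  }
  p
}

#' Shannon diversity of clone frequencies
#'
#' `H = -sum(p log p)` with `0 log 0 = 0`; natural log (nats) by default,
#' base 2 available via `base`.
#'
#' @param p Probability vector of clone frequencies.
#' @param base Logarithm base (default `exp(1)`).
#' @return Entropy in the chosen base; 0 for a monoclonal repertoire,
#'   `log(R)` for `R` equally frequent clones.
#' @export
shannon_diversity <- function(p, base = exp(1)) {
  p <- check_probs(p)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Clonality (normalized-entropy complement)
#'
#' `1 - H / log(R)` for `R` clones: 0 for a perfectly even repertoire, 1 as
#' the repertoire approaches monoclonality. Invariant to the log base. A
#' single-clone repertoire is degenerate (the normalizer is 0) and returns 1
#' with a warning.
#'
#' @param p Probability vector of clone frequencies.
#' @return Clonality in `[0, 1]`.
#' @export
clonality <- function(p) {
  p <- check_probs(p)
  if (length(p) < 2) {
    warning("single-clone repertoire: clonality is degenerate, returning 1",
            call. = FALSE)
    return(1)
  }
  1 - shannon_diversity(p) / log(length(p))
}

#' Summed frequency of hyperexpanded clones
#'
#' @param p Probability vector of clone frequencies.
#' @param threshold Frequency above which a clone counts as hyperexpanded
#'   (default 0.01).
#' @return Sum of `p` over clones with `p > threshold`.
#' @export
hyperexpanded_fraction <- function(p, threshold = 0.01) {
  p <- check_probs(p)
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)", call. = FALSE)
  }
  sum(p[p > threshold])
}

#' Frequency of the most abundant clone
#'
#' @param table A clonotype table.
#' @param use_normalized Use `normalized_count` instead of `raw_count`.
#' @return The dominant clone's relative frequency (ties give the shared
#'   frequency).
#' @export
dominant_clone_proportion <- function(table, use_normalized = FALSE) {
  counts <- metric_counts(table, use_normalized)
  max(to_frequencies(counts))
}

metric_counts <- function(table, use_normalized) {
  table <- validate_clonotype_table(table)
  if (nrow(table) == 0) stop("empty clonotype table", call. = FALSE)
  if (use_normalized) {
    if (!"normalized_count" %in% names(table) ||
        anyNA(table$normalized_count)) {
      stop("table has no filled normalized_count column; run ",
           "normalize_clonotypes() first", call. = FALSE)
    }
    table$normalized_count
  } else {
    table$raw_count
  }
}

#' One-row repertoire summary
#'
#' Computes the standard repertoire metrics from a clonotype table's raw or
#' normalized counts: clone richness, Shannon diversity, clonality, maximum
#' clonal frequency, and the hyperexpanded-clone fraction.
#'
#' @param table A clonotype table.
#' @param use_normalized Use normalized counts (default `FALSE`).
#' @param threshold Hyperexpanded-clone frequency threshold.
#' @param base Log base for the Shannon index.
#' @return A one-row tibble: `n_clones`, `shannon_h`, `clonality`,
#'   `max_clonal_freq`, `hyperexpanded_fraction`, `threshold`.
#' @export
repertoire_summary <- function(table, use_normalized = FALSE,
                               threshold = 0.01, base = exp(1)) {
  p <- to_frequencies(metric_counts(table, use_normalized))
  tibble::tibble(
    n_clones = length(p),
    shannon_h = shannon_diversity(p, base = base),
    clonality = if (length(p) >= 2) clonality(p) else 1,
    max_clonal_freq = max(p),
    hyperexpanded_fraction = hyperexpanded_fraction(p, threshold),
    threshold = threshold)
}

#' Tabulate clonotype dropout across replicates
#'
#' Counts, for each `k`, the distinct clonotypes (keyed by exact
#' `(cdr3_nt, v_name, j_name)`) detected in exactly `k` of the `n`
#' replicates. Detection dropout across technical replicates reflects
#' sampling stochasticity at finite sequencing depth. With `top_fraction`
#' the tabulation is restricted to the union of each replicate's most
#' frequent clones (fraction of its clone list by count rank), focusing the
#' tabulation on abundant clones; detection still means presence anywhere
#' in a replicate.
#'
#' @param replicates A list of >= 2 clonotype tables.
#' @param top_fraction Optional fraction in (0, 1] selecting each
#'   replicate's top clones by raw count.
#' @return A tibble `k`, `n_clones` for `k = 1..n` (number of replicates).
#' @export
dropout_table <- function(replicates, top_fraction = NULL) {
  if (!is.list(replicates) || length(replicates) < 2) {
    stop("need a list of at least 2 replicate tables", call. = FALSE)
  }
  keys <- purrr::map(replicates, function(t) {
    t <- validate_clonotype_table(t)
    unique(paste(t$cdr3_nt, t$v_name, t$j_name, sep = "|"))
  })
  if (!is.null(top_fraction)) {
    if (top_fraction <= 0 || top_fraction > 1) {
      stop("top_fraction must be in (0, 1]", call. = FALSE)
    }
    top <- purrr::map(replicates, function(t) {
      t <- validate_clonotype_table(t)
      t <- t[order(-t$raw_count), ]
      n_top <- max(1L, ceiling(top_fraction * nrow(t)))
      unique(paste(t$cdr3_nt[seq_len(n_top)], t$v_name[seq_len(n_top)],
                   t$j_name[seq_len(n_top)], sep = "|"))
    })
    universe <- unique(unlist(top))
    keys <- purrr::map(keys, ~ intersect(.x, universe))
  }
  presence <- table(unlist(keys))
  n <- length(replicates)
  tibble::tibble(
    k = seq_len(n),
    n_clones = vapply(seq_len(n), function(k) sum(presence == k), integer(1)))
}
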