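#' Reshape per-pair values into a V x J matrix
#'
#' @param values Numeric vector in pair-index order, or a tibble carrying a
#'   per-pair column (`m_rel`, `total`, `count`, or `m_hat` -- the first one
#'   present is used).
#' @param panel The `primer_panel` defining the grid.
#' @return A `n_V x n_J` numeric matrix with primer names as dimnames;
#'   `vj_table(x)[v, j]` is `x[pair_index(panel, v, j)]`.
#' @export
vj_table <- function(values, panel) {
  stopifnot(inherits(panel, "primer_panel"))
  if (is.data.frame(values)) {
    col <- intersect(c("m_rel", "total", "count", "m_hat", "factor"),
                     names(values))
    if (!length(col)) stop("no per-pair value column found", call. = FALSE)
    values <- values[[col[1]]]
  }
  if (length(values) != n_pairs(panel)) {
    stop("values must have one entry per primer pair (",
         n_pairs(panel), ")", call. = FALSE)
  }
  matrix(values, nrow = length(panel$v_names),
         ncol = length(panel$j_names), byrow = TRUE,
         dimnames = list(panel$v_names, panel$j_names))
}

#' Signed Pearson residuals of a V x J count table
#'
#' Measures departure of primer-pair efficiencies from V x J independence.
#' Expected counts are `E = row total x column total / grand total` and the
#' residual is `(O - E) / sqrt(E)`; positive residuals mark primer pairs
#' over-represented relative to the separable expectation. The sum of
#' squared residuals is the classic contingency chi-squared statistic, and a
#' rank-one table (exactly separable efficiencies) gives all-zero residuals.
#'
#' Rows or columns that are entirely zero carry no information about
#' dependence and are dropped with a warning.
#'
#' @param O Non-negative `n_V x n_J` matrix of observed values (typically
#'   pooled ST means reshaped by [vj_table()]).
#' @return An object of class `vj_residuals`: list with `values` (residual
#'   matrix), `observed`, `expected`, `chi_square`, and clustering orders
#'   `row_order`, `col_order` (identity until [cluster_order()] is called).
#' @export
pearson_residuals <- function(O) {
  O <- as.matrix(O)
  if (any(O < 0) || anyNA(O)) {
    stop("observed table must be non-negative", call. = FALSE)
  }
  if (sum(O) == 0) stop("zero grand total", call. = FALSE)
  zr <- rowSums(O) == 0
  zc <- colSums(O) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " all-zero row(s) and ", sum(zc),
            " all-zero column(s)", call. = FALSE)
    O <- O[!zr, !zc, drop = FALSE]
  }
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  R <- (O - E) / sqrt(E)
  structure(list(values = R, observed = O, expected = E,
                 chi_square = sum(R^2),
                 row_order = seq_len(nrow(R)),
                 col_order = seq_len(ncol(R))),
            class = "vj_residuals")
}

#' @export
print.vj_residuals <- function(x, ...) {
  cat("<vj_residuals> ", nrow(x$values), " x ", ncol(x$values),
      ", chi-square = ", signif(x$chi_square, 5), "\n", sep = "")
  invisible(x)
}

#' Hierarchically cluster residual rows and columns
#'
#' Orders V primers and J primers so that groups with similar dependence
#' patterns sit adjacent in a heatmap (average linkage on Euclidean
#' distances between residual rows/columns; deterministic given the input).
#'
#' @param res A `vj_residuals` object (>= 2 rows and columns).
#' @return The object with `row_order` and `col_order` replaced by the
#'   dendrogram leaf orders.
#' @export
cluster_order <- function(res) {
  stopifnot(inherits(res, "vj_residuals"))
  if (nrow(res$values) < 2 || ncol(res$values) < 2) {
    stop("need at least 2 rows and 2 columns to cluster", call. = FALSE)
  }
  res$row_order <- stats::hclust(stats::dist(res$values),
                                 method = "average")$order
  res$col_order <- stats::hclust(stats::dist(t(res$values)),
                                 method = "average")$order
  res
}

#' Tidy residuals into long form
#'
#' @param x A `vj_residuals` object.
#' @param ... Unused.
#' @return A tibble `v_name`, `j_name`, `observed`, `expected`, `residual`.
#' @method tidy vj_residuals
#' @export
tidy.vj_residuals <- function(x, ...) {
  long <- expand.grid(v_name = rownames(x$values),
                      j_name = colnames(x$values),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tibble::as_tibble(dplyr::mutate(
    long,
    observed = as.vector(x$observed),
    expected = as.vector(x$expected),
    residual = as.vector(x$values)))
}
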