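#' Scaling factors from a batch of ST counts
#'
#' The batch-mean scaling factor for template `i` is `SF_i = C_i. / C..`:
#' its mean count across the batch's samples divided by the grand mean over
#' all templates. Factors average exactly 1 by construction, and dividing a
#' template's counts by its factor removes that primer pair's amplification
#' bias while preserving the batch's ST grand total exactly.
#'
#' Templates with all-zero counts get no factor (their rows are absent from
#' the result, with a warning): a zero factor would be meaningless and
#' silently passing raw counts through would corrupt downstream metrics.
#'
#' @param x An `st_counts` tibble.
#' @return A tibble of class `scaling_factors`: `pair`, `v_name`, `j_name`,
#'   `factor`, with attribute `kind = "batch_mean"`.
#' @export
batch_scaling_factors <- function(x) {
  stopifnot(inherits(x, "st_counts"))
  m <- count_matrix(x)
  if (all(m == 0)) stop("all-zero ST count matrix", call. = FALSE)
  row_means <- unname(rowMeans(m))
  sf <- row_means / mean(row_means)
  new_scaling_factors(st_panel(x), sf, "batch_mean",
                      provenance = attr(x, "batch_id"))
}

#' Scaling factors from NB mean estimates
#'
#' The NB-mean scaling factor for template `i` is `m_i / m_bar`, the
#' estimated NB mean relative to the panel average. Because the MLE of each
#' mean is the arithmetic batch mean, NB-mean factors computed from a single
#' batch are numerically identical to [batch_scaling_factors()]; their value
#' is that they can be estimated once from ST-only data (or pooled batches)
#' and applied to samples sequenced without any spike-ins.
#'
#' @param fit An `nb_panel_fit` (see [fit_panel()]) or a `combined_means`
#'   tibble (see [pool_batches()]).
#' @return A `scaling_factors` tibble with attribute `kind = "nb_mean"`.
#' @export
nb_scaling_factors <- function(fit) {
  if (inherits(fit, "nb_panel_fit")) {
    panel <- fit$panel
    f <- fit$per_st$m_hat / fit$m_bar
    prov <- paste(fit$batch_ids, collapse = ",")
  } else if (inherits(fit, "combined_means")) {
    panel <- attr(fit, "panel")
    f <- fit$m_rel
    prov <- "combined"
  } else {
    stop("expected an nb_panel_fit or combined_means object", call. = FALSE)
  }
  new_scaling_factors(panel, f, "nb_mean", provenance = prov)
}

new_scaling_factors <- function(panel, f, kind, provenance = NA_character_) {
  out <- dplyr::mutate(pair_names(panel), factor = as.numeric(f))
  zero <- !is.finite(out$factor) | out$factor <= 0
  if (any(zero)) {
    warning(sum(zero), " template(s) without a usable mean have no scaling ",
            "factor", call. = FALSE)
    out <- out[!zero, ]
  }
  structure(out, class = c("scaling_factors", class(out)),
            panel = panel, kind = kind, provenance = provenance)
}

#' Normalize per-primer-pair totals
#'
#' Divides each primer-pair total by its scaling factor:
#' `C'_i = C_i / SF_i`. Applied with batch-mean factors to the ST matrix
#' that generated them, the ST grand total is conserved exactly.
#'
#' @param totals A tibble from [clonotype_primer_totals()] (columns `pair`,
#'   `total`), or a bare numeric vector in pair-index order.
#' @param sf A `scaling_factors` tibble.
#' @return A tibble `pair`, `v_name`, `j_name`, `total`, `factor`,
#'   `norm_total` (zero totals stay zero; a nonzero total without a factor
#'   is an error).
#' @export
normalize_primer_totals <- function(totals, sf) {
  stopifnot(inherits(sf, "scaling_factors"))
  panel <- attr(sf, "panel")
  if (!is.data.frame(totals)) {
    if (length(totals) != n_pairs(panel)) {
      stop("totals length must match the panel", call. = FALSE)
    }
    totals <- dplyr::mutate(pair_names(panel), total = as.numeric(totals))
  }
  out <- dplyr::left_join(totals, sf[c("pair", "factor")], by = "pair")
  missing_f <- is.na(out$factor) & out$total > 0
  if (any(missing_f)) {
    bad <- out[missing_f, ]
    stop("no scaling factor for primer pair(s) with nonzero totals: ",
         paste(utils::head(paste(bad$v_name, bad$j_name, sep = "|"), 5),
               collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(out, norm_total = ifelse(.data$total == 0, 0,
                                         .data$total / .data$factor))
}

#' Normalize clonotype counts by primer-pair scaling factors
#'
#' Each primer-pair total is normalized by its scaling factor, and the
#' normalized total is redistributed to the pair's clonotypes in proportion
#' to their raw counts: a clonotype holding proportion `p` of its pair's raw
#' total receives `p` of the normalized total. Within-pair proportions are
#' therefore unchanged exactly (the operation reduces to
#' `raw_count / SF_i`); across pairs, relative abundances shift by the
#' factor ratios, removing the amplification bias. Normalized counts are
#' real-valued, not re-rounded.
#'
#' @param table A clonotype table.
#' @param sf A `scaling_factors` tibble covering every pair present in
#'   `table`.
#' @return The table with a `normalized_count` column filled; row order
#'   preserved.
#' @export
normalize_clonotypes <- function(table, sf) {
  stopifnot(inherits(sf, "scaling_factors"))
  panel <- attr(sf, "panel")
  table <- validate_clonotype_table(table, panel)
  idx <- pair_index(panel, table$v_name, table$j_name)
  f <- sf$factor[match(idx, sf$pair)]
  bad <- is.na(f) & table$raw_count > 0
  if (any(bad)) {
    stop("no scaling factor for primer pair(s) carrying clonotype counts: ",
         paste(unique(utils::head(
           paste(table$v_name[bad], table$j_name[bad], sep = "|"), 5)),
           collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(table,
                normalized_count = ifelse(.data$raw_count == 0, 0,
                                          .data$raw_count / f))
}

#' Within-sample spread before and after normalization
#'
#' Quantifies how much template-to-template variation normalization removes.
#' Per sample it reports the Q3/Q1 fold ratio and the coefficient of
#' variation across template counts, raw and normalized (type-7 quantiles).
#' It also reports the panel-wide IQR contrast: the median (across samples)
#' IQR of log relative frequencies over templates -- template-to-template
#' variation, i.e. amplification bias -- against the median (across
#' templates) IQR over samples -- sample-to-sample variation. A large fold
#' difference between the two says the observed count differences are
#' dominated by primer-pair bias, not noise.
#'
#' @param x An `st_counts` tibble.
#' @param sf A `scaling_factors` tibble on the same panel.
#' @return A list of class `spread_report` with
#'   \describe{
#'     \item{per_sample}{tibble `sample`, `q3q1_raw`, `q3q1_norm`,
#'       `cv_raw`, `cv_norm`,}
#'     \item{iqr_contrast}{one-row tibble `median_iqr_template`,
#'       `median_iqr_sample`, `fold` (computed on raw counts, log relative
#'       frequencies).}
#'   }
#' @export
spread_report <- function(x, sf) {
  stopifnot(inherits(x, "st_counts"), inherits(sf, "scaling_factors"))
  m <- count_matrix(x)
  f <- sf$factor[match(seq_len(nrow(m)), sf$pair)]
  keep <- !is.na(f)
  norm <- m[keep, , drop = FALSE] / f[keep]
  q31 <- function(mat) {
    apply(mat, 2, function(col) {
      q <- stats::quantile(col, c(0.25, 0.75), type = 7, names = FALSE)
      q[2] / q[1]
    })
  }
  cv <- function(mat) apply(mat, 2, function(col) stats::sd(col) / mean(col))
  per_sample <- tibble::tibble(
    sample = colnames(m),
    q3q1_raw = unname(q31(m[keep, , drop = FALSE])),
    q3q1_norm = unname(q31(norm)),
    cv_raw = unname(cv(m[keep, , drop = FALSE])),
    cv_norm = unname(cv(norm)))
  rel <- sweep(m, 2, colSums(m), "/")
  logrel <- log(rel[keep, , drop = FALSE])
  logrel[!is.finite(logrel)] <- NA
  iqr <- function(v) diff(stats::quantile(v, c(0.25, 0.75), type = 7,
                                          na.rm = TRUE, names = FALSE))
  iqr_template <- stats::median(apply(logrel, 2, iqr))
  iqr_sample <- stats::median(apply(logrel, 1, iqr))
  structure(list(
    per_sample = per_sample,
    iqr_contrast = tibble::tibble(
      median_iqr_template = iqr_template,
      median_iqr_sample = iqr_sample,
      fold = iqr_template / iqr_sample)),
    class = "spread_report")
}

#' @export
print.spread_report <- function(x, ...) {
  cat("<spread_report> ", nrow(x$per_sample), " samples\n", sep = "")
  cat("  max Q3/Q1 raw ", signif(max(x$per_sample$q3q1_raw), 4),
      " -> normalized ", signif(max(x$per_sample$q3q1_norm), 4), "\n",
      sep = "")
  cat("  template-to-template vs sample-to-sample IQR fold: ",
      signif(x$iqr_contrast$fold, 4), "\n", sep = "")
  invisible(x)
}
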