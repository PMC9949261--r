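#' Fit a negative binomial to one template's replicate counts
#'
#' The NB is parameterized by its mean `m` and dispersion `d`, with
#' `E(C) = m` and `var(C) = m + d m^2`; `d = 0` is the Poisson boundary.
#' For i.i.d. replicate counts the maximum-likelihood estimate of `m` is the
#' arithmetic mean, and `d` is estimated by maximizing the profile
#' log-likelihood in `d` on `[0, d_max]` with a bounded scalar optimizer;
#' under-dispersed data clip to `d = 0`.
#'
#' @param counts Non-negative integer vector, length >= 2, not all zero.
#' @param d_max Upper bound of the dispersion search (default 10).
#' @return A one-row tibble: `m_hat`, `d_hat`, `n`, `loglik`.
#' @examples
#' fit_nb_single(c(7, 7, 7, 7))   # zero variance: d_hat = 0
#' fit_nb_single(c(10, 30))       # m_hat = 20
#' @export
fit_nb_single <- function(counts, d_max = 10) {
  counts <- as.numeric(counts)
  if (length(counts) < 2) {
    stop("need at least 2 replicate counts", call. = FALSE)
  }
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  if (all(counts == 0)) {
    stop("degenerate input: all counts are zero", call. = FALSE)
  }
  m <- mean(counts)
  ll <- function(d) {
    if (d <= 0) sum(stats::dpois(counts, m, log = TRUE))
    else sum(stats::dnbinom(counts, mu = m, size = 1 / d, log = TRUE))
  }
  ll0 <- ll(0)
  if (stats::var(counts) <= m) {
    d_hat <- 0
    loglik <- ll0
  } else {
    opt <- stats::optimize(ll, c(1e-12, d_max), maximum = TRUE, tol = 1e-8)
    if (opt$objective > ll0) {
      d_hat <- opt$maximum
      loglik <- opt$objective
    } else {
      d_hat <- 0
      loglik <- ll0
    }
  }
  tibble::tibble(m_hat = m, d_hat = d_hat, n = length(counts),
                 loglik = loglik)
}

#' Fit the NB panel model to an ST count matrix
#'
#' Fits a separate NB to each template's replicate counts (mean = row mean,
#' dispersion by profile MLE) and takes the common dispersion as the median
#' of the per-template dispersion estimates. Templates with all-zero rows
#' are excluded from the common dispersion and from the panel mean `m_bar`
#' with a warning; they receive no scaling factor downstream.
#'
#' @param x An `st_counts` tibble with >= 2 sample columns.
#' @param d_max Dispersion search upper bound.
#' @return An object of class `nb_panel_fit`: a list with `per_st` (tibble
#'   `pair`, `v_name`, `j_name`, `m_hat`, `d_hat`, `n`, `loglik`),
#'   `common_dispersion` (median of `d_hat`), `m_bar` (mean of `m_hat`),
#'   `batch_ids`, and `panel`.
#' @export
fit_panel <- function(x, d_max = 10) {
  stopifnot(inherits(x, "st_counts"))
  m <- count_matrix(x)
  if (ncol(m) < 2) {
    stop("need at least 2 samples to fit dispersions", call. = FALSE)
  }
  zero <- rowSums(m) == 0
  if (any(zero)) {
    warning(sum(zero), " template(s) with all-zero counts excluded from ",
            "the common dispersion and m_bar", call. = FALSE)
  }
  fits <- purrr::map(seq_len(nrow(m)), function(i) {
    if (zero[i]) {
      tibble::tibble(m_hat = 0, d_hat = NA_real_, n = ncol(m),
                     loglik = NA_real_)
    } else {
      fit_nb_single(m[i, ], d_max = d_max)
    }
  })
  per_st <- dplyr::bind_cols(pair_names(st_panel(x)), dplyr::bind_rows(fits))
  structure(list(
    per_st = per_st,
    common_dispersion = stats::median(per_st$d_hat[!zero]),
    m_bar = mean(per_st$m_hat[!zero]),
    batch_ids = attr(x, "batch_id"),
    panel = st_panel(x)),
    class = "nb_panel_fit")
}

#' @export
print.nb_panel_fit <- function(x, ...) {
  cat("<nb_panel_fit> ", nrow(x$per_st), " templates, n = ",
      x$per_st$n[1], " samples\n",
      "  common dispersion d = ", signif(x$common_dispersion, 4),
      ", m_bar = ", signif(x$m_bar, 5), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a panel fit into one row per template
#'
#' @param x An `nb_panel_fit`.
#' @param ... Unused.
#' @return The per-template tibble of mean and dispersion estimates.
#' @method tidy nb_panel_fit
#' @export
tidy.nb_panel_fit <- function(x, ...) x$per_st

#' One-row summary of a panel fit
#'
#' @param x An `nb_panel_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_templates`, `n_samples`,
#'   `common_dispersion`, `m_bar`, `n_zero_templates`.
#' @method glance nb_panel_fit
#' @export
glance.nb_panel_fit <- function(x, ...) {
  tibble::tibble(
    n_templates = nrow(x$per_st),
    n_samples = x$per_st$n[1],
    common_dispersion = x$common_dispersion,
    m_bar = x$m_bar,
    n_zero_templates = sum(x$per_st$m_hat == 0))
}

#' Mean-variance diagnostic table
#'
#' Per template: the empirical mean, the unbiased sample variance, and the
#' model variance `v = m + d m^2`. On log-log scales the model line has
#' slope ~2 at large means (`log v ~ log d + 2 log m`), and reduces to the
#' Poisson line `v = m` at `d = 0`.
#'
#' @param x An `st_counts` tibble (>= 2 samples).
#' @param dispersion Common dispersion `d` used for the model line.
#' @return A tibble sorted by `m_hat`: `pair`, `v_name`, `j_name`, `m_hat`,
#'   `v_hat`, `v_model`.
#' @seealso [plot_mean_variance()]
#' @export
mean_variance_table <- function(x, dispersion) {
  stopifnot(inherits(x, "st_counts"))
  m <- count_matrix(x)
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  out <- dplyr::mutate(pair_names(st_panel(x)),
                       m_hat = unname(rowMeans(m)),
                       v_hat = unname(apply(m, 1, stats::var)),
                       v_model = .data$m_hat + dispersion * .data$m_hat^2)
  dplyr::arrange(out, .data$m_hat)
}

#' Pool ST batches into combined mean estimates
#'
#' Batches may differ in equimolar ST input concentration and sample count.
#' Each batch's per-template mean vector is first made relative (divided by
#' its own grand mean, which absorbs any concentration difference), then
#' averaged across batches weighted by batch sample count, and finally
#' rescaled to unit mean. The result is the combined relative-mean vector
#' `m_i / m_bar`, directly usable as NB-mean scaling factors; with a single
#' batch it reduces to the per-batch maximum-likelihood means.
#'
#' @param batches A list of `st_counts` tibbles on the same panel (or a
#'   single `st_counts`).
#' @return A tibble `pair`, `v_name`, `j_name`, `m_rel` with
#'   `mean(m_rel) = 1`, of class `combined_means`.
#' @export
pool_batches <- function(batches) {
  if (inherits(batches, "st_counts")) batches <- list(batches)
  if (!length(batches)) stop("need at least one batch", call. = FALSE)
  panel <- st_panel(batches[[1]])
  key <- paste(panel$v_names, collapse = "|")
  rel <- purrr::map(batches, function(b) {
    bp <- st_panel(b)
    if (!identical(bp$v_names, panel$v_names) ||
        !identical(bp$j_names, panel$j_names)) {
      stop("all batches must share the same primer panel", call. = FALSE)
    }
    m <- unname(rowMeans(count_matrix(b)))
    m / mean(m)
  })
  w <- purrr::map_dbl(batches, ~ length(sample_ids(.x)))
  combined <- Reduce(`+`, purrr::map2(rel, w, `*`)) / sum(w)
  combined <- combined / mean(combined)
  out <- dplyr::mutate(pair_names(panel), m_rel = combined)
  structure(out, class = c("combined_means", class(out)), panel = panel)
}

#' Monte-Carlo spread floor under template independence
#'
#' Estimates how much within-sample template-to-template spread remains
#' after NB-mean normalization when counts truly are independent equimolar
#' NB draws with common mean and dispersion -- the best achievable
#' (lower-bound) spread for a given `(m, d)`. Observed post-normalization
#' spreads below this floor indicate positive dependence between primer
#' pairs.
#'
#' @param m Common NB mean.
#' @param d Common dispersion.
#' @param n_st Number of templates per sample.
#' @param n_samples Samples per simulated batch.
#' @param n_rep Monte-Carlo replicates.
#' @param seed Integer seed.
#' @return A tibble with one row per statistic (`iqr_fold` = per-sample
#'   Q3/Q1 ratio, `cv` = per-sample coefficient of variation), giving the
#'   Monte-Carlo `mean`, `sd` across replicates, and `n_rep`.
#' @export
independence_spread_bound <- function(m, d, n_st, n_samples, n_rep, seed) {
  if (m <= 0 || d < 0 || n_st < 2 || n_samples < 1 || n_rep < 1) {
    stop("all parameters must be positive (d may be 0)", call. = FALSE)
  }
  if (missing(seed)) {
    stop("independence_spread_bound() requires a seed", call. = FALSE)
  }
  withr_seed(seed, {
    stats_rep <- purrr::map(seq_len(n_rep), function(r) {
      cm <- matrix(rnb_md(n_st * n_samples, m, d), nrow = n_st)
      f <- rowMeans(cm) / mean(cm)
      norm <- cm / f
      q <- apply(norm, 2, stats::quantile, probs = c(0.25, 0.75), type = 7)
      tibble::tibble(
        iqr_fold = stats::median(q[2, ] / q[1, ]),
        cv = stats::median(apply(norm, 2, stats::sd) /
                             colMeans(norm)))
    })
    stats_rep <- dplyr::bind_rows(stats_rep)
    tibble::tibble(
      statistic = c("iqr_fold", "cv"),
      mean = c(mean(stats_rep$iqr_fold), mean(stats_rep$cv)),
      sd = c(stats::sd(stats_rep$iqr_fold), stats::sd(stats_rep$cv)),
      n_rep = n_rep)
  })
}

#' Correlation of log relative means between two fits
#'
#' Measures scaling-factor stability across experiments as the Pearson
#' correlation of `log(m_i / m_bar)` between two panel fits (equivalently,
#' of `log(m_i)`, since the grand-mean shift does not affect correlation).
#' Templates with a zero mean in either fit are excluded with a warning.
#'
#' @param fit_a,fit_b `nb_panel_fit` objects (or `combined_means` tibbles)
#'   on the same panel.
#' @return Pearson correlation on the natural-log scale.
#' @export
scaling_factor_stability <- function(fit_a, fit_b) {
  ma <- fit_means(fit_a)
  mb <- fit_means(fit_b)
  if (length(ma) != length(mb)) {
    stop("fits must be on the same panel", call. = FALSE)
  }
  ok <- ma > 0 & mb > 0
  if (any(!ok)) {
    warning(sum(!ok), " template(s) with zero mean excluded", call. = FALSE)
  }
  if (sum(ok) < 3) {
    stop("need at least 3 templates with nonzero means in both fits",
         call. = FALSE)
  }
  stats::cor(log(ma[ok]), log(mb[ok]))
}

fit_means <- function(x) {
  if (inherits(x, "nb_panel_fit")) return(x$per_st$m_hat)
  if (inherits(x, "combined_means")) return(x$m_rel)
  stop("expected an nb_panel_fit or combined_means object", call. = FALSE)
}
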