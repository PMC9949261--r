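#' Run the full normalization pipeline
#'
#' Ties the stages together: demultiplex spike-in reads from merged FASTQ
#' (or load an ST count matrix directly), derive scaling factors, normalize
#' an assembler-exported clonotype table, and compute repertoire metrics.
#' Clonotype assembly itself is consumed, never performed. Every output TSV
#' carries a provenance comment (seed, package version, factor source), and
#' a run summary table is always written.
#'
#' @param config A named list (or YAML path) with entries:
#'   \describe{
#'     \item{design}{ST design YAML path (required with `fastq`).}
#'     \item{fastq}{merged FASTQ to demultiplex (optional).}
#'     \item{st_counts}{ST count matrix TSV (optional; alternative factor
#'       source).}
#'     \item{clones}{clonotype table TSV (optional).}
#'     \item{out_prefix}{output path prefix (required).}
#'     \item{normalization}{`"nb_mean"` (default) or `"batch_mean"`.}
#'     \item{seed}{integer seed recorded in outputs (default 1).}
#'     \item{hyper_threshold}{hyperexpanded threshold (default 0.01).}
#'     \item{max_dist}{barcode edit-distance tolerance (default 1).}
#'   }
#' @return Invisibly, a list with the in-memory results (`st_counts`,
#'   `fit`, `factors`, `clones`, `metrics`, `summary`) and the paths
#'   written.
#' @export
pipeline_run <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_prefix)) {
    stop("config$out_prefix is required", call. = FALSE)
  }
  seed <- config$seed %||% 1L
  kind <- config$normalization %||% "nb_mean"
  if (!kind %in% c("nb_mean", "batch_mean")) {
    stop("normalization must be 'nb_mean' or 'batch_mean'", call. = FALSE)
  }
  prov <- sprintf("seed=%d otsp=%s factors=%s", as.integer(seed),
                  as.character(utils::packageVersion("otsp")), kind)
  paths <- character()
  out <- function(suffix) paste0(config$out_prefix, suffix)
  res <- list()

  if (!is.null(config$fastq)) {
    if (is.null(config$design)) {
      stop("demultiplexing stage: config$design is required with fastq",
           call. = FALSE)
    }
    design <- read_st_design(config$design)
    dm <- tryCatch(
      demux_reads(config$fastq, design,
                  max_dist = config$max_dist %||% 1L,
                  non_st_path = out("_non_st.fastq")),
      error = function(e) stop("demultiplexing stage failed: ",
                               conditionMessage(e), call. = FALSE))
    paths <- c(paths, out("_non_st.fastq"))
    res$demux <- dm
    res$st_counts <- st_counts(matrix(dm$counts$count, ncol = 1),
                               design$panel, sample_ids = "demuxed",
                               batch_id = "demuxed")
    readr::write_tsv(dm$summary, out("_demux_summary.tsv"))
    paths <- c(paths, out("_demux_summary.tsv"))
  } else if (!is.null(config$st_counts)) {
    res$st_counts <- tryCatch(
      read_st_counts(config$st_counts),
      error = function(e) stop("ST-count input stage failed: ",
                               conditionMessage(e), call. = FALSE))
  }

  if (!is.null(res$st_counts)) {
    if (kind == "nb_mean") {
      if (length(sample_ids(res$st_counts)) >= 2) {
        res$fit <- fit_panel(res$st_counts)
        res$factors <- nb_scaling_factors(res$fit)
      } else {
        stop("factor stage: nb_mean factors need >= 2 ST samples; ",
             "use batch_mean or supply a multi-sample ST matrix",
             call. = FALSE)
      }
    } else {
      res$factors <- batch_scaling_factors(res$st_counts)
    }
    write_scaling_factors(res$factors, out("_scaling_factors.tsv"))
    paths <- c(paths, out("_scaling_factors.tsv"))
  }

  if (!is.null(config$clones)) {
    if (is.null(res$factors)) {
      stop("normalization stage: no scaling factors available; supply ",
           "fastq or st_counts", call. = FALSE)
    }
    clones <- read_clonotype_table(config$clones)
    res$clones <- normalize_clonotypes(clones, res$factors)
    write_clonotype_table(res$clones, out("_clones_normalized.tsv"),
                          header = prov)
    res$metrics <- dplyr::bind_rows(
      dplyr::mutate(repertoire_summary(
        res$clones, use_normalized = FALSE,
        threshold = config$hyper_threshold %||% 0.01), counts = "raw"),
      dplyr::mutate(repertoire_summary(
        res$clones, use_normalized = TRUE,
        threshold = config$hyper_threshold %||% 0.01),
        counts = "normalized"))
    writeLines(paste0("# ", prov), out("_metrics.tsv"))
    readr::write_tsv(res$metrics, out("_metrics.tsv"), append = TRUE,
                     col_names = TRUE)
    paths <- c(paths, out("_clones_normalized.tsv"), out("_metrics.tsv"))
  }

  res$summary <- tibble::tibble(
    stage = c("demux", "factors", "normalize"),
    ran = c(!is.null(res$demux), !is.null(res$factors),
            !is.null(res$clones)),
    detail = c(
      if (!is.null(res$demux)) {
        sprintf("%d reads, %d ST assigned", res$demux$summary$n_reads_total,
                res$demux$summary$n_st_assigned)
      } else "skipped",
      if (!is.null(res$factors)) {
        sprintf("%s factors for %d pairs", kind, nrow(res$factors))
      } else "skipped",
      if (!is.null(res$clones)) {
        sprintf("%d clonotypes normalized", nrow(res$clones))
      } else "skipped"))
  writeLines(paste0("# ", prov), out("_run_summary.tsv"))
  readr::write_tsv(res$summary, out("_run_summary.tsv"), append = TRUE,
                   col_names = TRUE)
  res$paths <- c(paths, out("_run_summary.tsv"))
  invisible(res)
}
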