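#' ST count matrices
#'
#' Counts `C_ij` of synthetic template `i` (one per primer pair, in
#' pair-index order) across the samples `j` of one batch. Stored as a tibble
#' with identifier columns `v_name`, `j_name` followed by one numeric column
#' per sample, carrying the batch id and relative ST input concentration as
#' attributes.
#'
#' @param counts Numeric matrix (`n_pairs x n_samples`) of non-negative
#'   counts, rows in pair-index order; or a tibble already shaped as above.
#' @param panel The `primer_panel` the rows index.
#' @param sample_ids Sample column names; defaults to `S1..Sn`.
#' @param batch_id Batch label.
#' @param concentration Relative ST input amount for the batch (positive
#'   scalar; only ratios between batches matter).
#' @return A tibble of class `st_counts`.
#' @export
st_counts <- function(counts, panel, sample_ids = NULL,
                      batch_id = "batch1", concentration = 1) {
  stopifnot(inherits(panel, "primer_panel"))
  if (is.data.frame(counts)) {
    m <- as.matrix(counts[setdiff(names(counts), c("pair", "v_name", "j_name"))])
  } else {
    m <- as.matrix(counts)
  }
  if (nrow(m) != n_pairs(panel)) {
    stop("count matrix must have one row per primer pair (",
         n_pairs(panel), "), got ", nrow(m), call. = FALSE)
  }
  if (ncol(m) < 1) stop("need at least one sample column", call. = FALSE)
  if (any(m < 0) || anyNA(m)) {
    stop("ST counts must be non-negative and non-missing", call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- colnames(m)
    if (is.null(sample_ids) || anyDuplicated(sample_ids)) {
      sample_ids <- sprintf("S%d", seq_len(ncol(m)))
    }
  }
  colnames(m) <- sample_ids
  if (concentration <= 0) stop("concentration must be positive", call. = FALSE)
  out <- dplyr::bind_cols(pair_names(panel)[c("v_name", "j_name")],
                          tibble::as_tibble(m))
  structure(out,
            class = c("st_counts", class(out)),
            panel = panel, batch_id = batch_id,
            concentration = concentration)
}

#' Extract the numeric count matrix from an `st_counts` tibble
#'
#' @param x An `st_counts` tibble.
#' @return Numeric matrix, `n_pairs x n_samples`, sample ids as colnames.
#' @export
count_matrix <- function(x) {
  stopifnot(inherits(x, "st_counts"))
  m <- as.matrix(x[setdiff(names(x), c("v_name", "j_name"))])
  rownames(m) <- paste(x$v_name, x$j_name, sep = "|")
  m
}

st_panel <- function(x) attr(x, "panel")

sample_ids <- function(x) setdiff(names(x), c("v_name", "j_name"))

#' Read or write an ST count matrix as TSV
#'
#' The TSV has columns `v_name`, `j_name` followed by one column per sample;
#' lines starting with `#` are metadata comments (batch id, concentration).
#'
#' @param x An `st_counts` tibble.
#' @param path File path.
#' @param panel Panel to validate against; reconstructed from the file's
#'   `v_name`/`j_name` order when `NULL`.
#' @return `read_st_counts()` returns an `st_counts` tibble;
#'   `write_st_counts()` returns `path` invisibly.
#' @export
write_st_counts <- function(x, path) {
  stopifnot(inherits(x, "st_counts"))
  hdr <- sprintf("# batch_id=%s concentration=%g",
                 attr(x, "batch_id"), attr(x, "concentration"))
  writeLines(hdr, path)
  readr::write_tsv(tibble::as_tibble(unclass_st(x)), path, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

unclass_st <- function(x) {
  class(x) <- setdiff(class(x), "st_counts")
  x
}

#' @rdname write_st_counts
#' @export
read_st_counts <- function(path, panel = NULL) {
  hdr <- readLines(path, n = 1L)
  batch_id <- "batch1"
  concentration <- 1
  if (startsWith(hdr, "#")) {
    m <- regmatches(hdr, regexec("batch_id=(\\S+) concentration=(\\S+)", hdr))[[1]]
    if (length(m) == 3) {
      batch_id <- m[2]
      concentration <- as.numeric(m[3])
    }
  }
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (is.null(panel)) {
    panel <- primer_panel(unique(tbl$v_name), unique(tbl$j_name))
  }
  ord <- order(pair_index(panel, tbl$v_name, tbl$j_name))
  tbl <- tbl[ord, ]
  st_counts(tbl, panel,
            sample_ids = setdiff(names(tbl), c("v_name", "j_name")),
            batch_id = batch_id, concentration = concentration)
}
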