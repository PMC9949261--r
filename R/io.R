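#' Read a clonotype table from an assembler's tabular export
#'
#' Accepts the TSV shape produced by clonotype assemblers. Column names are
#' matched case-insensitively against a set of common aliases per field
#' (e.g. `cloneCount`/`count` for the raw count, `nSeqCDR3`/`cdr3_nt` for
#' the CDR3 nucleotide sequence); supply `col_map` to override. Rows with a
#' missing or non-numeric count are reported with their line numbers.
#'
#' @param path TSV path.
#' @param col_map Named list mapping the canonical fields `raw_count`,
#'   `cdr3_nt`, `v_name`, `j_name` (and optionally `cdr3_aa`, `clone_id`,
#'   `normalized_count`) to candidate column names in the file.
#' @param panel Optional `primer_panel` to validate V/J names against.
#' @return A clonotype table tibble.
#' @export
read_clonotype_table <- function(path, col_map = default_col_map(),
                                 panel = NULL) {
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  lower <- tolower(names(raw))
  pick <- function(field, required = TRUE) {
    hit <- which(lower %in% tolower(col_map[[field]]))
    if (!length(hit)) {
      if (required) {
        stop("missing mandatory column for '", field, "' (accepted names: ",
             paste(col_map[[field]], collapse = ", "), ")", call. = FALSE)
      }
      return(NULL)
    }
    raw[[hit[1]]]
  }
  count <- suppressWarnings(as.numeric(pick("raw_count")))
  bad <- which(is.na(count))
  if (length(bad)) {
    stop("malformed count in data row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  tbl <- clonotype_table(
    cdr3_nt = pick("cdr3_nt"),
    v_name = pick("v_name"),
    j_name = pick("j_name"),
    raw_count = count,
    clone_id = pick("clone_id", required = FALSE),
    cdr3_aa = pick("cdr3_aa", required = FALSE))
  nc <- pick("normalized_count", required = FALSE)
  if (!is.null(nc)) tbl$normalized_count <- as.numeric(nc)
  validate_clonotype_table(tbl, panel)
}

#' @rdname read_clonotype_table
#' @export
default_col_map <- function() {
  list(
    raw_count = c("raw_count", "count", "cloneCount", "clone_count", "reads"),
    cdr3_nt = c("cdr3_nt", "nSeqCDR3", "cdr3nt", "nt_sequence"),
    cdr3_aa = c("cdr3_aa", "aaSeqCDR3", "cdr3aa", "aa_sequence"),
    v_name = c("v_name", "v", "bestVHit", "v_segment", "v_gene"),
    j_name = c("j_name", "j", "bestJHit", "j_segment", "j_gene"),
    clone_id = c("clone_id", "cloneId", "id"),
    normalized_count = c("normalized_count", "norm_count"))
}

#' Write a clonotype table as TSV
#'
#' @param table A clonotype table.
#' @param path Output path.
#' @param header Optional provenance comment lines (written prefixed
#'   with `#`).
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(table, path, header = NULL) {
  if (!is.null(header)) {
    writeLines(paste0("# ", header), path)
    readr::write_tsv(table, path, append = TRUE, col_names = TRUE)
  } else {
    readr::write_tsv(table, path)
  }
  invisible(path)
}

#' Read or write scaling factors as TSV
#'
#' The TSV carries `v_name`, `j_name`, `factor`, `kind`; a `#` comment line
#' records provenance.
#'
#' @param sf A `scaling_factors` tibble.
#' @param path File path.
#' @param panel Panel to attach on read; reconstructed from the file when
#'   `NULL`.
#' @return `read_scaling_factors()` returns a `scaling_factors` tibble;
#'   `write_scaling_factors()` returns `path` invisibly.
#' @export
write_scaling_factors <- function(sf, path) {
  stopifnot(inherits(sf, "scaling_factors"))
  writeLines(sprintf("# kind=%s provenance=%s", attr(sf, "kind"),
                     attr(sf, "provenance")), path)
  out <- dplyr::mutate(tibble::as_tibble(sf)[c("v_name", "j_name", "factor")],
                       kind = attr(sf, "kind"))
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_scaling_factors
#' @export
read_scaling_factors <- function(path, panel = NULL) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (is.null(panel)) {
    panel <- primer_panel(unique(tbl$v_name), unique(tbl$j_name))
  }
  full <- rep(NA_real_, n_pairs(panel))
  full[pair_index(panel, tbl$v_name, tbl$j_name)] <- tbl$factor
  new_scaling_factors(panel, full, kind = tbl$kind[1] %||% "batch_mean",
                      provenance = basename(path))
}
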