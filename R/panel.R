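#' Define a multiplex primer panel
#'
#' A primer panel is the ordered set of V-segment forward primers and
#' J-segment reverse primers used in the multiplex PCR. Every V x J
#' combination defines one primer pair and one synthetic template (ST), so a
#' panel of 20 V and 13 J primers spans 260 primer pairs.
#'
#' @param v_names Character vector of V-primer names (unique, non-empty).
#' @param j_names Character vector of J-primer names (unique, non-empty).
#'
#' @return An object of class `primer_panel`: a list with elements `v_names`
#'   and `j_names`.
#' @examples
#' panel <- primer_panel(c("V1", "V2"), c("J1", "J2", "J3"))
#' n_pairs(panel)
#' @export
primer_panel <- function(v_names, j_names) {
  v_names <- stringr::str_trim(as.character(v_names))
  j_names <- stringr::str_trim(as.character(j_names))
  if (length(v_names) == 0 || length(j_names) == 0) {
    stop("primer panel needs at least one V and one J primer", call. = FALSE)
  }
  if (anyDuplicated(v_names)) {
    stop("duplicated V-primer names: ",
         paste(unique(v_names[duplicated(v_names)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(j_names)) {
    stop("duplicated J-primer names: ",
         paste(unique(j_names[duplicated(j_names)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(v_names = v_names, j_names = j_names),
            class = "primer_panel")
}

#' Default 20 V x 13 J murine TCR-beta panel
#'
#' Placeholder primer names `V01..V20` / `J01..J13` reproducing the default
#' panel geometry (260 primer pairs). Real primer names from a panel design
#' can be supplied to [primer_panel()] directly.
#'
#' @return A `primer_panel` with 20 V and 13 J primers.
#' @export
default_panel <- function() {
  primer_panel(sprintf("V%02d", 1:20), sprintf("J%02d", 1:13))
}

#' @export
print.primer_panel <- function(x, ...) {
  cat("<primer_panel> ", length(x$v_names), " V x ", length(x$j_names),
      " J = ", n_pairs(x), " primer pairs\n", sep = "")
  invisible(x)
}

#' Number of primer pairs in a panel
#'
#' @param panel A `primer_panel`.
#' @return Integer, `length(v_names) * length(j_names)`.
#' @export
n_pairs <- function(panel) {
  stopifnot(inherits(panel, "primer_panel"))
  length(panel$v_names) * length(panel$j_names)
}

#' Canonical primer-pair index
#'
#' Maps a (V, J) primer combination to its canonical row index. Pairs are
#' ordered J-fastest: pair `i` of `(v, j)` is
#' `(v_idx - 1) * n_J + j_idx` with 1-based indices, so the first V primer
#' with the first J primer is pair 1 and the last V with the last J is pair
#' `n_V * n_J` (260 on the default panel).
#'
#' @param panel A `primer_panel`.
#' @param v_name,j_name Primer names (vectorised; recycled to common length).
#' @return Integer vector of pair indices in `1..n_pairs(panel)`.
#' @examples
#' pair_index(default_panel(), "V01", "J01")  # 1
#' pair_index(default_panel(), "V20", "J13")  # 260
#' @seealso [pair_names()] for the inverse.
#' @export
pair_index <- function(panel, v_name, j_name) {
  stopifnot(inherits(panel, "primer_panel"))
  v_idx <- match(stringr::str_trim(as.character(v_name)), panel$v_names)
  j_idx <- match(stringr::str_trim(as.character(j_name)), panel$j_names)
  if (anyNA(v_idx)) {
    bad <- unique(v_name[is.na(v_idx)])
    stop("unknown V-primer name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(j_idx)) {
    bad <- unique(j_name[is.na(j_idx)])
    stop("unknown J-primer name(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  (v_idx - 1L) * length(panel$j_names) + j_idx
}

#' Recover (V, J) names from pair indices
#'
#' Inverse of [pair_index()].
#'
#' @param panel A `primer_panel`.
#' @param index Integer vector of pair indices in `1..n_pairs(panel)`.
#' @return A tibble with columns `pair`, `v_name`, `j_name`.
#' @export
pair_names <- function(panel, index = seq_len(n_pairs(panel))) {
  stopifnot(inherits(panel, "primer_panel"))
  index <- as.integer(index)
  if (any(index < 1L | index > n_pairs(panel), na.rm = TRUE) || anyNA(index)) {
    stop("pair index out of range 1..", n_pairs(panel), call. = FALSE)
  }
  nj <- length(panel$j_names)
  tibble::tibble(
    pair = index,
    v_name = panel$v_names[(index - 1L) %/% nj + 1L],
    j_name = panel$j_names[(index - 1L) %% nj + 1L]
  )
}

#' Per-primer-pair clonotype totals
#'
#' Sums raw clonotype counts within each primer pair: entry `i` is the total
#' count of all clonotypes amplified with primer pair `i` (`C_i` in the
#' normalization procedure). The vector conserves the table's total read
#' count exactly.
#'
#' @param table A clonotype table (see [clonotype_table()]).
#' @param panel A `primer_panel`; every `(v_name, j_name)` in `table` must
#'   resolve to a pair.
#' @return A tibble with one row per primer pair: `pair`, `v_name`,
#'   `j_name`, `total` (0 for pairs with no clonotypes).
#' @export
clonotype_primer_totals <- function(table, panel) {
  table <- validate_clonotype_table(table, panel)
  idx <- pair_index(panel, table$v_name, table$j_name)
  totals <- rep(0, n_pairs(panel))
  agg <- rowsum(as.numeric(table$raw_count), idx)
  totals[as.integer(rownames(agg))] <- agg[, 1]
  dplyr::mutate(pair_names(panel), total = totals)
}

#' Construct and validate a clonotype table
#'
#' A clonotype table is a tibble with one row per distinct clonotype:
#' `clone_id`, `cdr3_nt` (CDR3 nucleotide sequence), optional `cdr3_aa`,
#' `v_name`, `j_name`, `raw_count`, and optionally `normalized_count`.
#' This is the tabular export shape produced by clonotype assemblers.
#'
#' @param cdr3_nt Character vector of CDR3 nucleotide sequences.
#' @param v_name,j_name Primer/segment names per clonotype.
#' @param raw_count Non-negative integer counts.
#' @param clone_id Optional ids; defaults to `clone_1..clone_n`.
#' @param cdr3_aa Optional amino-acid CDR3 sequences.
#' @return A tibble of class `tbl_df` with the columns above.
#' @export
clonotype_table <- function(cdr3_nt, v_name, j_name, raw_count,
                            clone_id = NULL, cdr3_aa = NULL) {
  n <- length(cdr3_nt)
  if (is.null(clone_id)) clone_id <- sprintf("clone_%d", seq_len(n))
  if (is.null(cdr3_aa)) cdr3_aa <- NA_character_
  tbl <- tibble::tibble(
    clone_id = as.character(clone_id),
    cdr3_nt = toupper(as.character(cdr3_nt)),
    cdr3_aa = as.character(cdr3_aa),
    v_name = stringr::str_trim(as.character(v_name)),
    j_name = stringr::str_trim(as.character(j_name)),
    raw_count = as.numeric(raw_count)
  )
  if (any(tbl$raw_count < 0)) {
    stop("raw_count must be non-negative", call. = FALSE)
  }
  tbl
}

validate_clonotype_table <- function(table, panel = NULL) {
  need <- c("cdr3_nt", "v_name", "j_name", "raw_count")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("clonotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(table$raw_count < 0, na.rm = TRUE)) {
    stop("clonotype table has negative raw counts", call. = FALSE)
  }
  if (!is.null(panel)) {
    bad_v <- !table$v_name %in% panel$v_names
    bad_j <- !table$j_name %in% panel$j_names
    if (any(bad_v | bad_j)) {
      rows <- which(bad_v | bad_j)
      stop("clonotype rows with V/J names not in the panel: rows ",
           paste(utils::head(rows, 10), collapse = ", "),
           if (length(rows) > 10) " ..." else "", call. = FALSE)
    }
  }
  tibble::as_tibble(table)
}
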