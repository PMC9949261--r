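#' Synthetic-template (ST) design
#'
#' An ST design couples a primer panel with the internal barcode scheme used
#' to identify spike-in reads after sequencing: a single universal barcode
#' (9 bp by default) shared by every ST, and one specific barcode (16 bp by
#' default) per V x J template. Templates themselves are ~200 bp
#' double-stranded DNA fragments carrying partial V and J sequences around
#' the barcode region.
#'
#' Barcode assignment at an edit-distance tolerance of 1 is unambiguous only
#' if specific barcodes are pairwise at Levenshtein distance >= 3; the
#' constructor enforces this.
#'
#' @param panel A [primer_panel()].
#' @param universal_barcode DNA string common to all STs.
#' @param specific_barcodes Character vector, one barcode per pair in
#'   pair-index order (length `n_pairs(panel)`).
#' @param template_length Total ST length in bp (default 200).
#' @return An object of class `st_design`.
#' @seealso [make_st_design()] to generate a design with random barcodes.
#' @export
st_design <- function(panel, universal_barcode, specific_barcodes,
                      template_length = 200L) {
  stopifnot(inherits(panel, "primer_panel"))
  universal_barcode <- toupper(universal_barcode)
  specific_barcodes <- toupper(specific_barcodes)
  if (length(specific_barcodes) != n_pairs(panel)) {
    stop("need exactly ", n_pairs(panel), " specific barcodes, got ",
         length(specific_barcodes), call. = FALSE)
  }
  if (!grepl("^[ACGT]+$", universal_barcode) ||
      !all(grepl("^[ACGT]+$", specific_barcodes))) {
    stop("barcodes must be non-empty A/C/G/T strings", call. = FALSE)
  }
  dmat <- utils::adist(specific_barcodes)
  if (any(dmat[upper.tri(dmat)] < 3)) {
    stop("specific barcodes must be pairwise edit distance >= 3",
         call. = FALSE)
  }
  design <- structure(
    list(panel = panel,
         universal_barcode = universal_barcode,
         specific_barcodes = specific_barcodes,
         template_length = as.integer(template_length)),
    class = "st_design")
  design
}

#' @export
print.st_design <- function(x, ...) {
  cat("<st_design> ", n_pairs(x$panel), " templates (",
      length(x$panel$v_names), "V x ", length(x$panel$j_names), "J), ",
      nchar(x$universal_barcode), " bp universal + ",
      nchar(x$specific_barcodes[1]), " bp specific barcodes, ",
      x$template_length, " bp templates\n", sep = "")
  invisible(x)
}

#' Generate an ST design with random barcodes
#'
#' Draws a universal barcode and one specific barcode per primer pair by
#' rejection sampling until the design's distance invariants hold: all
#' specific barcodes pairwise Levenshtein distance >= 3, and the universal
#' barcode at distance >= 3 from every same-length window of every specific
#' barcode (so a universal-barcode hit cannot be confused with a specific
#' one at tolerance 1).
#'
#' @param panel A [primer_panel()]; defaults to the 20 x 13 panel.
#' @param seed Integer seed; the design is a deterministic function of
#'   `(panel, seed)`.
#' @param universal_length,specific_length Barcode lengths in bp.
#' @param template_length ST length in bp.
#' @param max_tries Retry budget for rejection sampling.
#' @return An `st_design`.
#' @examples
#' design <- make_st_design(primer_panel(c("V1", "V2"), c("J1", "J2")), seed = 1)
#' @export
make_st_design <- function(panel = default_panel(), seed,
                           universal_length = 9L, specific_length = 16L,
                           template_length = 200L, max_tries = 200L) {
  stopifnot(inherits(panel, "primer_panel"))
  if (missing(seed)) stop("make_st_design() requires a seed", call. = FALSE)
  np <- n_pairs(panel)
  bases <- c("A", "C", "G", "T")
  rand_bc <- function(n, len) {
    vapply(seq_len(n), function(i) {
      paste(sample(bases, len, replace = TRUE), collapse = "")
    }, character(1))
  }
  withr_seed(seed, {
    specific <- rand_bc(np, specific_length)
    for (try in seq_len(max_tries)) {
      dmat <- utils::adist(specific)
      diag(dmat) <- Inf
      bad <- which(apply(dmat, 1, min) < 3)
      if (!length(bad)) break
      specific[bad] <- rand_bc(length(bad), specific_length)
      if (try == max_tries) {
        stop("could not satisfy barcode distance constraints; ",
             "try longer specific barcodes", call. = FALSE)
      }
    }
    windows <- unlist(lapply(specific, function(b) {
      n <- nchar(b) - universal_length + 1L
      substring(b, seq_len(n), seq_len(n) + universal_length - 1L)
    }))
    universal <- NULL
    for (try in seq_len(max_tries)) {
      cand <- rand_bc(1, universal_length)
      if (min(utils::adist(cand, windows)) >= 3) {
        universal <- cand
        break
      }
    }
    if (is.null(universal)) {
      stop("could not find a universal barcode at distance >= 3 from all ",
           "specific-barcode windows; try a longer universal barcode",
           call. = FALSE)
    }
    st_design(panel, universal, specific, template_length)
  })
}

# run code under a local RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Read or write an ST design as YAML
#'
#' The on-disk form carries primer names and barcodes only, so designs are
#' portable across index conventions.
#'
#' @param design An `st_design`.
#' @param path File path.
#' @return `read_st_design()` returns an `st_design`;
#'   `write_st_design()` returns `path` invisibly.
#' @export
write_st_design <- function(design, path) {
  stopifnot(inherits(design, "st_design"))
  pn <- pair_names(design$panel)
  yaml::write_yaml(list(
    v_names = design$panel$v_names,
    j_names = design$panel$j_names,
    universal_barcode = design$universal_barcode,
    template_length = design$template_length,
    specific_barcodes = stats::setNames(
      as.list(design$specific_barcodes),
      paste(pn$v_name, pn$j_name, sep = "|"))
  ), path)
  invisible(path)
}

#' @rdname write_st_design
#' @export
read_st_design <- function(path) {
  x <- yaml::read_yaml(path)
  panel <- primer_panel(x$v_names, x$j_names)
  pn <- pair_names(panel)
  keys <- paste(pn$v_name, pn$j_name, sep = "|")
  bc <- unlist(x$specific_barcodes[keys])
  if (anyNA(bc) || length(bc) != n_pairs(panel)) {
    stop("design file is missing specific barcodes for some primer pairs",
         call. = FALSE)
  }
  st_design(panel, x$universal_barcode, unname(bc),
            x$template_length %||% 200L)
}
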