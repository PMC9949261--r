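#' Locate a barcode in a read by windowed edit distance
#'
#' Scans every window of the read whose length is within `max_dist` of the
#' barcode length and returns the leftmost window at Levenshtein distance
#' `<= max_dist` (substitutions, insertions and deletions each cost 1, so
#' `max_dist = 1` is the "one-nucleotide mismatch or indel" tolerance used
#' for spike-in identification). Ties between windows starting at the same
#' position resolve to the minimal distance; ties between positions resolve
#' to the leftmost.
#'
#' @param read DNA string to search.
#' @param barcode DNA barcode to find.
#' @param max_dist Maximum Levenshtein distance (default 1).
#' @return A one-row tibble (`position`, `distance`) with the 1-based window
#'   start, or a zero-row tibble when no window qualifies.
#' @export
find_barcode <- function(read, barcode, max_dist = 1L) {
  if (!nzchar(read) || !nzchar(barcode)) {
    stop("read and barcode must be non-empty", call. = FALSE)
  }
  if (max_dist < 0) stop("max_dist must be >= 0", call. = FALSE)
  w <- barcode_windows(read, nchar(barcode), max_dist)
  if (nrow(w) == 0) return(tibble::tibble(position = integer(), distance = integer()))
  d <- as.integer(utils::adist(barcode, w$window))
  ok <- d <= max_dist
  if (!any(ok)) {
    return(tibble::tibble(position = integer(), distance = integer()))
  }
  pos <- min(w$start[ok])
  at <- ok & w$start == pos
  tibble::tibble(position = pos, distance = min(d[at]))
}

# all windows of the read with length within max_dev of len
barcode_windows <- function(read, len, max_dev) {
  n <- nchar(read)
  lens <- max(1L, len - max_dev):(len + max_dev)
  out <- lapply(lens, function(l) {
    if (l > n) return(NULL)
    starts <- seq_len(n - l + 1L)
    tibble::tibble(start = starts,
                   window = substring(read, starts, starts + l - 1L))
  })
  dplyr::bind_rows(out)
}

# min edit distance over all windows of the read, per barcode
min_window_dists <- function(read, barcodes, max_dev = 1L) {
  w <- barcode_windows(read, nchar(barcodes[1]), max_dev)
  d <- utils::adist(barcodes, w$window)
  apply(d, 1, min)
}

revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Assign a read to a synthetic template
#'
#' Implements the two-stage spike-in identification: a read is flagged as ST
#' when the universal barcode is found anywhere in it (or, by default, in
#' its reverse complement) at edit distance `<= max_dist`; a flagged read is
#' then assigned to the unique template whose specific barcode matches at
#' the same tolerance. Reads flagged as ST but matching no specific barcode
#' uniquely (a tie at minimal distance, or no match at all) are reported as
#' ambiguous, counted, and dropped -- never fractionally allocated.
#'
#' @param read DNA string.
#' @param design An `st_design`.
#' @param max_dist Edit-distance tolerance (default 1, one mismatch or
#'   indel).
#' @param search_revcomp Also search the reverse complement (default
#'   `TRUE`; merged reads can be in either orientation).
#' @return A one-row tibble with `status` (`"assigned"`, `"ambiguous"`, or
#'   `"not_st"`) and `pair` (the pair index, `NA` unless assigned).
#' @export
assign_st <- function(read, design, max_dist = 1L, search_revcomp = TRUE) {
  stopifnot(inherits(design, "st_design"))
  oriented <- read
  hit <- find_barcode(read, design$universal_barcode, max_dist)
  if (nrow(hit) == 0 && search_revcomp) {
    oriented <- revcomp(read)
    hit <- find_barcode(oriented, design$universal_barcode, max_dist)
  }
  if (nrow(hit) == 0) {
    return(tibble::tibble(status = "not_st", pair = NA_integer_))
  }
  d <- min_window_dists(oriented, design$specific_barcodes, max_dist)
  best <- min(d)
  cand <- which(d == best)
  if (best > max_dist || length(cand) > 1) {
    return(tibble::tibble(status = "ambiguous", pair = NA_integer_))
  }
  tibble::tibble(status = "assigned", pair = cand)
}

#' Demultiplex reads into ST counts and non-ST reads
#'
#' Partitions merged reads into spike-in (ST) and clonotype reads, and
#' quantifies each template from the specific barcodes. Every read lands in
#' exactly one tally: assigned to a template, ambiguous, or non-ST. Non-ST
#' reads are passed through unmodified for downstream clonotype assembly;
#' ST-flagged reads are removed from it.
#'
#' @param reads A tibble with columns `read_id` and `seq` (as returned by
#'   [read_fastq()] or [generate_fixture_fastq()]), or a FASTQ path.
#' @param design An `st_design`.
#' @param max_dist Edit-distance tolerance for both barcodes.
#' @param search_revcomp Also match reverse-complemented reads.
#' @param non_st_path Optional FASTQ path to write the non-ST reads to.
#' @return A list with
#'   \describe{
#'     \item{counts}{tibble `pair`, `v_name`, `j_name`, `count` (one row per
#'       template; sums to the number of assigned reads),}
#'     \item{non_st}{tibble of the non-ST reads (`read_id`, `seq`),}
#'     \item{summary}{one-row tibble `n_reads_total`, `n_st_flagged`,
#'       `n_st_assigned`, `n_st_ambiguous`, `n_non_st`.}
#'   }
#' @export
demux_reads <- function(reads, design, max_dist = 1L, search_revcomp = TRUE,
                        non_st_path = NULL) {
  stopifnot(inherits(design, "st_design"))
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  if (!all(c("read_id", "seq") %in% names(reads))) {
    stop("reads must have columns read_id and seq", call. = FALSE)
  }
  res <- purrr::map(reads$seq, assign_st, design = design,
                    max_dist = max_dist, search_revcomp = search_revcomp)
  res <- dplyr::bind_rows(
    tibble::tibble(status = character(), pair = integer()), res)
  counts <- rep(0L, n_pairs(design$panel))
  assigned <- res$pair[res$status == "assigned"]
  if (length(assigned)) {
    tab <- table(assigned)
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  non_st <- reads[res$status == "not_st", c("read_id", "seq")]
  if (!is.null(non_st_path)) write_fastq(non_st$read_id, non_st$seq, non_st_path)
  list(
    counts = dplyr::mutate(pair_names(design$panel), count = counts),
    non_st = non_st,
    summary = tibble::tibble(
      n_reads_total = nrow(reads),
      n_st_flagged = sum(res$status != "not_st"),
      n_st_assigned = sum(res$status == "assigned"),
      n_st_ambiguous = sum(res$status == "ambiguous"),
      n_non_st = sum(res$status == "not_st")))
}

#' @rdname demux_reads
#' @export
demux_fastq <- demux_reads
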