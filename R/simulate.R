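#' Amplification-bias model
#'
#' Describes per-primer-pair amplification efficiencies as the mean
#' parameters `m_i` of negative-binomial (NB) count distributions with a
#' common dispersion `d` (`var = m + d m^2`). An optional V x J interaction
#' matrix layers non-separable efficiency structure on top of the V and J
#' main effects, mimicking the primer-pair dependence seen in real panels.
#'
#' @param panel A `primer_panel`.
#' @param st_means Positive vector of NB means, one per pair in pair-index
#'   order.
#' @param dispersion Common NB dispersion `d >= 0`; `d = 0` is Poisson.
#' @param interaction Optional `n_V x n_J` multiplicative matrix with rows
#'   and columns averaging 1; applied on top of `st_means`.
#' @return An object of class `bias_model`.
#' @seealso [sample_bias_model()] for a randomly generated separable model.
#' @export
bias_model <- function(panel, st_means, dispersion = 0.125,
                       interaction = NULL) {
  stopifnot(inherits(panel, "primer_panel"))
  st_means <- as.numeric(st_means)
  if (length(st_means) != n_pairs(panel)) {
    stop("st_means must have one entry per primer pair", call. = FALSE)
  }
  if (any(st_means <= 0) || anyNA(st_means)) {
    stop("all ST means must be strictly positive", call. = FALSE)
  }
  if (length(dispersion) != 1 || dispersion < 0) {
    stop("dispersion must be a single value >= 0", call. = FALSE)
  }
  if (!is.null(interaction)) {
    nv <- length(panel$v_names)
    nj <- length(panel$j_names)
    if (!is.matrix(interaction) || nrow(interaction) != nv ||
        ncol(interaction) != nj || any(interaction <= 0)) {
      stop("interaction must be a positive ", nv, " x ", nj, " matrix",
           call. = FALSE)
    }
    # pair order is J-fastest, so transpose before flattening
    st_means <- st_means * as.vector(t(interaction))
  }
  structure(list(panel = panel, st_means = st_means,
                 dispersion = dispersion,
                 interaction = interaction),
            class = "bias_model")
}

#' @export
print.bias_model <- function(x, ...) {
  cat("<bias_model> ", n_pairs(x$panel), " primer pairs, d = ",
      x$dispersion, ", mean range ",
      signif(min(x$st_means), 3), "..", signif(max(x$st_means), 3),
      if (!is.null(x$interaction)) ", with V x J interaction" else "",
      "\n", sep = "")
  invisible(x)
}

#' Draw a random separable bias model
#'
#' Generates V and J primer efficiency effects so that `log(m_i)` is
#' additive in V and J and spans about `log_spread` natural-log units
#' (default 4, i.e. roughly a 50-fold range between the weakest and
#' strongest primer pair, matching the spread typical of unbalanced
#' multiplex panels).
#'
#' @param panel A `primer_panel`.
#' @param base_mean Geometric-mean NB count level.
#' @param log_spread Total natural-log range of the means.
#' @param dispersion Common NB dispersion.
#' @param interaction Optional interaction matrix, as in [bias_model()].
#' @param seed Integer seed.
#' @return A `bias_model`.
#' @export
sample_bias_model <- function(panel, base_mean = 1000, log_spread = 4,
                              dispersion = 0.125, interaction = NULL, seed) {
  if (missing(seed)) stop("sample_bias_model() requires a seed", call. = FALSE)
  withr_seed(seed, {
    a <- log_spread / 4
    v_eff <- stats::runif(length(panel$v_names), -a, a)
    j_eff <- stats::runif(length(panel$j_names), -a, a)
    log_m <- log(base_mean) + outer(v_eff, j_eff, `+`)
    bias_model(panel, exp(as.vector(t(log_m))), dispersion, interaction)
  })
}

# NB sampler in the (mu, d) parameterization: gamma-Poisson mixture with
# shape 1/d gives var = m + d m^2 exactly; d = 0 short-circuits to Poisson.
rnb_md <- function(n, mu, d) {
  if (d == 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / d)
}

#' Simulate an ST count matrix
#'
#' Draws counts independently per (template, sample) from `NB(m_i, d)` with
#' `E(C) = m_i` and `var(C) = m_i + d m_i^2`; `d = 0` gives Poisson draws.
#' Identical seeds give identical matrices.
#'
#' @param model A `bias_model`.
#' @param n_samples Number of replicate samples (columns).
#' @param seed Integer seed.
#' @param batch_id,concentration Batch metadata stored on the result; counts
#'   are scaled in expectation by `concentration` (equimolar input across
#'   templates within a batch).
#' @return An `st_counts` tibble.
#' @examples
#' panel <- primer_panel(c("V1", "V2"), c("J1", "J2"))
#' m <- bias_model(panel, c(50, 100, 200, 400), dispersion = 0.1)
#' simulate_st_counts(m, n_samples = 3, seed = 7)
#' @export
simulate_st_counts <- function(model, n_samples, seed,
                               batch_id = "batch1", concentration = 1) {
  stopifnot(inherits(model, "bias_model"))
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (missing(seed)) stop("simulate_st_counts() requires a seed", call. = FALSE)
  np <- n_pairs(model$panel)
  withr_seed(seed, {
    counts <- matrix(
      rnb_md(np * n_samples,
             mu = rep(model$st_means * concentration, n_samples),
             d = model$dispersion),
      nrow = np, ncol = n_samples)
    st_counts(counts, model$panel, batch_id = batch_id,
              concentration = concentration)
  })
}

#' Simulate a clonotype repertoire read through a biased panel
#'
#' Given true clone frequencies and each clone's V/J primer pair, the
#' expected raw count of clone `c` is proportional to
#' `freq_c * m_pair(c)`, scaled so expected counts sum to `depth`; realized
#' counts are NB draws around that expectation with the model's dispersion.
#' This reproduces how multiplex amplification distorts clone proportions by
#' the primer-pair efficiency ratios.
#'
#' @param clone_freqs Probability vector of true clone frequencies
#'   (sums to 1 within 1e-9).
#' @param vj_pairs Integer pair index per clone (into the model's panel).
#' @param model A `bias_model`.
#' @param depth Total expected read count.
#' @param seed Integer seed.
#' @param drop_zero Drop clones with a realized count of 0 (sampling
#'   dropout), default `TRUE`.
#' @return A clonotype table (see [clonotype_table()]) with random CDR3
#'   sequences; the true frequency and pair of each clone are kept in
#'   columns `true_freq` and `pair`.
#' @export
simulate_repertoire <- function(clone_freqs, vj_pairs, model, depth, seed,
                                drop_zero = TRUE) {
  stopifnot(inherits(model, "bias_model"))
  if (missing(seed)) stop("simulate_repertoire() requires a seed", call. = FALSE)
  if (abs(sum(clone_freqs) - 1) > 1e-9) {
    stop("clone frequencies must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  vj_pairs <- as.integer(vj_pairs)
  if (length(vj_pairs) != length(clone_freqs) ||
      any(vj_pairs < 1 | vj_pairs > n_pairs(model$panel))) {
    stop("vj_pairs must give a valid pair index per clone", call. = FALSE)
  }
  eff <- clone_freqs * model$st_means[vj_pairs]
  mu <- depth * eff / sum(eff)
  withr_seed(seed, {
    counts <- rnb_md(length(mu), mu, model$dispersion)
    cdr3 <- vapply(seq_along(mu), function(i) {
      paste(sample(c("A", "C", "G", "T"), 36, replace = TRUE), collapse = "")
    }, character(1))
    pn <- pair_names(model$panel, vj_pairs)
    tbl <- clonotype_table(cdr3, pn$v_name, pn$j_name, counts)
    tbl$true_freq <- clone_freqs
    tbl$pair <- vj_pairs
    if (drop_zero) tbl <- tbl[tbl$raw_count > 0, ]
    tbl
  })
}

mutate_bases <- function(seqs, error_rate) {
  if (error_rate == 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- stats::runif(length(ch)) < error_rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(bases, b), 1)
      }, character(1))
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a barcoded FASTQ fixture with a truth table
#'
#' Emits, for each template `i`, `st_reads[i]` synthetic reads embedding the
#' universal barcode immediately followed by template `i`'s specific barcode
#' at a randomized offset inside random flanking sequence, plus the supplied
#' clonotype-like reads; optional uniform substitution errors. The truth
#' table records each read's origin so demultiplexing can be scored exactly.
#'
#' @param design An `st_design`.
#' @param st_reads Integer vector of reads to emit per template
#'   (length `n_pairs`).
#' @param clonotype_reads Character vector of non-ST read sequences (may be
#'   empty).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param read_length Length of the emitted ST reads (bp).
#' @param path Optional FASTQ output path; when given the reads are written
#'   as 4-line FASTQ records with constant placeholder qualities.
#' @return A tibble (`read_id`, `seq`, `origin`) where `origin` is the
#'   1-based pair index for ST reads and `NA` for clonotype reads.
#' @export
generate_fixture_fastq <- function(design, st_reads, clonotype_reads =
                                     character(), error_rate = 0, seed,
                                   read_length = 120L, path = NULL) {
  stopifnot(inherits(design, "st_design"))
  if (missing(seed)) {
    stop("generate_fixture_fastq() requires a seed", call. = FALSE)
  }
  if (error_rate < 0 || error_rate >= 1) {
    stop("error_rate must be in [0, 1)", call. = FALSE)
  }
  st_reads <- as.integer(st_reads)
  if (length(st_reads) != n_pairs(design$panel) || any(st_reads < 0)) {
    stop("st_reads must be a non-negative count per template", call. = FALSE)
  }
  ins_len <- nchar(design$universal_barcode) +
    nchar(design$specific_barcodes[1])
  if (read_length < ins_len + 2L) {
    stop("read_length too short for the barcode insert", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  withr_seed(seed, {
    origin <- rep(seq_along(st_reads), st_reads)
    st_seqs <- vapply(origin, function(i) {
      insert <- paste0(design$universal_barcode, design$specific_barcodes[i])
      flank <- read_length - nchar(insert)
      left <- sample.int(flank - 1L, 1)
      paste0(
        paste(sample(bases, left, replace = TRUE), collapse = ""),
        insert,
        paste(sample(bases, flank - left, replace = TRUE), collapse = ""))
    }, character(1))
    seqs <- mutate_bases(c(st_seqs, as.character(clonotype_reads)), error_rate)
    truth <- tibble::tibble(
      read_id = sprintf("read_%04d", seq_along(seqs)),
      seq = seqs,
      origin = c(origin, rep(NA_integer_, length(clonotype_reads))))
    if (!is.null(path)) write_fastq(truth$read_id, truth$seq, path)
    truth
  })
}

#' Write sequences as FASTQ with placeholder qualities
#'
#' @param ids Read identifiers.
#' @param seqs Character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' Parses 4-line FASTQ records (qualities are not retained). Malformed
#' input is reported with the offending record number.
#'
#' @param path FASTQ path (optionally gzipped).
#' @return A tibble with columns `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      lines <- readLines(path, warn = FALSE)
      rec <- NA_integer_
      if (length(lines) %% 4 != 0) {
        rec <- length(lines) %/% 4 + 1L
      } else {
        at <- seq(1, length(lines), by = 4)
        bad <- which(!startsWith(lines[at], "@") |
                       !startsWith(lines[at + 2], "+"))
        if (length(bad)) rec <- bad[1]
      }
      stop("malformed FASTQ record ", rec, " in ", path, ": ",
           conditionMessage(e), call. = FALSE)
    })
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(x)),
    seq = unname(as.character(x)))
}
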