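# Independent brute-force oracles and tiny fixtures shared across tests.

# Levenshtein distance by the classic quadratic DP (independent of
# utils::adist, which the package uses).
lev_dp <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca)
  nb <- length(cb)
  d <- matrix(0L, na + 1L, nb + 1L)
  d[, 1] <- 0:na
  d[1, ] <- 0:nb
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      cost <- if (ca[i] == cb[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + cost)
    }
  }
  d[na + 1, nb + 1]
}

# leftmost window at edit distance <= max_dist, by exhaustive enumeration
brute_find_barcode <- function(read, barcode, max_dist) {
  n <- nchar(read)
  len <- nchar(barcode)
  for (start in seq_len(n)) {
    dists <- integer()
    for (l in max(1, len - max_dist):(len + max_dist)) {
      if (start + l - 1 > n) next
      dists <- c(dists, lev_dp(substr(read, start, start + l - 1), barcode))
    }
    if (length(dists) && min(dists) <= max_dist) {
      return(list(position = start, distance = min(dists)))
    }
  }
  NULL
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

tiny_panel <- function() primer_panel(c("Va", "Vb"), c("Ja", "Jb", "Jc"))

tiny_design <- function(seed = 11) make_st_design(tiny_panel(), seed = seed)

# st_counts from an explicit matrix on a panel sized to match
counts_fixture <- function(m, batch_id = "b1", concentration = 1) {
  nv <- if (nrow(m) %% 2 == 0) 2 else 1
  panel <- primer_panel(sprintf("V%d", seq_len(nv)),
                        sprintf("J%d", seq_len(nrow(m) / nv)))
  st_counts(m, panel, batch_id = batch_id, concentration = concentration)
}
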