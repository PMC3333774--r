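# Independent brute-force oracles and fixture builders.  These deliberately
# avoid the package's compiled kernel and accelerated paths so that tests
# compare two independent routes to the same answer.

# hamming distance with N mismatching everything, character-by-character
oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  sum(ca != cb | ca == "N" | cb == "N")
}

# minimal-distance best-stratum assignment by exhaustive search
oracle_assign <- function(seq, lib_seqs, max_mismatch = 2L) {
  d <- vapply(lib_seqs, function(s) oracle_hamming(seq, s), numeric(1),
              USE.NAMES = FALSE)
  dmin <- min(d)
  if (dmin > max_mismatch) return(list(status = "unmapped", idx = NA, distance = NA))
  at_min <- which(d == dmin)
  if (length(at_min) > 1L) return(list(status = "ambiguous", idx = NA, distance = NA))
  list(status = "unique", idx = at_min, distance = dmin)
}

# all-pairs distance histogram by exhaustive enumeration
oracle_pair_hist <- function(seqs) {
  n <- length(seqs)
  d <- integer(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) d <- c(d, oracle_hamming(seqs[i], seqs[j]))
  }
  d
}

# zero-FPR FNR and FPR-at-FNR-5% by exhaustive threshold sweep
# (calls are "score < threshold")
oracle_sweep <- function(null_scores, depl_scores) {
  ths <- sort(unique(c(null_scores, depl_scores, Inf, -Inf)))
  fpr <- vapply(ths, function(t) mean(null_scores < t), numeric(1))
  fnr <- vapply(ths, function(t) mean(depl_scores >= t), numeric(1))
  zero_fpr <- fpr == 0
  ok5 <- fnr <= 0.05
  list(fnr_at_zero_fpr = min(fnr[zero_fpr]),
       fpr_at_fnr5 = if (any(ok5)) min(fpr[ok5]) else NA_real_)
}

random_seq <- function(n, len = 19L) {
  vapply(seq_len(n), function(i)
    paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

# write a plain 4-line-per-record FASTQ
write_fastq <- function(seqs, path, quals = NULL) {
  quals <- quals %||% strrep("I", nchar(seqs))
  lines <- if (length(seqs))
    paste0("@r", seq_along(seqs), "\n", seqs, "\n+\n", quals) else character(0)
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small in-memory library fixture
tiny_lib <- function(seqs, ids = paste0("h", seq_along(seqs)),
                     genes = paste0("G", seq_along(seqs))) {
  hairpin_library(tibble::tibble(construct_id = ids, gene_symbol = genes,
                                 sense_seq = seqs))
}

# embed 19-mers into 26-base reads with the default window (3..21)
embed_read <- function(sense, flank5 = "TA", flank3 = "GGCAG") {
  paste0(flank5, sense, flank3)
}
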