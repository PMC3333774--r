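#' Read sequences from a FASTQ file
#'
#' Reads a (possibly gzip-compressed) FASTQ file and returns the read
#' sequences as a character vector.  Base qualities are parsed and discarded:
#' identical reads are binned regardless of quality, so qualities never
#' influence counting.
#'
#' @param path FASTQ path, plain or `.gz`.
#' @param expect_length If set, reads of any other length are returned as
#'   `NA` so that downstream tallies route them to `filtered` instead of
#'   failing.
#' @return Character vector of read sequences (upper case; `NA` for
#'   length-mismatched reads when `expect_length` is set).
#' @export
read_fastq_seqs <- function(path, expect_length = NULL) {
  if (!file.exists(path)) abort(paste0("FASTQ file not found: ", path))
  fail <- function(rec, why) {
    abort(sprintf("malformed/truncated FASTQ record at record %d of '%s' (%s)",
                  rec, path, why))
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      n_lines <- count_lines(path)
      fail(n_lines %/% 4 + 1, conditionMessage(e))
    })
  # a trailing partial record parses silently in some readers: every record
  # must occupy exactly four lines
  n_lines <- count_lines(path)
  if (n_lines != 4L * length(seqs))
    fail(length(seqs) + (n_lines > 4L * length(seqs)), "incomplete record")
  out <- toupper(as.character(seqs, use.names = FALSE))
  if (!is.null(expect_length)) out[nchar(out) != expect_length] <- NA_character_
  out
}

# newline count through a (possibly gzip) connection, in chunks
count_lines <- function(path) {
  con <- gzfile(path, "rb")  # gzfile reads plain files transparently
  on.exit(close(con))
  n <- 0L
  last <- as.raw(10L)
  repeat {
    chunk <- readBin(con, "raw", n = 1048576L)
    if (!length(chunk)) break
    n <- n + sum(chunk == as.raw(10L))
    last <- chunk[length(chunk)]
  }
  if (last != as.raw(10L)) n <- n + 1L  # file not ending in a newline
  n
}

#' Trim reads to the sense window
#'
#' Extracts the 1-based inclusive window (`trim_start`..`trim_end`) holding
#' the 19-nt sense sequence -- bases 3 to 21 of a 26-base read for the
#' sequencing chemistry this package models.  Output is upper case and `.`
#' (an alternative uncalled-base symbol) is mapped to `N`.  Reads shorter
#' than `trim_end` yield `NA` and are tallied as filtered by the caller.
#'
#' @param seqs Character vector of raw read sequences.
#' @param trim_start,trim_end 1-based inclusive window.
#' @return Character vector of trimmed sequences (`NA` where too short).
#' @export
trim_reads <- function(seqs, trim_start = 3L, trim_end = 21L) {
  if (trim_start < 1L || trim_end < trim_start)
    abort("invalid trim window")
  out <- substr(seqs, trim_start, trim_end)
  len <- nchar(seqs)
  len[is.na(len)] <- 0L
  out[len < trim_end] <- NA_character_
  out <- toupper(out)
  gsub(".", "N", out, fixed = TRUE)
}

#' Uncalled-base filter
#'
#' A trimmed read is kept if it contains at most `max_n` uncalled bases
#' (`N`) in the sense window; the default of two follows the base-calling
#' convention the package models.
#'
#' @param seqs Character vector of trimmed sequences.
#' @param max_n Maximum number of `N` bases tolerated.
#' @return Logical vector, `TRUE` = keep (`FALSE` for `NA` input).
#' @export
filter_uncalled <- function(seqs, max_n = 2L) {
  n_count <- stringr::str_count(seqs, stringr::fixed("N"))
  !is.na(seqs) & n_count <= max_n
}

#' Hamming distance between equal-length sequences
#'
#' Counts mismatching positions, with an uncalled base (`N`) mismatching
#' every base including another `N`: an uncalled position carries no
#' evidence of identity, and counting it as a mismatch composes correctly
#' with the mismatch cap.  Vectorized over pairs.
#'
#' @param a,b Character vectors of equal-length sequences (recycled).
#' @param cap Distances above `cap` are reported as `cap + 1`.
#' @return Integer vector of distances.
#' @export
hamming_distance <- function(a, b, cap = .Machine$integer.max) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) hamming_cpp(a[i], b[i], as.integer(cap)),
         integer(1))
}

#' Bin identical trimmed reads
#'
#' @param trimmed Character vector of trimmed sequences (no `NA`s).
#' @return Tibble with columns `trimmed_seq` and `multiplicity`.
#' @export
bin_reads <- function(trimmed) {
  tibble(trimmed_seq = trimmed) |>
    count(.data$trimmed_seq, name = "multiplicity")
}

#' Assign read bins to library hairpins
#'
#' Best-stratum minimal-hamming assignment: each bin is assigned to the
#' library sequence at minimal distance if that minimum is attained by
#' exactly one sequence and does not exceed `max_mismatch`.  Ties at the
#' minimal distance are `ambiguous` (a unique hit at distance 1 still wins
#' even if several sequences sit at distance 2); minima above the cap are
#' `unmapped`.  Exact matches are resolved through a hash lookup before the
#' distance search -- semantically identical to the brute-force search
#' because distance 0 is uniquely minimal unless the library itself contains
#' duplicate sense sequences, which the lookup detects and reports as
#' ambiguous.
#'
#' @param bins Tibble from [bin_reads()], or a character vector of sequences.
#' @param lib A `hairpin_library`.
#' @param max_mismatch Mismatch cap (default 2).
#' @return The input tibble with columns `status` (`unique`, `ambiguous`,
#'   `unmapped`), `construct_id` and `distance` (`NA` unless unique).
#' @export
assign_bins <- function(bins, lib, max_mismatch = 2L) {
  stopifnot(inherits(lib, "hairpin_library"))
  if (!nrow(lib)) abort("empty hairpin library")
  if (is.character(bins)) bins <- tibble(trimmed_seq = bins, multiplicity = 1L)
  seqs <- bins$trimmed_seq

  status <- rep(NA_character_, length(seqs))
  construct <- rep(NA_character_, length(seqs))
  distance <- rep(NA_integer_, length(seqs))

  # distance-0 short circuit via hash lookup
  dup_seqs <- unique(lib$sense_seq[duplicated(lib$sense_seq)])
  exact <- match(seqs, lib$sense_seq)
  hit0 <- !is.na(exact)
  amb0 <- hit0 & seqs %in% dup_seqs
  uni0 <- hit0 & !amb0
  status[amb0] <- "ambiguous"
  status[uni0] <- "unique"
  construct[uni0] <- lib$construct_id[exact[uni0]]
  distance[uni0] <- 0L

  todo <- which(!hit0)
  if (length(todo)) {
    res <- align_bins_cpp(seqs[todo], lib$sense_seq, as.integer(max_mismatch))
    d <- res[, "distance"]
    unmapped <- is.na(d)
    amb <- !unmapped & res[, "n_best"] > 1L
    uni <- !unmapped & !amb
    status[todo[unmapped]] <- "unmapped"
    status[todo[amb]] <- "ambiguous"
    status[todo[uni]] <- "unique"
    construct[todo[uni]] <- lib$construct_id[res[uni, "best_idx"]]
    distance[todo[uni]] <- d[uni]
  }
  bins$status <- status
  bins$construct_id <- construct
  bins$distance <- distance
  bins
}

#' Align one FASTQ sample against a hairpin library
#'
#' The full per-sample deconvolution: read, trim to the sense window, drop
#' reads with more than `max_n` uncalled bases, bin identical sequences, and
#' assign each bin at minimal hamming distance with ambiguity exclusion.
#' Returns an `alignment_tally` holding per-construct, per-edit-distance
#' read counts and the exact read bookkeeping
#' `filtered + unique + ambiguous + unmapped = total`.
#'
#' @param fastq FASTQ path (plain or gzip), or a character vector of raw
#'   read sequences.
#' @param lib A `hairpin_library`.
#' @param sample_id Sample label for the tally.
#' @param trim_start,trim_end Sense window (1-based inclusive).
#' @param max_mismatch Mismatch cap for assignment.
#' @param max_n Uncalled-base tolerance within the window.
#' @return An `alignment_tally`: list with `sample_id`, `counts` (tibble
#'   `construct_id`, `distance`, `reads`) and `totals`.
#' @export
align_sample <- function(fastq, lib, sample_id = NULL,
                         trim_start = 3L, trim_end = 21L,
                         max_mismatch = 2L, max_n = 2L) {
  stopifnot(inherits(lib, "hairpin_library"))
  if (is.character(fastq) && length(fastq) == 1L && file.exists(fastq)) {
    sample_id <- sample_id %||% sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq))
    seqs <- read_fastq_seqs(fastq)
  } else {
    sample_id <- sample_id %||% "sample"
    seqs <- toupper(as.character(fastq))
  }
  total <- length(seqs)
  trimmed <- trim_reads(seqs, trim_start, trim_end)
  keep <- filter_uncalled(trimmed, max_n)
  filtered <- sum(!keep)
  bins <- bin_reads(trimmed[keep])
  bins <- assign_bins(bins, lib, max_mismatch)

  by_status <- bins |>
    summarise(reads = sum(.data$multiplicity), .by = "status")
  n_of <- function(s) {
    i <- match(s, by_status$status)
    if (is.na(i)) 0L else by_status$reads[i]
  }
  counts <- bins |>
    filter(.data$status == "unique") |>
    summarise(reads = sum(.data$multiplicity),
              .by = c("construct_id", "distance")) |>
    arrange(match(.data$construct_id, lib$construct_id), .data$distance)

  structure(
    list(
      sample_id = sample_id,
      counts = counts,
      totals = list(total = total, filtered = filtered,
                    unique = n_of("unique"), ambiguous = n_of("ambiguous"),
                    unmapped = n_of("unmapped")),
      params = list(trim_start = trim_start, trim_end = trim_end,
                    max_mismatch = max_mismatch, max_n = max_n,
                    library = attr(lib, "name"))
    ),
    class = "alignment_tally"
  )
}

#' @export
print.alignment_tally <- function(x, ...) {
  t <- x$totals
  cat(sprintf(
    "<alignment_tally '%s': %d reads | filtered %d, unique %d, ambiguous %d, unmapped %d>\n",
    x$sample_id, t$total, t$filtered, t$unique, t$ambiguous, t$unmapped))
  invisible(x)
}

#' Per-sample alignment statistics
#'
#' @param tallies A list of `alignment_tally` objects (or a single one).
#' @return Tibble with one row per sample: read bookkeeping totals and
#'   unique reads split by edit distance (`unique_d0`, `unique_d1`, ...).
#' @export
alignment_stats <- function(tallies) {
  if (inherits(tallies, "alignment_tally")) tallies <- list(tallies)
  map(tallies, function(t) {
    base <- tibble(sample_id = t$sample_id, total = t$totals$total,
                   filtered = t$totals$filtered, unique = t$totals$unique,
                   ambiguous = t$totals$ambiguous, unmapped = t$totals$unmapped)
    dmax <- t$params$max_mismatch
    for (d in 0:dmax) {
      base[[paste0("unique_d", d)]] <-
        sum(t$counts$reads[t$counts$distance == d])
    }
    base
  }) |> list_rbind()
}

#' Collapse alignment tallies into a count matrix
#'
#' Distance-resolved counts are summed per construct; rows follow library
#' order and every library construct is present (zero where unseen); one
#' column per sample.
#'
#' @param tallies List of `alignment_tally` objects from the same library.
#' @param lib The `hairpin_library` they were aligned against.
#' @return Tibble: `construct_id` plus one integer column per sample.
#' @export
count_matrix <- function(tallies, lib) {
  if (inherits(tallies, "alignment_tally")) tallies <- list(tallies)
  ids <- vapply(tallies, function(t) t$sample_id, "")
  if (anyDuplicated(ids))
    abort(paste0("duplicate sample_id: ", ids[duplicated(ids)][1]))
  out <- tibble(construct_id = lib$construct_id)
  for (t in tallies) {
    col <- t$counts |> summarise(reads = sum(.data$reads), .by = "construct_id")
    v <- col$reads[match(out$construct_id, col$construct_id)]
    v[is.na(v)] <- 0L
    out[[t$sample_id]] <- as.integer(v)
  }
  out
}

#' Write a count matrix and companion per-sample stats
#'
#' @inheritParams count_matrix
#' @param path Output TSV for the count matrix.
#' @param stats_path Output TSV for per-sample statistics (default:
#'   `path` with a `.stats.tsv` suffix).
#' @return The count-matrix tibble, invisibly.
#' @export
write_count_matrix <- function(tallies, lib, path,
                               stats_path = sub("\\.tsv$", ".stats.tsv", path)) {
  if (inherits(tallies, "alignment_tally")) tallies <- list(tallies)
  cm <- count_matrix(tallies, lib)
  params <- tallies[[1]]$params
  write_tsv_commented(cm, path, params)
  write_tsv_commented(alignment_stats(tallies), stats_path, params)
  invisible(cm)
}

#' Read a count matrix TSV
#'
#' First column `construct_id`, one integer column per sample; `#` comment
#' headers are skipped.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_count_matrix <- function(path) {
  cm <- read_tsv_commented(path)
  if (names(cm)[1] != "construct_id")
    abort("count matrix must have 'construct_id' as its first column")
  if (anyDuplicated(cm$construct_id)) abort("duplicate construct_id rows")
  num <- setdiff(names(cm), "construct_id")
  if (any(vapply(cm[num], function(x) any(x < 0 | x != floor(x)), TRUE)))
    abort("counts must be non-negative integers")
  cm[num] <- lapply(cm[num], as.integer)
  cm
}
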