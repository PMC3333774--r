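#' Construct a hairpin reference library
#'
#' A hairpin library is the set of 19-nucleotide shRNA sense sequences that
#' sequencing reads are aligned against, one row per construct with a unique
#' `construct_id`, a `gene_symbol` annotation, the `sense_seq`, and an
#' optional `gene_id`.  Duplicate sense sequences are allowed (two constructs
#' can share a barcode) but force ambiguity at distance zero; they are
#' reported by [duplicate_sense_pairs()].
#'
#' @param x A data frame with columns `construct_id`, `gene_symbol`,
#'   `sense_seq` and optionally `gene_id`.
#' @param name Library name used in reports.
#' @param sense_length Required sense-sequence length (19 for the screens
#'   this package models).
#' @return A tibble of class `hairpin_library`.
#' @export
hairpin_library <- function(x, name = "library", sense_length = 19L) {
  need <- c("construct_id", "gene_symbol", "sense_seq")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    abort(paste0("hairpin library lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  lib <- as_tibble(x)
  if (!"gene_id" %in% names(lib)) lib$gene_id <- NA_character_
  lib <- lib[c("construct_id", "gene_symbol", "sense_seq", "gene_id")]
  lib$construct_id <- as.character(lib$construct_id)
  lib$gene_symbol <- as.character(lib$gene_symbol)
  lib$sense_seq <- toupper(as.character(lib$sense_seq))

  if (any(!nzchar(lib$construct_id)) || anyNA(lib$construct_id))
    abort("construct_id must be non-empty")
  dup <- lib$construct_id[duplicated(lib$construct_id)]
  if (length(dup))
    abort(paste0("duplicate construct_id: ", paste(unique(dup), collapse = ", ")))
  bad_len <- nchar(lib$sense_seq) != sense_length
  bad_chr <- grepl(paste0("[^ACGT]"), lib$sense_seq)
  bad <- bad_len | bad_chr
  if (any(bad)) {
    abort(paste0(
      "invalid sense sequence (must be ", sense_length, " nt over A/C/G/T) for construct(s): ",
      paste(head(lib$construct_id[bad], 5), collapse = ", "),
      if (sum(bad) > 5) sprintf(" and %d more", sum(bad) - 5)
    ))
  }
  structure(lib, name = name, sense_length = sense_length,
            class = c("hairpin_library", class(lib)))
}

#' Read a tab-delimited hairpin library
#'
#' The expected format is plain TSV with columns `construct_id`,
#' `gene_symbol`, `sense_seq` and an optional fourth `gene_id` column, in
#' that order.  A header line is auto-detected (the third field of a header
#' is not a valid nucleotide sequence) unless `has_header` is set explicitly.
#' Windows line endings are tolerated.
#'
#' @param path Path to the TSV file.
#' @param has_header `TRUE`, `FALSE`, or `NA` to auto-detect.
#' @param name Library name; defaults to the file name.
#' @inheritParams hairpin_library
#' @return A `hairpin_library` tibble, rows in file order.
#' @export
read_hairpin_library <- function(path, has_header = NA,
                                 name = basename(path), sense_length = 19L) {
  if (!file.exists(path)) abort(paste0("library file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) abort("library file is empty")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3L | nf > 4L)
  if (length(bad))
    abort(sprintf("malformed library row at line %d: expected 3 or 4 tab-separated columns, found %d",
                  bad[1], nf[bad[1]]))
  if (is.na(has_header)) {
    third <- toupper(fields[[1]][3])
    has_header <- !grepl("^[ACGTN]+$", third)
  }
  if (has_header) {
    fields <- fields[-1]
    if (!length(fields)) abort("library file has a header but no records")
  }
  df <- tibble(
    construct_id = vapply(fields, `[`, "", 1),
    gene_symbol  = vapply(fields, `[`, "", 2),
    sense_seq    = vapply(fields, `[`, "", 3),
    gene_id      = vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_, "")
  )
  hairpin_library(df, name = name, sense_length = sense_length)
}

#' Write a hairpin library back to TSV
#'
#' Inverse of [read_hairpin_library()]: tab-delimited, no comment header, so
#' that a read/write round trip reproduces the original content.
#'
#' @param lib A `hairpin_library`.
#' @param path Output path.
#' @param header Write a header line (default `FALSE`, matching the bare
#'   format most library files use).
#' @return `path`, invisibly.
#' @export
write_hairpin_library <- function(lib, path, header = FALSE) {
  stopifnot(inherits(lib, "hairpin_library"))
  df <- as.data.frame(lib)
  if (all(is.na(df$gene_id))) df$gene_id <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Report constructs sharing a sense sequence
#'
#' Constructs with identical sense sequences cannot be told apart by the
#' aligner: every read matching them is ambiguous at distance zero.
#'
#' @param lib A `hairpin_library`.
#' @return A tibble with one row per shared `sense_seq`, listing
#'   `construct_ids` and the number of constructs `n`.
#' @export
duplicate_sense_pairs <- function(lib) {
  stopifnot(inherits(lib, "hairpin_library"))
  as_tibble(lib) |>
    summarise(n = n(),
              construct_ids = paste(.data$construct_id, collapse = ","),
              .by = "sense_seq") |>
    filter(.data$n > 1L)
}

#' Pairwise hamming-distance profile of a library
#'
#' A QC summary of library separability: the histogram of hamming distances
#' over all unordered sequence pairs, bucketed at `0..max_report` plus an
#' overflow bucket.  A well-designed library has essentially all pairs beyond
#' the aligner's mismatch cap, so mismatch-tolerant counting cannot confuse
#' constructs.  Brute-force over all n(n-1)/2 pairs with early exit; intended
#' for QC, not for very large libraries in tight loops.
#'
#' @param lib A `hairpin_library`.
#' @param max_report Largest distance reported individually.
#' @param mismatch_cap The aligner's mismatch cap, used for the
#'   `pairs_within_cap` summary attribute (must be `<= max_report`).
#' @return A tibble with columns `distance` (`"0"`..`"max_report"`,
#'   `">max_report"`) and `n_pairs`; attributes `pairs_within_cap` and
#'   `total_pairs`.
#' @export
edit_distance_profile <- function(lib, max_report = 5L, mismatch_cap = 2L) {
  stopifnot(inherits(lib, "hairpin_library"))
  if (!nrow(lib)) abort("library is empty")
  if (mismatch_cap > max_report) abort("mismatch_cap must be <= max_report")
  hist <- pairwise_hamming_hist_cpp(lib$sense_seq, as.integer(max_report))
  out <- tibble(
    distance = c(as.character(0:max_report), paste0(">", max_report)),
    n_pairs = as.integer(hist)
  )
  attr(out, "pairs_within_cap") <- sum(hist[seq_len(mismatch_cap + 1L)])
  attr(out, "total_pairs") <- nrow(lib) * (nrow(lib) - 1L) / 2
  out
}

#' @export
print.hairpin_library <- function(x, ...) {
  cat(sprintf("<hairpin_library '%s': %d constructs, %d genes, %d-nt sense>\n",
              attr(x, "name"), nrow(x),
              length(unique(x$gene_symbol)), attr(x, "sense_length")))
  NextMethod()
}
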