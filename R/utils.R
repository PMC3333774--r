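#' Write a TSV with a reproducibility header
#'
#' Every table the package writes carries `#`-prefixed comment lines recording
#' the package version and the effective parameters that produced it, so a
#' result file is self-describing.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param params Named list of parameters to record in the header.
#' @return `path`, invisibly.
#' @export
write_tsv_commented <- function(x, path, params = list()) {
  header <- c(
    paste0("# poolscreen ", as.character(packageVersion("poolscreen"))),
    if (length(params)) {
      paste0("# ", names(params), " = ",
             vapply(params, function(p) paste(format(p), collapse = ","), ""))
    }
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_commented()]
#'
#' @param path File path; `#` comment lines are skipped.
#' @return A tibble.
#' @export
read_tsv_commented <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

# Derive a stream of reproducible sub-seeds from one master seed without
# disturbing the caller's RNG state.  Drawing n + k seeds leaves the first n
# unchanged, so adding samples or replicates never perturbs earlier ones.
derive_seeds <- function(master_seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Standardize an arm label to "reference"/"test".
normalize_arm <- function(arm) {
  out <- dplyr::case_match(
    tolower(as.character(arm)),
    c("reference", "ref", "control") ~ "reference",
    c("test", "treatment", "depletion", "depleted") ~ "test",
    .default = NA_character_
  )
  if (anyNA(out)) {
    abort(paste0("unknown arm label(s): ",
                 paste(unique(arm[is.na(out)]), collapse = ", "),
                 " (expected 'reference' or 'test')"))
  }
  out
}

#' Validate a sample sheet
#'
#' A sample sheet maps count-matrix columns to screen structure: one row per
#' sample with `sample_id`, `pool_id`, `arm` (`"reference"` or `"test"`) and
#' `replicate_id`.  Each (pool, replicate) must contain exactly one reference
#' and one test sample.
#'
#' @param sheet A data frame with columns `sample_id`, `pool_id`, `arm`,
#'   `replicate_id`.
#' @return A validated tibble with normalized arm labels.
#' @export
sample_sheet <- function(sheet) {
  need <- c("sample_id", "pool_id", "arm", "replicate_id")
  missing_cols <- setdiff(need, names(sheet))
  if (length(missing_cols))
    abort(paste0("sample sheet lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  out <- as_tibble(sheet)[need]
  out$sample_id <- as.character(out$sample_id)
  out$arm <- normalize_arm(out$arm)
  if (anyDuplicated(out$sample_id))
    abort("duplicate sample_id in sample sheet")
  bad <- out |>
    count(.data$pool_id, .data$replicate_id, .data$arm) |>
    filter(.data$n != 1L)
  pairing <- out |>
    count(.data$pool_id, .data$replicate_id) |>
    filter(.data$n != 2L)
  if (nrow(bad) || nrow(pairing))
    abort("each (pool_id, replicate_id) needs exactly one reference and one test sample")
  out
}
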