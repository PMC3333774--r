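#' Read a flat key = value run configuration
#'
#' The configuration format is deliberately minimal: one `key = value` pair
#' per line, `#` comments and blank lines ignored (a YAML-compatible
#' subset, trivially diffable).  Values stay strings; [run_pipeline()]
#' coerces them.
#'
#' @param path Config file path.
#' @return Named list of character values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*)$", lines))
  if (any(lengths(kv) != 3L))
    abort(paste0("cannot parse config line: ", lines[which(lengths(kv) != 3L)[1]]))
  setNames(lapply(kv, function(m) trimws(m[3])),
           vapply(kv, `[`, "", 2))
}

pipeline_defaults <- function() {
  list(
    seed = 1L, outdir = "poolscreen_out",
    # simulation
    simulate = FALSE, n_hairpins = 10000L, abundance_sigma = 0.5,
    depletion = "1000x0.75,1000x0.5,1000x0.25", noise_sigma = 0.08,
    reads_per_sample = 1e7, n_replicates = 2L, emit_fastq = FALSE,
    sim_reads = 1e6, read_error_rate = 0.005, n_rate = 0.001,
    # alignment
    library = NULL, fastq = NULL, sample_ids = NULL, counts = NULL,
    samples = NULL, trim_start = 3L, trim_end = 21L, max_mismatch = 2L,
    max_n = 2L,
    # normalization
    pseudocount = 0.5, span = 0.5, degree = 1L, loess_family = "symmetric",
    min_ref_count = 100, quantile_normalize = FALSE, rank_only = FALSE,
    summary = "median", s0_quantile = 0.9,
    # hit calling
    deviation_k = 0.5, alpha = 0.75, permutations = 1000L,
    call_genes = FALSE
  )
}

coerce_config <- function(cfg) {
  def <- pipeline_defaults()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  out <- def
  for (k in names(cfg)) {
    v <- cfg[[k]]
    proto <- def[[k]]
    out[[k]] <-
      if (is.logical(proto)) tolower(as.character(v)) %in% c("true", "1", "yes")
      else if (is.integer(proto)) as.integer(v)
      else if (is.numeric(proto)) as.numeric(v)
      else as.character(v)
  }
  out
}

#' Run the full screen-analysis workflow
#'
#' Ties the stages into one deterministic run: simulate a screen (or align
#' supplied FASTQ files, or load a count matrix), normalize and score,
#' call hits, and -- when simulation truth exists -- evaluate detection
#' performance.  Every stage writes the same TSV the corresponding
#' subcommand/function produces, a structured `run.log` records per-stage
#' read and hairpin tallies, and the effective configuration is written
#' verbatim to the output directory, so a run is reproducible from its
#' outputs alone.
#'
#' @param config Named list of settings, or a path to a `key = value` file
#'   for [read_run_config()].  Unset keys take package defaults.
#' @param overrides Named list applied over `config` (CLI flags beat file).
#' @return Invisibly, a list with the stage results (`counts`, `scores`,
#'   `hits`, `eval` where applicable) and `outdir`.
#' @export
run_pipeline <- function(config = list(), overrides = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- read_run_config(config)
  config[names(overrides)] <- overrides
  cfg <- coerce_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$outdir, "run.log")
  logf <- function(stage, ...) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                    stage, sprintf(...))
    cat(line, "\n")
    cat(line, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logf(name, "FAILED: %s", conditionMessage(e))
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  # effective config, verbatim
  writeLines(paste0(names(cfg), " = ",
                    vapply(cfg, function(v)
                      if (is.null(v)) "" else paste(format(v), collapse = ","),
                      "")),
             file.path(cfg$outdir, "config.effective"))
  out <- list(outdir = cfg$outdir)

  lib <- NULL
  if (!is.null(cfg$library)) {
    lib <- stage("library", read_hairpin_library(cfg$library))
    logf("library", "%d constructs from %s", nrow(lib), cfg$library)
  }

  sim <- NULL
  if (cfg$simulate) {
    sc_cfg <- sim_config(n_hairpins = cfg$n_hairpins,
                         abundance_sigma = cfg$abundance_sigma,
                         depletion = cfg$depletion,
                         noise_sigma = cfg$noise_sigma,
                         reads_per_sample = cfg$reads_per_sample,
                         n_replicates = cfg$n_replicates,
                         read_error_rate = cfg$read_error_rate,
                         n_rate = cfg$n_rate, seed = cfg$seed)
    if (is.null(lib) && cfg$emit_fastq)
      lib <- random_hairpin_library(cfg$n_hairpins, seed = cfg$seed)
    sim <- stage("simulate", simulate_screen(sc_cfg, lib = lib))
    write_tsv_commented(sim$truth, file.path(cfg$outdir, "truth.tsv"),
                        list(seed = cfg$seed))
    logf("simulate", "%d hairpins, %d samples",
         cfg$n_hairpins, 2L * cfg$n_replicates)
  }

  counts <- sheet <- NULL
  if (!is.null(sim) && cfg$emit_fastq) {
    # FASTQ-level route: emit reads per sample, then align them back
    tallies <- stage("align", {
      lapply(seq_len(nrow(sim$sheet)), function(i) {
        row <- sim$sheet[i, ]
        fq <- file.path(cfg$outdir, paste0(row$sample_id, ".fastq.gz"))
        emit_fastq(sim, lib, fq, n_reads = cfg$sim_reads, arm = row$arm,
                   seed = cfg$seed + i)
        align_sample(fq, lib, sample_id = row$sample_id,
                     trim_start = cfg$trim_start, trim_end = cfg$trim_end,
                     max_mismatch = cfg$max_mismatch, max_n = cfg$max_n)
      })
    })
    for (t in tallies)
      logf("align", "%s: total %d | filtered %d unique %d ambiguous %d unmapped %d",
           t$sample_id, t$totals$total, t$totals$filtered, t$totals$unique,
           t$totals$ambiguous, t$totals$unmapped)
    counts <- write_count_matrix(tallies, lib,
                                 file.path(cfg$outdir, "counts.tsv"))
    sheet <- sim$sheet
  } else if (!is.null(sim)) {
    counts <- sim$counts
    sheet <- sim$sheet
    write_tsv_commented(counts, file.path(cfg$outdir, "counts.tsv"),
                        list(seed = cfg$seed))
  } else if (!is.null(cfg$fastq)) {
    if (is.null(lib)) abort("alignment needs a library file")
    fastqs <- strsplit(cfg$fastq, ",", fixed = TRUE)[[1]]
    ids <- if (!is.null(cfg$sample_ids))
      strsplit(cfg$sample_ids, ",", fixed = TRUE)[[1]] else NULL
    tallies <- stage("align", {
      lapply(seq_along(fastqs), function(i)
        align_sample(fastqs[i], lib, sample_id = ids[i],
                     trim_start = cfg$trim_start, trim_end = cfg$trim_end,
                     max_mismatch = cfg$max_mismatch, max_n = cfg$max_n))
    })
    counts <- write_count_matrix(tallies, lib,
                                 file.path(cfg$outdir, "counts.tsv"))
    if (!is.null(cfg$samples)) sheet <- read_tsv_commented(cfg$samples)
  } else if (!is.null(cfg$counts)) {
    counts <- stage("counts", read_count_matrix(cfg$counts))
    if (is.null(cfg$samples)) abort("a sample sheet is required with --counts")
    sheet <- read_tsv_commented(cfg$samples)
  }
  out$counts <- counts

  if (!is.null(counts) && !is.null(sheet)) {
    scores <- stage("normalize", normalize_screen(
      counts, sheet, lib = lib, pseudocount = cfg$pseudocount,
      span = cfg$span, degree = cfg$degree, loess_family = cfg$loess_family,
      min_ref_count = cfg$min_ref_count,
      quantile_normalize = cfg$quantile_normalize, rank_only = cfg$rank_only,
      summary = cfg$summary, s0_quantile = cfg$s0_quantile))
    write_tsv_commented(scores$scores, file.path(cfg$outdir, "scores.tsv"),
                        scores$params)
    write_tsv_commented(scores$summary, file.path(cfg$outdir, "summary.tsv"),
                        scores$params)
    logf("normalize", "%d hairpins scored, %d filtered per pool",
         nrow(scores$summary), sum(!scores$summary$keep))
    out$scores <- scores

    hits <- stage("hits", call_hits(scores, deviation_k = cfg$deviation_k))
    write_tsv_commented(hits, file.path(cfg$outdir, "hits.tsv"),
                        list(deviation_k = cfg$deviation_k))
    logf("hits", "%d depleted, %d enriched",
         sum(hits$hit == "depleted", na.rm = TRUE),
         sum(hits$hit == "enriched", na.rm = TRUE))
    out$hits <- hits

    if (cfg$call_genes && (!is.null(lib) || "gene_symbol" %in% names(scores$summary))) {
      genes <- stage("genes", gene_scores(
        scores, lib = lib, alpha = cfg$alpha,
        n_perm = cfg$permutations, seed = cfg$seed))
      write_tsv_commented(genes, file.path(cfg$outdir, "genes.tsv"),
                          list(alpha = cfg$alpha, permutations = cfg$permutations))
      out$genes <- genes
    }

    if (!is.null(sim) && nrow(sim$config$depletion)) {
      ev <- stage("evaluate", evaluate_detection(
        scores, sim$truth, counts = counts, sheet = sheet))
      write_tsv_commented(ev$groups, file.path(cfg$outdir, "eval.tsv"),
                          list(seed = cfg$seed))
      logf("evaluate", "zero-FPR threshold %.3f, replicate r2 %s",
           ev$zero_fpr_threshold, format(ev$replicate_r2, digits = 4))
      out$eval <- ev
    }
  }
  invisible(out)
}
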