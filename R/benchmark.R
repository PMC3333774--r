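#' Engineered-depletion sensitivity benchmark
#'
#' Runs the full simulate -> normalize -> evaluate chain for a
#' single-depletion-group engineered screen and reports detection metrics
#' per seed.  Defaults reproduce the reference conditions the package's
#' sensitivity analysis is calibrated on: a 10,000-hairpin pool with 1,000
#' hairpins depleted, lognormal abundance (sigma 0.5), log2 multiplicative
#' noise 0.08, and 10^7 reads per sample, scored with the default pipeline
#' (pseudocount 0.5, robust loess span 0.5, pool-MAD rescaling).
#'
#' @param seeds Integer vector of simulation seeds (one screen per seed).
#' @param retention Retention factor of the depleted group (0.5 = 50%
#'   depleted).
#' @param n_depleted Size of the depleted group.
#' @param min_ref_count Abundance filter threshold (0 disables filtering).
#' @param n_hairpins,abundance_sigma,noise_sigma,reads_per_sample Generative
#'   parameters, see [sim_config()].
#' @return Tibble with one row per seed: `fnr_at_zero_fpr` and
#'   `fpr_at_fnr5` (percent), `mean_ratio`, `n_kept_depleted`.
#' @export
benchmark_depletion <- function(seeds, retention = 0.5, n_depleted = 1000L,
                                min_ref_count = 100,
                                n_hairpins = 10000L, abundance_sigma = 0.5,
                                noise_sigma = 0.08, reads_per_sample = 1e7) {
  map(seeds, function(s) {
    cfg <- sim_config(n_hairpins = n_hairpins,
                      abundance_sigma = abundance_sigma,
                      depletion = tibble(n = n_depleted, retention = retention),
                      noise_sigma = noise_sigma,
                      reads_per_sample = reads_per_sample,
                      n_replicates = 1L, seed = s)
    sim <- simulate_screen(cfg)
    sc <- normalize_screen(sim$counts, sim$sheet,
                           min_ref_count = min_ref_count)
    ev <- evaluate_detection(sc, sim$truth, counts = sim$counts,
                             sheet = sim$sheet)
    g <- ev$groups[1, ]
    tibble(seed = s,
           fnr_at_zero_fpr = 100 * g$fnr_at_zero_fpr,
           fpr_at_fnr5 = 100 * g$fpr_at_fnr5,
           mean_ratio = g$mean_ratio,
           n_kept_depleted = g$n)
  }) |> list_rbind()
}

#' Replicate-reproducibility benchmark
#'
#' Simulates biological replicates of the full three-level engineered-
#' depletion design (1,000 hairpins each at retention 0.75, 0.5 and 0.25 in
#' a 10,000-hairpin pool) and reports the squared Pearson correlation of
#' loess-normalized log2 ratios between replicates.
#'
#' @inheritParams benchmark_depletion
#' @param n_replicates Number of biological replicates (default 2).
#' @param depletion Depletion design (see [sim_config()]).
#' @return Tibble with one row per seed: `replicate_r2`.
#' @export
benchmark_reproducibility <- function(seeds, n_replicates = 2L,
                                      depletion = "1000x0.75,1000x0.5,1000x0.25",
                                      min_ref_count = 100,
                                      n_hairpins = 10000L,
                                      abundance_sigma = 0.5,
                                      noise_sigma = 0.08,
                                      reads_per_sample = 1e7) {
  map(seeds, function(s) {
    cfg <- sim_config(n_hairpins = n_hairpins,
                      abundance_sigma = abundance_sigma,
                      depletion = depletion, noise_sigma = noise_sigma,
                      reads_per_sample = reads_per_sample,
                      n_replicates = n_replicates, seed = s)
    sim <- simulate_screen(cfg)
    sc <- normalize_screen(sim$counts, sim$sheet,
                           min_ref_count = min_ref_count)
    tibble(seed = s, replicate_r2 = unname(replicate_r2(sc)[1]))
  }) |> list_rbind()
}

#' Hairpin detection completeness at a given read depth
#'
#' Simulates a null screen (no depletion) and reports the percentage of
#' hairpins receiving at least one read in every reference sample -- the
#' sequencing-coverage analogue of probe-above-background rates in
#' microarray deconvolution.
#'
#' @inheritParams benchmark_depletion
#' @param n_replicates Number of replicates (reference samples checked).
#' @param seed Single simulation seed.
#' @return One-row tibble: `pct_detected_all`, per-sample minimum
#'   `pct_detected_each`.
#' @export
benchmark_completeness <- function(seed = 1L, n_replicates = 4L,
                                   n_hairpins = 10000L, abundance_sigma = 0.5,
                                   noise_sigma = 0.08,
                                   reads_per_sample = 1e7) {
  cfg <- sim_config(n_hairpins = n_hairpins, abundance_sigma = abundance_sigma,
                    depletion = NULL, noise_sigma = noise_sigma,
                    reads_per_sample = reads_per_sample,
                    n_replicates = n_replicates, seed = seed)
  sim <- simulate_screen(cfg)
  refs <- sim$sheet$sample_id[sim$sheet$arm == "reference"]
  m <- as.matrix(sim$counts[refs]) >= 1L
  tibble(pct_detected_all = 100 * mean(rowSums(m) == length(refs)),
         pct_detected_each = 100 * min(colMeans(m)))
}

#' Read-level alignment recovery benchmark
#'
#' Generates a synthetic hairpin library, emits error-bearing FASTQ reads
#' from a simulated reference sample, aligns them back with the default
#' tolerances, and reports what fraction of quality-kept reads aligned
#' uniquely -- the end-to-end check that mismatch-tolerant counting absorbs
#' realistic sequencing error.
#'
#' @param seed RNG seed for the library, simulation and read emission.
#' @param n_hairpins Library size (default 1000).
#' @param n_reads Reads emitted (default 1e6).
#' @param read_error_rate,n_rate Per-base substitution / uncalled rates.
#' @param max_mismatch,max_n Aligner tolerances.
#' @param fastq_path Where to write the temporary FASTQ (default tempfile).
#' @return One-row tibble: `pct_unique_of_kept`, `pct_kept`, read totals.
#' @export
benchmark_alignment <- function(seed = 1L, n_hairpins = 1000L, n_reads = 1e6,
                                read_error_rate = 0.005, n_rate = 0.001,
                                max_mismatch = 2L, max_n = 2L,
                                fastq_path = tempfile(fileext = ".fastq")) {
  lib <- random_hairpin_library(n_hairpins, seed = seed)
  cfg <- sim_config(n_hairpins = n_hairpins, depletion = NULL,
                    reads_per_sample = max(n_reads, n_hairpins),
                    n_replicates = 1L, read_error_rate = read_error_rate,
                    n_rate = n_rate, seed = seed)
  sim <- simulate_screen(cfg, lib = lib)
  emit_fastq(sim, lib, fastq_path, n_reads = n_reads, arm = "reference",
             seed = seed + 1L)
  on.exit(unlink(fastq_path))
  tally <- align_sample(fastq_path, lib, sample_id = "bench",
                        max_mismatch = max_mismatch, max_n = max_n)
  t <- tally$totals
  kept <- t$total - t$filtered
  tibble(pct_unique_of_kept = 100 * t$unique / kept,
         pct_kept = 100 * kept / t$total,
         total = t$total, filtered = t$filtered, unique = t$unique,
         ambiguous = t$ambiguous, unmapped = t$unmapped)
}
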