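#' Generate a random hairpin library
#'
#' Synthetic stand-in for a proprietary screening library: `n` constructs
#' with uniform-random 19-mer sense sequences (duplicates rejected and
#' redrawn) and round-robin gene assignments with `hairpins_per_gene`
#' constructs per gene.
#'
#' @param n Number of constructs.
#' @param hairpins_per_gene Constructs per synthetic gene (default 3).
#' @param seed RNG seed.
#' @param sense_length Sense-sequence length (default 19).
#' @return A `hairpin_library`.
#' @export
random_hairpin_library <- function(n, hairpins_per_gene = 3L, seed = 1L,
                                   sense_length = 19L) {
  set.seed(seed)
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), k * sense_length, replace = TRUE),
                nrow = k)
    apply(m, 1, paste0, collapse = "")
  }
  seqs <- draw(n)
  while (anyDuplicated(seqs)) {
    i <- which(duplicated(seqs))
    seqs[i] <- draw(length(i))
  }
  genes <- paste0("GENE", rep(seq_len(ceiling(n / hairpins_per_gene)),
                              each = hairpins_per_gene)[seq_len(n)])
  hairpin_library(
    tibble(construct_id = paste0("sh", seq_len(n)),
           gene_symbol = genes, sense_seq = seqs),
    name = sprintf("synthetic-%d", n), sense_length = sense_length)
}

# parse a depletion design string like "1000x0.75,1000x0.5,1000x0.25"
parse_depletion_design <- function(x) {
  if (is.null(x) || !length(x) || identical(x, "")) {
    return(tibble(n = integer(0), retention = numeric(0)))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("n", "retention") %in% names(x)))
    return(as_tibble(x)[c("n", "retention")])
  }
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+)x([0-9.]+)$", parts))
  if (any(lengths(m) != 3L)) abort("cannot parse depletion design: ", x)
  tibble(n = as.integer(vapply(m, `[`, "", 2)),
         retention = as.numeric(vapply(m, `[`, "", 3)))
}

#' Configure a simulated engineered-depletion screen
#'
#' The generative model mirrors the structure of a pooled screen readout:
#' hairpin starting abundances are lognormal
#' (`p ~ exp(Normal(0, abundance_sigma))`, renormalized); the test arm
#' retains a designed fraction `d` of each manipulated hairpin's abundance;
#' each sample's per-hairpin read count is
#' `Poisson(reads_per_sample x q x 2^Normal(0, noise_sigma))` with `q` the
#' arm's renormalized abundance, so sequencing is Poisson sampling and all
#' upstream multiplicative noise (culture, PCR) is carried by the
#' log2-scale `noise_sigma`.  Defaults are calibrated to a 10,000-hairpin
#' pool sequenced at 10^7 reads per sample.
#'
#' @param n_hairpins Pool size (default 10000).
#' @param abundance_sigma Natural-log SD of starting abundance (default 0.5,
#'   roughly a 30-fold abundance spread).
#' @param depletion Engineered depletion design: a string like
#'   `"1000x0.75,1000x0.5,1000x0.25"` (counts x retention), a data frame
#'   with columns `n` and `retention`, or `NULL` for a null screen.
#'   Retention is the fraction of abundance kept (0.25 = 75% depleted).
#' @param noise_sigma Log2-scale SD of per-sample multiplicative
#'   extra-Poisson noise (default 0.08).
#' @param reads_per_sample Sequenced reads per sample (default 1e7).
#' @param n_replicates Biological replicates (default 2); each replicate is
#'   an independent reference/test sample pair.
#' @param read_error_rate Per-base substitution probability for FASTQ
#'   emission (default 0.005).
#' @param n_rate Per-base uncalled (`N`) probability (default 0.001).
#' @param seed Master seed; per-sample RNG streams derive from it, so adding
#'   replicates never perturbs earlier ones.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_hairpins = 10000L, abundance_sigma = 0.5,
                       depletion = "1000x0.75,1000x0.5,1000x0.25",
                       noise_sigma = 0.08, reads_per_sample = 1e7,
                       n_replicates = 2L, read_error_rate = 0.005,
                       n_rate = 0.001, seed = 1L) {
  design <- parse_depletion_design(depletion)
  if (sum(design$n) > n_hairpins)
    abort("depletion design references more hairpins than the pool holds")
  if (any(design$retention <= 0 | design$retention > 1))
    abort("retention factors must be in (0, 1]")
  if (any(c(read_error_rate, n_rate) < 0) || any(c(read_error_rate, n_rate) > 1))
    abort("error rates must be in [0, 1]")
  if (abundance_sigma < 0 || noise_sigma < 0)
    abort("sigmas must be >= 0")
  if (reads_per_sample < n_hairpins)
    abort("reads_per_sample must be >= n_hairpins")
  structure(
    list(n_hairpins = as.integer(n_hairpins),
         abundance_sigma = abundance_sigma, depletion = design,
         noise_sigma = noise_sigma, reads_per_sample = reads_per_sample,
         n_replicates = as.integer(n_replicates),
         read_error_rate = read_error_rate, n_rate = n_rate,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Simulate an engineered-depletion screen at the count level
#'
#' Draws ground-truth abundances and depletion assignments from a
#' [sim_config()], then per-sample read counts for `n_replicates`
#' reference/test pairs.  Fully reproducible from the config seed.
#'
#' @param cfg A [sim_config()].
#' @param lib Optional `hairpin_library` supplying construct ids (its size
#'   must match `n_hairpins`); by default ids are `sh1..shN`.
#' @return A `sim_screen` list: `truth` (tibble `construct_id`, `p`
#'   (relative abundance, sums to 1), `retention`), `counts` (count-matrix
#'   tibble), `sheet` (a [sample_sheet()]), and `config`.
#' @export
simulate_screen <- function(cfg, lib = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_hairpins
  ids <- if (!is.null(lib)) {
    if (nrow(lib) != n) abort("library size does not match n_hairpins")
    lib$construct_id
  } else paste0("sh", seq_len(n))

  seeds <- derive_seeds(cfg$seed, 1L + 2L * cfg$n_replicates)
  set.seed(seeds[1])
  p <- exp(rnorm(n, 0, cfg$abundance_sigma))
  p <- p / sum(p)
  retention <- rep(1, n)
  if (nrow(cfg$depletion)) {
    picked <- sample.int(n, sum(cfg$depletion$n))
    retention[picked] <- rep(cfg$depletion$retention, cfg$depletion$n)
  }
  truth <- tibble(construct_id = ids, p = p, retention = retention)

  q_ref <- p
  q_test <- p * retention / sum(p * retention)
  counts <- tibble(construct_id = ids)
  sheet <- list()
  for (r in seq_len(cfg$n_replicates)) {
    for (arm in c("reference", "test")) {
      s <- seeds[1L + 2L * (r - 1L) + (arm == "test") + 1L]
      set.seed(s)
      q <- if (arm == "reference") q_ref else q_test
      lambda <- cfg$reads_per_sample * q * 2^rnorm(n, 0, cfg$noise_sigma)
      sid <- paste0(if (arm == "reference") "ref" else "test", r)
      counts[[sid]] <- rpois(n, lambda)
      sheet[[sid]] <- tibble(sample_id = sid, pool_id = "pool1",
                             arm = arm, replicate_id = as.character(r))
    }
  }
  structure(list(truth = truth, counts = counts,
                 sheet = sample_sheet(list_rbind(sheet)), config = cfg),
            class = "sim_screen")
}

#' @export
print.sim_screen <- function(x, ...) {
  d <- x$config$depletion
  cat(sprintf(
    "<sim_screen: %d hairpins, %d replicate pair(s), %s depleted; %.3g reads/sample>\n",
    x$config$n_hairpins, x$config$n_replicates,
    if (nrow(d)) paste(d$n, "x", d$retention, collapse = ", ") else "none",
    x$config$reads_per_sample))
  invisible(x)
}

# apply sparse per-base events (substitution or N) to a character vector of
# equal-length reads; handles several events on one read in passes
mutate_bases <- function(reads, read_idx, pos, new_base) {
  if (!length(read_idx)) return(reads)
  len <- nchar(reads[1])
  # several events can hit one read; apply them in passes so no edit is lost
  pass <- stats::ave(read_idx, read_idx, FUN = seq_along)
  for (k in seq_len(max(pass))) {
    sel <- pass == k
    ri <- read_idx[sel]
    p <- pos[sel]
    reads[ri] <- paste0(substring(reads[ri], 1L, p - 1L), new_base[sel],
                        substring(reads[ri], p + 1L, len))
  }
  reads
}

#' Emit simulated FASTQ reads for one sample
#'
#' Writes 26-base reads: a fixed 2-base 5' flank, the 19-nt sense sequence
#' of a hairpin drawn with probability proportional to its (arm-specific)
#' abundance, and a fixed 5-base 3' flank; the flank defaults are arbitrary
#' stand-ins for the vector's constant regions.  Substitution errors hit
#' each base independently at `read_error_rate` (uniform over the three
#' alternative bases) and uncalled bases at `n_rate`.  Base qualities are a
#' constant placeholder (the aligner ignores them).
#'
#' @param sim A `sim_screen` from [simulate_screen()].
#' @param lib The `hairpin_library` supplying sense sequences (same size and
#'   order as the simulated pool).
#' @param path Output FASTQ path (gzip if it ends in `.gz`).
#' @param n_reads Number of reads to emit.
#' @param arm `"reference"` or `"test"` (determines abundances).
#' @param seed RNG seed for this emission.
#' @param flank5,flank3 Constant flanking bases around the sense sequence.
#' @return Tibble of true per-hairpin read counts for the emitted sample.
#' @export
emit_fastq <- function(sim, lib, path, n_reads = 1e6,
                       arm = c("reference", "test"), seed = 1L,
                       flank5 = "TA", flank3 = "GGCAG") {
  stopifnot(inherits(sim, "sim_screen"), inherits(lib, "hairpin_library"))
  arm <- match.arg(arm)
  if (nrow(lib) != nrow(sim$truth))
    abort("library size does not match the simulated pool")
  q <- sim$truth$p
  if (arm == "test") {
    q <- q * sim$truth$retention
    q <- q / sum(q)
  }
  set.seed(seed)
  idx <- sample.int(nrow(lib), n_reads, replace = TRUE, prob = q)
  reads <- paste0(flank5, lib$sense_seq[idx], flank3)
  L <- nchar(reads[1])

  # per-base independent events drawn sparsely: the number of hit positions
  # is binomial over the n_reads x L base grid and the positions uniform,
  # which is exactly the independent per-base model without materializing
  # the full grid
  draw_events <- function(rate) {
    k <- rbinom(1L, n_reads * L, rate)
    cells <- sample(n_reads * L, k)
    list(read = (cells - 1L) %% n_reads + 1L,
         pos = (cells - 1L) %/% n_reads + 1L)
  }
  if (sim$config$read_error_rate > 0) {
    ev <- draw_events(sim$config$read_error_rate)
    old <- substring(reads[ev$read], ev$pos, ev$pos)
    # substitute uniformly over the three alternative bases by a random
    # cyclic shift in the base alphabet
    bases <- c("A", "C", "G", "T")
    alt <- bases[((match(old, bases) - 1L + sample.int(3L, length(old),
                                                       replace = TRUE)) %% 4L) + 1L]
    reads <- mutate_bases(reads, ev$read, ev$pos, alt)
  }
  if (sim$config$n_rate > 0) {
    ev <- draw_events(sim$config$n_rate)
    reads <- mutate_bases(reads, ev$read, ev$pos, rep("N", length(ev$read)))
  }

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  qual <- strrep("I", L)
  writeLines(paste0("@read", seq_len(n_reads), "\n", reads, "\n+\n", qual), con)
  tibble(construct_id = lib$construct_id,
         true_reads = tabulate(idx, nbins = nrow(lib)))
}

#' Binomial read-depth subsampling of a count matrix
#'
#' Thins every cell independently: each of a cell's reads is kept with
#' probability `fraction`, emulating a shallower sequencing run
#' (Poisson counts stay Poisson with rate scaled by `fraction`).
#'
#' @param counts Count-matrix tibble (first column `construct_id`).
#' @param fraction Keep probability in (0, 1].
#' @param seed RNG seed.
#' @return A count-matrix tibble of the same shape.
#' @export
subsample_counts <- function(counts, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  if (fraction == 1) return(counts)
  set.seed(seed)
  out <- as_tibble(counts)
  for (s in setdiff(names(out), "construct_id")) {
    out[[s]] <- rbinom(nrow(out), out[[s]], fraction)
  }
  out
}

#' Evaluate depletion detection against simulation truth
#'
#' Sweeps score thresholds against the ground truth of an engineered-
#' depletion simulation and reports, per depletion group: the false negative
#' rate at the most permissive threshold admitting zero false positives
#' (`fnr_at_zero_fpr`: fraction of the group not scoring below every
#' non-manipulated hairpin), the false positive rate at the threshold where
#' the group's FNR first reaches 5% (`fpr_at_fnr5`), and the group mean of
#' raw per-hairpin test/reference count ratios (`mean_ratio`; zero-reference
#' hairpins excluded and tallied).  Also returns the pooled ROC curve and
#' the replicate reproducibility r^2.
#'
#' Scores enter through a `screen_scores` object; hairpins flagged by the
#' abundance filter are excluded from threshold setting and from the rates
#' (so a filtered run reports rates on the kept set).
#'
#' @param scores A `screen_scores` object.
#' @param truth Truth tibble from [simulate_screen()] (`construct_id`,
#'   `retention`).
#' @param counts Optional count matrix for the ratio summary.
#' @param sheet Sample sheet for `counts` (defaults to the one in `scores`
#'   workflows; required with `counts`).
#' @return A `screen_eval` list: `groups` tibble, `replicate_r2`, `roc`
#'   tibble, `n_ratio_excluded`.
#' @export
evaluate_detection <- function(scores, truth, counts = NULL, sheet = NULL) {
  stopifnot(inherits(scores, "screen_scores"))
  summ <- scores$summary
  df <- summ |>
    inner_join(truth[c("construct_id", "retention")], by = "construct_id") |>
    filter(.data$keep, is.finite(.data$score))
  if (nrow(df) != nrow(summ) && nrow(df) == 0L)
    abort("scores and truth share no hairpins")
  groups <- sort(unique(df$retention[df$retention < 1]))
  if (!length(groups)) abort("no depleted hairpins in the truth")

  null_scores <- df$score[df$retention == 1]
  thr0 <- min(null_scores)

  ratios <- NULL
  if (!is.null(counts)) {
    sheet <- sample_sheet(sheet %||% abort("sheet required with counts"))
    pairs <- sheet |>
      select("pool_id", "replicate_id", "arm", "sample_id") |>
      pivot_wider(names_from = "arm", values_from = "sample_id")
    per_rep <- map(seq_len(nrow(pairs)), function(i) {
      ref <- counts[[pairs$reference[i]]]
      test <- counts[[pairs$test[i]]]
      tibble(construct_id = counts$construct_id,
             ratio = ifelse(ref > 0, test / ref, NA_real_))
    }) |> list_rbind()
    ratios <- per_rep |>
      summarise(ratio = mean(.data$ratio, na.rm = TRUE),
                any_zero_ref = anyNA(.data$ratio), .by = "construct_id")
  }

  group_rows <- map(groups, function(g) {
    gs <- df$score[df$retention == g]
    fnr0 <- mean(gs >= thr0)
    # smallest threshold bringing this group's FNR to <= 5%, then the FPR there
    k <- ceiling(0.95 * length(gs))
    t5 <- sort(gs)[k]
    fpr5 <- mean(null_scores <= t5)
    row <- tibble(retention = g, n = length(gs),
                  fnr_at_zero_fpr = fnr0, fpr_at_fnr5 = fpr5)
    if (!is.null(ratios)) {
      ids <- df$construct_id[df$retention == g]
      rr <- ratios[ratios$construct_id %in% ids, ]
      row$mean_ratio <- mean(rr$ratio, na.rm = TRUE)
      row$n_ratio_excluded <- sum(rr$any_zero_ref)
    }
    row
  }) |> list_rbind()

  # pooled ROC over all depleted vs null, thresholds at observed scores
  depl <- df$retention < 1
  ths <- c(-Inf, sort(unique(df$score)), Inf)
  roc <- tibble(
    threshold = ths,
    fpr = vapply(ths, function(t) mean(null_scores < t), numeric(1)),
    tpr = vapply(ths, function(t) mean(df$score[depl] < t), numeric(1)))

  structure(
    list(groups = group_rows,
         replicate_r2 = unname(replicate_r2(scores)[1]),
         roc = roc,
         zero_fpr_threshold = thr0),
    class = "screen_eval")
}

#' @export
print.screen_eval <- function(x, ...) {
  cat("<screen_eval>\n")
  print(as.data.frame(x$groups), row.names = FALSE)
  cat(sprintf("replicate r^2: %s\n",
              ifelse(is.na(x$replicate_r2), "NA (single replicate)",
                     format(x$replicate_r2, digits = 4))))
  invisible(x)
}

#' @rdname evaluate_detection
#' @param x A `screen_eval` object.
#' @param ... Unused.
#' @export
tidy.screen_eval <- function(x, ...) x$groups

#' @rdname evaluate_detection
#' @export
glance.screen_eval <- function(x, ...) {
  tibble(replicate_r2 = x$replicate_r2,
         zero_fpr_threshold = x$zero_fpr_threshold,
         n_groups = nrow(x$groups))
}

#' @rdname evaluate_detection
#' @param object A `screen_eval` object.
#' @export
autoplot.screen_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate")
}
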