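#' Hit thresholds from quantile-quantile departure
#'
#' Formalizes the visual practice of calling hits where the score
#' distribution leaves the normal reference line of a QQ plot.  The
#' reference line runs through the robust location/scale of the scores
#' (median, 1.4826 x MAD).  Each order statistic is compared with its
#' expected normal quantile at the Blom plotting position
#' `(i - 3/8) / (n + 1/4)`; walking inward from each tail, the outermost
#' contiguous run of points whose absolute departure from the line exceeds
#' `deviation_k` is called, and the threshold is the observed value at the
#' first conforming order statistic (infinite when the most extreme point
#' already conforms, i.e. no hits).  Note that a heavy planted tail drags
#' the genuinely extreme order statistics of the remaining sample off their
#' fixed-rank expectations, so a small boundary layer of non-planted scores
#' (a few tenths of a percent) can be swept up along with a large outlier
#' run; the null behaviour is unaffected.
#'
#' @param scores Numeric vector of summarized hairpin scores (>= 100).
#' @param deviation_k Departure tolerance in score units (default 0.5).
#' @param fixed_z If non-`NULL`, bypass the QQ rule and set thresholds at
#'   `median -/+ fixed_z * scaled MAD` (a conventional fallback, e.g. 3).
#' @return List with `threshold_low`, `threshold_high` (scores strictly
#'   beyond them are hits), and the flagged counts `n_low`, `n_high`.
#' @export
qq_threshold <- function(scores, deviation_k = 0.5, fixed_z = NULL) {
  x <- scores[is.finite(scores)]
  n <- length(x)
  if (n < 100L) abort("qq_threshold needs >= 100 scores")
  ctr <- median(x)
  scl <- mad(x)
  if (scl == 0) abort("degenerate scale: MAD of scores is zero")
  if (!is.null(fixed_z)) {
    return(list(threshold_low = ctr - fixed_z * scl,
                threshold_high = ctr + fixed_z * scl,
                n_low = sum(x < ctr - fixed_z * scl),
                n_high = sum(x > ctr + fixed_z * scl)))
  }
  xs <- sort(x)
  # expected value of order statistic i at its Blom plotting position
  expected <- ctr + scl * qnorm((seq_len(n) - 0.375) / (n + 0.25))
  walk <- function(obs) {  # obs ordered most-extreme-first, lower-tail scale
    i <- 0L
    while (i < n - 1L && abs(obs[i + 1L] - expected[i + 1L]) > deviation_k)
      i <- i + 1L
    i
  }
  n_low <- walk(xs)
  # the upper tail reuses the same walk on the sample mirrored about the
  # robust center (same median and MAD, tails swapped)
  n_high <- walk(2 * ctr - rev(xs))
  list(
    threshold_low = if (n_low > 0L) xs[n_low + 1L] else -Inf,
    threshold_high = if (n_high > 0L) rev(xs)[n_high + 1L] else Inf,
    n_low = n_low, n_high = n_high
  )
}

#' Call per-hairpin hits from summarized scores
#'
#' @param x A `screen_scores` object or a tibble with columns
#'   `construct_id`, `score` and optionally `keep`.
#' @param deviation_k,fixed_z Passed to [qq_threshold()]; thresholds are
#'   estimated per pool on hairpins passing the abundance filter.
#' @return Tibble with one row per hairpin: `score`, `hit` (`"depleted"`,
#'   `"enriched"`, `"none"`; `NA` for filtered hairpins) and the pool
#'   thresholds.
#' @export
call_hits <- function(x, deviation_k = 0.5, fixed_z = NULL) {
  summ <- if (inherits(x, "screen_scores")) x$summary else as_tibble(x)
  if (!"keep" %in% names(summ)) summ$keep <- TRUE
  if (!"pool_id" %in% names(summ)) summ$pool_id <- "pool"
  summ |>
    group_split(.data$pool_id) |>
    map(function(sc) {
      th <- qq_threshold(sc$score[sc$keep], deviation_k = deviation_k,
                         fixed_z = fixed_z)
      sc |>
        mutate(
          threshold_low = th$threshold_low,
          threshold_high = th$threshold_high,
          hit = case_when(
            !.data$keep ~ NA_character_,
            .data$score < th$threshold_low ~ "depleted",
            .data$score > th$threshold_high ~ "enriched",
            .default = "none"))
    }) |>
    list_rbind()
}

# weighted top-two score for one gene's hairpin scores (sorted internally)
weighted_top2 <- function(scores, alpha, direction) {
  s <- sort(scores, decreasing = (direction == "enrichment"))
  if (length(s) == 1L) return(s)
  alpha * s[1] + (1 - alpha) * s[2]
}

#' Gene-level weighted-average scores with permutation p-values
#'
#' Collapses hairpin scores to genes with a weighted average of the two
#' most extreme hairpins in the tested direction:
#' `alpha * first + (1 - alpha) * second` (default `alpha = 0.75`).  Genes
#' represented by a single hairpin score as that hairpin and are flagged.
#' Significance is assessed empirically: for each gene size, `n_perm`
#' size-matched hairpin sets are drawn at random from the same pool's scored
#' hairpins and `p = (1 + #{perm at least as extreme}) / (1 + n_perm)`;
#' Benjamini-Hochberg q-values are appended.
#'
#' @param x A `screen_scores` object (with gene annotation) or a tibble with
#'   columns `construct_id`, `gene_symbol`, `score` and optionally `keep`.
#' @param lib Optional `hairpin_library` supplying `gene_symbol` when `x`
#'   lacks it.
#' @param alpha Weight on the most extreme hairpin, in `[0, 1]`.
#' @param direction `"depletion"` (hits are negative) or `"enrichment"`.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutation draws.
#' @return Tibble: `gene_symbol`, `n_hairpins`, `score`, `p_value`,
#'   `q_value`, `single_hairpin` flag, `direction`.
#' @export
gene_scores <- function(x, lib = NULL, alpha = 0.75,
                        direction = c("depletion", "enrichment"),
                        n_perm = 1000L, seed = 1L) {
  direction <- match.arg(direction)
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1]")
  summ <- if (inherits(x, "screen_scores")) x$summary else as_tibble(x)
  if (!"gene_symbol" %in% names(summ)) {
    if (is.null(lib)) abort("gene annotation needed: supply `lib` or a gene_symbol column")
    summ <- summ |>
      left_join(as_tibble(lib)[c("construct_id", "gene_symbol")],
                by = "construct_id")
  }
  if (anyNA(summ$gene_symbol))
    abort("unknown gene for construct(s): ",
          paste(head(summ$construct_id[is.na(summ$gene_symbol)], 5), collapse = ", "))
  if (!"keep" %in% names(summ)) summ$keep <- TRUE
  summ <- summ[summ$keep & is.finite(summ$score), ]

  obs <- summ |>
    summarise(n_hairpins = n(),
              score = weighted_top2(.data$score, alpha, direction),
              .by = "gene_symbol")
  pool_scores <- summ$score

  set.seed(seed)
  sizes <- sort(unique(obs$n_hairpins))
  perm_by_size <- setNames(lapply(sizes, function(k) {
    vapply(seq_len(n_perm), function(i) {
      weighted_top2(pool_scores[sample.int(length(pool_scores), k)],
                    alpha, direction)
    }, numeric(1))
  }), as.character(sizes))

  more_extreme <- if (direction == "depletion") `<=` else `>=`
  sort_sign <- if (direction == "depletion") 1 else -1
  obs |>
    mutate(
      p_value = map_dbl(seq_len(n()), function(i) {
        perm <- perm_by_size[[as.character(obs$n_hairpins[i])]]
        (1 + sum(more_extreme(perm, obs$score[i]))) / (1 + n_perm)
      }),
      q_value = p.adjust(.data$p_value, method = "BH"),
      single_hairpin = .data$n_hairpins == 1L,
      direction = direction) |>
    arrange(.data$p_value, sort_sign * .data$score)
}
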