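#' Log2-transform a count matrix
#'
#' @param counts A count-matrix tibble (first column `construct_id`) or a
#'   numeric vector/matrix of non-negative counts.
#' @param pseudocount Added before the log to keep zero counts finite
#'   (default 0.5).
#' @return Same shape as the input, log2-transformed.
#' @export
log2_counts <- function(counts, pseudocount = 0.5) {
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  tf <- function(x) {
    if (any(x < 0, na.rm = TRUE)) abort("counts must be non-negative")
    log2(x + pseudocount)
  }
  if (is.data.frame(counts)) {
    out <- as_tibble(counts)
    num <- setdiff(names(out), "construct_id")
    out[num] <- lapply(out[num], tf)
    out
  } else {
    tf(counts)
  }
}

#' Log ratio (M) and mean log abundance (A)
#'
#' Given log2-scale reference and test vectors, returns the per-hairpin
#' log ratio `M = test - reference` (so depletion in the test arm is
#' negative) and the mean log abundance `A = (test + reference)/2`.
#'
#' @param log2_test,log2_ref Numeric vectors on the log2 scale.
#' @return Tibble with columns `M` and `A`.
#' @export
log_ratio <- function(log2_test, log2_ref) {
  if (length(log2_test) != length(log2_ref))
    abort("columns have unequal length")
  tibble(M = log2_test - log2_ref, A = (log2_test + log2_ref) / 2)
}

#' Loess normalization of log ratios against abundance
#'
#' Screen arms show systematic, abundance-dependent biases in the log ratio;
#' a locally weighted regression of `M` on `A` estimates that trend and the
#' normalized score is the residual `M - fit(A)`.  The default fit is
#' robust (`family = "symmetric"`, tricube neighbourhood weights with
#' biweight robustness iterations) so that hairpins with genuine, large
#' depletion -- which concentrate at low abundance precisely because they are
#' depleted -- do not drag the trend down and mask themselves.
#'
#' @param M,A Numeric vectors (log ratio, mean log abundance).
#' @param span Loess span in (0, 1] (default 0.5).
#' @param degree Local polynomial degree (default 1).
#' @param family `"symmetric"` (robust, default) or `"gaussian"` (plain
#'   least squares, no robustness iterations).
#' @param subset Optional logical vector: fit the trend on these points only
#'   (e.g. hairpins passing the abundance filter) but return normalized
#'   values for all, with the fit clamped to the fitted abundance range.
#' @return Tibble with columns `normalized` and `fit`.
#' @export
loess_normalize <- function(M, A, span = 0.5, degree = 1L,
                            family = c("symmetric", "gaussian"),
                            subset = NULL) {
  family <- match.arg(family)
  if (length(M) != length(A)) abort("M and A have unequal length")
  if (span <= 0 || span > 1) abort("span must be in (0, 1]")
  subset <- subset %||% rep(TRUE, length(M))
  ok <- subset & is.finite(M) & is.finite(A)
  if (sum(ok) < 10L)
    abort("too few points for a local fit; use a larger span or more hairpins")
  fit <- tryCatch(
    loess(M[ok] ~ A[ok], span = span, degree = degree, family = family,
          control = stats::loess.control(surface = "interpolate")),
    error = function(e) abort(paste0(
      "loess fit failed (", conditionMessage(e),
      "); try a larger span")))
  # clamp prediction to the fitted range so excluded points still normalize
  A_cl <- pmin(pmax(A, min(A[ok])), max(A[ok]))
  f <- predict(fit, A_cl)
  tibble(normalized = M - f, fit = f)
}

#' Robust z-scores by pool MAD rescaling
#'
#' Centers at the pool median and divides by the scaled median absolute
#' deviation (1.4826 x raw MAD, consistent with the standard deviation under
#' normality), so each pool's scores have median 0 and scaled MAD 1.
#'
#' @param x Numeric vector of scores.
#' @param subset Optional logical: estimate location/scale on these points
#'   only, rescale all.
#' @return Numeric vector of robust z-scores.
#' @export
mad_rescale <- function(x, subset = NULL) {
  subset <- subset %||% rep(TRUE, length(x))
  v <- x[subset & is.finite(x)]
  if (length(unique(v)) < 2L) abort("degenerate pool: fewer than 2 distinct scores")
  s <- mad(v)
  if (s == 0) abort("degenerate pool: MAD is zero")
  (x - median(v)) / s
}

#' Quantile normalization across replicate columns
#'
#' Classic quantile normalization: each column's order statistics are
#' replaced by the across-column mean of order statistics, so all columns
#' end with identical marginal distributions (sorted columns are equal
#' exactly); ties within a column receive the mean of the reference values
#' across the tied rank span.  With `rank_only = TRUE` the values are
#' instead replaced by their within-column ranks (mean rank for ties),
#' a cruder harmonization kept for comparison.
#'
#' @param x Numeric matrix or data frame, hairpins x replicates.
#' @param rank_only Replace values by ranks instead of mean order statistics.
#' @return Matrix of the same shape.
#' @export
quantile_normalize_scores <- function(x, rank_only = FALSE) {
  m <- as.matrix(x)
  if (ncol(m) < 2L) abort("quantile normalization needs >= 2 replicate columns")
  if (rank_only) {
    out <- apply(m, 2, function(col) rank(col, ties.method = "average",
                                          na.last = "keep"))
    dimnames(out) <- dimnames(m)
    return(out)
  }
  limma::normalizeQuantiles(m, ties = TRUE)
}

#' Flag hairpins with low reference representation
#'
#' Hairpins scarcely present in the reference arm carry mostly sampling
#' noise; they are flagged (per pool) when their mean reference-arm count
#' falls below `min_ref_count`, excluded from trend/scale estimation and hit
#' calling, but retained in all outputs with the flag set.
#'
#' @param counts Count-matrix tibble (first column `construct_id`).
#' @param sheet A [sample_sheet()].
#' @param min_ref_count Threshold on the mean reference count (default 100).
#' @return Tibble `construct_id`, `pool_id`, `mean_ref_count`, `keep`.
#' @export
filter_low_abundance <- function(counts, sheet, min_ref_count = 100) {
  sheet <- sample_sheet(sheet)
  ref <- sheet[sheet$arm == "reference", ]
  map(split(ref, ref$pool_id), function(rr) {
    m <- rowMeans(as.matrix(counts[rr$sample_id]))
    tibble(construct_id = counts$construct_id,
           pool_id = rr$pool_id[1],
           mean_ref_count = m,
           keep = m >= min_ref_count)
  }) |> list_rbind()
}

#' Summarize replicate scores per hairpin
#'
#' `median` takes the component-wise median across replicates.
#' `regularized_t` computes a moderated statistic
#' `d = mean / (s0 + s / sqrt(n))`, where `s` is the per-hairpin standard
#' deviation across replicates and `s0` a small-variance fudge set to the
#' `s0_quantile` quantile (default 90th) of `s` over the scored hairpins,
#' shrinking the denominator so hairpins with accidentally tiny replicate
#' spread cannot explode.
#'
#' @param x Numeric matrix, hairpins x replicates.
#' @param method `"median"` or `"regularized_t"`.
#' @param s0_quantile Quantile of the per-hairpin standard deviations used
#'   for the fudge factor.
#' @param s0 Override the fudge factor directly.
#' @param subset Optional logical: estimate `s0` from these rows only.
#' @return Numeric vector, one summary score per hairpin.
#' @export
summarize_replicates <- function(x, method = c("median", "regularized_t"),
                                 s0_quantile = 0.9, s0 = NULL, subset = NULL) {
  method <- match.arg(method)
  m <- as.matrix(x)
  if (method == "median") {
    return(unname(apply(m, 1, median)))
  }
  if (ncol(m) < 2L) abort("regularized_t needs >= 2 replicates")
  subset <- subset %||% rep(TRUE, nrow(m))
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  s0 <- s0 %||% quantile(s[subset & is.finite(s)], s0_quantile, names = FALSE)
  unname(mu / (s0 + s / sqrt(ncol(m))))
}

#' Normalize and score a pooled screen
#'
#' The full statistical pipeline from a count matrix to per-hairpin scores,
#' applied in a fixed order: abundance filter, log2 transform
#' (`+ pseudocount`), log ratio test - reference, loess normalization of M
#' against A within each pool, MAD rescaling within each pool, optional
#' quantile normalization across replicates, and replicate summarization.
#'
#' @param counts Count-matrix tibble (first column `construct_id`) as
#'   produced by [count_matrix()] or [read_count_matrix()].
#' @param sheet A [sample_sheet()] covering the count columns.
#' @param lib Optional `hairpin_library` for gene annotation of the output.
#' @param pseudocount Pseudocount before log2 (default 0.5).
#' @param span,degree,loess_family Passed to [loess_normalize()].
#' @param min_ref_count Abundance filter threshold (default 100; 0 disables).
#' @param quantile_normalize Harmonize replicate score distributions
#'   (default `FALSE`; enable when replicate distributions are visibly
#'   heterogeneous).
#' @param rank_only Use rank replacement instead of quantile normalization.
#' @param summary Replicate summary method, `"median"` (default) or
#'   `"regularized_t"`.
#' @param s0_quantile Fudge-factor quantile for `"regularized_t"`.
#' @return An object of class `screen_scores`: list with `scores` (long
#'   per-replicate tibble holding every intermediate -- `log2_ref`,
#'   `log2_test`, `A`, `M`, `loess_fit`, `score_loess`, `score`),
#'   `summary` (one row per hairpin per pool with the summarized `score` and
#'   `keep` flag) and `params`.  Use [tidy()], [glance()] and [autoplot()]
#'   to inspect it.
#' @export
normalize_screen <- function(counts, sheet, lib = NULL,
                             pseudocount = 0.5, span = 0.5, degree = 1L,
                             loess_family = c("symmetric", "gaussian"),
                             min_ref_count = 100,
                             quantile_normalize = FALSE, rank_only = FALSE,
                             summary = c("median", "regularized_t"),
                             s0_quantile = 0.9) {
  loess_family <- match.arg(loess_family)
  summary <- match.arg(summary)
  sheet <- sample_sheet(sheet)
  missing_cols <- setdiff(sheet$sample_id, names(counts))
  if (length(missing_cols))
    abort(paste0("count matrix lacks sample column(s): ",
                 paste(missing_cols, collapse = ", ")))
  flags <- filter_low_abundance(counts, sheet, min_ref_count)

  pairs <- sheet |>
    select("pool_id", "replicate_id", "arm", "sample_id") |>
    pivot_wider(names_from = "arm", values_from = "sample_id")

  scores <- map(seq_len(nrow(pairs)), function(i) {
    pool <- pairs$pool_id[i]
    keep <- flags$keep[flags$pool_id == pool]
    lr <- log2_counts(counts[[pairs$reference[i]]], pseudocount)
    lt <- log2_counts(counts[[pairs$test[i]]], pseudocount)
    ma <- log_ratio(lt, lr)
    lo <- loess_normalize(ma$M, ma$A, span = span, degree = degree,
                          family = loess_family, subset = keep)
    z <- mad_rescale(lo$normalized, subset = keep)
    tibble(construct_id = counts$construct_id,
           pool_id = pool, replicate_id = pairs$replicate_id[i],
           keep = keep, log2_ref = lr, log2_test = lt,
           A = ma$A, M = ma$M, loess_fit = lo$fit,
           score_loess = lo$normalized, score = z)
  }) |> list_rbind()

  if (quantile_normalize || rank_only) {
    scores <- scores |>
      group_split(.data$pool_id) |>
      map(function(sc) {
        wide <- sc |>
          select("construct_id", "replicate_id", "score") |>
          pivot_wider(names_from = "replicate_id", values_from = "score")
        m <- as.matrix(wide[-1])
        keep <- sc$keep[match(wide$construct_id, sc$construct_id)]
        m[keep, ] <- quantile_normalize_scores(m[keep, , drop = FALSE],
                                               rank_only = rank_only)
        long <- as_tibble(m) |>
          mutate(construct_id = wide$construct_id) |>
          pivot_longer(-"construct_id", names_to = "replicate_id",
                       values_to = "score_qn")
        sc |>
          left_join(long, by = c("construct_id", "replicate_id")) |>
          mutate(score = .data$score_qn, score_qn = NULL)
      }) |>
      list_rbind()
  }

  summ <- scores |>
    group_split(.data$pool_id) |>
    map(function(sc) {
      wide <- sc |>
        select("construct_id", "keep", "replicate_id", "score") |>
        pivot_wider(names_from = "replicate_id", values_from = "score")
      m <- as.matrix(wide[-(1:2)])
      tibble(construct_id = wide$construct_id,
             pool_id = sc$pool_id[1],
             keep = wide$keep,
             n_replicates = ncol(m),
             score = summarize_replicates(m, method = summary,
                                          s0_quantile = s0_quantile,
                                          subset = wide$keep))
    }) |>
    list_rbind()
  if (!is.null(lib)) {
    summ <- summ |>
      left_join(as_tibble(lib)[c("construct_id", "gene_symbol")],
                by = "construct_id") |>
      relocate("gene_symbol", .after = "construct_id")
  }

  structure(
    list(scores = scores, summary = summ,
         params = list(pseudocount = pseudocount, span = span,
                       degree = degree, loess_family = loess_family,
                       min_ref_count = min_ref_count,
                       quantile_normalize = quantile_normalize,
                       rank_only = rank_only, summary = summary,
                       s0_quantile = s0_quantile)),
    class = "screen_scores"
  )
}

#' @export
print.screen_scores <- function(x, ...) {
  cat(sprintf(
    "<screen_scores: %d hairpins x %d replicate pair(s) in %d pool(s); summary = %s>\n",
    length(unique(x$scores$construct_id)),
    length(unique(x$scores$replicate_id)),
    length(unique(x$scores$pool_id)), x$params$summary))
  invisible(x)
}

#' @rdname normalize_screen
#' @param x A `screen_scores` object.
#' @param ... Unused.
#' @export
tidy.screen_scores <- function(x, ...) x$scores

#' @rdname normalize_screen
#' @export
glance.screen_scores <- function(x, ...) {
  r2 <- replicate_r2(x)
  x$scores |>
    summarise(n_hairpins = n_distinct(.data$construct_id),
              n_replicates = n_distinct(.data$replicate_id),
              n_filtered = sum(!.data$keep) / n_distinct(.data$replicate_id),
              .by = "pool_id") |>
    mutate(replicate_r2 = r2[match(.data$pool_id, names(r2))])
}

#' Squared Pearson correlation of normalized log ratios between replicates
#'
#' @param x A `screen_scores` object.
#' @param use_keep Restrict to hairpins passing the abundance filter.
#' @return Named numeric vector, one mean pairwise r^2 per pool (`NA` for
#'   single-replicate pools).
#' @export
replicate_r2 <- function(x, use_keep = TRUE) {
  stopifnot(inherits(x, "screen_scores"))
  pools <- split(x$scores, x$scores$pool_id)
  vapply(pools, function(sc) {
    if (use_keep) sc <- sc[sc$keep, ]
    wide <- sc |>
      select("construct_id", "replicate_id", "score_loess") |>
      pivot_wider(names_from = "replicate_id", values_from = "score_loess")
    m <- as.matrix(wide[-1])
    if (ncol(m) < 2L) return(NA_real_)
    cc <- cor(m, use = "pairwise.complete.obs")^2
    mean(cc[upper.tri(cc)])
  }, numeric(1))
}

#' Diagnostic plots for screen scores
#'
#' `type = "ma"` shows the MA cloud with the fitted loess trend before
#' (`stage = "raw"`) or after (`stage = "normalized"`) normalization, one
#' panel per pool/replicate; `type = "density"` overlays per-replicate score
#' densities; `type = "replicates"` draws the pairwise replicate scatter of
#' normalized log ratios.
#'
#' @param object A `screen_scores` object.
#' @param type One of `"ma"`, `"density"`, `"replicates"`.
#' @param stage For `"ma"`: `"raw"` or `"normalized"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_scores <- function(object, type = c("ma", "density", "replicates"),
                                   stage = c("raw", "normalized"), ...) {
  type <- match.arg(type)
  stage <- match.arg(stage)
  sc <- object$scores |> filter(.data$keep)
  if (type == "ma") {
    y <- if (stage == "raw") "M" else "score_loess"
    p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$A, y = .data[[y]])) +
      ggplot2::geom_point(alpha = 0.2, size = 0.4) +
      ggplot2::facet_grid(rows = ggplot2::vars(.data$pool_id),
                          cols = ggplot2::vars(.data$replicate_id)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
      ggplot2::labs(x = "mean log2 abundance (A)",
                    y = if (stage == "raw") "log2 ratio (M)" else "normalized log2 ratio")
    if (stage == "raw")
      p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$loess_fit),
                                  colour = "red")
    return(p)
  }
  if (type == "density") {
    return(
      ggplot2::ggplot(sc, ggplot2::aes(x = .data$score,
                                       colour = factor(.data$replicate_id))) +
        ggplot2::geom_density() +
        ggplot2::facet_wrap(ggplot2::vars(.data$pool_id)) +
        ggplot2::labs(x = "hairpin score", colour = "replicate")
    )
  }
  wide <- sc |>
    select("construct_id", "pool_id", "replicate_id", "score_loess") |>
    pivot_wider(names_from = "replicate_id", values_from = "score_loess")
  reps <- setdiff(names(wide), c("construct_id", "pool_id"))
  if (length(reps) < 2L) abort("replicate scatter needs >= 2 replicates")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data[[reps[1]]], y = .data[[reps[2]]])) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$pool_id)) +
    ggplot2::labs(x = paste("replicate", reps[1]),
                  y = paste("replicate", reps[2]))
}
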