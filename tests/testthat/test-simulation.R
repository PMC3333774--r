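test_that("simulation is reproducible and replicate streams are stable", {
  cfg <- sim_config(n_hairpins = 500, depletion = "50x0.5",
                    reads_per_sample = 5e5, n_replicates = 2, seed = 8)
  s1 <- simulate_screen(cfg)
  s2 <- simulate_screen(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)

  # adding a replicate leaves earlier samples untouched
  cfg3 <- sim_config(n_hairpins = 500, depletion = "50x0.5",
                     reads_per_sample = 5e5, n_replicates = 3, seed = 8)
  s3 <- simulate_screen(cfg3)
  expect_identical(s3$counts[c("ref1", "test1", "ref2", "test2")],
                   s1$counts[c("ref1", "test1", "ref2", "test2")])
})

test_that("simulated counts follow the generative design", {
  # null design at high depth: test/reference ratios compatible with 1
  cfg <- sim_config(n_hairpins = 200, depletion = NULL, noise_sigma = 0,
                    reads_per_sample = 2e6, n_replicates = 1, seed = 3)
  sim <- simulate_screen(cfg)
  lam <- 2e6 * sim$truth$p
  ratio <- sim$counts$test1 / sim$counts$ref1
  sd_ratio <- sqrt(2 / lam)  # delta-method Poisson sd of the ratio
  expect_gt(mean(abs(ratio - 1) <= 3 * sd_ratio), 0.985)

  # a 50%-retention group recovers its mean ratio
  cfg2 <- sim_config(n_hairpins = 2000, depletion = "500x0.5",
                     noise_sigma = 0, reads_per_sample = 2e7,
                     n_replicates = 1, seed = 4)
  sim2 <- simulate_screen(cfg2)
  depl <- sim2$truth$retention < 1
  r <- sim2$counts$test1[depl] / sim2$counts$ref1[depl]
  # renormalization inflates test abundances by 1/sum(p*d)
  scale <- 1 / sum(sim2$truth$p * sim2$truth$retention)
  expect_equal(mean(r), 0.5 * scale, tolerance = 0.02)
})

test_that("emitted FASTQ round-trips through the aligner", {
  lib <- random_hairpin_library(80, seed = 12)
  cfg <- sim_config(n_hairpins = 80, depletion = NULL, reads_per_sample = 8e4,
                    read_error_rate = 0, n_rate = 0, seed = 12)
  sim <- simulate_screen(cfg, lib = lib)
  fq <- withr::local_tempfile(fileext = ".fastq.gz")
  truth_reads <- emit_fastq(sim, lib, fq, n_reads = 5000, seed = 2)
  tal <- align_sample(fq, lib)
  # error-free reads all align uniquely at distance 0
  expect_equal(tal$totals$unique, 5000L)
  expect_true(all(tal$counts$distance == 0L))
  # per-hairpin counts equal the emission truth exactly
  cm <- count_matrix(tal, lib)
  expect_equal(cm[[2]], truth_reads$true_reads)

  # per-hairpin fractions track abundance within 3 binomial sd
  p <- sim$truth$p
  se <- sqrt(p * (1 - p) / 5000)
  expect_true(all(abs(truth_reads$true_reads / 5000 - p) <= 3 * se + 1e-9))
})

test_that("error-bearing reads mostly align within the mismatch cap", {
  lib <- random_hairpin_library(150, seed = 7)
  cfg <- sim_config(n_hairpins = 150, depletion = NULL, reads_per_sample = 1e5,
                    read_error_rate = 0.005, n_rate = 0.001, seed = 7)
  sim <- simulate_screen(cfg, lib = lib)
  fq <- withr::local_tempfile(fileext = ".fastq")
  emit_fastq(sim, lib, fq, n_reads = 20000, seed = 3)
  tal <- align_sample(fq, lib)
  kept <- tal$totals$total - tal$totals$filtered
  expect_gte(tal$totals$unique / kept, 0.9)
  # substitutions show up as distance-1/2 assignments
  expect_gt(sum(tal$counts$reads[tal$counts$distance > 0]), 0)
})

test_that("binomial subsampling thins counts distributionally", {
  cfg <- sim_config(n_hairpins = 1000, depletion = NULL, noise_sigma = 0,
                    reads_per_sample = 1e6, n_replicates = 1, seed = 21)
  sim <- simulate_screen(cfg)
  expect_identical(subsample_counts(sim$counts, 1), sim$counts)

  sub <- subsample_counts(sim$counts, 0.25, seed = 2)
  tot0 <- sum(sim$counts$ref1); tot <- sum(sub$ref1)
  se <- sqrt(tot0 * 0.25 * 0.75)
  expect_lt(abs(tot - 0.25 * tot0), 3 * se)

  # thinning a Poisson count keeps it Poisson: mean ~ variance at rate/2
  x <- rpois(20000, 40)
  th <- subsample_counts(tibble::tibble(construct_id = seq_along(x), s = x),
                         0.5, seed = 3)$s
  expect_equal(mean(th), 20, tolerance = 3 * sqrt(20 / 20000) / 20)
  expect_equal(var(th), 20, tolerance = 0.05)

  # composition: thinning twice equals thinning once at the product
  ab <- subsample_counts(subsample_counts(sim$counts, 0.6, seed = 4),
                         0.5, seed = 5)$ref1
  onepass <- subsample_counts(sim$counts, 0.3, seed = 6)$ref1
  expect_equal(mean(ab), mean(onepass), tolerance = 0.01)
  expect_equal(var(ab), var(onepass), tolerance = 0.05)
  expect_error(subsample_counts(sim$counts, 0), "fraction")
})

test_that("detection evaluation matches an exhaustive threshold sweep", {
  # hand-built score list with a known overlap
  null_s <- c(-1.2, -0.5, 0, 0.3, 0.8, 1.1)
  depl_s <- c(-5, -4, -1.5, -0.9)
  summ <- tibble::tibble(
    construct_id = paste0("h", 1:10),
    pool_id = "p", keep = TRUE, n_replicates = 1L,
    score = c(null_s, depl_s))
  truth <- tibble::tibble(construct_id = paste0("h", 1:10),
                          retention = c(rep(1, 6), rep(0.5, 4)))
  sc <- structure(list(summary = summ,
                       scores = tibble::tibble(construct_id = summ$construct_id,
                                               pool_id = "p", keep = TRUE,
                                               replicate_id = "1",
                                               score_loess = summ$score,
                                               score = summ$score),
                       params = list()),
                  class = "screen_scores")
  ev <- evaluate_detection(sc, truth)
  o <- oracle_sweep(null_s, depl_s)
  expect_equal(ev$groups$fnr_at_zero_fpr, o$fnr_at_zero_fpr)
  expect_equal(ev$groups$fnr_at_zero_fpr, 0.25)  # only -0.9 survives the zero-FPR cut
  expect_equal(ev$groups$fpr_at_fnr5, o$fpr_at_fnr5)

  # separable scores: perfect detection
  summ2 <- summ; summ2$score <- c(1:6, -4, -3, -2, -1)
  sc$summary <- summ2
  ev2 <- evaluate_detection(sc, truth)
  expect_equal(ev2$groups$fnr_at_zero_fpr, 0)
  expect_equal(ev2$groups$fpr_at_fnr5, 0)

  # indistinguishable scores: nothing detected at zero FPR
  summ3 <- summ; summ3$score <- rep(c(-1, 0, 1), length.out = 10)
  sc$summary <- summ3
  expect_equal(evaluate_detection(sc, truth)$groups$fnr_at_zero_fpr, 1)

  # ROC is monotone
  expect_true(all(diff(ev$roc$fpr) >= 0))
  expect_true(all(diff(ev$roc$tpr) >= 0))
})

test_that("normalized ratios recover log2 retention within Monte-Carlo error", {
  # depleted hairpins are kept to a few percent of the pool so the loess
  # trend is estimated from essentially null hairpins and cannot absorb
  # any of the depletion signal it is supposed to preserve
  reps <- lapply(1:4, function(s) {
    cfg <- sim_config(n_hairpins = 4000, depletion = "100x0.75,100x0.5,100x0.25",
                      reads_per_sample = 4e6, n_replicates = 1, seed = 100 + s)
    sim <- simulate_screen(cfg)
    sc <- normalize_screen(sim$counts, sim$sheet)
    merged <- merge(sc$scores, sim$truth, by = "construct_id")
    # loess-normalized M is recentred; compare group means to the null group
    vapply(c(0.75, 0.5, 0.25), function(d) {
      mean(merged$score_loess[merged$retention == d]) -
        mean(merged$score_loess[merged$retention == 1])
    }, numeric(1))
  })
  m <- do.call(rbind, reps)
  for (j in 1:3) {
    d <- c(0.75, 0.5, 0.25)[j]
    mc_sd <- sd(m[, j]) / sqrt(nrow(m))
    expect_lt(abs(mean(m[, j]) - log2(d)), 3 * mc_sd + 0.03)
  }
})

test_that("sim configuration is validated", {
  expect_error(sim_config(n_hairpins = 10, depletion = "50x0.5"),
               "more hairpins")
  expect_error(sim_config(depletion = "10x1.5"), "retention")
  expect_error(sim_config(read_error_rate = 2), "rates")
  expect_error(sim_config(n_hairpins = 100, depletion = NULL,
                          reads_per_sample = 10), "reads_per_sample")
  expect_error(sim_config(n_hairpins = 100, depletion = "10@0.5"), "parse")
})
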