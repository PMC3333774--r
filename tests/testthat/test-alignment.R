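test_that("FASTQ reading is codec-transparent and flags truncated records", {
  seqs <- embed_read(random_seq(2))
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(seqs, path)
  expect_equal(read_fastq_seqs(path), seqs)

  gz <- withr::local_tempfile(fileext = ".fastq.gz")
  con <- gzfile(gz, "wt"); writeLines(readLines(path), con); close(con)
  expect_equal(read_fastq_seqs(gz), read_fastq_seqs(path))

  trunc <- withr::local_tempfile(fileext = ".fastq")
  writeLines(head(readLines(path), 6), trunc)  # record 2 cut mid-way
  expect_error(read_fastq_seqs(trunc), "record 2")

  # length enforcement routes odd-length reads to NA (-> filtered tally)
  mixed <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(c(seqs, strrep("A", 30)), mixed)
  got <- read_fastq_seqs(mixed, expect_length = 26)
  expect_equal(is.na(got), c(FALSE, FALSE, TRUE))
})

test_that("trimming extracts the 1-based inclusive sense window", {
  s <- random_seq(1)
  expect_equal(trim_reads(embed_read(s), 3, 21), s)
  expect_equal(trim_reads(s, 1, 19), s)
  # too short for the window: flagged for the filtered tally
  expect_true(is.na(trim_reads(strrep("A", 20), 3, 21)))
  # '.' is an uncalled base, case is normalized
  expect_equal(trim_reads("ta.cgtacgtacgtacgtacgtacgt", 3, 21),
               paste0("N", toupper(substr("cgtacgtacgtacgtacg", 1, 18))))
})

test_that("the uncalled-base filter allows at most max_n Ns in the window", {
  expect_true(filter_uncalled(strrep("A", 19)))
  expect_true(filter_uncalled(paste0("NN", strrep("A", 17))))
  expect_false(filter_uncalled(paste0("NNN", strrep("A", 16))))
  expect_false(filter_uncalled(NA_character_))
  expect_true(filter_uncalled(paste0("NNN", strrep("A", 16)), max_n = 3))
})

test_that("hamming distance counts mismatches with N mismatching everything", {
  x <- random_seq(1)
  expect_equal(hamming_distance(x, x), 0L)
  expect_equal(hamming_distance(strrep("A", 19),
                                paste0(strrep("A", 17), "CC")), 2L)
  expect_equal(hamming_distance(paste0("N", strrep("A", 18)),
                                strrep("A", 19)), 1L)
  # N mismatches N as well: an uncalled base never confirms identity
  expect_equal(hamming_distance(paste0("N", strrep("A", 18)),
                                paste0("N", strrep("A", 18))), 1L)
  expect_error(hamming_distance("ACGT", "ACGTA"), "unequal")
  expect_equal(hamming_distance(strrep("A", 19), strrep("C", 19), cap = 2), 3L)
})

test_that("bin assignment is best-stratum with ambiguity exclusion", {
  lib <- tiny_lib(c(strrep("A", 19), strrep("C", 19)))
  a <- assign_bins(strrep("A", 19), lib)
  expect_equal(a$status, "unique")
  expect_equal(a$construct_id, "h1")
  expect_equal(a$distance, 0L)

  lib2 <- tiny_lib(c(strrep("A", 19), paste0(strrep("A", 17), "CC")))
  # one mismatch to each library sequence: ambiguous at the minimal stratum
  amb <- assign_bins(paste0(strrep("A", 18), "C"), lib2)
  expect_equal(amb$status, "ambiguous")
  expect_true(is.na(amb$construct_id))

  un <- assign_bins(paste0(strrep("A", 15), "GGGG"), lib2)
  expect_equal(un$status, "unmapped")

  # a unique hit at distance 1 wins even with several sequences at distance 2
  lib3 <- tiny_lib(c(strrep("A", 19),
                     paste0(strrep("A", 17), "CC"),
                     paste0(strrep("A", 17), "GG")))
  bs <- assign_bins(paste0(strrep("A", 18), "T"), lib3)
  expect_equal(bs$status, "unique")
  expect_equal(bs$construct_id, "h1")
  expect_equal(bs$distance, 1L)

  # duplicated library sequences force ambiguity at distance 0
  lib4 <- tiny_lib(c(strrep("A", 19), strrep("A", 19)))
  expect_equal(assign_bins(strrep("A", 19), lib4)$status, "ambiguous")
})

test_that("align_sample tallies conserve reads exactly", {
  lib <- tiny_lib(c(strrep("A", 19), strrep("C", 19),
                    paste0(strrep("A", 17), "CC")))
  fq <- withr::local_tempfile(fileext = ".fastq")
  reads <- c(rep(embed_read(strrep("A", 19)), 85),          # exact h1
             rep(embed_read(paste0(strrep("A", 18), "C")), 10),  # tie h1/h3
             rep(embed_read(paste0(strrep("G", 19))), 5))   # unmapped
  write_fastq(reads, fq)
  tal <- align_sample(fq, lib, sample_id = "s1")
  expect_equal(tal$totals,
               list(total = 100L, filtered = 0L, unique = 85L,
                    ambiguous = 10L, unmapped = 5L))
  with(tal$totals, expect_identical(filtered + unique + ambiguous + unmapped,
                                    total))
  expect_equal(tal$counts$reads[tal$counts$construct_id == "h1"], 85L)

  # all-identical input: a single construct at distance 0
  write_fastq(rep(embed_read(strrep("C", 19)), 1000), fq)
  tal2 <- align_sample(fq, lib)
  expect_equal(tal2$counts,
               tibble::tibble(construct_id = "h2", distance = 0L,
                              reads = 1000L))
})

test_that("accelerated aligner equals the brute-force oracle read by read", {
  for (seed in 1:3) {
    set.seed(seed)
    lib <- tiny_lib(random_seq(60))
    # reads: exact, 1-2 errors, heavy errors, and N-bearing
    base <- sample(lib$sense_seq, 300, replace = TRUE)
    mutate_at <- function(s, k, alphabet = c("A", "C", "G", "T", "N")) {
      pos <- sample(19, k)
      for (p in pos) substr(s, p, p) <- sample(alphabet, 1)
      s
    }
    nerr <- sample(0:5, length(base), replace = TRUE, prob = c(5, 3, 2, 1, 1, 1))
    reads <- mapply(mutate_at, base, nerr)
    res <- assign_bins(reads, lib, max_mismatch = 2)
    for (i in seq_along(reads)) {
      o <- oracle_assign(reads[i], lib$sense_seq, 2L)
      expect_identical(res$status[i], o$status)
      if (o$status == "unique") {
        expect_identical(res$construct_id[i], lib$construct_id[o$idx])
        expect_identical(res$distance[i], as.integer(o$distance))
      }
    }
  }
})

test_that("raising the mismatch cap never loses assignments", {
  set.seed(11)
  lib <- tiny_lib(random_seq(40))
  base <- sample(lib$sense_seq, 200, replace = TRUE)
  reads <- vapply(base, function(s) {
    for (p in sample(19, sample(0:4, 1))) substr(s, p, p) <- sample(c("A","C","G","T"), 1)
    s
  }, "", USE.NAMES = FALSE)
  prev_assigned <- -1L; prev_unmapped <- Inf
  for (mm in 0:4) {
    res <- assign_bins(reads, lib, max_mismatch = mm)
    assigned <- sum(res$status %in% c("unique", "ambiguous"))
    unmapped <- sum(res$status == "unmapped")
    expect_gte(assigned, prev_assigned)
    expect_lte(unmapped, prev_unmapped)
    prev_assigned <- assigned; prev_unmapped <- unmapped
  }
})

test_that("count matrices conserve tallies and are order-invariant", {
  lib <- tiny_lib(random_seq(10))
  fq1 <- withr::local_tempfile(fileext = ".fastq")
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  set.seed(2)
  write_fastq(embed_read(sample(lib$sense_seq, 200, replace = TRUE)), fq1)
  write_fastq(character(0), fq2)
  t1 <- align_sample(fq1, lib, sample_id = "s1")
  t2 <- align_sample(fq2, lib, sample_id = "s2")

  cm <- count_matrix(list(t1, t2), lib)
  expect_equal(cm$construct_id, lib$construct_id)
  expect_equal(sum(cm$s1), t1$totals$unique)
  expect_true(all(cm$s2 == 0L))

  cm_perm <- count_matrix(list(t2, t1), lib)
  expect_identical(cm_perm[c("construct_id", "s1", "s2")],
                   cm[c("construct_id", "s1", "s2")])
  expect_error(count_matrix(list(t1, t1), lib), "duplicate sample_id")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(list(t1, t2), lib, path)
  expect_identical(read_count_matrix(path), cm)
  stats <- alignment_stats(list(t1, t2))
  expect_equal(stats$total, c(200L, 0L))
  expect_equal(stats$unique_d0 + stats$unique_d1 + stats$unique_d2,
               stats$unique)
})
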