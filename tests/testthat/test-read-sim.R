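test_that("error model parameters are validated", {
  expect_s3_class(error_model(), "cyp_error_model")
  expect_error(error_model(del_rate = 0.5), "0.5")
  expect_error(error_model(sub_rate = -0.1), "rates")
  expect_error(error_model(mean_q = 0), "mean_q")
  expect_error(error_model(truncation_frac_range = c(0.9, 0.3)), "truncation")
})

test_that("zero error rates reproduce the input exactly", {
  seq <- random_test_dna(3000, 11)
  em <- error_model(0, 0, 0, truncation_prob = 0)
  out <- apply_error_model(seq, em, 5)
  expect_identical(out$sequence, seq)
  expect_identical(nchar(out$quality), nchar(out$sequence))
  expect_identical(c(out$n_sub, out$n_ins, out$n_del), c(0L, 0L, 0L))
})

test_that("realized error rates match the binomial expectation within 3 SE", {
  n <- 10000L
  seq <- random_test_dna(n, 21)
  em <- error_model(sub_rate = 0.02, ins_rate = 0.015, del_rate = 0.02,
                    truncation_prob = 0)
  reps <- 200L
  counts <- vapply(seq_len(reps), function(s) {
    out <- apply_error_model(seq, em, 5000 + s)
    c(out$n_sub, out$n_ins, out$n_del)
  }, numeric(3))
  for (i in 1:3) {
    rate <- c(0.02, 0.015, 0.02)[i]
    se <- sqrt(n * rate * (1 - rate) / reps)
    expect_lt(abs(mean(counts[i, ]) - n * rate), 3 * se)
  }
})

test_that("diploid simulation is exact in counts and deterministic", {
  h1 <- test_hap("*1.001")
  h5 <- test_hap("*5.001")
  em0 <- error_model(truncation_prob = 0)
  reads <- simulate_diploid_reads(h1, h5, 40, em0, seed = 9)
  expect_identical(nrow(reads), 80L)
  expect_identical(as.integer(table(reads$allele_index)), c(40L, 40L))
  expect_true(all(reads$full_span))
  # identity case: all rates zero reproduces the source haplotype
  em00 <- error_model(0, 0, 0, truncation_prob = 0)
  pure <- simulate_diploid_reads(h1, h5, 3, em00, seed = 2)
  fwd <- pure[pure$strand == "+", ]
  for (i in seq_len(nrow(fwd))) {
    src <- if (fwd$allele_index[i] == 1) h1$sequence else h5$sequence
    expect_identical(fwd$sequence[i], src)
  }
  # determinism: same seed, byte-identical FASTQ
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(simulate_diploid_reads(h1, h5, 10, error_model(), seed = 4), f1)
  write_fastq(simulate_diploid_reads(h1, h5, 10, error_model(), seed = 4), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(simulate_diploid_reads("", h5, 5), "empty")
})

test_that("FASTQ writing round-trips sequences and qualities exactly", {
  h1 <- test_hap("*1.001")
  reads <- simulate_diploid_reads(h1, h1, 5, error_model(), seed = 3)
  path <- tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  expect_identical(length(readLines(path)), 4L * nrow(reads))
  back <- read_fastq(path)
  expect_identical(back$read_id, reads$read_id)
  expect_identical(back$sequence, reads$sequence)
  expect_identical(back$quality, reads$quality)
  # 3 records -> 12 lines
  p3 <- tempfile()
  write_fastq(reads[1:3, ], p3)
  expect_identical(length(readLines(p3)), 12L)
  # empty set -> empty valid file with a warning
  pe <- tempfile()
  expect_warning(write_fastq(reads[0, ], pe), "empty")
  expect_identical(nrow(read_fastq(pe)), 0L)
})

test_that("every emitted read appears in the truth table exactly once", {
  h1 <- test_hap("*1.001")
  h2 <- test_hap("*2.001x2")
  reads <- simulate_diploid_reads(h1, h2, 15, error_model(), seed = 8)
  tt <- truth_table(reads)
  expect_identical(sort(tt$read_id), sort(unique(reads$read_id)))
  expect_identical(nrow(tt), nrow(reads))
  expect_identical(anyDuplicated(tt$read_id), 0L)
  expect_identical(unique(tt$fragment_length[tt$allele_index == 2]), 52000L)
  path <- tempfile(fileext = ".tsv")
  write_truth_tsv(reads, path)
  expect_identical(nrow(utils::read.delim(path)), nrow(reads))
})

test_that("truncated reads lose full-span status by construction", {
  h1 <- test_hap("*1.001")
  em <- error_model(truncation_prob = 1)
  reads <- simulate_diploid_reads(h1, h1, 10, em, seed = 6)
  expect_false(any(reads$full_span))
  expect_true(all(nchar(reads$sequence) < 39551 * 0.97))
})
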