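test_that("anchors are found on intact reads and lost with the missing flank", {
  m <- test_model()
  a <- detect_anchors(m, m$reference)
  expect_setequal(a$anchor_id, c("FLANK_5P", "FLANK_3P"))
  expect_true(all(a$match_fraction > 0.95))
  trunc <- substr(m$reference, 1, 24000)
  at <- detect_anchors(m, trunc)
  expect_identical(at$anchor_id, "FLANK_5P")
})

test_that("anchors survive nanopore-like error rates in at least 95% of trials", {
  m <- test_model()
  ref <- m$reference
  em <- error_model() # 5.5% total error
  hits <- vapply(1:100, function(s) {
    r <- apply_error_model(ref, em, 31000 + s)$sequence
    a <- detect_anchors(m, r)
    all(c("FLANK_5P", "FLANK_3P") %in% a$anchor_id)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("track alignment reproduces the expected gap structure", {
  m <- test_model()
  # no-SV read vs REF: nothing 1 kb or larger
  g_ref <- align_read_to_track(m, m$reference, "REF")$gaps
  expect_identical(nrow(g_ref[g_ref$length >= 1000, ]), 0L)
  # no-SV read vs track A: exactly one spacer-window gap, exactly one spacer long
  g_a <- align_read_to_track(m, m$reference, "A")$gaps
  in_win <- g_a[g_a$within_spacer_window, ]
  expect_identical(nrow(in_win), 1L)
  expect_identical(in_win$length, 1560L)
  # deletion read vs REF: a single 14,551 bp gap outside the spacer window
  g_5 <- align_read_to_track(m, test_hap("*5.001")$sequence, "REF")$gaps
  expect_identical(g_5$length, 14551L)
  expect_false(any(g_5$within_spacer_window))
  # a tandem read on its own track aligns without gaps
  g_t <- align_read_to_track(m, test_hap("*36+*10.001")$sequence, "A")$gaps
  expect_identical(nrow(g_t), 0L)
})

test_that("spacer-gap decision follows length and window-overlap rules", {
  m <- test_model()
  track_a <- build_custom_track(m, "A")
  win <- track_a$spacer_window
  gap <- function(start, len) {
    data.frame(start = start, end = start + len, length = len,
               within_spacer_window = NA)
  }
  g1 <- gap(win[1], 1560L)
  expect_identical(detect_spacer_gap(g1, track_a)$spacer_status, "ABSENT")
  expect_identical(detect_spacer_gap(g1, track_a)$gap_length, 1560L)
  none <- g1[0, ]
  expect_identical(detect_spacer_gap(none, track_a)$spacer_status, "PRESENT")
  # a short in-window gap plus a spacer-sized gap elsewhere: spacer present
  g2 <- rbind(gap(win[1], 300L), gap(win[1] - 8000L, 1560L))
  expect_identical(detect_spacer_gap(g2, track_a)$spacer_status, "PRESENT")
  expect_error(detect_spacer_gap(g1, build_custom_track(m, "REF")),
               "spacer_window")
})

test_that("track selection is a pure function of the stated read features", {
  m <- test_model()
  s_t <- summarize_read(m, test_hap("*36+*10.001")$sequence)
  expect_identical(select_reference_track(s_t), "A")
  s_d <- summarize_read(m, test_hap("*2.001x2")$sequence)
  expect_identical(select_reference_track(s_d), "B")
  s_r <- summarize_read(m, m$reference)
  expect_identical(select_reference_track(s_r), "REF")
  s_13 <- summarize_read(m, test_hap("*13+*2.001")$sequence)
  expect_identical(select_reference_track(s_13), "B")
  # purity: identical feature lists give identical tracks
  fake <- list(length_class = "TANDEM", five_prime_origin = "D7_LIKE",
               spacer_in_tandem = TRUE)
  expect_identical(select_reference_track(fake), select_reference_track(fake))
  fake$spacer_in_tandem <- FALSE
  expect_identical(select_reference_track(fake), "UNCLASSIFIED")
})

test_that("fragment lengths of fixture groups match the printed spectrum", {
  for (case in list(list("*1.001", 39551L), list("*5.001", 25000L),
                    list("*36+*10.001", 52000L), list("*2.001x2", 52000L))) {
    g <- group_summaries(test_hap(case[[1]]), 6,
                         error_model(truncation_prob = 0), seed = 17)
    expect_identical(measure_fragment_length(g), case[[2]])
  }
  expect_error(measure_fragment_length(list()), "empty")
})

test_that("anchored span estimates fragment length without truth labels", {
  m <- test_model()
  s <- summarize_read(m, test_hap("*5.001")$sequence)
  expect_identical(s$fragment_length, 25000L)
  g <- group_summaries(test_hap("*5.001"), 5, error_model(), seed = 23,
                       use_truth_length = FALSE)
  est <- measure_fragment_length(g)
  expect_lt(abs(est - 25000) / 25000, 0.05)
})

test_that("structure classification recovers each fixture kind", {
  m <- test_model()
  em <- error_model()
  cases <- list(
    list("*1.001", "NO_SV", "REF"),
    list("*5.001", "DELETION", "REF"),
    list("*2.001x2", "DUPLICATION", "B"),
    list("*36+*10.001", "HYBRID_TANDEM", "A"),
    list("*13+*2.001", "HYBRID_TANDEM", "B"))
  for (case in cases) {
    g <- group_summaries(test_hap(case[[1]]), 8, em, seed = 29)
    sc <- classify_structure(g, m)
    expect_identical(sc$kind, case[[2]])
    expect_identical(sc$selected_track, case[[3]])
  }
  g5 <- group_summaries(test_hap("*5.001"), 8, em, seed = 31)
  expect_identical(classify_structure(g5, m)$fragment_length_bp, 25000L)
})

test_that("undersized or tied groups yield NO_CALL, never a silent NO_SV", {
  m <- test_model()
  g <- group_summaries(test_hap("*1.001"), 2, error_model(), seed = 37)
  sc <- classify_structure(g, m)
  expect_identical(sc$kind, "NO_CALL")
  expect_match(sc$reason, "minimum")
  # constructed tie between two kinds
  fake <- function(kind) {
    list(kind = kind, fragment_length = 39551L, length_class = "NO_SV",
         five_prime_origin = NA_character_, spacer_in_tandem = NA,
         exon_origins = rep(NA_character_, 9))
  }
  tie <- c(lapply(1:2, function(i) fake("NO_SV")),
           lapply(1:2, function(i) fake("DELETION")))
  sc2 <- classify_structure(tie, m)
  expect_identical(sc2$kind, "NO_CALL")
  expect_match(sc2$reason, "tie")
})

test_that("unalignable input is flagged rather than forced onto a track", {
  m <- test_model()
  junk <- random_test_dna(30000, 999)
  aln <- align_read_to_track(m, junk, "REF")
  expect_true(aln$unalignable)
  s <- summarize_read(m, junk)
  expect_false(s$full_span)
  expect_lt(s$score, qc_params()$min_alignment_score)
})
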