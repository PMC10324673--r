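test_that("fixture locus reproduces the printed fragment and window arithmetic", {
  m <- test_model()
  expect_identical(nchar(m$reference), 39551L)
  expect_identical(inclusive_span(42122008, 42161558), 39551L)
  expect_identical(diff(analysis_window(m)), 38254L)
  expect_identical(inclusive_span(42123069, 42161322), 38254L)
  expect_identical(sum(locus_segments()$length), 39551L)
})

test_that("locus construction is deterministic in the seed", {
  m1 <- build_locus_model(101L)
  m2 <- build_locus_model(101L)
  m3 <- build_locus_model(102L)
  expect_identical(m1$reference, m2$reference)
  expect_identical(m1$tracks$A$sequence, m2$tracks$A$sequence)
  expect_false(identical(m1$reference, m3$reference))
})

test_that("segment configuration errors are rejected", {
  seg <- locus_segments()
  bad <- seg; bad$length[3] <- 0L
  expect_error(build_locus_model(7L, bad), "length")
  bad <- seg; bad$name[2] <- bad$name[1]
  expect_error(build_locus_model(7L, bad), "unique")
  bad <- seg; bad$role[bad$role == "SPACER"] <- "INTERGENIC"
  expect_error(build_locus_model(7L, bad), "SPACER")
})

test_that("custom tracks carry the spacer structure", {
  m <- test_model()
  a <- build_custom_track(m, "A")
  b <- build_custom_track(m, "B")
  expect_identical(diff(a$spacer_window), 1560L)
  expect_false(any(grepl("TD_SPACER", b$segment_map$instance)))
  # oracle: direct sum of the two tracks' segment lengths
  expect_identical(sum(a$segment_map$length) - sum(b$segment_map$length), 1560L)
  expect_identical(a$length - b$length, 1560L)
  expect_error(build_custom_track(m, "C"), "track_id")
})

test_that("haplotype lengths match the fragment spectrum and conserve segments", {
  cases <- list("*1.001" = 39551L, "*5.001" = 25000L, "*2.001x2" = 52000L,
                "*36+*10.001" = 52000L, "*68+*4.001" = 52000L,
                "*13+*2.001" = 52000L)
  for (lbl in names(cases)) {
    h <- test_hap(lbl)
    expect_identical(h$length, cases[[lbl]])
    # segment-length conservation, exact integer check
    expect_identical(h$length, sum(h$layout$length))
    expect_identical(nchar(h$sequence), h$length)
  }
  expect_identical(nrow(test_hap("*1.001")$variants), 0L)
  expect_length(test_hap("*5.001")$copies, 0L)
  dup <- test_hap("*2.001x2")
  expect_identical(sort(unique(dup$variants$copy)), c("regular", "tandem"))
  expect_identical(nrow(dup$variants), 4L)
})

test_that("haplotype construction rejects unknown alleles", {
  expect_error(build_haplotype_sequence(test_model(), "*99.001", test_defs()),
               "unknown")
  expect_error(parse_allele("99"), "unparseable")
  expect_error(parse_diplotype("*1.001"), "unparseable")
})

test_that("cut sites are found with the 3-bp-5'-of-PAM rule", {
  set.seed(42)
  guide <- random_test_dna(20, 7)
  # plus strand: protospacer at 0-based offset 100, PAM AGG
  seq <- paste0(random_test_dna(100, 1), guide, "AGG", random_test_dna(80, 2))
  hits <- find_cut_sites(seq, guide)
  expect_identical(hits$position, 117L)
  expect_identical(hits$strand, "+")
  # guide absent
  expect_identical(nrow(find_cut_sites(random_test_dna(300, 3), guide)), 0L)
  # guide present only as reverse complement
  rcseq <- paste0(random_test_dna(60, 4), "CCT",
                  chartr("ACGT", "TGCA",
                         paste(rev(strsplit(guide, "")[[1]]), collapse = "")),
                  random_test_dna(60, 5))
  hits <- find_cut_sites(rcseq, guide)
  expect_identical(hits$strand, "-")
  expect_identical(hits, oracle_cut_sites(rcseq, guide))
  # input validation
  expect_error(find_cut_sites(seq, "ACGTNACGTNACGTNACGTN"), "ambiguous")
  expect_error(find_cut_sites(seq, "ACGT"), "20-nt")
})

test_that("cut-site finder agrees with the exhaustive both-strand oracle", {
  for (s in 1:100) {
    seq <- random_test_dna(5000, 1000 + s)
    guide <- substr(seq, 2001, 2020) # planted by construction
    expect_identical(find_cut_sites(seq, guide), oracle_cut_sites(seq, guide),
                     info = paste("seed", s))
  }
})

test_that("in-silico digestion releases the cut-to-cut fragment", {
  m <- test_model()
  d <- digest_locus(m)
  expect_identical(nchar(d$fragment), 39551L)
  expect_identical(d$fragment, m$reference)
  expect_identical(diff(range(d$cut_positions)), 39551L)
})

test_that("allele definition validation enforces the containment invariants", {
  defs <- test_defs()
  expect_s3_class(defs, "cyp_allele_defs")
  # suballele missing a core variant
  bad <- as.data.frame(defs)[, 1:5]
  i <- which(bad$suballele == "*2.033")
  bad$sub_variants[i] <- strsplit(bad$sub_variants[i], ";")[[1]][3]
  expect_error(longstar:::validate_allele_definitions(bad), "contain")
  # position outside the analysis window
  bad2 <- as.data.frame(defs)[, 1:5]
  bad2$core_variants[bad2$suballele == "*4.001"] <- "99999:A>G"
  bad2$sub_variants[bad2$suballele == "*4.001"] <- "99999:A>G"
  expect_error(longstar:::validate_allele_definitions(bad2), "window")
  # empty sub_variants for the reference suballele is accepted
  expect_identical(nrow(defs$sub[[match("*1.001", defs$suballele)]]), 0L)
})

test_that("allele definitions round-trip through TSV and load from extdata", {
  defs <- test_defs()
  path <- tempfile(fileext = ".tsv")
  write_allele_definitions(defs, path)
  back <- load_allele_definitions(path)
  expect_identical(as.data.frame(back)[, 1:5], as.data.frame(defs)[, 1:5])
  shipped <- system.file("extdata", "allele_definitions.tsv",
                         package = "longstar")
  expect_true(nzchar(shipped))
  sh <- load_allele_definitions(shipped)
  expect_identical(as.data.frame(sh)[, 1:5], as.data.frame(defs)[, 1:5])
  expect_error(load_allele_definitions(tempfile()), "not found")
})
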