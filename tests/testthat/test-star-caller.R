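test_that("variant profiles read planted alleles exactly on clean reads", {
  m <- test_model()
  defs <- test_defs()
  sites <- longstar:::definition_sites(defs)
  h2 <- test_hap("*2.033")
  f <- read_features(m, h2$sequence)
  obs <- extract_variant_profile(m, f, sites)
  names(obs) <- sites$pos
  expect_identical(unname(obs[as.character(c(29650, 31200, 33500))]),
                   rep("ALT", 3))
  expect_true(all(obs[setdiff(names(obs),
                              as.character(c(29650, 31200, 33500)))] == "REF"))
})

test_that("sites under a read gap are MISSING, never reference support", {
  m <- test_model()
  defs <- test_defs()
  sites <- longstar:::definition_sites(defs)
  h1 <- test_hap("*1.001")
  # delete 400 bp centred on site 29650 (0-based haplotype coordinate)
  pos0 <- longstar:::window_to_seq0(m, 29650L)
  gapped <- paste0(substr(h1$sequence, 1, pos0 - 200),
                   substr(h1$sequence, pos0 + 200, nchar(h1$sequence)))
  f <- read_features(m, gapped)
  obs <- extract_variant_profile(m, f, sites)
  expect_identical(obs[match(29650L, sites$pos)], "MISSING")
})

test_that("tandem-copy profiling separates the two gene copies", {
  m <- test_model()
  defs <- test_defs()
  sites <- longstar:::definition_sites(defs)
  ht <- test_hap("*36+*10.001") # *10 core variant only in the 3' regular copy
  f <- read_features(m, ht$sequence)
  reg <- extract_variant_profile(m, f, sites)
  i10 <- match(29750L, sites$pos)
  expect_identical(reg[i10], "ALT")
  hd <- test_hap("*2.001x2") # both copies carry the *2 core variants
  fd <- read_features(m, hd$sequence)
  td <- extract_variant_profile(m, fd, sites, copy = "tandem",
                                origin_map = rep("D6", 9))
  expect_identical(td[match(29650L, sites$pos)], "ALT")
  expect_identical(td[match(31200L, sites$pos)], "ALT")
})

test_that("error-free heterozygous read sets partition perfectly", {
  m <- test_model(); defs <- test_defs()
  em0 <- error_model(0, 0, 0, truncation_prob = 0)
  reads <- simulate_diploid_reads(test_hap("*2.033"), test_hap("*29.001"),
                                  5, em0, seed = 41)
  summ <- lapply(reads$sequence, function(s) summarize_read(m, s))
  cl <- cluster_reads(summ, m, defs)
  expect_length(cl$clusters, 2L)
  for (cc in cl$clusters) {
    expect_identical(length(unique(reads$allele_index[cc])), 1L)
  }
})

test_that("suballele-level heterozygosity is resolved into two clusters", {
  m <- test_model(); defs <- test_defs()
  reads <- simulate_diploid_reads(test_hap("*1.058"), test_hap("*1.059"),
                                  20, error_model(), seed = 43)
  reads <- reads[reads$full_span, ]
  summ <- lapply(reads$sequence, function(s) summarize_read(m, s))
  cl <- cluster_reads(summ, m, defs)
  expect_length(cl$clusters, 2L)
  acc <- max(vapply(1:2, function(k) {
    tab <- table(factor(reads$allele_index[cl$clusters[[k]]], levels = 1:2))
    max(tab) / sum(tab)
  }, numeric(1)))
  expect_gte(acc, 0.9)
})

test_that("read clustering assigns reads to the truth cluster at depth 40", {
  m <- test_model(); defs <- test_defs()
  correct <- 0L; total <- 0L
  for (s in 1:5) {
    reads <- simulate_diploid_reads(test_hap("*1.001"), test_hap("*4.001"),
                                    40, error_model(), seed = 600 + s)
    reads <- reads[reads$full_span, ]
    summ <- lapply(reads$sequence, function(x) summarize_read(m, x))
    cl <- cluster_reads(summ, m, defs)
    expect_length(cl$clusters, 2L)
    # orient clusters to truth by majority
    for (k in seq_along(cl$clusters)) {
      truth <- reads$allele_index[cl$clusters[[k]]]
      correct <- correct + max(table(truth))
      total <- total + length(truth)
    }
  }
  expect_gte(correct / total, 0.95)
})

test_that("homozygous samples collapse to a single cluster", {
  m <- test_model(); defs <- test_defs()
  reads <- simulate_diploid_reads(test_hap("*1.001"), test_hap("*1.001"),
                                  10, error_model(), seed = 47)
  reads <- reads[reads$full_span, ]
  summ <- lapply(reads$sequence, function(s) summarize_read(m, s))
  cl <- cluster_reads(summ, m, defs)
  expect_length(cl$clusters, 1L)
  expect_true(cl$homozygous)
})

test_that("consensus calling recovers planted variants with no false positives", {
  m <- test_model(); defs <- test_defs()
  h2 <- test_hap("*2.033")
  ok_all <- TRUE
  for (s in 1:3) {
    g <- group_summaries(h2, 25, error_model(), seed = 700 + s)
    sc <- classify_structure(g, m)
    cons <- consensus_and_call(m, g, sc, defs, discover = TRUE,
                               seed = 800 + s)
    called <- cons$regular$calls
    alt <- called$key[called$status == "ALT"]
    truth <- longstar:::variant_keys(
      defs$sub[[match("*2.033", defs$suballele)]])
    ok_all <- ok_all && setequal(alt, truth)
  }
  expect_true(ok_all)
})

test_that("shallow sites propagate as site-level NO_CALL", {
  sites <- data.frame(pos = 1L, ref = "A", alt = "G", key = "1:A>G")
  obs <- matrix(c("ALT", "MISSING", "MISSING"), ncol = 1)
  out <- longstar:::site_consensus(sites, obs)
  expect_identical(out$status, "NO_CALL")
  obs2 <- matrix(rep("ALT", 5), ncol = 1)
  expect_identical(longstar:::site_consensus(sites, obs2)$status, "ALT")
  expect_identical(longstar:::site_consensus(sites, obs2)$supporting_fraction, 1)
  # 60/40 mixtures are undecidable at the 0.7 majority threshold
  obs3 <- matrix(c(rep("ALT", 6), rep("REF", 4)), ncol = 1)
  expect_identical(longstar:::site_consensus(sites, obs3)$status, "NO_CALL")
})

test_that("star-allele assignment follows containment and maximality", {
  defs <- test_defs()
  key_of <- function(lbl) longstar:::variant_keys(
    defs$sub[[match(lbl, defs$suballele)]])
  # reference allele
  r <- assign_star_allele(character(0), defs)
  expect_identical(r$core, "*1")
  expect_identical(r$suballele, "*1.001")
  # exact suballele match
  r2 <- assign_star_allele(key_of("*2.033"), defs)
  expect_identical(r2$suballele, "*2.033")
  expect_false(r2$novel)
  # core match with an undefined extra is a novel suballele of that core
  r3 <- assign_star_allele(c(key_of("*2.001"), "30000:A>G"), defs)
  expect_identical(r3$core, "*2")
  expect_true(r3$novel)
  expect_identical(r3$extra_variants, "30000:A>G")
  expect_identical(r3$suballele, "*2.new1")
})

test_that("emitted suballele definitions contain their core set", {
  defs <- test_defs()
  for (lbl in c("*1.001", "*1.058", "*2.001", "*2.033", "*4.001", "*10.001",
                "*29.001")) {
    called <- longstar:::variant_keys(defs$sub[[match(lbl, defs$suballele)]])
    r <- assign_star_allele(called, defs)
    expect_identical(r$suballele, lbl)
    core_set <- longstar:::variant_keys(
      defs$core[[match(r$core, defs$star_allele)]])
    expect_true(all(core_set %in% called))
  }
})

test_that("diplotype assembly follows the tandem-annotation conventions", {
  mk <- function(label, kind = "NO_SV") {
    structure(list(label = label, no_call = FALSE, reason = NA_character_,
                   structure = list(kind = kind)),
              class = "cyp_allele_call")
  }
  d <- assemble_diplotype(list(mk("*29.001"), mk("*2.001x2", "DUPLICATION")))
  expect_identical(d$diplotype, "*2.001x2/*29.001")
  d2 <- assemble_diplotype(list(mk("*68+*4.001", "HYBRID_TANDEM"),
                                mk("*1.037")))
  expect_identical(d2$diplotype, "*1.037/*68+*4.001")
  d3 <- assemble_diplotype(list(mk("*1.001")))
  expect_identical(d3$diplotype, "*1.001/*1.001")
  # symmetry: swapping the two alleles leaves the formatted string unchanged
  d4 <- assemble_diplotype(list(mk("*1.037"),
                                mk("*68+*4.001", "HYBRID_TANDEM")))
  expect_identical(d4$diplotype, d2$diplotype)
  nc <- structure(list(label = NA_character_, no_call = TRUE,
                       reason = "x", structure = list(kind = "NO_CALL")),
                  class = "cyp_allele_call")
  d5 <- assemble_diplotype(list(nc, nc))
  expect_true(d5$no_call)
})

test_that("diplotype normalization strips suballele resolution only", {
  expect_identical(normalize_diplotype("*2.001x2/*29.001"), "*2x2/*29")
  expect_identical(normalize_diplotype("*1.037/*68+*4.001"), "*1/*68+*4")
  expect_identical(normalize_diplotype("*2.new1/*5.001"), "*2/*5")
})
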