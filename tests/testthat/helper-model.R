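# Shared fixtures: the default locus model and definition table are built
# once per test run; haplotypes are cached on demand.

.test_env <- new.env(parent = emptyenv())

test_model <- function() {
  if (is.null(.test_env$model)) .test_env$model <- build_locus_model(7L)
  .test_env$model
}

test_defs <- function() {
  if (is.null(.test_env$defs)) {
    .test_env$defs <- default_allele_definitions(test_model())
  }
  .test_env$defs
}

test_hap <- function(label) {
  key <- paste0("hap:", label)
  if (is.null(.test_env[[key]])) {
    .test_env[[key]] <- build_haplotype_sequence(test_model(), label,
                                                 test_defs())
  }
  .test_env[[key]]
}

# Independent brute-force oracle for the cut-site finder: examine every
# 23-mer on both strands and apply the blunt-cut rule directly.
oracle_cut_sites <- function(seq, guide, pam = "NGG") {
  n <- nchar(seq)
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  hits <- list()
  for (i in seq_len(n - 22L)) { # 1-based window start, 23-mer
    w <- substr(seq, i, i + 22L)
    proto <- substr(w, 1, 20)
    pamseq <- substr(w, 21, 23)
    if (proto == guide && grepl("^[ACGT]GG$", pamseq)) {
      hits[[length(hits) + 1L]] <- data.frame(position = (i - 1L) + 17L,
                                              strand = "+")
    }
    # minus strand: the reverse complement of the 23-mer reads protospacer+PAM
    wrc <- rc(w)
    if (substr(wrc, 1, 20) == guide && grepl("^[ACGT]GG$", substr(wrc, 21, 23))) {
      # plus-strand protospacer occupies [i+3-1 .. ], cut at 0-based (i-1)+6
      hits[[length(hits) + 1L]] <- data.frame(position = (i - 1L) + 6L,
                                              strand = "-")
    }
  }
  if (length(hits) == 0) {
    return(data.frame(position = integer(0), strand = character(0)))
  }
  out <- unique(do.call(rbind, hits))
  out[order(out$position), , drop = FALSE]
}

random_test_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Per-read structural summaries for a simulated allele group.
group_summaries <- function(hap, n_reads, err = error_model(), seed = 1L,
                            use_truth_length = TRUE) {
  reads <- simulate_diploid_reads(hap, hap, ceiling(n_reads * 0.75), err, seed)
  reads <- reads[reads$full_span, , drop = FALSE]
  reads <- utils::head(reads, n_reads)
  lapply(seq_len(nrow(reads)), function(i)
    summarize_read(test_model(), reads$sequence[i],
                   truth_length = if (use_truth_length)
                     reads$fragment_length[i] else NULL))
}
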