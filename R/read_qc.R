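# Read-level gates: length filter, mean-quality threshold, full-span
# requirement, alignment-score filter, and sample-level coverage QC.

#' QC parameters
#'
#' @param min_read_length minimum read length in bp (reads shorter than this
#'   are removed; boundary inclusive), default 20,000.
#' @param min_mean_q minimum per-read mean PHRED quality (probability-space
#'   mean), default 7.
#' @param min_alignment_score minimum internal aligner score (count of chained
#'   track-unique 17-mer matches); the default is calibrated so that
#'   error-free full-span reads pass comfortably and reads matching less than
#'   half the locus fail.
#' @param min_full_span_reads minimum full-span reads for a sample-level
#'   pass, default 35.
#' @return list of class `cyp_qc_params`.
#' @export
qc_params <- function(min_read_length = 20000L, min_mean_q = 7,
                      min_alignment_score = 2000L, min_full_span_reads = 35L) {
  if (any(c(min_read_length, min_mean_q, min_alignment_score,
            min_full_span_reads) < 0)) {
    stop("QC thresholds must be >= 0", call. = FALSE)
  }
  structure(list(min_read_length = min_read_length, min_mean_q = min_mean_q,
                 min_alignment_score = min_alignment_score,
                 min_full_span_reads = min_full_span_reads),
            class = "cyp_qc_params")
}

#' Filter reads on length and mean quality
#'
#' A read passes iff its length is at least `min_read_length` (the filter
#' removes reads under 20 kb by default) and its probability-space mean PHRED
#' quality is at least `min_mean_q`.
#'
#' @param reads data.frame with `sequence` and `quality` columns.
#' @param params a `cyp_qc_params`.
#' @return list with `reads` (passing subset) and `counts`
#'   (input / pass_length / pass_quality).
#' @export
filter_reads <- function(reads, params = qc_params()) {
  if (nrow(reads) == 0) {
    return(list(reads = reads,
                counts = c(input = 0L, pass_length = 0L, pass_quality = 0L)))
  }
  if (!"quality" %in% names(reads) || anyNA(reads$quality) ||
      any(!nzchar(reads$quality))) {
    stop("missing quality strings: cannot evaluate the quality gate",
         call. = FALSE)
  }
  len_ok <- nchar(reads$sequence) >= params$min_read_length
  r1 <- reads[len_ok, , drop = FALSE]
  mq <- vapply(r1$quality, function(q) mean_phred(char_to_phred(q)), numeric(1))
  q_ok <- mq >= params$min_mean_q
  r2 <- r1[q_ok, , drop = FALSE]
  r2$mean_q <- mq[q_ok]
  list(reads = r2,
       counts = c(input = nrow(reads), pass_length = nrow(r1),
                  pass_quality = nrow(r2)))
}

#' Does a read span the entire targeted region?
#'
#' True iff both the 5' and 3' cut-site flank anchors are detected.  Reads
#' with large internal deletions (a *5 allele) still span both targeted sites
#' and return TRUE.
#'
#' @param model a `cyp_locus_model`.
#' @param read read sequence, `cyp_read_features`, or `cyp_read_summary`.
#' @return logical.
#' @export
check_full_span <- function(model, read) {
  if (is(read, "cyp_read_summary")) return(read$full_span)
  anchors <- detect_anchors(model, read)
  all(c("FLANK_5P", "FLANK_3P") %in% anchors$anchor_id)
}

#' Coverage profile and sample-level QC over the analysis window
#'
#' Because every retained read spans the analysis window, the minimum depth
#' equals the full-span read count; the sample passes when that count reaches
#' `min_full_span_reads`.
#'
#' @param spans data.frame of covered intervals per read (`start`, `end`,
#'   0-based half-open, in fragment coordinates); full-span reads cover the
#'   whole fragment.
#' @param window 0-based half-open window, default the model analysis window.
#' @param params a `cyp_qc_params`.
#' @return list with `depth` (integer vector over the window), `mean_depth`,
#'   `min_depth`, `n_reads`, `sample_pass`.
#' @export
coverage_profile <- function(spans, window, params = qc_params()) {
  wlen <- window[2] - window[1]
  if (is.null(spans) || nrow(spans) == 0) {
    return(list(depth = integer(wlen), mean_depth = 0, min_depth = 0L,
                n_reads = 0L, sample_pass = FALSE))
  }
  ir <- IRanges::IRanges(start = spans$start + 1L, end = spans$end)
  cov <- IRanges::coverage(ir, width = max(window[2], max(spans$end)))
  depth <- as.integer(cov)[(window[1] + 1L):window[2]]
  list(depth = depth, mean_depth = mean(depth), min_depth = min(depth),
       n_reads = nrow(spans),
       sample_pass = nrow(spans) >= params$min_full_span_reads)
}

#' Assemble a QC report
#'
#' Gate counts are non-increasing along the gate order: input, length,
#' quality, full-span, alignment score.
#'
#' @param counts named integer vector from the pipeline gates.
#' @param coverage result of [coverage_profile()].
#' @return list of class `cyp_qc_report`.
#' @export
qc_report <- function(counts, coverage) {
  structure(list(counts = counts,
                 mean_depth = coverage$mean_depth,
                 min_depth = coverage$min_depth,
                 sample_pass = coverage$sample_pass),
            class = "cyp_qc_report")
}

#' @export
print.cyp_qc_report <- function(x, ...) {
  cat("QC report: ", paste(names(x$counts), x$counts, sep = "=",
                           collapse = ", "), "\n", sep = "")
  cat("  mean depth ", round(x$mean_depth, 1), ", min depth ", x$min_depth,
      ", sample_pass ", x$sample_pass, "\n", sep = "")
  invisible(x)
}
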