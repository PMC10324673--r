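#' @importFrom methods is
#' @importFrom stats median rnorm runif setNames
#' @importFrom utils read.delim write.table adist head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded helpers never disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a deterministic 31-bit sub-seed from a base seed and a label.
# Keeps derived seeds independent across uses without consuming the caller RNG.
derive_seed <- function(seed, label) {
  h <- utf8ToInt(paste0(label, ":", as.character(seed)))
  s <- 0
  for (v in h) s <- (s * 131 + v) %% 2147483647L
  as.integer(s)
}

# Seeded uniform random nucleotide sequence of length n (single string).
random_dna <- function(n, seed) {
  stopifnot(n > 0)
  with_seed(seed, paste(sample(DNA_BASES, n, replace = TRUE), collapse = ""))
}

# Substitute a fraction `rate` of positions (seeded, without replacement) to a
# different base. Used for the paralog / copy divergence model.
mutate_dna <- function(seq, rate, seed) {
  n <- nchar(seq)
  k <- round(n * rate)
  if (k == 0) return(seq)
  with_seed(seed, {
    pos <- sample.int(n, k)
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
    }
    paste(ch, collapse = "")
  })
}

# Reverse complement of a plain character sequence.
revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Inclusive genomic span
#'
#' Length in bp of a 1-based inclusive coordinate interval, the convention in
#' which targeted-enrichment regions are printed in reports.
#'
#' @param start,end 1-based inclusive coordinates.
#' @return integer span in bp.
#' @examples
#' inclusive_span(42123069, 42161322)
#' @export
inclusive_span <- function(start, end) {
  stopifnot(end >= start)
  as.integer(end - start + 1)
}

# Mean PHRED quality via probability-space averaging: convert each Q to an
# error probability, average, convert back.
mean_phred <- function(q) {
  if (length(q) == 0) return(NA_real_)
  -10 * log10(mean(10^(-q / 10)))
}

phred_to_char <- function(q) {
  intToUtf8(pmin(pmax(round(q), 0L), 93L) + 33L, multiple = FALSE)
}

char_to_phred <- function(s) {
  utf8ToInt(s) - 33L
}
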