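# Nanopore-like read simulation from a diploid pair of excision-fragment
# haplotypes.  Reads are adapter-free (the molecule is the CRISPR-excised
# fragment), carry truth labels, and use a flat substitution/insertion/
# deletion error model with PHRED qualities drawn from a truncated normal.

#' Construct and validate an error model
#'
#' Defaults emulate the observed read quality of the targeted nanopore runs
#' (mean Q around 14) with enough truncated reads that the full-span exclusion
#' rule is exercised.
#'
#' @param sub_rate,ins_rate,del_rate per-base substitution / insertion /
#'   deletion probabilities.
#' @param mean_q,q_sd parameters of the per-base PHRED quality distribution.
#' @param truncation_prob probability that a read is truncated (pore dropout).
#' @param truncation_frac_range interval for the retained fraction of a
#'   truncated read.
#' @return list of class `cyp_error_model`.
#' @export
error_model <- function(sub_rate = 0.02, ins_rate = 0.015, del_rate = 0.02,
                        mean_q = 14, q_sd = 3, truncation_prob = 0.15,
                        truncation_frac_range = c(0.3, 0.95)) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates >= 1)) {
    stop("error rates must lie in [0, 1)", call. = FALSE)
  }
  if (sum(rates) >= 0.5) {
    stop("sub_rate + ins_rate + del_rate must be < 0.5", call. = FALSE)
  }
  if (mean_q <= 0) stop("mean_q must be > 0", call. = FALSE)
  if (truncation_prob < 0 || truncation_prob > 1 ||
      length(truncation_frac_range) != 2 ||
      any(truncation_frac_range <= 0) || any(truncation_frac_range > 1) ||
      diff(truncation_frac_range) < 0) {
    stop("invalid truncation parameters", call. = FALSE)
  }
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
                 mean_q = mean_q, q_sd = q_sd, truncation_prob = truncation_prob,
                 truncation_frac_range = truncation_frac_range),
            class = "cyp_error_model")
}

#' Apply the error model to a sequence
#'
#' Introduces independent per-base substitutions, deletions, and single-base
#' insertions (after the base), and draws a PHRED+33 quality string for the
#' mutated sequence.
#'
#' @param sequence input sequence (character).
#' @param model a `cyp_error_model`.
#' @param seed integer seed.
#' @return list with `sequence`, `quality`, and realized event counts
#'   `n_sub`, `n_ins`, `n_del`.
#' @export
apply_error_model <- function(sequence, model = error_model(), seed = 1L) {
  stopifnot(is(model, "cyp_error_model"))
  n <- nchar(sequence)
  if (n == 0) stop("empty sequence", call. = FALSE)
  with_seed(seed, {
    ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
    u <- runif(n)
    s <- model$sub_rate; d <- model$del_rate; i <- model$ins_rate
    sub_idx <- which(u < s)
    del_idx <- which(u >= s & u < s + d)
    ins_idx <- which(u >= s + d & u < s + d + i)
    if (length(sub_idx)) {
      # substitute to one of the three other bases, uniformly
      shift <- sample.int(3L, length(sub_idx), replace = TRUE)
      cur <- match(ch[sub_idx], DNA_BASES)
      ch[sub_idx] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
    if (length(ins_idx)) {
      ch[ins_idx] <- paste0(ch[ins_idx],
                            sample(DNA_BASES, length(ins_idx), replace = TRUE))
    }
    if (length(del_idx)) ch[del_idx] <- ""
    out <- paste(ch, collapse = "")
    m <- nchar(out)
    q <- pmin(pmax(round(rnorm(m, model$mean_q, model$q_sd)), 2L), 41L)
    list(sequence = out, quality = phred_to_char(q),
         n_sub = length(sub_idx), n_ins = length(ins_idx),
         n_del = length(del_idx))
  })
}

#' Simulate reads from a diploid pair of haplotypes
#'
#' Emits exactly `depth_per_allele` reads per allele (depth is a per-allele
#' read count, not coverage).  Each read starts from the full excised
#' fragment; with probability `truncation_prob` it is truncated from one end
#' (losing one cut-site flank anchor and therefore full-span status), then
#' errors are applied and the read is reported on a random strand.  Reads are
#' emitted in randomized allele order.
#'
#' @param hapA,hapB `cyp_haplotype` objects (or plain sequences).
#' @param depth_per_allele reads per allele (>= 1).
#' @param model a `cyp_error_model`.
#' @param seed integer seed; the full read set is deterministic given it.
#' @return a `cyp_simreads` data.frame with columns `read_id`, `sequence`,
#'   `quality`, and truth columns `allele_index`, `source_label`, `full_span`,
#'   `fragment_length`, `strand`.
#' @export
simulate_diploid_reads <- function(hapA, hapB, depth_per_allele = 40L,
                                   model = error_model(), seed = 1L) {
  stopifnot(depth_per_allele >= 1)
  haps <- list(hapA, hapB)
  seqs <- lapply(haps, function(h) if (is(h, "cyp_haplotype")) h$sequence else h)
  labels <- vapply(haps, function(h)
    if (is(h, "cyp_haplotype")) h$label else NA_character_, character(1))
  if (any(!nzchar(unlist(seqs)))) stop("empty haplotype sequence", call. = FALSE)

  rows <- list()
  for (a in 1:2) {
    frag <- seqs[[a]]
    flen <- nchar(frag)
    for (j in seq_len(depth_per_allele)) {
      rs <- derive_seed(seed, sprintf("read:%d:%d", a, j))
      meta <- with_seed(rs, list(
        trunc = runif(1) < model$truncation_prob,
        frac = runif(1, model$truncation_frac_range[1],
                     model$truncation_frac_range[2]),
        from_5p = runif(1) < 0.5,
        flip = runif(1) < 0.5
      ))
      piece <- frag
      if (meta$trunc) {
        keep <- max(1L, floor(flen * meta$frac))
        piece <- if (meta$from_5p) substr(frag, 1L, keep)
                 else substr(frag, flen - keep + 1L, flen)
      }
      err <- apply_error_model(piece, model, derive_seed(rs, "err"))
      sq <- err$sequence; ql <- err$quality
      if (meta$flip) {
        sq <- revcomp_chr(sq)
        ql <- paste(rev(strsplit(ql, "", fixed = TRUE)[[1]]), collapse = "")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = sq, quality = ql, allele_index = a,
        source_label = labels[a], full_span = !meta$trunc,
        fragment_length = flen, strand = if (meta$flip) "-" else "+",
        stringsAsFactors = FALSE)
    }
  }
  reads <- do.call(rbind, rows)
  ord <- with_seed(derive_seed(seed, "shuffle"), sample.int(nrow(reads)))
  reads <- reads[ord, , drop = FALSE]
  reads <- cbind(read_id = sprintf("read_%04d", seq_len(nrow(reads))), reads)
  rownames(reads) <- NULL
  class(reads) <- c("cyp_simreads", "data.frame")
  reads
}

#' Write simulated reads to FASTQ (PHRED+33)
#'
#' @param reads a `cyp_simreads` (or any data.frame with `read_id`,
#'   `sequence`, `quality`).
#' @param path output FASTQ path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0) {
    warning("writing empty FASTQ file: ", path)
    cat("", file = path)
    return(invisible(path))
  }
  lines <- character(4L * nrow(reads))
  lines[seq(1, by = 4, length.out = nrow(reads))] <- paste0("@", reads$read_id)
  lines[seq(2, by = 4, length.out = nrow(reads))] <- reads$sequence
  lines[seq(3, by = 4, length.out = nrow(reads))] <- "+"
  lines[seq(4, by = 4, length.out = nrow(reads))] <- reads$quality
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path.
#' @return data.frame with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path, call. = FALSE)
  info <- file.info(path)
  if (info$size == 0) {
    return(data.frame(read_id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  }
  tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    out <- data.frame(read_id = sub(" .*", "", names(x)),
                      sequence = as.character(x),
                      quality = as.character(S4Vectors::mcols(x)$qualities),
                      stringsAsFactors = FALSE)
    if (any(nchar(out$quality, type = "bytes") !=
            nchar(out$sequence, type = "bytes"))) {
      stop("sequence/quality length mismatch")
    }
    out
  }, error = function(e) stop("malformed FASTQ: ", conditionMessage(e),
                              call. = FALSE))
}

#' Truth table of a simulated read set
#'
#' @param reads a `cyp_simreads`.
#' @return data.frame with one row per read: `read_id`, `allele_index`,
#'   `source_label`, `full_span`, `fragment_length`, `strand`.
#' @export
truth_table <- function(reads) {
  as.data.frame(reads)[, c("read_id", "allele_index", "source_label",
                           "full_span", "fragment_length", "strand")]
}

#' Write the truth table as TSV
#'
#' @param reads a `cyp_simreads`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_truth_tsv <- function(reads, path) {
  write.table(truth_table(reads), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
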