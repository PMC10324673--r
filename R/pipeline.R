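# End-to-end pipeline entry points: simulation, genotyping, batch reporting.
# These are the functions the command-line interface wraps.

longstar_version <- function() {
  tryCatch(as.character(utils::packageVersion("longstar")),
           error = function(e) "0.0.0.dev")
}

run_config <- function(seed, extra = list()) {
  c(list(tool = "longstar", version = longstar_version(), seed = seed),
    extra)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

# Short reproducibility hash of an R object (via its JSON serialization).
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE)
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# "# longstar <version> seed=<s> config=<hash>" stamp for report files.
stamp_line <- function(seed, cfg, comment = "# ") {
  sprintf("%slongstar %s seed=%d config=%s", comment, longstar_version(),
          as.integer(seed), config_hash(cfg))
}

write_stamped_table <- function(df, path, seed, cfg) {
  writeLines(stamp_line(seed, cfg), path)
  suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' The nine study diplotypes
#'
#' The fixture sample set: three samples without structural variation and six
#' with a deletion, duplication, or hybrid tandem arrangement.
#'
#' @return named character vector of diplotype strings.
#' @export
fixture_diplotypes <- function() {
  c(S1 = "*1.058/*1.059",
    S2 = "*1.001/*2.033",
    S3 = "*1.001/*4.001",
    S4 = "*2.001/*36+*10.001",
    S5 = "*4.001/*68+*4.001",
    S6 = "*1.045/*5.001",
    S7 = "*1.001/*13+*2.001",
    S8 = "*2.001x2/*29.001",
    S9 = "*1.037/*68+*4.001")
}

#' Simulate a sample and write FASTQ plus truth files
#'
#' @param diplotype diplotype specification string, e.g. "*1.037/*68+*4.001".
#' @param out_dir output directory (created if needed).
#' @param depth reads per allele.
#' @param seed simulation seed.
#' @param model a `cyp_locus_model` (default model built at seed 7).
#' @param defs allele definitions (defaults derived from `model`).
#' @param err a `cyp_error_model`.
#' @return invisibly, a list with the simulated reads and output paths.
#' @export
run_simulate <- function(diplotype, out_dir, depth = 40L, seed = 1L,
                         model = NULL, defs = NULL, err = error_model()) {
  if (is.null(model)) model <- default_model()
  if (is.null(defs)) defs <- default_allele_definitions(model)
  alleles <- parse_diplotype(diplotype)
  haps <- lapply(alleles, build_haplotype_sequence, model = model, defs = defs)
  reads <- simulate_diploid_reads(haps[[1]], haps[[2]], depth, err, seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(fastq = file.path(out_dir, "reads.fastq"),
                truth = file.path(out_dir, "truth.tsv"),
                config = file.path(out_dir, "sim_config.json"))
  write_fastq(reads, paths$fastq)
  write_truth_tsv(reads, paths$truth)
  write_json(run_config(seed, list(
    subcommand = "simulate", diplotype = diplotype, depth = depth,
    error_model = unclass(err),
    reads_per_allele = as.list(table(reads$allele_index)))), paths$config)
  invisible(list(reads = reads, paths = paths, haplotypes = haps))
}

#' Genotype a sample from FASTQ
#'
#' Runs the full pipeline: parse, length/quality gates, segment-feature
#' detection, full-span and alignment-score gates, coverage QC, read-backed
#' phasing into the two alleles, structural classification, per-copy
#' consensus variant calling, star/suballele assignment, and diplotype
#' assembly.  A sample-level NO_CALL (e.g. too few full-span reads) is a
#' successful run with a reason recorded.
#'
#' @param fastq path to a FASTQ file, or a data.frame of reads.
#' @param out_dir output directory for reports (NULL to skip writing).
#' @param model a `cyp_locus_model` (default model at seed 7).
#' @param defs allele definitions (defaults derived from `model`).
#' @param params a `cyp_qc_params`.
#' @param min_cluster_reads per-allele minimum read count, default 3.
#' @param discover search for non-definition variant sites, default TRUE.
#' @param seed seed for the (small) sampling steps.
#' @return list of class `cyp_genotype_result`.
#' @export
run_genotype <- function(fastq, out_dir = NULL, model = NULL, defs = NULL,
                         params = qc_params(), min_cluster_reads = 3L,
                         discover = TRUE, seed = 1L) {
  if (is.null(model)) model <- default_model()
  if (is.null(defs)) defs <- default_allele_definitions(model)
  reads <- if (is.character(fastq)) read_fastq(fastq) else fastq

  f <- filter_reads(reads, params)
  summaries <- lapply(f$reads$sequence, function(s) summarize_read(model, s))
  span_ok <- vapply(summaries, `[[`, logical(1), "full_span")
  summaries <- summaries[span_ok]
  n_span <- sum(span_ok)
  score_ok <- vapply(summaries, function(s)
    s$score >= params$min_alignment_score, logical(1))
  summaries <- summaries[score_ok]
  counts <- c(f$counts, pass_span = n_span, pass_score = length(summaries))

  frag_len <- nchar(model$reference)
  spans <- if (length(summaries)) {
    data.frame(start = 0L, end = frag_len)[rep(1, length(summaries)), ,
                                           drop = FALSE]
  } else data.frame(start = integer(0), end = integer(0))
  cov <- coverage_profile(spans, model$analysis_window, params)
  qc <- qc_report(counts, cov)

  result <- structure(list(qc = qc, clusters = NULL, structures = NULL,
                           calls = NULL, diplotype = NULL,
                           no_call = FALSE, reason = NA_character_,
                           seed = seed),
                      class = "cyp_genotype_result")
  if (!cov$sample_pass) {
    result$no_call <- TRUE
    result$reason <- sprintf("insufficient full-span reads (%d < %d)",
                             length(summaries), params$min_full_span_reads)
  } else {
    cl <- cluster_reads(summaries, model, defs, min_cluster_reads)
    if (!is.na(cl$no_call)) {
      result$no_call <- TRUE
      result$reason <- cl$no_call
    } else {
      calls <- lapply(seq_along(cl$clusters), function(i)
        call_allele(model, summaries[cl$clusters[[i]]], defs,
                    min_cluster_reads, discover,
                    derive_seed(seed, paste0("allele", i))))
      dip <- assemble_diplotype(calls)
      result$clusters <- cl
      result$structures <- lapply(calls, `[[`, "structure")
      result$calls <- calls
      result$diplotype <- dip
      result$no_call <- isTRUE(dip$no_call)
      result$reason <- dip$reason
    }
  }
  if (!is.null(out_dir)) write_genotype_outputs(result, out_dir, model, seed)
  result
}

#' @export
print.cyp_genotype_result <- function(x, ...) {
  print(x$qc)
  if (isTRUE(x$no_call)) {
    cat("Sample NO_CALL: ", x$reason, "\n", sep = "")
  } else {
    print(x$diplotype)
  }
  invisible(x)
}

write_genotype_outputs <- function(result, out_dir, model, seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  qc <- result$qc
  write_json(run_config(seed, list(
    subcommand = "genotype",
    counts = as.list(qc$counts), mean_depth = qc$mean_depth,
    min_depth = qc$min_depth, sample_pass = qc$sample_pass)),
    file.path(out_dir, "qc_report.json"))
  write_stamped_table(
    data.frame(gate = names(qc$counts), reads = as.integer(qc$counts)),
    file.path(out_dir, "qc_report.tsv"), seed, qc$counts)

  dip <- if (isTRUE(result$no_call)) NA_character_
         else result$diplotype$diplotype
  write_json(run_config(seed, list(
    subcommand = "genotype", diplotype = dip,
    no_call = result$no_call, reason = result$reason,
    alleles = if (is.null(result$calls)) NULL else lapply(result$calls,
      function(cc) list(label = cc$label,
                        kind = cc$structure$kind,
                        track = cc$structure$selected_track,
                        fragment_length_bp = cc$structure$fragment_length_bp,
                        n_reads = cc$structure$n_reads)))),
    file.path(out_dir, "diplotype.json"))

  if (!is.null(result$structures)) {
    st <- do.call(rbind, lapply(seq_along(result$structures), function(i) {
      s <- result$structures[[i]]
      data.frame(allele = i, kind = s$kind,
                 track = if (is.na(s$selected_track)) "" else s$selected_track,
                 five_prime_origin = if (is.na(s$five_prime_origin)) ""
                   else s$five_prime_origin,
                 spacer_in_tandem = s$spacer_present_in_tandem_copy,
                 fragment_length_bp = s$fragment_length_bp,
                 n_reads = s$n_reads)
    }))
    write_stamped_table(st, file.path(out_dir, "structure_calls.tsv"),
                        seed, st)
  }
  if (!is.null(result$calls)) {
    write_vcf(result, model, file.path(out_dir, "variants.vcf"), seed)
  }
  invisible(out_dir)
}

# Minimal VCFv4.2 emitter for the called variants, positions reported against
# the reference track in 1-based fragment coordinates (window coordinates are
# echoed in INFO).
write_vcf <- function(result, model, path, seed = NA_integer_) {
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##source=longstar-%s", longstar_version()),
             sprintf("##longstar_seed=%s", seed),
             sprintf("##contig=<ID=REF,length=%d>", nchar(model$reference)),
             "##INFO=<ID=WPOS,Number=1,Type=Integer,Description=\"1-based analysis-window position\">",
             "##INFO=<ID=ALLELE,Number=1,Type=Integer,Description=\"Allele (cluster) index\">",
             "##INFO=<ID=COPY,Number=1,Type=String,Description=\"Gene copy (regular or tandem)\">",
             "##INFO=<ID=SF,Number=1,Type=Float,Description=\"Supporting read fraction\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO"), collapse = "\t"))
  for (i in seq_along(result$calls)) {
    cons <- result$calls[[i]]$variants
    if (is.null(cons)) next
    for (nm in names(cons)) {
      calls <- cons[[nm]]$calls
      alt <- calls[calls$status == "ALT", , drop = FALSE]
      if (nrow(alt) == 0) next
      for (r in seq_len(nrow(alt))) {
        lines <- c(lines, paste(
          "REF", window_to_seq0(model, alt$pos[r]) + 1L, ".",
          alt$ref[r], alt$alt[r], ".", "PASS",
          sprintf("WPOS=%d;ALLELE=%d;COPY=%s;SF=%.3f",
                  alt$pos[r], i, cons[[nm]]$copy, alt$supporting_fraction[r]),
          sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate the nine fixture samples
#'
#' Writes one subdirectory per sample with FASTQ, truth table and the echoed
#' simulation config, using per-sample seeds derived from `seed`.
#'
#' @param out_dir parent output directory.
#' @param seed base seed.
#' @param depth reads per allele.
#' @param model,defs,err as in [run_simulate()].
#' @return data.frame with `sample`, `diplotype`, `dir`.
#' @export
make_fixture_samples <- function(out_dir, seed = 1L, depth = 40L,
                                 model = NULL, defs = NULL,
                                 err = error_model()) {
  if (is.null(model)) model <- default_model()
  if (is.null(defs)) defs <- default_allele_definitions(model)
  dips <- fixture_diplotypes()
  out <- data.frame(sample = names(dips), diplotype = unname(dips),
                    dir = file.path(out_dir, names(dips)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    run_simulate(out$diplotype[i], out$dir[i], depth,
                 derive_seed(seed, paste0("fixture:", out$sample[i])),
                 model, defs, err)
  }
  out
}

#' Summarize genotyping results of a batch of samples
#'
#' Scans each sample directory for `diplotype.json` (and `sim_config.json`
#' with the simulated truth, when present) and builds a per-sample table with
#' detected diplotypes and core-allele + structural concordance.
#'
#' @param dirs parent directory or vector of sample directories.
#' @param path optional output TSV path.
#' @return data.frame with one row per sample; attribute `concordance` holds
#'   the concordant fraction over samples with known truth.
#' @export
run_report <- function(dirs, path = NULL) {
  if (length(dirs) == 1 && dir.exists(dirs) &&
      !file.exists(file.path(dirs, "diplotype.json"))) {
    dirs <- list.dirs(dirs, recursive = FALSE)
  }
  dirs <- dirs[file.exists(file.path(dirs, "diplotype.json"))]
  if (length(dirs) == 0) stop("no genotype results found", call. = FALSE)
  rows <- lapply(dirs, function(d) {
    dj <- jsonlite::read_json(file.path(d, "diplotype.json"))
    truth <- NA_character_
    cfg <- file.path(d, "sim_config.json")
    if (file.exists(cfg)) {
      truth <- jsonlite::read_json(cfg)$diplotype
      if (is.null(truth)) truth <- NA_character_
    }
    detected <- if (is.null(dj$diplotype) || isTRUE(dj$no_call)) NA_character_
                else dj$diplotype
    kinds <- if (is.null(dj$alleles)) "" else
      paste(vapply(dj$alleles, function(a) a$kind, character(1)),
            collapse = ",")
    concordant <- if (is.na(truth)) NA else
      !is.na(detected) &&
        normalize_diplotype(detected) == normalize_diplotype(truth)
    data.frame(sample = basename(d), known_diplotype = truth,
               detected_diplotype = ifelse(is.na(detected),
                 paste0("NO_CALL(", dj$reason, ")"), detected),
               structural_kinds = kinds, concordant = concordant,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  scored <- !is.na(tab$concordant)
  attr(tab, "concordance") <- if (any(scored))
    mean(tab$concordant[scored]) else NA_real_
  if (!is.null(path)) {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tab
}

# Cached default model (seed 7) shared across pipeline calls in a session.
default_model_env <- new.env(parent = emptyenv())

#' Default locus model (seed 7), cached per session
#'
#' @return a `cyp_locus_model`.
#' @export
default_model <- function() {
  if (is.null(default_model_env$model)) {
    default_model_env$model <- build_locus_model(7L)
  }
  default_model_env$model
}
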