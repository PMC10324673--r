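# Segment-aware alignment of full-span reads to reference tracks.
#
# The engine is a projection aligner built for the segmental structure of the
# locus: every segment instance in the model carries instance-unique 17-mers
# (from the paralog/copy divergence model plus planted markers), so a single
# Aho-Corasick scan of a read yields positioned, origin-labelled segment
# blocks.  Blocks are then assigned colinearly to track segments by role,
# preferring the 5'-most compatible slot; uncovered track intervals become
# gap records (the Fig-2-style spacer gap falls out of skipping a spacer slot
# the read does not carry).

KMER_K <- 17L
MIN_BLOCK_HITS <- 3L
GAP_FLOOR <- 200L
ANCHOR_LEN <- 500L
ANCHOR_MIN_MATCH <- 0.7
SPACER_GAP_RANGE <- c(1200L, 2000L)

# Length-class boundaries (bp), midway between fixture fragment lengths.
LENGTH_CLASSES <- list(DELETION = c(20000, 30000), NO_SV = c(35000, 43000),
                       TANDEM = c(45000, Inf))

# ---- feature index -----------------------------------------------------------

# Build (and cache on the model) the universe-unique k-mer index: a PDict over
# every 17-mer that occurs exactly once across all segment instances, plus
# lookup vectors mapping each pattern to its (instance, offset).
feature_index <- function(model) {
  if (!is.null(model$cache$index)) return(model$cache$index)
  inst <- model$instances
  kms <- lapply(inst, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - KMER_K + 1L), KMER_K:n)
  })
  all_k <- unlist(kms, use.names = FALSE)
  inst_id <- rep(names(inst), lengths(kms))
  offset <- unlist(lapply(kms, seq_along), use.names = FALSE) - 1L
  dup <- duplicated(all_k) | duplicated(all_k, fromLast = TRUE)
  keep <- !dup
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(all_k[keep]))
  idx <- list(pdict = pd, instance = inst_id[keep], offset = offset[keep],
              lens = vapply(inst, nchar, integer(1)))
  model$cache$index <- idx
  idx
}

# Scan one read for unique-k-mer hits; auto-orients (reverse-complements)
# when the forward scan is sparse.
scan_read <- function(model, sequence) {
  idx <- feature_index(model)
  scan1 <- function(seq) {
    m <- Biostrings::matchPDict(idx$pdict, Biostrings::DNAString(seq))
    st <- Biostrings::startIndex(m)
    ln <- lengths(st)
    hit <- which(ln > 0)
    if (length(hit) == 0) {
      return(list(read_pos = integer(0), instance = character(0),
                  offset = integer(0), n = 0L))
    }
    pos <- unlist(st[hit], use.names = FALSE) - 1L
    list(read_pos = pos,
         instance = rep.int(idx$instance[hit], ln[hit]),
         offset = rep.int(idx$offset[hit], ln[hit]),
         n = length(pos))
  }
  fwd <- scan1(sequence)
  if (fwd$n >= max(50L, nchar(sequence) / 500)) {
    return(list(hits = fwd, orientation = "+", sequence = sequence))
  }
  rc <- revcomp_chr(sequence)
  bwd <- scan1(rc)
  if (bwd$n > fwd$n) {
    list(hits = bwd, orientation = "-", sequence = rc)
  } else {
    list(hits = fwd, orientation = "+", sequence = sequence)
  }
}

#' Detect segment blocks of a read
#'
#' Scans the read for instance-unique 17-mers, orients it, and reports the
#' ordered segment blocks it carries, each with its estimated read interval
#' and supporting hit count.  This is the per-read evidence that all later
#' structural reasoning uses.
#'
#' @param model a `cyp_locus_model`.
#' @param sequence read sequence (character).
#' @return object of class `cyp_read_features`.
#' @export
read_features <- function(model, sequence) {
  sc <- scan_read(model, sequence)
  idx <- feature_index(model)
  hits <- sc$hits
  blocks <- data.frame(instance = character(0), role = character(0),
                       origin = character(0), start = integer(0),
                       length = integer(0), nhits = integer(0))
  if (hits$n > 0) {
    f <- factor(hits$instance)
    nh <- tabulate(f, nbins = nlevels(f))
    starts <- vapply(split(hits$read_pos - hits$offset, f), median, numeric(1))
    keep <- nh >= MIN_BLOCK_HITS
    if (any(keep)) {
      inst <- levels(f)[keep]
      blocks <- data.frame(instance = inst,
                           role = instance_role(inst),
                           origin = instance_origin(inst),
                           start = as.integer(round(starts[keep])),
                           length = unname(idx$lens[inst]),
                           nhits = nh[keep], stringsAsFactors = FALSE)
      blocks <- blocks[order(blocks$start), , drop = FALSE]
      rownames(blocks) <- NULL
    }
  }
  structure(list(blocks = blocks, orientation = sc$orientation,
                 sequence = sc$sequence, read_length = nchar(sequence),
                 n_hits = hits$n, score = hits$n),
            class = "cyp_read_features")
}

#' @export
print.cyp_read_features <- function(x, ...) {
  cat("Read features: ", nrow(x$blocks), " segment blocks, ", x$n_hits,
      " unique k-mer hits, orientation ", x$orientation, "\n", sep = "")
  invisible(x)
}

# ---- anchors -----------------------------------------------------------------

#' Detect cut-site flank anchors in a read
#'
#' Seed-and-verify: candidate positions come from the flank segments'
#' instance-unique k-mers; each candidate is verified by approximate matching
#' of the 500-bp anchor window (the fragment end adjoining each cut site)
#' against the read, requiring a match fraction of at least 0.7.
#'
#' @param model a `cyp_locus_model`.
#' @param read read sequence or a `cyp_read_features`.
#' @return data.frame of anchor hits: `anchor_id`, `read_offset`,
#'   `track_offset`, `match_fraction`.
#' @export
detect_anchors <- function(model, read) {
  feats <- if (is(read, "cyp_read_features")) read else read_features(model, read)
  seq <- feats$sequence
  n <- nchar(seq)
  frag_len <- nchar(model$reference)
  out <- list()
  for (a in c("FLANK_5P", "FLANK_3P")) {
    inst_name <- if (a == "FLANK_5P") "F5" else "F3"
    inst_seq <- model$instances[[inst_name]]
    if (a == "FLANK_5P") {
      anchor_ref <- substr(inst_seq, 1L, ANCHOR_LEN)
      track_off <- 0L
      cand <- feats$blocks$start[feats$blocks$instance == inst_name]
    } else {
      il <- nchar(inst_seq)
      anchor_ref <- substr(inst_seq, il - ANCHOR_LEN + 1L, il)
      track_off <- frag_len - ANCHOR_LEN
      b <- feats$blocks[feats$blocks$instance == inst_name, ]
      cand <- if (nrow(b)) b$start + b$length - ANCHOR_LEN else integer(0)
    }
    if (length(cand) == 0) next
    # block starts are k-mer-median estimates, accurate to a few bp even at
    # nanopore error rates, so a +/-100 bp verification window suffices
    w0 <- max(0L, cand[1] - 100L)
    w1 <- min(n, cand[1] + ANCHOR_LEN + 100L)
    if (w1 - w0 < ANCHOR_LEN * 0.6) next
    win <- substr(seq, w0 + 1L, w1)
    d <- adist(anchor_ref, win, partial = TRUE)[1, 1]
    mf <- 1 - d / ANCHOR_LEN
    if (mf >= ANCHOR_MIN_MATCH) {
      out[[length(out) + 1L]] <- data.frame(
        anchor_id = a, read_offset = cand[1], track_offset = track_off,
        match_fraction = mf, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(anchor_id = character(0), read_offset = integer(0),
                      track_offset = integer(0), match_fraction = numeric(0)))
  }
  do.call(rbind, out)
}

# ---- track alignment ---------------------------------------------------------

coarse_role <- function(role) {
  ifelse(role == "GENE", "GENE",
  ifelse(role == "REP", "REP",
  ifelse(role == "SPACER", "SPACER",
  ifelse(role == "INTERGENIC", "IG", role))))
}

# Merge adjacent same-coarse-role rows of a layout/block table into
# super-slots; keeps the member instance list of each super-slot.
merge_by_role <- function(df) {
  if (nrow(df) == 0) return(list())
  cr <- coarse_role(df$role)
  grp <- cumsum(c(TRUE, cr[-1] != cr[-length(cr)]))
  lapply(split(seq_len(nrow(df)), grp), function(ix) {
    list(role = cr[ix[1]],
         start = df$start[ix[1]],
         end = df$start[ix[length(ix)]] + df$length[ix[length(ix)]],
         instances = df$instance[ix],
         members = df[ix, , drop = FALSE])
  })
}

#' Align a read to a reference track
#'
#' Segment-aware projection alignment: the read's segment blocks are merged
#' into role blocks and assigned colinearly to the track's role slots,
#' preferring the 5'-most compatible slot.  Track intervals supported by
#' shared instances (or by whole-slot gene homology) count as covered;
#' uncovered intervals of at least 200 bp are reported as gap records.
#'
#' @param model a `cyp_locus_model`.
#' @param read read sequence or `cyp_read_features`.
#' @param track a `cyp_track` (or track id).
#' @return object of class `cyp_track_alignment`: assignment table, gap
#'   records, per-segment match fractions, alignment score, flags.
#' @export
align_read_to_track <- function(model, read, track) {
  if (is.character(track)) track <- build_custom_track(model, track)
  feats <- if (is(read, "cyp_read_features")) read else read_features(model, read)
  rblocks <- merge_by_role(feats$blocks)
  tslots <- merge_by_role(track$segment_map)

  covered <- matrix(numeric(0), ncol = 2) # 0-based half-open track intervals
  assign_rows <- list()
  cursor <- 1L
  for (rb in rblocks) {
    slot_i <- NULL
    for (j in seq(cursor, length.out = max(0L, length(tslots) - cursor + 1L))) {
      if (tslots[[j]]$role == rb$role) { slot_i <- j; break }
    }
    if (is.null(slot_i)) next # no compatible slot left: read-side insertion
    sl <- tslots[[slot_i]]
    cursor <- slot_i + 1L
    shared <- intersect(rb$instances, sl$instances)
    cov <- sl$members[sl$members$instance %in% shared, , drop = FALSE]
    if (nrow(cov)) {
      covered <- rbind(covered, cbind(cov$start, cov$start + cov$length))
    }
    if (length(shared) == 0 || rb$role == "GENE") {
      # homologous segment placed onto a same-role slot (e.g. a no-SV read's
      # CYP2D6 over the tandem-position copy, a hybrid copy's mixed-origin
      # exons over an all-D7 track copy, or a deletion read's fused REP over
      # the track's REP7): cover the slot up to the block's extent
      covered <- rbind(covered,
                       c(sl$start, min(sl$end,
                                       sl$start + (rb$end - rb$start))))
    }
    assign_rows[[length(assign_rows) + 1L]] <- data.frame(
      role = rb$role, read_start = rb$start, read_end = rb$end,
      track_start = sl$start, track_end = sl$end,
      shared_instances = paste(shared, collapse = ","),
      stringsAsFactors = FALSE)
  }

  gaps <- uncovered_gaps(covered, track)
  cov_len <- if (nrow(covered)) {
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = covered[, 1] + 1L, end = covered[, 2]))))
  } else 0L
  seg_match <- segment_match_fractions(track, covered)
  structure(list(
    track_id = track$track_id,
    assignment = if (length(assign_rows)) do.call(rbind, assign_rows) else NULL,
    gaps = gaps,
    segment_match = seg_match,
    score = feats$score,
    covered_fraction = cov_len / track$length,
    unalignable = (cov_len / track$length) < 0.30
  ), class = "cyp_track_alignment")
}

uncovered_gaps <- function(covered, track) {
  empty <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                      within_spacer_window = logical(0))
  if (nrow(covered) == 0) return(empty)
  cov <- IRanges::reduce(IRanges::IRanges(start = covered[, 1] + 1L,
                                          end = covered[, 2]))
  gaps <- IRanges::gaps(cov, start = min(IRanges::start(cov)),
                        end = max(IRanges::end(cov)))
  if (length(gaps) == 0) return(empty)
  df <- data.frame(start = IRanges::start(gaps) - 1L, end = IRanges::end(gaps),
                   stringsAsFactors = FALSE)
  df$length <- df$end - df$start
  df <- df[df$length >= GAP_FLOOR, , drop = FALSE]
  df$within_spacer_window <- spacer_overlap_ok(df, track$spacer_window)
  rownames(df) <- NULL
  df
}

spacer_overlap_ok <- function(gaps, window) {
  if (is.null(window) || nrow(gaps) == 0) return(rep(FALSE, nrow(gaps)))
  ov <- pmin(gaps$end, window[2]) - pmax(gaps$start, window[1])
  ov >= 0.5 * (window[2] - window[1])
}

segment_match_fractions <- function(track, covered) {
  map <- track$segment_map
  if (nrow(covered) == 0) {
    return(data.frame(instance = map$instance, match_fraction = 0))
  }
  cov <- IRanges::reduce(IRanges::IRanges(start = covered[, 1] + 1L,
                                          end = covered[, 2]))
  mf <- vapply(seq_len(nrow(map)), function(i) {
    seg <- IRanges::IRanges(start = map$start[i] + 1L,
                            end = map$start[i] + map$length[i])
    sum(IRanges::width(IRanges::intersect(cov, seg))) / map$length[i]
  }, numeric(1))
  data.frame(instance = map$instance, match_fraction = mf)
}

#' Decide spacer presence from gap records
#'
#' A read lacks the spacer (status ABSENT) iff a gap of spacer-like length
#' (1,200-2,000 bp) overlaps at least half of the track's expected spacer
#' window; unrelated gaps are ignored.
#'
#' @param gaps gap-record data.frame from [align_read_to_track()].
#' @param track the track aligned against; must carry a `spacer_window`.
#' @return list with `spacer_status` ("PRESENT"/"ABSENT") and `gap_length`.
#' @export
detect_spacer_gap <- function(gaps, track) {
  if (is.null(track$spacer_window)) {
    stop("detect_spacer_gap requires a track with a spacer_window (track A)",
         call. = FALSE)
  }
  cand <- gaps[gaps$length >= SPACER_GAP_RANGE[1] &
               gaps$length <= SPACER_GAP_RANGE[2] &
               spacer_overlap_ok(gaps, track$spacer_window), , drop = FALSE]
  if (nrow(cand)) {
    list(spacer_status = "ABSENT", gap_length = cand$length[1])
  } else {
    list(spacer_status = "PRESENT", gap_length = NA_integer_)
  }
}

# ---- per-read structural summary --------------------------------------------

length_class_of <- function(len) {
  if (is.na(len)) return(NA_character_)
  for (cls in names(LENGTH_CLASSES)) {
    b <- LENGTH_CLASSES[[cls]]
    if (len >= b[1] && len <= b[2]) return(cls)
  }
  "UNCLASSIFIED"
}

# Exon-origin call of the duplicated-position gene copy from per-exon
# instance hits: D6 vs D7 tandem exon variants.
tandem_exon_origins <- function(blocks) {
  vapply(seq_len(N_EXONS), function(e) {
    h6 <- blocks$nhits[blocks$instance == sprintf("TD_EX%d_D6", e)]
    h7 <- blocks$nhits[blocks$instance == sprintf("TD_EX%d_D7", e)]
    h6 <- if (length(h6)) h6 else 0L
    h7 <- if (length(h7)) h7 else 0L
    if (h6 + h7 < MIN_BLOCK_HITS) NA_character_
    else if (h6 > h7) "D6" else if (h7 > h6) "D7" else NA_character_
  }, character(1))
}

#' Summarize one read's structural evidence
#'
#' Combines anchors, fragment-length estimate, tandem-unit features (5'-region
#' origin, spacer, per-exon origins) into the per-read feature vector that
#' track selection and structure classification vote over.
#'
#' @param model a `cyp_locus_model`.
#' @param sequence read sequence.
#' @param truth_length optional known pre-error fragment length.
#' @return list of class `cyp_read_summary`.
#' @export
summarize_read <- function(model, sequence, truth_length = NULL) {
  feats <- read_features(model, sequence)
  anchors <- detect_anchors(model, feats)
  full_span <- all(c("FLANK_5P", "FLANK_3P") %in% anchors$anchor_id)
  frag_len <- if (!is.null(truth_length) && !is.na(truth_length)) {
    as.integer(truth_length)
  } else if (full_span) {
    a5 <- anchors$read_offset[anchors$anchor_id == "FLANK_5P"]
    a3 <- anchors$read_offset[anchors$anchor_id == "FLANK_3P"]
    as.integer(a3 + ANCHOR_LEN - a5)
  } else NA_integer_

  b <- feats$blocks
  nh <- function(nm) { v <- b$nhits[b$instance == nm]; if (length(v)) v else 0L }
  up6 <- nh("TD_UP_D6"); up7 <- nh("TD_UP_D7")
  five_prime <- if (up6 + up7 < MIN_BLOCK_HITS) NA_character_
                else if (up6 > up7) "D6_LIKE" else "D7_LIKE"
  has_unit <- nh("TD_REP") >= MIN_BLOCK_HITS || up6 + up7 >= MIN_BLOCK_HITS
  spacer <- if (!has_unit) NA else nh("TD_SPACER") >= MIN_BLOCK_HITS
  origins <- tandem_exon_origins(b)

  kind <- NA_character_
  lc <- length_class_of(frag_len)
  if (!is.na(lc)) {
    if (lc == "DELETION") kind <- "DELETION"
    else if (lc == "NO_SV") kind <- "NO_SV"
    else if (lc == "TANDEM") {
      called <- origins[!is.na(origins)]
      kind <- if (any(called == "D7")) "HYBRID_TANDEM"
              else if (sum(called == "D6") >= 5) "DUPLICATION"
              else NA_character_
    } else kind <- "UNCLASSIFIED"
  }
  structure(list(features = feats, anchors = anchors, full_span = full_span,
                 fragment_length = frag_len, length_class = lc, kind = kind,
                 five_prime_origin = five_prime, spacer_in_tandem = spacer,
                 exon_origins = origins, score = feats$score),
            class = "cyp_read_summary")
}

#' Select the reference track for a read
#'
#' Pure function of the read's structural features: no-SV- or deletion-length
#' reads go to REF; tandem-length reads with a D7-like duplicated-position 5'
#' region and a spacer go to track A; D6-like 5' region without spacer go to
#' track B; anything else is UNCLASSIFIED.
#'
#' @param summary a `cyp_read_summary` (or compatible list with
#'   `length_class`, `five_prime_origin`, `spacer_in_tandem`).
#' @return one of "REF", "A", "B", "UNCLASSIFIED".
#' @export
select_reference_track <- function(summary) {
  lc <- summary$length_class
  if (is.na(lc) || lc == "UNCLASSIFIED") return("UNCLASSIFIED")
  if (lc %in% c("NO_SV", "DELETION")) return("REF")
  fp <- summary$five_prime_origin
  sp <- summary$spacer_in_tandem
  if (!is.na(fp) && !is.na(sp)) {
    if (fp == "D7_LIKE" && isTRUE(sp)) return("A")
    if (fp == "D6_LIKE" && !isTRUE(sp)) return("B")
  }
  "UNCLASSIFIED"
}

#' Measure the cut-to-cut fragment length of a read group
#'
#' Median pre-error (truth) fragment length when truth is available, else the
#' median anchored-alignment span of the full-span reads.
#'
#' @param summaries list of `cyp_read_summary`.
#' @return integer bp.
#' @export
measure_fragment_length <- function(summaries) {
  if (length(summaries) == 0) stop("empty read group", call. = FALSE)
  lens <- vapply(summaries, function(s) s$fragment_length, integer(1))
  lens <- lens[!is.na(lens)]
  if (length(lens) == 0) stop("no measurable reads in group", call. = FALSE)
  as.integer(round(median(lens)))
}

#' Classify the structural configuration of a per-allele read group
#'
#' Majority vote across the group's per-read structural calls; ties and
#' undersized groups yield NO_CALL (never a silent default to NO_SV).
#'
#' @param summaries list of `cyp_read_summary` for one allele's reads.
#' @param model a `cyp_locus_model` (for breakpoint coordinates).
#' @param min_reads minimum reads required for a call (default 3).
#' @return object of class `cyp_structure_call`.
#' @export
classify_structure <- function(summaries, model, min_reads = 3L) {
  no_call <- function(reason) {
    structure(list(kind = "NO_CALL", reason = reason,
                   selected_track = NA_character_,
                   five_prime_origin = NA_character_,
                   spacer_present_in_tandem_copy = NA,
                   breakpoints = NULL, fragment_length_bp = NA_integer_,
                   n_reads = length(summaries)),
              class = "cyp_structure_call")
  }
  if (length(summaries) < min_reads) {
    return(no_call(sprintf("only %d reads in group (minimum %d)",
                           length(summaries), min_reads)))
  }
  votes <- vapply(summaries, function(s)
    if (is.na(s$kind)) "UNCLASSIFIED" else s$kind, character(1))
  tab <- sort(table(votes), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) {
    return(no_call("tied majority vote across reads"))
  }
  kind <- names(tab)[1]
  if (kind == "UNCLASSIFIED") {
    return(no_call("reads match no supported structural pattern"))
  }
  frag <- measure_fragment_length(summaries)

  mode_of <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA)
    names(sort(table(x), decreasing = TRUE))[1]
  }
  fp <- mode_of(vapply(summaries, `[[`, character(1), "five_prime_origin"))
  sp <- mode_of(vapply(summaries, function(s)
    if (is.na(s$spacer_in_tandem)) NA_character_
    else as.character(s$spacer_in_tandem), character(1)))
  sp <- if (is.na(sp)) NA else as.logical(sp)

  track <- select_reference_track(list(
    length_class = if (kind %in% c("DUPLICATION", "HYBRID_TANDEM")) "TANDEM" else kind,
    five_prime_origin = fp, spacer_in_tandem = sp))

  origins <- NULL
  if (kind %in% c("DUPLICATION", "HYBRID_TANDEM")) {
    om <- vapply(seq_len(N_EXONS), function(e) {
      mode_of(vapply(summaries, function(s) s$exon_origins[e], character(1)))
    }, character(1))
    origins <- om
  }
  breakpoints <- structure_breakpoints(model, kind)
  structure(list(kind = kind, reason = NA_character_,
                 selected_track = track, five_prime_origin = fp,
                 spacer_present_in_tandem_copy = if (kind %in%
                   c("DUPLICATION", "HYBRID_TANDEM")) isTRUE(sp) else NA,
                 exon_origins = origins,
                 breakpoints = breakpoints,
                 fragment_length_bp = frag,
                 n_reads = length(summaries),
                 votes = as.list(tab)),
            class = "cyp_structure_call")
}

# Reference-track coordinates of the event boundaries for each kind.
structure_breakpoints <- function(model, kind) {
  map <- model$segment_map
  at <- function(nm) map$start[map$instance == nm]
  if (kind == "DELETION") {
    c(start = at("REP7"), end = at("REP6"))
  } else if (kind %in% c("DUPLICATION", "HYBRID_TANDEM")) {
    c(start = at("UP_D6"), end = at("UP_D6")) # insertion point of the unit
  } else NULL
}

#' @export
print.cyp_structure_call <- function(x, ...) {
  cat("StructureCall: ", x$kind, sep = "")
  if (!is.na(x$fragment_length_bp)) {
    cat(" (", x$fragment_length_bp, " bp, track ", x$selected_track, ")",
        sep = "")
  }
  if (x$kind == "NO_CALL") cat(" - ", x$reason, sep = "")
  cat("\n")
  invisible(x)
}
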