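# Synthetic segmental model of the CYP2D6-CYP2D7-CYP2D8 excision fragment.
#
# The locus is modelled as an ordered list of segments laid out 5'->3' in gene
# orientation: 5' flank, CYP2D8, intergenic, CYP2D7 with its downstream spacer
# and REP7, intergenic, CYP2D6 with its downstream REP6, 3' flank.  Paralogy is
# emulated by deriving CYP2D7/CYP2D8 (and their upstream regions) from the
# CYP2D6 sequence at a fixed 2% divergence; tandem-copy segments carry a
# further 1.5% copy-specific divergence so that every segment instance is
# identifiable from instance-unique k-mers at nanopore error rates.

# ---- fixture constants -------------------------------------------------------

# Genomic anchors (1-based inclusive, chr22 / NC_000022.11).
GENOMIC_CUT_5P <- 42122008
GENOMIC_CUT_3P <- 42161558
GENOMIC_WIN_5P <- 42123069
GENOMIC_WIN_3P <- 42161322

FRAGMENT_LEN_NO_SV <- 39551L
ANALYSIS_WINDOW_LEN <- 38254L
FRAGMENT_LEN_DELETION <- 25000L
FRAGMENT_LEN_TANDEM <- 52000L
SPACER_LEN <- 1560L
DELETION_BLOCK_LEN <- 14551L
TANDEM_UNIT_LEN <- 12449L

GENE_LEN <- 4500L
EXON_LEN <- 500L
N_EXONS <- 9L

# 0-based half-open analysis window within the cut-to-cut fragment.
WINDOW_START0 <- as.integer(GENOMIC_WIN_5P - GENOMIC_CUT_5P) # 1061
WINDOW_END0 <- as.integer(GENOMIC_WIN_3P - GENOMIC_CUT_5P + 1) # 39315

PARALOG_DIVERGENCE <- 0.02
COPY_DIVERGENCE <- 0.015

# Fixture variant positions (1-based, analysis-window coordinates).  All fall
# inside the regular-position CYP2D6 gene body (window 29551..34050).  These
# positions are synthetic stand-ins for PharmVar-defined sites.
FIXTURE_SITES <- c(
  c2a = 29650L, c2b = 31200L, s33 = 33500L,
  c4a = 29900L, c10a = 29750L,
  c29a = 30500L, c29b = 32800L,
  s37 = 31650L, s45 = 32100L, s58 = 30220L, s59 = 33900L
)

#' Default segment table of the reference (no-SV) locus layout
#'
#' Thirteen ordered segments whose lengths sum to the 39,551 bp cut-to-cut
#' fragment.  Upstream ("5' region") segments are INTERGENIC segments with a
#' gene origin so that the D6-like vs D7-like nature of a tandem copy's 5'
#' region is a sequence-level property.
#'
#' @return data.frame with columns `name`, `role`, `origin`, `length`.
#' @export
locus_segments <- function() {
  data.frame(
    name = c("F5", "UP_D8", "G_D8", "IG87", "UP_D7", "G_D7", "SPACER",
             "REP7", "IG76", "UP_D6", "G_D6", "REP6", "F3"),
    role = c("FLANK_5P", "INTERGENIC", "GENE_D8", "INTERGENIC", "INTERGENIC",
             "GENE_D7", "SPACER", "REP7", "INTERGENIC", "INTERGENIC",
             "GENE_D6", "REP6", "FLANK_3P"),
    origin = c("NEUTRAL", "D8", "D8", "NEUTRAL", "D7", "D7", "D7", "D7",
               "NEUTRAL", "D6", "D6", "D6", "NEUTRAL"),
    length = c(2000L, 1500L, 4500L, 5000L, 1500L, 4500L, SPACER_LEN, 600L,
               7951L, 1500L, GENE_LEN, 600L, 3840L),
    stringsAsFactors = FALSE
  )
}

validate_segments <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("name", "role", "origin", "length") %in% names(segments)))
  if (any(segments$length <= 0)) {
    stop("configuration error: all segment lengths must be > 0", call. = FALSE)
  }
  if (anyDuplicated(segments$name)) {
    stop("configuration error: segment names must be unique", call. = FALSE)
  }
  if (sum(segments$role == "SPACER") != 1L) {
    stop("configuration error: reference layout must contain exactly one SPACER segment",
         call. = FALSE)
  }
  segments
}

# Plant one fixed, seeded marker 31-mer per 500 bp block of a gene-derived
# instance.  Markers make segment identification unambiguous at nanopore
# error rates on top of the divergence-derived unique k-mers.
plant_markers <- function(seq, tag, seed, offset = 235L) {
  n <- nchar(seq)
  starts <- seq.int(offset, n - 31L, by = EXON_LEN)
  for (i in seq_along(starts)) {
    mk <- random_dna(31L, derive_seed(seed, paste0("marker:", tag, ":", i)))
    substr(seq, starts[i], starts[i] + 30L) <- mk
  }
  seq
}

# ---- model construction ------------------------------------------------------

build_instances <- function(seed, segments) {
  s <- function(label) derive_seed(seed, label)
  len <- setNames(segments$length, segments$name)
  inst <- list()

  # neutral segments
  for (nm in c("F5", "IG87", "IG76", "F3")) {
    inst[[nm]] <- random_dna(len[[nm]], s(nm))
  }
  # PAM-compatible bases at the two cut boundaries (guides straddle the cuts):
  # fragment 0-based positions 4-5 carry the plus-strand GG, and the two
  # positions 6-5 bp from the fragment end carry the minus-strand CC.
  substr(inst$F5, 5L, 6L) <- "GG"
  f3n <- nchar(inst$F3)
  substr(inst$F3, f3n - 5L, f3n - 4L) <- "CC"
  # gene family: D7/D8 derived from D6 at fixed paralog divergence
  inst$G_D6 <- plant_markers(random_dna(len[["G_D6"]], s("G_D6")), "G_D6", seed)
  inst$G_D7 <- plant_markers(mutate_dna(inst$G_D6, PARALOG_DIVERGENCE, s("G_D7")),
                             "G_D7", seed)
  inst$G_D8 <- plant_markers(mutate_dna(inst$G_D6, PARALOG_DIVERGENCE, s("G_D8")),
                             "G_D8", seed)
  inst$UP_D6 <- random_dna(len[["UP_D6"]], s("UP_D6"))
  inst$UP_D7 <- mutate_dna(inst$UP_D6, PARALOG_DIVERGENCE, s("UP_D7"))
  inst$UP_D8 <- mutate_dna(inst$UP_D6, PARALOG_DIVERGENCE, s("UP_D8"))
  inst$REP6 <- random_dna(len[["REP6"]], s("REP6"))
  inst$REP7 <- mutate_dna(inst$REP6, PARALOG_DIVERGENCE, s("REP7"))
  inst$SPACER <- random_dna(len[["SPACER"]], s("SPACER"))

  # tandem-unit instances (copy-specific divergence from their type sources)
  inst$TD_PAD_A <- random_dna(TANDEM_UNIT_LEN - len[["UP_D6"]] - GENE_LEN -
                                SPACER_LEN - len[["REP6"]], s("TD_PAD_A")) # 4289
  inst$TD_PAD_B <- random_dna(TANDEM_UNIT_LEN - len[["UP_D6"]] - GENE_LEN -
                                len[["REP6"]], s("TD_PAD_B")) # 5849
  inst$TD_UP_D6 <- mutate_dna(inst$UP_D6, COPY_DIVERGENCE, s("TD_UP_D6"))
  inst$TD_UP_D7 <- mutate_dna(inst$UP_D7, COPY_DIVERGENCE, s("TD_UP_D7"))
  inst$TD_SPACER <- mutate_dna(inst$SPACER, COPY_DIVERGENCE, s("TD_SPACER"))
  inst$TD_REP <- mutate_dna(inst$REP6, COPY_DIVERGENCE, s("TD_REP"))

  # per-exon tandem gene variants; defined variant offsets are restored to the
  # source base so that allele-defining sites are origin-neutral in a copy
  site_off <- (FIXTURE_SITES + 1060L) - 30611L # 0-based offsets in gene body
  for (e in seq_len(N_EXONS)) {
    for (org in c("D6", "D7")) {
      src <- substr(inst[[paste0("G_", org)]], (e - 1L) * EXON_LEN + 1L,
                    e * EXON_LEN)
      nm <- sprintf("TD_EX%d_%s", e, org)
      v <- plant_markers(mutate_dna(src, COPY_DIVERGENCE, s(nm)), nm, seed,
                         offset = 100L)
      here <- site_off[site_off %/% EXON_LEN == (e - 1L)] %% EXON_LEN + 1L
      for (p in here) substr(v, p, p) <- substr(src, p, p)
      inst[[nm]] <- v
    }
  }
  inst
}

layout_table <- function(inst, names) {
  lens <- vapply(inst[names], nchar, integer(1))
  data.frame(
    instance = names,
    role = instance_role(names),
    origin = instance_origin(names),
    start = cumsum(c(0L, lens[-length(lens)])),
    length = unname(lens),
    stringsAsFactors = FALSE
  )
}

instance_role <- function(nm) {
  out <- character(length(nm))
  out[grepl("^G_|^TD_EX", nm)] <- "GENE"
  out[grepl("^UP_|^TD_UP|^IG|^TD_PAD", nm)] <- "INTERGENIC"
  out[grepl("SPACER", nm)] <- "SPACER"
  out[grepl("^REP|^TD_REP", nm)] <- "REP"
  out[nm == "F5"] <- "FLANK_5P"
  out[nm == "F3"] <- "FLANK_3P"
  out
}

instance_origin <- function(nm) {
  out <- rep("NEUTRAL", length(nm))
  out[grepl("D6", nm)] <- "D6"
  out[grepl("D7", nm)] <- "D7"
  out[grepl("D8", nm)] <- "D8"
  out[nm %in% c("SPACER", "TD_SPACER", "REP7")] <- "D7"
  out[nm %in% c("REP6", "TD_REP")] <- "D6"
  out
}

ref_layout_names <- function() {
  c("F5", "UP_D8", "G_D8", "IG87", "UP_D7", "G_D7", "SPACER", "REP7",
    "IG76", "UP_D6", "G_D6", "REP6", "F3")
}

# Instance list of a duplicated-position tandem unit.  Haplotype units are
# always 12,449 bp: spacer-bearing units use the short neutral pad, no-spacer
# units the long one.  The custom tracks both use the short pad, so track B is
# exactly one spacer length shorter than track A; a no-spacer read then shows
# a harmless upstream insertion against track B rather than any track gap.
tandem_unit_names <- function(five_prime_origin, spacer, origin_map = NULL,
                              pad = if (spacer) "TD_PAD_A" else "TD_PAD_B") {
  if (is.null(origin_map)) {
    origin_map <- rep(if (five_prime_origin == "D7") "D7" else "D6", N_EXONS)
  }
  c(pad, paste0("TD_UP_", five_prime_origin),
    sprintf("TD_EX%d_%s", seq_len(N_EXONS), origin_map),
    if (spacer) "TD_SPACER", "TD_REP")
}

concat_instances <- function(inst, names) {
  paste(unlist(inst[names], use.names = FALSE), collapse = "")
}

#' Build the synthetic CYP2D6-CYP2D7-CYP2D8 locus model
#'
#' Constructs the full fixture: reference (no-SV) cut-to-cut sequence, the two
#' custom reference tracks for tandem arrangements, segment maps, analysis
#' window, and the padded genomic context with planted guide protospacers for
#' in-silico Cas9 digestion.
#'
#' @param seed integer seed controlling all sequence content (default 7).
#' @param segments segment table as returned by [locus_segments()].
#' @return an object of class `cyp_locus_model`.
#' @export
build_locus_model <- function(seed = 7L, segments = locus_segments()) {
  segments <- validate_segments(segments)
  inst <- build_instances(seed, segments)

  ref_names <- ref_layout_names()
  ref_map <- layout_table(inst, ref_names)
  ref_seq <- concat_instances(inst, ref_names)
  stopifnot(nchar(ref_seq) == sum(segments$length))

  ins_at <- function(unit) append(ref_names, unit, after = match("IG76", ref_names))
  a_names <- ins_at(tandem_unit_names("D7", spacer = TRUE))
  b_names <- ins_at(tandem_unit_names("D6", spacer = FALSE, pad = "TD_PAD_A"))
  a_map <- layout_table(inst, a_names)
  b_map <- layout_table(inst, b_names)

  sp_row <- a_map[a_map$instance == "TD_SPACER", ]
  tracks <- list(
    REF = new_track("REF", ref_seq, ref_map, NULL),
    A = new_track("A", concat_instances(inst, a_names), a_map,
                  c(sp_row$start, sp_row$start + sp_row$length)),
    B = new_track("B", concat_instances(inst, b_names), b_map, NULL)
  )

  model <- structure(list(
    seed = as.integer(seed),
    segments = segments,
    instances = inst,
    reference = ref_seq,
    segment_map = ref_map,
    tracks = tracks,
    cut_site_5p = 0L,
    cut_site_3p = nchar(ref_seq),
    analysis_window = c(WINDOW_START0, WINDOW_END0),
    genomic = list(cut = c(GENOMIC_CUT_5P, GENOMIC_CUT_3P),
                   window = c(GENOMIC_WIN_5P, GENOMIC_WIN_3P)),
    cache = new.env(parent = emptyenv())
  ), class = "cyp_locus_model")
  model$genome <- build_genomic_context(model)
  model
}

new_track <- function(id, seq, map, spacer_window) {
  structure(list(track_id = id, sequence = seq, segment_map = map,
                 spacer_window = spacer_window, length = nchar(seq)),
            class = "cyp_track")
}

#' @export
print.cyp_locus_model <- function(x, ...) {
  cat("CYP2D6-2D7-2D8 synthetic locus model (seed ", x$seed, ")\n", sep = "")
  cat("  cut-to-cut fragment: ", nchar(x$reference), " bp\n", sep = "")
  cat("  analysis window: ", x$analysis_window[1], "-", x$analysis_window[2],
      " (0-based half-open, ", diff(x$analysis_window), " bp)\n", sep = "")
  cat("  tracks: ", paste(sprintf("%s=%d bp", names(x$tracks),
      vapply(x$tracks, `[[`, integer(1), "length")), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Build the reference locus sequence
#'
#' Returns the no-SV locus specification together with its concrete cut-to-cut
#' sequence.  Coordinates are 0-based half-open internally; reports use
#' 1-based inclusive coordinates.
#'
#' @inheritParams build_locus_model
#' @return list with elements `spec` (segment map, cut sites, analysis window)
#'   and `sequence` (character).
#' @export
build_reference_locus <- function(seed = 7L, segments = locus_segments()) {
  model <- build_locus_model(seed, segments)
  list(
    spec = list(segments = model$segment_map,
                cut_site_5p = model$cut_site_5p,
                cut_site_3p = model$cut_site_3p,
                analysis_window = model$analysis_window),
    sequence = model$reference
  )
}

#' Retrieve a custom reference track
#'
#' Track A is the hybrid-duplication arrangement: the duplicated-position
#' (5'-most) gene copy has a CYP2D7-like 5' region and a downstream spacer.
#' Track B is the full-duplication arrangement: D6-like 5' region and no
#' spacer in the duplicated-position downstream region.  REF is the no-SV
#' layout.
#'
#' @param model a `cyp_locus_model`.
#' @param track_id one of "REF", "A", "B".
#' @return a `cyp_track` object.
#' @export
build_custom_track <- function(model, track_id) {
  stopifnot(is(model, "cyp_locus_model"))
  if (!track_id %in% names(model$tracks)) {
    stop("invalid track_id: ", track_id, " (must be REF, A or B)", call. = FALSE)
  }
  model$tracks[[track_id]]
}

#' Analysis window of the locus model
#'
#' @param model a `cyp_locus_model`.
#' @return integer vector `c(start, end)`, 0-based half-open, in fragment
#'   coordinates.
#' @export
analysis_window <- function(model) model$analysis_window

# window (1-based) <-> fragment sequence (0-based) coordinates
window_to_seq0 <- function(model, pos1) model$analysis_window[1] + pos1 - 1L
seq0_to_window <- function(model, pos0) pos0 - model$analysis_window[1] + 1L

# ---- genomic context + in-silico digestion ----------------------------------

# Pad the fragment with neutral sequence and plant one protospacer+PAM across
# each cut boundary so that Cas9 digestion of the padded "genome" releases
# exactly the cut-to-cut fragment.
build_genomic_context <- function(model, pad = 2000L) {
  frag <- model$reference
  nn <- nchar(frag)
  pad5 <- random_dna(pad, derive_seed(model$seed, "pad5"))
  pad3 <- random_dna(pad, derive_seed(model$seed, "pad3"))
  genome <- paste0(pad5, frag, pad3)
  # guide 5p: plus strand, blunt cut at 0-based genome position `pad`
  g5 <- substr(genome, pad - 16L, pad + 3L)      # 0-based [pad-17, pad+2]
  # guide 3p: minus strand, cut at 0-based position pad + nn
  p <- pad + nn - 3L                              # 0-based protospacer start
  g3 <- revcomp_chr(substr(genome, p + 1L, p + 20L))
  list(sequence = genome, pad = pad, guide_5p = g5, guide_3p = g3)
}

#' Find Cas9 cut sites for a guide in a sequence
#'
#' Scans both strands for protospacer + PAM occurrences and reports the blunt
#' cut coordinate 3 bp 5' of the PAM.  Overlapping occurrences are all
#' reported.
#'
#' @param genome_seq uppercase ACGT character sequence.
#' @param guide 20-nt protospacer (unambiguous ACGT).
#' @param pam PAM pattern in IUPAC code, default "NGG".
#' @return data.frame with columns `position` (0-based blunt-cut coordinate)
#'   and `strand` ("+" or "-"), sorted by position.
#' @export
find_cut_sites <- function(genome_seq, guide, pam = "NGG") {
  guide <- toupper(guide)
  if (nchar(guide) != 20L) {
    stop("input error: guide must be a 20-nt protospacer", call. = FALSE)
  }
  if (grepl("[^ACGT]", guide)) {
    stop("input error: ambiguous bases in guide", call. = FALSE)
  }
  subj <- Biostrings::DNAString(genome_seq)
  pam_len <- nchar(pam)
  pam_fwd <- iupac_regex(pam)
  pam_rev <- iupac_regex(revcomp_chr(pam))

  hits <- list()
  fwd <- Biostrings::start(Biostrings::matchPattern(guide, subj))
  for (s in fwd) { # 1-based protospacer start
    pam_seq <- substr(genome_seq, s + 20L, s + 19L + pam_len)
    if (nchar(pam_seq) == pam_len && grepl(pam_fwd, pam_seq)) {
      hits[[length(hits) + 1L]] <- data.frame(position = s + 16L, strand = "+")
    }
  }
  rev <- Biostrings::start(Biostrings::matchPattern(revcomp_chr(guide), subj))
  for (s in rev) {
    pam_seq <- substr(genome_seq, s - pam_len, s - 1L)
    if (s > pam_len && grepl(pam_rev, pam_seq)) {
      # protospacer plus-strand 0-based start p = s - 1; blunt cut falls
      # between p+2 and p+3, reported as p + 3 (first base 3' of the cut on
      # the plus strand), mirroring the plus-strand convention.
      hits[[length(hits) + 1L]] <- data.frame(position = s + 2L, strand = "-")
    }
  }
  if (length(hits) == 0) {
    return(data.frame(position = integer(0), strand = character(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$position), , drop = FALSE]
}

iupac_regex <- function(pat) {
  map <- Biostrings::IUPAC_CODE_MAP
  parts <- vapply(strsplit(toupper(pat), "")[[1]], function(ch) {
    if (!ch %in% names(map)) stop("invalid PAM character: ", ch, call. = FALSE)
    b <- map[[ch]]
    if (nchar(b) == 1) b else paste0("[", b, "]")
  }, character(1))
  paste0("^", paste(parts, collapse = ""), "$")
}

#' Digest a genomic context in silico with the model's guide pair
#'
#' @param model a `cyp_locus_model`.
#' @return list with the excised fragment sequence and the two 0-based cut
#'   coordinates in the padded genomic context.
#' @export
digest_locus <- function(model) {
  g <- model$genome
  c5 <- find_cut_sites(g$sequence, g$guide_5p)
  c3 <- find_cut_sites(g$sequence, g$guide_3p)
  cuts <- sort(c(c5$position, c3$position))
  stopifnot(length(cuts) >= 2)
  frag <- substr(g$sequence, cuts[1] + 1L, cuts[length(cuts)])
  list(fragment = frag, cut_positions = cuts)
}

# ---- structural classes and haplotypes --------------------------------------

STRUCTURAL_KINDS <- c("NO_SV", "DELETION", "DUPLICATION", "HYBRID_TANDEM")

#' Hybrid tandem-copy catalogue
#'
#' The three hybrid gene copies supported by the fixture, with the 5'-region
#' origin, spacer status of the tandem copy's downstream region, and the
#' per-exon origin map that identifies each hybrid.
#'
#' @return data.frame with one row per hybrid label.
#' @export
hybrid_catalog <- function() {
  data.frame(
    label = c("*36", "*68", "*13"),
    five_prime_origin = c("D7", "D7", "D6"),
    spacer = c(TRUE, TRUE, FALSE),
    origin_map = c(paste(c(rep("D6", 8), "D7"), collapse = ","),
                   paste(c("D6", rep("D7", 8)), collapse = ","),
                   paste(c("D6", rep("D7", 8)), collapse = ",")),
    stringsAsFactors = FALSE
  )
}

hybrid_origin_map <- function(label) {
  cat <- hybrid_catalog()
  row <- cat[cat$label == label, ]
  if (nrow(row) == 0) stop("unknown hybrid allele: ", label, call. = FALSE)
  list(origin_map = strsplit(row$origin_map, ",")[[1]],
       five_prime_origin = row$five_prime_origin,
       spacer = row$spacer)
}

#' Parse a single star-allele specification string
#'
#' Supported forms: plain suballele ("*1.001"), full-gene deletion ("*5",
#' "*5.001"), duplication ("*2.001x2"), and tandem arrangements with the
#' 5'-most (duplicated-position) copy listed first ("*36+*10.001").
#'
#' @param label allele string.
#' @return list describing the structural kind and the gene copies, 5' first.
#' @export
parse_allele <- function(label) {
  label <- trimws(label)
  if (!grepl("^\\*", label)) {
    stop("unparseable allele label: ", label, call. = FALSE)
  }
  core_of <- function(x) sub("\\..*$", "", x)
  if (grepl("\\+", label)) {
    parts <- strsplit(label, "+", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("unparseable tandem allele: ", label, call. = FALSE)
    hy <- hybrid_origin_map(core_of(parts[1]))
    return(list(label = label, kind = "HYBRID_TANDEM",
                tandem_copy = parts[1], regular_copy = parts[2],
                five_prime_origin = hy$five_prime_origin,
                spacer = hy$spacer, origin_map = hy$origin_map))
  }
  if (grepl("x2$", label)) {
    sub <- sub("x2$", "", label)
    return(list(label = label, kind = "DUPLICATION",
                tandem_copy = sub, regular_copy = sub,
                five_prime_origin = "D6", spacer = FALSE,
                origin_map = rep("D6", N_EXONS)))
  }
  if (core_of(label) == "*5") {
    return(list(label = label, kind = "DELETION",
                tandem_copy = NULL, regular_copy = NULL))
  }
  list(label = label, kind = "NO_SV", tandem_copy = NULL,
       regular_copy = label)
}

#' Parse a diplotype specification string
#'
#' @param x diplotype string such as "*1.037/*68+*4.001".
#' @return list of two parsed alleles.
#' @export
parse_diplotype <- function(x) {
  parts <- strsplit(trimws(x), "/", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop("unparseable diplotype string: ", x, call. = FALSE)
  }
  lapply(parts, parse_allele)
}

#' Build a concrete haplotype sequence for an allele specification
#'
#' Realizes one parental allele of the excision fragment: the no-SV layout,
#' the REP-mediated full-gene deletion, or a tandem arrangement with a
#' duplicated-position gene copy, with allele-defining SNVs applied.  Returns
#' the sequence between cut sites with truth annotations (variant positions in
#' haplotype coordinates, copy boundaries, spacer coordinates).
#'
#' @param model a `cyp_locus_model`.
#' @param allele allele string or the result of [parse_allele()].
#' @param defs an allele-definition table from [load_allele_definitions()] or
#'   [default_allele_definitions()].
#' @return an object of class `cyp_haplotype`.
#' @export
build_haplotype_sequence <- function(model, allele, defs) {
  stopifnot(is(model, "cyp_locus_model"))
  if (is.character(allele)) allele <- parse_allele(allele)
  if (!allele$kind %in% STRUCTURAL_KINDS) {
    stop("unsupported structural kind: ", allele$kind, call. = FALSE)
  }
  ref_names <- ref_layout_names()
  if (allele$kind == "NO_SV") {
    names <- ref_names
  } else if (allele$kind == "DELETION") {
    names <- setdiff(ref_names, c("REP7", "IG76", "UP_D6", "G_D6"))
  } else {
    if (is.null(allele$origin_map)) {
      stop("HYBRID_TANDEM requires an exon-origin map", call. = FALSE)
    }
    unit <- tandem_unit_names(allele$five_prime_origin, allele$spacer,
                              allele$origin_map)
    names <- append(ref_names, unit, after = match("IG76", ref_names))
  }
  layout <- layout_table(model$instances, names)
  seq <- concat_instances(model$instances, names)

  # apply allele-defining SNVs per gene copy
  variants <- data.frame(hap_pos = integer(0), window_pos = integer(0),
                         ref = character(0), alt = character(0),
                         copy = character(0))
  copies <- list()
  g_reg <- layout[layout$instance == "G_D6", ]
  if (!is.null(allele$regular_copy)) {
    vs <- allele_variants(defs, allele$regular_copy)
    res <- apply_copy_variants(seq, vs, g_reg$start, model)
    seq <- res$seq
    if (nrow(res$variants)) res$variants$copy <- "regular"
    variants <- rbind(variants, res$variants)
    copies$regular <- list(label = allele$regular_copy,
                           gene_start = g_reg$start,
                           gene_end = g_reg$start + GENE_LEN,
                           origin_map = rep("D6", N_EXONS))
  }
  if (!is.null(allele$tandem_copy)) {
    td_start <- layout$start[grepl("^TD_EX1_", layout$instance)]
    if (allele$kind == "DUPLICATION") {
      vs <- allele_variants(defs, allele$tandem_copy)
      res <- apply_copy_variants(seq, vs, td_start, model)
      seq <- res$seq
      if (nrow(res$variants)) res$variants$copy <- "tandem"
      variants <- rbind(variants, res$variants)
    }
    copies$tandem <- list(label = allele$tandem_copy,
                          gene_start = td_start,
                          gene_end = td_start + GENE_LEN,
                          origin_map = allele$origin_map)
  }

  sp <- layout[layout$instance %in% c("SPACER", "TD_SPACER"), ]
  structure(list(
    label = allele$label,
    kind = allele$kind,
    sequence = seq,
    length = nchar(seq),
    layout = layout,
    copies = copies,
    variants = variants,
    five_prime_origin = if (!is.null(allele$tandem_copy)) {
      if (allele$five_prime_origin == "D7") "D7_LIKE" else "D6_LIKE"
    } else NA_character_,
    spacer_in_tandem_copy = isTRUE(allele$spacer),
    spacer_coords = sp
  ), class = "cyp_haplotype")
}

# Substitute defined variants of one gene copy into the haplotype sequence.
# `gene_start` is the 0-based haplotype coordinate of the copy's gene body.
apply_copy_variants <- function(seq, vs, gene_start, model) {
  if (is.null(vs) || nrow(vs) == 0) {
    return(list(seq = seq, variants = data.frame(
      hap_pos = integer(0), window_pos = integer(0),
      ref = character(0), alt = character(0), copy = character(0))))
  }
  g_off <- window_to_seq0(model, vs$pos) -
    model$segment_map$start[model$segment_map$instance == "G_D6"]
  hap_pos <- gene_start + g_off # 0-based
  for (i in seq_len(nrow(vs))) {
    have <- substr(seq, hap_pos[i] + 1L, hap_pos[i] + 1L)
    if (have != vs$ref[i]) {
      stop("reference mismatch applying variant at window position ",
           vs$pos[i], call. = FALSE)
    }
    substr(seq, hap_pos[i] + 1L, hap_pos[i] + 1L) <- vs$alt[i]
  }
  list(seq = seq,
       variants = data.frame(hap_pos = hap_pos, window_pos = vs$pos,
                             ref = vs$ref, alt = vs$alt,
                             copy = NA_character_))
}

#' @export
print.cyp_haplotype <- function(x, ...) {
  cat("Haplotype ", x$label, " [", x$kind, "], ", x$length, " bp, ",
      nrow(x$variants), " defined variant(s)\n", sep = "")
  invisible(x)
}

# ---- allele definitions ------------------------------------------------------

transition <- function(b) c(A = "G", G = "A", C = "T", T = "C")[[b]]

#' Default allele-definition table for the fixture locus
#'
#' Builds the definition table for the alleles required by the nine study
#' diplotypes: *1 (and suballeles .001/.037/.045/.058/.059), *2 (.001/.033),
#' *4 (.001), *10 (.001), *29 (.001), *5 (.001, full-gene deletion), and the
#' hybrids *36, *68, *13.  Variant positions are fixture-invented; reference
#' bases are taken from the model's generated sequence so the table always
#' matches the model it was built from.
#'
#' @param model a `cyp_locus_model`.
#' @return a validated allele-definition table (class `cyp_allele_defs`).
#' @export
default_allele_definitions <- function(model) {
  ref_at <- function(wpos) {
    p <- window_to_seq0(model, wpos)
    substr(model$reference, p + 1L, p + 1L)
  }
  var_str <- function(keys) {
    if (length(keys) == 0) return("")
    paste(vapply(keys, function(k) {
      pos <- FIXTURE_SITES[[k]]
      r <- ref_at(pos)
      sprintf("%d:%s>%s", pos, r, transition(r))
    }, character(1)), collapse = ";")
  }
  rows <- list(
    list("*1", "*1.001", "NONE", character(0), character(0)),
    list("*1", "*1.037", "NONE", character(0), "s37"),
    list("*1", "*1.045", "NONE", character(0), "s45"),
    list("*1", "*1.058", "NONE", character(0), "s58"),
    list("*1", "*1.059", "NONE", character(0), "s59"),
    list("*2", "*2.001", "NONE", c("c2a", "c2b"), character(0)),
    list("*2", "*2.033", "NONE", c("c2a", "c2b"), "s33"),
    list("*4", "*4.001", "NONE", "c4a", character(0)),
    list("*10", "*10.001", "NONE", "c10a", character(0)),
    list("*29", "*29.001", "NONE", c("c29a", "c29b"), character(0)),
    list("*5", "*5.001", "DELETION", character(0), character(0)),
    list("*36", "*36", "HYBRID_TANDEM", character(0), character(0)),
    list("*68", "*68", "HYBRID_TANDEM", character(0), character(0)),
    list("*13", "*13", "HYBRID_TANDEM", character(0), character(0))
  )
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(star_allele = r[[1]], suballele = r[[2]], structural_kind = r[[3]],
               core_variants = var_str(r[[4]]),
               sub_variants = var_str(c(r[[4]], r[[5]])),
               stringsAsFactors = FALSE)
  }))
  validate_allele_definitions(df)
}

parse_variant_str <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(data.frame(pos = integer(0), ref = character(0), alt = character(0)))
  }
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+):([ACGT])>([ACGT])$", parts))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) {
    stop("malformed variant token(s): ", paste(parts[bad], collapse = ", "),
         call. = FALSE)
  }
  data.frame(pos = as.integer(vapply(m, `[`, character(1), 2)),
             ref = vapply(m, `[`, character(1), 3),
             alt = vapply(m, `[`, character(1), 4),
             stringsAsFactors = FALSE)
}

variant_keys <- function(df) {
  if (nrow(df) == 0) return(character(0))
  sprintf("%d:%s>%s", df$pos, df$ref, df$alt)
}

#' Load an allele-definition table from TSV
#'
#' Expected columns: `star_allele`, `suballele`, `structural_kind`,
#' `core_variants`, `sub_variants`; variants as semicolon-separated
#' `pos:ref>alt` tokens with 1-based analysis-window positions.
#'
#' @param path TSV file path.
#' @return validated table of class `cyp_allele_defs`.
#' @export
load_allele_definitions <- function(path) {
  if (!file.exists(path)) {
    stop("allele definition file not found: ", path, call. = FALSE)
  }
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("star_allele", "suballele", "structural_kind",
            "core_variants", "sub_variants")
  if (!all(need %in% names(df))) {
    stop("allele definition table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  validate_allele_definitions(df[need])
}

validate_allele_definitions <- function(df) {
  df$core <- lapply(df$core_variants, parse_variant_str)
  df$sub <- lapply(df$sub_variants, parse_variant_str)
  errs <- character(0)
  for (i in seq_len(nrow(df))) {
    core_keys <- variant_keys(df$core[[i]])
    sub_keys <- variant_keys(df$sub[[i]])
    if (!all(core_keys %in% sub_keys)) {
      errs <- c(errs, sprintf(
        "row %d (%s): suballele variant set does not contain its core's variants",
        i, df$suballele[i]))
    }
    allpos <- c(df$core[[i]]$pos, df$sub[[i]]$pos)
    if (length(allpos) && (min(allpos) < 1 || max(allpos) > ANALYSIS_WINDOW_LEN)) {
      errs <- c(errs, sprintf("row %d (%s): variant position outside analysis window",
                              i, df$suballele[i]))
    }
  }
  # *1 core must be the empty (reference) set
  ref_rows <- df$star_allele == "*1"
  if (any(vapply(df$core[ref_rows], nrow, integer(1)) > 0)) {
    errs <- c(errs, "*1 core must be the empty variant set")
  }
  # suballeles of the same core must differ from each other
  for (core in unique(df$star_allele)) {
    keysets <- vapply(df$sub[df$star_allele == core], function(d)
      paste(sort(variant_keys(d)), collapse = "|"), character(1))
    if (anyDuplicated(keysets[df$structural_kind[df$star_allele == core] == "NONE"]) &&
        sum(df$star_allele == core) > 1) {
      errs <- c(errs, sprintf("suballeles of core %s do not differ", core))
    }
  }
  if (length(errs)) {
    stop("allele definition validation error:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)
  }
  structure(df, class = c("cyp_allele_defs", "data.frame"))
}

#' Write an allele-definition table to TSV
#'
#' @param defs a `cyp_allele_defs` table.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_allele_definitions <- function(defs, path) {
  cols <- c("star_allele", "suballele", "structural_kind",
            "core_variants", "sub_variants")
  write.table(as.data.frame(defs)[cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a locus configuration file
#'
#' JSON (or YAML, when the yaml package is installed) with an optional `seed`
#' and an optional `segments` list of objects with `name`, `role`, `origin`,
#' `length`.  Omitted fields fall back to the fixture defaults.
#'
#' @param path configuration file path.
#' @return list with `seed` and `segments`, suitable for
#'   [build_locus_model()].
#' @export
read_locus_config <- function(path) {
  if (!file.exists(path)) {
    stop("locus config not found: ", path, call. = FALSE)
  }
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs require the yaml package; use JSON instead",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  seed <- if (is.null(cfg$seed)) 7L else as.integer(cfg$seed)
  segments <- if (is.null(cfg$segments)) {
    locus_segments()
  } else {
    seg <- as.data.frame(cfg$segments, stringsAsFactors = FALSE)
    seg$length <- as.integer(seg$length)
    validate_segments(seg)
  }
  list(seed = seed, segments = segments)
}

#' Export the reference and custom tracks as FASTA
#'
#' @param model a `cyp_locus_model`.
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
write_tracks_fasta <- function(model, path) {
  seqs <- Biostrings::DNAStringSet(vapply(model$tracks, `[[`, character(1),
                                          "sequence"))
  names(seqs) <- names(model$tracks)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Export a haplotype's truth annotations as BED and TSV
#'
#' Writes `<prefix>.bed` with the segment layout (0-based half-open, BED
#' convention) and `<prefix>_variants.tsv` with the applied variants in
#' haplotype and analysis-window coordinates.
#'
#' @param hap a `cyp_haplotype`.
#' @param prefix output path prefix.
#' @return character vector of the two paths, invisibly.
#' @export
write_haplotype_truth <- function(hap, prefix) {
  bed <- file.path(paste0(prefix, ".bed"))
  tsv <- file.path(paste0(prefix, "_variants.tsv"))
  writeLines(sprintf("%s\t%d\t%d\t%s", hap$label, hap$layout$start,
                     hap$layout$start + hap$layout$length,
                     hap$layout$instance), bed)
  write.table(hap$variants, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(bed, tsv))
}

# Variant set (data.frame pos/ref/alt) for a suballele or core label.
allele_variants <- function(defs, label) {
  i <- match(label, defs$suballele)
  if (is.na(i)) {
    # accept a bare core label, meaning its core-defining set
    j <- which(defs$star_allele == label)
    if (length(j) == 0) stop("unknown suballele label: ", label, call. = FALSE)
    return(defs$core[[j[1]]])
  }
  defs$sub[[i]]
}
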