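# Direct read-backed phasing and star-allele calling.
#
# Because every analyzed read spans the whole excision fragment, phasing is
# combinatorial rather than statistical: reads partition into the two
# parental alleles by their structural signature plus their variant profile,
# and each allele's gene copies are called from a majority consensus over the
# reads of that cluster alone.

PROBE_FLANK <- 15L           # probe = 31 bp centred on the site
PROBE_WINDOW <- 80L          # search window half-width around expected position
PROBE_MAX_DIST <- 8L         # max partial edit distance for a usable probe hit
SITE_MAJORITY <- 0.7         # alt fraction required to call a variant
MIN_SITE_DEPTH <- 3L         # informative reads required per site

# ---- definition sites and probes --------------------------------------------

# Unique variant sites of a definition table: data.frame(pos, ref, alt, key).
definition_sites <- function(defs) {
  all <- do.call(rbind, c(defs$core, defs$sub))
  if (is.null(all) || nrow(all) == 0) {
    return(data.frame(pos = integer(0), ref = character(0), alt = character(0),
                      key = character(0)))
  }
  all <- unique(all)
  all <- all[order(all$pos), , drop = FALSE]
  all$key <- variant_keys(all)
  rownames(all) <- NULL
  all
}

# Window position (1-based) -> 0-based offset into the CYP2D6 gene body.
gene_offset <- function(model, pos) {
  g0 <- model$segment_map$start[model$segment_map$instance == "G_D6"]
  window_to_seq0(model, pos) - g0
}

# Reference/alt probe pair for one site in a given copy context.
# For the regular-position copy the context is the reference fragment; for a
# tandem copy it is the copy-specific exon instance, with the centre base
# forced to ref/alt.
site_probe <- function(model, pos, ref, alt, copy = "regular",
                       origin_map = NULL) {
  g <- gene_offset(model, pos)
  if (g < 0 || g >= GENE_LEN) {
    stop("site at window position ", pos, " is outside the gene body",
         call. = FALSE)
  }
  if (copy == "regular") {
    c0 <- window_to_seq0(model, pos)
    lo <- max(0L, c0 - PROBE_FLANK)
    ctx <- substr(model$reference, lo + 1L, c0 + PROBE_FLANK + 1L)
    centre <- c0 - lo + 1L
  } else {
    e <- g %/% EXON_LEN + 1L
    off <- g %% EXON_LEN
    org <- if (is.null(origin_map)) "D6" else origin_map[e]
    inst <- model$instances[[sprintf("TD_EX%d_%s", e, org)]]
    lo <- max(0L, off - PROBE_FLANK)
    ctx <- substr(inst, lo + 1L, min(EXON_LEN, off + PROBE_FLANK + 1L))
    centre <- off - lo + 1L
  }
  pr <- pa <- ctx
  substr(pr, centre, centre) <- ref
  substr(pa, centre, centre) <- alt
  list(ref = pr, alt = pa)
}

# Expected 0-based read position of a site in a given copy, from the read's
# segment blocks; NA when the copy's block is absent.
expected_read_pos <- function(feats, model, pos, copy, origin_map = NULL) {
  g <- gene_offset(model, pos)
  b <- feats$blocks
  if (copy == "regular") {
    st <- b$start[b$instance == "G_D6"]
    if (length(st) == 0) return(NA_integer_)
    return(st[1] + g)
  }
  e <- g %/% EXON_LEN + 1L
  off <- g %% EXON_LEN
  for (org in unique(c(if (!is.null(origin_map)) origin_map[e], "D6", "D7"))) {
    st <- b$start[b$instance == sprintf("TD_EX%d_%s", e, org)]
    if (length(st)) return(st[1] + off)
  }
  NA_integer_
}

#' Extract a read's variant profile at a set of sites
#'
#' For every profiled site, compares a reference and an alternate 31-bp probe
#' against the read around the expected position (approximate matching
#' absorbs nearby sequencing errors).  A site under a read gap, outside the
#' read, or with an undecidable comparison is recorded as MISSING, never as
#' reference support.
#'
#' @param model a `cyp_locus_model`.
#' @param feats a `cyp_read_features` for the (oriented) read.
#' @param sites data.frame with `pos`, `ref`, `alt` (window coordinates).
#' @param copy "regular" or "tandem": which gene copy to profile.
#' @param origin_map per-exon origin of the tandem copy, when known.
#' @return character vector over sites: "REF", "ALT" or "MISSING".
#' @export
extract_variant_profile <- function(model, feats, sites, copy = "regular",
                                    origin_map = NULL) {
  n <- nchar(feats$sequence)
  obs <- rep("MISSING", nrow(sites))
  if (nrow(sites) == 0) return(obs)
  for (i in seq_len(nrow(sites))) {
    p <- expected_read_pos(feats, model, sites$pos[i], copy, origin_map)
    if (is.na(p)) next
    lo <- max(0L, p - PROBE_WINDOW)
    hi <- min(n, p + PROBE_WINDOW + 2L * PROBE_FLANK + 1L)
    if (hi - lo < 2L * PROBE_FLANK + 1L) next
    win <- substr(feats$sequence, lo + 1L, hi)
    probes <- site_probe(model, sites$pos[i], sites$ref[i], sites$alt[i],
                         copy, origin_map)
    dr <- adist(probes$ref, win, partial = TRUE)[1, 1]
    da <- adist(probes$alt, win, partial = TRUE)[1, 1]
    if (min(dr, da) > PROBE_MAX_DIST || dr == da) next
    obs[i] <- if (da < dr) "ALT" else "REF"
  }
  obs
}

# ---- clustering --------------------------------------------------------------

STRUCT_FEAT_WEIGHT <- 3

# Per-read profile row: structural pseudo-sites + variant observations.
read_profile_row <- function(summary, model, sites) {
  obs <- extract_variant_profile(model, summary$features, sites)
  c(length_class = if (is.na(summary$length_class)) NA_character_
      else summary$length_class,
    five_prime = summary$five_prime_origin,
    spacer = if (is.na(summary$spacer_in_tandem)) NA_character_
      else as.character(summary$spacer_in_tandem),
    setNames(ifelse(obs == "MISSING", NA_character_, obs),
             paste0("site_", sites$pos)))
}

profile_distance_matrix <- function(mat, struct_cols = seq_len(ncol(mat)) <= 3) {
  w <- ifelse(struct_cols, STRUCT_FEAT_WEIGHT, 1)
  n <- nrow(mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- !is.na(mat[i, ]) & !is.na(mat[j, ])
      if (!any(ok)) { d[i, j] <- d[j, i] <- NA; next }
      mis <- (mat[i, ok] != mat[j, ok]) * w[ok]
      d[i, j] <- d[j, i] <- sum(mis) / sum(w[ok])
    }
  }
  d[is.na(d)] <- 0.5
  d
}

profile_consensus <- function(mat) {
  apply(mat, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0) return(NA_character_)
    names(sort(table(col), decreasing = TRUE))[1]
  })
}

# Columns of the profile matrix that discriminate the two alleles: structural
# pseudo-sites with a substantial minority value, and variant sites whose
# alternate fraction among informative reads is intermediate (heterozygous).
discriminating_columns <- function(mat) {
  n <- nrow(mat)
  vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[!is.na(col)]
    if (length(col) < max(4L, 0.2 * n)) return(FALSE)
    tab <- sort(table(col), decreasing = TRUE)
    length(tab) >= 2 && tab[2] >= max(2L, 0.2 * length(col))
  }, logical(1))
}

#' Cluster full-span reads into the two parental alleles
#'
#' Agglomerative 2-way partition on weighted Hamming distance over shared
#' non-missing profile entries; the profile combines structural pseudo-sites
#' (fragment-length class, duplicated-position 5'-region origin, spacer
#' status) with the definition-site observations.  The partition is driven by
#' the discriminating (heterozygous) profile columns, followed by
#' consensus-based reassignment; a sample with no discriminating column, or
#' whose two candidate clusters' consensus profiles differ at zero entries,
#' is called homozygous and returned as a single cluster.
#'
#' @param summaries list of `cyp_read_summary` for the sample's full-span reads.
#' @param model a `cyp_locus_model`.
#' @param defs allele definitions (profiled sites).
#' @param min_reads minimum reads per allele (default 3).
#' @return list with `clusters` (list of index vectors into `summaries`),
#'   `homozygous`, `profiles` (matrix), `no_call` reason or NA.
#' @export
cluster_reads <- function(summaries, model, defs, min_reads = 3L) {
  sites <- definition_sites(defs)
  if (length(summaries) < 2L * min_reads) {
    return(list(clusters = list(), homozygous = NA, profiles = NULL,
                no_call = sprintf("insufficient reads for phasing (%d < %d)",
                                  length(summaries), 2L * min_reads)))
  }
  mat <- t(vapply(summaries, read_profile_row, character(3 + nrow(sites)),
                  model = model, sites = sites))
  disc <- discriminating_columns(mat)
  if (!any(disc)) {
    return(list(clusters = list(seq_along(summaries)), homozygous = TRUE,
                profiles = mat, no_call = NA_character_))
  }
  sub <- mat[, disc, drop = FALSE]
  d <- profile_distance_matrix(sub, struct_cols = which(disc) <= 3)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  grp <- stats::cutree(hc, k = 2)
  # consensus reassignment over the discriminating columns
  for (iter in 1:2) {
    cons <- lapply(1:2, function(k)
      profile_consensus(sub[grp == k, , drop = FALSE]))
    grp <- vapply(seq_len(nrow(sub)), function(i) {
      dk <- vapply(1:2, function(k) {
        ok <- !is.na(sub[i, ]) & !is.na(cons[[k]])
        if (!any(ok)) return(0.5)
        mean(sub[i, ok] != cons[[k]][ok])
      }, numeric(1))
      if (dk[1] == dk[2]) grp[i] else which.min(dk)
    }, integer(1))
    if (length(unique(grp)) == 1) break
  }
  c1 <- which(grp == 1); c2 <- which(grp == 2)
  if (length(c1) == 0 || length(c2) == 0) {
    return(list(clusters = list(seq_along(summaries)), homozygous = TRUE,
                profiles = mat, no_call = NA_character_))
  }
  cons1 <- profile_consensus(mat[c1, , drop = FALSE])
  cons2 <- profile_consensus(mat[c2, , drop = FALSE])
  ok <- !is.na(cons1) & !is.na(cons2)
  if (sum(cons1[ok] != cons2[ok]) == 0) {
    return(list(clusters = list(seq_along(summaries)), homozygous = TRUE,
                profiles = mat, no_call = NA_character_))
  }
  list(clusters = list(c1, c2), homozygous = FALSE, profiles = mat,
       no_call = NA_character_)
}

# ---- consensus and variant calling ------------------------------------------

# Copy-level reference sequence of the gene body (for discovery).
copy_reference <- function(model, copy, origin_map = NULL) {
  if (copy == "regular") {
    g0 <- model$segment_map$start[model$segment_map$instance == "G_D6"]
    return(substr(model$reference, g0 + 1L, g0 + GENE_LEN))
  }
  if (is.null(origin_map)) origin_map <- rep("D6", N_EXONS)
  paste(vapply(seq_len(N_EXONS), function(e)
    model$instances[[sprintf("TD_EX%d_%s", e, origin_map[e])]], character(1)),
    collapse = "")
}

# Discover candidate non-definition variant sites of one gene copy by
# aligning a small sample of reads' gene blocks to the copy reference and
# tallying recurrent identical mismatches.
discover_variant_sites <- function(model, feats_list, copy = "regular",
                                   origin_map = NULL, n_sample = 8L,
                                   min_frac = 0.6, seed = 1L) {
  ref <- copy_reference(model, copy, origin_map)
  take <- with_seed(seed, sample(seq_along(feats_list),
                                 min(n_sample, length(feats_list))))
  tallies <- list()
  n_used <- 0L
  for (i in take) {
    feats <- feats_list[[i]]
    p0 <- expected_read_pos(feats, model, seq0_to_window(model,
            model$segment_map$start[model$segment_map$instance == "G_D6"]),
            copy, origin_map)
    if (is.na(p0)) next
    lo <- max(0L, p0 - 100L)
    hi <- min(nchar(feats$sequence), p0 + GENE_LEN + 100L)
    block <- substr(feats$sequence, lo + 1L, hi)
    if (nchar(block) < GENE_LEN * 0.8) next
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(block), Biostrings::DNAString(ref),
      type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3),
      gapOpening = 5, gapExtension = 2)
    mt <- Biostrings::mismatchTable(aln)
    n_used <- n_used + 1L
    if (nrow(mt)) {
      tallies[[length(tallies) + 1L]] <- data.frame(
        pos = mt$SubjectStart, base = as.character(mt$PatternSubstring),
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(pos = integer(0), ref = character(0), alt = character(0),
                      key = character(0))
  if (n_used < 3L || length(tallies) == 0) return(empty)
  tt <- do.call(rbind, tallies)
  key <- paste(tt$pos, tt$base)
  cnt <- table(key)
  keep <- names(cnt)[cnt >= max(MIN_SITE_DEPTH, ceiling(min_frac * n_used))]
  if (length(keep) == 0) return(empty)
  parts <- strsplit(keep, " ", fixed = TRUE)
  pos_g <- vapply(parts, function(x) as.integer(x[1]), integer(1))
  alt <- vapply(parts, `[`, character(1), 2)
  ok <- alt %in% DNA_BASES
  pos_g <- pos_g[ok]; alt <- alt[ok]
  if (length(pos_g) == 0) return(empty)
  # window coordinate = window position of the gene start + 0-based offset
  g_w0 <- seq0_to_window(model,
    model$segment_map$start[model$segment_map$instance == "G_D6"])
  out <- data.frame(pos = g_w0 + pos_g - 1L,
                    ref = substring(ref, pos_g, pos_g), alt = alt,
                    stringsAsFactors = FALSE)
  out <- out[out$ref != out$alt, , drop = FALSE]
  out$key <- variant_keys(out)
  unique(out)
}

#' Per-copy consensus and variant calls for one allele cluster
#'
#' Profiles every cluster read at the definition sites plus any discovered
#' high-frequency mismatch sites, then emits majority-consensus variant calls
#' per gene copy: a site is called alternate when at least 70% of informative
#' reads support it, with a minimum informative depth of 3; shallower sites
#' propagate as site-level NO_CALLs.
#'
#' @param model a `cyp_locus_model`.
#' @param summaries the cluster's `cyp_read_summary` list.
#' @param structure the cluster's `cyp_structure_call`.
#' @param defs allele definitions.
#' @param discover whether to search for non-definition variant sites.
#' @param seed seed for the discovery read sample.
#' @return list with per-copy variant calls and site tables.
#' @export
consensus_and_call <- function(model, summaries, structure, defs,
                               discover = TRUE, seed = 1L) {
  feats_list <- lapply(summaries, `[[`, "features")
  copies <- list()
  if (structure$kind %in% c("NO_SV", "DUPLICATION", "HYBRID_TANDEM")) {
    copies$regular <- list(copy = "regular", origin_map = rep("D6", N_EXONS))
  }
  if (structure$kind == "DUPLICATION") {
    copies$tandem <- list(copy = "tandem", origin_map = rep("D6", N_EXONS))
  }
  base_sites <- definition_sites(defs)
  out <- list()
  for (nm in names(copies)) {
    cp <- copies[[nm]]
    sites <- base_sites
    if (discover) {
      dv <- discover_variant_sites(model, feats_list, cp$copy, cp$origin_map,
                                   seed = derive_seed(seed, paste0("disc:", nm)))
      new <- dv[!dv$key %in% sites$key, , drop = FALSE]
      if (nrow(new)) sites <- rbind(sites, new)
    }
    obs <- t(vapply(feats_list, function(f)
      extract_variant_profile(model, f, sites, cp$copy, cp$origin_map),
      character(nrow(sites))))
    calls <- site_consensus(sites, obs)
    out[[nm]] <- list(copy = cp$copy, sites = sites, calls = calls)
  }
  out
}

site_consensus <- function(sites, obs) {
  if (nrow(sites) == 0) {
    return(data.frame(pos = integer(0), ref = character(0), alt = character(0),
                      key = character(0), status = character(0),
                      supporting_fraction = numeric(0), depth = integer(0)))
  }
  res <- lapply(seq_len(nrow(sites)), function(i) {
    o <- obs[, i]
    inf <- o[o != "MISSING"]
    depth <- length(inf)
    if (depth < MIN_SITE_DEPTH) {
      return(data.frame(status = "NO_CALL", supporting_fraction = NA_real_,
                        depth = depth))
    }
    fa <- mean(inf == "ALT")
    if (fa >= SITE_MAJORITY) {
      data.frame(status = "ALT", supporting_fraction = fa, depth = depth)
    } else if ((1 - fa) >= SITE_MAJORITY) {
      data.frame(status = "REF", supporting_fraction = 1 - fa, depth = depth)
    } else {
      data.frame(status = "NO_CALL", supporting_fraction = NA_real_,
                 depth = depth)
    }
  })
  cbind(sites, do.call(rbind, res))
}

# ---- star-allele assignment --------------------------------------------------

star_numeric <- function(label) {
  m <- regmatches(label, regexec("^\\*([0-9]+)(?:\\.([0-9]+))?", label))[[1]]
  if (length(m) < 2) return(Inf)
  as.numeric(m[2]) + ifelse(is.na(m[3]) || m[3] == "", 0,
                            as.numeric(paste0("0.", m[3])))
}

#' Assign a star allele and suballele to a called variant set
#'
#' Chooses the core allele whose defining variants are all present and whose
#' defining set is largest (ties resolved toward the lowest numeric star id
#' and flagged AMBIGUOUS); then the suballele whose full variant set equals
#' the call.  A matching core with unmatched extra variants yields a NOVEL
#' suballele of that core with the extras listed.
#'
#' @param called character vector of called variant keys ("pos:ref>alt").
#' @param defs allele definitions.
#' @return list of class `cyp_haplotype_call`: `core`, `suballele`, `novel`,
#'   `extra_variants`, `ambiguous`.
#' @export
assign_star_allele <- function(called, defs) {
  snv <- defs[defs$structural_kind == "NONE", , drop = FALSE]
  cores <- unique(snv$star_allele)
  core_sets <- lapply(cores, function(cn)
    variant_keys(snv$core[[match(cn, snv$star_allele)]]))
  names(core_sets) <- cores
  contained <- vapply(core_sets, function(ks) all(ks %in% called), logical(1))
  if (!any(contained)) {
    return(structure(list(core = NA_character_, suballele = NA_character_,
                          novel = FALSE, extra_variants = called,
                          ambiguous = FALSE, no_call = TRUE),
                     class = "cyp_haplotype_call"))
  }
  sizes <- lengths(core_sets)[contained]
  cand <- names(sizes)[sizes == max(sizes)]
  ambiguous <- length(cand) > 1
  core <- cand[order(vapply(cand, star_numeric, numeric(1)))][1]

  rows <- which(snv$star_allele == core)
  sub_label <- NA_character_
  for (r in rows) {
    if (setequal(variant_keys(snv$sub[[r]]), called)) {
      sub_label <- snv$suballele[r]
      break
    }
  }
  extras <- setdiff(called, core_sets[[core]])
  if (is.na(sub_label)) {
    out <- list(core = core, suballele = paste0(core, ".new1"), novel = TRUE,
                extra_variants = extras, ambiguous = ambiguous,
                no_call = FALSE)
  } else {
    # containment soundness re-check at call time
    stopifnot(all(core_sets[[core]] %in% called))
    out <- list(core = core, suballele = sub_label, novel = FALSE,
                extra_variants = character(0), ambiguous = ambiguous,
                no_call = FALSE)
  }
  structure(out, class = "cyp_haplotype_call")
}

# Label the hybrid tandem copy from the structure call via the catalogue.
match_hybrid_label <- function(structure) {
  cat <- hybrid_catalog()
  fp <- sub("_LIKE$", "", structure$five_prime_origin)
  for (i in seq_len(nrow(cat))) {
    if (cat$five_prime_origin[i] != fp) next
    if (!identical(cat$spacer[i],
                   isTRUE(structure$spacer_present_in_tandem_copy))) next
    map <- strsplit(cat$origin_map[i], ",")[[1]]
    om <- structure$exon_origins
    ok <- !is.na(om)
    if (sum(ok) >= 5 && all(om[ok] == map[ok])) return(cat$label[i])
  }
  NA_character_
}

# ---- allele- and sample-level assembly --------------------------------------

#' Call one allele (cluster) end to end
#'
#' @param model a `cyp_locus_model`.
#' @param summaries the cluster's reads.
#' @param defs allele definitions.
#' @param min_reads per-group minimum for a structural call.
#' @param discover discovery of non-definition sites.
#' @param seed seed for discovery sampling.
#' @return list of class `cyp_allele_call`.
#' @export
call_allele <- function(model, summaries, defs, min_reads = 3L,
                        discover = TRUE, seed = 1L) {
  structure_call <- classify_structure(summaries, model, min_reads)
  if (structure_call$kind == "NO_CALL") {
    return(structure(list(structure = structure_call, label = NA_character_,
                          no_call = TRUE, reason = structure_call$reason,
                          copies = NULL, variants = NULL),
                     class = "cyp_allele_call"))
  }
  if (structure_call$kind == "DELETION") {
    del_rows <- defs$suballele[defs$structural_kind == "DELETION"]
    label <- if (length(del_rows)) del_rows[1] else "*5"
    return(structure(list(structure = structure_call, label = label,
                          no_call = FALSE, reason = NA_character_,
                          copies = list(), variants = NULL),
                     class = "cyp_allele_call"))
  }
  cons <- consensus_and_call(model, summaries, structure_call, defs,
                             discover = discover, seed = seed)
  copy_calls <- list()
  for (nm in names(cons)) {
    called <- cons[[nm]]$calls$key[cons[[nm]]$calls$status == "ALT"]
    copy_calls[[nm]] <- assign_star_allele(called, defs)
  }
  label <- switch(structure_call$kind,
    NO_SV = copy_calls$regular$suballele,
    DUPLICATION = {
      if (identical(copy_calls$tandem$suballele, copy_calls$regular$suballele))
        paste0(copy_calls$regular$suballele, "x2")
      else paste0(copy_calls$tandem$suballele, "+", copy_calls$regular$suballele)
    },
    HYBRID_TANDEM = {
      hy <- match_hybrid_label(structure_call)
      if (is.na(hy)) NA_character_
      else paste0(hy, "+", copy_calls$regular$suballele)
    })
  no_call <- is.na(label) ||
    any(vapply(copy_calls, function(cc) isTRUE(cc$no_call), logical(1)))
  structure(list(structure = structure_call, label = label,
                 no_call = no_call,
                 reason = if (no_call) "unresolved allele assignment"
                          else NA_character_,
                 copies = copy_calls, variants = cons),
            class = "cyp_allele_call")
}

#' Assemble the sample diplotype from per-allele calls
#'
#' Formats the two allele calls in the field's tandem-annotation convention:
#' the most 5' (duplicated-position) gene copy listed first within an allele,
#' duplications as "<allele>x2", and the two alleles ordered by the numeric
#' star id of their first-listed copy.
#'
#' @param calls list of one or two `cyp_allele_call`.
#' @return list of class `cyp_diplotype_call`: `diplotype` string, `alleles`,
#'   `no_call`, `reason`.
#' @export
assemble_diplotype <- function(calls) {
  if (length(calls) == 1) calls <- list(calls[[1]], calls[[1]])
  labels <- vapply(calls, function(cc)
    if (isTRUE(cc$no_call)) NA_character_ else cc$label, character(1))
  if (all(is.na(labels))) {
    return(structure(list(diplotype = NA_character_, alleles = calls,
                          no_call = TRUE,
                          reason = paste(unique(vapply(calls, `[[`,
                            character(1), "reason")), collapse = "; ")),
                     class = "cyp_diplotype_call"))
  }
  shown <- ifelse(is.na(labels), "NO_CALL", labels)
  key <- vapply(shown, function(l)
    if (l == "NO_CALL") Inf else star_numeric(sub("x2$", "", l)), numeric(1))
  ord <- order(key)
  structure(list(diplotype = paste(shown[ord], collapse = "/"),
                 alleles = calls[ord], no_call = FALSE,
                 reason = NA_character_),
            class = "cyp_diplotype_call")
}

#' @export
print.cyp_diplotype_call <- function(x, ...) {
  cat("Diplotype: ", if (isTRUE(x$no_call)) paste("NO_CALL -", x$reason)
      else x$diplotype, "\n", sep = "")
  invisible(x)
}

#' Strip suballele resolution from a diplotype string
#'
#' Reduces e.g. "*2.001x2/*29.001" to "*2x2/*29" for core-allele +
#' structural-level comparisons.
#'
#' @param x diplotype string.
#' @return normalized string.
#' @export
normalize_diplotype <- function(x) {
  gsub("\\.(new)?[0-9]+", "", x)
}
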