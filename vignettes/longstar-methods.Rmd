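---
title: "Methods: full-locus CYP2D6 genotyping from CRISPR-excised long reads"
author: "longstar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: full-locus CYP2D6 genotyping from CRISPR-excised long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The procedure

`longstar` genotypes the CYP2D6–CYP2D7–CYP2D8 locus from long reads that
each span the entire CRISPR-excised fragment. The analytical chain is:

1. **Read gates.** Reads under 20,000 bp or with a mean PHRED quality below
   7 are removed. Mean quality is computed in probability space (convert
   each Q to an error probability, average, convert back); an arithmetic
   mean would overstate the quality of reads with low-Q stretches. Reads
   that do not carry both cut-site flank anchors ("full-span") are excluded:
   only a molecule that spans the whole locus phases it unambiguously. A
   final gate requires an internal alignment score (count of chained
   locus-unique 17-mers) of at least 2,000, calibrated so error-free
   full-span reads pass by an order of magnitude while reads matching under
   half the locus fail; the analogous mapper-score constant is aligner-specific
   and does not transfer across scoring schemes.
2. **Sample gate.** At least 35 full-span reads are required per sample.
   Since each retained read covers the whole analysis window, the minimum
   window depth equals the full-span read count.
3. **Structural classification.** Each read votes with its fragment length
   (truth length in simulation, anchored span otherwise), the origin of the
   duplicated-position copy's 5′ region (D6-like vs D7-like), spacer
   presence, and per-exon origin of the tandem copy. Length classes are
   20–30 kb = deletion, 35–43 kb = no-SV, >45 kb = tandem/duplication —
   boundaries placed midway between the fixture fragment lengths (25,000 /
   39,551 / 52,000 bp) and configurable. A group call is the majority vote;
   ties and groups under 3 reads return NO_CALL, never a silent no-SV.
4. **Phasing.** Full-span reads are partitioned into the two parental
   alleles by their profile: three structural pseudo-sites (length class,
   5′-region origin, spacer) plus an observation (REF/ALT/MISSING) at every
   allele-definition site. Columns that are heterozygous in the sample
   (intermediate alternate fraction, or a structural column with a ≥20%
   minority) drive an agglomerative 2-way split followed by consensus
   reassignment. With no discriminating column, or when the two candidate
   clusters' consensus profiles agree everywhere, the sample is homozygous.
5. **Consensus and star alleles.** Per allele cluster and per gene copy, a
   site is called alternate when ≥70% of informative reads support it with
   at least 3 informative reads; shallower or intermediate sites propagate
   as site NO_CALLs. Missing observations (gaps, unreadable probes) are
   never counted as reference support. The core allele is the one whose
   defining variants are all present and whose defining set is largest
   (ties go to the lowest numeric star id and are flagged); the suballele
   must match the full called set exactly, otherwise the call is a novel
   suballele of that core, locally labelled `<core>.new1` — registry-style
   numbers are never auto-assigned. Hybrid tandem copies are labelled from
   a catalogue keyed on 5′-region origin, spacer status and the per-exon
   origin map. Deletion alleles take the deletion suballele from the
   definition table. Diplotypes list the 5′ (duplicated-position) copy
   first within an allele and order alleles by numeric star id.

## The synthetic locus

The fixture emulates the locus as 13 ordered segments (flanks, three gene
bodies, upstream regions, intergenic spans, the 1,560 bp spacer downstream
of CYP2D7, and the REP6/REP7 recombination elements), summing to the
39,551 bp cut-to-cut fragment implied by the assay's guide coordinates; the
analysis window is the 38,254 bp sub-interval used for variant calling. Coordinates are
0-based half-open internally and 1-based inclusive in human-readable
output.

Paralogy is modelled by deriving the CYP2D7/CYP2D8 gene and upstream
segments from the CYP2D6 segment at a fixed 2% divergence, and tandem-copy
segments at a further 1.5% copy-specific divergence, with one fixed marker
31-mer planted per 500 bp gene block. Real paralogs diverge unevenly
(exonic conversion tracts, indels); the uniform model is a deliberate
simplification that still forces the classifier to work from sparse
divergent sites at nanopore error rates. Gene bodies are nine 500 bp "exon
blocks", giving hybrid alleles exact per-exon origin maps (\*36 = exons 1–8
D6 + exon 9 D7; \*68 and \*13 = exon 1 D6 + exons 2–9 D7, distinguished by
the 5′-region origin and spacer status of the tandem copy).

Structural classes are realized with exact integer lengths chosen to
reproduce the assay's fragment spectrum (~25 / ~38 / up to 52 kb): the deletion allele removes a
14,551 bp REP-to-REP block (25,000 bp fragment; the real \*5 breakpoints
are not modelled — this is a stand-in, not a claim about the allele), and
tandem arrangements insert a 12,449 bp duplicated-position unit (52,000 bp
fragment). Track A carries the spacer-bearing unit (52,000 bp) and track B
the spacer-less unit, so the two tracks differ by exactly the 1,560 bp
spacer. To keep *all* tandem haplotypes at 52 kb, the spacer-less
haplotypes carry a 1,560 bp longer neutral upstream pad than track B's
unit; against track B this surplus is a read-side insertion and produces no
gap record, so classification is unaffected. This was the one point where
the fragment-length spectrum and the track-pair geometry could not both be
satisfied by a single shared unit, and the fragment spectrum was given
priority.

In-silico digestion plants one protospacer+NGG across each cut boundary of
a padded genomic context; the Cas9 blunt cut is reported 3 bp 5′ of the PAM
on either strand, and digesting the context releases exactly the reference
fragment.

## The read simulator

Reads start from a full excised fragment per parental allele (depth is a
per-allele read count). Errors are flat, independent per base:
substitution 0.02, insertion 0.015, deletion 0.02 (≈5.5% total), matching
nanopore-class data with mean Q ≈ 14 (qualities are drawn from a normal
with sd 3, clipped to [2, 41]). With probability 0.15 a read is truncated
to a uniform 30–95% of the fragment from a random end — enough truncated
molecules that the full-span exclusion rule is genuinely exercised. Reads
are emitted on random strands in randomized allele order.

What the simulator does **not** model: homopolymer-biased errors,
signal-level artefacts, adapter/barcode sequence, chimeric reads,
coverage bias, and real paralog sequence. Passing tests therefore
demonstrate the pipeline's logic — gating, classification, phasing,
consensus arithmetic — under controlled sequence divergence, not
performance on real flow-cell data.

## The alignment engine

The engine is a segment-aware projection aligner rather than a generic
dynamic-programming aligner (production analyses of this assay
use an external long-read mapper; the pipeline keeps the alignment
contract pluggable).
Every segment instance in the model carries instance-unique 17-mers; a
single Aho–Corasick scan (`Biostrings::matchPDict`) of a read yields
positioned, origin-labelled segment blocks (reads are auto-oriented by
re-scanning the reverse complement when the forward scan is sparse). Blocks
merge into role blocks (flank / intergenic / gene / spacer / REP) and are
assigned colinearly to the track's role slots, always taking the 5′-most
compatible slot. Track intervals supported by shared instances — or by
same-role homology, as when a no-SV read's CYP2D6 lies over a track's
tandem-position copy — count as covered; uncovered stretches of ≥200 bp
become gap records. A read lacking the spacer therefore shows a single
spacer-length gap inside track A's spacer window, reproducing the
diagnostic alignment signature this assay reads by eye in a browser.
Spacer decision rule: a gap of 1,200–2,000 bp overlapping at least half of
the spacer window means the spacer is absent; the window tolerates indel
noise around a 1,560 bp event. Anchor detection is seed-and-verify: flank
k-mer seeds propose a position, and a 500 bp anchor window is verified by
approximate matching with a ≥0.7 match-fraction threshold — at the default
5.5% error rate observed match fractions are ≈0.94, so the threshold only
rejects genuinely absent flanks.

Numerical/degenerate-input choices: block positions are medians of k-mer
offsets (robust to indel drift); majority-vote ties resolve to NO_CALL
(conservative, never toward a specific SV); unalignable reads (<30% track
coverage) are flagged, not dropped silently; probe comparisons that tie or
exceed the edit budget record MISSING rather than guessing.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `min_read_length` | 20,000 | bp | removes molecules that cannot span the locus informatively |
| `min_mean_q` | 7 | PHRED | basecall-quality floor; probability-space mean per read |
| `min_alignment_score` | 2,000 | chained unique 17-mers | calibrated internal analogue of a mapper score gate |
| `min_full_span_reads` | 35 | reads | sample-level evidence floor; equals minimum window depth |
| site majority | 0.7 | fraction | consensus threshold; with ≈2% per-base substitution error, binomial misclassification at depth ≥3 is negligible |
| min site depth | 3 | reads | below this a site is NO_CALL, never imputed |
| per-group minimum | 3 | reads | minimum evidence for a per-allele structural call (the assay QC itself fixes only a per-sample minimum) |
| spacer gap window | 1,200–2,000 | bp | indel tolerance around the 1,560 bp spacer |
| length classes | 20–30 / 35–43 / >45 | kb | midpoints between fixture fragment lengths |

## Problem sizes used by the test and acceptance suites

Simulated samples use 40 reads per allele at the default error model; the
nine-diplotype concordance check runs the full pipeline on all nine
samples; classification robustness uses 20 seeded replicates per structural
class at 40 reads per group; consensus recovery uses 20 seeded replicates
at depth 100 with 10 planted SNVs; the cut-site finder is checked against
an exhaustive both-strand oracle on 100 random 5 kb sequences. These sizes
were chosen to make each statistical check decisive at its stated threshold
on a single CPU.

## Known limitations

* The sequence model is synthetic; concordance results are fixture
  recoveries, not clinical validation.
* Only the four supported structural classes are modelled; multi-copy
  amplifications (x3+), rearrangements with more than two gene copies per
  allele, and unlisted hybrids return UNCLASSIFIED/NO_CALL.
* Suballele calls at elevated error rates can degrade to novel-suballele
  calls of the correct core (extra low-level false sites); core-allele and
  structural calls are the robust layer.
* The variant-calling procedure (majority consensus against the selected
  track with discovery by recurrent-mismatch tallying) is the simplest
  method consistent with direct read-backed haplotyping; it is not a
  general-purpose small-variant caller, and indel alleles are out of scope.
* A SNP shared between cores (as reported for one \*35-associated SNP on a
  novel \*2 suballele) does not alter core priority: assignment keeps
  containment-maximality and flags ambiguity instead.
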