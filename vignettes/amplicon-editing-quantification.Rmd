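---
title: "Quantifying HDR and NHEJ editing outcomes from amplicon deep sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying HDR and NHEJ editing outcomes from amplicon deep sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliconHDR)
```

## The measurement problem

A Cas9 double-strand break at a programmed genomic site is resolved by one of
two repair routes. Homology-directed repair (HDR) copies a co-delivered
single-stranded oligodeoxynucleotide (ssODN) template and yields a precise,
scarless allele carrying exactly the programmed edit. End-joining repair
(NHEJ/MMEJ, not distinguished here) is error-prone and leaves unprogrammed
insertions or deletions at the cut. Deep sequencing of a PCR amplicon
spanning the site therefore yields a mixture of three allele classes — HDR,
indel, and unedited wild type — and the quantity of interest when comparing
delivery strategies is the *precise-to-imprecise* balance: the HDR:indel
read ratio, and its fold change between a treatment and a control condition.

`ampliconHDR` estimates these from single-orientation amplicon FASTQ reads
given (i) a locus description — wild-type amplicon, protospacer and PAM
strand, primer pair — and (ii) a donor description — ssODN sequence, strand,
homology-arm geometry, and (optionally) an explicit edit list.

## Locus model and coordinates

All coordinates are 0-based. The cut site is a *bond* index (between-base),
and edits are half-open intervals; this removes the off-by-one ambiguity
that plagues between-base features. The cut bond is placed 3 nt 5′ of the
NGG PAM on the protospacer strand — the canonical blunt SpCas9 geometry —
after requiring that the protospacer occurs exactly once on its declared
strand with an NGG immediately 3′ of it. Staggered cuts, non-NGG Cas
variants and multi-guide loci are out of scope.

Donors may be given on either strand; non-PAM-strand donors are
reverse-complemented into plus-strand amplicon coordinates before use (an
involution, tested as such), and the biotin end is carried as metadata only.
The expected HDR allele is reconstructed by applying the programmed edits to
the amplicon (`expected_hdr_allele()`). Edits may also be inferred from the
ssODN alone by anchoring its homology arms on the amplicon and diffing the
edited core against the reference span; when both are given, the explicit
declaration wins. We reconstruct the *full* edited allele rather than
pattern-matching the ssODN subsequence: the full-allele route makes
"matched the donor template" well defined even when sequencing errors or
additional indels are present, and the tolerant classification mode below
covers the cases where a subsequence match would have been more forgiving.

## Preprocessing

Four stages, in this order:

1. **Quality filter** — keep reads with mean Phred ≥ `min_mean_q`
   (default 20). The threshold itself is conventional amplicon practice; the
   pipeline's behaviour, not the exact value, is what matters downstream,
   and it is exposed.
2. **Collapse** — group identical sequences into unique sequences with
   counts (descending count, ties lexicographic, so all downstream output is
   deterministic).
3. **Frequency filter** — drop unique sequences seen fewer than `min_count`
   times (default 10, read strictly: a count of exactly 10 is kept). This is
   the classic guard against sequencing-error singletons.
4. **Target identification** — a sequence is a target when the forward
   primer matches within the first 5 nt of one end and the reverse
   complement of the reverse primer within the last 5 nt of the other
   (substitutions only, default 0 mismatches; never indels). Reverse-
   orientation matches are flipped into plus orientation, and the retained
   sequence is trimmed to the primer-to-primer span, defining the amplicon
   ends. Trimming and target identification share one pass so there is a
   single definition of the amplicon span.

Placing the frequency filter after collapsing but before target
identification follows the narrative order of the underlying protocol;
the stage thresholds are all exposed, so the alternative reading (filtering
after target identification) is a parameter change, not a code change.
Counts are conserved and logged at every stage (`stage_counts`), and the
property suite asserts the conservation identities.

## Alignment

Every surviving target sequence is globally aligned to the wild-type
amplicon (Needleman–Wunsch; three-state recurrence for affine gaps). The
default scheme — match +2, mismatch −1, gap open −6, gap extend −1 — favours
consolidated gaps, so that a biological indel is reported as one discrete
event rather than scattered single-base gaps; a linear mode (per-base gap
penalty, no opening charge) is available. Amplicons are short, so no banding
or heuristics are used, and end gaps are charged ordinary penalties because
targets are primer-trimmed to full span before alignment.

Two normalisations make event coordinates reproducible:

- **Deterministic traceback** with fixed operator priority (diagonal >
  deletion > insertion on ties), and
- **left-shifting** of every indel to its leftmost score-equivalent
  position, the standard variant-normalisation convention in homopolymer or
  repeat context.

Event extraction scans alignment columns into maximal runs of match,
mismatch, insertion and deletion, each with 0-based reference position
(bond index for insertions), length and bases. Two identities hold for
every alignment and are enforced by property tests: match + mismatch +
deletion lengths sum to the reference length, and match + mismatch +
insertion lengths to the query length. Score additivity (event-wise
recomputation equals the DP optimum) is likewise tested, and the DP score is
checked against an exhaustive enumeration of *all* global alignments for
hundreds of random short pairs — the oracle was written before the DP and
shares no code with it.

## Classification

Each target sequence receives exactly one label via a fixed decision order:

1. exact identity with the reconstructed HDR allele → **HDR**;
2. exact identity with the amplicon → **WT**;
3. otherwise align to the amplicon; in the tolerant `edits_present` mode
   (default), **HDR** when every programmed edit is reproduced by the event
   list with no other indels and at most `max_outside_mismatches` (default
   2) stray substitutions;
4. otherwise **NHEJ** when any non-programmed indel overlaps the cut-site
   bond window `[cut − window_nt, cut + window_nt]` (default half-width
   5 nt; deletions occupy their bond interval, insertions sit at one bond);
5. otherwise **AMBIGUOUS**.

Choices worth spelling out:

- *HDR before NHEJ.* A read could in principle satisfy both; precedence is
  HDR-first, matching the order in which the criteria are defined. But a
  read carrying the programmed edit *plus* an extra indel is imprecise
  (rule 3 requires "no other indels"), because precise repair means
  scarless; such reads are labelled NHEJ with `hdr_marker_present = TRUE`
  for auditing. Both audit flags (`hdr_marker_present`, `indel_in_window`)
  are populated for every read regardless of label.
- *The window is a parameter, not a truth.* Repair indels concentrate at
  the break, but no universal half-width exists; ±5 nt is the default and
  the NHEJ count is provably non-decreasing in the window (tested).
- *Substitutions never count as NHEJ by default* — indels are the
  imprecision currency of the ratio statistic; an opt-in flag treats
  in-window substitutions as NHEJ for sensitivity analysis.
- *Why a tolerant HDR mode at all?* With per-base error `e` and amplicon
  length `L`, a fraction `1 − (1 − e)^L` of genuinely edited reads carries
  at least one stray mismatch; `exact_allele` mode pushes all of them into
  AMBIGUOUS, deflating HDR% (and WT%) while leaving the ratio's numerator
  noisy. `edits_present` recovers them; the exact-mode HDR set is provably
  a subset of the tolerant-mode set (tested), and both modes are reported.

## Summaries and comparisons

Percentages are computed over *classified target reads*: ambiguous reads
stay in the denominator but join neither numerator (raw-read denominators
remain available via `stage_counts`). The HDR:indel ratio is
`reads_HDR / reads_NHEJ`, undefined — flagged, never infinite — when no NHEJ
reads exist; an optional +0.5/+0.5 pseudocount mode is off by default
because fabricating finite fold changes from zero-indel samples is worse
than declaring them undefined. Fold enrichment between conditions is the
ratio of the two ratios, with undefined flags propagating. Clonal genotype
tables (one clone, one count) flow through `summarize_sample()` unchanged,
so clone-level Sanger data and read-level deep-sequencing data use the same
statistic.

## The simulator: what it emulates, and what it does not

`simulate_sample()` emits single-orientation reads spanning the full
amplicon — the geometry of short-amplicon HiSeq/MiSeq runs — with a known
per-read truth class: WT (amplicon), HDR (reconstructed edited allele),
NHEJ (amplicon with one indel whose breakpoint lies within
`position_jitter_nt` of the cut bond), plus three nuisance classes:
off-target reads (shuffled amplicon, no primers), low-quality reads (flat
`q_low` qualities) and reverse-complemented reads. Every base then passes
through a uniform substitution-error channel. Nuisance fractions carve
their share out of the total first; the remaining mass is split across
WT/HDR/NHEJ in proportion to the configured mixture.

The default indel model is chosen once to reflect empirical SpCas9 repair
spectra at typical loci and is not a tuning knob: deletions dominate
(`p_deletion = 0.8`); deletion lengths fall off geometrically
(`del_len_geometric_p = 0.35`, capped at 25 nt) with the deleted interval
drawn uniformly among those containing the jittered cut bond (break-centred
resection); insertions are mostly the canonical +1
(`ins_len_geometric_p = 0.9`, capped at 5 nt) with uniformly random bases at
the jittered bond; breakpoints stay within ±1 nt of the cut. Qualities are
flat per read (high for normal reads, low for LOWQ reads) because the
filter under test is a mean-quality threshold, not a quality profile. Reads
default to 50,000 per sample, a repository choice for a plausible per-sample
amplicon depth rather than a published value.

Deliberately **not** simulated: paired-end reads and merging, PCR chimeras,
adapter read-through, position-dependent error profiles, compound NHEJ
events (one indel per read), and mosaic or diploid genotype structure.
Passing the simulator-based tests therefore demonstrates the pipeline's
bookkeeping and classification logic under a clean generative model — it
does not certify behaviour on real libraries with correlated errors, PCR
jackpots or heteroduplex artifacts.

## Numerical and degenerate-input conventions

- Alignment requires non-empty A/C/G/T strings (N is rejected past
  preprocessing); empty FASTQ files produce a valid all-zero summary with
  flagged undefined ratios, not an error.
- Simulation is byte-deterministic given its seed, restores the caller's
  RNG state, and the pipeline itself is randomness-free, so identical
  inputs give byte-identical FASTQ and reports (tested by checksum).
- A donor identical to the reference, overlapping edits, edits outside the
  amplicon, ambiguous guide placement (absent, duplicated, or PAM-less
  protospacer) are all rejected with named error classes
  (`donor_error`, `locus_error`).
- Unique-sequence tables are ordered by descending count then sequence;
  classification preserves input order; summaries are invariant under
  permutation of the input reads (tested).

## Test problem sizes

The suite exercises the oracle comparison on 200 random pairs of length ≤ 8
(the enumeration oracle is exponential), event conservation on 1,000 random
alignments, noise-free end-to-end recovery on 10,000 reads,
mixture-parameter recovery on 50,000 reads at 0.1% substitution error, and
fold-enrichment recovery on a 2 × 50,000-read condition pair with a true
10-fold ratio difference — sizes chosen so the whole suite runs in a few
minutes on one CPU while keeping binomial noise well inside the asserted
tolerances.

## Known limitations

- **Frequency-filter retention bias.** The `< min_count` filter interacts
  with sequencing error in a class-dependent way. At depth `N`, each
  *specific* single-error variant of an allele with mixture fraction `p`
  occurs about `N · p · e / 3` times. For an abundant wild-type allele at
  high depth this can clear the threshold (those reads survive, classified
  AMBIGUOUS, inflating the denominator), while error variants of minority
  HDR/NHEJ alleles and rare indel alleles fall below it (deflating their
  numerators). The acceptance suite documents the consequence at
  N = 50,000, e = 0.001: HDR% and the HDR:indel ratio recover within their
  tolerances, but NHEJ% is underestimated by more than its ±0.8-point band
  under the default filter — with the filter disabled the same sample
  recovers all three essentially exactly. The corresponding assertion is
  left failing rather than loosened: it is a real property of
  frequency-filtered amplicon pipelines at these settings, relevant
  whenever absolute NHEJ% (rather than the ratio) is the quantity of
  interest.
- **Zygosity is invisible.** A clone that repaired one allele by HDR and
  left the other wild type contributes wild-type reads; no second-allele
  inference is attempted.
- **Single-locus runs.** Multiplexed designs are handled by running each
  locus separately; there is no demultiplexing.
- **No significance testing.** Replicate-level statistics are outside the
  package's scope; it reports per-sample estimates and condition fold
  changes only.
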