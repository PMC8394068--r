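---
title: "Methods: scanning bivalve mitogenomes for sperm transmission elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning bivalve mitogenomes for sperm transmission elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stescan)
```

## Background and scope

Doubly uniparental inheritance (DUI) bivalves transmit two mitochondrial
genomes: a male (M) lineage through sperm and a female (F) lineage through
eggs. The sperm transmission element (STE) is a ~22 bp control-region motif
(`CCATAAATGTTTGAAAATAAGG` in the *Mytilus galloprovincialis*
recently-masculinized genome) whose protein-binding activity is thought to
protect M-type mitochondria from degradation during spermatogenesis.
`stescan` implements the computational side of the search for STE-like
signatures in other bivalves: extraction of the large unassigned region
(LUR) of an annotated mitogenome, a calibrated fixed-width sliding-window
scan, a randomization test of match significance, similarity/flank
reporting, and a neighbor-joining overview tree. Wet-lab validation (EMSAs,
DNA bending and secondary-structure prediction) is out of scope, as is
automated retrieval of public genomes: users supply annotated records, and
the synthetic-genome module stands in for them during testing.

## The sliding-window scan

Every window of the motif length $W$ (22 bp by default) along the target is
scored with an exact scheme: $S = m \cdot s_{match} + (W - m) \cdot
s_{mismatch}$, where $m$ is the count of identical unambiguous bases. No
ambiguous matching is allowed: any non-ACGT base mismatches everything.
Windows with $S \ge T_s$ are accepted; runs of mutually overlapping
accepted windows on the same strand are merged into one hit, represented by
the maximum-score window (leftmost on ties), so the hit count is the number
of distinct motif copies. The minus strand is scanned on the reverse
complement and mapped back to forward coordinates. On circular records the
first $W - 1$ bases are appended so origin-spanning windows are scored once.

The scoring values $(+5, -4)$ are the classical DNA match/mismatch scores;
under them the calibrated threshold $T_s = 56$ is exactly the $16/22$
(72.7%) identity boundary, since $16 \cdot 5 - 6 \cdot 4 = 56$, and every
score threshold corresponds to an identity threshold
$k = \lceil (T_s - W s_{mismatch}) / (s_{match} - s_{mismatch}) \rceil$.
`calibrate_threshold()` reproduces the calibration procedure: given
reference sequences with known copy numbers (three copies in the
*M. galloprovincialis* RM control region, one each in the
*M. galloprovincialis* M and *M. trossulus* M references), it evaluates the
merged-hit count at every integer threshold and returns the **largest**
threshold at which every reference yields exactly its expected count — the
conservative choice, preferring fewer, more credible matches over more
numerous dubious ones.

Tunable parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `motif` | 22 bp STE | query; window length = motif length |
| `match`, `mismatch` | +5, −4 | exact scoring scheme |
| `ts` | 56 | acceptance threshold (= 16/22 identities) |
| `strand_mode` | `both` | LUR and genome scans cover both strands |
| `min_lur_length` | 100 bp | smallest reported LUR (longest always kept) |

Two interpretation choices were genuinely open. First, whether the original
LUR screens were single- or double-stranded is not documented; we scan both
strands by default (reverse-orientation hits are reported in the reference
table) and expose `strand_mode`. Second, no rule is documented for how many
LURs per genome were assessed; `extract_lurs()` therefore reports *every*
maximal unannotated interval at least `min_lur_length` long, plus always
the single longest, which is a superset of any plausible selection and can
be filtered downstream.

## LUR extraction rules

A LUR boundary is set only by protein-coding (CDS) and rRNA features. tRNAs
are neither masked nor allowed to break an interval — a gap containing
tRNAs is one contiguous LUR. Features of uncertain annotation
(`misc_feature`, and DUI ORFs reclassified to `orf_uncertain` through an
override table) never bound LURs, mirroring cases where an F-ORF is
annotated as a miscellaneous feature rather than a gene. Internal
coordinates are 0-based half-open, with `end > length` denoting an
origin-wrapping interval on circular records; all written reports are
1-based inclusive. Ambiguous bases are kept in LUR sequence, excluded from
base-frequency denominators, and always count as mismatches when scanned —
the conservative treatment.

## The randomization test

The null question: how often would a composition-matched random sequence
contain a window as similar to the motif as the observed candidate? For a
candidate with observed percent similarity $p$ in a LUR of length $L$ with
base frequencies $\pi^* = \langle \pi_T, \pi_C, \pi_G, \pi_A \rangle$,
`mc_null_test()` generates 1000 i.i.d. random sequences of length $L$ from
$\pi^*$ (and, for comparison, from uniform frequencies), slides the 22 bp
window in the forward orientation, and counts windows with at least
$k = $ `min_matches_for_percent(p, 22)` identities. Overlapping qualifying
windows are all counted (a single replicate can contribute several), and
both the total count and the number of replicates with ≥ 1 hit are
reported; the pseudo p-value is the latter divided by the number of
replicates. Significance is flagged at raw pseudo $p \le 0.05$ with no
multiple-testing correction, matching the published convention; a
Bonferroni column is emitted alongside for transparency. The
`min_matches_for_percent()` conversion subtracts 0.05 before rounding up so
that one-decimal reported percentages map back to the intended integer
identity count (72.7% → 16/22; the footnoted 77.3% entry → 17/22).

The null scan is single-orientation: published compositions are
strand-specific (forward or reverse depending on the candidate's
orientation), so generating from the appropriate strand's frequencies and
scanning forward matches the original design. A both-strand null is
available by running the complementary composition.

### Exact analytic oracle

Under the i.i.d. base model the identity count of one window is a sum of
$W$ independent Bernoulli variables with $p_i = \pi_{b_i}$, the background
frequency of the motif base at position $i$ — a Poisson-binomial
distribution. `window_match_prob_exact()` computes $P(m \ge k)$ by dynamic
programming over the $W$ positions, exact to floating precision, and
`expected_total_hits()` applies linearity of expectation —
$n \cdot (L - W + 1) \cdot P(m \ge k)$ — which is exact despite window
overlap. Every Monte-Carlo run carries its analytic expectation, and the
test suite requires agreement within four estimated standard errors at all
19 reference operating points. The oracle is itself cross-validated against
sampled independent windows and, under uniform frequencies, against the
closed-form Binomial$(22, 1/4)$ tail. Note the analytic expectation covers
the *total* count; the distribution of "replicates with ≥ 1 hit" under
window dependence is deliberately left to the Monte-Carlo (near-match
windows cluster, so that count falls slightly below the total).

Printed reference compositions are rounded to three significant digits and
can sum to 0.999–1.001; entry points renormalize compositions within 0.005
of 1 and reject anything further off.

### Reproducibility

Every stochastic routine takes a mandatory seed. Replicate-level seeds are
drawn once from a stream keyed by the master seed, so individual replicates
can be regenerated in isolation and a run is reproducible end to end; the
caller's RNG state is always restored.

## Similarity and flank reports

Ungapped percent identity is $100 m / W$. Gapped similarity uses global
Needleman–Wunsch alignment under the scan's substitution scores with affine
gap penalties (open 10, extend 0.5, configurable); the percentage
denominator is the full alignment length *including gap columns*, so a
24-column alignment with 15 matches reads 62.5%. A pairwise global aligner
is used deliberately: every reported similarity is a pairwise percentage
against the known motif, so multiple alignment adds nothing here, though
exact column counts can differ by about one gap placement from a multiple
aligner's and gapped percentages should be read as descriptive. The 30 bp
upstream flank is taken 5′ of each hit on the hit's own strand (truncated
at linear boundaries, wrapped on circular ones) and summarized by adenine
fraction and longest adenine run — descriptive only, with no significance
test attached.

## Overview phylogeny

The taxonomic overview tree uses p-distances with pairwise deletion (sites
with a gap or ambiguity in either sequence of a pair are excluded; an error
is raised if a pair has no comparable sites) and classical neighbor-joining
with lexicographic tie-breaking, with column-bootstrap support (1000
replicates by default) expressed as integer percentages on internal nodes.
Inputs are pre-aligned sequences; alignment trimming is the caller's
responsibility via explicit coordinates. Negative NJ branch lengths are
clamped to zero with the deficit moved to the sibling edge — a display
convention that leaves path lengths approximately intact. The tree is an
overview device, not a rigorous phylogeny: no model-based distances, no
likelihood methods, and topology should be read qualitatively.

## The synthetic-genome generator

`generate_annotated_genome()` builds a circular genome from a gene template
(by default 13 protein-coding genes, 2 rRNAs and 22 tRNAs at representative
mitochondrial lengths, tRNAs interleaved between boundary genes), 20 bp
fixed low-complexity spacers between features, and a single LUR of
specified length and composition carrying planted motif copies at
controlled identity. Planted mismatch positions are drawn uniformly without
replacement and substituted bases never equal the motif base, so a planted
copy has *exactly* the requested identity; no divergence model beyond that
is attempted. The template must start and end with a boundary gene so the
LUR interval is uniquely defined, and a rotation parameter moves the origin
anywhere, including inside the LUR, to exercise circular coordinates.

What the generator emulates: LUR length and base composition at the
published operating points, annotation structure (including uncertain
features), circularity, and motif copies at known identity and strand. What
it does not: codon structure, tRNA secondary structure, strand-asymmetric
mutation, tandem repeats, or recombination/masculinization events. Passing
round-trip tests therefore demonstrates correctness of coordinates,
scanning and counting — not that real LURs are i.i.d. sequence. In
particular, real control regions contain repeats that could inflate chance
match counts relative to the i.i.d. null; the pseudo p-values share this
caveat with the original design.

## Problem sizes and runtime choices

The shipped tests reproduce the full 19-row randomization screen at 1000
replicates per run (both composition modes, ~40 s), validate planted-motif
recovery on 100 synthetic 2000 bp LURs spanning the published compositions
with copies at every identity from 14/22 to 22/22, and property-test
neighbor-joining on 100 random 5–8 taxon additive trees. The
Poisson-binomial oracle is cross-validated on 20,000 independent sampled
windows; bootstrap tests use 200 replicates. These sizes were chosen to
give comfortable statistical margins (4σ bands on totals, 3σ on
proportions) while keeping a full test run under a minute.

## Known limitations

* The scan is ungapped and fixed-width; STE homologs with indels are only
  visible through the gapped similarity report after detection, and
  extremely diverged motifs below the calibrated threshold are invisible by
  design (the threshold prefers false negatives over false positives).
* The i.i.d. null ignores repeat structure and local composition
  heterogeneity within LURs.
* Reproduction of published Monte-Carlo tables is itself stochastic: a
  fresh run matches each printed pseudo p-value only within binomial error,
  and entries whose printed values were outlying draws of their own
  1000-replicate runs (as diagnosed by the exact oracle) may sit just
  outside a 3σ band.
* GenBank parsing covers single-record flat files with standard
  LOCUS/FEATURES/ORIGIN structure and simple locations
  (`complement`, two-segment origin-spanning `join`); exotic location
  strings fall back to their outer span.
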