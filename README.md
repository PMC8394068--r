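# stescan

Detection and significance testing of sperm transmission element (STE)
motifs in bivalve mitochondrial genomes.

## The problem

Bivalves with doubly uniparental inheritance (DUI) carry two sex-associated
mitochondrial genomes: an M-type transmitted through sperm and an F-type
transmitted through eggs. A short motif in the control region of the
*Mytilus galloprovincialis* recently-masculinized genome — the 22 bp sperm
transmission element, `CCATAAATGTTTGAAAATAAGG` — binds a protein complex and
is implicated in protecting M-type mitochondria during spermatogenesis.
Searching for homologs of so short a motif across deeply diverged
mitogenomes is statistically delicate: naive searches drown in chance
matches. `stescan` provides the full in-silico workflow for this search, for
anyone screening annotated mitogenomes for short control-region signatures:

* **LUR extraction** — the large unassigned region (LUR), the longest
  stretch of a genome not covered by protein-coding or rRNA genes, is where
  control regions live. tRNAs and uncertainly annotated ORFs never bound a
  LUR; circular coordinates (origin-wrapping intervals) are handled
  throughout (`read_genbank()`, `extract_lurs()`).
* **Calibrated sliding-window scan** — every motif-length window is scored
  with an exact scheme (match +5, mismatch −4, no ambiguous matches) and
  accepted at a threshold Ts calibrated on references with known copy
  numbers; with the default Ts = 56 a 22 bp window is accepted iff it has
  ≥ 16/22 (72.7%) identities (`scan_sequence()`, `calibrate_threshold()`).
* **Monte-Carlo null model** — the significance of an observed match is the
  proportion of 1000 random sequences, matched in length and base
  composition to the LUR, containing an equal-or-better window match (the
  pseudo p-value). An exact Poisson-binomial dynamic program gives the
  analytic per-window match probability `P(identities ≥ k)` under the
  i.i.d. base model for cross-validation (`mc_null_test()`,
  `window_match_prob_exact()`, `run_table1()`).
* **Similarity and flank reports** — ungapped and global gapped percent
  identity of each candidate to the query (gap columns count against
  similarity), plus the 30 bp upstream flank with adenine statistics
  (`similarity_report()`).
* **Overview phylogeny** — neighbor-joining on p-distances with pairwise
  deletion, with column-bootstrap support (`p_distance_matrix()`,
  `neighbor_joining()`, `bootstrap_support()`).
* **Synthetic genomes with known truth** — annotated circular mitogenomes
  with a LUR of specified length/composition and planted motif copies at
  controlled identity, so the whole pipeline is testable without downloads
  (`synth_spec()`, `generate_annotated_genome()`).

`run_pipeline()` orchestrates the two-pass screen: LURs first, and any
genome with a LUR hit is automatically re-screened across its entire
circular sequence.

## Worked example

Simulate a genome whose 3590 bp LUR carries one exact motif copy and one
diverged (16/22) copy on the minus strand, recover both, and test their
significance:

```r
library(stescan)
motif <- ste_motif()

spec <- synth_spec(seed = 7, lur_length = 3590,
                   lur_freqs = c(0.282, 0.158, 0.209, 0.350),  # <T,C,G,A>
                   planted = data.frame(m = c(22, 16), strand = c("+", "-"),
                                        offset = c(500, 2100)))
sim  <- generate_annotated_genome(spec)
lurs <- extract_lurs(sim$genome)
lurs[1, c("start", "end", "length", "piT", "piC", "piG", "piA")]
#>   start   end length   piT   piC   piG   piA
#> 1 15412 19002   3590 0.274 0.155 0.213 0.357

scan_sequence(lurs$sequence[1], motif, scoring_scheme(ts = 56),
              target_id = sim$genome$id)
#>   target_id start  end strand  m score   pct
#> 1 SYNTH0001   500  522      + 22   110 100.0
#> 2 SYNTH0001  2100 2122      - 16    56  72.7

mc_null_test(L = lurs$length[1],
             freqs = as.numeric(lurs[1, c("piT", "piC", "piG", "piA")]),
             k = 16, motif = motif, seed = 42)
#> <ste_null> L=3590, k=16/22, empirical frequencies, 1000 replicates
#>   total hits: 99   seqs with >=1 hit: 94   pseudo p: 0.094
#>   analytic expected total: 76.91
```

Both planted copies are recovered at their exact positions and identities
(start is 0-based within the LUR). The null test says a 16/22 match in a
LUR of this length and composition is *not* individually compelling: ~9% of
composition-matched random sequences contain one as good, and the exact
analytic expectation (76.9 qualifying windows per 1000 replicates) agrees
with the Monte-Carlo total. An exact 22/22 copy, by contrast, has a
per-window probability of about 1e-13 under this background
(`window_match_prob_exact(motif, c(0.282, 0.158, 0.209, 0.351), 22)`).

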