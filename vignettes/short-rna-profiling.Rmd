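---
title: "Profiling unusually short RNA fragments: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling unusually short RNA fragments: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sRNAtlas)
```

## The problem

Standard sRNA-seq library preparation size-selects 16-30 nt inserts and most
annotation pipelines discard anything shorter as unmappable noise. Yet
total-RNA libraries sequenced across an extended 8-30 nt window show that the
8-15 nt range is dominated by a small number of highly recurrent fragments of
longer non-coding RNAs — rRNA-derived fragments (rRFs), tRNA-derived
fragments (tRFs), snoRNA-derived RNAs (sdRNAs), miRNA fragments and piRNA
fragments — often discrete in length and sharing a common core with short 5'
extensions. `sRNAtlas` implements the analysis side of that observation:
ingest, classification, profiling, fragment-family resolution, conservation,
and a simulator that generates ground-truthed data with the same structure.

## Unique reads and normalization

Reads identical in both sequence and length are collapsed into one *unique
read* carrying a raw count and `RPM = count / N * 1e6`, with `N` the number
of retained reads in the 8-30 nt window of that library. The denominator is
per-library, so RPM always sums to $10^6$ and window shares/biotype
percentages are exact re-partitions of it; this is asserted as an invariant
in the test suite. Diversity statistics count unique reads and are therefore
invariant to read duplication.

Adapter trimming truncates at the leftmost occurrence of the 3' adapter,
requiring at least 6 exactly matching bases of the adapter prefix when the
occurrence runs off the read end. The rule is deterministic by construction;
error-tolerant adapter matching is deliberately not offered, because a
probabilistic trimmer makes the collapse step (and hence every downstream
count) irreproducible across runs and parameter choices. Reads with no
adapter occurrence cannot be delimited — the insert was longer than the read
— and are discarded, as are adapter dimers (empty insert after trimming).
Quality filtering is concretized as mean Phred >= 20 (inclusive) and no N;
both thresholds are configurable, and FASTA input bypasses the quality test.

## The classification model

Each unique read receives exactly one biotype call through a prioritized,
two-pass search of per-biotype reference sets:

* **Pass 1 (m = 0):** biotypes are searched in priority order; the first
  biotype containing the read exactly (sense strand, substring) wins.
* **Pass 2 (m = 1):** reads unassigned after pass 1 are re-searched
  allowing one substitution. Post-transcriptional modifications misread by
  reverse transcriptase and SNPs otherwise divert genuine fragments into
  the unclassified pile.
* Reads unassigned after both passes are `undefined` — a value, not an
  error.

The two passes reconcile two requirements that look contradictory at first
sight: classification should be strict (no mismatch needed when an exact
home exists) yet tolerant (one substitution may rescue a read that would
otherwise be lost). An exact hit in a low-priority biotype therefore always
beats a one-mismatch hit in a high-priority biotype; the per-read mismatch
count is retained in the output so the strict view (exact hits only) can be
recovered by filtering.

The default order is `rRNA > tRNA > miRNA_mature > miRNA_precursor >
snoRNA > piRNA > other_ncRNA`. Only one part of it is a hard constraint,
enforced by `priority_policy()`: rRNA and tRNA must precede piRNA, because
many annotated piRNAs are themselves exact sub-sequences of tRNAs or rRNAs
and would otherwise absorb tRF/rRF reads. Whether mature or precursor miRNA
should be searched first is genuinely open; mature-first was chosen so that
a read equal to a mature miRNA is never reported as a precursor fragment,
and the order is a constructor argument for users who disagree.

Matching is substitution-only on the sense strand: no gaps, no
reverse-complement search, 0-based half-open coordinates throughout.
References containing non-ACGTU characters are excluded at load (with a
report) rather than masked, keeping Hamming semantics exact. The substring
index is built on `Biostrings` pattern matching and every hit is re-verified
by direct Hamming comparison; its contract — exhaustiveness over all
(reference, offset) pairs at m <= 1 — is tested against a brute-force
all-offsets scan on 1,000 random instances.

Call boundaries that the data alone do not fix were set as follows:

* **piRNA vs piRF:** a hit spanning the full database entry (start 0, end =
  entry length) is `piRNA`; anything shorter is a fragment, `piRF`. The
  full-span rule (rather than strict string equality) lets the pass-2
  mismatch budget apply to full-length modified piRNAs too.
* **miRNA vs miRNA_fragment:** a read >= 16 nt whose hit reaches within
  2 nt of both termini of the mature entry is `miRNA` (the isomiR
  convention); everything else, including 8-15 nt "semi-miRNA" 5'
  sub-reads, is `miRNA_fragment`.
* **Origin labels** use an end tolerance of 3 nt: dominant sdRNAs are
  reported as snoRNA 5' ends even when the first 1-3 bases are missing, so
  a fragment starting at offset <= 3 still counts as `five_prime` (and
  symmetrically for 3' ends; both together give `full_length`, else
  `middle`).
* **Ties within a biotype** resolve to the first hit in (ref_id, start)
  order; the competing hit count is kept in `n_hits` so multi-parent
  ambiguity is auditable rather than silently dropped.

## Profiling choices

Window shares split the profile at 15|16 nt — the boundary between the
unusually short window and the standard size-selection window. Biotype
composition is reported as percent of window RPM with `undefined` as its own
class; an empty window contributes no rows rather than NaN. Dominant
sequences are ranked by count with lexicographic tie-break, and their share
is percent of all reads *of that length*. Peak listing is argmax plus local
maxima with no smoothing.

Abundance heatmap values (per biotype, samples x lengths, log10 RPM) are
partitioned into three groups, relabelled high/mid/low by center. Zero-RPM
cells are masked, not pseudocounted: a zero cell means "no reads under this
condition" and belongs in the heatmap's gray boxes, while any pseudocount
would place it on the log scale at an arbitrary height that the clustering
would then organize around. The partition itself is computed by **exact 1-D
k-means**: dynamic programming over contiguous partitions of the sorted
values (the 1-D Euclidean optimum is always contiguous in value order).
This is deterministic with no seeding at all and returns the global optimum
— a quantile-seeded Lloyd iteration was considered and rejected because it
can stall in local optima on small cell sets, and determinism would then
depend on the seeding heuristic rather than on the objective. Biotypes with
fewer distinct non-masked values than k are fitted with fewer clusters and
flagged. Contiguity of the returned clusters in value order is re-checked
on every run.

## Fragment families

"Seed" grouping is concretized as substring containment seeded by the
shortest sequences: after sorting ascending by (length, lexicographic), each
unclaimed sequence founds a group and claims every unclaimed longer sequence
containing it. The seed is thus the minimal common core whenever the
shortest member is contained in all others (as in the 12/13/18/19-nt rRF
family, seed `GACTCTTAGCGG`); transitive chaining through non-substring
overlap is deliberately not performed, so a variant carrying an internal
substitution does not join a family — it surfaces instead in the near-miss
table (equal-length, cross-group pairs within Hamming distance 1),
preserving the information without guessing at family membership. Repeated
seed occurrences in a member anchor at the leftmost position, with the
multiplicity logged.

Staircase reports order members by decreasing length and flag counts above
`outlier_factor` x the group median (default 10x — "abnormally high" needs a
threshold and an order of magnitude above the ladder background is a
conservative one; the factor is configurable and echoed in the report
header). The truncation direction compares each member against the longest:
all-suffix families indicate 5'->3' loss, all-prefix families 3'->5'. The
interpretation of staircases as exonucleolytic degradation is prose, not
computation; no kinetic model is fitted.

The shared 3'-terminal motif of a family (e.g. ATGA in dominant short
sdRNAs) is reported as the most frequent terminal k-mer (default k = 4) with
its support fraction.

## Conservation

A sequence is conserved when present — exact string identity — in at least
one sample of every group, within a length window. Groups pool samples per
species: requiring presence in every individual sample would conflate
sequencing depth with conservation. The default window is 8-14 nt (the
literal reading of "shorter than 15 nt"); pass `c(8, 15)` for the full short
window. Cross-species single-mismatch matching is out of scope — the
comparison is of sequences, not homology. Biotype calls may disagree between
species (different reference sets); the first group's call is reported and
disagreements are logged.

## The simulator

The generator emulates the fragment structure the analysis targets, not
sequencing chemistry. Reads are drawn multinomially from weighted events on
seeded random references:

* **discrete** events emit one fixed parent interval — recurrent fragments
  of discrete length;
* **full_length** events emit the whole entry — mature miRNAs and piRNAs;
* **ladder** events emit lengths `min_len..max_len` anchored at one end
  with weight proportional to `decay^(max_len - len)` — degradation
  staircases.

Substitution errors are applied per base at rate epsilon to the insert only,
never to the adapter, so trimming stays deterministic and classification
accuracy can be studied in isolation; adapter-error robustness is explicitly
not simulated, nor are quality-score errors, ligation bias or
modification-dependent RT bias — all real features of sRNA-seq data that
passing tests therefore say nothing about. Reads are padded with random
bases and truncated to 51 cycles at constant Q40, the single-end geometry
under which with a 21-nt adapter every 8-30 nt insert leaves the full
adapter visible. A rejection step regenerates the references until no
emitted fragment occurs exactly in a reference of equal or higher priority
than its parent's (and no planted core occurs where it was not planted),
which guarantees that at epsilon = 0 every read classifies to its intended
biotype — making "100% recovery" a meaningful end-to-end assertion rather
than a statistical accident. The draw order (events, then ladder lengths,
then errors, then padding) is fixed, so a seed reproduces the FASTQ byte for
byte.

`table_scenario()` is the canned configuration used throughout the tests:
a 160-nt rRNA carrying the nested 12/13/18/19-nt family (5' extensions C /
TCGTAC / CTCGTAC, weights 0.18/0.22/0.13/0.04), a tRNA whose 5' 18-mer
`GCATTGGTGGTTCAGTGG` is also present verbatim as a piRNA entry (weight
0.12), a full-length 22-nt miRNA (0.10) and 28-nt piRNA (0.06), a 12-nt
snoRNA 5' fragment ending in ATGA (0.05), and a 3'-anchored background
ladder on a second rRNA (0.10, lengths 8-20, decay 0.55). The weights were
fixed once so that the dominant 12-mer owns most of its length stratum and
roughly half the abundance falls below 16 nt, the regime reported for
bilaterian total-RNA libraries.

## Problem sizes and numerical notes

The test suite simulates 50,000 reads for end-to-end recovery and
3-sigma-bound checks on window shares, biotype composition and dominant
shares (binomial standard errors at that depth are ~0.2-0.7 percentage
points), 1,000 random instances for index-oracle equivalence, 500 for
classifier-oracle equivalence, and 100 instances of n <= 12 for the k-means
optimum check; these sizes make the whole suite run in about two minutes on
one core. Expected values for the stochastic checks come from
`expected_spectrum()`, the analytic per-(event, length) distribution implied
by the configuration — never from the observed data being tested.

Floating-point tolerances: RPM conservation is asserted at 1e-6 relative;
k-means objective equality at 1e-9 absolute. All coordinates are 0-based
half-open internally; report writers that render 1-based labels must say so
in their headers.

## Known limitations

* Classification is reference-database-bound: fragment calls inherit the
  completeness and version of the supplied FASTA sets, and `undefined`
  mixes genuinely novel sequences with database gaps.
* One substitution maximum, substitutions only: indel-bearing reads and
  heavily modified reads (> 1 misread base) end up `undefined`.
* No tRF sub-nomenclature (tRF-5a/5b, tiRNA halves) — origin labels stay at
  the 5'/3'/middle/full-length level.
* No differential abundance between samples; all statistics are
  descriptive.
* The simulator's uniform-random references lack the base composition,
  secondary structure and paralogy of real rRNA/tRNA space; recovery rates
  on it bound what the code can do, not what real libraries will yield.
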