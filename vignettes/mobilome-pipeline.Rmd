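---
title: "Methods: eccDNA detection, LTR dating and the TIP landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eccDNA detection, LTR dating and the TIP landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobilomekit)
```

# Scope

`mobilomekit` implements the bespoke computations of a mobilome analysis
of active LTR retrotransposons (RTEs): which elements produce
extrachromosomal circular DNA (eccDNA) under stress, how old each intact
element is, how LTR sequences group into families, how insertion
polymorphisms (TIPs) distribute over chromosome compartments and genes
across an accession panel, and whether a family conserves an additional
ORF (aORF) beyond GAG/POL.  Everything upstream of these computations —
basecalling, read alignment, TE annotation, split-read TIP calling — is
consumed as standard-format input (FASTA/GFF3/BED/TSV), not
re-implemented.  A seeded synthetic-data generator emulates all of those
inputs with known truth, so the full pipeline runs and is tested at desk
scale.

# eccDNA enrichment testing

Mobilome-Seq compares a Plasmid-Safe-digested library (PS+), in which
linear DNA is degraded and circular DNA survives, against an untreated
control (PS−).  For each element we form the 2×2 table

|            | PS+                   | PS−                    |
|------------|-----------------------|------------------------|
| on element | $a$                   | $c$                    |
| rest       | $N_+ - a$             | $N_- - c$              |

where $N_\pm$ are library totals, and compute the two-sided Fisher exact
p-value: conditioning on all margins, the first cell is hypergeometric,
and the p-value sums the probabilities of all tables whose point
probability does not exceed the observed one (relative tie tolerance
$10^{-7}$).  Elements pass at raw $p < 0.01$ — no multiple-testing
correction, mirroring a raw-cutoff screen; a Benjamini–Hochberg option
exists but is off by default.

Two curation rules are applied on top of the p-value.  First, the
original screen's manual "uniform coverage" curation is operationalised
as a breadth filter: the fraction of element positions covered by at
least one PS+ read must reach `breadth_min` (default 0.8).  When no
coverage information is supplied the filter is recorded as unapplied
rather than silently passed.  Second, the PS+ proportion must exceed the
PS− proportion: eccDNA is *enriched* by digestion, so significant
depletion must not pass.  The empty table (0,0,0,0) returns $p = 1$ with
a warning instead of aborting the pipeline on unannotated elements.
The element-versus-rest table construction is this package's choice of
differential-enrichment proxy; the odds ratio reported is the
0.5-corrected sample estimate, flagged as such in the output metadata.

# LTR insertion dating

The two LTRs of an element are identical on insertion and diverge with
age.  Each pair is globally aligned (Needleman–Wunsch, affine gaps,
defaults match +1 / mismatch −1 / gap open −2 / gap extend −1, where a
length-$L$ gap run costs $open + (L-1)\,extend$).  Traceback in the
underlying engine is deterministic, so outputs are byte-stable.  A flag
accepts pre-aligned pairs so an external aligner can be mirrored
exactly.

Columns with a gap or an `N` in either row are excluded from the
comparable sites — the K2P model is defined on substitutions only, and
the generator plants no indels, so this choice keeps truth exact.
Transition ($P$) and transversion ($Q$) proportions feed the Kimura
two-parameter distance

$$K = -\tfrac{1}{2}\ln\!\big((1-2P-Q)\sqrt{1-2Q}\big),$$

whose domain requires $1-2P-Q > 0$ and $1-2Q > 0$; outside it (saturated
divergence) the element is reported by name in an explicit error rather
than silently clamped.  Age follows as $T = K/(2r)$ with
$r = 10^{-8}$ substitutions/site/year by default (overridable), reported
in Mya.  Terminal TG/CA motifs are not trimmed; the LTR intervals are
taken as annotated.

```{r}
k2p_distance(0.1, 0.05)
insertion_time(0.02, r = 1e-8)   # Mya
```

# Family assignment and consensus

Families follow the 80-80-80 rule: a query belongs to a family when its
best database hit has ≥80% identity over ≥80% of the query's length and
the query is ≥80 bp.  Identity is computed over the aligned region
(columns where both rows carry a base); coverage is the fraction of the
query inside that region.  Ties between database hits break by longer
aligned region, then lexicographic family id, so assignment is
order-invariant.  Sub-threshold queries return a reason code
(`query_too_short`, `identity_below_threshold`,
`coverage_below_threshold`) instead of an error.

Clustering to the family level uses deterministic greedy centroid
clustering at the same 0.80 identity threshold: sequences are visited
longest-first (ties by name) and join the first centroid they match,
else found a new cluster.  This replaces an external mean-shift
clusterer while preserving the 0.80 semantics, and a hook accepts
pre-computed cluster files.  Within-cluster multiple alignment is a star
alignment against the centroid — adequate for the near-identical
within-family sequences it is applied to, not a general MSA; external
alignments can be imported.  Consensus is majority-rule: per column the
most frequent symbol is emitted if its fraction reaches the threshold
(default 0.7, mirroring the convention of the eponymous consensus
function in common use), else `N`/`X`; gap-majority columns emit a gap
that is stripped from the ungapped consensus.  Ties among equally
frequent symbols break alphabetically, for determinism.

# Centromeres, compartments and TIPs

Centromeres are called from the density of centromere-specific repeat
hits: hits at **strictly more than** 70% similarity are counted into
100-kb windows by their midpoints, windows with **strictly more than**
6 hits are flagged, and adjacent flagged windows merge into the
centromere.  Both strict inequalities follow the prose of the original
rule ("more than 70%", "more than 6").  Midpoint counting (rather than
any-overlap) is this package's stated choice.  The pericentromere is
10% of the chromosome length, split 5% on each side of the centromere
and truncated at chromosome ends; the symmetric split is a design
choice where the source rule says only "on both sides".  If several
flagged runs exist, all are kept as centromeric (a `largest_only`
option restricts to the longest run); chromosomes with no flagged
window are labelled entirely arm, with a warning.  The three
compartments are disjoint and tile each chromosome exactly — a tested
invariant.

TIPs are filtered to **strictly more than** 5 supporting reads, then
classified: compartment by half-open `[start, end)` point-in-interval
lookup, genic context as lying within a gene body (full annotated span,
introns included) extended ±2000 bp.  All coordinates are BED-style
0-based half-open; GFF3 is converted on read.  Sharing spectra count
the accessions carrying each TIP; group summaries report per-accession
TIP counts as mean ± sample sd and compare groups with two-sided
Welch (unequal-variance) t-tests — the unequal-variance form is chosen
deliberately where the source says only "t-test" — starred at 0.05,
0.01, 0.001 and 0.0001.

# ORF discovery and aORF surveys

`find_orfs()` scans all six frames; an ORF runs from a start codon to
the first in-frame stop, with the stop codon inside the coordinate span
but excluded from the protein.  The minimum length default of 300 is in
**nucleotides** (≥99 codons plus stop), matching the convention of the
ORF finder whose options it mirrors; shorter aORFs (e.g. a 70-aa
protein, 210 nt) require lowering `min_length` explicitly.  Per frame
segment the maximal ORF (first eligible ATG) is reported;
`require_atg = FALSE` opens ORFs at any non-stop codon, and unterminated
ORFs at sequence ends are reported only with `include_partial = TRUE`,
flagged.  `remove_nested_orfs()` drops any ORF whose interval is
contained in a retained same-strand ORF, resolved longest-first (ties
by start, then frame); opposite strands never mask each other.

The family survey replaces a BLASTP search with Smith–Waterman local
alignment under BLOSUM62 (gap open −11, extend −1).  A member carries
the aORF when **any** of its predicted ORFs reaches both thresholds —
identity over the aligned region and coverage of the reference protein,
both defaulting to 50% since the source states none.  Ranking by "any
passing hit first" matters: a chance 3-residue perfect local alignment
scores 100% identity at ~2% coverage and must not shadow the real hit.

# The synthetic generator: what it emulates, and what not

The generator's defaults are the emulated study conditions, chosen once:

* **Genome** — 2 chromosomes × 10 Mb with a 20% centromeric block
  placed away from the ends. Real sunflower chromosomes are ~20× larger
  with comparably dominant pericentromeres; 10 Mb keeps every stage
  seconds-fast while leaving ≥100 windows per chromosome.
* **Elements** — 20 planted RTEs, 1-kb LTRs around a 3-kb internal
  region, LTR pair divergences 0.01–0.10 substitutions/site at
  transition:transversion odds κ = 2 (a typical plant nuclear bias).
* **Divergence semantics** — `divergence` is the K2P model distance:
  each copy evolves for half of it under the exact K2P transition
  matrix, with no indels.  The K2P estimator is therefore consistent
  for the configured value, and the realized raw difference fraction is
  slightly *below* the distance (multiple hits), e.g. 0.0388 at
  distance 0.04 — the generator's bookkeeping and the closed form agree,
  and tests check realized differences against the closed form, not
  against the distance.  κ is the ts:tv odds per substitution event
  (transition probability κ/(κ+1)), recorded in the output metadata.
* **eccDNA counts** — Poisson background of 50 reads per element per
  library; truly circular elements (20% of elements) draw PS+ at 20×
  background, matching the ~20-fold enrichment observed at a known
  circular locus.  Coverage breadth is a deterministic read-occupancy
  proxy (each read covers ~5% of the element).
* **Repeat-hit track** — Poisson point hits at 30/100 kb inside the
  true centromere versus 0.5/100 kb on arms (similarity 75–100%), plus
  a 2/100 kb low-similarity (40–70%) background that the similarity
  filter must discard.  Hits are point intervals, not repeat sequences:
  the centromere caller only consumes positions.
* **TIPs** — 1000 TIPs in three groups; groups 1 and 3 fall in the
  centromere/pericentromere with probability 0.8, group 2 with 0.1.
  A TIP is carried by 1–2 accessions with probability 0.85 (else
  uniformly by 3–12 of the 12-accession panel), and support reads are
  negative-binomial with mass straddling the >5 filter.
* **aORF family** — 523 members, exactly 500 carriers, a planted
  151-aa proline-rich (24 P, 15.9%) reference protein
  reverse-translated into an ATG…TAA cassette inside random flanks.
  Carriers receive codon-level substitution noise that never creates a
  stop, so the planted reading frame always survives; non-carriers have
  the cassette replaced by random sequence of equal length.

What the generator does **not** emulate: nanopore read-level error,
basecalling artifacts, nested/fragmented elements, indel evolution in
LTRs (a deliberate default — it keeps alignment-free truth exact),
reference-genome repeat structure, or linkage between accessions.
Passing tests therefore demonstrate the correctness and calibration of
the *computations* under their stated models, not performance on real
sequencing data.

# Numerical choices and degenerate inputs

* Fisher tie comparison uses relative tolerance $10^{-7}$; the test
  suite checks equality with an independent log-binomial enumeration to
  $10^{-9}$ relative error over every table with $N \le 40$.
* The aligner validates |gap open| ≥ |gap extend| and rejects empty or
  non-ACGTN input; `N` scores 0 against everything so ambiguity neither
  attracts nor repels the traceback.
* `enrichment_ratio(x, 0)` returns `Inf` as an explicit sentinel (and 0
  for 0/0); saturated K2P inputs raise a named error; empty TIP tables
  and empty ORF sets return empty results, not errors.
* Determinism: every stochastic generator takes a seed; identical
  config + seed reproduces files byte-for-byte (hash-tested), and all
  tie-breaks (alignment traceback, cluster founding order, consensus
  symbols, best-hit selection) are fixed.

# Problem sizes

The test suite and the acceptance script run, per invocation: the full
Fisher enumeration to $N = 40$; 20 × 500 null elements and 500 elements
at 20× enrichment for the detector's operating characteristics; 100
1-kb LTR pairs per divergence level for dating recovery; 20 seeded
repeat-hit tracks on a 10-Mb chromosome for centromere recovery; 1000
TIPs for the sharing spectrum; and the 523-member aORF survey.  These
sizes were chosen as the smallest at which each statistical check is
decisive (3-standard-error bands, binomial tolerances) while the whole
pipeline stays in the tens of seconds.

# Known limitations

* The greedy clusterer is order-deterministic but, like all greedy
  centroid methods, can split a family whose diameter exceeds the
  threshold even when consecutive members are within it.
* The star MSA assumes the centroid is representative; highly gapped
  families should be aligned externally and imported.
* Fisher element-versus-rest tables across elements share library
  totals, so per-element tests are not strictly independent; the
  type-I simulation covers the regime used here.
* Welch t-tests on per-accession counts treat accessions as
  exchangeable replicates; population structure is not modelled.
* The breadth filter is a proxy for visual uniform-coverage curation;
  it cannot distinguish one-end pileups from genuine circle coverage
  at equal breadth.
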