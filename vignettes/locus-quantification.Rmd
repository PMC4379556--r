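---
title: "Locus-resolution ERV quantification: models, parameters and design"
author: "hervloci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locus-resolution ERV quantification: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the models it
implements, the assumptions behind them, the parameters that matter, and the
design choices made where more than one defensible option existed.

```{r setup, message = FALSE}
library(hervloci)
```

## 1. The quantification model

The analysis treats each catalogued element — provirus, solo LTR,
fragmentary LTR or host-gene decoy — as an independent reference
"chromosome". Alignment is ungapped and complete: every location at which a
read pair fits with at most `max_mm` mismatches per mate (default 2,
matching common short-read aligner settings) is enumerated, with
concordance defined as same element, opposite strands, FR orientation, and
an implied insert inside configured bounds. A pair is *unique* only when
exactly one concordant location exists within the budget — not merely one
*best* location. A pair with a perfect hit at one locus and a 2-mismatch
hit at another is multi-mapped: between near-identical paralogs a secondary
hit two mismatches away is exactly the false-assignment risk the unique
filter exists to remove. Unique pairs carry MAPQ 50 and multi-mapped pairs
MAPQ 1, so unique-only filtering downstream is literally a `MAPQ >= 50`
filter on the SAM output.

Fragment mass per element is computed three ways:

* **unfiltered_uniform** — each pair contributes $1/k$ to each of its $k$
  locations (a pair with five locations gives each 20 % of a fragment);
* **unique_only** — multi-mapped pairs are discarded;
* **em_rescue** — starting from the uniform allocation, each multi-mapped
  pair is reallocated across its locations proportionally to current
  per-base abundance $c_i/L_i$, iterating until the largest relative change
  falls below $10^{-6}$ (or 200 iterations). This is the EM algorithm for a
  multinomial mixture in which a fragment picks an element with probability
  $\pi_i$ and a uniform position within it, so the observed-data likelihood
  is non-decreasing; a test verifies the monotonicity on simulated data.

FPKM divides by the **full element length**: elements (~9.5 kb) far exceed
the insert (~180–200 b), so an effective-length correction would be a
uniform ≤2 % shift; leaving it out keeps the abundance definition exactly
(fragments × 10⁹)/(length × total mapped pairs). The per-million
denominator $N$ is the run's total concordantly aligned pair count and is
**identical across modes**. This matters: if unique-only quantification
renormalised by its own (smaller) mapped count, a catalogue of two
identical duplicates would show no loss at all under unique filtering —
the signature the mappability analysis exists to measure would cancel out
of the ratio. Relative abundance normalises FPKM over provirus elements
only; solo LTRs and host decoys receive FPKM but do not enter the family
denominator.

Junction-spanning (spliced) reads are recovered by a separate single-split
aligner and feed mechanism classification as junction evidence; they are
not added to fragment counts. They are a small fraction of any library,
and element-level abundance is insensitive to them at the depths used here.

## 2. The mappability simulation

Unique-only filtering buys specificity at the price of underrepresenting
young, near-identical loci. The simulation quantifies that price: every
provirus is sequenced uniformly to the same depth (default 20X, 250-b
paired, error-free), the pool is re-aligned, and expression computed both
unfiltered and unique-only. Because all elements are equally represented,
the *mean unfiltered FPKM* is the natural comparator, and
$u_i = 1 - F^{unq}_i/\bar F^{unf}$ is the fraction of locus $i$'s signal
lost to filtering; $u > 0.15$ flags the locus. A per-element variant
$u'_i = 1 - F^{unq}_i/F^{unf}_i$ is emitted alongside because the global
mean can over/undershoot per-element loss when lengths differ (type-1
elements are 292 bp shorter).

Simulation is error-free by default so mappability is isolated from
sequencing error; an `error_rate` argument exists for sensitivity analysis.
For two paralogs at per-site divergence $d$, a read of length $L$ from one
maps onto the other exactly when it covers at most `max_mm` diagnostic
sites, so the expected single-end loss is $P(\mathrm{Binom}(L, d) \le
m)$ — which reduces to the zero-diagnostic-site form $(1-d)^L$ when the
cross-mapping budget is 0. Both forms are verified against simulation in
the test suite. Reads are simulated from, and re-aligned to, the provirus
set itself; including the solo LTRs in the re-alignment reference would
additionally charge every provirus LTR with solo-LTR ambiguity, which is a
different question from inter-provirus mappability.

## 3. The synthetic family: what it emulates, and what it does not

No raw sequencing data accompany the study conditions this package
emulates, so validation rests on a generator whose statistical structure
matches the family being modelled:

* a 9.5-kb ancestor with 968-bp LTRs (U3 1–792, R 793–870, U5 871–968; the
  transcription start at the U3–R border, position 793, and an alternative
  start at 826 inside R), a 192-bp gag leader, and intact ORFs sized so gag
  encodes 666 aa (gag 2001, pro 900, pol 2700, env 1740 nt);
* the eight canonical promoter motifs planted at their canonical LTR
  positions (GA 379–386 `GGGAAGGG`; E boxes 465–476 `TTGCAGTTGAGA`,
  485–496 `AGGCATCTGTCT`, 832–843 `CTCCATATGCTG`; GC boxes 602–606
  `GGCGG`, 759–763 `CCCCC`; TATA 790–797 `AATAAATA`; Inr 807–812
  `CTCAGA`);
* twelve descendant proviruses on a divergence gradient from 0.002
  (recently integrated, human-specific-like) to 0.08 (old 5B-like), one
  *identical* post-integration duplicate pair, three type-1 members
  carrying the 292-bp pol–env deletion, two solo-LTR recombinants (donor
  5'-LTR U3+R fused to 3'-LTR U5, the structure LTR–LTR recombination
  leaves), and one member hypermutated by replacing 30 % of plus-strand G
  with A — the strand-biased signature that produces long branches in
  trees without modelling editing context.

Substitutions are uniform over positions and target bases
(Jukes–Cantor-like); there are **no indels** except the engineered deletion
and the solo-LTR fusion. That choice keeps every alignment gap-free (so the
ungapped aligner and the brute-force oracle are exact), keeps p-distances
interpretable, and gives a natural multiple alignment for the phylogeny
module. Real ERV families contain indels, target-site duplications,
internal recombinants and CpG-biased mutation; none of those are modelled,
so green tests here certify the *pipeline*, not robustness to every real
mutational process. Ages are expressed directly as divergence proportions;
no molecular-clock calibration to Mya is attempted.

Two sequence positions are treated as conserved rather than mutable: the
splice-acceptor AG at gag-leader positions 1016–1017 (re-planted after
mutation in every descendant) and, in the chimera scenario's upstream
fragment, the donor GT after position 1074. Splice sites are under strong
constraint in functional transcripts; fixing them guarantees the engineered
chimeric junction always obeys GT..AG regardless of the divergence draw.

The type-1 deletion is **centred on** the annotated pol–env boundary
(removing the 3' end of pol and the 5' start of env) rather than starting
at it. The real type-1 lesion spans the boundary, and centring is also what
makes the classifier's reference-window scheme coherent: a 600-bp boundary
window must retain ≥40 bp of alignable flank on both sides of the deleted
region for anchor placement.

### Host contexts and truth profiles

Each element can be embedded in one of six host-context scenarios, which
map to transcription-mechanism truths:

| scenario | mechanism truth | emulates |
|---|---|---|
| isolated | ltr_driven | a provirus alone in its locus |
| divergent_neighbor_gene | ltr_driven (+ separate neighbor transcript) | an LTR-driven provirus downstream of a divergently transcribed gene |
| upstream_neighbor_gene | read_through | a same-sense neighbor reading through into the element |
| intronic | intronic_passenger | a provirus retained in a host intron, covered as pre-mRNA |
| upstream_fragmentary_ltr | upstream_ltr_chimeric | a fragmentary LTR 551 bp upstream starting mid-R (826) and splicing its leader (donor after 1074) into the element leader (acceptor 1018) |
| antisense_neighbor | antisense | a downstream element driving minus-strand transcription across the provirus |

The scenario list extends the minimal set by `upstream_neighbor_gene`: a
read-through truth (neighbor + flank + element on one strand) cannot be
generated from an opposite-sense neighbor, and the classifier needs at
least one locus whose upstream flank is covered on the *same* strand.

The truth profile assigns each transcript a molar fraction per sample.
Virion fractions reweight cell fractions by a per-element packaging
efficiency — a free parameter, defaulting to high for young loci, low for
old ones and zero for one old locus, because the biological determinant of
packaging (plausibly a 5'-leader signal) is hypothesised but not
established; the package deliberately does not pretend to compute it from
sequence. Neighbor/host transcripts are packaged non-specifically at 5 %
efficiency, emulating background packaging of abundant cellular mRNA.

`expectedAbundance()` converts molar fractions into the quantifier's
abundance scale (fraction × transcript length / element length,
renormalised over proviruses). It uses the full transcript length, which
for transcripts extending into host flanks (read-through, intronic)
slightly overstates the element-resident signal; recovery tests therefore
use element-resident (LTR-driven) truths, and cross-sample comparisons use
it only for signs and ranks.

## 4. Read simulation and trimming

Libraries default to 250-b paired reads. Insert sizes are normal, truncated
to the published ranges: mean 180, range 98–522 (cell library, stranded)
and mean 200, range 100–568 (virion library, unstranded — its preparation
chemistry erases strand marks, so antisense calls are impossible for that
sample and the classifier says so). The SDs (65 and 75) are not published
quantities; they were fixed once so the stated ranges sit 4–5 SD from the
mean. Strandedness follows the dUTP fr-firststrand convention: mate 2
carries transcript sense, so the aligner infers transcript strand as mate
2's alignment strand. Fragments are allocated to transcripts by a
multinomial over molar fraction × length — the length weighting that makes
FPKM recover molar fraction. Errors are i.i.d. substitutions (default
0.005/base; the aligner is ungapped so indel errors are out of model), with
reduced base quality at error positions.

Trimming is a fixed, simple policy — exact ≥10-bp 3' adapter overlap, 4-base
sliding-window mean quality < 25 truncation, both mates ≥ 100 bases or the
pair is dropped — not a re-implementation of any particular trimming tool,
whose full parameter sets are tool-specific.

## 5. Mechanism classification

Classification works on strand-aware per-base coverage of each element and
its flanks (default 2000 bp), built from fragment spans with 1/k weighting,
or from unique pairs only (`unique_only = TRUE`, used by the pipeline: for
a young element the two near-identical LTRs otherwise exchange multi-mapped
reads and smear coverage into the U3 of the 5' LTR, corrupting TSS
estimates). The decision sequence, with all thresholds exposed in
`mechanismThresholds()`:

1. **silent** — mean element depth < 0.1 (the only absolute threshold; all
   others are ratios, so classification is invariant to depth scaling);
2. **antisense** — minus-strand fraction > 0.8 (stranded data only);
3. **upstream_ltr_chimeric** — ≥ 2 spliced reads whose donor lies upstream
   of the element and acceptor inside its leader;
4. **intronic_passenger** — both flanks ≥ 0.5× element mean depth on the
   dominant strand;
5. **read_through** — upstream flank ≥ 0.5× element mean;
6. **ltr_driven** otherwise, with TSS = first position whose cumulative 5'
   depth exceeds 10 % of the coverage plateau (90th percentile of element
   depth). The cumulative rule is robust at realistic depths; a pointwise
   rule wanders tens of bases downstream at sparse coverage.

The intronic test is evaluated *before* read-through although it is the
stronger condition: read-through's condition (upstream covered) is a strict
subset of intronic's (both flanks covered), so the opposite order could
never produce an intronic call. The original classification this emulates
was done by visual inspection; every threshold here is a package decision,
stated and configurable. Loci in mixed states (e.g. antisense signal plus
elevated sense coverage) receive a single label plus the underlying
metrics, not a mixture.

## 6. Phylogenetics

Distances are p-distances (proportion of differing sites) under pairwise
deletion — for each pair, all sites where neither sequence has a gap or N.
Trees are Saitou–Nei neighbor joining with negative branch lengths clamped
to zero; bootstrap support resamples alignment columns with replacement
(default 1000 replicates) and reports the percentage of replicates
containing each original bipartition. Input must be pre-aligned; for
synthetic families the substitution-only evolution makes the sequences
natively aligned. Standard implementations (`ape`) perform the distance and
NJ computations behind this module's interface; correctness tests use
independent oracles (hand-counted distances, additive matrices built from
known trees) rather than comparing the library with itself.

## 7. Enrichment bookkeeping

Virion/cell ratios use raw abundances when both samples detect a locus; a
locus undetected in one sample is floored at 0.01 % for the ratio and
flagged `cell_only`/`virion_only`. The similar band is [0.5, 2.0] — a
package decision; the emulated analysis sorted loci into
increased/decreased/similar panels without stating a cutoff. Fold text
truncates to an integer at ≥10-fold (25.32 %/0.38 % → "66-fold decrease"; a
nearest-integer rule would print 67 and contradict the published phrasing)
and gives one decimal below 10-fold. Exact ratios are always emitted
alongside the text. No significance testing is attempted: the design has no
replicates, and inventing a test would lend false precision.

## 8. Numerical and bookkeeping choices

* Counting and EM run over *equivalence classes* (pairs sharing a multiset
  of elements), with each class's allocation vector forced to sum exactly
  to its pair count; mass conservation then holds to ~10⁻¹² even at 2×10⁵
  pairs. The forcing can perturb the converged EM likelihood in the tenth
  significant digit, which is why the monotonicity test carries a 10⁻⁴
  slack.
* Index seeds are 2-bit packed (≤31 nt, default 25). Pigeonhole
  completeness needs only `max_mm + 1` disjoint seeds per query, which a
  25-nt seed satisfies for reads ≥75 nt at the default budget; equivalence
  with brute-force enumeration is tested directly on random instances.
* N bases never match anything (including N), i.e. they always count as
  mismatches — simple and conservative for quantification.
* Anchors for type classification are 40 bp with up to 30 % mismatches,
  placed by exhaustive best-match scan; the deletion-length windows are
  [250, 330] for type 1 (centred on 292, tolerant of flank
  micro-variation) and [−10, 10] for type 2. The exact inferred length is
  always reported next to the class.
* Ties: motif scanning prefers fewer mismatches, then smaller displacement
  from the canonical position; spliced alignment prefers fewer total
  mismatches, then GT–AG junctions.
* All randomness is seeded through `withr::with_seed`; the pipeline derives
  per-stage seeds from one master seed, and reruns are byte-identical.

## 9. Problem sizes

The shipped validation uses a 12-provirus family (plus two solo LTRs):
EM-recovery checks run at 2×10⁵ read pairs, where multinomial noise on a
percentage-scale abundance is ≈0.1 pp against a ±2 pp acceptance band;
mechanism classification uses five scenario loci at ≥800 aligned fragments
each; brute-force aligner equivalence uses 20 random catalogues × 200
reads; bootstrap checks use 200 replicates; end-to-end determinism runs the
full pipeline twice at 5×10³ pairs per sample, depth being irrelevant to
byte-identity. These sizes are the package's validation design: large
enough that the statistical assertions are sharp, small enough to run
routinely.

## 10. Known limitations

* Ungapped alignment: real indel variation between a sample and the
  catalogue would shift, not just mismatch, reads. The model is exact for
  the generator's substitution-only evolution.
* Identical duplicates are fundamentally unresolvable: EM preserves their
  initialisation split (~50/50) and unique-only sees nothing; both are
  reported, neither is "corrected".
* Isoform structure within an element is not deconvolved; abundance is
  element-level.
* `expectedAbundance()` treats flank-extending transcripts approximately
  (see §3).
* The packaging efficiency is an input, not an inference; the package
  measures enrichment, it does not explain it.
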