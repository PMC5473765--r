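---
title: "Methods: LTR retrotransposon detection, dating, and abundance"
author: "retrochrono developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LTR retrotransposon detection, dating, and abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

LTR retrotransposons replicate by reverse transcription and insert as a
unit flanked by two long terminal repeats (LTRs) and a 4–6 bp target-site
duplication (TSD) of the host sequence. Two biological facts drive
everything in this package:

1. **The two LTRs of an element are identical at insertion.** Their
   subsequent divergence $K$ is therefore a molecular clock: with a
   per-site per-year substitution rate $r$ on each LTR, the insertion age
   is $T = K/(2r)$. The default rate is $r = 1.3\times10^{-8}$, the
   standard value for rice LTR sequences.
2. **The pol domain order separates the superfamilies.** Ty1-*copia*
   elements carry PR–IN–RT, Ty3-*gypsy* PR–RT–IN; elements without a
   recognizable pol complement are *unclassified* (many are
   nonautonomous).

Around these two facts the package implements the full analysis chain:
structural detection of intact elements, superfamily classification,
family clustering on 5′-LTR identity, insertion dating, neighbor-joining
phylogenies of RT domains, and a short-read depth proxy for family copy
number. Every stage is validated on synthetic genomes whose planted
elements have known family, age, strand, state, and coordinates.

# The synthetic world

`build_genome()` plants elements into an i.i.d. random background. Its
defaults *are* the stated world of the validation suite, chosen once:

* **Aging** applies the exact Jukes–Cantor transition kernel
  independently to each LTR (and the internal region) for $d = r\,T$
  expected substitutions per site. The observed LTR-pair mismatch
  proportion then has expectation $\tfrac34(1 - e^{-8rT/3})$, and the JC
  correction $K = -\tfrac34\ln(1-\tfrac43 p)$ recovers $2rT$ without
  bias — this is why the end-to-end age-recovery regression is expected
  to have slope 1. No indels are introduced by default; the generator
  makes no claim to model the indel dynamics of real decay.
* **TSDs** are 4–6 random bases duplicated exactly on both flanks.
  Solo LTRs (unequal-recombination products) keep *both* host TSD
  copies, which is what their detection rests on. Fragments lose a
  uniform 40–90% internal span, most of one LTR (5–20% kept) and that
  flank's TSD — otherwise a "fragment" with two complete LTR ends would,
  by definition, be intact.
* **Strands** are sampled at 50% minus by default; minus-strand copies
  are reverse-complemented in place with the TSD flanks unchanged.
* **Domains**: each genome draws ancestral GAG/PR/IN/RT proteins
  (100/60/90/120 aa), each family diverges them by 15% amino-acid
  replacement, and the coding sequences are embedded in the internal
  region in the superfamily's canonical order with random synonymous
  codons. `domain_references()` exposes the planted proteins as the
  reference set; the package deliberately bundles no curated profile
  database, so real-data runs must supply their own references.
* **Reads**: exact `coverage × L / (2 × read_length)` pairs, uniform
  fragment starts, normal insert sizes (300 ± 20), per-base substitution
  errors only, constant qualities.

What a green test does *not* establish: performance on nested, indel-rich,
or low-complexity repeat landscapes; detection of ancient (> ~10 MY)
copies; correctness of the progressive aligner on gappy RT sets (planted
RTs are gap-free).

# Detection

`find_intact_elements()` is a seed–chain–extend detector: exact 20-mer
seeds are paired at separations compatible with the element length
bounds, chained on common diagonals, and extended by ungapped x-drop
(+1/−3, drop 15) to delimit the two repeat copies. Boundaries are then
refined to the offsets carrying an identical 4–6 bp flanking duplication.
Among the exact-duplication candidates we rank by a *contrast score* —
repeat-pair matches in the 12 columns just inside the implied element
minus matches just outside, summed over both ends — then by TSD length,
then by smallest shift. The contrast score is what pins boundaries to
within a few bases: ranking by TSD length alone lets chance 5–6-mers at
shifted offsets win, and boundary identity alone cannot see inward
shifts (interior columns are equally correlated).

A candidate is accepted only if the two repeats align (end-gap-free
global alignment, identity = matches over gap-free columns) at ≥ 0.75.
Two guards handle structured false positives:

* a **chimera/tandem guard** rejects candidates whose internal region is
  covered by ≥ half an LTR-length of the candidate's own LTR 12-mers —
  this removes both tandem arrays masquerading as LTR pairs and chimeric
  calls that span two neighbouring copies of one family;
* `remove_tandem_false_positives()` re-checks surviving calls with an
  80% coverage threshold, the automated stand-in for the original
  manual curation of tandem-repeat artifacts.

**Known limitation.** A solo LTR lying within the element length bounds
of another same-family LTR copy, with a chance 4–6 bp duplication at the
right offsets, is structurally indistinguishable from an intact element;
such chimeras survive when their intervening sequence contains no extra
LTR copy. Strongly diverged tandem arrays can likewise escape the 12-mer
filters. Both are inherent to homology-free structural search.

# Classification and clustering

`scan_domains()` translates the internal region in six frames and runs
Smith–Waterman (BLOSUM62, open 10 / extend 4) against each reference,
keeping the best hit per domain above score 100 and 30% reference
coverage, resolving cross-domain overlaps by score.
`classify_superfamily()` reads the pol order along the coding strand.

`cluster_families()` is single linkage over the pairwise 5′-LTR graph —
the semantics of all-against-all clustering: an edge requires identity
strictly above 0.80 *and* the aligned span to cover at least 50% of both
LTRs (the reciprocal reading of the published criterion; the source is
ambiguous on whether one or both LTRs must be covered, and reciprocal is
the stricter, deterministic choice). Comparisons are strand-aware, since
genomic LTR copies come in both orientations. An 11-mer sharing
prefilter (≥ 2%) skips alignments that cannot reach the threshold; at
the 0.80/0.50 operating point passing pairs share ≳ 4% of their words,
so the filter does not change results on the tested worlds.
`name_and_rank_families()` sorts by intact count (reference genome count
when labels are supplied), ties by total count then smallest member id,
names families `OAL001…`, and assigns copy classes: high (> 20),
low (2–20), single (1).

# Dating

`ltr_pair_divergence()` aligns the LTR pair end-gap-free and counts
mismatches over gap-free columns; gap columns are excluded from numerator
and denominator (standard practice; the source does not specify its gap
handling). `correct_divergence()` applies JC69 by default — the original
analysis fitted an unnamed substitution model, and below $K \lesssim
0.13$ (5 MY) the model choice is numerically negligible, so the
closed-form JC keeps the package dependency-free; `raw_p` is provided
for sensitivity. Elements without a TSD, with fewer than 50 aligned
sites, or with $p \ge 0.75$ are flagged undatable. Age summaries report
interpolated 5/25/75/95% quantiles; the optional display cap (mirroring
the capping of very old insertions at a plot margin) never alters stored
ages.

# Phylogenetics

`neighbor_joining()` is the classical algorithm: Q-criterion join
selection with ties broken by the smallest current index pair, standard
branch-length formulas, negative branches clamped at zero with the
deficit recorded. On additive matrices it returns the generating tree
exactly; the test suite verifies this against an exhaustive
topology-enumeration + least-squares oracle. Distances are uncorrected
p-distances on amino-acid alignments by default. The multiple alignment
is a greedy center-star (longest sequence as center, pairwise global
alignments merged on a master gap profile): exact on the gap-free
planted RT sets that constitute the test surface, and only ever a guide
alignment — reproducing hand-curated alignments is not attempted.
`assign_lineages()` does nearest-seed assignment by p-distance with exact
ties unassigned; the package ships no lineage seeds.

# Read-depth abundance

`build_ltr_library()` deduplicates reference LTRs greedily, longest
first, joining a representative when alignment matches cover ≥ 0.95 of
the shorter sequence (strand-aware, with an 11-mer prefilter), and drops
LTRs shorter than 150 bp. `map_reads()` seeds each read (both
orientations, several spread 31-mers) against the library and scores
ungapped placements that may overhang the representative ends; a
placement passes with ≥ 31 bases of overlap and at most 2 mismatches per
100 overlapping bases, and each read splits weight $1/n$ over its $n$
equal-best placements — a deterministic replacement for random placement
of multireads.

Per-representative depth is mean per-base weighted coverage; normalized
depth divides by the genome-wide mean depth, computed as total read
bases over genome length (identical in expectation to a whole-genome
mapping pass on uniform reads, and one mapper pass cheaper). Family
depth is the *length-weighted sum* over the family's representatives —
a sum, because it must be invariant to how finely deduplication split
the family; a mean would halve the estimate whenever a family yields two
representatives. Since every intact element carries two LTRs,
`copies_est = norm_depth / 2`. Edge losses (placements with < 31 bp
overlap are unscorable) depress the proxy by roughly 3–10% depending on
LTR length and divergence from the representative; the depth validation
world therefore uses recently-amplified families (point age 0.1 MY),
the regime in which the 2-mismatch budget retains member reads and which
matches how the proxy is used (representatives at 0.95 identity).

# Orchestration and reproducibility

`run_pipeline()` executes the stages in canonical order, writes every
artifact plus a manifest under one output directory, and aborts with a
stage-tagged error when a prerequisite stage is disabled. One global
seed fans out to per-stage seeds by a stable hash of the stage name, so
toggling a stage never perturbs another stage's random stream; identical
configuration and seed reproduce all text artifacts byte for byte.
Structured stage logs echo the effective parameters — the reproducible
stand-in for curation steps that cannot be automated faithfully.

# Numerical choices

* Alignment scoring: nucleotide match +1 / mismatch −1, gap open 6 /
  extend 1, free end gaps. Mismatch-tolerant enough to keep diverged
  LTR pairs full-length (expected column score stays positive up to
  p ≈ 0.5), so the divergence estimate is not truncated.
* Scattered-vs-blocked divergence: because identity excludes gap
  columns, a contiguous diverged block can be gapped out and excluded;
  the JC generator produces scattered substitutions, for which this
  effect is negligible.
* Detector defaults (min LTR 100, max 3500, element 1000–20000, seed
  k = 20, TSD window 20) are package choices — the original tool's
  parameters are unpublished. k = 20 keeps expected false seed pairs on
  random background near $n^2/4^{20}$, i.e. ≪ 1 per Mb².
* All quantiles are type-7 (linear interpolation); all coordinates are
  0-based half-open internally and 1-based inclusive in GFF3.

# Validation summary

The acceptance suite (`tests/testthat/test-acceptance.R`) recomputes,
from freshly generated worlds: the dating closed forms; age-recovery
regression slope within [0.95, 1.05] on 200 elements aged U[0, 5] MY;
detection recall ≥ 0.95 at ≤ 5 bp boundary error on a 2 Mb genome with
zero calls on 1 Mb of random background; family clustering with Rand
index 1.0 against truth and equality with a matrix-closure single-linkage
oracle; the exhaustive 16-case superfamily rule; exact NJ recovery on
additive matrices up to n = 8 against a topology-enumeration oracle; a
depth proxy with Pearson r ≥ 0.9 and slope within [0.85, 1.15] across 20
families of 1–50 copies; and dedupe cutoff/idempotence behaviour. These
are properties of the stated synthetic worlds, not of any real genome.
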