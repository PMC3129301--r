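---
title: "Dating and grouping LTR retrotransposon insertions: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating and grouping LTR retrotransposon insertions: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroclock)
```

## The scientific problem

When an LTR retrotransposon inserts into a genome, its two long terminal
repeats (LTRs) are identical: both are copied from the same template during
reverse transcription. From that moment on each LTR accumulates point
mutations independently, so the divergence $D$ between the two LTRs of one
element is a molecular clock for the insertion itself:

$$T = \frac{D}{2r},$$

where $r$ is the substitution rate per site per year and the factor 2
accounts for both copies evolving. `retroclock` implements this estimator
end to end for element collections such as the *Fatima* gypsy family of
Triticeae: locating the LTR pair inside each element, aligning the two
copies, estimating $D$ with its standard error, converting to years, and —
one level up — building neighbor-joining trees of family members from
conserved-domain alignments, attaching bootstrap supports, and classifying
clades into genome-specific groups (the A, B and D subgenomes of hexaploid
wheat and its diploid relatives). A composition module reproduces the
Table-style accounting used when describing an annotated BAC clone, and an
in-silico PCR operation checks insertion-site-based polymorphism (ISBP)
markers.

## Divergence model

The two LTRs are compared with the Kimura two-parameter (K2P) distance,
which corrects transitions ($A \leftrightarrow G$, $C \leftrightarrow T$)
and transversions separately. With $P$ and $Q$ the transition and
transversion difference proportions over the $n$ compared sites,

$$D = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q),$$

and the delta-method standard error is, with $c_1 = 1/(1-2P-Q)$,
$c_2 = 1/(1-2Q)$ and $c_3 = (c_1+c_2)/2$,

$$\mathrm{SE} = \sqrt{\frac{c_1^2 P + c_3^2 Q - (c_1 P + c_3 Q)^2}{n}}.$$

Site counting uses the *complete deletion* convention for LTR pairs: any
column holding a gap in either row is excluded, and `N` residues are treated
exactly like gaps (missing data). When either logarithm argument drops to
zero or below, the distance is *saturated*; `retroclock` raises a typed
error rather than returning `NaN`, so batch runs can report individual
elements as undatable instead of failing — old elements routinely saturate.
The same convention applies to column exclusion in distance matrices, where
the default is *pairwise deletion* (each pair of rows drops only its own
missing-data columns), the standard choice for tree building from domain
alignments; complete deletion is available as an option.

The default rate is $r = 1.3 \times 10^{-8}$ substitutions per site per
year, the widely used value for plant LTR retrotransposons; every function
takes `rate` as an argument. Ages are reported in years and in MY
(`T_mya`); the command-line report rounds MYA to one decimal, the precision
at which such ages are customarily quoted.

## Locating the LTR pair

Each element is compared against itself: k-mer seeds (default `seed_k = 12`)
shared between the leading and trailing windows of the element are extended
without gaps along their diagonal under an X-drop rule (+1 match, −1
mismatch, drop 30), and the maximal-scoring run becomes a candidate repeat.
Candidates must satisfy `min_len = 80` bp, `min_identity = 0.80`, and a
maximum length of 40% of the element; they are ranked by *terminality* (the
combined distance of the repeat's outer ends from the element termini), then
identity, then length. Terminality outranks identity because LTRs are
terminal by definition: a slightly better-matching internal repeat (for
example inside a nested insertion) should not beat the true terminal pair.
These thresholds are conservative for the 1.5-kb scale of the LTRs this
package targets and are all exposed as arguments.

Intact LTRs start with `5'-TG` and end with `CA-3'`. `anchor_motifs()`
searches within ±5 bp of the candidate's outer boundaries for the nearest
shift that restores these dinucleotides. Because the two LTRs are copies of
one repeat, a shift found for the 5' start is applied to the 3' start too
(and likewise for the ends), keeping the two LTR lengths exactly equal. If
no shift works, the candidate is returned unchanged with the motif flags set
to `FALSE` — anchoring never discards a detection.

The detector finds direct repeats only; inverted repeats are never
considered (LTRs are direct by definition). De novo discovery in whole
genomic contigs, target-site-duplication detection, and solo-LTR analysis
are out of scope: the input is a collection of already-excised elements.

## Aligning the two LTRs

The pair is aligned with an exact affine-gap global aligner (Gotoh
algorithm, implemented in C++). A gap run of length $L$ costs
$\text{open} + \text{extend}\,(L-1)$; the defaults — match +2, mismatch −1,
open 5, extend 1 — discourage spurious terminal gaps between near-identical
copies. Terminal gaps are charged like internal ones by default, because
both LTRs are complete units; `free_end_gaps = TRUE` switches to
semi-global behaviour for fragmentary input. Traceback ties are broken
deterministically (diagonal, then up, then left), so identical inputs always
produce byte-identical alignments. The aligner's scores are cross-checked in
the test suite against an exhaustive enumeration of all alignments of tiny
strings and against an independent implementation.

## Trees, supports, and genome groups

Distance trees use the Saitou–Nei neighbor-joining agglomeration with the
Studier–Keppler criterion $Q(i,j) = (N-2)\,d(i,j) - R_i - R_j$. Two
numerical conventions make results reproducible and well-formed:

* **Tie-breaking.** Active nodes are held in sorted-label order and the
  first minimal pair wins, so the output is invariant to permutations of
  the input matrix.
* **Negative branch lengths.** NJ's least-squares branch estimates can come
  out slightly negative; they are clamped to zero with the deficit moved to
  the sister branch, which preserves path lengths through the joined node
  (the usual Kuhner–Felsenstein adjustment). Downstream Newick consumers
  therefore always see non-negative lengths.

Bootstrap supports come from resampling alignment columns with replacement,
rebuilding the distance matrix and NJ tree for each replicate, and counting
how often each internal bipartition of the point-estimate tree recurs.
Distance-method phrasing in the literature sometimes couples NJ with a
"maximum likelihood model" for the distances; that combination is not well
defined, so this package uses K2P distances throughout — for dating and for
trees — which keeps the two halves of the pipeline on one model. Replicates
whose resampled matrix saturates are skipped and counted; more than half
skipped is an error, since supports from a minority of usable replicates
would be misleading.

`classify_genome_groups()` turns a labelled tree into groups: every internal
edge splits the tips in two, and a side is *genome-specific* when at least
`purity_threshold` (default 0.90) of its labelled tips carry one genome and
the side holds at least `min_size` (default 5) tips. Maximal non-nested
specific sides are reported; everything else forms a single `mixed` group —
the residue of a tree after removing subtrees stays connected. The defaults
reflect the observation scale of the motivating analyses, where a
predominantly B-genome clade may legitimately contain a ~5-element subgroup
from another genome; both knobs are arguments. Unlabelled tips are counted
towards sizes but never towards purity.

## Composition accounting

`composition_report()` reproduces published-table arithmetic exactly, which
pins three conventions:

* Percentages are `length / total_len * 100` rounded **half-up** to 0.1
  (banker's rounding would flip several printed values).
* The gene-island span is `max(end) - min(start)` — the coordinate
  difference, not the inclusive width — matching the arithmetic used in the
  annotation this package's fixtures encode (33 407 − 9 737 = 23 670).
* Protein length from an intronless CDS span is `(end − start + 1)/3 − 1`,
  excluding the terminal stop codon; the five bundled gene spans all verify
  against their published residue counts.

All coordinates are 1-based inclusive throughout the package. Rolled-up
fractions are computed from base pairs, not by summing rounded class
percentages; for the bundled BAC table the two routes differ in the first
decimal for the total-TE and unassigned rows (55.5 vs 55.6, 39.3 vs 39.2),
and the base-pair route is reported. Primers for `insilico_pcr()` may be
written with hyphens or whitespace (`ccaga-taccc-...`), which are stripped;
matches are exact and case-insensitive, and products are capped at 5 kb by
default, the practical upper bound for standard PCR marker assays.

## The synthetic-data generator

`simulate_element()` and `simulate_family()` provide ground truth that no
real collection can: exact LTR coordinates, true insertion times, and
planted group memberships. Sequences evolve under the K80 model using its
closed-form transition probabilities, with rates $\alpha$ (transitions) and
$\beta$ (transversions) satisfying $\alpha + 2\beta = r$ and
$\alpha/\beta = \kappa$. Defaults: `ltr_len = 1500` (the scale of the solo
LTRs in the bundled BAC annotation), `internal_len = 6000`,
$r = 1.3\times10^{-8}$, $\kappa = 2$ (no family-specific estimate exists;
2 is the common vertebrate/plant convention), uniform base composition.
Families evolve a shared ancestral domain down a two-level tree (group
stems, then members), so between-group divergence is controlled by
`stem_time` and within-group divergence by `crown_time`.

Two deliberate simplifications:

* **No indels.** Synthetic families are natively aligned, cleanly
  separating estimator behaviour from alignment quality, which is out of
  scope (the pipeline consumes pre-aligned domains).
* **Terminal motifs are conserved.** The `TG`/`CA` dinucleotides of each
  evolved LTR copy are held invariant, as they are in elements that survive
  intact (they are required in cis for transposition). This removes 4 of
  ~1500 sites from the clock, a bias below 0.3% — far inside the estimator's
  sampling error.

Consequently, passing tests show that detection, dating, and grouping work
when the model is matched and alignment is exact; they do not certify
behaviour on real data with indels, nested insertions, gene conversion
between LTRs, solo-LTR recombination products, or rate variation across
sites — all listed out of scope.

All randomness flows through R's RNG; every simulating function takes a
`seed` and restores the caller's RNG state, so runs are byte-reproducible.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle: exhaustive
alignment enumeration and a second aligner for `global_align()`; hand-derived
closed-form values for K2P and the clock conversion; generating trees (and an
independent NJ implementation) for `neighbor_joining()`; planted simulation
truth for detection, dating, and grouping. The heavier checks use 200
simulated elements per true age in {0.5, 1.0, 1.6, 2.5} MYA for estimator
consistency (mean recovery within 5%), 100 elements at 4% LTR divergence for
boundary accuracy (≥95% within ±3 bp), 100 random additive matrices of up to
8 taxa for NJ, and a 21-member three-group family with a 1200-bp domain —
the span of concatenated reverse-transcriptase/RNase-H domain alignments —
and 100 bootstrap replicates for group recovery. These sizes give stable
statistics at interactive runtimes.

## Known limitations

* Dating requires both LTRs; truncated ("-1p") copies and solo LTRs are
  reported as undatable, never silently dropped.
* K2P assumes equal base frequencies and no rate variation across sites;
  strongly skewed composition or mutational hotspots (e.g. methylated CpG/CHG
  contexts in plants) bias $D$ and hence $T$.
* The age estimate also inherits all uncertainty in $r$; with a different
  clock rate, reported ages rescale as $1/r$.
* The detector's ungapped diagonal extension tolerates substitutions but not
  indels between the two LTR copies; an element whose LTRs differ by an
  insertion will be detected with boundaries on the dominant diagonal, and
  the subsequent affine-gap alignment absorbs the indel for dating.
* Saturation puts a hard ceiling (around $D \approx 1$, i.e. tens of MY at
  plant rates) on datable ages, reached long after LTR detection itself
  becomes impossible in practice.
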