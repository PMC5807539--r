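---
title: "Methods: barcode delimitation, primer evaluation and clock dating in whiteflydelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode delimitation, primer evaluation and clock dating in whiteflydelim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whiteflydelim)
```

`whiteflydelim` re-implements, as one tested pipeline, the analytical chain
used to survey the *Bemisia tabaci* cryptic species complex with partial
(867 bp) *mtCO1* barcodes: evaluating and redesigning degenerate PCR
primers, delimiting putative species against a labelled reference panel
with a fixed divergence threshold, building distance trees, and converting
clock-like trees to absolute ages against a fossil calibration. This
vignette is the package's own account of the models, the parameters that
matter, the numerical choices, and what the tests do and do not establish.

## Percent-identity species delimitation

The delimitation model is deliberately simple and mirrors how whitefly
putative species are operationally defined: a fixed pairwise-divergence
band of 3.5–4.0% on the barcode separates species. Divergence is the
uncorrected p-distance under **pairwise deletion**: a column contributes to
a pair's comparison only when both residues are unambiguous A/C/G/T, so
gaps and IUPAC ambiguity codes are excluded from numerator and denominator
alike. Identity is reported as `100·(1 − p)` to 0.1%, matching how survey
tables print it.

Two decisions here were genuinely open:

* **Threshold end.** The default `threshold_divergence = 0.035` is the
  conservative end of the published band. The liberal end (0.040) is
  selectable, but 3.5% is the default because at that setting a query at
  exactly 96.5% identity to a Mediterranean-clade reference remains
  assigned to the known species — consistent with how surveys treat the
  boundary — while 4.0% would additionally absorb some genuinely distinct
  clusters.
* **Boundary rule.** Only divergence *strictly greater* than the threshold
  creates a new cluster; equality assigns to the known species. The
  criterion is worded as "more than" the band, and the strict rule keeps
  the known-species set maximal at the boundary.

Queries that clear the threshold against every reference are grouped into
new putative species by linkage clustering on their pairwise divergences,
cut at the same threshold. **Single linkage** is the default because it
reproduces the transitive membership implied by the criterion itself (any
chain of ≤ 3.5% neighbours is one species); complete linkage is offered for
users who want compact clusters, since intra-new-species grouping is not
pinned down by the criterion. New clusters get neutral `NEW1, NEW2, …`
names in order of first occurrence; mapping them to formal names
(SSA9, SSA10, …) is editorial, not computational, and is left to the user.

Ties between equally close references are broken by lexicographic accession
and flagged in the assignment table, so downstream reports never depend on
storage order.

## Primer evaluation and in-silico PCR

Primer/template compatibility uses the IUPAC expansion rule symmetric in
both arguments: two codes anneal at a position when their unambiguous
expansions intersect (`R` matches `A` and `G`; `N` matches everything).
Annealing quality is the **mismatch count** over the primer window —
deliberately the whole model. There is no melting-temperature or
thermodynamic scoring, because the phenomenon the pipeline reproduces
(old-primer failure on part of the species complex) is explained at the
level of accumulated substitution mismatches, and a thermodynamic layer
would add parameters no stage downstream consumes. Gaps in a template
window count as mismatches; there is no indel-tolerant annealing model.

Binding-site coordinates are 0-based and half-open on the plus strand
everywhere; a reverse-orientation site is a plus-strand window equal to the
primer's reverse complement, reported with strand `-` and with mismatch
positions re-indexed to the primer's own 5′ end. In-silico PCR pairs every
plus-strand forward site with every downstream minus-strand reverse site
and reports products spanning both footprints, capped at
`max_product = 2000` nt with `max_mismatches = 3` per site — permissive
enough to accept the degenerate redesign on realistic templates while still
rejecting the six-mismatch failure mode of the old reverse primer.

Degenerate-consensus design takes an aligned, gap-free block and emits, per
column, the minimal IUPAC code covering exactly the observed bases, so the
designed primer matches every input with zero mismatches and its degeneracy
is the product of per-column observed-set sizes. Columns containing gaps or
`N` are refused rather than silently widened: an `N` would force degeneracy
4 at that position and the caller should decide whether to trim instead.

## Distances and trees

Pairwise global alignment (Needleman–Wunsch, via Biostrings) backs the
`align-pairs` mode with linear scoring `match = 1`, `mismatch = −1`,
`gap = −2` and no separate gap-extension cost: barcode pairs from one locus
are near-collinear, so affine gaps buy nothing. On gap-free, equal-length
inputs the `prealigned` and `align-pairs` modes provably coincide, and the
test-suite asserts it.

The K2P correction `d = −½ ln((1 − 2P − Q)√(1 − 2Q))` is computed
per pair under the same pairwise-deletion policy. When the logarithm's
argument is non-positive, the pair is *saturated*: the distance is returned
as undefined and matrix construction fails loudly, listing the pairs,
rather than clamping to an arbitrary large value.

Tree building is intentionally desk-scale: canonical neighbor-joining for
topology and UPGMA (average linkage, node height = half the merge distance)
for ultrametric trees. Bayesian topology inference and relaxed-clock MCMC
are explicitly out of scope; NJ/UPGMA are stand-ins, and node-for-node
reproduction of published Bayesian topologies is not expected or claimed.
Negative NJ branch lengths are clamped to zero with the total deficit
recorded as an attribute. Outgroup rooting locates the unique branch whose
removal separates outgroup from ingroup (erroring, with the offending set
named, when no such branch exists) and places the root at its midpoint —
the natural point estimate when nothing more is known about rates on that
branch.

## Strict-clock dating

Dating assumes a strict molecular clock: node heights on an ultrametric
tree are proportional to elapsed time, so fixing the root to the fossil
calibration mean (default `root_age_mean = 130` mya, with
`root_age_sd = 20` mya describing the calibration's uncertainty) scales
every height linearly into mya. The calibration is a *point* calibration by
default: the sd is used only to jitter the root age across bootstrap
replicates when `jitter_calibration = TRUE`, because the package carries no
posterior machinery that a full prior would require. The conventional
starting value 123 mya associated with this calibration is stored for
provenance and plays no role in the arithmetic.

Ultrametricity is checked (root-to-tip spread ≤ 1e-6 by default) before
calibration, and a coefficient-of-variation clock test (flag limit 0.1) on
root-to-tip path lengths of the rooted additive tree guards the clock
assumption; in the pipeline a flagged clock warns and proceeds, because a
flagged tree can still be dated — the flag is the caveat. Note that this
statistic is rooting-sensitive: a misplaced root (for instance, midpoint
rooting on a long, asymmetric outgroup branch) inflates it even under a
perfect clock, so it should be read jointly with confidence in the rooting.

Intervals come from a nonparametric column bootstrap (default 100
replicates, seeded): resample alignment columns with replacement, recompute
distances, rebuild UPGMA, recalibrate, and record each focal clade's age
where that clade is monophyletic in the replicate; replicates where it is
absent are counted and excluded. For dating, K2P-corrected distances matter
more than elsewhere in the pipeline: the p-distance's saturation
nonlinearity compresses deep nodes relative to shallow ones, which the
linear calibration would then distort, whereas the K2P estimator restores
approximate linearity in time.

These dates are internal-consistency estimates of a simplified model.
Published whitefly divergence dates rest on relaxed-clock Bayesian
inference over hundreds of sequences; the strict-clock stand-in makes no
claim to reproduce them, and the package treats such dates as qualitative
context only.

## The synthetic-data generator

Every input the pipeline needs is generated in code, seeded end-to-end:

* **Trees** come from a Yule (pure-birth) process conditioned on the tip
  count, built tipward-to-root with epoch durations `Exp(k·λ)` while `k`
  lineages exist, so the expected root age is `Σ 1/(k·λ)` for `k = 2…n` —
  a closed form the tests check against. A coalescent alternative was not
  implemented: delimitation and dating consume node ages, not
  population-genetic structure.
* **Sequences** evolve by the closed-form K80 transition-probability
  matrix per branch (`JC69` is the `kappa = 1` special case), with the
  per-branch transition/transversion tally logged so model behaviour
  (e.g. transition dominance at high kappa) is observable, and with the
  Jukes–Cantor expected p-distance
  `(3/4)(1 − e^(−8·rate·t/3))` available as an independent oracle.
* **Panels** follow a species plan (members per species, within-species
  divergence cap, between-species floor; optional reference-less "novel"
  species). Plans are enforced by construction plus post-hoc verification
  with the distance module, with rejection sampling capped at 1000
  attempts before a hard error — simple and transparent, at the cost of
  refusing plans that are combinatorially tight.
* **Primer templates** carry planted binding sites with exact, known
  mismatch positions, so in-silico PCR outcomes are decidable by
  construction.

The generator's defaults are the study conditions the pipeline is
validated under: 867-nt sequences (the survey fragment length), ≤ 2%
within-species and ≥ 6% between-species divergence for panels — safely
either side of the 3.5% threshold, as real reference panels are — and a
substitution rate of 0.005/site/my with 8-taxon trees for clock
simulations. What the generator does **not** emulate bounds what passing
tests show about real data: no indels (so alignment stress is untested
beyond small constructed cases), no rate heterogeneity across sites or
lineages (so the clock test's power against realistic violations is not
measured), no nuclear copies of mitochondrial sequence (NUMTs) — a known
hazard for whitefly barcodes that can only be excluded upstream — and no
base-compositional bias. Perfect precision/recall on generated panels
demonstrates correctness of the criterion's implementation, not that real
surveys are this clean.

## Problem sizes and numerical conventions

The validation suite uses sizes chosen to make Monte-Carlo statements
stable while keeping the whole suite fast to iterate: 50-seed NJ recovery
on ≤ 12-tip additive trees, 20-replicate clock-age recovery on 5000-nt
alignments (mean relative node-age error ≤ 15%), 20-seed delimitation
recovery on 867-nt panels, 50-replicate Jukes–Cantor expectation checks.
UPGMA ultrametricity is asserted to 1e-9; newick round-trips to 1e-9;
ultrametricity for calibration to 1e-6 (looser, since user trees may come
through file round-trips). Deterministic tie-breaking (lexicographic ids
in assignment ties; first-occurrence ordering for cluster names) keeps
every run bit-reproducible under a fixed seed.

Degenerate inputs fail early and loudly by policy: empty sequences, gapped
inputs to gap-free operations, saturated distance pairs, non-ultrametric
trees passed to calibration, outgroups that do not form a split, and
infeasible species plans are all errors with the offending object named,
never silent coercions.

## Known limitations

* The delimitation threshold is global and fixed; the package does not
  attempt coalescent or model-based delimitation, and a barcode-only
  criterion inherits every caveat of single-locus species assignment.
* The strict clock is a strong simplification; its dates are pipeline
  diagnostics, not biogeographic estimates.
* Alignment is pairwise-global only; there is no multiple-sequence
  alignment, so `prealigned` inputs are assumed to come from an external
  aligner when they are not synthetic.
* The primer model counts mismatches only; primers that fail
  thermodynamically despite few mismatches are outside the model.
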