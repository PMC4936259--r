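---
title: "corebild: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{corebild: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical model behind `corebild`, the
parameters that matter, the design decisions that were genuinely open, and
what the synthetic validation does and does not demonstrate.

## The model

### Column scores

The unit of evidence is an alignment column restricted to one subfamily.
Writing `c = (c_1, …, c_20)` for its residue counts (`M = Σ c_a`
observations; gaps and `X` contribute nothing), two generative hypotheses
are compared:

* **Relatedness**: all residues are drawn i.i.d. from a single unknown
  composition `θ`, itself drawn from a Dirichlet mixture
  `θ ~ Σ_j q_j Dir(α_j)`. The marginal likelihood `Q(c)` has the
  standard Dirichlet-multinomial closed form per component (evaluated with
  log-gamma functions), mixed over components.
* **Independence**: each residue is an independent draw from background
  frequencies `p`, giving `P(c) = Π_a p_a^{c_a}`.

The BILD score is the log-odds `S = log Q − log P` in nats. Two useful
identities are exercised heavily by the test suite: `S` depends on the
column only through its counts (exchangeability), and `Q` factorizes into
a sequential product of posterior-predictive probabilities — adding
residues one at a time, in any order, reproduces the closed form to
1e-9.

### Normalizing scores to probabilities

The block threshold is applied on a probability scale. We map
`prob = σ(S) = e^S / (1 + e^S)`, the posterior probability of the
relatedness model under equal prior odds. An alternative — dividing `S`
by the number of observations before the logistic, giving a
per-observation odds scale — is available via `perObsDivisor`, but it is
not the default for a measured reason: on that scale the threshold 0.05
corresponds to about −2.9 nats *per residue*, a bar that uniform-random
columns clear easily (they sit at 0.10–0.33), so block detection loses
all contrast. With `σ(S)`, background columns of 8 or more observations
score below 1e-2 and strongly conserved columns score near 1, which is
the contrast the 0.05 threshold needs.

Columns with fewer than 2 observations are forced to probability 0: a
single observation is dominated by the prior and should never certify
conservation on its own.

### Core blocks

A sliding window (default 7 columns) passes over the per-column
probabilities; a column is covered when it lies in at least one window
whose mean probability is strictly above the threshold (default 0.05).
Maximal covered runs become candidate blocks; because a single spike
column can qualify a whole window, a final filter keeps only runs whose
own mean probability is above the threshold — a core block is a *segment*
with mean score above the threshold, not merely the shadow of one good
window. Each block records the sum of raw `S` values as its score.

The window length is a compromise: it must be shorter than the minimum
region span (21 columns) so blocks can seed regions, yet long enough to
suppress single-column noise; 7 is the default and it is configurable.
The threshold comparisons are strict (`>`), as are the block-relatedness
zero rule and the region score cutoff below.

### Relatedness between blocks

Blocks in different subfamilies that overlap in the alignment are
compared column-by-column with
`R(x, y) = S(xy) − S(x) − S(y) = log [Q(xy) / (Q(x) Q(y))]`,
where `xy` pools the two columns' counts; background terms cancel. `R` is
symmetric and exactly zero against an empty column, so columns where one
subfamily is fully gapped contribute nothing. A block is related to the
query when the sum of `R` over the shared columns of at least one
query-subfamily block is strictly positive. The minimum overlap for a
comparison defaults to a single column (configurable); no gapped
block-to-block realignment is attempted — blocks are compared as they sit
in the master alignment.

### Inconsistent segments

For every sequence and every core block of its subfamily, the sequence's
residues across the block are scored as
`Σ log P(residue | column)` using the posterior predictive of each
column — with the sequence's own residues removed from the counts first
(leave-one-out), so a sequence can never validate itself. This matters
most at the small subfamily sizes Bayesian scoring is meant to serve.

The unrelatedness baseline is the expected probability of a
uniform-random residue per column, `Σ_a (1/20) P(a | column)`, accumulated
in log space. Because the posterior predictive normalizes over residues,
this reduces analytically to `log(1/20)` per paired column; the package
computes it through the predictive anyway so the contract holds for any
predictive model. Positions where the sequence is gapped are skipped in
the score, and the baseline is shortened to the same paired positions, so
the two totals always cover identical lengths. A segment scoring below
the baseline is flagged inconsistent and excluded from region chaining
for that sequence. Tracks are computed once and then flagged — there is
no iterative masking and recomputation.

### Orphans, regions, ranking

Sequences whose minimum distance to every other sequence is at least 0.85
(identity distance over mutually ungapped columns; pairs with fewer than
10 such columns get distance 1) are orphans. Orphans are compared
directly with the query subfamily's blocks using the same
posterior-predictive criterion (no leave-one-out — they are not members);
blocks they pass become their blocks for chaining. The query is never
discarded: if it qualifies as an orphan it becomes a singleton subfamily.

Per sequence, the query-related blocks in which it has at least one
unflagged residue are chained left to right: consecutive blocks join one
region when the inter-block gap (next start minus previous end, in
alignment columns) is at most 40; regions spanning fewer than 21 columns
are discarded (exactly 21 is kept). The region score is the sum of member
block scores. A sequence is retained iff some region scores strictly
above the cutoff (default 0, consistent with the strict positive-sum
relatedness convention); survivors are ranked by total region score,
descending, with ties broken by input order.

### Subfamily clustering

The clustering contract is: an automatic number of subfamilies from the
identity distance, deterministic, with divergent sequences set aside
first. It is implemented as average-linkage hierarchical clustering cut
at the largest gap in the sorted merge heights; a gap must exceed
`minSplitGap` (default 0.1) to justify splitting at all, which decides
the all-one-family case. Singleton clusters left by the cut are
reassigned to the nearest multi-member cluster by average distance. An
injected external clustering can replace this step by constructing a
`SubfamilyPartition` directly — every downstream stage takes the
partition object, not the clustering. Exact merge-height ties could in
principle make the tree order-dependent; on real or simulated distances
with noise this does not arise, and the order-invariance property is
tested on such data.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `window` | 7 | columns | sliding-window length for block detection |
| `blockThreshold` | 0.05 | probability | strict lower bound on mean window/run score |
| `maxGap` | 40 | columns | maximum inter-block distance within a region |
| `minRegionLength` | 21 | columns | minimum region span (inclusive) |
| `scoreCutoff` | 0 | nats | strict lower bound on a retaining region's score |
| `orphanThreshold` | 0.85 | distance | minimum-distance floor for orphans |
| `minSplitGap` | 0.1 | distance | merge-height gap required to split subfamilies |
| `minObs` | 2 | residues | observations needed for a nonzero column score |
| `minOverlap` | 1 | columns | overlap needed to compare two blocks |

`maxGap`, `minRegionLength` and `blockThreshold` are the method's
published operating point; the others are implementation parameters with
the defaults above.

## The synthetic prior

Scoring needs a Dirichlet-mixture prior; the package parses any mixture
in the UCSC flat-file format, including published alignment-trained ones.
For self-contained tests it ships `syntheticMixture20()`: 20 equally
weighted components, component `a` having
`α = c (m e_a + (1−m)/20·1)` with `m = 0.8`, `c = 2`, uniform background.

The shape was chosen for *separation*, measured on simulated columns
before any validation expectation was frozen: with it, uniform-background
columns of ≥ 8 observations score near 0 and 90 %-conserved columns score
near 1. Its relative entropy (2.58 bits) is higher than the mid-PAM
(~0.6 bits) range of alignment-trained mixtures. That is deliberate: a
symmetric, single-residue-peaked mixture flattened to 0.6 bits makes
`Q ≈ P` everywhere and destroys the contrast, whereas trained mixtures
reach low entropy through asymmetric, biochemically structured components
that a synthetic symmetric prior cannot imitate. Two consequences to keep
in mind when extrapolating test results to real data: (i) the synthetic
prior grants no partial credit to biochemically similar substitutions, so
segment rescue needs higher identity than it would under a trained prior
(the orphan-rescue fixture uses 75 % identity over blocks where a trained
prior would plausibly admit lower); (ii) relative-entropy values quoted
for the synthetic prior are not comparable to published values for
trained priors.

## What the generator emulates — and what it does not

`generateFixture()` builds alignments with known truth: subfamilies
sharing planted conserved blocks (tight per-column compositions, optional
per-subfamily consensus), background columns drawn uniformly, unrelated
sequences drawn entirely from background and verified to share under
50 % identity with the query, optional corrupted segments (uniform
overwrites across a block), and optional subfamily-level identity
structure for clustering fixtures. The same seed gives byte-identical
output from a private RNG stream.

It does **not** model indel evolution (gaps only arise in hand-written
test alignments), biochemical substitution structure, compositional bias,
or fragmentary sequences. Passing the synthetic validation therefore
demonstrates the pipeline's internal correctness and its behaviour under
idealized signal/noise contrast — not performance on real alignment
databases, where misalignment, similar-residue substitution and domain
architecture complicate all five stages.

Validation problem sizes: 50 simulated alignments of 15 members + 4
unrelated sequences (240 columns, two shared 30-column domains, two
corrupted segments) for end-to-end rates; 50 single-family alignments of
12 members with one 60-column domain for column-level recovery (typical
conserved-domain length); 40 clustering fixtures covering 1–4 planted
subfamilies.

## Numerical choices

* All scores in nats; relative entropy reported in bits (the conventional
  scale for substitution-matrix comparisons).
* Probabilities are floored at 1e-300 before logs; empty columns return
  `log Q = 0` exactly.
* Mixture weights must sum to 1 within 1e-6 at parse time and are then
  renormalized; `Alpha=` lines may carry 20 values or 21 (leading total).
* When a mixture file has no `Background=` line, the background is the
  mixture-implied marginal `p_a = Σ_j q_j α_{ja}/α*_j`, which makes every
  single-observation BILD score exactly zero — a convenient calibration
  point used by the tests.
* Degenerate inputs: a window longer than the track yields no blocks with
  a warning; a query subfamily without blocks leaves all other blocks
  unrelated and all orphans unrescued, with warnings; a sequence fully
  gapped across a block receives no verdict for it and cannot claim it.

## Known limitations

* No realignment: removed sequences are dropped, never re-aligned; blocks
  are compared only as aligned.
* No iteration between flagging and track computation.
* The orphan criterion (0.85) and the minimum subfamily size implied by
  `minObs` are pragmatic defaults, not estimated quantities.
* Selenocysteine/pyrrolysine and ambiguity codes (U, O, B, Z, J) are
  rejected at parse time rather than recoded; `X` is accepted as missing
  data but never contributes evidence.
* With subfamilies of fewer than ~8 sequences, coincidental residue pairs
  inflate column scores and block boundaries blur; results at such sizes
  should be read with care regardless of prior.
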