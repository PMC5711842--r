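---
title: "Phenotypic-vector analysis of modular segmentation screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic-vector analysis of modular segmentation screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segscreen)
```

## The data model

A whole-organism chemical screen for segmentation phenotypes scores each
treatment — one compound at one concentration in one experiment (wild-type
replicate or clock-mutant background) — on twelve ordinal parameters, each 0
(indistinguishable from an untreated control of the same genotype) to 3
(strong difference). Six parameters describe general morphology (embryonic
development E, head H, yolk Y, dorsal–ventral D, axis elongation A, tail
shape T) and six describe segmentation (secondary tail appendage S, myotome
boundary defects BD, anterior/trunk/posterior axial position AD/TD/PD,
segment shape BS). The twelve scores form the treatment's *phenotypic
vector*.

Three modelling commitments shape everything downstream:

* **Absent is not zero.** A lethal or unscored well carries no vector; an
  all-zero vector means *scored and normal*. Non-analyzable treatments are
  removed before any statistic is computed, never imputed.
* **Scores are ordinal integers.** Fractional input is rejected rather than
  rounded; every statistic that treats scores as numeric (means, variances,
  correlations) does so explicitly and documents it.
* **Deterministic order.** Tables are normalized to (compound,
  concentration, experiment) order at load, and every ranking or
  agglomeration tie is broken lexicographically, so results are identical
  across platforms and input orderings.

### Well-level consensus

Scores are assigned per well from several embryos. The well-level score of a
parameter is the largest value supported by at least `min_embryos` embryos —
equivalently the `min_embryos`-th largest per-embryo score. With the default
3 of 5 this reproduces the usual "phenotype shown by at least three of five
embryos" rule; for smaller wells the support requirement degrades to
`ceiling(0.6 n)`. The rule is monotone (raising any embryo's score never
lowers the consensus) and returns the common vector exactly when embryos
agree. The per-parameter reading is one consistent interpretation of a
criterion that is usually stated per phenotype; it is the only one that
yields a well-defined vector when embryos disagree on different parameters.

## Hit statistics

For one vector split into segmentation scores $x_{\mathrm{seg}}$ and
morphology scores $x_{\mathrm{morph}}$ (each $n = 6$):

$$\mathrm{SSMD} \;=\;
\frac{\bar x_{\mathrm{seg}} - \bar x_{\mathrm{morph}}}
     {\sqrt{s^2_{\mathrm{seg}} + s^2_{\mathrm{morph}}}},
\qquad
\Delta \;=\; \bar x_{\mathrm{seg}} - \bar x_{\mathrm{morph}},$$

with sample variances ($n-1$ denominator; the SSMD literature's
sample-statistic convention — the screen itself does not fix the
denominator). When both variances vanish the SSMD is defined as 0 for a zero
numerator and signed infinity otherwise, so rankings remain total without an
epsilon fudge.

**Exclusions.** The SSMD ranking drops treatments with
$\bar x_{\mathrm{seg}} < 0.2$ (no specific signal) *or*
$\bar x_{\mathrm{morph}} > 2$ (dominated by toxicity). The two clauses
target opposite failure modes, so the union is the default; a conjunction
reading — which would exclude almost nothing, since a near-zero
segmentation half and a near-saturated morphology half rarely coincide —
is available through the `conjunction` switch in `ranking_config()`. The mean-difference ranking keeps
$\bar x_{\mathrm{morph}} < 2$ and $\Delta > 0$, both strict, taken literally.

**Direct-segmentation predicate.** A treatment *qualifies* when
$\bar x_{\mathrm{morph}} < 2$, $\Delta > 0$ and
$\bar x_{\mathrm{seg}} \ge 0.2$. This replaces the manual evaluation of
ranked lists that produced the original hit list; the published 22-compound
list is not recomputable without the raw scores and that manual judgment, so
the predicate is the explicit, configurable stand-in.

**Hit calling.** A compound is a hit when at least one treatment qualifies
and the support is not confined to exactly one wild-type replicate (the
wild-type reproducibility filter; qualifying in a mutant alone is
acceptable — that is the point of the sensitized background). Genotype
classes are assigned in a fixed order: `her1_only` (qualifies in the her1
mutant and nowhere else), `her1_enhanced` (her1 support strictly stronger in
segmentation mean than the best analyzable wild-type treatment at the same
concentration), `hes6_suppressed` (qualifying wild-type/her1 support at a
concentration where the analyzable hes6 treatment fails to qualify),
`wild_type_supported`, else `mixed`. Two consequences of this order are
worth knowing: suppression requires an *analyzable* hes6 treatment (a
lethal hes6 well is missing data, not suppression), and with all four
experiments analyzable a wild-type-only hit profile is classified
`hes6_suppressed`, which mirrors how suppression was counted in practice.

## Replicate QC

Reproducibility between two experiments is measured on the treatments
analyzable in *both*: the Pearson correlation over all paired (treatment,
parameter) scores with the usual t-transform p-value, and the normalized
Hamming distance — the proportion of paired measurements that differ at all
(binary mismatch, not magnitude-weighted). Treatments lost in one replicate
are excluded from both metrics and logged; counting them as disagreement is
the flagged alternative, not the default. "Correlation" is Pearson
throughout (a Spearman option exists but is never the default).

## Clustering

Phenotypic similarity uses correlation distance $1 - r$ along the vector
(range $[0, 2]$; symmetric and zero on the diagonal, but not a metric — no
triangle inequality). Constant vectors have undefined correlation, so
clustering takes all analyzable treatments with a nonconstant, not-all-zero
vector; "no phenotype" treatments carry no correlation information and are
excluded and listed. Agglomeration is plain average linkage (UPGMA-style),
implemented in the package rather than delegated so that exact ties merge
the lexicographically earliest pair of cluster representatives —
`stats::hclust` does not guarantee an order, and reproducible cluster
identities matter downstream. Average linkage is monotone for any
dissimilarity, so dendrogram heights never invert.

Flat clusters cut the tree at distance $1 - 0.6 = 0.4$, the only coherent
reading of a "correlation cutoff of 0.6" under a correlation metric.
Cluster labels operationalize the verbal cluster descriptions: the
*first-class* cluster maximizes $\bar x_{\mathrm{seg}} /
(\bar x_{\mathrm{morph}} + 1)$ among clusters of size ≥ 2; *secondary tail*
requires the S and T means to be the two dominant morphology-plus-tail
signals, each ≥ 1.5; *seg-plus-morph* requires
$\bar x_{\mathrm{seg}} \ge 1$ and $\bar x_{\mathrm{morph}} \ge 2$. All
thresholds are arguments. Pulse-retest candidates are drawn uniformly
without replacement from the labeled cluster under a caller-supplied seed,
with the caller's RNG state restored.

Newick export uses the ultrametric height-splitting convention: an internal
node sits at half its merge distance, each branch is the parent's node
height minus the child's, and leaves sit at height 0, so two leaves merged
at distance 0.2 serialize as `(A:0.1,B:0.1);` and cophenetic distances
reconstruct merge heights exactly.

## Concentration profiles and networks

Treatments classify as `lethal`, `any_defect` (any parameter > 0) or
`no_defect`; unscored non-lethal wells are unclassifiable and reported.
Lethal counts per (experiment, concentration) cell feed a two-factor ANOVA
without interaction — with one observation per cell that is the only
estimable reading of a "2-way ANOVA" on this design. Counts, not
proportions, are the response (the design is balanced, so the distinction is
cosmetic); when every cell is identical all sums of squares vanish and
F = 0, p = 1 by convention rather than an exception. The bipartite
compound–parameter network of a screen slice carries score > 0 edges
weighted 1–3, parameter-node frequency equal to degree (asserted at
construction), and lethal compounds as flagged isolated nodes; SIF export
fixes the relation name to `scores` and carries weights only in GraphML,
since SIF has no edge-attribute slot.

## The synthetic screen: what the generator states and what it does not

The generator is the package's stated world: 243 compounds × three
concentrations (2/10/50 µM) × four experiments (wt_A, wt_B, her1, hes6),
five embryos per well. Each compound belongs to a latent class — `inactive`
(60%), `direct_seg` (10%, the planted hits), `seg_plus_morph` (12%),
`morph_only` (8%), `secondary_tail` (5%), `toxic` (5%). Proportions are
chosen so that the direct-hit rate matches the ~9% primary hit frequency of
a well-designed modular screen and the strong-morphology cluster is large
enough to sample pulse candidates from; they are design constants, not
fitted quantities.

Scores arise from a latent-severity model: severity × per-parameter weight
pattern, plus per-embryo Gaussian noise (`noise_sd = 0.3` on the latent
scale), discretized at cutpoints 0.5/1.5/2.5 and clamped to [0, 3]; the
well vector is the 3-of-5 consensus. Any monotone latent model would do;
this one inverts trivially in tests. Dose activation is a threshold step —
effects are absent below the activation concentration and saturate above —
because concentration series in such screens show all-or-nothing activity
windows rather than graded dose response. Activity windows for `direct_seg`
compounds start at 2/10/50 µM with probability 1/6, 1/2, 1/3, and a window
starting at 10 µM extends to 50 µM with probability 2/3, which makes
exactly two-thirds of planted hits single-concentration in expectation —
the headline masking statistic. (The companion per-concentration masking
rates quoted for such screens are not simultaneously satisfiable in a
start-threshold model; the aggregate two-thirds figure is the one the
analysis reports, so it is the one calibrated to.) Above its window a
masked compound acquires a strong morphology latent (2.2–3.2), which is
what "masking" means operationally: the phenotype persists but the
predicate rejects it.

Genotype structure: 30% of `direct_seg` compounds are her1-only hits —
wild-type severity below the scoring threshold, amplified 5–8× in the her1
mutant, the enhancer reading of a sensitized background; 60% carry a hes6
multiplier of 0.1, suppressing the phenotype in the hes6 mutant. Lethality
is a hazard curve `1 − exp(−0.7 · max(0, morph − 2))` in the morphology
latent, so death is concentration-coupled through toxicity; scale 0
disables it. wt_A and wt_B share every latent value and differ only through
noise realizations; an optional `batch_shift` exists solely to stress-test
the reproducibility filter. The `seg_plus_morph` weight pattern engages all
axial-position codes (BD, AD, TD, PD), matching the axis-wide boundary
disruption described for strong-morphology compounds and ensuring the
planted class satisfies the cluster definition it is named for.

What the generator does **not** emulate: plate-positional artifacts,
scorer drift or inter-scorer disagreement, graded dose–response, chemical
structure, partially penetrant wells beyond embryo noise, and the empirical
inter-replicate noise level of manual scoring — at the stated
`noise_sd = 0.3` the synthetic wild-type replicates agree far more closely
(r ≈ 0.96, Hamming ≈ 0.02) than real manually scored replicates
(r ≈ 0.63, Hamming ≈ 0.1). A green recovery test therefore establishes that
the pipeline's logic is correct on data with the stated structure, not that
the screen's published statistics are reproduced.

## Numerical choices

* Variances with $n-1$; tiny negative values from vectorized cancellation
  clamped to 0 before the square root.
* SSMD zero-denominator convention: 0 or signed infinity (see above).
* Flat cuts compare heights to the threshold with a $10^{-12}$ tolerance so
  exact-threshold merges are included deterministically.
* Exact distance ties in agglomeration are broken by the lexicographically
  smallest pair of cluster representative labels; floating ties between
  mathematically equal but differently rounded values are not detected,
  which is why the test oracles compare value-and-sortedness rather than
  raw positions.
* All randomness (generator, candidate sampling) is seeded explicitly and
  never leaks into the caller's RNG state.

## Known limitations

* The published 22-compound hit list, r = 0.63 replicate correlation and
  0.1 Hamming distance depend on unreleased raw scores and manual curation;
  the package reproduces the procedures, not those numbers.
* SSMD and mean-difference rankings agree only moderately on discretized
  consensus vectors (Spearman ρ ≈ 0.5–0.8 on default synthetic screens):
  the SSMD denominator promotes uniform-mild vectors (low within-half
  variance) over concentrated-strong ones, while the mean difference orders
  them oppositely. Exact uniformity is common after consensus
  discretization, so the divergence is structural, and the ≥ 0.8
  concordance regression bound fails honestly at the stated world rather
  than being tuned to pass.
* Correlation distance ignores vector magnitude: a compound scoring 1 on
  BD/PD and one scoring 3 on BD/PD are identical to the clustering. That is
  faithful to the fingerprint reading but means severity separates hits
  only through the rankings, not the clusters.
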