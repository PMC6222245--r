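---
title: "Experience-based SEEG planning: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Experience-based SEEG planning: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seegplan)
```

## The problem

StereoelectroencephaloGraphy (SEEG) localises the epileptogenic zone by
implanting on the order of ten to twenty intracerebral electrodes, each
defined by an entry point (EP) on the skull and a target point (TP) deep in
the brain. Existing planning software optimises individual trajectories
against geometric safety constraints (vessel clearance, insertion angle) but
offers no help with the step that comes *before* optimisation: deciding which
set of trajectories to start from. That choice is driven by the implanting
centre's accumulated experience.

`seegplan` models that experience from retrospective data. Given the plans of
previously implanted patients, an anatomical label volume in a common average
space, and per-patient affine registrations, it mines the cohort into a
reusable model, then maps a chosen *planning strategy* into a new subject's
anatomy as an initialised plan a surgeon can edit or feed to an optimiser.

## The model

### Trajectory descriptors and exploratory patterns

Each trajectory is classified by the pair of atlas zones it connects,
d = [entry zone; target zone]. The electrode tip is not necessarily the
clinical target — the target can be any zone the electrode crosses — so the
package uses a deterministic surrogate for the surgeon's judgement: the
target zone is the *deepest* traversed member of a configurable set of
admissible target zones, and the entry zone is the *first* traversed member
of the admissible entry set (the atlas does not label scalp or skull, so the
first cortical zone stands in for the skin entry site). Labels are read by
nearest-voxel lookup at 1 mm arc-length steps; labels are categorical, so no
interpolation is ever applied, and the extraction is invariant to the step as
long as it is below half the thickness of the thinnest zone crossed.

White matter and unlabelled voxels are ignored during traversal. A
trajectory whose *terminal* zone is an exclusion structure (ventricles,
brain stem, cerebellum) is an outlier, as is one that traverses no
admissible entry or target zone; outliers never enter pattern grouping. The
default zone configuration for Desikan–Killiany-style label tables also
encodes three clinically motivated merges: hippocampus with
para-hippocampus (neither can be explored without the other), the occipital
labels (lingual, cuneus, precuneus, pericalcarine) into a single occipital
zone, and the putamen into the insular zone, so that electrodes crossing the
insula and ending in the putamen belong to the insular pattern.

Non-outlier trajectories from all patients, mapped to the average space
through each subject's affine, are pooled by exact descriptor equality into
*exploratory patterns*.

### Mean trajectories: iterative k-means with a significance rule

Large regions are often explored with several electrodes in one plan, so a
pattern may hold more than one distinct "lane" of trajectories. The number
of lanes is bounded by U, the largest number of same-descriptor electrodes
any single plan used. Each pattern is clustered by k-means starting at
k = U on the joint 6-D vectors (EP ⊕ TP) — joint, rather than clustering
entries and targets separately, so a cluster can never pair entries with the
wrong targets. A cluster is *significant* only if it holds at least 5 % of
the pattern's members (inclusive, compared on the real-valued product); if
any cluster fails, k is decremented and k-means rerun, down to a documented
floor of k = 1 (the behaviour when the rule would drive k below 1 is not
otherwise defined, and a pattern must yield at least one mean trajectory).

Each final cluster becomes a *mean trajectory*: centroid EP and TP plus
scalar dispersions σ_ep and σ_tp, the RMS Euclidean distance of member
points from the centroid. The dispersion is scalar rather than per-axis
because validation uses it as a radius. Within a pattern, clusters are
numbered by descending member count with ties broken by lexicographic order
of the entry centroid, so rebuilt bundles are bit-reproducible.

Two determinism choices matter here. First, the k-means RNG state depends
only on the user seed and the current k — never on the iteration history —
so the iterative procedure and an exhaustive sweep over k see identical
clusterings; the test suite exploits this to check the iteration against an
independent sweep oracle. Second, the k-means itself is the Hartigan–Wong
implementation in `stats::kmeans()` with 10 random restarts. Ten seeded
restarts give the same practical protection against bad local optima as a
dedicated seeding heuristic while reusing a battle-tested implementation;
the two exact cases (k = 1, and k equal to the number of distinct points)
are solved in closed form because `stats::kmeans()` does not accept them.

### Planning strategies: Jaccard clustering of plan vectors

Every plan becomes a boolean vector over the ordered mean-trajectory list —
one bit per mean trajectory the plan contributed to (membership comes from
the clustering assignment, not from re-matching). Plans are clustered
agglomeratively on pairwise Jaccard distance, 1 − |∩|/|∪| over the TRUE
supports (two empty vectors are at distance 0 by convention). Average
linkage (UPGMA) is the default: it is the usual companion of Jaccard
dissimilarity and avoids single-linkage chaining; the linkage is
configurable. The dendrogram is cut at a flat threshold — in clinical use
this is chosen by inspecting the dendrogram to balance the number of groups
against their population, so the threshold is an explicit parameter (CLI
default 0.7) and the dendrogram can be exported for exactly that inspection.

Each flat group yields a *strategy*: the bits supported by at least two
member plans. A singleton group can never reach that threshold; its
degenerate all-false strategy is kept and flagged rather than dropped, so
the group partition is preserved.

### Initialisation and the 2σ criterion

A strategy is mapped into a new subject by pushing each selected mean
trajectory through the inverse of the subject's affine. To score the mapping
against a manual plan, initialised and manual trajectories are paired by a
minimum-cost one-to-one assignment on d_ep + d_tp (Hungarian algorithm,
implemented in the package since no assignment solver is otherwise
available), restricted to descriptor-compatible pairs when the manual
descriptors are computable. A pair is *correctly mapped* when
d_ep ≤ 2σ_ep **and** d_tp ≤ 2σ_tp, both inclusive; the joint (AND)
reading follows the conjunction in the criterion's definition. The reported
fraction is over paired trajectories. A singleton mean trajectory has σ = 0
and can only pass at exactly zero distance; such pairs are flagged, since a
zero radius reflects lack of data, not precision.

## The synthetic cohort generator

No public SEEG planning cohort exists, so the package ships a simulator with
known ground truth; it is first-class, tested code. It emulates, in order:
plans drawn from a small set of planted strategies; each strategy a subset
of planted mean trajectories in a canonical average space; per-trajectory
isotropic Gaussian noise; per-electrode dropout; optional per-plan electrode
multiplicity; and random invertible per-subject affines, so the pipeline's
average-space normalisation is genuinely exercised rather than bypassed.
Ground truth is kept in a sidecar the pipeline never reads.

The label volume is deliberately schematic: the x axis is divided into
columns, each carrying a cortical entry slab near the top of the volume and
a deep target block below, separated by white-matter filler, so a roughly
vertical trajectory picks up exactly one descriptor. Pair columns hold two
planted mean trajectories 40 mm apart in y (so those patterns genuinely
need k = 2); singleton columns hold one.

Default conditions and the reasoning behind them:

* **40 plans, 4 strategies, 12 planted mean trajectories, noise σ = 2 mm,
  within-pattern separation 40 mm.** Noise of 2 mm per axis is a realistic
  figure for residual inter-subject variability after affine normalisation;
  40 mm separation is 20 σ, comfortably above the 10 σ regime where k-means
  recovery is reliable.
* **Each mean trajectory belongs to 3 of the 4 strategies** (balanced
  round-robin membership). With 10 plans per strategy this gives every mean
  trajectory about 30 member trajectories. The choice is driven by a
  chi-square tail bound: the planted-centroid error after averaging n
  members is √(σ²/n · χ²₃), and demanding sub-2 mm error *in every one* of
  hundreds of mean-trajectory draws needs n ≈ 30 (at n = 10 the per-draw
  failure probability is ~2 %, i.e. near-certain failure somewhere).
  Overlapping strategy supports also make plan clustering harder and
  therefore a more honest test: between-strategy Jaccard distance drops
  from 1 (disjoint) to ≈ 0.5.
* **Dropout 0.02 per electrode.** Real plans deviate from any fixed
  strategy; a small omission rate models that without detaching plans from
  their strategy: a plan must lose ≥ 4 of its 9 electrodes (probability
  ~2 × 10⁻⁵) before its Jaccard distance to its own group approaches the
  between-strategy level.
* **Recovery cut threshold 0.45**, midway between the within-strategy
  (~0.15) and between-strategy (~0.55) distances this geometry produces.
  This mirrors how the threshold is chosen in practice — from the
  dendrogram gap — and is distinct from the CLI's generic default of 0.7.
* **Column width 24 mm** (12 σ margins), making a noisy endpoint slipping
  into a neighbouring column's zone — which would mint a spurious pattern —
  a ~10⁻⁹ event.
* **Affine jitter**: rotations up to ±10°, isotropic scale 0.9–1.1,
  translations up to ±10 mm, representative of affine template
  registrations.

What the simulator does **not** emulate: real cortical geometry and
folding, atlas segmentation error, non-affine registration residuals,
vessel anatomy (the metrics module is tested on simple point/tube masks),
surgeon-specific target choices within a crossed zone, and the long-tailed
pattern-size imbalance of clinical cohorts. Passing the recovery suite
therefore shows the pipeline is correct under its stated noise model, not
that clinical cohorts of any particular size will yield this many patterns
or strategies.

## Numerical and degenerate-input choices

* All world coordinates are RAS mm; voxel indices are 0-based; points
  outside the grid read label 0.
* Affines must have last row (0,0,0,1) and an upper-left 3×3 determinant
  above 1e-12 in magnitude; registration round-trips are accurate to well
  below 1e-9 mm.
* The model bundle is one JSON document with a schema version; doubles are
  written with 17 significant digits so write→read is exactly the identity.
* U larger than the number of distinct points is clamped with a warning.
* Forbidden assignment pairs use a large finite cost and are reported as
  unpaired if chosen, keeping the Hungarian arithmetic finite.
* An empty vessel mask yields infinite clearance with a warning; the
  proximal/distal tract split depth defaults to 10 mm as a configurable
  surrogate for optimiser-specific definitions.

## Problem sizes in the test suite

The suite runs entirely on simulated data: 200 fuzzed patterns (≤ 30
members, U ≤ 4) against the sweep oracle; 20 cohort seeds of the default
40-plan design for end-to-end recovery; 1000 random affines; all 4096
ordered pairs of 6-bit vectors for the Jaccard closed form; 100 random 6×6
assignment instances against brute-force permutation enumeration; and a
2000-draw Monte-Carlo oracle for the expected 2σ pass rate on held-out
subjects. These sizes were chosen so the full suite documents the method's
behaviour in well under a minute on a laptop.

## Known limitations

* The descriptor's target rule is a proxy; where clinical judgement
  disagrees with "deepest admissible zone", the zone configuration must be
  edited to encode it.
* Strategies are as good as the cut threshold; no automatic selection
  (silhouette, gap statistic) is provided, by design.
* The initialised plan ignores patient-specific safety constraints; it is a
  starting point for optimisation, not an implantable plan, and the risk
  metrics here are simplified (no optimiser is included).
* FreeSurfer-native formats (aseg.mgz, .lta, talairach.xfm) are not read;
  inputs are plain NIfTI, CSV and 4×4 text affines, and conversion is the
  caller's responsibility.
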