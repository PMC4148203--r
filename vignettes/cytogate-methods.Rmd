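---
title: "Automated template gating: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated template gating: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytogate)
```

This vignette is the package's own account of what it computes, which
assumptions each step makes, and where a genuinely open design choice was
resolved one way rather than another.

## The gating model

A gating strategy is a rooted tree of populations. Every non-root population
carries a gate over one or two channels; its event set is, by construction,

$$\mathrm{ind}(\text{child}) = \mathrm{ind}(\text{parent}) \wedge
  g(\text{events}),$$

so child counts can never exceed parent counts, and all gate fitting sees
parent-population events only. This mirrors how manual analysts work and is
what makes the resulting populations interpretable and matchable across
samples without any post-hoc cluster alignment: the hierarchy *is* the
matching.

Index vectors are cached per (sample, population). The cache is what makes
Boolean combination analysis cheap: the $2^k$ disjoint subsets of $k$
threshold gates are tabulated from a per-event $k$-bit code assembled from
cached vectors, never by re-reading events. Replacing a gate invalidates the
cache for that population and its descendants; an invalidated-then-recomputed
tree is tested to equal a cold recompute.

**Half-open thresholds.** All 1-D thresholds and rectangle edges use
$[\min, \max)$. Consequence: the `+` and `-` partitions of a marker are
exactly disjoint and exhaustive, so the $2^k$ combination counts sum to the
parent count as an integer identity — the accounting that downstream
polyfunctionality analysis relies on. Whether manual gate boundaries are
closed or open is not standardised anywhere; half-open is this package's
convention, chosen for that exact-partition property, and documented rather
than inferred.

**Missing populations.** A failed fit (or an absent per-sample gate) marks
the population *missing* for that sample — all-false indices, proportion 0,
a `missing` flag in the statistics table, and a warning — instead of
aborting the run. An empty parent likewise propagates flagged zero-proportion
children. Rationale: in multi-hundred-sample studies a single pathological
sample must not kill the pipeline, and the flag keeps the omission visible.

## Gate-fitting algorithms

All density-based fitters share one KDE convention: Gaussian kernel,
Silverman rule-of-thumb bandwidth times a per-population `adjust` factor,
evaluated on a 512-point grid over the data range (or an explicit
`gate_range`), with extrema detected after 3-point smoothing and ties broken
toward smaller x for determinism.

- **mindensity** — threshold at the density minimum between the two dominant
  modes; `[t, Inf)` is positive. Two robustness guards are layered on the
  raw "two highest local maxima" rule, both needed in practice: a *height
  floor* (`peak_floor`, default 1% of the tallest peak) discards sampling
  bumps in KDE tails, and *prominence merging* treats adjacent peaks whose
  separating valley is shallower than 5% of the lower peak as one mode
  (noise double-tips on a single peak otherwise yield a "valley" inside it).
  Strictly unimodal input is an error ("no valley found") unless a
  `gate_range` licenses falling back to the deepest interior minimum.
- **tailgate** — for rare populations without a density valley. The density
  is normalised (peak = 1, support rescaled to unit width) and walked
  rightward from the dominant mode; past the steep shoulder (directional
  slope $\le -tol$), the threshold is the first grid point where the descent
  has flattened (slope $> -tol$, default `tol = 0.01`). The one-sided rule is
  deliberate: a two-sided $|slope| < tol$ test can step across its own
  acceptance window when a small positive bump makes the slope cross zero
  steeply, whereas "descent has flattened" is crossed exactly once. The
  quantitative stopping rule is this package's documented choice; `side =
  "left"` mirrors the data. The normalisation makes `tol` scale-free across
  channels.
- **quantileGate** — type-7 empirical quantile (default `probs = 0.99`),
  the standard reference-threshold construction from a non-stimulated
  control.
- **singletGate** — least-absolute-deviations line (IRLS) of height on
  area; keep events within `band` (default 2.5) MADs of the residuals, as a
  parallelogram spanning the area range. LAD rather than least squares so
  the doublet cloud does not drag the line.
- **boundary** — rectangle strictly inside supplied instrument limits,
  excluding events pinned at a detector's min or max. Limits must be
  *supplied* (`min=`/`max=` per dim; an absent side is open): defaulting to
  the observed range would by definition pin the most extreme observed
  event and contradict "no pinned events, all kept".
- **flowClust2d** — seeded EM over a K-component bivariate Gaussian
  mixture (k-means initialisation, 10 restarts, best log-likelihood),
  returning the $\chi^2_2(level)$ ellipse of the component nearest `target`
  (or the heaviest one). This is a deliberate behavioural simplification of
  t-mixture/Box-Cox model-based gating: heavy tails and skew are not
  modelled, which matters for outlier-rich channels and is why the ellipse
  coverage property is only asserted for Gaussian data.
- **dnaGate** — the CyTOF singlet gate. Each DNA intercalator channel is
  cut at the valleys separating its dominant (cell) mode from its nearest
  prominent neighbour below (debris/background) and above (doublets — on
  the DNA-DNA diagonal, unlike scatter doublets, so a diagonal band alone
  cannot remove them); within that box a LAD diagonal band of `band`
  (default 3) MADs keeps the singlet cloud. The exact construction is not
  prescribed anywhere; this box-plus-band geometry is the package's design,
  validated against labelled synthetic mixtures.
- **refGate** — copies a gate fitted on designated source samples (selected
  by a metadata key/value within each group, e.g. the unstimulated
  stimulation), optionally shifted; execution defers until the source
  samples' parent is gated.

Every fitter is a pure function of (data, args, seed); repeated calls are
identical, which is what makes whole-pipeline reruns byte-identical.

## The template language

Eight CSV columns: `alias, pop, parent, dims, gating_method, gating_args,
collapseDataForGating, groupBy`. Rows execute strictly in file order, and a
parent must be defined earlier (forward references are an error): the mental
model is a script, not a constraint solver. `pop` supports `marker+`,
`marker-`, two-marker forms, and `+/-` wildcards: `cd4+/-cd8+/-` expands to
the four quadrants sharing two fitted thresholds, so the quadrants partition
the parent exactly. Marker resolution against the data is case-insensitive
and punctuation-blind, against the marker map first and channel names
second — panels and FCS keywords rarely agree on spelling, and this is what
keeps one template applicable to any data set with the panel.

`groupBy` (colon-separated metadata keys) partitions samples per row;
`collapseDataForGating` pools the group's parent events so one gate is
fitted per group and attached to every member — used where samples must be
directly comparable, e.g. all stimulations of one subject-visit share one
cytokine threshold. A missing `groupBy` key in any sample's metadata is a
loud error, not a silent singleton group. `gating_args` cells are
comma-separated `key=value` pairs with typed coercion (number, `a:b` range,
logical, string).

## Boolean subsets and frequency filtering

`enumerate_subsets` emits all $2^k$ rows per (sample, parent), including
zero counts — downstream paired statistics need features aligned across
samples, so absence is data, not a missing row. `filter_low_frequency`
removes a (parent, combination) only if it fails the threshold (default 1%)
in *every* sample; whether such a filter should be per-sample or pooled is
ambiguous in common practice, and the keep-if-any rule is the conservative
choice for screening (documented here, easily changed by the caller).
Combination labels follow the declared marker order with `+`/`-` suffixes;
bit $i$ of `combo_code` is marker $i$, 1 = positive.

## Downstream statistics

Background correction subtracts the matched negative-control proportion per
(subject, visit, method, combination) and keeps negative values: truncating
at zero would break the symmetry that the paired analyses and the mixed
model assume under the null. Subset screening fits, per combination,

$$p_{sv} = \beta_0 + \beta_1 \mathbb{1}[\text{post}] + \beta_2
\mathbb{1}[\text{arm B}] + \beta_3 \mathbb{1}[\text{post}]\,
\mathbb{1}[\text{arm B}] + b_s + \varepsilon_{sv}, \quad b_s \sim N(0,
\sigma_b^2)$$

by REML and tests $\beta_3 > 0$ with a one-sided Wald test, Bonferroni-
corrected over combinations. Random intercept only — the simplest member of
the family consistent with "linear mixed model with random subject effect".
The Wald statistic is referred to a t distribution with the between-subject
degrees of freedom of the interaction contrast (subjects minus arms), not a
normal: in the balanced two-visit design the statistic *is* the two-sample t
on per-subject post-minus-pre differences, and simulation showed the normal
reference roughly doubles the familywise error at 50 subjects (0.096
measured over 500 null replicates, versus the Bonferroni-nominal 0.049).
The familywise type-I error of the whole screen is verified by
simulation (100 desk-scale null replicates; the acceptance script runs the
full 500) to stay near the Bonferroni-nominal level, and power against a
+0.01 absolute interaction with 0.002 residual SD is verified to exceed
90%.

Lin's concordance coefficient uses population (n-denominator) moments; the
degenerate conventions (both constant and equal → 1, both constant and
different → 0) make method-agreement reports total. The paired Wilcoxon test
drops zero differences, uses the exact signed-rank distribution when $n \le
25$ without ties (verified against full $2^n$ enumeration), and the
tie-corrected continuity-corrected normal approximation otherwise; all-zero
differences report $p = 1$ with an explicit flag rather than an error.

## What the synthetic data does and does not establish

The ICS generator emits one sample per subject x visit x stimulation with a
debris/doublet/dead/CD3/CD4/CD8 hierarchy, five cytokine-like markers with
rare positive tails (0.3–0.5% for true cytokines; 12–15% for the
cytotoxicity markers), a +0.01 absolute positivity spike in the responding
arm at post-vaccination for the spiked stimulations, and optional per-sample
drift of a designated marker's negative peak (uniform shift up to 0.8
transformed units, log-uniform SD scale up to 0.3 — the regime in which a
fixed global threshold demonstrably misclassifies at least 5x more events
than per-sample thresholds). The CyTOF generator emits an unstimulated and
two stimulated samples with DNA-DNA background/singlet/doublet structure,
four maturational subsets, and nine functional markers whose positivity is
1% per marker when unstimulated (so a 99th-percentile reference threshold
sits exactly at the positivity boundary) and subset-graded when stimulated
(naive low, effector-memory high degree of functionality).

Marker intensities are generated **directly on the transformed scale**, so
the generator can report exact ground truth (per-event labels, true valley
positions computed by brute-force minimisation of the analytic mixture
density) without compounding transform error; scatter channels are linear.
Events are Gaussian mixtures with independent channels given the class
label. Real data are not: spectral spillover, correlated autofluorescence,
CyTOF tailing and acquisition-time drift are absent. A green test therefore
establishes that the algorithms recover the stated structure when their
model assumptions hold — correctness and calibration of the machinery — not
that any particular clinical panel will gate well; that remains a
template-tuning exercise on real data, by design.

Two sizes appear deliberately. Most tests run desk-scale scenarios (2–3
subjects, 2,000–20,000 events). The drift-recovery bound (threshold within
±0.15 of the true valley for *every* sample) is asserted at 150,000 events
per sample, generated in batches of eight: at 20,000 events a CD8 parent
holds only ~4,000 events and the KDE-argmin sampling noise alone produces
occasional 0.2-unit excursions (its bias is ≤ 0.02), while production ICS
files are an order of magnitude larger still. The 470-sample accounting
check runs 1,000-event samples — cardinality, not precision, is what it
measures.

## Numerical and degenerate-input conventions

- Event data are float32 on disk and through FCS round-trips (the FCS `F`
  datatype); tests compare against an explicit float32 cast.
- Spillover compensation requires a unit diagonal and reciprocal condition
  number above 1e-12; compensation solves `observed = true . spill` by
  matrix inverse.
- KDE grids degenerate-widen by 1e-6 when all values are equal; density
  fitters require ≥ 50 finite values, mixtures ≥ 200, singlet gates ≥ 100.
- Polygon membership uses even-odd ray casting with boundary points counted
  inside (tolerance 1e-12 relative to vertex scale).
- EM restarts on degenerate covariances (ridge 1e-9) and fails only when
  all restarts degenerate.
- The exact Wilcoxon path requires no ties among |differences|; ties or
  n > 25 switch to the tie-corrected normal approximation.
- Seeds: every stochastic routine takes an explicit seed; per-sample
  streams are derived as `(seed * 10007 + 97 * index) mod (2^31 - 19)` so
  sample order and count do not perturb other samples' draws.

## Known limitations

- Only arcsinh (and linear/none) transforms; no logicle/biexponential.
- FCS reader: versions 3.0/3.1, list mode, datatypes F and I; analysis
  segments and FCS 2.0 are out of scope, as are FlowJo workspace import and
  GatingML export.
- Gaussian EM stands in for t-mixture model-based gating (see above).
- The store is single-writer; no compression or concurrent access.
- `screen_subsets` fits one model per combination; with thousands of
  combinations the loop is linear and unparallelised.
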