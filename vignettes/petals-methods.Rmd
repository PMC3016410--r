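---
title: "Petal mining and bimodal coexpression ranking: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Petal mining and bimodal coexpression ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petals)
```

This vignette is the package's own account of its science: the models
and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the design choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` do not themselves compute.

## 1. The model

### 1.1 Network refinement

Public PPI compendia carry a large false-positive load. Edge
reliability is modeled by logistic regression on four features per
edge:

| feature | meaning | range |
|---|---|---|
| `obs_count` | times the interaction was reported | 0, 1, 2, … |
| `coexpr` | Pearson correlation of the endpoint genes | [−1, 1]; 0 if either gene is off the array or constant |
| `clustering` | mean of the endpoints' clustering coefficients | [0, 1]; a node of degree < 2 contributes 0 |
| `localization` | Jaccard overlap of subcellular compartment sets | [0, 1]; 0 if either set is empty |

Training uses a curated positive edge set against randomly drawn other
edges (the classical assumption that a random interaction is probably
not a trusted one — note the negatives are therefore *noisily*
labeled, which bounds attainable held-out accuracy). The probability
cutoff is the mean over `n_repeats = 100` random 80/20 splits of the
held-out threshold maximizing Youden's J. Filtering keeps edges with
probability ≥ cutoff and never drops vertices, giving G′(V, E′).

False negatives are then imputed: two families *interact* when at
least one **observed** edge of G′ joins them; every non-adjacent pair
of proteins whose families interact gains an edge with provenance
`imputed` and observation count 0. Computing family evidence from
observed edges only makes imputation idempotent (an imputed edge never
begets more imputed edges), which the test suite checks.

### 1.2 Bounded path mining

For driver `c_a` and candidate `c_i`, the bound `d_i` is the BFS
distance in the **raw** network G, falling back to G″ only when the
pair is disconnected in G. The enumeration itself runs on G″. The
bound is *inclusive* (`length ≤ d_i`): an exclusive bound could return
no path at all for a connected pair, while the inclusive bound
guarantees that the shortest path itself is always among the
candidates — the property the heuristic exists to provide. Exhaustive
DFS is exponential in the bound, so
`build_blossom()` has a `max_bound` cap (default 8) and skips — with a
warning — candidates whose bound exceeds it; this is a safety valve of
this implementation, not part of the method.

Each path φ is scored two ways:

* `r(φ)`: mean of |r| over consecutive node pairs, thresholded at
  `γ = 0.6`; paths whose average absolute coexpression falls below γ
  are discarded (low-coexpression chains are unlikely to be jointly
  functional).
* `p_φ`: the path's GO association-rule count against a null of
  random simple paths with the same edge count, drawn by random walks
  that restart when they would revisit a node. With add-one smoothing,
  `p_φ = (1 + #{null ≥ observed}) / (1 + n_null)`, so `p_φ` is never 0.
  Rules are unordered pairs of leaf GO terms supported by protein
  pairs that are both co-members of a known pathway and adjacent in
  the network. The rule apparatus is deliberately simple — unordered
  term pairs, support counted over pathway-co-membership ∩ adjacency,
  fixed-length null paths — richer definitions (ordered rules,
  confidence/lift weighting) are out of scope. Since the nulls have
  the same length as the observed path, raw counts and per-edge
  averages give identical p-values, so raw counts are used.

Paths passing both filters merge into the petal; an empty petal means
no significant path, and such candidates are dropped from the blossom.

Within one petal the null rule-count sample is computed once per
distinct path length and shared across that petal's paths of the same
length — the null distribution depends only on the edge count, so this
is a pure performance measure (seeds derive from the master seed and
the length, keeping results independent of path enumeration order).

### 1.3 Activity, active coexpression, bimodality

Activity is the scaled absolute Welch statistic,

$$t_i = \frac{\mu_{MT,i} - \mu_{WT,i}}
       {\sqrt{\sigma^2_{MT,i}/n_{MT} + \sigma^2_{WT,i}/n_{WT}}},
  \qquad \alpha_i = \frac{|t_i|}{\max_j |t_j|} \in [0, 1],$$

with unbiased (n−1) sample variances. A gene constant in both groups
with equal means gets t = 0, not NaN; a gene constant in both groups
with shifted means has infinite t and is assigned activity 1 while
being excluded from the scaling maximum; if every t is 0, every α is
0. The denominator is $\max_j |t_j|$ over all genes on the array, so
α lands in [0, 1] with the most differentially expressed gene at 1.

Active coexpression weights each petal row by its activity,
`r′(i, x) = α_i · r(i, x)`, so coexpression only counts where the
source gene is differentially expressed. Pearson correlations pool WT
and MT samples into one correlation estimate (coexpression is a
property of the tissue, estimated from the combined normalized data;
a per-group option would halve the effective sample size); constant
genes get r = 0 so vectorization never propagates NaN.

The bimodality statistic compares second moments:

$$\beta_P = -\tfrac12\left( E[x^2_{P,D}] - E[x^2_{P,S}] \right),$$

with sample = vec(R′(P, D)) and background = vec(R′(P, S)), self pairs
excluded from both. Negative β means the petal's coexpression to the
targets has heavier two-sided tails than to the array at large —
coordinated positive *and* negative coregulation. The equivalent
torque formulation — the integral of x·ΔF(x) for ΔF the difference of
the two empirical CDFs — is implemented separately
(`beta_torque_oracle()`, trapezoidal rule on a grid spanning both
supports) purely as a cross-check; the acceptance suite verifies the
two agree to 10⁻³ at a 10⁵-point grid.

Significance: `n_perm` (default 10000) uniform target sets of size
|D| from S, `p = #{β_rand < β_P} / n_perm`. Three deliberate choices:

* **Cardinality |D|.** The random sets stand in for the target set D,
  so they match its size (configurable).
* **Lower tail by default.** More-negative β = stronger bimodal
  signal, so the one-sided lower-tail rank is the primary p-value;
  `two_sided = TRUE` ranks on |β| instead.
* **p = 0 is reportable.** The raw rank can be zero; `smoothed = TRUE`
  gives the add-one variant for downstream multiple-testing safety. A
  Benjamini–Hochberg column is appended to rankings as clearly
  supplementary output.

Background S includes D (D ⊂ S; excluding the targets from their own
background would bias β positive for small arrays). Empirical CDFs
use the right-continuous ≤ convention.

## 2. Parameters that matter

| parameter | default | unit / range | rationale |
|---|---|---|---|
| `gamma` | 0.6 | mean abs. correlation | the method's published path-coexpression operating point |
| `p_threshold` | 0.05 | probability | conventional significance level for paths |
| `n_perm` | 10000 | permutations | p resolution of 10⁻⁴; scale down (≥ 1000) for desk runs |
| `n_null` | 1000 | null paths | p_φ resolution of 10⁻³; 100 is the floor |
| `n_repeats` | 100 | training splits | stabilizes the averaged Youden cutoff |
| `min_support` | 1 | protein pairs | smallest defensible support for a reconstructed rule corpus |
| `max_bound` | 8 | edges | safety cap on exponential search (this implementation) |
| `cutoff` | trained | probability | override available: a historical operating cutoff depends on its exact network snapshot and cannot be re-derived |

All randomness flows from one master seed through named substreams
(per stage, per candidate, per path length), so per-candidate results
are independent of processing order and the pipeline is a pure
function of (inputs, config, seed).

## 3. The synthetic world

`generate_fixture()` emulates the *shape* of the data the method was
built for — desk-scale, with known ground truth:

* 500 genes; 8 WT + 8 MT samples (two fractions of four per condition
  collapse to eight per group); ~1500 background interactions from a
  preferential-attachment model; 31 proteomic targets; 6 candidate
  genes, each linked to the driver by a planted 3-edge path; 600
  planted low-evidence edges for the filter to remove.
* Expression follows a latent-factor model: each petal has a factor
  `f_c = φ·g + √(1−φ²)·u_c` coupled (φ = 0.6) to a shared driver
  factor `g`; petal genes load 0.93 on their factor; half the targets
  load ±0.81 on the *planted* petal's factor (alternating sign — that
  is what makes the coexpression bimodal); the rest are noise.
  Differential expression is a +1.5 mean shift on petal genes in MT
  (|t| ≈ 3 at n = 8 + 8) with small N(0, 0.3) shifts on background
  genes so activity is non-degenerate.
* Annotations give position k of every planted path the k-th
  "signaling" leaf term (plus its parent, exercising leaf
  restriction), and each planted path is also a known pathway, so
  every planted edge is supported by a mined rule; background genes
  get random terms from a disjoint pool, so random paths carry ~0
  rules.
* Planted-path proteins carry petal-specific families and the driver
  its own, so if the reliability filter drops a planted edge the
  imputation stage restores it from the surviving sibling edges — the
  same mechanism by which imputation reconnects candidates on real
  data. Random background edges avoid planted-path nodes entirely, so
  each petal's node set is unambiguous ground truth.

**Calibration, derived once from the model algebra** (not tuned
against test outcomes): with shift δ, pooled correlation between
co-shifted genes gains a δ²/4 term and gene variance a factor
v = 1 + δ²/4, so

* adjacent petal genes: r = (0.93² + 0.5625)/1.5625 ≈ 0.91, chosen so
  the planted path clears γ = 0.6 with ≥ 3 Fisher-z standard errors
  at n = 16;
* petal gene ↔ true target: r = 0.93·0.81/√1.5625 ≈ 0.60, the stated
  operating point;
* decoy petal gene ↔ true target: r ≈ 0.93·φ²·0.81/1.25 ≈ 0.22 —
  leakage through the driver coupling is quadratic in φ, which is why
  φ = 0.6.

**What the generator does not emulate** — and hence what a green test
does not establish: probe-level microarray noise and normalization
artifacts; the heavy-tailed degree of real PPI data beyond what
preferential attachment gives; correlated annotation errors; any
identifier-mapping problem (one shared namespace is assumed
throughout); and gel-proteomics physics. Green tests establish that
the *algorithms* do what the model says, not that the model captures
intestinal tumor biology.

## 4. Numerical and degenerate-input choices

* Pearson r of constant genes is 0 (flagged), never NaN.
* An all-zero activity vector yields an all-zero R′ and β = 0.
* `beta()` rejects empty or non-finite inputs outright.
* The torque oracle pads its grid by 10⁻⁹ of the range so the
  rightmost support point is inside the integration window.
* Youden thresholds are midpoints between adjacent held-out
  probabilities, clamped inside (0, 1).
* Petals and paths are emitted in lexicographic order; ranking ties
  break by β, then candidate name.
* Self-loops in edge lists are skipped with a warning; repeated lines
  sum observation counts; imputed edges always carry count 0.

## 5. Known limitations

* Exhaustive path enumeration is exponential in the diameter bound;
  the `max_bound` cap trades completeness for predictability on dense
  networks.
* The null-path sampler (random walk with restart-on-revisit) is the
  stated reconstruction, not a uniform sampler over simple paths; for
  rule-count nulls this bias is second-order but real.
* With 16 samples, correlation estimates carry Fisher-z standard
  errors of ≈ 0.28; at the stated target-petal correlation of ≈ 0.6 a
  noticeable minority of simulated replicates realize jointly low
  correlations and the permutation test cannot flag the planted petal
  — a sample-size limit of the stated world, not a code path that can
  be fixed (quantified in the acceptance suite and the decisions
  ledger).
* Negative training edges are noisily labeled by construction, so
  held-out accuracy of the reliability model on real-shaped data is
  bounded well below 1 even when the model is correct.
* The reliability filter is a thresholded probabilistic classifier: at
  a class separation of 2 within-class standard deviations on one
  feature its misclassification rate per class is the Bayes rate
  Φ(−1) ≈ 15.9%, which no cutoff choice can beat. Recovery of a
  planted unreliable-edge set can therefore only be as good as that
  bound allows (the acceptance suite measures the filter at the Bayes
  optimum).
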