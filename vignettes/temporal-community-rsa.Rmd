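---
title: "Detecting temporal community structure in multivariate trial responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting temporal community structure in multivariate trial responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Observers view long sequences of visual objects. Fifteen *recurring* objects
reappear hundreds of times; occasional *singular* objects appear exactly once.
In the *structured* condition the recurring objects are arranged on a modular
graph — three "temporal communities" of five objects each, every node of
degree 4 — and the presentation order is a constrained random walk on that
graph, so objects of a community tend to follow one another. In the
*unstructured* condition the walk runs on the complete graph and no
sequential dependencies exist.

Multivariate responses are recorded per functional parcel (roughly 200
voxels, 9 time points per trial, so an `Ndim = 9 * Nvox`-dimensional pattern
per trial). Two questions are asked of these patterns:

1. **Identity selectivity** — can the object shown on a trial be decoded
   from the pattern?
2. **Community sensitivity** — are patterns evoked by objects of the *same*
   community more (or less) similar than patterns evoked by objects of
   *different* communities, over and above identity itself?

The second question is deceptively fragile: community co-membership is
correlated with temporal proximity by design (same-community trials are
close in time), and trial responses are temporally autocorrelated, so naive
distance comparisons manufacture "community structure" out of slow drift.
Most of this package is machinery for asking question 2 without fooling
oneself.

## The analysis pipeline

### Discriminative subspace (direct LDA)

Per observer and parcel, responses are reduced from `Ndim` dimensions to the
`kappa - 1 = 14`-dimensional subspace `S` that optimally discriminates the
`kappa = 15` recurring-object classes, via direct linear discriminant
analysis (DLDA): eigendecompose the between-class scatter and whiten its
range (at most 14 dimensions survive), then eigendecompose and whiten the
within-class scatter inside that range, then standardize every output
dimension to unit variance on the training data. The standardization makes
Euclidean distance in `S` a standardized (Mahalanobis-like) distance. Two
numerical guards keep the fit stable when `Ndim` is large relative to the
trial count: between-class eigenvalues below `1e-10` of the leading one are
dropped, and within-class eigenvalues are regularized by `1e-6` of their
mean before inversion. Eigenvector signs follow a
largest-component-positive convention, so fits are bit-reproducible.

With unit-variance coordinates, the *normalized amplitude*
`a_k = sqrt(mean(y_k^2))` of a projected trial sits just below 1 (the root
mean square of 14 standardized coordinates), and the *normalized distance*
`d_kl = sqrt(mean((y_k - y_l)^2))` between unrelated trials sits near 1.40
— the mean distance between two random points on the 14-dimensional unit
hypersphere, `expected_random_distance(14) = 1.4017`, computed from the
closed Gamma-function form. We define the function on the sphere dimension
`n` (the sphere `S^n` lives in `n + 1` ambient dimensions): the circle is
`n = 1` with mean chord `4 / pi`, the ordinary sphere `n = 2` with `4 / 3`.

### Where the subspace is fitted: cross-run by default

`parcel_distances()` fits the subspace, for every run, on the *other* runs
only, and projects the held-out run before measuring its pairwise distances
(`subspace_fit = "cross-run"`). Fitting once on all data
(`subspace_fit = "all"`) is also offered, but it is not the default for a
reason we consider a genuine methodological point: with temporally
clustered communities, slow drift leaks into the estimated class means —
same-community classes co-occur within episodes and inherit correlated
drift — and a subspace optimized on the same data amplifies exactly those
directions. The resulting bias makes within-community distances smaller at
*every* latency, so it survives both the residual correction and the
latency sweep below. In simulations with drift and no community effect the
all-data fit produced consistently positive community sensitivity, while
the cross-run fit is centred on zero. Identity decoding
(`classify_accuracy()`) is cross-validated for the same reason, with the
`fitted_on` field of every subspace keeping an audit trail.

### Temporal-autocorrelation residualization

All within-run pairs of recurring trials enter a
`pairwise_distance_set` with their object pair, latency `delta` (in trials;
one trial is 3 s), and normalized distance. Per parcel, the delay profile
`T(delta)` — the mean distance at each latency, pooled over observers and
runs — estimates the autocorrelation footprint; with the calibrated
generator defaults it shows the empirical regime of roughly 5% smaller
distances at delays below 4 trials. `residual_correct()` then forms

```
d_corr = d_raw - T(delta) + mean(T)
```

where `mean(T)` is the unweighted average over observed delays. The
correction recentres every delay onto the grand mean, is idempotent, and
refuses (rather than extrapolates) when a pair's delay is missing from the
profile. The profile includes same-object pairs by default
(`include_same_object = TRUE`): it describes temporal correlation of
responses, not object structure; a switch excludes them.

### Community sensitivity, latency sweep, and the consistency criterion

Corrected distances between *distinct* objects are split into
within-community and between-community groups;
`delta_bw = D_B - D_W` is the signed community sensitivity (positive =
relative within-community attraction), tested with a pooled-variance
two-sample t-test (`t_bw`; Welch by flag). Same-object pairs are excluded:
including them would conflate identity selectivity with community
structure, and the four pair types — same/different community crossed with
adjacent/non-adjacent, splitting the 105 pairs 27/3/3/72 on the modular
graph — are defined only for distinct objects. `pair_type_stats()` compares
each type against the pooled distances of all four types (the pool
deliberately contains the tested type's own members; the overlapping-sample
t-test is the documented behaviour).

Because within-community pairs have systematically shorter latencies, a
residual confound would be strongest at short latencies.
`latency_sweep()` therefore recomputes `t_bw` for every lower latency bound
`tau_lb` in `1..30` (trials), adjusting p-values across parcels within each
bound by Benjamini–Hochberg FDR (`q = 0.05`). The consistency measure
`tau_sig` is the largest bound up to which *every* bound was significant; a
parcel counts as community sensitive only when `tau_sig` reaches 30, i.e.
the effect persists even when all pairs closer than 30 trials (90 s) are
discarded. A bound with no surviving pairs counts as non-significant, so a
parcel with sparse long-latency coverage can never be declared sensitive.

The statistical unit is the trial pair. Distances sharing a trial are
dependent, which leaves the t statistic mildly overdispersed (empirically
`sd(t)` near 1.15 under the null) — two-sided rejections run somewhat above
nominal, symmetrically in sign. We evaluated aggregating to object-pair
cell means per (observer, run) instead; it removes the overdispersion but
is so conservative at desk scale that even the raw-distance temporal
artifact becomes undetectable, which would defeat the diagnostic contrast
the sweep is designed to expose. The `tau_sig = 30` consistency screen,
plus FDR across parcels, is the operative guard.

### Identity decoding and group inference

`classify_accuracy()` performs leave-one-run-out nearest-centroid decoding:
per fold, subspace and class centroids are fitted on the training runs,
held-out trials are assigned to the nearest centroid (ties broken by lowest
object id, for determinism). Group-level inference uses the *minimum*
accuracy across observers with a permutation null: labels are shuffled
within run (preserving per-run class counts), the full cross-validated
minimum is recomputed `B` times, and `p_min = (1 + #{null >= obs}) /
(B + 1)`. Fewer than 100 permutations are refused. This tests the global
null that *no* observer carries identity information; when some observers
carry signal and one does not, the observed minimum falls to chance level
but the test may still reject — correctly, since the global null is false.
The full prevalence machinery (what fraction of observers carry
information) is deliberately out of scope.

### Geometry: automorphism averaging and embedding

Observers need not share activity patterns, so their 15 x 15 object
distance matrices cannot be averaged entry-wise. Averaging each matrix over
all permutations of object labels that preserve graph structure makes every
entry depend only on the structural relation of its pair, after which
observer averaging is meaningful. The modular graph's automorphism group
has order 1296 — the 6 symmetries of the community triangle times `3!`
permutations of the three internal objects per community; the two linking
(boundary) objects of a community are pinned by which neighbouring
community they connect to — and `permutation_average()` uses the exact
group average by default. It is a projection (idempotent) and preserves the
off-diagonal grand mean; a sampled mode reproduces the
random-permutation estimator and converges to the exact average. The
averaged matrix is embedded in the plane with nonmetric MDS (stress-1,
`MASS::isoMDS`, best of 20 seeded restarts plus a classical-scaling start;
metric scaling by flag). The three-fold symmetry of the embedded maps is a
consequence of the averaging, and `internal_linking_summary()` tabulates
mean distances by role pair (internal/linking) and community relation.

## The synthetic generator

`simulate_parcel()` produces a trial response as

```
x_k = mu_obj(k) + community_beta * (c_comm(k) - mu_bar) + drift_k + eps_k
```

- `mu_o`: fixed random class means, per-dimension SD `identity_snr *
  noise_sd`. The identity signal lives in (at most) 14 dimensions of
  class-mean differences, as the analysis assumes.
- `community_beta` shifts each class mean away from the grand mean toward
  (or past) its community centroid. For two objects of the *same* community
  the term cancels exactly, so `beta > 0` increases between-community
  separation only: relative within-community attraction, matching positive
  community sensitivity. Negative `beta` yields the opposite sign. This is
  deliberately a mean-shift mechanism (not a covariance change): it induces
  the distance pattern the statistics target and is analytically checkable.
  The sign relation is monotone only up to moderate `|beta|`; the
  recovery suite documents a detection threshold near `|beta| = 0.5` at its
  study size and uses 0.6.
- `drift_k`: a shared additive AR(1) vector across trials (`drift_rho =
  0.8`, stationary SD `drift_sd = 0.43`, reset between runs). The defaults
  are calibrated so the delay profile of projected responses dips by about
  5% at delays below 4 trials — the empirical short-delay regime the
  residualization must remove. The slight excess above the grand mean at
  delays 6–15 emerges only weakly from an AR(1) mechanism; we treat the
  published mid-range excess as a calibration target without claiming a
  mechanism, and do not reproduce its full size.
- `eps_k`: isotropic Gaussian noise, SD `noise_sd = 1` (all signal
  strengths are expressed relative to it).
- Singular trials get a fresh random mean each and no community term, so
  projection and exclusion logic is exercised.

`simulate_study()` gives every observer independent sequences, class means
and noise — the analysis never assumes shared patterns across observers —
and is bit-reproducible from its seed; all randomness in the package flows
through explicit seeds (kept below `2^31`).

Sequences follow the experimental design: quasi-random walks with no
immediate repetition (X to X) and no direct return (X to Y to X), the start
node uniform and the second step excluding only the start;
post-selection of the best of `n_candidates = 200` walks under a
least-squares balance cost over per-object counts and directed-edge usage
counts (the published design defers the exact counterbalancing rule to
prior work, so the cost is explicit and configurable); and 20 singular
trials interspersed at uniform positions among the 180 recurring trials of
a run. Repetition-latency and community-episode statistics are computed on
the recurring-object walk with singulars excluded; under that convention
the structured walks show a median repetition latency near 5.5 steps and a
mean episode length near 9.4 trials (about 28 s at 3 s per trial), and the
unstructured walks a median latency near 10.5. For unstructured walks under
counterfactual labels the episode length has the closed form
`1 + (4/13) / (1 - 3/13) = 1.4`: after the first within-community step the
previous node blocks one continuation, a small point the no-backtracking
constraint forces.

### What the generator does not emulate

No hemodynamics, no voxel-level spatial correlation, no head motion, no
overlapping analysis windows (the AR(1) drift stands in for their net
autocorrelation), no behavioural task. Passing tests therefore show that
the *statistical* machinery recovers known structure under the stated
noise model — not that real responses satisfy that model. In particular
the generator's noise is isotropic and Gaussian; heavy-tailed or spatially
structured noise would first hit the DLDA whitening stage.

## Problem sizes and numerical choices

The verification suite runs the pipeline at desk scale: parcels of 45–100
voxels with 1–2 time points (`Ndim` 45–90 instead of ~1800), 2–18 runs of
200 trials, and walk ensembles of 100 x 180 steps. The spurious-sensitivity
control uses the design's full 18 runs per replicate; the recovery study
uses 2 observers x 6 runs. Counterbalancing candidate pools are reduced
(10–20) where only walk legality matters. Tolerances follow the quantity:
exact identities (pair counts, `delta_bw = D_B - D_W`, BH adjustment) are
asserted to machine precision; stochastic regime statistics to 10%;
Monte-Carlo cross-checks to their sampling error.

Degenerate inputs fail loudly: classes with fewer than two trials, a
between-class scatter that is numerically zero, latency bounds that empty a
group, delays missing from a profile, and permutation counts below 100 are
all errors, not silent fallbacks.

## Known limitations

- The pooled trial-pair t-test inherits mild overdispersion from distance
  dependence (above); per-parcel inference leans on the consistency screen
  and cross-parcel FDR rather than exact type-I control.
- `tau_sig` is reported in trials; with sparse designs the bound-30 subset
  can be empty, in which case the parcel is capped at the largest defined
  bound and cannot be flagged sensitive.
- The automorphism enumeration is specific to the canonical modular graph;
  arbitrary graphs are supported structurally elsewhere but not here.
- The minimum-statistic test addresses the global null only; prevalence
  estimation is out of scope.
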