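---
title: "Mutant-cycle free-energy analysis with mutantcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutant-cycle free-energy analysis with mutantcycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutantcycle)
```

## The model

The package works with changes in the free energy of unfolding upon
mutation. For a mutation set $S$ (the wild type being the empty set), the
stability change between a reference state $r$ and a target state $t
\supset r$ is $\Delta\Delta G_r^t$ in kJ/mol. Three layers of structure
are built on top of these numbers.

**Double mutant cycle.** For a pair of mutations $A$, $B$,

$$\delta_r^{AB} = \Delta\Delta G_r^{AB} - \Delta\Delta G_r^{A}
  - \Delta\Delta G_r^{B}.$$

$\delta = 0$ is perfect additivity; $\delta \ne 0$ is a thermodynamic
coupling. Because free energy is a state function, $\Delta\Delta G_r^{AB}$
may equivalently be accumulated along any pathway of measured legs
(directly, or via the $A$ or the $B$ intermediate), and all pathways agree
on a consistent table — a property the test suite asserts to $10^{-10}$
kJ/mol.

**Triple mutant box.** With an external third mutation $C$, the pair's
coupling in the $C$ background is $\delta_C^{AB}$, computable either
directly (the cycle formula with $C$ as reference) or by the exact
decomposition

$$\delta_C^{AB} = \delta_{WT}^{AB} + \Delta\Delta G_{AB}^{ABC}
  + \Delta\Delta G_{WT}^{C} - \Delta\Delta G_{A}^{AC}
  - \Delta\Delta G_{B}^{BC},$$

which expresses the background effect through the cost of introducing $C$
into each corner of the original cycle. Both routes are consequences of
state-function additivity; `triple_box()` exposes both and the suite
verifies their identity on randomly generated consistent tables.

**Unfolded-state cancellation.** A stability change is the difference
between the alchemical transformation in the folded and the unfolded
state. When unfolded legs are unavailable, `ddg_from_legs()` can treat a
mutation's unfolded contribution as a constant shared by every
introduction of that mutation. The resulting $\Delta\Delta G$ values are
only defined up to per-mutation offsets (they are flagged
`offset_relative`), but every coupling $\delta$ is invariant under such
offsets, because each single mutation enters a cycle once with each sign.
This invariance is asserted exactly in the tests, and it is the reason the
cycle analysis is robust to unfolded-state errors.

## Free-energy estimators

The package's work-based estimators replace molecular-dynamics output with
any source of forward/reverse non-equilibrium work samples (`work_set`,
kJ/mol, each direction's work stored in its own convention).

* **BAR** solves the Bennett self-consistency condition
  $\sum_i f(\beta(W_i - \Delta G) + M) = \sum_j f(\beta(W'_j + \Delta G) -
  M)$, $f$ the Fermi function, $M = \ln(n_f/n_r)$, by bracketed root
  finding. The residual is monotone in $\Delta G$, so the root is unique;
  the bracket is $[\min - 10s, \max + 10s]$ of the pooled values
  $\{W_f, -W_r\}$ (half-width floored at 1 kJ/mol so degenerate inputs
  still bracket), and the tolerance is $10^{-8}$ kJ/mol. When the two work
  distributions do not overlap the residual is numerically flat and any
  root is meaningless; this is detected through the Fermi occupancy at the
  solution and reported as an explicit error rather than a silent extreme
  value.
* **CGI** fits normal densities to the forward and negated-reverse work
  and returns their intersection between the two means (the Crooks
  theorem places the true crossing at $\Delta G$). Equal fitted variances
  give the midpoint of the means; unequal variances solve the log-density
  quadratic, and the absence of a crossing between the means — possible
  for heavily nested distributions — is an error with a diagnostic.
* **Jarzynski** provides one-sided exponential averages, computed with a
  log-sum-exp reduction. The finite-sample estimator is biased (forward
  high, reverse low), so the two one-sided estimates straddle BAR *on
  average*; per replicate the ordering holds only in a majority of runs
  because the estimators are strongly correlated, and the tests assert the
  statistical ordering at 95% confidence rather than a per-replicate
  guarantee.

Uncertainties come from `bootstrap_error()`: independent resampling with
replacement within each direction, the standard deviation of the
estimator over resamples. The default is 100 resamples with R's seeded
default generator; the seed policy (forward indices drawn before reverse,
one `set.seed` per call, caller's RNG state restored) is part of the
documented contract and is mirrored by an independent naive loop in the
tests.

Defaults: $T = 298.15$ K with $k = 0.008314462618$ kJ/(mol K); work files
are plain text, one value per line, `#` comments allowed.

## Error propagation in the cycle algebra

Every coupling is a signed combination of table entries. `nonadditivity()`
and `triple_box()` first resolve each $\Delta\Delta G$ term to a pathway
of table edges (shortest chain; ties broken by lexicographic order of the
intermediate state labels, for determinism), then accumulate the *net
coefficient* of every edge. Uncertainty is quadrature over edges weighted
by their net coefficients. This matters when pathways share edges: in a
table holding only single-introduction legs, $\Delta\Delta G_{WT}^{AB}$
composed via $A$ reuses the $WT \to A$ leg that the $-\Delta\Delta
G_{WT}^{A}$ term subtracts, and the shared noise cancels exactly. Naive
quadrature over the three composed terms would overstate the error by
$\sqrt 2$; with edge-level propagation the reported standard error matched
the replicate standard deviation within a few percent in the package's
simulation tests. When all three terms are independent table entries the
result coincides with the familiar three-term quadrature
($\sqrt{3}\,\sigma$ for equal uncertainties). Covariances between
separately estimated legs are assumed zero; correlated-leg input is out of
scope.

Charge-changing mutations (aspartate/glutamate/lysine/arginine gained or
lost, e.g. N118D) are flagged on parsing, but the table algebra treats
their edges like any others — couplings involving them are computed from
the plain cycle formula with no charge corrections.

A pair is *called* coupled by `is_correlated()` when $|\delta| >
\max(1\ \mathrm{kJ/mol}, 2\sigma)$. The 1 kJ/mol floor is a practical
choice of the order of typical leg uncertainties; any δ ≠ 0 is a coupling
in principle, but a threshold is needed for classification, and the same
1 kJ/mol default is used by `classify_change()` to separate "additive"
from "coupled" backgrounds.

## Scans and classification

`positional_scan()` computes $\delta_C^{AB}$ for every substitution at one
external position (19 non-wild-type canonical residues by default, the
identity substitution always excluded) and summarises the position by the
mean unsigned coupling with its standard error (sample SD of $|\delta|$
over substitutions divided by $\sqrt n$; the $n-1$ SD is used).
Substitutions whose edges are missing from the table are excluded and
listed, not fatal. `classify_change()` maps a (reference, new) coupling
pair to one of five exhaustive, mutually exclusive categories — erased,
emergent, inverted, amplified, retained — anchored at the additive
threshold.

## Benchmarking

`compare_ddg()` reports the average unsigned error, the Pearson
correlation, the ordinary-least-squares regression of calculated on
experimental values (the axis convention is a deterministic package
choice), and the fraction of points within a ±band, default 4.184 kJ/mol
(1 kcal/mol). Degenerate inputs with zero variance yield a typed
"undefined" correlation rather than NaN. `stratify_by_distance()`
partitions pairs into half-open distance bins $[e_i, e_{i+1})$ and
benchmarks each bin, flagging bins with fewer than two points as
insufficient; this supports the question of whether predictive accuracy
is retained from proximal to distant pairs.

Distances come from `read_structure()` / `residue_distance()`: PDB ATOM
records (HETATM ignored), alternate locations resolved per atom to the
highest occupancy with ties going to altloc "A", insertion codes appended
to the position. Both the Cα–Cα and the minimum heavy-atom (non-hydrogen)
distance are exposed; `min_heavy` is the stratification default since
side-chain proximity is what mediates direct contacts. Which atoms to use
is genuinely open — both conventions appear in the literature — so both
are first-class.

## The synthetic generator

`generate_landscape()` plants a ground-truth free-energy surface:

$$G(S) = \sum_{m \in S} g_m \;+\; \sum_{\{a,b\} \subseteq S} c_{ab}
 \;+\; \sum_{(\{a,b\},c) \subseteq S} t_{abc}, \qquad G(WT) = 0,$$

with additive single effects $g_m \sim U(-8, 8)$ kJ/mol, pairwise
couplings $c_{ab} \sim U(-10, 10)$ and triangular terms $t_{abc} \sim
U(-10, 10)$. The coupling range spans the largest couplings reported for
strongly nonadditive pairs in staphylococcal nuclease (around 10 kJ/mol),
and the single-effect range covers typical stability changes of point
mutations; the triangular range allows full cancellation of any pair
coupling, the "eraser" scenario in which one background substitution
makes a strongly coupled pair perfectly additive ($t = -c$).

`emit_ddg_table()` converts a landscape into the measurable quantity —
single-introduction edges of a mutation hypercube, plus optional Gaussian
noise with the noise SD recorded as the entry uncertainty.
`generate_work_samples()` draws forward work from $N(\Delta G +
\beta\sigma^2/2,\ \sigma^2)$ and reverse work from $N(-\Delta G +
\beta\sigma^2/2,\ \sigma^2)$ — the unique family that is Gaussian in both
directions and satisfies the Crooks fluctuation theorem exactly, which
makes the planted value recoverable without model error and keeps the
tests analytic.

What the generator does *not* emulate: anharmonic or multimodal work
distributions, correlated legs, slow conformational degrees of freedom,
unfolded-state structure, or any force-field physics. Passing the
recovery tests therefore shows the *statistical machinery* is correct and
calibrated — not that any particular simulation protocol would reach the
same accuracy on a real protein.

## Numerical choices and problem sizes

* BAR root tolerance $10^{-8}$ kJ/mol; identity checks between exact
  algebraic routes are asserted at $10^{-10}$; oracle equality for plain
  statistics at $10^{-12}$.
* Bootstrap default 100 resamples; the simulation tests use 30–40
  resamples per edge, which is enough for a standard error known to
  ~10–15%.
* The parameter-recovery suite uses 200 replicates at 1000–5000 work
  samples per direction for the estimators, and 200 independent pairs at
  300 samples per direction and per edge for the end-to-end chain — sizes
  at which the expected coverage of a $3\sigma$ interval comfortably
  exceeds the asserted 95%.
* Degenerate inputs are first-class: zero-variance work sets, zero-noise
  tables, empty bins and zero-variance benchmark vectors all take defined
  paths rather than erroring or propagating NaN.

## Known limitations

* Uncertainties assume independent table entries; no covariance input.
* `compose_path()` enumerates simple paths for its consistency
  diagnostic, which is exponential in pathological dense tables; the
  intended inputs are mutation hypercubes and sparse experimental tables.
* The PDB reader handles single-model ATOM records only (no mmCIF,
  assemblies, or symmetry mates), by design.
* One-sided Jarzynski estimates carry finite-sample bias and are provided
  as a consistency check, not as the primary estimator.
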