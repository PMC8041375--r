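# mutantcycle

Thermodynamic coupling analysis of protein mutations in R: double and
triple mutant cycle free-energy algebra, non-equilibrium work estimators,
third-site mutational scans, and calc-vs-experiment benchmarking.

## The problem

When two residues of a protein are mutated together, the change in the
free energy of unfolding is often not the sum of the single-mutation
effects. The deviation

δ<sub>ref</sub><sup>AB</sup> = ΔΔG<sub>ref</sub><sup>AB</sup> −
ΔΔG<sub>ref</sub><sup>A</sup> − ΔΔG<sub>ref</sub><sup>B</sup>

is the *nonadditivity* of the pair (A, B) at reference state *ref*
(subscript = reference, superscript = target). δ = 0 means the mutations
act independently; δ ≠ 0 means they are thermodynamically coupled — a
physical counterpart of the correlated-mutation signal exploited by
contact prediction and protein design. Couplings can persist over large
distances, and, remarkably, a coupling between a pair can be switched on,
off, amplified or inverted by a *third* mutation elsewhere in the protein.
The triple mutant box quantifies this: δ<sub>C</sub><sup>AB</sup> is the
pair's coupling in the background of mutation C, and it decomposes exactly
into the wild-type coupling plus the free-energy costs of introducing C
into each corner of the original double mutant cycle.

`mutantcycle` implements this algebra with edge-level error propagation,
plus everything needed to feed and validate it:

* **Estimators** — ΔG from forward/reverse non-equilibrium work samples by
  the Bennett acceptance ratio (BAR), the Crooks Gaussian intersection
  (CGI), and one-sided Jarzynski averaging, with seeded bootstrap
  uncertainties (`estimate_bar()`, `estimate_cgi()`,
  `estimate_jarzynski()`, `bootstrap_error()`).
* **Cycle algebra** — ΔΔG tables keyed by (reference, target) mutation
  states, pathway composition, nonadditivity, and the triple-box
  decomposition (`ddg_table()`, `compose_path()`, `nonadditivity()`,
  `triple_box()`).
* **Scans** — all substitutions at an external site, summarised by the
  mean unsigned coupling, and classification of each background as
  erasing / retaining / amplifying / inverting / creating the coupling
  (`positional_scan()`, `classify_change()`).
* **Benchmarking** — average unsigned error, Pearson correlation, linear
  regression and the fraction within ±1 kcal/mol (4.184 kJ/mol) against
  experiment, with optional inter-residue-distance stratification
  (`compare_ddg()`, `stratify_by_distance()`, `read_structure()`,
  `residue_distance()`).
* **Synthetic ground truth** — free-energy landscapes with planted
  pairwise and triangular couplings and exactly Crooks-consistent Gaussian
  work distributions, so every stage can be checked against known answers
  (`generate_landscape()`, `emit_ddg_table()`, `generate_work_samples()`).

All energies are kJ/mol; temperatures kelvin; k = 0.008314462618
kJ/(mol·K).

## Worked example

Estimate a free-energy leg from work samples, compute a coupling, and
watch a third mutation erase it:

```r
library(mutantcycle)

## BAR on Crooks-consistent work samples with a planted dG of 5 kJ/mol
ws <- generate_work_samples(true_dg = 5, sigma = 2, n_forward = 1000,
                            n_reverse = 1000, seed = 42)
estimate_bar(ws, n_boot = 100, seed = 1)
#> 4.980 ± 0.045 kJ/mol (bar)

## a strongly coupled pair: delta = 9 - 2 - 3 = 4 kJ/mol
tab <- ddg_table(reference = c("", "", ""),
                 target = c("L37A", "G79S", "L37A+G79S"),
                 value = c(2.0, 3.0, 9.0), uncertainty = 0.5)
nonadditivity(tab, "L37A", "G79S")
#> delta_WT^{L37A+G79S} = 4.000 ± 0.866 kJ/mol

## a planted triangular term that cancels the pair coupling
model <- generate_landscape(n_sites = 4, n_pair_couplings = 1,
                            n_triangular = 1, pair_range = c(5, 9),
                            seed = 7)
model$triangular[[1]]$effect <- -model$pair_couplings[[1]]$effect
tri <- model$triangular[[1]]
box <- emit_ddg_table(model, list(c(tri$pair, tri$third)),
                      noise_sd = 0.3, seed = 11)
d_wt <- nonadditivity(box, tri$pair[1], tri$pair[2])
d_bg <- triple_box(box, tri$pair[1], tri$pair[2], tri$third)
format(d_wt)
#> "delta_WT^{C4T+H3K} = 6.358 ± 0.424 kJ/mol"
format(d_bg)
#> "delta_W2G^{C4T+H3K} = 0.160 ± 0.424 kJ/mol"
classify_change(d_wt, d_bg)
#> [1] "erased"
```

The first number is the BAR solution of the Bennett self-consistency
equation with its bootstrap standard error — within noise of the planted
5 kJ/mol. The pair coupling of 4 kJ/mol carries the quadrature error
√3 · 0.5 of its three independent table entries. In the synthetic triple
mutant box the wild-type coupling (≈ 6.4 kJ/mol) disappears (≈ 0.2 kJ/mol)
when the third-site mutation is present, and the change is classified as
`erased` — the behaviour this package is built to detect and dissect.

A thin command-line wrapper over the same functions ships at
`inst/cli/mutantcycle.R` (subcommands `estimate`, `nonadd`, `triplebox`,
`scan`, `benchmark`, `distance`, `simulate`).

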