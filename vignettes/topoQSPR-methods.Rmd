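---
title: "Degree-based topological indices and univariate QSPR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-based topological indices and univariate QSPR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoQSPR)
```

## The model

A hydrogen-suppressed molecular graph G(V, E) is simple, finite and
connected: vertices are the heavy atoms, edges are bonds with multiplicity
collapsed to one. The degree d_u of a vertex is its number of neighbours —
the graph-theoretic analogue of heavy-atom valence, capped at 4 for organic
skeletons. Nine classical degree-based topological indices are supported
(ABC, RA, S, GA, M1, M2, H, HM, F; see `indexNames()` and the README table
for the per-edge terms). Because every term is a symmetric function of the
unordered endpoint-degree pair, each index factors through the *edge
partition*: the counts |E_{m,n}|, m ≤ n, of edges joining a degree-m vertex
to a degree-n one. The partition is therefore the package's central
sufficient statistic — `edgePartition()` derives it from a graph,
`computeIndex()` evaluates any index from it, and
`computeIndexFromGraph()` provides a deliberately independent edge-by-edge
evaluation path used to cross-check the partition route in the test suite
(the two agree to 1e-9 relative on thousands of random graphs).

Structure–property modeling is the univariate linear QSPR form

P = A + b·TI + error,

fitted by ordinary least squares (`stats::lm`) per (index, property) pair.
Reported per fit: intercept A and slope b; Pearson r of the retained pairs
and r²; the standard error of estimate √(SSE/(n−2)); and the
single-predictor F statistic on (1, n−2) degrees of freedom with its
upper-tail p value (algebraically F = r²(n−2)/(1−r²), and equal to the
squared slope t statistic). Missing property values are handled by
*pairwise deletion*: each model drops only the molecules missing either of
its own two variables, so refractivity models use n = 9 of the eleven drugs
while the other properties use all 11. No multiple-testing correction is
applied across the 45 models, matching the published analysis; the
significance flag is the disjunction p < 0.05 or r > 0.6, because the
published convention labels rows significant wherever r exceeds 0.6 even
when p alone would not (both sub-conditions are reported separately so
users can apply a stricter rule).

## Assumptions and their limits

The linear form is assumed, not selected: no transformation, weighting or
multivariate extension is attempted, because the point of the package is a
faithful, reusable implementation of this specific analysis. With n = 11
molecules a single high-leverage compound can move r by several hundredths;
the diagnostics (SE, F, p) should be read as descriptive for samples this
small. Connectivity is enforced at graph construction — the index formulas
would happily sum over a disconnected graph, but molecular graphs are
connected, so a disconnected input is treated as a data error (the message
lists component sizes) rather than silently accepted.

## Tunable parameters

* `maxDegree` (default 4, dimensionless) in `randomMolecularGraph()`: the
  valence-like degree cap; the drug graphs here never exceed 3, but 4 is the
  natural cap for carbon skeletons.
* `noiseSd` (property units) in `linearProperty()`: the Gaussian error
  standard deviation; 0 gives the exact line.
* `coefDigits` in `predictProperty()` / `predictionTable()`: decimals to
  which coefficients are rounded before predicting (default `NULL` = full
  precision for the former; 3 for the latter, see below).
* `roundDigits` / `roundHalfUp()`: presentation rounding only; all internal
  computation is double precision.
* `variant` in `loadPropertyTable()`: `"table2"` (default) or
  `"tables15-18"`, selecting between two conflicting printed versions of
  three property values (see the discrepancy ledger below).

## Numerical choices

*Rounding.* Printed descriptor tables follow the half-up convention
(6.8265 → 6.83), not R's round-half-even, so presentation rounding goes
through `roundHalfUp()` with a one-ulp guard against representation error.
It is never applied before arithmetic.

*Prediction-table coefficients.* The published actual-vs-predicted tables
are exactly reproduced by A and b rounded to 3 decimals (e.g. the psoralen
complexity prediction under the M1 model, −214.531 + 6.269 × 78 = 274.451,
where full-precision coefficients give 274.463). `predictionTable()`
therefore defaults to `coefDigits = 3`, while `predictProperty()` defaults
to full precision; the choice is explicit at both call sites.

*Degenerate inputs.* A perfect linear relationship gives SE = 0; the F
statistic is then reported as `Inf` with p = 0 rather than a large finite
number. Zero variance in the predictor or the response is an error (r is
undefined), as is a model with fewer than 3 complete pairs. The empty edge
partition is rejected; a single edge between two degree-1 atoms gives
ABC = 0 (the m + n − 2 numerator vanishes) and GA = RA = 1, all legitimate.

*Ties and canonical forms.* Degree pairs are stored unordered with m ≤ n
(all nine terms are symmetric), partitions sorted by (m, n), and index
columns always emitted in the order ABC, RA, S, GA, M1, M2, H, HM, F.

## The synthetic-data generator

`randomMolecularGraph()` grows a uniform random spanning tree subject to the
degree cap (each new vertex attaches to a uniformly chosen existing vertex
with spare capacity), then adds extra edges drawn uniformly from the
non-adjacent, below-cap pairs — by default a random count up to n/4, enough
to create the fused-ring-like degree-2/3/4 mixtures that exercise every
partition class. `linearProperty()` inverts the QSPR model with i.i.d.
Gaussian noise, the conventional linear-model error (no error model is
stated for the original analysis). What the generator emulates is exactly
the degree structure — simple, connected, bounded-degree graphs — and
nothing else: no rings-versus-chains statistics, heteroatom patterns or
bond orders, because the indices are blind to them. Passing tests therefore
demonstrate correctness of the index algebra and the regression machinery,
not that the generator's graphs are drug-like. All generators take a
mandatory (or explicit) integer seed, use a local RNG state that leaves the
caller's stream untouched, and `recoveryExperiment()` reports its derived
per-molecule seeds for replay. Test and experiment sizes (tens of molecules
of 4–60 atoms; 1000 graphs for the invariant sweeps) were chosen as the
smallest scales at which the asymptotic claims — error shrinking with n,
identity HM = F + 2·M2, path equivalence — are comfortably separated from
noise.

## Design decisions

*Printed values as regression inputs.* The bundled descriptor table stores
the published 2-decimal values and regressions run on them, since the
published models were evidently fitted to (approximately) those values;
recomputing descriptors at full precision from structures is impossible
anyway for the nine drugs whose edge partitions were never printed.

*Discrepancy ledger instead of silent choices.* The published tables
conflict internally in at least nine places — duplicated observations with
two different values (monobenzone polarity 23.50 vs 35.50, azathioprine
refractivity 69.94 vs 59.94, fluticasone molar volume 323.20 vs 336.6),
proof-vs-statement typos (psoralen HM 336 vs 386; azathioprine H 9.60 vs
8.60), and descriptor cells that disagree with their defining formulas
(azathioprine GA printed 19.68 vs computed 19.63, ABC 14.08 vs 14.09;
psoralen RA printed 6.82 vs computed 6.83). `knownDiscrepancies()` records
each with both locations and the default followed: property conflicts
default to the property table (with the `variant` switch exposing the
alternative), formula conflicts default to the definition. The agreement
report emitted by `reproducePublishedTables()` flags every non-matching cell
and marks the ledgered ones.

*Reproducibility boundary.* Recomputing all 45 models from the bundled
tables reproduces, at printed precision, the complexity models for M1, M2,
HM and F, the F-enthalpy model, the H-enthalpy correlation, and the
two worked descriptor rows (ledgered cells aside). Most remaining printed
statistics — including all enthalpy models for the other indices — are not
derivable from the bundled inputs at any rounding: some printed slopes
exceed the |r|·sd(P)/sd(TI) bound the printed data permit, so they must
stem from descriptor or property values that were never published. The
package reports what the data in hand imply and flags the rest, rather than
hard-coding printed numbers.

## Known limitations

Only the nine degree-based indices are implemented — no distance-based or
spectral descriptors. Edge lists carry no chemistry beyond connectivity;
SMILES ingestion is deliberately out of scope (any external parser can be
used to produce an edge list). The regression module is strictly
univariate OLS. Units are carried as opaque labels; the mixed units of the
published property table are preserved, not converted.
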