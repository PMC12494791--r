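---
title: "Degree-based indices and edge-entropies of polymer chains: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-based indices and edge-entropies of polymer chains: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyentropy)
```

## The model

A polymer chain of `n` repeat units is a simple connected molecular graph:
atoms are vertices, bonds are edges, no bond orders, no geometry. Both
built-in families keep all vertex degrees in 1..4 (carbon valence). The
central object is not the graph itself but its **degree-based edge
partition**: edges grouped by the unordered pair of endpoint degrees
`(lo, hi)`. For a chain family the class frequencies are linear functions
`a·n + b` of the unit count, because each added unit contributes a fixed
bundle of edges plus a fixed reclassification at the single connector bond.
`polyentropy` stores this as a `SymbolicPartition`; polyester has 7
classes summing to `23n − 1` edges, polycarbonate 8 classes summing to
`31n − 1`.

A degree-based index is `TI(G) = Σ f(d_u, d_v)` over edges, for a
symmetric weight `f`. On a partition this is `Σ_i U_i f_i`, and since the
`U_i(n)` are linear and the `f_i` constants, `TI(n) = I_a·n + I_b`. The
edge-entropy is the Shannon entropy of the distribution that assigns each
edge probability proportional to its weight:

$$ENT = \ln TI - \frac{1}{TI}\sum_i U_i f_i \ln f_i
      = \ln I(n) - \frac{S(n)}{I(n)},$$

with `S(n)` again linear in `n`. `ENT` lies in `[0, ln m]` for `m` edges,
attaining `ln m` exactly when all per-edge weights are equal (e.g. any
index on a regular graph, or GA on any graph whose edges all join
equal-degree vertices).

### Logarithm base

All logarithms are natural. The published formulas write "log", but their
numeric tables are only consistent with `ln` (the one-unit polyester
first-Zagreb entropy 3.07 requires it; in base 10 the value would be
1.33). The package fixes `ln` everywhere, including the regression
`ENT = a·ln TI + b`.

### Zero weights

`0·ln 0 := 0`, so a class of zero weight (ABC on a (1,1) edge)
contributes nothing to `S`. The total `TI` must still be positive;
otherwise the entropy is undefined and `entropyValue()` raises an error
rather than returning `NaN`.

## Exactness

The five rational indices (M1, M2, ReZG1–3) are computed in exact integer
rational arithmetic (numerator/denominator pairs held in doubles, far
below 2^53), so integer-valued results such as `ReZG1 = 22n` come out
*exactly* integer and table cells can be compared with `==` rather than a
tolerance. ABC and GA are irrational and use double precision.

Closed forms are obtained by two-point interpolation: the partition is
evaluated at `n = 1, 2`, giving `a = v(2) − v(1)`, `b = 2v(1) − v(2)`,
and the result is verified at `n = 3`. Linearity is a theorem here, not an
assumption, so a verification failure is an internal error. The same
interpolation yields `S(n)`; entropy closed forms agree with direct
per-`n` evaluation to better than 1e-9 over `n = 1..20` (tested).

## Chain templates

The published unit structures exist only as drawings, and the stated
polycarbonate vertex count (`29n`) cannot be reconciled with a
fully-hydrogenated bisphenol-A repeat unit (33 atoms). The package
therefore treats the **edge partition tables as authoritative** and ships
explicit unit graphs constructed to realize them: a 22-vertex unicyclic
polyester unit and a 29-vertex bicyclic polycarbonate unit, each with
head/tail attachment vertices chosen so that the connector bond's
degree-reclassification keeps every class frequency linear in `n` from
`n = 1` on. Any realization with this property is equivalent for
degree-based analysis; the tests verify template-vs-partition agreement
for `n = 1..5`. Vertex ids are 1-based throughout (R convention), and
edge-list files are 1-based as is usual in chemistry formats, so no
boundary conversion exists to get wrong.

## The audit

"What was previously reported" is data, not code: a bundled JSON fixture
(`inst/extdata/reported_values.json`) transcribes the published closed
forms, the `n = 1..10` tables and the regression statistics.
`auditClosedForms()` recomputes all 28 closed forms (14 index, 14
entropy) from the partitions and compares coefficients at a default
tolerance of 5e-3 (absorbing the mixed 2-4-decimal rounding of the
source). Nine forms are flagged `MISMATCH` — polyester ABC (constant
+0.0617 printed vs −0.6171 recomputed) and GA (slope 20.287 vs 21.2414),
polycarbonate GA (30.027 vs 28.9480), ReZG3 (1168 vs 1200), the
polycarbonate first-Zagreb entropy log-sum slope (311.1514 vs 276.4940),
and the entropy forms downstream of the mis-summed indices. Whether these
stem from a differently drawn structure or arithmetic slips is
undecidable from the published material; the package reproduces the
partition-consistent values and surfaces the deltas instead of guessing.

One reported table cell (polycarbonate ReZG2 entropy at `n = 1`, 3.444)
disagrees with its own closed form (3.3447); the table comparison in
`reproduceTables()` flags it. The reported decimal table columns were
printed from *truncated* closed-form coefficients, so their drift from
exact values grows with `n` (polyester ReZG2: 0.00067·n); whether
individual cells were truncated or rounded is unknowable, which is why
table comparisons use an absolute 5e-3 band rather than printed-precision
ulps.

## Regression

`fitLogModel()` is ordinary least squares of entropy on `ln(index)` via
`lm()`, reporting slope, intercept, `R`, `R²`, the standard error of the
estimate, `F = R²(N−2)/(1−R²)` and its upper-tail p-value; a numerically
exact fit reports `R² = 1, SE = 0, F = ∞, p = 0`. Fits run on the exactly
recomputed series, not the published rounded cells: slopes then reproduce
the published ones to a few 1e-4 wherever the underlying series are
internally consistent, while intercepts can drift by ~1e-3 (the published
fits used rounded intermediates). With `R² ≈ 0.9999`, `F` and `p` are
hypersensitive to third-decimal input rounding, so they are reported but
not treated as reproduction targets. The published prose is ambiguous
about which variable is "independent"; the tabulated models
unambiguously regress entropy on the log-index, which is what is
implemented.

## Synthetic generators

The generators exist so every pipeline stage can be property-tested
without external data, and they emulate the structural assumptions of the
chain analysis: simple connected graphs with degrees capped at 4, biased
to trees and unicyclic graphs (one ring per repeat unit is the molecular
norm; `"connected"` mode adds a few extra cycles for stress tests).
`randomSymbolicPartition()` does not sample coefficient tables — it
generates a random unit template and extracts its chain partition
symbolically, which guarantees realizability and degree-consistency by
construction; the class count is an outcome of the draw, with the unit
size (default 12 vertices) as the tunable knob. `noisyLogSeries()` draws
`x` log-uniformly over about two decades and adds Gaussian noise to
`a·ln x + b`, matching the regression model's error structure exactly.

All generators are pure functions of an explicit seed (the caller's RNG
state is saved and restored), so every test is reproducible. What passing
these property tests does *not* show: anything about graphs with degrees
above 4, disconnected systems, multigraphs, or real measured polymer
properties — the generators probe the mathematics of the analysis, not
chemistry.

## Numerical choices and problem sizes

* Rational arithmetic everywhere it is exact; doubles elsewhere.
* Closed-form vs direct agreement asserted at 1e-9 (entropy) and 1e-12 /
  exact (indices); dual-route index equality (grouped partition vs
  edge-by-edge) checked on 200 random graphs per run.
* Table and coefficient comparisons against reported values at 5e-3;
  regression slope comparisons at 2e-3.
* Class iteration order is always lexicographic in `(lo, hi)` and CSV
  floats are written with 12 significant digits, so repeated pipeline
  runs are byte-identical.
* Test-suite problem sizes — chains to `n = 20`, random graphs of 5–40
  vertices, 500 regression replicates of size 30 for slope-interval
  coverage — were chosen as the smallest sizes at which the asserted
  properties are non-trivial; everything runs in well under a minute.

## Limitations

* Only degree-based indices: no distance-based (Wiener) or spectral
  descriptors, no vertex-orbit entropies.
* No SMILES/InChI input, aromaticity or 3D structure; graphs are plain
  simple graphs.
* The built-in templates are *a* realization of the published partitions,
  not a verified transcription of the published drawings — for
  degree-based quantities this distinction is immaterial, for anything
  else it is not.
* Entropy comparisons against the published tables inherit that source's
  mixed truncation/rounding; agreement tighter than ~5e-3 per cell is not
  claimable.
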