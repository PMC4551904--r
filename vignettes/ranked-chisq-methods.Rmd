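---
title: "Ranked chi-square association testing: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranked chi-square association testing: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chirank)
```

## The model

The data are tag-level counts: `n[s, j, v]` is the (possibly normalized,
hence non-integer) count of tag `s` — one poly(A)-site isoform of a gene —
in condition `j` (1 = rest, 2 = stimulated) and replicate `v = 1..r`. For a
gene with `Z_g >= 2` tags, each tag is tested against the *rest of its
gene*: the 2×2 table rows are (tag `s`, sum of the gene's other tags), the
columns are the two conditions. Each observed count is modeled as an
association effect plus replicate noise, `n[s,i,j,v] = n[s,i,j] +
e[s,i,j,v]`; the effect is constant across replicates, the noise is not.

Two statistics summarize each tag:

* the **treatment chi-square** `chi2_treat`, the Pearson chi-square of the
  2×2 table of replicate means. Averaging reduces the noise in each cell by
  a factor `r` but does not remove it, so `chi2_treat` estimates the
  association chi-square with an upward noise bias; its distribution under
  no association is *not* the 1-df chi-square, which is why no p-value is
  ever attached to it.
* the **null chi-square** `chi2_null`, the Pearson chi-square of a table
  whose columns are two replicates of the *same* condition (rows are the
  tag states). Condition effects cancel by construction; what remains is
  pure replicate noise, in direct analogy to estimating a noise variance
  from within-group variation.

Both per-tag profiles are sorted ascending and compared position by
position. At threshold `Delta`, the declared set is the longest ranked
suffix on which `chi2_treat - chi2_null > Delta` holds at every position;
the suffix rule guarantees every declared tag individually satisfies the
declaration inequality even when the rank-wise difference is not monotone.

## Why the null is a single unscaled pair table

The null construction is the one genuinely open design point, and it is
deliberately isolated in `null_chi2()` so alternatives can be swapped. Two
axes were explored during development (at S = 5000 simulated tags; the
behaviors below are reproduced qualitatively by the calibration tests):

**Scale.** A replicate-pair table carries single-replicate noise, while
the treatment statistic is built from `r`-replicate means whose
proportion-level noise is `r` times smaller. We keep the pair chi-square
*unscaled*: the null profile then sits roughly a factor `r` above the
treatment statistic's noise component, acting as a conservative hurdle
that only genuine association effects clear. Under pure noise the
treatment profile falls entirely inside the null profile and the method
declares nothing — the intended degenerate behavior, which the test suite
asserts. (Rescaling by 1/r makes the two profiles match in distribution
under the null, but then extreme treatment-noise draws routinely cross the
bar and the false-positive accounting below cannot see all of them.)

**Aggregation.** Averaging the pair chi-squares over all `r(r-1)/2` pairs
and both conditions (`scheme = "mean"`, also provided) uses all replicate
information and has the same expectation, but an average of six correlated
chi-squares has a markedly lighter upper tail than the single draw that
the treatment statistic is. A null profile with a too-light tail cannot
supply false-positive candidates for the treatment profile's own noise
extremes, and in calibration runs this produced occasional small
underestimates of the FDR at sparse thresholds. The default
(`scheme = "single"`) therefore scores *one* pair table per tag, keeping
the 1-df-shape tail; `chi_square_profile()` rotates the condition and the
replicate pair deterministically with the tag's row index so that all
replicates contribute to the profile and results are reproducible.

## FDR estimation

With both profiles sorted, position `a` starts the declared suffix
(`N = S - a + 1` declared tags) and position `b` is the first null rank
with `chi2_null[b] - chi2_null[a] > Delta`: null tags at ranks `b..S` are
the potential false positives. Each is counted with probability

```
p(t) = ( chi2_null[t] * t / ( chi2_null[S] * S ) )^x ,  x = (2 r / chi2_null[S])^2
```

a geometric-mean-style combination of the rank ratio and the value ratio,
with the exponent shrinking toward 0 (hence `p -> 1`, maximal
conservatism) when the null maximum is large relative to the replicate
number. `F = sum(p)` over `b..S` and `FDR = min(1, F / N)`, scanned over
`Delta = U * chi2_null[S]` for `U = 0, 1/n_grid, ..., 1`. The suite checks
this whole scan cell-by-cell against a brute-force enumeration, verifies
`est FDR >= true FDR` across 120 full-scale seeded calibration runs, and
verifies that forcing `x = 0` never yields a smaller estimate than the
default exponent.

Edge policies, all exact and tested:

* a 2×2 table with any zero marginal has chi-square 0 (no evidence), never
  `NaN`;
* if even the top rank fails the suffix rule, the record is flagged
  (`N = 0`, FDR undefined) and `declare_tags()` returns the empty set with
  a warning;
* if no null rank clears the `b` cut, `F = 0` and `FDR = 0` — there are no
  candidate false positives under the construction;
* ranking ties break by tag id, so all outputs are byte-deterministic;
* the per-tag `fdr` column is the curve FDR at the smallest grid threshold
  at which the tag first enters a declared set (a step-function q-value
  analogue; the method itself only defines set-level FDR).

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `fdr_alpha` | 0.05 | declaration bound on estimated FDR |
| `grid_size` | 101 points (`n_grid = 100`) | step 0.01 on the relative threshold `U`; finer grids only refine the chosen `Delta` |
| `coverage` | 0.9 | per-gene aggregate-frequency coverage; tags are kept from most to least abundant until their share *strictly exceeds* it |
| `null_chi2` scheme | `"single"` | see above; `"mean"` retained for comparison |
| `r` (replicates) | data-defined, `>= 2` | 2 conditions must have equal `r`; the null estimator needs at least one within-condition pair |
| normalization | median-of-ratios | size factors from per-tag geometric-mean references (tags positive in all libraries), centered to geometric mean 1; idempotent |
| Fisher rounding | `"round"` | mean tables are fractional; `"floor"` available, both exposed because the choice is not standardized |

## The simulator

The simulator exists to answer one question: is the estimated FDR curve
conservative relative to the truth? It emulates the stated generation
protocol:

1. from a template table, per-tag cell means and variances over replicates
   (`estimate_cell_moments`);
2. per tag, one mean and one variance chosen independently and uniformly
   among the four cells; a full 2×2-by-replicate series drawn from a
   negative binomial with `mu` = chosen mean and **`size` = chosen
   variance** — the protocol's literal, non-standard parameterization.
   When the chosen variance is at most the chosen mean it is degenerate
   for a negative binomial (which is always overdispersed) and the draw
   falls back to `Poisson(mu)`; a useful consequence is that simulated
   counts are never more than twice-Poisson dispersed;
3. association effects injected into a fraction of units:
   `n[i,j] = U[i,j] * N_i * N_j / N_tot` with `N`-masses
   `Normal(100, 50)` truncated positive and one uniform `U[i,j]` per
   cell, rounded and added identically to every replicate of cell
   `(i, j)`. The per-cell uniforms matter: with row- and column-level
   uniforms only, the injected table factorizes into an exact independence
   table with zero chi-square — no association at all. The bound
   `n[i,j] <= N_i N_j / N_tot` is preserved.

Each simulated unit is an independent two-tag gene (site row + rest row),
so rebuilding 2×2 tables by gene complement reproduces exactly the drawn
tables, units stay independent, and effect injection cannot leak into the
tables of unrelated tags through a shared complement row. Both tags of an
effect unit are truly associated (their tables are row swaps) and both are
labeled as effects.

**Template defaults** (`simulate_template`): baseline means log-normal
with `meanlog = log(5)`, `sdlog = 1`, template dispersion `size = 3`,
i.e. normalized low-count 3'-end tag data — median ~5 counts per tag and
library, middle 95% roughly 0.7–36, replicate CV ~0.8. In this regime the
null chi-square profile of a few thousand tags spans roughly 0–10, and the
injected effect masses (up to ~25 counts per cell) dominate baselines —
the regime in which this class of method is intended to operate. Chosen
once, for these anchors, not adjusted against test outcomes.

**What a green calibration test does not establish.** The simulator draws
independent units with at most twice-Poisson noise and effects constant
across replicates. Real 3'-end data have correlated tags within genes,
sample-specific library artifacts (internal priming, mapping multireads),
batch structure, and biological effects that vary across replicates. The
conservativeness demonstrated on the simulated world therefore supports,
but does not prove, conservativeness on real data — particularly for
datasets with heavy-tailed replicate inconsistency, where the estimator's
hurdle may cost substantial power.

## Baselines

The reference tests are deliberately plain: mean-table Pearson (1-df upper
tail), mean-table Fisher (exact, on rounded means), and the CMH chi-square
across replicate strata (replicate `v` of each condition paired; no
continuity correction; degenerate strata skipped), with Benjamini–Hochberg
step-up adjustment. All four have independent oracles in the test suite
(enumeration, hypergeometric moments, `p.adjust`, `mantelhaen.test`).

One honest caveat: in this package's simulated world, ranking tags by the
CMH statistic is about as good as ranking them by the treatment chi-square
— effects injected identically into every replicate are exactly what CMH
is built to pool. The advantage of the ranked chi-square method is not a
better ranking but calibration-free error control where parametric
p-values are unreliable; comparisons that neutralize p-value
miscalibration (e.g. truth-matched cutoffs) can therefore come out as a
tie. The power-ordering acceptance test reports this comparison as
measured.

## Known limitations

* The null-construction derivation this design replaces was not available;
  `scheme = "single"`/`"mean"` bracket the plausible readings and the
  choice is documented above, but a different original construction cannot
  be ruled out.
* The conservative hurdle (unscaled null) trades power for safety: at
  small effect sizes the declared set at `fdr_alpha = 0.05` can be empty
  even when effects exist.
* Per-tag FDR values are a reporting convenience layered on a set-level
  method; they are step functions of the grid and not proper q-values.
* Fisher on fractional mean tables requires an arbitrary integerization;
  both options are exposed and neither is canonical.
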