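---
title: "QSAR model building, validation and screening with qsarlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QSAR model building, validation and screening with qsarlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(qsarlab)
```

## The modelling problem

Quantitative structure–activity relationship (QSAR) modelling relates
numeric molecular descriptors of a compound series to a measured
biological activity. The series packaged here is a set of 39 imidazolone
derivatives with anti-proliferative IC50 values against the MCF-7 breast
cancer cell line; the modelling target is

$$\mathrm{pIC_{50}} = -\log_{10}(\mathrm{IC_{50}} \times 10^{-6})
                    = 6 - \log_{10}(\mathrm{IC_{50}[\mu M]}),$$

so higher values mean more potent compounds and the dynamic range of the
series is roughly 4–5.2. Descriptors (spatial autocorrelations,
Burden-matrix eigenvalues, radial distribution function values, ...) are
computed by external software and enter this package as a plain
compounds × descriptors CSV; `qsarlab` starts where the descriptor
calculator stops.

The model family is deliberately simple: multiple linear regression on a
handful of descriptors,

$$\mathrm{pIC_{50}} = \beta_0 + \sum_{j=1}^{k} \beta_j D_j,$$

with the modelling work concentrated in *which* $k$ descriptors to use,
and in honest internal/external validation of the result.

## Pretreatment and data splitting

A raw descriptor export contains hundreds of columns that are constant,
near-constant, or duplicates of each other. `pretreat()` removes

* columns with variance at or below `variance_tol` (default `1e-8`), and
* for every pair with $|r| \ge$ `corr_threshold` (default 0.99), the
  column that appears later in input order (the keep-first rule, which
  makes the operation deterministic and idempotent).

The calibration/validation split uses the Kennard–Stone maximin
procedure (`kennard_stone()`): descriptors are standardized using the
mean and standard deviation of the *full* compound set, the first two
calibration compounds are a globally maximally distant pair in Euclidean
distance, and every subsequent pick maximizes its minimum distance to
the compounds already selected. Ties are broken by the smallest input
row index so a split is reproducible without any random seed. Both an
explicit `n_train` and a `train_fraction` (floored, so 0.7 of 39 gives
the 27/12 split used by the packaged study) are supported. The split is
made *before* model selection, so the validation compounds never
influence the choice of descriptors.

## Descriptor-subset search (GFA) and the lack-of-fit score

`gfa()` searches descriptor subsets with a genetic algorithm: a
population of candidate supports evolves by tournament selection, union
crossover (a child's support is drawn from the union of its parents')
and add/remove/swap mutation, with equation sizes confined to
`model_size_min:model_size_max` (default 3–5, bracketing the
4-descriptor equations this kind of study reports). Each candidate is
scored by Friedman's lack-of-fit,

$$\mathrm{LOF} = \frac{\mathrm{SSE}/M}{\left(1 - \frac{c + d\,p}{M}\right)^2},$$

where $M$ is the number of calibration compounds, $c$ the number of
non-intercept terms, $p$ the total parameter count ($c+1$ here, counting
the intercept) and $d$ the smoothing parameter. LOF is a penalized mean
squared error: it decreases with fit quality but grows quickly as
equations gain terms.

**Choice of the smoothing default.** When equations of different sizes
compete over a pool of $q$ candidate descriptors, the extra descriptor
that wins a size-$(k{+}1)$ equation is the *best* of roughly $q-k$
candidates, so the expected SSE reduction it brings is several times a
single chi-square draw — for a pool of ~30 descriptors, around 15–20% of
the SSE, independent of the noise level. A mild smoothing such as
$d = 0.5$ separates the size-4 and size-5 penalty factors by only ~9%,
so the search systematically prefers equations padded with one noise
descriptor. The default here is $d = 2$ (within the cost range Friedman
recommends for GCV-type penalties), which makes the size penalty exceed
the selection-driven SSE drop at these pool sizes; with it, the search
recovers a planted 4-descriptor truth from 30 candidates in 8 of 10
seeds, versus 0 of 10 at $d = 0.5$. `smoothing_d` remains fully
configurable, and `lof()` can be called with any $d$ directly.

One integer seed drives the entire run through R's generator, so a GFA
run is bit-reproducible; a fitness cache keyed by the sorted support
keeps repeated evaluations free, and the ranked result list is drawn
from *every* support evaluated during the search, best LOF first.

## Validation statistics

All of the usual equation-quality statistics are implemented exactly as
defined, each as its own small function:

* `r_squared(y_obs, y_pred, ref_mean)` — $1 - \mathrm{SS_{res}}/\mathrm{SS_{tot}}$
  about a caller-specified reference mean; internal validation uses the
  training mean.
* `adjusted_r2(r2, n, p)` — the standard (Ezekiel) small-sample
  correction $1 - (1-R^2)(n-1)/(n-p-1)$. Applied to the packaged study's
  printed training $R^2 = 0.6981$ with $n = 27,\ p = 4$ it reproduces
  the printed 0.6433, which is why this form (rather than any variant)
  is used.
* `q2_loo(X, y, support)` — leave-one-out cross-validation by *exact
  refitting*: each compound is dropped, the equation is refit from
  scratch and the held-out activity predicted. No shortcut formula is
  used, so the function doubles as its own reference behaviour; PRESS
  and the per-compound LOO predictions are returned alongside $Q^2$.
* `external_r2pred(y_obs, y_pred, y_mintrn)` — predictive $R^2$ over the
  validation set, with the total sum of squares taken about the
  *calibration* mean activity, and both sums of squares exposed for
  reporting.
* `vif()` (each descriptor regressed on the others; perfectly collinear
  descriptors report `Inf` rather than erroring), `mean_effect()`
  (signed contributions $\beta_j \sum_i D_{ij}$ normalized to sum to 1)
  and `correlation_matrix()` for the descriptor diagnostics.

`evaluate_against_criteria()` applies the field's minimum recommended
values — $R^2 \ge 0.6$, $Q^2 \ge 0.5$, $R^2 - Q^2 < 0.3$, at least 5
validation compounds, external $R^2 \ge 0.5$. The confidence-level
criterion ($p < 0.05$) that usually accompanies this table is carried in
the output but marked *not evaluated*: no specific test statistic is
attached to it, and silently substituting one (say, the overall
regression F-test) would change its meaning; it is excluded from the
overall verdict.

## Applicability domain

The leverage of a compound is the hat-matrix quadratic form
$h_i = x_i (X^TX)^{-1} x_i^T$ over the calibration design with an
intercept column appended; training leverages lie in $[0,1]$ and sum to
$k+1$, a property the test suite checks on every random design. The
warning leverage is $h^\ast = 3(k+1)/n$ — for the packaged 4-descriptor
equation on 27 compounds, $3 \cdot 5/27 = 0.56$. `williams_data()`
assembles the Williams-plot table: standardized residuals
(residual / training SEE, the convention adopted here since the
published plot does not define its standardization) against leverages,
with a compound flagged as a response outlier when
$|\text{std. residual}| > 3$ and as structurally outside the domain when
$h_i > h^\ast$ (strictly; a compound sitting exactly on the warning
leverage is still inside).

## Drug-likeness screening

`lipinski_violations()` applies the rule of five (violations: MW > 500,
logP > 5, HBD > 5, HBA > 10; a compound fails only on two or more
violations) and `radar_check()` the six-axis bioavailability window
(XLOGP3 in [−0.7, 5], MW in [150, 500], TPSA in [20, 130],
log S ≥ −6, Csp³ fraction ≥ 0.25, fewer than 9 rotatable bonds). Two
wording traps in the source material are resolved in favour of the
conventional definitions: the acceptor cutoff is 10 (not the garbled
"10.6"), and the solubility/saturation axes use the standard directions
(log S *at least* −6; saturation *at least* 0.25) — all cutoffs are
overridable if a user wants the literal variants. Axes whose property is
missing are reported "not evaluated" rather than failing.

## The synthetic-data generator

Real descriptor matrices for this series cannot be rebuilt from the
published tables (only the validation subset of Model 1's four
descriptors is printed), so the package ships a generator with planted
ground truth. `generate_dataset()` draws descriptors standard normal
with exchangeable correlation $\rho$ inside consecutive blocks (via the
Cholesky factor of the block correlation matrix, documented so an oracle
can regenerate it), computes
$y = \beta_0 + \sum \beta_j x_j + \varepsilon$, $\varepsilon \sim
N(0, \sigma^2)$, directly on the pIC50 scale (intercept 5, coefficients
a few tenths, mirroring the 4–6 range and signal size of a real series),
and appends constant and duplicated nuisance columns for the
pretreatment stage to find.

`make_benchmark()` fixes three study conditions:

* **easy** — 40 compounds, 30 descriptors, 4 true ones in distinct
  blocks, $\rho = 0.2$, $\sigma = 0.05$: the regime where subset search
  should almost always succeed.
* **paper_like** — 39 compounds and 1000 columns before pretreatment
  (960 informative + 20 constant + 20 duplicated), $\rho = 0.3$,
  $\sigma = 0.2$: the shape of a real descriptor-calculator export.
* **hard** — as easy but decoys correlated with the truth at
  $\rho = 0.9$ and $\sigma = 0.2$: recovery is only partial by design
  (the suite asserts at least 3 of 10 seeds; 6 of 10 is typical).

What the generator does *not* emulate: realistic descriptor marginals
(real descriptors are skewed, bounded, often discrete), activity
censoring, measurement error in the descriptors themselves, or any
chemistry. Passing tests on these benchmarks therefore demonstrate the
*statistical machinery* — selection, fitting, validation — not that any
particular real series will yield a good model.

## Numerical choices and degenerate inputs

* OLS goes through the QR decomposition (`lm.fit`); rank-deficient
  designs are refused with the offending column names rather than
  silently dropping terms.
* A collinear support inside the GFA search is given infinite LOF
  instead of aborting the run.
* Zero total sum of squares (constant activities) is an error everywhere
  a coefficient of determination is computed.
* Kennard–Stone standardization guards zero-variance columns (they
  contribute nothing to distances rather than dividing by zero).
* Model JSON is written with 17 significant digits so coefficients
  round-trip bit-exactly.
* Problem sizes in the test suite: stochastic claims use 10 fixed seeds
  of the 40 × 30 benchmarks, LOO oracles run at $n \le 30$, and the
  sampling-theory check uses 200 replicates of an $n = 200$ fit — all
  chosen to make the suite complete in about a minute on one core.

## Known limitations

* The GA operators of the commercial GFA implementations are
  proprietary; this package promises the contract (seeded determinism,
  LOF-ranked search over linear supports, non-increasing best-so-far)
  but not bit-identical populations to any other tool.
* Only linear terms are searched — no splines, quadratics or
  descriptor transformations.
* The packaged study's own training descriptor matrix is not published,
  so its training $R^2 = 0.6981$ and $Q^2 = 0.5460$ cannot be recomputed
  from shipped data; the package instead verifies every statistic's
  defining identity and reproduces the numbers that *are* recomputable
  (external validation sums, adjusted $R^2$, warning leverage, the
  validation-set predictions, and the rule-of-five screen).
* The published mean-effect/VIF table is not exactly recoverable from
  the printed validation descriptors (the compound set used is unknown);
  `mean_effect()` therefore takes the compound set as an explicit
  argument and no golden value is asserted for that table.
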