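---
title: "Methods: fluoride exposure modelling, Monte Carlo risk, and the HQ surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fluoride exposure modelling, Monte Carlo risk, and the HQ surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluorisk)
```

# The exposure model

fluorisk implements the standard USEPA algebra for non-carcinogenic risk
from a single contaminant in drinking water. For a fluoride concentration
$C$ (mg/L) and an age cohort with ingestion rate $IR$ (L/day), exposure
frequency $EF$ (days/year), exposure duration $ED$ (years), body weight
$BW$ (kg) and averaging time $AT$ (days), the chronic daily intake is

$$ CDI = \frac{C \cdot IR \cdot EF \cdot ED}{BW \cdot AT} \quad
   \left[\tfrac{mg}{kg \cdot day}\right], $$

and the hazard quotient is $HQ = CDI / RfD$ with the oral reference dose
$RfD = 0.06$ mg/kg/day for fluoride. $HQ > 1$ flags potential
non-carcinogenic risk.

Two intake quantities are exposed side by side. `compute_cdi()` returns
the body-weight-normalised CDI above; `compute_tdi()` returns the *total
daily intake* $TDI = C \cdot IR$ in mg/day. Published intake tables for
this kind of survey are frequently tabulated in mg/day — i.e. they are
TDI even when labelled CDI — so the package keeps both quantities with
explicit unit labels rather than forcing one interpretation.

The three shipped cohorts are:

| cohort    | AT (d) | EF (d/y) | ED (y) | BW (kg) | IR (L/d) | RfD (mg/kg/d) |
|-----------|-------:|---------:|-------:|--------:|---------:|--------------:|
| children  | 1460   | 365      | 4      | 15      | 0.78     | 0.06          |
| teenagers | 4745   | 365      | 13     | 50      | 2        | 0.06          |
| adults    | 14600  | 365      | 40     | 78      | 2.5      | 0.06          |

All three satisfy $EF \cdot ED = AT$ exactly, under which the HQ collapses
to $C \cdot IR / (BW \cdot RfD)$; `age_group_params()` warns (but does not
fail) when a user-supplied cohort breaks the identity, since the full
formula remains well defined.

## Rounding and reproduction conventions

Display rounding is half-away-from-zero (`round_half_up()`), because the
published tables this package reproduces follow that convention and base
R's round-half-to-even does not: HQ values are shown at 2 decimals, TDI at
3, concentrations at 2. Unrounded values are always retained, and every
aggregate (e.g. the cohort-average HQ) is computed from unrounded inputs
before any display rounding. This matters: averaging the *rounded*
children HQ column gives 2.00, while the unrounded average rounds to the
published 1.99.

The district exceedance fraction is the share of *site means* strictly
above the threshold (default 1.5 mg/L, the BIS/WHO limit). Site means are
used because survey tables publish per-site summaries; when replicates are
present a replicate-level fraction is reported alongside. The comparison
is strict (`>`): a site exactly at the threshold does not exceed it,
consistent with how sites at HQ = 1.00 are treated by the endpoint
classifier.

## Fluorosis endpoints

`classify_sites()` reports, per cohort, the percentage of sites whose
mean-concentration HQ strictly exceeds an endpoint threshold (default 1).
Only the **dental** endpoint ships with defaults. Reference doses that
would generate bone- or skeletal-fluorosis-specific HQ values are not
available for this exposure model, and the package deliberately does not
invent them; both endpoints are supported through
`endpoint_config(rfd_override = ...)` once the user supplies a defensible
value. With an override, HQ is recomputed as $CDI/RfD_{endpoint}$ from the
table's CDI column.

# Monte Carlo uncertainty propagation

`simulate_hq()` draws the six exposure inputs independently from
user-specified distributions (`dist_point`, `dist_uniform`,
`dist_triangular`, `dist_truncnorm`, `dist_lognormal`, and a finite
`dist_mixture`), applies the exposure algebra row-wise, and summarises the
HQ sample by moments and percentiles. Design choices:

- **Default input model** (`default_mcs_specs()`): the concentration is a
  uniform-weight mixture over sites of per-site triangular(min, mean, max)
  distributions — bounded, assumption-light, and fully determined by the
  published summaries. $BW$ and $IR$ are truncated normals centred on the
  cohort values, truncated at zero; $EF$, $ED$, $AT$ are point masses.
  These defaults are the package's own choice of an uncertainty model;
  risk tools that fit distributions to unpublished raw data will produce
  different percentiles, so published P95 values should be treated as
  order-of-magnitude context for the defaults, not exact targets.
- **Coefficients of variation**: `cv_bw = 0.12`, `cv_ir = 0.06`. The two
  are deliberately unequal: with identical CVs the two inputs play exactly
  symmetric roles in the multiplicative model and their sensitivity ranks
  would be a coin flip from seed to seed. The defaults encode the
  empirical pattern that across-individual body-weight variability
  dominates ingestion-rate variability in this pathway, which also yields
  the stable driver ordering $C > BW > IR$. Both are arguments, not
  constants.
- **Percentile estimator**: linear interpolation between order statistics
  (R's `quantile(type = 7)`), fixed and documented so percentiles are
  comparable across runs.
- **Iterations and seeding**: default $n = 10{,}000$; a seed is mandatory
  for every stochastic entry point, and identical seed + spec + n gives a
  bit-identical result. Sampling is inverse-CDF throughout, which also
  makes scaling equivariance exact: scaling the concentration
  distribution by $k$ scales every HQ percentile by $k$ under the same
  seed.

`sensitivity()` implements contribution-to-variance as commonly reported
by spreadsheet risk tools: the Spearman rank correlation $\rho_i$ between
each input's draws and the HQ sample, normalised as
$100 \cdot \rho_i^2 / \sum_j \rho_j^2$ percent. Signed $\rho_i$ is kept
for tornado-plot direction; point-mass inputs get 0%. This is a rank-based
screening measure, not a variance decomposition — Sobol-style global
sensitivity and correlated inputs are out of scope.

`convergence_check()` recomputes P95 on cumulative blocks and reports the
maximum relative change between successive cumulative estimates, flagging
drift above 1% — a pragmatic stability check for a bounded quantile,
not a formal convergence diagnostic.

# The synthetic replicate generator

The packaged survey (17 sites, `fluoride_sites()`) publishes only per-site
min/max/mean/std. `generate_site_replicates()` produces $n$ (default 5)
concentrations per site that

1. attain the published min and max **exactly** (the two extremes are
   pinned),
2. match the published mean to machine precision (the interior values are
   solved from the mean constraint, and the seeded jitter added to them is
   centred), and
3. approach the published std as closely as the remaining freedom allows:
   the jitter scale is solved from the target sum of squares and then
   capped so no value leaves $[\min, \max]$.

With $n = 5$, pinning min/max/mean spends three of the five degrees of
freedom, so the std target is met only approximately (within roughly
±30% relative in practice; the mean takes priority because all downstream
deterministic results depend on means and extremes only). Feasibility
requires $(n-2)\,\text{min} \le n\,\text{mean} - \text{min} - \text{max}
\le (n-2)\,\text{max}$; infeasible targets raise an error rather than
silently degrading.

What the generator emulates is the *sampling design*: 17 exchangeable
sites × 5 replicates with the published summaries. What it does not
emulate: temporal structure (the underlying survey sampled monthly over a
year), spatial correlation between sites, measurement error models, or any
geology. Tests passing on synthetic studies therefore demonstrate that the
pipeline reproduces the published arithmetic and behaves correctly on
study-shaped data — not that the package's defaults describe any real
aquifer.

# The neural-network surrogate

`train_final()` fits a fully connected feed-forward network mapping the
six exposure features $(C, EF, IR, ED, BW, AT)$ to HQ: ReLU hidden
activations, linear output, L2 penalty on hidden-layer weights, full-batch
Adam, early stopping on a held-out validation split with best-weight
restoration. The candidate grid searched by `grid_search()` under 5-fold
cross-validation is 64-32-16, 128-64-32, 64-32 and 128-64 neurons, L2
$\in \{0.01, 0.1\}$ and learning rate $\in \{0.01, 0.001\}$.

Choices the protocol leaves open, fixed here as package defaults:

- **Optimizer**: full-batch Adam. The datasets are tiny (tens of rows), so
  minibatching adds noise without benefit; Adam makes the two grid
  learning rates usable without per-architecture tuning. Epoch cap 2000
  with patience 100 for the final fit; cross-validation folds use a
  shorter budget (400/40) since they only rank candidates.
- **Dataset assembly** (`build_dataset()`): one row per water sample, and
  each sample is assigned to *one* cohort uniformly at random (seeded).
  This is an assumption — assigning every sample to all three cohorts
  would triple the row count — and it is what makes all six features vary
  across rows. $EF$ is constant (365) across cohorts and is therefore
  centred but not rescaled by `standardize()`, which fits its statistics
  on training rows only; validation and test rows reuse the training
  transform, and a regression test guards against refitting on all rows.
- **Split rule**: validation and test sizes are the rounded 10% fractions,
  training takes the remainder — 69/8/8 for 85 rows.
- **Best-of-seeds reporting**: training is stochastic (initialisation),
  so reproduction of the published accuracy uses the best of 5 training
  seeds (`train_over_seeds()`), with every per-seed result tabulated.

The target HQ is an exact, smooth, deterministic function of the features,
so high surrogate fidelity ($R^2 \ge 0.987$ on the held-out split) is the
expected behaviour, and the fidelity test is really a regression test on
the training machinery — initialisation, penalty, early stopping,
standardisation — rather than evidence of generalisation to noisy
real-world targets. Models serialise to plain JSON
(`write_surrogate()` / `read_surrogate()`), and `predict_hq()` warns when
asked to extrapolate more than 20% (of the per-feature training range)
outside the training hull.

# Problem sizes and numerical tolerances

The shipped tests run the deterministic reproduction on the full 17-site
table (exact at the published rounding), Monte Carlo checks at
$n = 10{,}000$ draws (closed-form quantile agreement is asserted within
three Monte Carlo standard errors), and the surrogate pipeline on the
85-row synthetic study with the full hyperparameter grid once and reduced
single-candidate grids elsewhere — sizes chosen so the entire suite
completes in about a minute while keeping every claim at its natural
scale. Grid-search ties on mean CV MSE are broken toward fewer
parameters; a fold that diverges marks the candidate failed rather than
aborting the search.

# Known limitations

- Single contaminant, ingestion pathway only; no hazard-index aggregation
  across contaminants and no dermal/inhalation routes.
- Inputs are sampled independently; no copulas or rank correlation between
  inputs.
- The default uncertainty model is a documented choice, not a fit to raw
  data; its P95 and contribution percentages are internally reproducible
  but not comparable digit-for-digit with tools that fit distributions to
  unpublished measurements.
- Endpoint classification is a threshold rule on HQ; it does not stage
  clinical severity or model dose-duration response.
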