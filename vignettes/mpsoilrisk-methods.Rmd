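---
title: "Methods: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpsoilrisk)
```

## The problem and the model

Stabilized sewage sludge applied to farmland carries the microplastics
(MPs) that wastewater treatment removed from the water phase. The package
quantifies the chronic risk this poses to soil biota by comparing two
distributions on the concentration axis (particles per kg dry weight):

* the **species sensitivity distribution (SSD)** — the distribution across
  soil species of the chronic no-effect threshold; its quantile at
  probability *p* is the concentration affecting a fraction *p* of
  species; the 5th percentile is the hazard concentration HC5;
* the **environmental exposure distribution (EED)** — the distribution of
  measured MP concentrations in a matrix (stabilized sludge,
  sludge-amended soil, control soil).

Risk is characterized two ways: by curve overlap (compliance fractions at
the HC5 upper confidence limit) and by a two-dimensional Monte Carlo
(MC2D) estimate of the proportion of affected species with an uncertainty
interval.

## Harmonization of effect descriptors

Source studies report NOEC, LOEC or HONEC values under heterogeneous
designs. Each retained entry is reduced to a chronic no-effect equivalent

    NOEC_eq = descriptor / (UF_T * UF_D * UF_C)

with all factors on the geometric ladder {1, 2, 4}:

| factor | meaning | default mapping |
|---|---|---|
| `UF_T` | exposure duration | >= 42 d -> 1; 14–41 d -> 2; > 5 and < 14 d -> 4 |
| `UF_D` | descriptor precision | NOEC_a 1; NOEC_b 2; LOEC_a 2; LOEC_b 4 |
| `UF_C` | endpoint severity | A (sub-organismal) 1; B (growth/reproduction/germination) 2; C (survival) 4 |

Durations of five days or less are acute and rejected outright. The
classification behind `UF_D`: a NOEC with a bracketing LOEC within a
factor of ten is precise (`NOEC_a`); a NOEC with a loose bracket (ratio >=
10) is `NOEC_b`; a HONEC-only study is `NOEC_b` and flagged right-censored
(the true threshold lies above the highest tested concentration); a
LOEC-only study is `LOEC_b` and flagged left-censored. Two decisions here
were genuinely open:

* **NOEC without any reported LOEC** (no bracket at all, but effects were
  seen — otherwise it would be a HONEC): precision is unknowable, so it
  falls in the loose class `NOEC_b` with no censoring flag. Treating it as
  precise would understate uncertainty on exactly the entries that carry
  the least design information.
* **Censoring flags are carried but not used in the likelihood.** The SSD
  is fitted on point values; a censored-likelihood fit is out of scope.
  The flags are preserved in `harmonized.csv` so a future fit can use
  them.

Within each study x species x particle group, a single governing
descriptor is retained: NOEC-bearing entries are preferred to LOEC-only
ones; the minimum value governs; on exact value ties a NOEC keeps the
*least* severe endpoint category (no effect on a mild endpoint at a
concentration that also spares survival is the informative statement, and
it avoids stacking a conservative category factor), while a LOEC keeps the
*most* severe category (an effect on survival dominates an equal-dose
effect on enzymes).

Species sensitivities are geometric means of `NOEC_eq` per species. Soil
bacteria and fungi collapse into one pseudo-species each — a handful of
community studies would otherwise flood the species list; microbial
endpoints measured inside an animal host are endpoints of the host
species and are unaffected. Week/month durations are assumed converted to
days upstream at curation (1 wk = 7 d, 4 wk = 28 d, 1 mo = 30 d); the
loader accepts days only.

## Particle number conversion

Mass concentrations convert through the mass of one particle,
`density * volume`: spheres `(4/3)pi(d/2)^3` (particles, beads and
fragments are treated as spheres), fibers as cylinders `pi(d/2)^2 L`,
films as square-faced slabs `L^2 t` (an optional width allows rectangular
faces). Characteristic diameters follow the field's reporting
conventions: half the mesh for sieved material, the midpoint of a band or
range, the reported d50, or proportion-weighted class midpoints. When a
fiber diameter is unreported a configurable default of 20 um is used (a
commonly reported fiber diameter; it is a parameter, not a constant in the
math). Polymer densities come from the entry itself when reported,
otherwise from an editable table of standard literature values
(`inst/extdata/densities.csv`) — a stand-in, clearly not measured data.
The conversion is exactly invertible (`number_to_mass()`), and that
round trip is pinned by test at 1e-9 relative error.

## Distribution fitting

Five positive families with pinned parameterizations (all with true scale
parameters, so dilution is exact in the parameter domain):
lognormal(meanlog, sdlog); loglogistic(shape, scale) with CDF
`1/(1+(x/scale)^-shape)`; Burr XII(shape1 = k, shape2 = c, scale = s) with
CDF `1-(1+(x/s)^c)^(-k)`; weibull(shape, scale); gamma(shape, scale). SSD
candidates: lognormal, loglogistic, Burr. EED candidates: all five.
Selection is by lowest AIC; families that fail to fit stay in the ranking
table with their error message rather than disappearing.

Numerical choices that matter:

* **Log-normal estimator.** `meanlog` is the log-mean; `sdlog` uses the
  n−1 (bias-corrected) denominator rather than the strict 1/n MLE. At the
  SSD's operating size (n ≈ 25 species) the MLE's downward bias in
  `sdlog` visibly shifts extreme quantiles (HC5) upward and degrades
  bootstrap interval coverage; the corrected estimator is the standard
  small-sample choice in SSD practice. Log-likelihood and AIC are
  evaluated at the reported parameters.
* **Numeric families** (log-logistic, Burr, Weibull, gamma) are fitted by
  Nelder–Mead on log-transformed parameters with moment-informed starts
  plus five *deterministic* quasi-random restarts — restarts must not
  consume the global RNG stream, or a rerun with the same seed would not
  reproduce (the Burr start is the log-logistic moment fit with k = 1,
  which Burr nests).
* **Identifiability box.** The Burr likelihood on small samples has
  near-flat ridges toward degenerate corners (k -> 0 with huge c, the
  Pareto limit, and k -> infinity, the Weibull limit) that produce
  meaningless parameter blow-ups. Parameters are kept in a wide box
  (k in [0.05, 200], c in [0.05, 20], scale within the data range times
  1e+-6; analogous wide boxes for the other numeric families) via a
  penalty. The box is far wider than anything physically plausible for
  concentration data.
* **Overflow-safe tails.** Burr and log-logistic density/CDF/quantile are
  computed in log space (`log1pexp`/`logexpm1`); the naive
  `(1-p)^(-1/k)` overflows for heavy-tail draws long before the quantile
  itself does.
* **Degenerate data** (zero log-variance) and n < 3 are refused, not
  coerced.

**Parametric bootstrap** (default 1001 iterations): simulate n
observations from the fitted model, refit the *same* family, store the
parameters; percentile summaries report the MLE-fit percentile (`point`),
the bootstrap median and the 2.5th/97.5th percentiles of the draws. Failed
refits are resampled; more than 10% failures aborts — on heavy-tailed data
that signals an unstable fit, and papering over it would silently corrupt
the uncertainty interval. Both the bootstrap median and the point
percentile are reported because the two can differ noticeably for extreme
quantiles; tables use the bootstrap median as the headline value.

Zeros in exposure tables (below-detection controls) are floored at load
time to half the smallest positive value, with a warning, so the same
vector is admissible to all five families (three of which have strictly
positive support).

## Exposure curation and dilution

Within each survey, one entry per treatment plant or field is kept (the
mean of its samples). A survey with more than nine sites is collapsed to
the bootstrap-median estimates of its 10th–90th percentiles from a
log-normal fit — nine values that preserve the survey's spread without
letting it dominate the fit. Every such mutation is logged with counts.

The realistic dilution factor is the ratio of the sludge and SAS
bootstrap-median 50th percentiles, rounded to an integer for the named
scenario. Dilution by d is applied in the parameter domain (scale / d;
meanlog − log d for the log-normal), which is equivalent in distribution
to dividing every sample by d but exact and instantaneous for scenario
sweeps; refitting divided samples would add only refit noise. Empirical
medians use the midpoint convention for even n (`stats::median`).

## Two-dimensional Monte Carlo

For each uncertainty iteration u (default 1001): draw one SSD parameter
set and one EED parameter set from their bootstrap ensembles —
*independently*, since the two data sources share nothing; then simulate
n_var species thresholds S and n_var exposures C (each simulated species
experiences an independently drawn concentration — this is what makes the
affected-status integrate over the EED), divide C by the dilution factor,
and record `proportion_u = mean(C > S)` (strict inequality; ties have
probability zero under continuous families). The scenario's point
estimate is the *median* of the 1001 proportions (the mean is also
reported; the two nearly coincide here), and the uncertainty interval is
their empirical 2.5th/97.5th percentiles. A `shared_variability = TRUE`
option reuses one matrix of uniform variates across uncertainty
iterations (the classic MC2D matrix layout); fresh draws per iteration
are the default — the two agree in distribution, fresh draws simply avoid
correlating scenario rows. Verdicts against the 5% protection goal:
"exceeds" if even the lower uncertainty bound is above 5%, "below" if the
upper bound is under it, otherwise "intersects".

Per-stage seeds are derived deterministically from the single master seed
by hashing the stage name (all below 2^31), so one integer reproduces the
entire run while stages remain independently reproducible.

## The synthetic world

`synthetic_truth()` states the world the generator emulates, chosen once
from the published geometry of this problem and not revisited:

* SSD: log-normal, median 8.5e4 and 5th percentile 145 nb/kg dw
  (`meanlog = log(85484)`, `sdlog ~ 3.88`) — an extremely wide
  distribution, which is exactly the stress regime worth testing;
* sludge EED: Burr XII with median ~1.9e4 and 95th percentile ~1.2e6
  (k = 0.38, c = 1.5, s = 6333, derived from those two percentiles);
* SAS EED: log-normal, median 1106, 5th percentile 74;
* control EED: Weibull, median 225, 95th percentile 3139;
* sample sizes 91 toxicity entries / 25 species, and 74 / 50 / 23
  exposure entries;
* within-species entry noise: log-normal, sd 0.5 on the log scale
  (entries scatter within roughly a factor e of their species mean — a
  realistic between-study spread; no value is stated for it anywhere, so
  it is chosen once here);
* entry metadata (duration bands, descriptor classes, endpoint categories
  at the 41/46/4 A/B/C frequencies) is drawn so that harmonization
  *exactly* reverses the uncertainty-factor divisor, and ~30% of entries
  are expressed in mg/kg with a full particle spec to exercise the
  conversion.

What the generator does **not** emulate: reporting ambiguities (sieve-text
parsing), censoring-informative designs, correlated species sensitivities,
spatial structure in exposure data, and measurement error in
concentrations. A green end-to-end test therefore establishes that the
statistical machinery recovers a known truth of the right geometry — not
that any real-world curation decision is correct.

## Known limitations

* The bootstrap interval conditions on the AIC-selected family;
  model-selection uncertainty is not propagated. The end-to-end recovery
  test measures the practical effect of this on HC5 interval coverage at
  n = 25 — coverage sits a few points below the nominal 95% precisely
  because the occasional heavy-tailed family choice narrows or shifts the
  interval.
* Censored descriptors (HONEC, LOEC-only) enter as point values; a
  censored likelihood would use them more honestly.
* The SSD weighs every species equally regardless of how many studies
  back it; no separate fits per polymer, shape or size class.
* MC2D assumes independence between a species' sensitivity and the
  concentration it encounters, and between the two fitted distributions.
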