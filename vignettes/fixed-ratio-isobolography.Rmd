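---
title: "Fixed-ratio isobolographic analysis: model, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixed-ratio isobolographic analysis: model, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isobolr)
```

## The model

Each arm of the experiment — drug A alone, drug B alone, and the fixed-ratio
mixture on its composed total dose — is modelled as linear in log dose with
homoscedastic Gaussian error:

$$y_i = a + b \,\log_{10}(d_i) + \varepsilon_i, \qquad
  \varepsilon_i \sim N(0, \sigma^2),$$

where $y$ is the percent of maximum possible effect (%MPE). %MPE is computed
from raw nociception times as $100\,(A - B)/A$ with $A$ the vehicle-group
mean and $B$ the animal's own time (`compute_mpe()`); it is deliberately
*not* clipped to $[0, 100]$ — hyperalgesic animals produce negative values
and the shipped data contain them, so clipping would bias the fit.

`fit_log_dose()` is unweighted ordinary least squares. The assumptions that
matter are (i) approximate linearity of mean %MPE in log dose over the
tested range — reasonable in the 0–80 %MPE window used here, although the
true dose-response is sigmoid, and (ii) constant residual variance across
dose groups. No weighting or heteroscedasticity correction is offered: the
classical calculus this package reproduces is unweighted, and the residual
scale (s ≈ 20–25 %MPE in the shipped data) is dominated by between-animal
variability rather than dose level.

The effective dose at target effect $\gamma$ (default 20 %MPE, the standard
level for this assay; any $\gamma \in (0, 100)$ is accepted) is the inverse
of the fitted line, with the textbook delta-method variance **on the log
scale**:

$$\widehat{\log ED_\gamma} = \frac{\gamma - a}{b}, \qquad
  V(\log ED_\gamma) = \frac{s^2}{b^2}
  \left(\frac{1}{N} + \frac{(\log ED_\gamma - \bar x)^2}{S_{xx}}\right).$$

`effective_dose()` warns when $\log ED_\gamma$ falls outside the fitted dose
range: the inversion is then an extrapolation and its variance formula is
optimistic.

One numerical note: the classical report block writes the residual quantity
$Q$ without squaring. Unsquared OLS residuals sum to zero identically, so
$Q$ is implemented as the residual *sum of squares* — the only reading that
reproduces the published slope variances.

## Design of the mixture experiment

The proportion factor $f = V(B)/(V(A)+V(B))$ uses the **log-scale** ED
variances (the only variances the single-drug calculus produces) and is then
applied to the **natural-scale** EDs: $a = f\,ED_A$, $b = (1-f)\,ED_B$,
$c = a + b$. This mixed-scale usage is the convention of the classical
procedure; it allocates the larger share of the mixture to the more
precisely estimated drug. `dose_ladder()` expands the design point into a
geometric series of dose pairs (defaults: 6 pairs, step 3, with the design
point as pair 4 — three steps down, two up), holding the component ratio
fixed to machine precision.

## The additivity comparison

`theoretical_additive()` computes $Z_{add} = f\,ED_A + (1-f)\,ED_B$ on the
natural dose scale with variance $V(Z_{add}) = f^2 V(A) + (1-f)^2 V(B)$
carried on the log scale, and `composite_t_test()` forms

$$t_{critical} = \frac{\log_{10} Z_{add} - \log_{10} Z_{mix}}
  {\sqrt{V(Z_{add}) + V(Z_{mix})}}, \qquad
  T_{tabulated} = \frac{t_{add} V(Z_{add}) + t_{mix} V(Z_{mix})}
  {V(Z_{add}) + V(Z_{mix})}.$$

Two conventions deserve comment because they are design choices of this
package, not forced by the arithmetic:

* **Critical values.** In `mode = "paper-compat"` (the default for
  reproducing tabulated analyses) $t_{add} = t_{mix} = 1.96$, the
  large-sample two-sided 5% value. In `mode = "exact"` Student critical
  values are used: $t_{mix}$ at $N_{mix}-2$ df, and $t_{add}$ at the pooled
  $N_A + N_B - 4$ df, since $Z_{add}$ combines two independent fits and no
  single-arm df is canonical. With the group sizes shipped here
  (df ≥ 45) the two modes differ by under 2%.
* **Direction.** $t_{critical}$ is kept signed (positive when
  $Z_{mix} < Z_{add}$); significance is judged on $|t_{critical}|$, and the
  verdict is *synergy* only when the difference is significant **and**
  $Z_{mix} < Z_{add}$ — a significant difference the other way is flagged
  *sub-additive* rather than silently reported as synergy.

The interaction index $\alpha = Z_{mix}/Z_{add}$ summarises the effect size;
`isobologram_coordinates()` exports the geometry (axis intercepts, additive
point, observed point) for plotting. The additive point
$(f ED_A, (1-f) ED_B)$ lies on the straight additivity isobole by
construction; the tests verify this identity numerically.

### A calibration caveat

The variance transport $V(Z_{add}) = f^2 V(A) + (1-f)^2 V(B)$ treats the
log-additive dose as if the two components contributed with weights $f$ and
$1-f$. The delta method gives weights $f ED_A / Z_{add}$ and
$(1-f) ED_B / Z_{add}$ instead; the two coincide exactly when the drugs are
equipotent ($ED_A = ED_B$), and the classical formula *understates*
$V(\log Z_{add})$ when one component dominates the additive sum — making the
composite test anticonservative for strongly unequal potencies such as the
shipped pair. The type-I-error calibration study in the test suite is
therefore run at the regime where the formula's own assumption holds: an
equal-potency additive null ($ED_{20} = 1$ nmol/site for both drugs, 60
animals per dose, 1000 replicates), where the empirical rejection rate is
required to stay within the one-sided band ≤ 7% around the nominal 5%. This
is a limitation of the classical calculus itself, inherited deliberately;
analyses of strongly unequal pairs should read a marginal $t_{critical}$
with caution (for the shipped data $t_{critical}$ exceeds its threshold
more than threefold, so the verdict is insensitive to it).

## What the synthetic generator emulates — and what it does not

`simulate_single()` draws %MPE linear in log dose with additive Gaussian
noise at user-specified dose levels and (possibly unequal) group sizes —
the structure of the real tables, including defaults mirroring the shipped
experiment (5 dose levels, 8–16 animals per level, σ ≈ 25 %MPE,
back-computed from the published residual variance). `simulate_combination()`
replays the whole design pipeline on the simulated single-drug *fits* (so
the proportion factor inherits sampling noise exactly as in practice),
builds the dose ladder, and generates the mixture arm on total dose with its
true ED equal to $\alpha_{true} \times Z_{add}(\text{truth})$; a single-drug
draw whose slope fails its t-test is redrawn from the same RNG stream, up to
ten times, as a real experiment would be repeated. All randomness flows from
the one seed in the spec; the caller's RNG state is untouched. With
$\sigma = 0$ both fitted ED variances vanish and $f$ is set to $1/2$ (the
formula is 0/0 there); this degenerate path is what makes exact noiseless
index recovery testable.

Not emulated: raw nociception times and their 300-s censoring (responses
enter as %MPE directly), dose-group heteroscedasticity, sigmoid saturation
outside the linear window, and litter or batch structure. A green
simulation test therefore establishes correctness of the *calculus* under
its own model, not robustness of the model to real-data violations.

## Data curation

The five shipped tables transcribe a published per-animal dataset. Doses
are the authoritative column; printed log columns are never trusted (the
source contains one sign typo and one off-by-a-decade log). Two curations,
each commented in the fixture file: a row printing dose 0.0003 with
log −2.52 is stored as 0.003, and the %MPE formula's missing parenthesis is
read in the standard form. The source's printed column sums are themselves
inconsistent with its own rows in two places (one response sum off by 16,
one log sum off by 0.36); the integrity tests compare recomputed sums
against the printed ones within bands that absorb these printing artefacts,
and all downstream statistics are recomputed from the rows only. pmol/site
doses are converted to nmol/site at the I/O boundary; everything internal
is nmol/site.

## Known limitations

* Linear %MPE regression, not probit/logistic: ED estimates far from the
  sampled effect range extrapolate a straight line into a sigmoid's tails.
* The additive-variance convention above; use `mode = "exact"` for honest
  df but there is no "fully delta-method" variance option, since it would
  no longer reproduce the classical tabulated results the package exists to
  reproduce.
* Two-drug fixed-ratio designs only; no response-surface or median-effect
  synergy models.
* Rounding happens only at render time; all reported comparisons against
  published values allow for the source's 1–3 significant-figure rounding.
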