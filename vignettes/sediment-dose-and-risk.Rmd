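---
title: "Dose and lifetime cancer risk from layered sediment contamination: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose and lifetime cancer risk from layered sediment contamination: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedidose)
```

## The assessment problem

A pond that received dredged sediments at a nuclear power plant holds
gamma-emitting contamination — Co-60 (half-life 5.27 y) up to a few
thousand Bq/kg wet weight and Cs-137 (30.05 y) up to a few tens of Bq/kg —
concentrated in the uppermost decimetre and declining with depth. Before the
site can be released for unrestricted use, the annual effective dose to a
member of the public living on the dried-out pond must fall below a
regulatory limit (0.1 mSv/y in Sweden). `sedidose` computes, for such a
site:

1. the **equivalent dose** $H_T$ to each tissue of a receptor of any age and
   sex from the layered source, integrated over the exposure period with
   radioactive decay and the receptor's anatomical growth inside the
   integral;
2. the sex-averaged **effective dose** $E = \sum_T w_T (H_{T,m} + H_{T,f})/2$
   with the ICRP 103 tissue weights;
3. the **lifetime attributable risk** (LAR) of cancer, per site and sex,
   from a survival-weighted integral of excess-rate models; and
4. **remediation scenarios** — removing the top $x$ cm of sediment or adding
   $x$ cm of clean cover — including the smallest action meeting the dose
   limit.

## Source model and slab algebra

Activity is modelled as piecewise-constant in depth (half-open 10-cm bins by
default, matching the core slicing; other thicknesses are accepted). The
conservative site profile is the **per-bin maximum** across cores on the
union of all slice boundaries. Measured campaigns rarely document how
individual cores were merged into calculation profiles; the maximum is the
simplest envelope that dominates every measurement, and it is what the
package's domination property tests assert. Depths below the deepest sampled
slice default to zero activity (keeping analytic oracles exact); an opt-in
`below = "extend"` mode prolongs the deepest bin to infinite depth for extra
conservatism when cores did not reach clean sediment.

External dose rates come from **cumulative-depth coefficients** $h(d)$: the
dose rate to a tissue per unit concentration of soil uniformly contaminated
from the surface to depth $d$ (reference soil, density 1600 kg/m³), tabulated
at $d \in \{1, 5, 15, \infty\}$ cm for six reference ages and both sexes —
the grid of the U.S. Federal Guidance soil tables. A slab $[a, b)$ then
contributes $h(b) - h(a)$, and a layered profile with cover $c$ contributes
$\sum_{\text{layers}} C \,[h(b + c) - h(a + c)]$. The clean cover is assumed
radiologically equivalent to the reference soil, so its shielding is realized
purely by this depth shift — no separate attenuation model. Plane (per-Bq/m²)
surface sources are deliberately not modelled; mixing areal and volumetric
units is a classic error source and the sediments are volumetric.

### Depth interpolation

The tables leave $h$ unknown between knots. The package interpolates the
**shortfall** $s(d) = h(\infty) - h(d)$ log-linearly in depth (and
extrapolates beyond 15 cm with the last segment's slope). The physical
motivation: the dose-rate deficit of a truncated source column decays
roughly exponentially as the column deepens, since deeper source layers are
exponentially attenuated. The scheme is *exact* for an exponential kernel
$h(d) = h_\infty(1 - e^{-d/\rho})$, which is precisely what the synthetic
tables use — so interpolation correctness is tested against a closed form to
1e-9, not against itself. A plain linear-in-$d$ mode (infinite-depth value
anchored at 45 cm) is available for sensitivity checks.

### Age dependence

Coefficients vary with receptor anatomy. The six reference ages are mapped
to knots $\{0, 1, 5, 10, 15, 20\}$ years with piecewise-linear interpolation
and an adult plateau from 20 y (the reference-age classes fix six anchors
but not the adult knot; 20 y follows common dosimetric practice). Depth
interpolation is applied within each bracketing reference age before the
linear mix, which keeps the result continuous in both variables and exact
for the synthetic tables, whose age factors are scalar multipliers.

## Equivalent and effective dose

The equivalent dose over an exposure of duration $T$ starting at age $A$ is

$$H_T(A, T) = f_{\text{out}} \int_0^{T} C(\tau)\, \dot h_T(A + \tau)\, d\tau,$$

with per-nuclide exponential decay inside $C(\tau)$ and the age-interpolated
coefficient inside $\dot h_T$. The integrand is a sum of (exponential ×
piecewise-linear) terms, so the integral is split at the age knots crossed
during the exposure and each smooth piece is integrated adaptively
(`stats::integrate`, relative tolerance 1e-8). With age-constant
coefficients the closed form $C_0 h\,(1 - e^{-\lambda T})/\lambda$ is
recovered to 1e-6 over $\lambda T$ from 0.01 to 5; the no-decay limit is
exactly $C_0 h T$. The outdoor fraction defaults to 1 (full-time occupancy on
the pond — the deliberately conservative assessment scenario).

Effective dose uses the ICRP 103 weights, shipped as an overridable data
set; the twelve remainder tissues are carried as one aggregate `remainder`
tissue with their joint weight of 0.12. A uniform organ-dose field therefore
returns itself ($\sum w_T = 1$), which the normalization tests assert.

## Lifetime attributable risk

For one cancer site, sex, organ dose $D$ and exposure age $e$:

$$\mathrm{LAR}(D, e) = \int_{e+L}^{a_{\max}} M(D, e, a)\, \frac{S(a)}{S(e+L)}\, da,$$

with attained age $a$, latency $L$ (5 y solid cancers, 2 y leukemia, applied
as a hard threshold — no phase-in ramp), survival curve $S$, and the
BEIR VII / EPA mixed excess-rate model

$$M = \frac{D}{\mathrm{DDREF}} \left[ w\,\beta_{\mathrm{ERR}}\,
e^{\gamma e^*} (a/60)^\eta\, \lambda_{\mathrm{base}}(a) +
(1 - w)\,\beta_{\mathrm{EAR}}\, e^{\gamma e^*} (a/60)^\eta \right],
\qquad e^* = \frac{\min(e, 30) - 30}{10}.$$

All parameters — per-site, per-sex $\beta$s, $\gamma$, $\eta$, transfer
weight $w$, DDREF, latency — are *data*, supplied as a CSV, never
hard-coded. The published reports print no parameter tables alongside their
results, so the shipped registry of 15 cancer sites carries synthetic values
on the scale of the literature (ERR a few tenths per Sv, $\gamma = -0.3$ per
decade, $\eta = -1.4$, $w = 0.7$, DDREF 1.5; leukemia DDREF 1). Headline
risk figures computed from the synthetic registry are therefore
order-of-magnitude companions to published site assessments, not
reproductions of them; users with access to the genuine EPA/BEIR VII values
load them with `read_risk_params()`. Both incidence and mortality are
supported by swapping the baseline-rate table and parameter set. Doses enter
as absorbed organ doses numerically equal to photon equivalent doses
(radiation weighting factor 1).

Numerical choices:

* The upper limit defaults to $a_{\max} = 110$ y (the integral's
  conventional form); "lifetime up to 120 years" appears in some risk
  definitions, so `a_max` is configurable, capped by the life-table end
  (110).
* $S$ is tabulated at integer ages and interpolated assuming a **constant
  force of mortality within each year of age** (log-linear in $S$) — the
  standard actuarial fractional-age assumption. It is exact for
  constant-hazard life tables, which is what makes the closed-form oracle
  $\mathrm{LAR} = m\,(e^{-\mu(e+L)} - e^{-\mu \cdot 110})/(\mu\, e^{-\mu(e+L)})$
  testable at 1e-6; plain linear interpolation would bias the integral by
  about $\mu^2/12$ relative (≈ 8e-6 at $\mu = 0.01$), larger than the
  quadrature tolerance itself.
* The integral is evaluated with 7-point Gauss–Legendre quadrature on each
  1-year segment: the integrand is smooth inside segments (its kinks sit at
  the integer ages where the interpolants change pieces), so the rule is
  accurate to machine precision there, and the whole evaluation is one
  vectorized pass — fast enough to sweep 91 exposure ages × 2 sexes × 15
  sites.
* LAR is linear in dose (linear-no-threshold after DDREF scaling) and
  invariant to rescaling $S$ — both asserted as properties.

## Remediation scenarios

Removal and covering are **mutually exclusive** actions (separate curves in
any assessment; a combined action is future work, and `remove_top()` refuses
to operate on a covered profile). Both strictly reduce the dose rate — cover
monotonicity follows from $h$ non-decreasing, removal monotonicity from
non-negative concentrations — so the search for the smallest action meeting
a dose limit is a **monotone bisection on a depth grid** (default 1 cm,
0–100 cm: published answers for comparable sites reach ~20 cm, and synthetic
sites can need more, so the default grid extends well past both). The search
is guaranteed to return the same answer as an exhaustive scan, which the
tests verify fixture by fixture. The limit is compared against the adult
effective dose by default (the regulatory convention); a flag selects the
newborn receptor instead, the most conservative choice since doses decrease
with age.

On the oracle configuration (uniform semi-infinite source, exponential
kernel with relaxation $\rho$), adding cover $c$ scales the dose by
$e^{-c/\rho}$, so the limit-meeting cover is $c = \rho \ln(E_0/E_{\lim})$ —
the analytic anchor for the search tests. Removing the top of a *uniform*
source barely changes the dose (the remaining column still looks
semi-infinite); removal pays off exactly when activity declines with depth,
as the measured sediments do.

## What the synthetic generator emulates — and what it does not

`synthetic_config()` fixes the study conditions; every generator is a pure
function of it (seed included):

* **Cores.** Ten locations, 40-cm cores sliced in 10-cm layers, reference
  date 2020-01-01. Slice concentration
  $C(d) = C_{\text{surf}}\, e^{-d_{\text{mid}}/\rho_p}\,
  e^{\mathcal N(0, \sigma)}$, clipped into the observed ranges (Co-60
  10–6000, Cs-137 5–50 Bq/kg wet weight). The surface draw is log-uniform
  (600–6000 and 20–50 Bq/kg), relaxation lengths 7 cm (Co-60) and 12 cm
  (Cs-137) express the observation that the decline is steeper for cobalt,
  and $\sigma = 0.5$ lognormal noise matches the right-skewed,
  strictly-positive scatter typical of environmental radioactivity. A config
  flag inverts the gradient of one chosen core, reproducing the occasional
  anomalous core whose activity increases with depth.
* **Kernels.** $h(d) = h_\infty f_{\text{age}} f_{\text{tissue}}
  (1 - e^{-d/10\,\text{cm}})$ with $h_\infty$ of 5e-6 (Co-60) and 1.5e-6
  (Cs-137) Sv/y per Bq/kg — chosen once so that a site like the measured pond yields
  effective doses of a few mSv/y, with the harder Co-60 photons dominating.
  Age factors fall from 1.30 (newborn) to 1.00 (adult), reproducing the
  qualitative newborn/adult dose ratio of published age-dependent soil
  coefficients; tissue factors vary mildly (±4%) so organs are not
  artificially identical.
* **Life tables.** Constant hazard ($S = e^{-\mu a}$, the closed-form
  oracle, $\mu = 0.01$/y default) or Gompertz
  ($S = e^{-(\alpha/\beta)(e^{\beta a} - 1)}$) on ages 0–110; constant or
  power-shaped baseline cancer rates with deterministic per-site scale
  factors.

What passing tests on these fixtures show: the *algebra and numerics* of the
pipeline — slab bookkeeping, interpolation, quadrature, monotonicity, search
— are correct to stated tolerances. What they do not show: that any
synthetic coefficient or risk parameter equals its real-world counterpart.
Real FGR-15 exports and EPA/BEIR VII parameters plug in through the CSV
readers without code changes; figure digitization of published depth
profiles is explicitly out of scope.

## Problem sizes and determinism

The shipped report (`run_report()`) evaluates six dose ages, ten LAR
exposure ages, a 0–30 cm sweep in 2-cm steps at age 30 and both limit
searches — about a minute of compute — and writes tidy CSVs plus a JSON
manifest (seed, config, version, output checksums; no wall-clock timestamp,
so reruns with the same config and seed are byte-identical). The test
suite's property loops use 2–4 cores per site and coarser sweep grids than
the report; these sizes were chosen so the full suite exercises every
acceptance property in about a minute while the analytic tolerances stay at
their stated values.

## Known limitations

* External exposure only: inhalation of resuspended dust, ingestion,
  foodstuff and drinking-water pathways are out of scope, as are
  cost–benefit analysis and derived concentration guideline levels.
* No decay chains; progeny in secular equilibrium must be folded into the
  coefficient data (as FGR-15-style tables do for Cs-137/Ba-137m).
* Upstanding-posture coefficients for the youngest age groups are known to
  be rough representations in the source data; no alternative posture model
  exists here either.
* No uncertainty propagation on LAR; single deterministic estimates only.
* Wet-weight concentrations throughout; no dry-weight conversion.
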