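---
title: "Measuring premature mortality: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring premature mortality: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppdkit)
```

This vignette is the package's own account of the models it implements:
what each quantity means, the conventions and tunable parameters, the
numerical choices at the edges, what the synthetic-data generator does and
does not emulate, and the known limitations.

## Life tables and the probability of premature death

Everything starts from an **abridged period life table**: age intervals
$[x, x+n)$ (conventionally $0$, $1\!-\!4$, then 5-year groups to an
open-ended $95+$), central death rates $m_x$, interval death
probabilities $q_x$, survivorship $l_x$ from a radix of 100 000, person
years $L_x$, and remaining life expectancy $e_x = T_x / l_x$. The
**probability of premature death** is read off the survivorship column:

$$\mathrm{PPD} = {}_{70}q_0 = 1 - \frac{l(70)}{l(0)}.$$

Both PPD and $e_0$ are synthetic-cohort quantities — independent of the
population's age structure — but they weight mortality differently: a
death averted at age 5 and one averted at age 65 move PPD equally, while
$e_0$ credits the younger death with more remaining years. PPD also
ignores mortality at 70 and above entirely. This is why PPD moves more
sharply than $e_0$ in low-mortality populations, and the package keeps
both.

### The $m_x \to q_x$ conversion

The published source of one's rates rarely states its life-table engine,
so the conversion rule is explicit and selectable:

* **`constant_hazard`** (default): $q_x = 1 - e^{-n m_x}$, i.e. the
  hazard is flat within each interval. Survivorship at every grid
  boundary is then exactly $l(x) = l(0)\exp(-\sum m\,n)$, which gives
  closed-form oracles for testing and makes boundary $l_x$ invariant to
  refining the grid under a shared hazard. $L_x = d_x / m_x$, so
  $m_x = d_x / L_x$ holds identically.
* **`midpoint`**: the classical $a_x = n/2$ rule with $a_0 = 0.1$ for
  the infant interval (infant deaths cluster near birth), and
  $q_x = n m_x / (1 + (n - a_x) m_x)$; this matches the construction of
  many published tables.

The open interval always has $q = 1$ and $L = l/m$; a zero $m$ there
with survivors present is rejected rather than patched, because $e_x$
would be undefined. Grid boundaries required by a calculation (70 for
PPD, 15 and 65 for the dependency ratio, the band cut-off and anchor
ages for valuation) are validated by name and never interpolated.
Both-sex tables are built from a both-sex rate schedule directly; the
package never averages sex-specific tables.

## Decline trajectories

Average annual decline rates are **estimated on the log scale**,
$r = -100\,\ln(p_1/p_0)/t$ %/yr, because that convention underlies the
halving-time identity $t_{1/2} = 69.3 / r$ (the constant is
$100\ln 2 = 69.3147\ldots$; the package uses the exact constant so the
estimate–halving-time round trip is exact, and prints 69.3 as published
tables do). Forward **projection uses discrete compounding**
$100\,(1 - (1 - r/100)^t)$ by default: at $r = 2.2$ %/yr this yields a
30% reduction after 16 years (29.95, printing as 30) and 50% after 31
years, the published milestone arithmetic, whereas the pure continuous
projector gives 29.7 after 16 years. The continuous projector is
selectable; both round to the same values for every in-scope check, and
the estimated-continuous / projected-discrete pairing is deliberate and
documented here rather than hidden.

Per-series rates can be estimated from the two endpoints (default — the
convention for "average rate over 2010–19" statements) or by a
log-linear regression over all years; on exactly exponential series the
two coincide. Track classification is `on_track` at $r \ge 2.2$
(boundary inclusive), `slow` at $r < 1.0$, `medium` between. The
">75 years" cap on printed halving times is presentation only
(`format_halving_time()`); internal values are never rounded or capped.
Horizons are calendar-year differences (2019 to 2050 is 31 years).

## Decomposing differences in life expectancy and in deaths

Age attribution uses **Arriaga's decomposition**: for closed intervals

$$\Delta_x = \frac{l^{1}_x}{l^{1}_0}\!\left(\frac{L^{2}_x}{l^{2}_x} -
\frac{L^{1}_x}{l^{1}_x}\right) + \frac{T^{2}_{x+n}}{l^{1}_0}
\!\left(\frac{l^{1}_x}{l^{2}_x} -
\frac{l^{1}_{x+n}}{l^{2}_{x+n}}\right),$$

with the open interval's contribution through its $T_x$ form. The terms
telescope, so contributions sum *exactly* to $e^2_0 - e^1_0$ — the
conservation property the summary tables rely on, and the main reason
this formulation was chosen over alternatives the background literature
leaves unspecified. Arriaga's attribution is mildly asymmetric in the
direction of comparison; `average = TRUE` reports the mean of the
forward and negated reverse runs, which is symmetric by construction.

The cause split within age $x$ is proportional to the cause-specific
rate difference $m^2_x f^2_{xc} - m^1_x f^1_{xc}$ (the standard Arriaga
cause extension). Shares sum to the age contribution by construction.
When the all-cause rates are equal in an interval, the age contribution
is provably zero up to round-off; any numerical residue is allocated
proportionally to the mean cause fractions so age totals are preserved
exactly. The partition is *approximate* relative to a counterfactual
cause-deletion calculation — cross-terms between causes do not vanish —
and the test suite quantifies that discrepancy on synthetic data (a few
percent of the total at realistic rate changes) instead of pretending
exactness. The `I-8` and `NCD-7` priority groupings ship as named
constants and are user-overridable; group percents are taken of the
*signed* total, so a cause working against the overall gap direction
shows a negative percent.

Changes in *death counts* mix demography with mortality. Writing deaths
as $D = P \sum_x c_x m_x$ (total population, age shares, rates), the
package uses the symmetric average-weight (Das Gupta) three-factor
standardization, which is exactly additive and antisymmetric: the
population-size, age-structure and rate components sum to $\Delta D$,
and swapping the periods negates each component.

## Valuing mortality change

A mortality change is valued with a **value-per-statistical-life to
income ratio** of 160 (default; the benefit-cost reference-case
convention for cross-country work):

$$\text{value (\% of income)} = 100 \times 160 \times
\big(r_{<75} + r_{\ge 75}\, e(80)/e(40)\big),$$

where the rates are annual deaths per person in the bands below and at
or-above the 75-year cut-off, and the old band is discounted by the
ratio of remaining life expectancies at the anchor ages 80 and 40 —
deaths at old ages represent fewer lost life years. The adjustment is
read from a supplied life table or passed as a scalar (per-country
tables are usually external); for senescent (rising-hazard) schedules it
lies strictly between 0 and 1, though a sufficiently pathological
non-monotone hazard could push it above 1, which is why the package does
not clamp it. Full-income change is definitionally the sum of the income
component and this mortality value, both relative to baseline income;
published component tables that were rounded before printing can be off
by one point in the sum, which is a property of the source tables, not
an adjustment made here. The income concept (e.g. GNI per capita, PPP)
is metadata on the inputs; the package performs no currency conversion.

## Excess mortality P-scores

The **P-score** is excess deaths over a period divided by the deaths
that would have been expected without the shock, in percent. The
baseline compounds reference-year deaths at an average annual change
(geometric mean of the pre-period year-over-year ratios), pro-rates
partial calendar years by actual day counts (leap years respected — the
choice matters because emergency periods end mid-year), and treats
deaths as uniform within a year for monthly series (yearly baseline /
12). Under that accounting the period P-score equals total excess over
total baseline and equals the baseline-weighted mean of the monthly
P-scores — an identity the tests verify to $10^{-9}$ — and is invariant
to common rescaling of observed and baseline, hence population-size
free. Excess deaths are an *input*: estimating them from raw all-cause
series is a different problem and out of scope.

## Pandemic risk

Annual exceedance probabilities $p$ convert to $n$-year horizons as
$1 - (1-p)^n$, assuming independent, identically distributed annual
risk — the assumption the published multi-year tables imply; clustering
or trending risk is out of scope. Expected annual deaths come from a
discrete severity distribution ($\sum \text{toll} \times
\text{probability}$) or equivalently from a step exceedance curve via
the threshold integral $\sum_i p_i (t_i - t_{i-1})$. Expected deaths are
turned into mortality impacts by adding $\text{deaths} \times
\text{share}_x / N_x$ to each interval's rate and rebuilding the life
table — reporting $\Delta$PPD in percentage points and $\Delta e_0$ in
years — and into welfare terms through the valuation above. The
catastrophe simulation that produces the exceedance curve and the
severity distribution is consumed as input, not re-derived.

## The synthetic-data generator

The generator emulates the *statistical shape* of the real inputs, with
ground truth controllable and recoverable:

* **Schedules**: a Gompertz–Makeham hazard $a + b e^{cx}$ with an added
  infant hump on $[0,1)$, averaged exactly over each interval (the open
  interval over its first 10 years, since it has no midpoint). Defaults
  ($a = 4\times10^{-4}$, $b = 5\times10^{-5}$, $c = 0.092$, hump
  $0.03$) describe a world-like population: PPD $\approx 0.33$, $e_0$
  in the low 70s, infant mortality about 30 per 1000.
* **Trajectories**: cause-specific rates decline *exactly*
  exponentially at declared rates, so `aarc()` recovers them to
  $10^{-9}$; the all-cause schedule is the cause sum, and cause
  fractions follow. The default age profile concentrates infections at
  young ages and NCDs at old ages. Because PPD is a concave functional
  of the cumulative hazard, the PPD-level decline is *slower* than the
  rate decline at high mortality (world-like PPD halving takes
  materially longer than $69.3/r$) and approaches it at low mortality;
  the tests exercise both regimes rather than asserting a single
  window.
* **Shocks**: monthly observed deaths equal to the trend baseline plus
  a raised-cosine wave whose total is fixed so the true period P-score
  equals the declared value exactly, with an old-skewed default age
  pattern.

What the generator does **not** emulate: heaping and registration error,
non-Gompertz old-age plateaus, cohort effects, migration, seasonality in
baseline deaths, or any calibration to a specific country. Passing tests
therefore demonstrate the *arithmetic* of the pipeline on structurally
realistic inputs, not agreement with any country's published values —
reproducing those would require the external life-table and
cause-of-death sources themselves.

## Problem sizes, determinism and degenerate inputs

Property-style tests run on the abridged 21-interval grid with hundreds
to a thousand random schedule pairs — ample for exercising conservation
identities at $10^{-9}$ while keeping the whole suite in seconds. All
generators are deterministic given their spec; randomness in tests is
seeded locally. Degenerate inputs are rejected with named diagnostics
rather than coerced: negative or non-finite rates, grids missing a
required boundary, cause fractions not summing to 1, zero working-age
population, zero-mortality open intervals with survivors, baselines that
are not positive, and non-contiguous age groups in CSV input (reported
with file row numbers).

## Known limitations

* Exact reproduction of externally published country tables is out of
  scope by design: their underlying data (and their life-table $a_x$
  conventions) are not part of the package's inputs.
* The cause partition inherits the usual cross-term ambiguity of
  cause-decomposition; the cause-deletion discrepancy is quantified, not
  eliminated.
* No statistical uncertainty is attached to decline rates or
  decompositions — the methods here are accounting identities on point
  estimates.
* Health-adjusted life expectancy, smoothing/graduation of raw death
  counts, excess-death estimation, and epidemic dynamics are
  deliberately not implemented.
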