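---
title: "Whole-tree chamber fluxes, carbon budgets, and stem growth under drought and recovery"
author: "treeflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-tree chamber fluxes, carbon budgets, and stem growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treeflux)
```

## The measurement problem

Whole-tree gas flux chambers enclose the shoot and the root system of a
potted tree in separate, continuously ventilated compartments. Supply air of
known CO2 and H2O content flows through each compartment; the tree depletes
CO2 (photosynthesis) or enriches it (respiration) and adds water vapor
(transpiration). Comparing the returned **sample** airstream against the
**reference** supply stream gives the compartment's net gas exchange without
touching the plant — continuously, for weeks, through a drought and the
recovery that follows.

`treeflux` implements the full analysis chain for such experiments:

1. **Chamber fluxes.** The molar CO2 flux of a compartment is the mass
   balance
   $$F_{\mathrm{CO_2}} = -\dot m\,(C_{\mathrm{sample}} - C_{\mathrm{ref}}),$$
   with $\dot m$ the molar air flow (mol s$^{-1}$) and both mole fractions
   on a **dry-air basis**: water vapor added by transpiration dilutes CO2,
   so each stream is first corrected as $C_{\mathrm{dry}} = C_{\mathrm{wet}}
   / (1 - w/1000)$ with $w$ in mmol mol$^{-1}$ (`dry_mole_fraction()`).
   Positive flux means carbon gain by the plant; root compartments are
   therefore negative. Plant-free blank chambers measure the small
   background differential of the system itself, and the time-matched blank
   differential (nearest blank within ±90 min, about one multiplexer cycle)
   is subtracted from every plant-chamber differential before the mass
   balance (`background_correct()`, `compute_fluxes()`).
2. **Leaf-area gas exchange.** Transpiration per leaf area follows the
   well-stirred chamber water balance; stomatal conductance is
   $g_{sw} = E/\Delta w$ with the leaf-to-air mole-fraction deficit
   $\Delta w = (e_{sat}(T_{air}) - e_{air})/P$, using the Tetens saturation
   curve and leaf temperature equal to air temperature. These formulas are
   the conventional ventilated-chamber derivations; no boundary-layer or
   energy-balance term is included, which is appropriate for fan-stirred
   chambers and documented as an approximation. Intrinsic water-use
   efficiency $WUE_i = A_{net}/g_{sw}$ may legitimately turn negative under
   net daytime respiration and is masked (not zeroed) where $g_{sw}$ is
   undefined.
3. **Carbon budget.** The daily compartment rate is the *mean* valid flux
   times $M_C = 12.01$ g mol$^{-1}$ times $86\,400$ s — mean-based
   integration rather than trapezoidal, matching how such chamber budgets
   are defined; the whole-plant rate is shoot + root, and cumulative carbon
   is the running sum of daily plant rates (`daily_carbon()`,
   `cumulative_carbon()`). Missing hours are excluded from the mean and a
   day with under 12 valid hours (configurable) is flagged.
4. **Stem growth.** Point-dendrometer displacement becomes absolute
   diameter (initial caliper diameter + displacement) and circular basal
   area. The **zero-growth concept** assumes no growth while the stem sits
   below its previously recorded maximum: cumulative growth is the running
   maximum of basal area, and the shortfall below that maximum is **tree
   water deficit**, a reversible dehydration signal (`zero_growth()`). The
   running maximum is never reset across the drought–recovery boundary, so
   rapid rehydration back to the pre-drought size correctly registers no
   growth; in addition the first recovery day is masked from reported
   growth (`recovery_mask()`).
5. **Hydraulic supply.** The Huber value $H_v$ is sapwood area per leaf
   area. Dendrometers measure over bark, and the package follows the
   experimental convention of using basal area as the sapwood proxy — by
   default its running maximum, so $H_v$ never decreases under constant
   leaf area. Units are mm$^2$ of sapwood per cm$^2$ of leaf, which places
   juvenile conifers near an operating point of ~0.08; the scale is a
   convention (the ratio itself is unit-bearing) and configurable.
6. **Summaries.** Daytime (09:00–14:00) and nighttime (00:00–05:00)
   window averages, the 05:00–17:00 midday growth window, treatment means
   with standard errors. All windows are half-open `[start, end)` to avoid
   double counting, and all treatment statistics average **per individual
   first**, then across individuals.

## The synthetic scenario generator

Chamber experiments of this kind have a handful of trees, three watering
treatments, and weeks of hourly data. The generator
(`scenario_config()`, `generate_scenario()`) reproduces that structure with
retained ground truth so every stage of the pipeline can be validated by
inversion:

```{r}
cfg <- scenario_config(n_trees = c(control = 2L, severe = 2L), seed = 1L)
ds <- generate_scenario(cfg)
ds
```

Default conditions are those of the juvenile Douglas fir greenhouse study
the package is built around: 28 days of drought, 35 days of recovery,
6/5/4 chamber trees in control/mild/severe treatments, supply air at
445.6 ppm CO2 and 8.0 mmol mol$^{-1}$ H2O, a 15-hour photoperiod, hourly
sampling, and blank-chamber background offsets of +0.15 ppm CO2 and
+0.03 mmol mol$^{-1}$ H2O. Gas exchange follows a truncated half-sine over
the photoperiod (light-driven assimilation; simple and differentiable), and
the unstressed operating point — leaf area 0.1 m$^2$, peak net assimilation
6.5 µmol m$^{-2}$ s$^{-1}$, shoot dark respiration 3×10$^{-7}$ and root
respiration 5.8×10$^{-7}$ mol s$^{-1}$ m$^{-2}$ leaf — was chosen once so
that control compartment daily rates sit near the published values
(≈ 0.24 g C d$^{-1}$ shoot, −0.06 g C d$^{-1}$ root). A ±20 % linear
seasonal trend emulates the steady seasonal rise of unstressed gas
exchange.

Drought enters as a **multiplicative effect trajectory on the whole net
compartment flux**: a linear ramp from 1 to 0.45 (mild) or 0.05 (severe)
across the drought, then a linear relaxation over 20 days of recovery to
1.0 (mild) or 0.5 (severe). Scaling the *net* flux — rather than only its
photosynthetic component — keeps the injected severe:control flux ratio
directly interpretable: during the final ten days the severe multiplier is
exactly 0.5, so the recovered terminal accumulation-rate ratio has a known
truth of 0.5. The ramps reproduce the qualitative severity ordering of the
study without asserting its printed treatment means, which derive from real
trees.

Stem traces combine (i) injected daily growth rates (defaults: the
published 0.58/0.28/0.04 mm$^2$ d$^{-1}$ under drought and 0.80/0.61/0.40
during recovery, with a 7-day post-drought growth delay for severe stress),
(ii) a configurable fraction of each day's growth inside the 05–17 h window
(default 30 % for controls), (iii) reversible diurnal shrink–swell that is
zero at night, and (iv) drought-induced elastic contraction proportional to
the water-status deficit, relaxing within ~2 days of rewatering. Because
shrink and contraction vanish at midnight for unstressed trees, the running
maximum recovers the injected growth exactly in the noise-free case.

One global seed expands into deterministic per-stream child seeds (one per
tree × channel), so adding a tree never perturbs existing streams and the
same configuration is bit-identical across runs.

What the generator does **not** emulate: instrument drift and calibration
steps, chamber leaks, soil–plant hydraulic feedbacks, leaf-area dynamics
(leaf area is constant, as assumed in the analysis), ABA signal
transduction, or NSC mass balance closed to the carbon budget. Passing
tests therefore demonstrate that the *analysis* is correct and unbiased
under the stated statistical structure — not that the structure captures
every property of real chamber data.

## A worked run

```{r}
res <- run_pipeline(ds, run_config(seed = 1L))
subset(res$period_summary, compartment == "plant")
res$tail_slopes
```

The severe-treatment terminal slope sits near half the control slope — the
injected ratio — and whole-plant rates equal shoot + root exactly on every
tree-day.

```{r}
part <- diurnal_partition(
  res$growth[res$growth$tree_id %in%
               ds$trees$tree_id[ds$trees$treatment == "control"], ])
part$daytime_fraction
```

## Numerical choices and edge cases

* **Dilution before background.** The blank differential is subtracted
  after both streams are converted to a dry basis; the generator and the
  analysis agree on this order, and on noise-free data the flux recovery is
  exact to floating-point (max relative error below 10$^{-12}$).
* **Resampling.** Raw chamber cycles are irregular (~80 min); series are
  linearly interpolated onto a common hourly clock, but never across gaps
  longer than 3 h (configurable) and never beyond the observed range.
  Undefined points (saturated chamber air, missing blanks, long gaps) stay
  `NA` and are excluded from means — they never enter as zeros.
* **Day boundaries** are UTC midnight, consistent with the 00:00–05:00
  nighttime window. Growth increments attach to the interval since the
  previous sample and are attributed to the interval's start hour; with
  hourly data, uniform growth then splits exactly 12/24 into the 05–17 h
  window.
* **OLS fits** (terminal accumulation rates, diurnal growth rates) use
  ordinary least squares with the classical slope standard error; an
  exactly collinear fit reports SE 0. Treatment-mean diurnal composites are
  fit by default (per-tree fits remain available by subsetting).
* **Running-maximum inflation under noise.** With dendrometer noise the
  running maximum creeps upward over pure-noise segments, biasing apparent
  growth slightly high near zero growth — visible as the severe treatment's
  near-zero (not exactly zero) drought growth. This is a known property of
  zero-growth extraction, not an implementation artifact; noise-free tests
  pin the exact behavior.
* **Problem sizes** used in the validation suite were chosen to keep the
  full run comfortable on a laptop: the noise-free oracle scenario uses 3
  treatments × 2 trees × 63 days hourly; parameter recovery uses 20 seeds
  of a 2-treatment scenario; the brute-force zero-growth oracle runs 100
  random traces of length 10$^4$.

## Known limitations

* Sapwood is proxied by whole over-bark basal area; real sapwood area is
  smaller, so $H_v$ is an index, not an anatomical measurement.
* Mesophyll conductance, boundary-layer conductance, leaf energy balance,
  and chamber leak modeling are out of scope; $g_{sw}$ assumes leaf
  temperature equals air temperature.
* Inferential statistics (mixed-effects models, smoothers, multiple
  comparisons) are deliberately excluded: the pipeline exports tidy tables
  for any statistics environment.
* Whether the original chamber systems computed the vapor deficit from leaf
  or air temperature, and whether background subtraction preceded or
  followed dilution correction, are conventions; the package fixes both
  (air temperature; dilution first) and documents them here.
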