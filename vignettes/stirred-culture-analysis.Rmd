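---
title: "Shear, kinetics and morphology analysis of stirred suspension cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shear, kinetics and morphology analysis of stirred suspension cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stircell)
```

`stircell` analyses ex vivo expansion of suspension cells (hematopoietic
cell lines being the motivating application) in small unbaffled stirred-tank
bioreactors. It answers three questions about an expansion run: *how harsh
is the hydrodynamic environment*, *how fast do the cells grow and consume
substrate*, and *does the shear deform them*. A synthetic-data generator
with exact ground truth closes the loop, so every analysis stage is testable
without wet-lab data.

## The hydrodynamic model

The vessel is an unbaffled cylinder stirred by a flat-blade paddle. From the
geometry (vessel diameter $D$, impeller diameter $d$, blade height $b$,
liquid height $H$, working volume $V_L$), the fluid (density $\rho$,
kinematic viscosity $\nu$) and the agitation speed $N$ (rev/s), the package
computes:

* impeller Reynolds number $Re = N d^2 / \nu$;
* power number $N_p$ from Nagata's correlation for unbaffled vessels,
  $N_p = A/Re + B\left[(10^3 + 1.2\,Re^{0.66})/(10^3 +
  3.2\,Re^{0.66})\right]^p$ with geometry factors $A(b/D, d/D)$,
  $B(b/D, d/D)$ and $p(b/D, d/D)$ (see `?nagata_power_number`);
* power draw $P = N_p N^3 d^5 \rho$ and specific energy dissipation
  $\varepsilon = P / (V_L\,\rho)$;
* maximum shear stress on a suspended cell,
  $\tau_{max} = 5.33\,\rho\,(\varepsilon\nu)^{1/2}$;
* integrated shear factor $ISF = 2\pi N d/(D - d)$, the averaged shear in
  the impeller–wall gap ($D$ is always the vessel and $d$ the impeller
  diameter; the package enforces $D > d$);
* Kolmogorov eddy length $\lambda_K = (\nu^3/\varepsilon)^{1/4}$ — cells an
  order of magnitude smaller than $\lambda_K$ essentially follow the local
  flow;
* a strict comparison of $\tau_{max}$ against a cell-type threshold,
  defaulting to 0.092 Pa, the reported ceiling for unimpaired hematopoietic
  stem-cell proliferation.

```{r hydro}
geom <- vessel_geometry(vessel_diameter = 0.065, impeller_diameter = 0.0325,
                        blade_height = 0.0039, liquid_height = 0.0299,
                        working_volume = 1e-4)
hydrodynamic_report(geom, fluid_properties(), agitation_condition(50))
```

**Blade height.** Characterisations of bench-top paddle vessels often omit
$b$, yet Nagata's $N_p$ depends on $b/D$. `stircell` therefore makes
`blade_height` a required geometry parameter and documents $b/D = 0.06$ as
the value used for the reference 100-ml vessel: a brute-force sweep of
$b/D \in [0.03, 0.15]$ (kept as a test) shows 0.06 is the unique value
reproducing the reference power-number pair $(0.78, 0.69)$ at the two
operating Reynolds numbers within $\pm 0.01$.

**Fluid defaults.** Culture media are hydrodynamically close to water, so
`fluid_properties()` defaults to $\rho = 1000$ kg/m³ and
$\nu = 10^{-6}$ m²/s.

**Internal consistency over table imitation.** Published operating tables
for such vessels are occasionally internally inconsistent (e.g. a tabulated
$Re$ pair whose ratio differs from the speed ratio, or an $\varepsilon$ that
cannot be produced by the tabulated $N_p$ through the power chain). The
package always computes the self-consistent chain from first principles; it
never patches individual values to match a printed table. For the reference
vessel the chain reproduces the consistent cells ($\varepsilon$ at 50 rpm,
$\tau_{max}$ and $\lambda_K$ from the tabulated $\varepsilon$, $ISF$ and
$Re$ at 100 rpm, $N_p$ at $Re \approx 1764$) within 1%, while the 50-rpm
$Re$ of 867.69 would require $\nu \approx 1.014\times10^{-6}$ m²/s and the
50-rpm $ISF$ of 5.46 is not obtainable from the formula (the chain gives
880.2 and 5.24).

**K~L~a.** No mass-transfer correlation is implemented; the volumetric
oxygen transfer coefficient is accepted as a measured input and copied
verbatim into reports.

rpm→rev/s conversion happens once, in `agitation_condition()`; every
formula downstream sees rev/s.

## Growth and metabolite kinetics

Batch growth is modelled as $C_x(t) = C_{x0} e^{\mu t}$. Because the model
is log-linear, `fit_growth()` uses ordinary least squares on
$\ln C_x$ vs $t$ — no nonlinear refinement — and reports $\mu$ (1/h),
$C_{x0}$ (cells/ml) and $R^2$ on the log scale. Fold expansion is reported
independently as final/initial density; the two are *not* forced to agree,
since a fitted $\mu$ and an observed endpoint carry different information
(with sparse sampling and a possible lag or decline phase, $C_{x0}e^{\mu T}$
need not equal the observed endpoint).

Metabolites follow the batch mass balance $\pm q_{met}\,C_x = dC_{met}/dt$
with constant specific rate $q_{met}$. With exponential growth this
integrates to

$$C(t) = C_0 \pm q\,m\,C_{x0}\,\frac{e^{\mu t} - 1}{\mu},$$

where $m = 1000$ ml/l reconciles per-ml densities with per-litre
concentrations ($m$ appears in exactly one place in the code, and is why
$q$ comes out in g·cell⁻¹·h⁻¹ at the pg/cell/h magnitude typical of
mammalian cells). The $\mu = 0$ limit is the linear profile; for tiny $\mu$
the implementation uses `expm1` so the limit is approached without
cancellation. Predicted depletion is floored at 0 g/l with a warning.

**Medium exchanges.** Partial medium replacement (here 50% on days 1, 3
and 5) makes raw concentration differences meaningless. An exchange at time
$\tau$ replacing a fraction $f$ with fresh concentration $C_f$ resets the
baseline to $(1-f)\,C(\tau^-) + f\,C_f$; `apply_exchange_correction()`
removes these jumps and returns the cumulative *biological* change, which is
continuous across events. Two conventions matter:

* a sample taken at an exchange time is the **pre-exchange** concentration
  (the spent medium is sampled before replacement);
* for events strictly inside a sampling interval, the biological rate is
  assumed constant within the interval and the unobserved $C(\tau^-)$ is
  recovered by affine propagation of that rate through the event algebra —
  exact whenever events coincide with sampling times, which is the default
  schedule.

`specific_metabolite_rate()` reports $q$ as a positive magnitude with a
consumption/production flag (the balance is written $\pm q$), both per
interval (using the arithmetic mean of the endpoint densities, matching
discrete sampling practice) and overall (exchange-corrected total change
divided by the time integral of the fitted exponential, which is the exact
inverse of the closed-form profile on noiseless data). The fraction of
lactate produced per glucose consumed, both exchange-corrected
(`lactate_glucose_ratio()`), indexes overflow metabolism.

## Morphology

`segment_cells()` thresholds the image with Otsu's histogram-bimodality
method (or a user-supplied cutoff), labels 8-connected foreground
components, and discards components touching the border (their shape is
censored) or smaller than 50 px² (debris). Axis lengths are the
ellipse-equivalent axes from second-order central moments, not bounding
boxes. Per-cell roundness is

$$R_c = \frac{4\,A}{\pi\,L_{maj}^2},$$

the definition used by mainstream image-analysis software; for an ideal
ellipse it equals the minor/major axis ratio. Raster discretization can push
$R_c$ marginally above 1; values up to 1.05 are clamped to 1, anything
larger is treated as a degenerate measurement. The classical circularity
$4\pi A/P^2$ is also reported as a secondary descriptor but is never used
for classification (pixel-counted perimeters bias it). The round-cell
frequency is the exact counting ratio
$f_r = \#\{R_c > 0.8\}/n$ with a *strict* inequality at the conventional
0.8 threshold.

The connected-component labelling is delegated to EBImage; since its
`bwlabel` is 4-connected, the package merges diagonally touching labels in
a union–find pass to obtain 8-connected components.

## The synthetic-data generator

`simulation_config()` fixes the simulated study conditions:

| parameter | default | rationale |
|---|---|---|
| seeding density $C_{x0}$ | $10^5$ cells/ml | standard seeding for suspension expansion |
| growth rate $\mu$ | 0.028 1/h | the low-shear (50 rpm) condition; 0.022 1/h is the high-shear arm |
| count sampling | days 0, 3, 5, 7 | typical counting schedule |
| counting noise | lognormal, $\sigma = 0.1$ | counts are positive, errors multiplicative; ~10% CV is realistic for hemocytometry |
| exchanges | 50% at 24, 72, 120 h | the fed-batch schedule of the emulated protocol |
| glucose $C_0$ / fresh | 2.0 g/l | standard basal-medium glucose |
| $q_{glc}$ | $3\times10^{-12}$ g·cell⁻¹·h⁻¹ | consumes ≈60% of the supplied glucose by 168 h under this schedule |
| $q_{lac}$ | $2.7\times10^{-12}$ g·cell⁻¹·h⁻¹ | lactate:glucose yield 0.9 g/g |
| metabolite noise | Gaussian, 0.05 g/l | enzymatic-assay scale error |
| image | 100 cells, round fraction 0.67, axis ratios 0.85–0.98 (round) / 0.40–0.70 (stretched) | the low-shear arm's observed morphology; the ratio bands deliberately exclude 0.75–0.85 so rasterization error cannot flip a ground-truth class |

All generators are driven by R's default Mersenne-Twister stream:
`set.seed(seed)` (offset by a small constant per generator so growth,
metabolite and image draws are independent) at function entry, which makes
output reproducible across platforms but does advance the session RNG.

What the generator does *not* emulate: lag and death phases, substrate
limitation (no Monod term), shear-dependent death or apoptosis kinetics,
cell–cell overlap and clumping in images, illumination gradients, or focus
blur. Passing the recovery tests therefore shows the estimators are
correct *under the stated models*, not that the models capture every
feature of real cultures.

```{r endtoend}
cfg <- simulation_config(seed = 42)
fit_growth(simulate_growth(cfg))
im <- render_cell_image(cfg)
round_fraction(segment_cells(im$image))
```

## Numerical and design choices

* **Estimator sizes.** The validation suite uses 200 replicate cultures for
  growth-rate recovery, 100 replicates for the metabolite $R^2$ study, and
  one 100-cell image (1024² px) per morphology check; these sizes give
  Monte-Carlo standard errors well below the tolerances being checked while
  keeping the suite quick.
* **Strictness conventions.** $\tau_{max} > \tau_{thr}$ and $R_c > 0.8$ are
  strict; boundary equality is "not exceeded" / "not round".
* **Degenerate inputs.** Zero agitation gives $Re = P = \varepsilon =
  \tau_{max} = 0$ and an undefined $N_p$ (reported as `NA`); a uniform
  image segments to zero regions without error; an empty region list makes
  $f_r$ an error (undefined statistic); zero observed variance makes $R^2$
  an error, except inside `specific_metabolite_rate()` where a constant
  concentration series legitimately yields `NA`.
* **Full precision first.** CSV outputs carry full precision; rounding
  happens only in printed text reports.

## Reproducing a whole analysis

`run_full_pipeline()` chains everything for a three-arm comparison (50 rpm,
100 rpm, static) on synthetic data and writes per-stage CSVs, a combined
comparison table and a JSON manifest (command, config snapshot, seed,
package version, file digests). Reruns with the same seed are
byte-identical. The same stages are exposed as the `hydro`, `growth`,
`metabolite`, `morph`, `simulate` and `all` subcommands of the thin
command-line wrapper in `inst/scripts/stircell.R`.

## Limitations

The hydrodynamic description is a correlation-level model: a single Nagata
form for unbaffled paddle vessels, no CFD, no baffled or non-paddle
geometries, no gas–liquid mass transfer. The kinetics assume a single
exponential phase and constant specific rates. The morphology stage does
not split touching cells (no watershed) and quantifies shape only — it does
not measure apoptosis or viability from images.
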