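# stircell

Quantitative analysis of suspension-cell expansion in small unbaffled
stirred-tank bioreactors, for bioprocess engineers characterising ex vivo
expansion of shear-sensitive cells (e.g. hematopoietic cell lines). The
package covers the three questions asked of such a run:

1. **How harsh is the shear environment?** From vessel geometry, fluid
   properties and agitation rate it computes the impeller Reynolds number
   `Re = N d² / ν`, the Nagata power number for unbaffled paddle vessels,
   power draw `P = N_p N³ d⁵ ρ`, specific energy dissipation
   `ε = P / (V_L ρ)`, maximum shear stress `τ_max = 5.33 ρ (εν)^½`, the
   integrated shear factor `ISF = 2πNd/(D−d)`, the Kolmogorov eddy length
   `λ_K = (ν³/ε)^¼`, and a strict comparison of `τ_max` against a
   cell-type threshold (default 0.092 Pa, the reported ceiling for
   hematopoietic stem-cell proliferation).
2. **How fast do the cells grow and metabolise?** Log-linear fitting of
   exponential batch growth `C_x = C_x0 exp(μt)`, fold expansion, and
   specific glucose/lactate rates from the batch mass balance
   `± q C_x = dC/dt`, with exchange-corrected accounting for partial
   medium replacements (e.g. 50% on days 1/3/5) and the lactate:glucose
   yield ratio.
3. **Does shear deform the cells?** Segmentation of grayscale micrographs
   (Otsu threshold, 8-connected components, border and small-object
   exclusion), per-cell roundness `R_c = 4A/(π L_maj²)` from
   moment-equivalent ellipse axes, and the round-cell frequency
   `f_r = #{R_c > 0.8}/n`.

A synthetic-data module generates growth series, metabolite profiles and
cell images with exact ground truth, so every stage is validated end to end
by parameter recovery. See the vignette
(`vignettes/stirred-culture-analysis.Rmd`) for the models, conventions and
design choices.

## Worked example

```r
library(stircell)

geom <- vessel_geometry(vessel_diameter = 0.065, impeller_diameter = 0.0325,
                        blade_height = 0.0039, liquid_height = 0.0299,
                        working_volume = 1e-4)
hydrodynamic_report(geom, fluid_properties(), agitation_condition(100))
#> Hydrodynamic report at 100 rpm
#>   Reynolds number               1760.42
#>   Power number N_p                0.693
#>   Power draw P (W)            1.163e-04
#>   Energy dissipation (W/kg)   1.163e-03
#>   Max shear stress (Pa)          0.1818
#>   Integrated shear (1/s)         10.472
#>   Kolmogorov length (um)          171.2
#>   Exceeds 0.092 Pa threshold: TRUE (margin +0.090 Pa)
```

At 100 rpm the maximum shear stress exceeds the 0.092 Pa proliferation
threshold (at 50 rpm the same chain gives 0.068 Pa — below it), and the
smallest eddies (~170 µm) remain an order of magnitude larger than a
~10 µm cell, so cells follow the local flow rather than being sheared by
individual eddies.

```r
cfg <- simulation_config(seed = 42)          # 1e5 cells/ml, mu = 0.028 1/h
s   <- simulate_metabolites(cfg)             # growth + glucose/lactate + exchanges
fit_growth(s)
#> Exponential growth fit: mu = 0.028 1/h, C_x0 = 1e+05 cells/ml, R^2 = 1.0000
specific_metabolite_rate(s, "glucose")
#> Specific glucose consumption rate: q = 3.092e-12 g/cell/h (R^2 = 0.986)

im <- render_cell_image(cfg)                 # 100 cells, 67 truly round
round_fraction(segment_cells(im$image))
#> Morphology: 100 cells, f_r = 0.670 (R_c > 0.8)
```

The fitted growth rate (0.028 1/h), glucose consumption (~3 pg/cell/h) and
round-cell frequency (0.67) recover the generator's ground truth.
`run_full_pipeline(out_dir, seed)` chains all stages for a three-arm
comparison (50 rpm / 100 rpm / static) and writes CSV reports plus a JSON
run manifest; `inst/scripts/stircell.R` exposes the same stages as
`hydro`, `growth`, `metabolite`, `morph`, `simulate` and `all`
subcommands.

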