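# 100-ml unbaffled paddle vessel used throughout: D = 65 mm, d/D = 0.5,
# b/D = 0.06, H/D = 0.46.
bench_vessel <- function(b_over_D = 0.06) {
  vessel_geometry(vessel_diameter = 0.065, impeller_diameter = 0.0325,
                  blade_height = 0.065 * b_over_D, liquid_height = 0.0299,
                  working_volume = 1e-4)
}

water <- function() fluid_properties(density = 1000, kinematic_viscosity = 1e-6)

# independent transcription of the Nagata unbaffled-vessel correlation,
# kept deliberately separate from the package implementation
nagata_oracle <- function(Re, dD, bD) {
  A <- 14 + bD * (670 * (dD - 0.6)^2 + 185)
  B <- 10^(1.3 - 4 * (bD - 0.5)^2 - 1.14 * dD)
  p <- 1.1 + 4 * bD - 2.5 * (dD - 0.5)^2 - 7 * bD^4
  A / Re + B * ((1e3 + 1.2 * Re^0.66) / (1e3 + 3.2 * Re^0.66))^p
}

# rasterize filled ellipses: shapes is a data.frame with columns
# cx, cy, a (semi-major), b (semi-minor), angle (rad)
raster_ellipses <- function(side, shapes, fg = 0.9, bg = 0.05) {
  img <- matrix(bg, side, side)
  x <- matrix(seq_len(side), side, side)
  y <- matrix(seq_len(side), side, side, byrow = TRUE)
  for (i in seq_len(nrow(shapes))) {
    dx <- x - shapes$cx[i]; dy <- y - shapes$cy[i]
    u <- dx * cos(shapes$angle[i]) + dy * sin(shapes$angle[i])
    v <- -dx * sin(shapes$angle[i]) + dy * cos(shapes$angle[i])
    img[(u / shapes$a[i])^2 + (v / shapes$b[i])^2 <= 1] <- fg
  }
  img
}

# exponential culture series with optional metabolites and exchanges
exp_series <- function(times = c(0, 72, 120, 168), mu = 0.028, c0 = 1e5, ...) {
  culture_time_series(times, c0 * exp(mu * times), ...)
}
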