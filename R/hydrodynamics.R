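#' Vessel geometry for a stirred cylindrical bioreactor
#'
#' Bundles the geometric parameters of an unbaffled, flat-blade paddle
#' stirred-tank bioreactor and checks their mutual consistency. The working
#' volume must agree with the cylinder defined by the vessel diameter and
#' liquid height to within 5% (free-surface curvature and probe displacement
#' account for small differences in practice).
#'
#' @param vessel_diameter Vessel (tank) inner diameter D in m.
#' @param impeller_diameter Impeller diameter d in m; must satisfy 0 < d < D.
#' @param blade_height Impeller blade height b in m. Paddle power-draw
#'   correlations are sensitive to b/D; see [nagata_power_number()].
#' @param liquid_height Liquid (medium) height H in m.
#' @param working_volume Working liquid volume V_L in m^3.
#' @return An object of class `vessel_geometry`: a list with the five input
#'   fields plus the derived read-only ratios `aspect_ratio` (H/D) and
#'   `d_over_D` (d/D) and `b_over_D` (b/D).
#' @examples
#' geom <- vessel_geometry(0.065, 0.0325, 0.0039, 0.0299, 1e-4)
#' geom$d_over_D  # 0.5
#' @export
vessel_geometry <- function(vessel_diameter, impeller_diameter, blade_height,
                            liquid_height, working_volume) {
  for (v in list(vessel_diameter, impeller_diameter, blade_height,
                 liquid_height, working_volume)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("all geometry parameters must be finite positive scalars",
           call. = FALSE)
    }
  }
  if (impeller_diameter >= vessel_diameter) {
    stop("impeller diameter must be smaller than vessel diameter",
         call. = FALSE)
  }
  cyl <- pi * (vessel_diameter / 2)^2 * liquid_height
  if (abs(working_volume - cyl) / working_volume > 0.05) {
    stop(sprintf(paste0("working volume (%.3g m^3) inconsistent with ",
                        "cylinder D x H (%.3g m^3): relative difference > 5%%"),
                 working_volume, cyl), call. = FALSE)
  }
  structure(
    list(vessel_diameter = vessel_diameter,
         impeller_diameter = impeller_diameter,
         blade_height = blade_height,
         liquid_height = liquid_height,
         working_volume = working_volume,
         aspect_ratio = liquid_height / vessel_diameter,
         d_over_D = impeller_diameter / vessel_diameter,
         b_over_D = blade_height / vessel_diameter),
    class = "vessel_geometry")
}

#' Fluid properties of the culture medium
#'
#' Density and viscosity of the liquid phase. Culture media are routinely
#' approximated by water at 37 C; the defaults are water at room-temperature
#' reference values (rho = 1000 kg/m^3, nu = 1e-6 m^2/s). Exactly one of
#' `dynamic_viscosity` or `kinematic_viscosity` may be given; the other is
#' derived as nu = mu_f / rho.
#'
#' @param density Density rho in kg/m^3.
#' @param dynamic_viscosity Dynamic viscosity mu_f in Pa s, or `NULL`.
#' @param kinematic_viscosity Kinematic viscosity nu in m^2/s, or `NULL`.
#' @return An object of class `fluid_properties` with fields `density`,
#'   `dynamic_viscosity` and `kinematic_viscosity`.
#' @examples
#' water <- fluid_properties()
#' water$kinematic_viscosity  # 1e-6
#' @export
fluid_properties <- function(density = 1000, dynamic_viscosity = NULL,
                             kinematic_viscosity = if (is.null(dynamic_viscosity)) 1e-6 else NULL) {
  if (!is.numeric(density) || length(density) != 1L || !is.finite(density) ||
      density <= 0) {
    stop("density must be a finite positive scalar", call. = FALSE)
  }
  if (!is.null(dynamic_viscosity) && !is.null(kinematic_viscosity)) {
    stop("give either dynamic_viscosity or kinematic_viscosity, not both",
         call. = FALSE)
  }
  if (is.null(dynamic_viscosity)) dynamic_viscosity <- kinematic_viscosity * density
  if (!is.numeric(dynamic_viscosity) || !is.finite(dynamic_viscosity) ||
      dynamic_viscosity <= 0) {
    stop("viscosity must be a finite positive scalar", call. = FALSE)
  }
  structure(
    list(density = density,
         dynamic_viscosity = dynamic_viscosity,
         kinematic_viscosity = dynamic_viscosity / density),
    class = "fluid_properties")
}

#' Agitation condition
#'
#' Impeller speed, normalised once at construction: all internal formulas use
#' revolutions per second.
#'
#' @param rpm Impeller speed in revolutions per minute (>= 0).
#' @return An object of class `agitation_condition` with fields `speed_rpm`
#'   and `speed_rps`.
#' @export
agitation_condition <- function(rpm) {
  if (!is.numeric(rpm) || length(rpm) != 1L || !is.finite(rpm) || rpm < 0) {
    stop("rpm must be a finite non-negative scalar", call. = FALSE)
  }
  structure(list(speed_rpm = rpm, speed_rps = rpm / 60),
            class = "agitation_condition")
}

#' Impeller Reynolds number
#'
#' Re = rho N d^2 / mu_f = N d^2 / nu, with N the impeller speed in rev/s and
#' d the impeller diameter.
#'
#' @param geometry A [vessel_geometry()].
#' @param fluid A [fluid_properties()].
#' @param agitation An [agitation_condition()].
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(geometry, fluid, agitation) {
  stopifnot(inherits(geometry, "vessel_geometry"),
            inherits(fluid, "fluid_properties"),
            inherits(agitation, "agitation_condition"))
  agitation$speed_rps * geometry$impeller_diameter^2 /
    fluid$kinematic_viscosity
}

#' Nagata power number for an unbaffled paddle-stirred vessel
#'
#' Power number N_p from Nagata's correlation for flat-blade paddle impellers
#' in unbaffled cylindrical vessels:
#' \deqn{N_p = A/Re + B \left(\frac{10^3 + 1.2\,Re^{0.66}}{10^3 + 3.2\,Re^{0.66}}\right)^p}
#' with geometry factors
#' \deqn{A = 14 + (b/D)\,[670\,(d/D - 0.6)^2 + 185]}
#' \deqn{B = 10^{\,1.3 - 4(b/D - 0.5)^2 - 1.14\,(d/D)}}
#' \deqn{p = 1.1 + 4(b/D) - 2.5\,(d/D - 0.5)^2 - 7\,(b/D)^4}
#'
#' @param geometry A [vessel_geometry()]; only the ratios d/D and b/D enter.
#' @param reynolds Impeller Reynolds number (> 0).
#' @return Dimensionless power number.
#' @export
nagata_power_number <- function(geometry, reynolds) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  if (!is.numeric(reynolds) || any(!is.finite(reynolds)) || any(reynolds <= 0)) {
    stop("Reynolds number must be finite and positive", call. = FALSE)
  }
  dD <- geometry$d_over_D
  bD <- geometry$b_over_D
  if (dD <= 0 || dD >= 1 || bD <= 0 || bD >= 1) {
    stop("geometry ratios d/D and b/D must lie in (0, 1)", call. = FALSE)
  }
  A <- 14 + bD * (670 * (dD - 0.6)^2 + 185)
  B <- 10^(1.3 - 4 * (bD - 0.5)^2 - 1.14 * dD)
  p <- 1.1 + 4 * bD - 2.5 * (dD - 0.5)^2 - 7 * bD^4
  re66 <- reynolds^0.66
  A / reynolds + B * ((1e3 + 1.2 * re66) / (1e3 + 3.2 * re66))^p
}

#' Impeller power draw
#'
#' P = N_p N^3 d^5 rho (W).
#'
#' @param power_number Dimensionless power number N_p (>= 0).
#' @inheritParams reynolds_number
#' @return Power in W.
#' @export
impeller_power <- function(power_number, agitation, geometry, fluid) {
  stopifnot(inherits(geometry, "vessel_geometry"),
            inherits(fluid, "fluid_properties"),
            inherits(agitation, "agitation_condition"))
  if (!is.numeric(power_number) || any(!is.finite(power_number)) ||
      any(power_number < 0)) {
    stop("power number must be finite and non-negative", call. = FALSE)
  }
  power_number * agitation$speed_rps^3 * geometry$impeller_diameter^5 *
    fluid$density
}

#' Specific energy dissipation rate
#'
#' epsilon = P / (V_L rho) in W/kg: the power input per unit mass of liquid,
#' which sets the turbulence intensity the cells experience.
#'
#' @param power Power draw P in W (>= 0).
#' @inheritParams reynolds_number
#' @return epsilon in W/kg.
#' @export
energy_dissipation <- function(power, geometry, fluid) {
  stopifnot(inherits(geometry, "vessel_geometry"),
            inherits(fluid, "fluid_properties"))
  if (!is.numeric(power) || any(!is.finite(power)) || any(power < 0)) {
    stop("power must be finite and non-negative", call. = FALSE)
  }
  power / (geometry$working_volume * fluid$density)
}

#' Maximum hydrodynamic shear stress on a suspended cell
#'
#' tau_max = 5.33 rho (epsilon nu)^(1/2) (Pa), the peak shear stress estimate
#' for a cell or aggregate suspended in homogeneous turbulence.
#'
#' @param epsilon Specific energy dissipation rate in W/kg (>= 0).
#' @param fluid A [fluid_properties()].
#' @return tau_max in Pa.
#' @export
max_shear_stress <- function(epsilon, fluid) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (!is.numeric(epsilon) || any(!is.finite(epsilon)) || any(epsilon < 0)) {
    stop("epsilon must be finite and non-negative", call. = FALSE)
  }
  5.33 * fluid$density * sqrt(epsilon * fluid$kinematic_viscosity)
}

#' Integrated shear factor
#'
#' ISF = 2 pi N d / (D - d) (1/s): an averaged shear measure in the gap
#' between the impeller tip and the vessel wall, used to gauge shear damage
#' to mammalian cells.
#'
#' @inheritParams reynolds_number
#' @return ISF in 1/s.
#' @export
integrated_shear_factor <- function(geometry, agitation) {
  stopifnot(inherits(geometry, "vessel_geometry"),
            inherits(agitation, "agitation_condition"))
  D <- geometry$vessel_diameter
  d <- geometry$impeller_diameter
  if (D <= d) stop("vessel diameter must exceed impeller diameter", call. = FALSE)
  2 * pi * agitation$speed_rps * d / (D - d)
}

#' Kolmogorov eddy length scale
#'
#' lambda_K = (nu^3 / epsilon)^(1/4) (m): the size of the smallest turbulent
#' eddies. Cells much smaller than lambda_K follow the local flow and are
#' largely shielded from eddy-scale stresses.
#'
#' @param epsilon Specific energy dissipation rate in W/kg (> 0).
#' @param fluid A [fluid_properties()].
#' @return lambda_K in m.
#' @export
kolmogorov_length <- function(epsilon, fluid) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (!is.numeric(epsilon) || any(!is.finite(epsilon)) || any(epsilon <= 0)) {
    stop("epsilon must be finite and positive", call. = FALSE)
  }
  (fluid$kinematic_viscosity^3 / epsilon)^0.25
}

#' Compare shear stress against a proliferation threshold
#'
#' Strict comparison of the maximum shear stress against a cell-type-specific
#' threshold; the default 0.092 Pa is the reported threshold above which
#' hematopoietic stem cell proliferation and function are impaired.
#'
#' @param tau_max Maximum shear stress in Pa (>= 0).
#' @param threshold Threshold shear stress in Pa (>= 0); default 0.092.
#' @return A list with `exceeds` (logical, `tau_max > threshold` strictly)
#'   and `margin` (`tau_max - threshold`, Pa).
#' @export
shear_threshold_check <- function(tau_max, threshold = 0.092) {
  if (!is.numeric(tau_max) || !is.numeric(threshold) ||
      any(!is.finite(c(tau_max, threshold))) || any(c(tau_max, threshold) < 0)) {
    stop("tau_max and threshold must be finite and non-negative", call. = FALSE)
  }
  list(exceeds = tau_max > threshold, margin = tau_max - threshold)
}

#' Full hydrodynamic characterisation of an agitation condition
#'
#' Chains [reynolds_number()], [nagata_power_number()], [impeller_power()],
#' [energy_dissipation()], [max_shear_stress()], [integrated_shear_factor()],
#' [kolmogorov_length()] and [shear_threshold_check()] into one report.
#' The volumetric oxygen transfer coefficient K_l a is never computed: if the
#' user measured it, the value is copied verbatim into the report.
#'
#' @inheritParams reynolds_number
#' @param kla Optional measured K_l a in 1/h (pass-through only).
#' @param threshold Shear-stress threshold in Pa; default 0.092.
#' @return An object of class `hydrodynamic_report`: a list with fields
#'   `speed_rpm`, `reynolds`, `power_number`, `power`, `epsilon`, `tau_max`,
#'   `isf`, `kolmogorov_length`, `kla` (or `NA`), `threshold`,
#'   `shear_exceeds_threshold` and `shear_margin`.
#' @examples
#' geom <- vessel_geometry(0.065, 0.0325, 0.0039, 0.0299, 1e-4)
#' rep50 <- hydrodynamic_report(geom, fluid_properties(), agitation_condition(50))
#' rep50$tau_max  # about 0.068 Pa
#' @export
hydrodynamic_report <- function(geometry, fluid, agitation, kla = NULL,
                                threshold = 0.092) {
  re <- reynolds_number(geometry, fluid, agitation)
  if (re > 0) {
    np <- nagata_power_number(geometry, re)
  } else {
    np <- NA_real_
  }
  p <- impeller_power(if (is.na(np)) 0 else np, agitation, geometry, fluid)
  eps <- energy_dissipation(p, geometry, fluid)
  tau <- max_shear_stress(eps, fluid)
  isf <- integrated_shear_factor(geometry, agitation)
  lk <- if (eps > 0) kolmogorov_length(eps, fluid) else Inf
  chk <- shear_threshold_check(tau, threshold)
  structure(
    list(speed_rpm = agitation$speed_rpm,
         reynolds = re,
         power_number = np,
         power = p,
         epsilon = eps,
         tau_max = tau,
         isf = isf,
         kolmogorov_length = lk,
         kla = if (is.null(kla)) NA_real_ else kla,
         threshold = threshold,
         shear_exceeds_threshold = chk$exceeds,
         shear_margin = chk$margin),
    class = "hydrodynamic_report")
}

#' @export
print.hydrodynamic_report <- function(x, ...) {
  cat(sprintf("Hydrodynamic report at %g rpm\n", x$speed_rpm))
  cat(sprintf("  Reynolds number            %10.2f\n", x$reynolds))
  cat(sprintf("  Power number N_p           %10.3f\n", x$power_number))
  cat(sprintf("  Power draw P (W)           %10.3e\n", x$power))
  cat(sprintf("  Energy dissipation (W/kg)  %10.3e\n", x$epsilon))
  cat(sprintf("  Max shear stress (Pa)      %10.4f\n", x$tau_max))
  cat(sprintf("  Integrated shear (1/s)     %10.3f\n", x$isf))
  cat(sprintf("  Kolmogorov length (um)     %10.1f\n",
              x$kolmogorov_length * 1e6))
  if (!is.na(x$kla)) cat(sprintf("  K_l a (1/h, measured)      %10.2f\n", x$kla))
  cat(sprintf("  Exceeds %.3f Pa threshold: %s (margin %+0.3f Pa)\n",
              x$threshold, x$shear_exceeds_threshold, x$shear_margin))
  invisible(x)
}
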