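#' Read a bioreactor configuration file
#'
#' Parses a flat key/value YAML document describing the vessel, fluid and
#' agitation. Recognised keys: `vessel_diameter_m`, `impeller_diameter_m`,
#' `blade_height_m`, `liquid_height_m`, `working_volume_m3`, `density_kg_m3`,
#' `kinematic_viscosity_m2_s`, `rpm` (scalar or list), and optional
#' `kla_per_h` (scalar or list parallel to `rpm`) and `shear_threshold_pa`.
#'
#' @param path Path to the YAML config file.
#' @return A list with `geometry` ([vessel_geometry()]), `fluid`
#'   ([fluid_properties()]), `rpm` (numeric vector), `kla` (numeric vector or
#'   `NULL`) and `threshold` (Pa).
#' @export
read_bioreactor_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("vessel_diameter_m", "impeller_diameter_m", "blade_height_m",
            "liquid_height_m", "working_volume_m3", "rpm")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("config is missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  geometry <- vessel_geometry(cfg$vessel_diameter_m, cfg$impeller_diameter_m,
                              cfg$blade_height_m, cfg$liquid_height_m,
                              cfg$working_volume_m3)
  fluid <- fluid_properties(
    density = if (is.null(cfg$density_kg_m3)) 1000 else cfg$density_kg_m3,
    kinematic_viscosity = if (is.null(cfg$kinematic_viscosity_m2_s)) 1e-6
                          else cfg$kinematic_viscosity_m2_s)
  kla <- if (is.null(cfg$kla_per_h)) NULL else as.numeric(unlist(cfg$kla_per_h))
  rpm <- as.numeric(unlist(cfg$rpm))
  if (!is.null(kla) && length(kla) != length(rpm)) {
    stop("kla_per_h must have one value per rpm", call. = FALSE)
  }
  list(geometry = geometry, fluid = fluid, rpm = rpm, kla = kla,
       threshold = if (is.null(cfg$shear_threshold_pa)) 0.092
                   else cfg$shear_threshold_pa)
}

#' Read a culture time series from CSV
#'
#' Expected columns: `time_h`, `viable_density_cells_per_ml`, and optionally
#' `glucose_g_per_l` and `lactate_g_per_l` (empty cells allowed for
#' unmeasured points). An optional companion exchange-schedule CSV has
#' columns `time_h`, `fraction`, `fresh_glucose_g_per_l`,
#' `fresh_lactate_g_per_l`.
#'
#' @param path Culture CSV path.
#' @param exchange_path Optional exchange-schedule CSV path.
#' @return A [culture_time_series()].
#' @export
read_culture_csv <- function(path, exchange_path = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_h", "viable_density_cells_per_ml") %in% names(df))) {
    stop("culture CSV needs columns time_h and viable_density_cells_per_ml",
         call. = FALSE)
  }
  ev <- NULL
  if (!is.null(exchange_path)) {
    ex <- utils::read.csv(exchange_path)
    ev <- data.frame(time_h = ex$time_h, fraction = ex$fraction)
    if (!is.null(ex$fresh_glucose_g_per_l)) ev$fresh_glucose <- ex$fresh_glucose_g_per_l
    if (!is.null(ex$fresh_lactate_g_per_l)) ev$fresh_lactate <- ex$fresh_lactate_g_per_l
  }
  culture_time_series(df$time_h, df$viable_density_cells_per_ml,
                      glucose = df$glucose_g_per_l,
                      lactate = df$lactate_g_per_l,
                      exchange_events = ev)
}

#' Write a culture time series to CSV
#'
#' Inverse of [read_culture_csv()]; writes full-precision values.
#'
#' @param series A [culture_time_series()].
#' @param path Output CSV path.
#' @param exchange_path Optional path for the exchange-schedule CSV.
#' @return `path`, invisibly.
#' @export
write_culture_csv <- function(series, path, exchange_path = NULL) {
  df <- data.frame(time_h = series$times,
                   viable_density_cells_per_ml = series$viable_density)
  if (!is.null(series$metabolites$glucose)) {
    df$glucose_g_per_l <- series$metabolites$glucose
  }
  if (!is.null(series$metabolites$lactate)) {
    df$lactate_g_per_l <- series$metabolites$lactate
  }
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(exchange_path) && !is.null(series$exchange_events)) {
    ev <- series$exchange_events
    out <- data.frame(time_h = ev$time_h, fraction = ev$fraction)
    if (!is.null(ev$fresh_glucose)) out$fresh_glucose_g_per_l <- ev$fresh_glucose
    if (!is.null(ev$fresh_lactate)) out$fresh_lactate_g_per_l <- ev$fresh_lactate
    utils::write.csv(out, exchange_path, row.names = FALSE)
  }
  invisible(path)
}
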