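#' Table-style hydrodynamic report over several agitation rates
#'
#' Builds one [hydrodynamic_report()] per agitation rate and arranges them as
#' a parameter-by-rate table mirroring the usual bioreactor characterisation
#' tables.
#'
#' @param geometry A [vessel_geometry()].
#' @param fluid A [fluid_properties()].
#' @param rpm Numeric vector of agitation rates in rpm.
#' @param kla Optional measured K_l a values (1/h), one per rpm
#'   (pass-through; never computed).
#' @param threshold Shear-stress threshold in Pa (default 0.092).
#' @return A data.frame with a `parameter` column and one column per rpm.
#' @examples
#' geom <- vessel_geometry(0.065, 0.0325, 0.0039, 0.0299, 1e-4)
#' hydro_report_table(geom, fluid_properties(), c(50, 100))
#' @export
hydro_report_table <- function(geometry, fluid, rpm, kla = NULL,
                               threshold = 0.092) {
  reports <- lapply(seq_along(rpm), function(i) {
    hydrodynamic_report(geometry, fluid, agitation_condition(rpm[i]),
                        kla = if (is.null(kla)) NULL else kla[i],
                        threshold = threshold)
  })
  fields <- c(reynolds = "Reynolds number, Re",
              power_number = "Power number, N_p",
              power = "Power draw, P (W)",
              epsilon = "Energy dissipated per unit mass, epsilon (W/kg)",
              tau_max = "Maximum shear stress, tau_max (Pa)",
              isf = "Integrated shear factor, ISF (1/s)",
              kolmogorov_length = "Size of smallest eddy, lambda_K (m)",
              kla = "Volumetric oxygen mass transfer coefficient, K_l a (1/h)",
              shear_exceeds_threshold = "Shear exceeds threshold")
  out <- data.frame(parameter = unname(fields))
  for (i in seq_along(rpm)) {
    out[[paste0("rpm_", rpm[i])]] <-
      vapply(names(fields), function(f) as.numeric(reports[[i]][[f]]),
             numeric(1))
  }
  out
}

#' Growth summary for one culture
#'
#' @param series A [culture_time_series()].
#' @return A list with `mu` (1/h), `initial_density` (cells/ml), `r_squared`,
#'   `final_density` (last observed density) and `fold_expansion`.
#' @export
growth_report <- function(series) {
  fit <- fit_growth(series)
  final <- series$viable_density[length(series$viable_density)]
  list(mu = fit$mu, initial_density = fit$initial_density,
       r_squared = fit$r_squared, final_density = final,
       fold_expansion = fold_expansion(series$viable_density[1], final))
}

#' Run manifest
#'
#' Writes a JSON manifest recording the command, configuration snapshot,
#' seed, package version, timestamp and MD5 digests of the input/output
#' files, so a run can be reproduced exactly.
#'
#' @param path Output JSON path.
#' @param command Command or function name that produced the outputs.
#' @param config Configuration snapshot (any JSON-encodable list).
#' @param seed Integer seed used.
#' @param files Character vector of input/output file paths to digest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config, seed, files = character(0)) {
  files <- files[file.exists(files)]
  manifest <- list(
    command = command,
    config = config,
    seed = seed,
    tool_version = as.character(utils::packageVersion("stircell")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    file_md5 = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# Per-condition defaults for the synthetic three-arm comparison:
# growth rates from the two agitated arms, a nominal static arm in between,
# and the observed round-cell fractions per arm.
pipeline_conditions <- function() {
  data.frame(condition = c("rpm50", "rpm100", "static"),
             rpm = c(50, 100, NA),
             mu = c(0.028, 0.022, 0.026),
             round_fraction = c(0.67, 0.41, 0.60))
}

#' Run the full synthetic analysis pipeline
#'
#' Generates synthetic cultures and micrographs for three culture arms (50
#' rpm, 100 rpm, static T-flask), runs the hydrodynamic, growth, metabolite
#' and morphology analyses, and writes one CSV per report plus a combined
#' comparison table and a JSON run manifest into `out_dir`. Reruns with the
#' same seed produce byte-identical CSVs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving all synthetic data.
#' @param geometry,fluid Vessel and fluid descriptions; defaults are the
#'   100-ml unbaffled paddle vessel and water.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the per-stage results (`hydrodynamics`,
#'   `growth`, `metabolites`, `morphology`, `comparison`).
#' @export
run_full_pipeline <- function(out_dir, seed = 1L,
                              geometry = vessel_geometry(0.065, 0.0325,
                                                         0.0039, 0.0299, 1e-4),
                              fluid = fluid_properties(),
                              quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  say <- function(...) if (!quiet) message(...)
  conds <- pipeline_conditions()
  stage <- "hydrodynamics"
  result <- tryCatch({
    say("stage: hydrodynamics")
    hydro <- hydro_report_table(geometry, fluid,
                                conds$rpm[!is.na(conds$rpm)])
    f <- file.path(out_dir, "hydrodynamics.csv")
    utils::write.csv(hydro, f, row.names = FALSE); written <- c(written, f)

    stage <- "growth/metabolites"
    say("stage: growth and metabolite kinetics")
    growth_rows <- list(); met_rows <- list()
    for (i in seq_len(nrow(conds))) {
      cfg <- simulation_config(seed = seed + 10L * i,
                               true_mu = conds$mu[i],
                               round_fraction_true = conds$round_fraction[i])
      s_met <- simulate_metabolites(cfg)
      f <- file.path(out_dir, paste0("culture_", conds$condition[i], ".csv"))
      write_culture_csv(s_met, f); written <- c(written, f)
      g <- growth_report(s_met)
      growth_rows[[i]] <- data.frame(condition = conds$condition[i],
                                     mu_per_h = g$mu,
                                     initial_density = g$initial_density,
                                     final_density = g$final_density,
                                     fold_expansion = g$fold_expansion,
                                     r_squared = g$r_squared)
      rates <- specific_metabolite_rate(s_met, "glucose")
      met_rows[[i]] <- data.frame(
        condition = conds$condition[i],
        q_glucose = rates$q, direction = rates$direction,
        r_squared = rates$r_squared,
        lactate_glucose_ratio = lactate_glucose_ratio(s_met))
    }
    growth_tab <- do.call(rbind, growth_rows)
    met_tab <- do.call(rbind, met_rows)
    f <- file.path(out_dir, "growth_summary.csv")
    utils::write.csv(growth_tab, f, row.names = FALSE); written <- c(written, f)
    f <- file.path(out_dir, "metabolite_summary.csv")
    utils::write.csv(met_tab, f, row.names = FALSE); written <- c(written, f)

    stage <- "morphology"
    say("stage: morphology")
    morph_rows <- list()
    for (i in seq_len(nrow(conds))) {
      cfg <- simulation_config(seed = seed + 10L * i,
                               true_mu = conds$mu[i],
                               round_fraction_true = conds$round_fraction[i])
      im <- render_cell_image(cfg)
      regions <- segment_cells(im$image)
      summ <- round_fraction(regions)
      f <- file.path(out_dir, paste0("cells_", conds$condition[i], ".csv"))
      utils::write.csv(regions, f, row.names = FALSE); written <- c(written, f)
      morph_rows[[i]] <- data.frame(condition = conds$condition[i],
                                    n_cells = summ$n_cells, f_r = summ$f_r,
                                    true_fraction = conds$round_fraction[i])
    }
    morph_tab <- do.call(rbind, morph_rows)
    f <- file.path(out_dir, "morphology_summary.csv")
    utils::write.csv(morph_tab, f, row.names = FALSE); written <- c(written, f)

    stage <- "report assembly"
    comparison <- merge(merge(growth_tab[, c("condition", "mu_per_h",
                                             "fold_expansion")],
                              met_tab[, c("condition", "q_glucose",
                                          "lactate_glucose_ratio")]),
                        morph_tab[, c("condition", "f_r")])
    f <- file.path(out_dir, "comparison.csv")
    utils::write.csv(comparison, f, row.names = FALSE); written <- c(written, f)
    list(hydrodynamics = hydro, growth = growth_tab, metabolites = met_tab,
         morphology = morph_tab, comparison = comparison)
  }, error = function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  write_manifest(file.path(out_dir, "manifest.json"), "run_full_pipeline",
                 list(conditions = conds,
                      geometry = unclass(geometry),
                      fluid = unclass(fluid)),
                 seed, written)
  say("done: ", out_dir)
  invisible(result)
}
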