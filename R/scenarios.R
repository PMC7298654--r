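# Scenario presets and structured-file IO.

#' Built-in pumping scenario presets
#'
#' The reference configurations of the single-versus-cascade comparison, all
#' on a 1 m tube of 1.6 mm inner diameter with a 4 cm deformation length:
#'
#' * `single_0.1` - one pump at 0.1 m, anchored so that its maximum in-plane
#'   shear rate at the deepest-occlusion instant is 885 1/s;
#' * `dual_0.1_0.5` - pumps at 0.1 m and 0.5 m, linked to the single
#'   scenario by equal total displaced-volume actuation (split equally);
#' * `sweep_0.2`, `sweep_0.3`, `sweep_0.4`, `sweep_0.5` - first pump fixed
#'   at 0.1 m, secondary pump at the named position, same equal-actuation
#'   linkage.
#'
#' Presets carry their calibration directive; apply it with
#' [realize_scenario()].
#'
#' @param wave_speed_m_s Roller speed shared by all presets.
#' @return Named list of `scenario_preset` objects.
#' @export
cascade_presets <- function(wave_speed_m_s = 0.025) {
  tube <- tube_spec()
  mk <- function(centers) cascade_config(tube, lapply(centers, function(xc)
    pump_unit(xc, wave_speed_m_s = wave_speed_m_s)))
  preset <- function(name, centers, calibration)
    structure(list(name = name, config = mk(centers),
                   fluid = newtonian_fluid(), calibration = calibration),
              class = "scenario_preset")
  anchor <- list(kind = "shear_anchor", value = 885)
  link <- list(kind = "equal_actuation", reference = "single_0.1")
  out <- list(
    single_0.1   = preset("single_0.1", 0.1, anchor),
    dual_0.1_0.5 = preset("dual_0.1_0.5", c(0.1, 0.5), link),
    sweep_0.2    = preset("sweep_0.2", c(0.1, 0.2), link),
    sweep_0.3    = preset("sweep_0.3", c(0.1, 0.3), link),
    sweep_0.4    = preset("sweep_0.4", c(0.1, 0.4), link),
    sweep_0.5    = preset("sweep_0.5", c(0.1, 0.5), link))
  out
}

#' Apply a preset's calibration directive
#'
#' Resolves a preset into a ready-to-run configuration: a shear anchor is
#' applied by bisecting the occlusion until the maximum in-plane shear rate
#' matches the anchor; an equal-actuation link first realizes (or reuses)
#' the reference scenario, measures its total cycle-averaged
#' displaced-volume rate, and calibrates the preset's pumps to the same
#' total (split equally over the units).
#'
#' @param preset A `scenario_preset` or the name of one in `presets`.
#' @param presets Preset list (default [cascade_presets()]), used to resolve
#'   references.
#' @param reference_actuation Optional precomputed total actuation of the
#'   reference scenario (m^3/s), to avoid recalibrating it.
#' @param fluid Fluid model used during calibration.
#' @param ... Passed to [calibrate_occlusion()].
#' @return A calibrated [cascade_config()] (with the `calibration`
#'   attribute).
#' @export
realize_scenario <- function(preset, presets = cascade_presets(),
                             reference_actuation = NULL,
                             fluid = newtonian_fluid(), ...) {
  if (is.character(preset)) {
    if (!preset %in% names(presets))
      stop("unknown preset `", preset, "`", call. = FALSE)
    preset <- presets[[preset]]
  }
  stopifnot(inherits(preset, "scenario_preset"))
  cal <- preset$calibration
  if (cal$kind == "shear_anchor") {
    return(calibrate_occlusion(preset$config, "peak_inplane_shear",
                               cal$value, fluid = fluid, ...))
  }
  if (cal$kind == "equal_actuation") {
    if (is.null(reference_actuation)) {
      ref_cfg <- realize_scenario(cal$reference, presets, fluid = fluid, ...)
      ref_sol <- solve_flow(ref_cfg, fluid, periods = 1, discard = 3)
      reference_actuation <- total_actuation(ref_sol)
    }
    return(calibrate_occlusion(preset$config, "total_actuation",
                               reference_actuation, fluid = fluid, ...))
  }
  stop("unknown calibration directive `", cal$kind, "`", call. = FALSE)
}

# ---- structured scenario files -------------------------------------------

known_keys <- list(
  top = c("tube", "pumps", "fluid", "solver", "waveform", "wavelength_m"),
  tube = c("length_m", "inner_diameter_m", "n_axial"),
  pump = c("center_m", "deformation_length_m", "occlusion", "wave_speed_m_s",
           "phase", "n_rollers", "capacity_pa"),
  fluid = c("model", "viscosity_pa_s", "density_kg_m3", "consistency",
            "index", "floor_shear_s", "plateau_mult", "onset_s", "rise_s"),
  solver = c("periods", "discard", "steps_per_period"))

reject_unknown <- function(block, allowed, where) {
  bad <- setdiff(names(block), allowed)
  if (length(bad) > 0)
    stop("unknown key(s) in ", where, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
}

fluid_from_spec <- function(fl) {
  if (is.null(fl)) return(newtonian_fluid())
  reject_unknown(fl, known_keys$fluid, "fluid block")
  model <- if (is.null(fl$model)) "newtonian" else fl$model
  pick <- function(key, default) if (is.null(fl[[key]])) default else fl[[key]]
  switch(model,
    newtonian = newtonian_fluid(pick("viscosity_pa_s", 1.0),
                                pick("density_kg_m3", 1000)),
    power_law = power_law_fluid(pick("consistency", 1.0), pick("index", 0.5),
                                pick("density_kg_m3", 1000),
                                pick("floor_shear_s", 1e-3)),
    gelling = gelling_fluid(
      power_law_fluid(pick("consistency", 1.0), pick("index", 1.0),
                      pick("density_kg_m3", 1000), pick("floor_shear_s", 1e-3)),
      pick("plateau_mult", 100), pick("onset_s", 600), pick("rise_s", 120)),
    stop("unknown fluid model `", model, "`", call. = FALSE))
}

#' Load a scenario configuration file
#'
#' Reads a YAML scenario file with blocks `tube`, `pumps`, `fluid` and
#' `solver` (SI units, unit-suffixed keys). Missing blocks receive the
#' defaults (1 m tube, 1.6 mm inner diameter, Newtonian fluid); unknown keys
#' are rejected by name.
#'
#' @param path Path to the YAML file.
#' @return List with elements `config` ([cascade_config()]), `fluid` and
#'   `solver` (list of solver settings).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  reject_unknown(raw, known_keys$top, "scenario file")
  tb <- raw$tube
  if (!is.null(tb)) reject_unknown(tb, known_keys$tube, "tube block")
  pick <- function(block, key, default)
    if (is.null(block[[key]])) default else block[[key]]
  tube <- tube_spec(pick(tb, "length_m", 1.0),
                    pick(tb, "inner_diameter_m", 1.6e-3) / 2,
                    pick(tb, "n_axial", 801L))
  pumps <- lapply(raw$pumps, function(pb) {
    reject_unknown(pb, known_keys$pump, "pump block")
    if (is.null(pb$center_m))
      stop("pump block lacks `center_m`", call. = FALSE)
    pump_unit(pb$center_m,
              pick(pb, "deformation_length_m", 0.04),
              pick(pb, "occlusion", 0.5),
              pick(pb, "wave_speed_m_s", 0.025),
              pick(pb, "phase", 0),
              pick(pb, "n_rollers", 2L),
              pb$capacity_pa)
  })
  sv <- raw$solver
  if (!is.null(sv)) reject_unknown(sv, known_keys$solver, "solver block")
  config <- cascade_config(tube, pumps,
                           waveform = pick(raw, "waveform", "bump"),
                           wavelength_m = raw$wavelength_m)
  list(config = config,
       fluid = fluid_from_spec(raw$fluid),
       solver = list(periods = pick(sv, "periods", 2L),
                     discard = pick(sv, "discard", 3L),
                     steps_per_period = pick(sv, "steps_per_period", 64L)))
}

#' Write a scenario configuration file
#'
#' Serializes a configuration (and optionally fluid/solver settings) to the
#' YAML schema read by [load_config()]. `load_config(write_config(x))`
#' round-trips.
#'
#' @param config A [cascade_config()].
#' @param path Output path.
#' @param fluid Optional fluid model.
#' @param solver Optional solver settings list.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path, fluid = NULL, solver = NULL) {
  out <- list(tube = list(length_m = config$tube$length_m,
                          inner_diameter_m = 2 * config$tube$inner_radius_m,
                          n_axial = config$tube$n_axial),
              pumps = lapply(config$pumps, function(p) {
                b <- list(center_m = p$center_m,
                          deformation_length_m = p$deformation_length_m,
                          occlusion = p$occlusion,
                          wave_speed_m_s = p$wave_speed_m_s,
                          phase = p$phase, n_rollers = p$n_rollers)
                if (!is.null(p$capacity_pa)) b$capacity_pa <- p$capacity_pa
                b
              }),
              waveform = config$waveform)
  if (!is.null(config$wavelength_m)) out$wavelength_m <- config$wavelength_m
  if (!is.null(fluid)) {
    out$fluid <- if (inherits(fluid, "newtonian_fluid"))
      list(model = "newtonian", viscosity_pa_s = fluid$viscosity_pa_s,
           density_kg_m3 = fluid$density_kg_m3)
    else if (inherits(fluid, "power_law_fluid"))
      list(model = "power_law", consistency = fluid$consistency,
           index = fluid$index, density_kg_m3 = fluid$density_kg_m3,
           floor_shear_s = fluid$floor_shear_s)
    else
      list(model = "gelling", consistency = fluid$base$consistency,
           index = fluid$base$index,
           density_kg_m3 = fluid$base$density_kg_m3,
           floor_shear_s = fluid$base$floor_shear_s,
           plateau_mult = fluid$plateau_mult, onset_s = fluid$onset_s,
           rise_s = fluid$rise_s)
  }
  if (!is.null(solver)) out$solver <- solver
  yaml::write_yaml(out, path)
  invisible(path)
}

# ---- report writing -------------------------------------------------------

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Write a machine-readable report directory
#'
#' Writes a deterministic file set for a report object: a JSON summary plus
#' CSV tables (axial profiles, histograms, time series as applicable) and a
#' `manifest.csv` with MD5 checksums of every written file. Numbers are
#' serialized at full precision; identical inputs give byte-identical
#' output.
#'
#' @param report A `shear_report`, `clog_report`, `shear_comparison` or
#'   `flow_solution`.
#' @param out_dir Output directory (created if needed).
#' @return Data frame manifest (file, md5), invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  jout <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    p
  }
  if (inherits(report, "shear_report")) {
    summ <- list(
      convention = report$convention,
      bin_width = report$bin_width,
      weighting = "area",
      deepest_instant_s = report$t_deep,
      max_pressure_pa = report$p_max,
      net_flow_m3_s = report$Q_net,
      calibration = report$calibration,
      pumps = lapply(report$pumps, function(p) list(
        center_m = p$center_m, occlusion = p$occlusion,
        xy_max = lapply(p$xy, function(m) m$value),
        yz_max = lapply(p$yz, function(m) m$value))))
    files <- c(files, jout(summ, "shear_summary.json"))
    files <- c(files, write_csv_plain(
      data.frame(x_m = report$profiles$x,
                 p_mean_pa = report$profiles$p_mean,
                 p_peak_pa = report$profiles$p_peak),
      file.path(out_dir, "pressure_profile.csv")))
    files <- c(files, write_csv_plain(
      data.frame(x_m = report$profiles$x,
                 Q_mean_m3_s = report$profiles$Q_mean,
                 Q_peak_m3_s = report$profiles$Q_peak),
      file.path(out_dir, "flow_profile.csv")))
    for (i in seq_along(report$pumps)) {
      h <- report$pumps[[i]]$hist_xy
      files <- c(files, write_csv_plain(
        data.frame(bin_lo_s = h$breaks[-length(h$breaks)],
                   bin_hi_s = h$breaks[-1], frequency = h$frequency),
        file.path(out_dir, sprintf("histogram_xy_pump%d.csv", i))))
      h <- report$pumps[[i]]$hist_yz
      files <- c(files, write_csv_plain(
        data.frame(bin_lo_s = h$breaks[-length(h$breaks)],
                   bin_hi_s = h$breaks[-1], frequency = h$frequency),
        file.path(out_dir, sprintf("histogram_yz_pump%d.csv", i))))
    }
  } else if (inherits(report, "clog_report")) {
    summ <- list(clog_time_s = report$clog_time_s,
                 initial_Q_m3_s = report$Q_init,
                 q_set_m3_s = report$q_set,
                 sustained_fraction = report$sustained_fraction,
                 capacities_pa = report$capacities_pa,
                 load_fraction = report$load_fraction)
    files <- c(files, jout(summ, "clog_report.json"))
    ts <- data.frame(time_s = report$time_s, Q_m3_s = report$Q_m3_s)
    for (i in seq_len(ncol(report$demand_pa)))
      ts[[sprintf("demand_pa_seg%d", i)]] <- report$demand_pa[, i]
    files <- c(files, write_csv_plain(
      ts, file.path(out_dir, "flow_timeseries.csv")))
  } else if (inherits(report, "shear_comparison")) {
    files <- c(files, jout(report$table, "comparison.json"))
    files <- c(files, write_csv_plain(
      report$table, file.path(out_dir, "comparison.csv")))
  } else if (inherits(report, "flow_solution")) {
    cy <- cycle_average(report)
    files <- c(files, write_csv_plain(
      data.frame(x_m = cy$x, p_mean_pa = cy$p_mean, p_peak_pa = cy$p_peak),
      file.path(out_dir, "pressure_profile.csv")))
    files <- c(files, write_csv_plain(
      data.frame(x_m = cy$x, Q_mean_m3_s = cy$Q_mean, Q_peak_m3_s = cy$Q_peak),
      file.path(out_dir, "flow_profile.csv")))
  } else stop("unsupported report type", call. = FALSE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  write_csv_plain(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}
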