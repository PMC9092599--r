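# Configuration files and run outputs.
#
# Config files are nested key-value YAML documents. Inputs are accepted in
# bench units (ml/min, cP, um, cells/ml, Pa); everything is converted to SI
# on load and all internal computation is SI.

.CONFIG_KEYS <- list(
  top = c("network", "fluid", "cell", "flow", "deposition",
          "concentration_per_ml", "total_volume_ml", "stop_fraction",
          "dt_s", "gravity", "seed", "facets"),
  network = c("source", "path", "generations", "root_diameter_um",
              "diameter_rule", "ratio", "length_to_diameter_ratio",
              "branch_angle_deg", "tortuosity_amplitude_um",
              "n_centerline_points", "tree_seed", "alpha_cm2",
              "wall_thickness_um", "p_par_Pa"),
  fluid = c("media_density_kg_m3", "media_viscosity_cP",
            "buffer_density_kg_m3", "buffer_viscosity_cP"),
  cell = c("diameter_um", "density_kg_m3"),
  flow = c("inlet_ml_min", "outlet_Pa", "parenchyma_Pa"),
  deposition = c("model", "C", "r0_um", "m_r_per_m2", "ml_Ka0", "lambda_m",
                 "kBT_J", "delta_eq_m", "F_S", "T_S", "drag_law"),
  facets = c("axial_bin_length_um", "n_azimuthal"))

#' Load and validate a simulation configuration
#'
#' Reads a nested key-value (YAML) document, validates it, fills defaults,
#' converts bench units (ml/min, cP, um, cells/ml) to SI and returns a ready
#' [seeding_config()]. All violations are collected and reported in a single
#' error. The receptor-ligand model requires an explicit `deposition.r0_um`:
#' the interaction-surface radius has no published source value, so the
#' config format refuses to guess it silently.
#'
#' @param path path to the config file.
#' @return A [seeding_config()]; the filled-in config is also echoed as the
#'   `echo` attribute (a plain list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  unknown <- setdiff(names(raw), .CONFIG_KEYS$top)
  if (length(unknown)) note(paste0("unknown top-level key(s): ",
                                   paste(unknown, collapse = ", ")))
  for (blk in c("network", "fluid", "cell", "flow", "deposition", "facets")) {
    if (!is.null(raw[[blk]])) {
      u <- setdiff(names(raw[[blk]]), .CONFIG_KEYS[[blk]])
      if (length(u)) note(paste0("unknown key(s) in '", blk, "': ",
                                 paste(u, collapse = ", ")))
    }
  }

  get_or <- function(blk, key, default) {
    v <- raw[[blk]][[key]]
    if (is.null(v)) default else v
  }

  ## flow block (required)
  if (is.null(raw$flow) || is.null(raw$flow$inlet_ml_min))
    note("missing required key: flow.inlet_ml_min")
  if (is.null(raw$flow) || is.null(raw$flow$outlet_Pa))
    note("missing required key: flow.outlet_Pa")
  inlet_ml_min <- get_or("flow", "inlet_ml_min", NA_real_)
  if (!is.na(inlet_ml_min) && inlet_ml_min <= 0)
    note("flow.inlet_ml_min must be > 0")

  ## deposition block
  model <- get_or("deposition", "model", "stokes")
  if (!model %in% c("contact", "stokes", "decuzzi"))
    note("deposition.model must be one of contact, stokes, decuzzi")
  C <- get_or("deposition", "C", 300)
  if (C <= 0) note("deposition.C must be > 0")
  if (identical(model, "decuzzi") && is.null(raw$deposition$r0_um))
    note("missing required key: deposition.r0_um (interaction radius has no published default)")

  ## cell / fluid
  d_cell_um <- get_or("cell", "diameter_um", 15)
  rho_cell <- get_or("cell", "density_kg_m3", 1050)
  if (d_cell_um <= 0) note("cell.diameter_um must be > 0")
  if (rho_cell <= 0) note("cell.density_kg_m3 must be > 0")
  mu_cP <- get_or("fluid", "media_viscosity_cP", 0.94)
  rho_media <- get_or("fluid", "media_density_kg_m3", 1000)
  mu_b_cP <- get_or("fluid", "buffer_viscosity_cP", 1.02)
  rho_b <- get_or("fluid", "buffer_density_kg_m3", 1005)
  if (mu_cP <= 0 || rho_media <= 0) note("media properties must be positive")

  conc_ml <- if (is.null(raw$concentration_per_ml)) 250000
             else raw$concentration_per_ml
  if (conc_ml < 0) note("concentration_per_ml must be >= 0")
  total_ml <- if (is.null(raw$total_volume_ml)) 20 else raw$total_volume_ml
  if (total_ml <= 0) note("total_volume_ml must be > 0")
  stop_frac <- if (is.null(raw$stop_fraction)) 0.01 else raw$stop_fraction
  if (stop_frac <= 0 || stop_frac > 1) note("stop_fraction must be in (0, 1]")
  dt <- raw$dt_s
  if (!is.null(dt) && dt <= 0) note("dt_s must be > 0")
  gravity <- if (is.null(raw$gravity)) c(0, 0, -9.81) else as.numeric(raw$gravity)
  if (length(gravity) != 3) note("gravity must be a 3-vector (m/s^2)")
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)

  ## network block
  src <- get_or("network", "source", "reference")
  if (!src %in% c("reference", "file", "tree"))
    note("network.source must be one of reference, file, tree")
  if (identical(src, "file") && is.null(raw$network$path))
    note("missing required key: network.path (network.source = file)")

  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)

  network <- switch(src,
    reference = reference_network(),
    file = read_network(raw$network$path),
    tree = generate_tree(
      generations = get_or("network", "generations", 4),
      root_diameter = get_or("network", "root_diameter_um", 300) * 1e-6,
      diameter_rule = get_or("network", "diameter_rule", "murray"),
      ratio = get_or("network", "ratio", 0.75),
      length_to_diameter_ratio = get_or("network",
                                        "length_to_diameter_ratio", 6),
      branch_angle = get_or("network", "branch_angle_deg", 35),
      tortuosity_amplitude = get_or("network", "tortuosity_amplitude_um",
                                    0) * 1e-6,
      n_centerline_points = get_or("network", "n_centerline_points", 2),
      seed = get_or("network", "tree_seed", 1),
      alpha = get_or("network", "alpha_cm2", 0) * 1e-4,
      wall_thickness = get_or("network", "wall_thickness_um", 50) * 1e-6,
      p_par = get_or("network", "p_par_Pa", 0)))

  dep <- if (identical(model, "decuzzi")) {
    deposition_model("decuzzi", params = decuzzi_params(
      m_r = get_or("deposition", "m_r_per_m2", 1e14),
      ml_Ka0 = get_or("deposition", "ml_Ka0", 4.15e-2),
      lambda = get_or("deposition", "lambda_m", 1e-10),
      kBT = get_or("deposition", "kBT_J", 4.14e-21),
      delta_eq = get_or("deposition", "delta_eq_m", 5e-9),
      F_S = get_or("deposition", "F_S", 1.668),
      T_S = get_or("deposition", "T_S", 0.944),
      r0 = raw$deposition$r0_um * 1e-6))
  } else deposition_model(model, C = C)

  cfg <- seeding_config(
    network = network,
    bc = boundary_conditions(inlet_ml_min * 1e-6 / 60,
                             raw$flow$outlet_Pa,
                             get_or("flow", "parenchyma_Pa", NA_real_)),
    model = dep,
    fluid = fluid_properties(rho_media, mu_cP * 1e-3, "media"),
    buffer = fluid_properties(rho_b, mu_b_cP * 1e-3, "buffer"),
    phenotype = cell_phenotype(d_cell_um * 1e-6, rho_cell),
    concentration = conc_ml * 1e6,
    total_volume = total_ml * 1e-6,
    stop_fraction = stop_frac,
    dt = dt, gravity = gravity, seed = seed,
    facet_axial_bin = get_or("facets", "axial_bin_length_um", 200) * 1e-6,
    facet_azimuthal_bins = get_or("facets", "n_azimuthal", 8),
    drag_law = get_or("deposition", "drag_law", "schiller_naumann"))
  attr(cfg, "echo") <- raw
  cfg
}

#' Write run outputs
#'
#' `write_run_summary()` writes a JSON summary (counts, efficiency, CoV,
#' saturation time, outlet flow fraction, seed); `write_events_csv()` writes
#' the deposition event log; `write_facet_counts_csv()` the per-facet
#' deposition table; `write_manifest()` a reproducibility manifest (config
#' file hash, seed, package version, timestamp, output paths).
#'
#' @param result a `simulation_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @rdname run-outputs
#' @export
write_run_summary <- function(result, path) {
  s <- list(model = result$config$model$model,
            seed = result$config$seed,
            counts = result$counts,
            final_efficiency_pct = result$final_efficiency,
            cov = result$cov,
            saturation_time_s = result$saturation_time,
            outlet_flow_fraction = result$flow$outlet_fraction,
            inlet_flow_ml_min = result$config$bc$inlet_flow * 6e7,
            stop_fraction = result$config$stop_fraction)
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname run-outputs
#' @export
write_events_csv <- function(result, path) {
  utils::write.csv(result$events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname run-outputs
#' @export
write_facet_counts_csv <- function(result, path) {
  utils::write.csv(result$facets, path, row.names = FALSE)
  invisible(path)
}

#' @rdname run-outputs
#' @param config_path path of the config file the run was loaded from
#'   (hashed into the manifest), or `NA`.
#' @param outputs character vector of output file paths the run produced.
#' @export
write_manifest <- function(config_path, outputs, path,
                           seed = NA_integer_) {
  m <- list(package = "vasoseed",
            version = as.character(utils::packageVersion("vasoseed")),
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
            config_file = if (is.na(config_path)) NULL else config_path,
            config_md5 = if (is.na(config_path)) NULL else
              unname(tools::md5sum(config_path)),
            seed = seed,
            outputs = as.list(outputs))
  jsonlite::write_json(m, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname run-outputs
#' @param sweep data.frame from [sweep_flow_rates()].
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(sweep, path, row.names = FALSE)
  invisible(path)
}
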