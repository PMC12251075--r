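#' Read an experiment configuration from JSON
#'
#' Schema (all blocks optional except `pumps`; omitted blocks fall back to
#' the package defaults):
#' \preformatted{
#' {
#'   "pumps": [{"role": "saline",
#'              "segments": [{"t_start_s": 0, "t_end_s": 3600, "rate_ml_h": 1.5}]},
#'             ...],
#'   "line":     {"dead_volume_ml": 1.0, "n_tanks": 5, "transport": "tanks"},
#'   "detector": {"relative_noise_sd": 0.005, "measurement_interval_s": 1,
#'                "rng_seed": 1},
#'   "geometry": {"path_length_mm": 10, "internal_volume_ul": 26},
#'   "dyes": {"EG": {"peak_wavelength": 631, "width": 40,
#'                   "peak_absorptivity": 0.0048, "baseline_absorptivity": 4.8e-5,
#'                   "stock_concentration": 25},
#'            "TZ": {...}}
#' }
#' }
#'
#' @param path Path to a JSON file.
#' @return List with elements `schedule`, `line`, `detector`, `geometry`,
#'   `dyes`, ready for [simulate_line()].
#' @export
read_experiment_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$pumps)) stop("config must define pumps")
  segments <- do.call(rbind, lapply(cfg$pumps, function(p) {
    do.call(rbind, lapply(p$segments, function(s) {
      data.frame(role = p$role, t_start_s = s$t_start_s,
                 t_end_s = s$t_end_s, rate_ml_h = s$rate_ml_h)
    }))
  }))
  schedule <- pump_schedule(segments)

  line <- do.call(line_config, drop_nulls(list(
    dead_volume_ml = cfg$line$dead_volume_ml,
    n_tanks = cfg$line$n_tanks,
    transport = cfg$line$transport,
    fluid_density_g_ml = cfg$line$fluid_density_g_ml
  )))
  detector <- do.call(detector_config, drop_nulls(list(
    relative_noise_sd = cfg$detector$relative_noise_sd,
    measurement_interval_s = cfg$detector$measurement_interval_s,
    rng_seed = cfg$detector$rng_seed
  )))
  geometry <- do.call(flow_cell_geometry, drop_nulls(list(
    path_length_mm = cfg$geometry$path_length_mm,
    internal_volume_ul = cfg$geometry$internal_volume_ul
  )))
  dyes <- if (is.null(cfg$dyes)) {
    default_dyes()
  } else {
    out <- lapply(names(cfg$dyes), function(nm) {
      d <- cfg$dyes[[nm]]
      dye_definition(
        nm,
        make_dye_spectrum(
          nm, d$peak_wavelength, d$width, d$peak_absorptivity,
          baseline_absorptivity = if (is.null(d$baseline_absorptivity)) 0
                                  else d$baseline_absorptivity
        ),
        d$stock_concentration
      )
    })
    stats::setNames(out, names(cfg$dyes))
  }
  list(schedule = schedule, line = line, detector = detector,
       geometry = geometry, dyes = dyes)
}

drop_nulls <- function(x) x[!vapply(x, is.null, logical(1))]
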