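# Printed steady-state fractions use 3 decimals below 0.2 and 2 above,
# matching the validation table's convention (0.167 vs 0.33/0.23/0.54).
table_round <- function(x) {
  vapply(x, function(v) round(v, if (v < 0.2) 3L else 2L), numeric(1))
}

#' Validation experiment presets
#'
#' The three validation experiments, encoded verbatim:
#' \itemize{
#'   \item `exp_a`: constant flows saline/EG/TZ = 1.5/0.5/1 mL/h for 60 min
#'     (baseline steady flow; expected fractions EG 0.167, TZ 0.33).
#'   \item `exp_b`: 7/3/3 mL/h for 15 min, then saline and EG pumps switch
#'     to 3/7/3 until 35 min (EG fraction steps 0.23 to 0.54, TZ stays 0.23).
#'   \item `exp_c`: 7/3/3 mL/h for 15 min, then saline and TZ pumps switch
#'     to 3/3/7 until 35 min (TZ steps 0.23 to 0.54, EG stays 0.23).
#' }
#' The stored expected fractions are checked against `Q_dye / Q_tot`
#' computed from the schedule at load time.
#'
#' @param name One of `"exp_a"`, `"exp_b"`, `"exp_c"`.
#' @return An object of class `experiment_preset`: list with `name`,
#'   `schedule` (a [pump_schedule()]), `duration_s`, `phases` (data.frame
#'   `phase`, `t_start_s`, `t_end_s`), and `expected` (data.frame `phase`,
#'   `solute`, `fraction` holding the printed values).
#' @export
experiment_preset <- function(name = c("exp_a", "exp_b", "exp_c")) {
  name <- match.arg(name)
  seg <- function(role, t0, t1, rate) {
    data.frame(role = role, t_start_s = t0, t_end_s = t1, rate_ml_h = rate)
  }
  if (name == "exp_a") {
    segments <- rbind(
      seg("saline", 0, 3600, 1.5), seg("EG", 0, 3600, 0.5), seg("TZ", 0, 3600, 1)
    )
    phases <- data.frame(phase = 1L, t_start_s = 0, t_end_s = 3600)
    expected <- data.frame(
      phase = c(1L, 1L), solute = c("EG", "TZ"), fraction = c(0.167, 0.33)
    )
  } else {
    rates2 <- if (name == "exp_b") c(saline = 3, EG = 7, TZ = 3)
              else c(saline = 3, EG = 3, TZ = 7)
    segments <- rbind(
      seg("saline", 0, 900, 7), seg("saline", 900, 2100, rates2[["saline"]]),
      seg("EG", 0, 900, 3), seg("EG", 900, 2100, rates2[["EG"]]),
      seg("TZ", 0, 900, 3), seg("TZ", 900, 2100, rates2[["TZ"]])
    )
    phases <- data.frame(phase = c(1L, 2L), t_start_s = c(0, 900),
                         t_end_s = c(900, 2100))
    expected <- data.frame(
      phase = c(1L, 1L, 2L, 2L),
      solute = c("EG", "TZ", "EG", "TZ"),
      fraction = if (name == "exp_b") c(0.23, 0.23, 0.54, 0.23)
                 else c(0.23, 0.23, 0.23, 0.54)
    )
  }
  preset <- structure(
    list(name = name, schedule = pump_schedule(segments),
         duration_s = max(segments$t_end_s), phases = phases,
         expected = expected),
    class = "experiment_preset"
  )
  # self-consistency: printed fractions must equal Q_dye/Q_tot after rounding
  for (i in seq_len(nrow(expected))) {
    comp <- expected_steady_fraction(preset, expected$phase[i],
                                     expected$solute[i], rounded = TRUE)
    if (abs(comp - expected$fraction[i]) > 1e-12) {
      stop("preset ", name, " expected fraction inconsistent with its schedule")
    }
  }
  preset
}

#' @export
print.experiment_preset <- function(x, ...) {
  cat(sprintf("<experiment_preset> %s: %d phase(s), %g s\n",
              x$name, nrow(x$phases), x$duration_s))
  print.data.frame(x$expected)
  invisible(x)
}

#' Expected steady-state normalized concentration
#'
#' At steady state the normalized concentration of a solute equals its flow
#' fraction: \eqn{C/C_0|_{t\to\infty} = Q_{solute} / Q_{tot}} for the
#' phase's pump rates.
#'
#' @param x An `experiment_preset` or `pump_schedule`.
#' @param phase Phase index (1-based, phases in time order).
#' @param solute Pump role of the solute (e.g. `"EG"`).
#' @param rounded If TRUE, apply the display rounding used in the
#'   validation table (3 decimals below 0.2, 2 above).
#' @return Dimensionless fraction.
#' @export
expected_steady_fraction <- function(x, phase, solute, rounded = FALSE) {
  schedule <- if (inherits(x, "experiment_preset")) x$schedule else x
  stopifnot(inherits(schedule, "pump_schedule"))
  br <- schedule_breaks(schedule)
  if (phase < 1 || phase > length(br) - 1) stop("no such phase")
  t_mid <- (br[phase] + br[phase + 1]) / 2
  q <- pump_rates(schedule, t_mid)
  if (sum(q) <= 0) stop("no_flow")
  if (!solute %in% names(q)) stop("unknown solute role '", solute, "'")
  f <- unname(q[solute] / sum(q))
  if (rounded) table_round(f) else f
}

#' Run a validation experiment end-to-end
#'
#' Full pipeline: simulate the infusion line and detector
#' ([simulate_line()]), recover dye concentrations from the dual-wavelength
#' intensities ([recover_concentrations()]), and compute the per-phase
#' steady-state accuracy/repeatability report ([steady_state_stats()]).
#' Deterministic under a fixed `seed`.
#'
#' `fast = TRUE` scales all schedule times and the line dead volume down
#' 10x. This preserves the dimensionless lag V/(Q t) exactly, so the
#' transient shape in normalized time — and every steady-state quantity —
#' is unchanged while the run completes in seconds.
#'
#' @param preset An [experiment_preset()] or its name.
#' @param line,dyes,geometry,detector Component configurations (defaults:
#'   [line_config()], [default_dyes()], [flow_cell_geometry()],
#'   [detector_config()]).
#' @param n_trials Independent trials (default 3, as in the validation
#'   protocol).
#' @param seed Master seed.
#' @param fast Scale times and dead volume down 10x (see Details).
#' @param window_s Steady-state analysis window: the last `window_s`
#'   seconds of each phase (default 300 s = 5 min; scaled in fast mode).
#' @param band_nm Wavelength averaging half-band.
#' @return An object of class `experiment_result`: list with `preset`,
#'   `timeseries` (list of trial data.frames), `concentrations` (list of
#'   data.frames `time_s`, `C_TZ_ug_ml`, `C_EG_ug_ml`, `C_TZ_norm`,
#'   `C_EG_norm`), `report` (data.frame, one row per phase x dye),
#'   `stats` (list of `steady_state_stats`), `cross_matrix`, and the
#'   configurations used.
#' @export
run_experiment <- function(preset, line = line_config(), dyes = default_dyes(),
                           geometry = flow_cell_geometry(),
                           detector = detector_config(),
                           n_trials = 3, seed = 1, fast = FALSE,
                           window_s = 300, band_nm = 1) {
  if (is.character(preset)) preset <- experiment_preset(preset)
  stopifnot(inherits(preset, "experiment_preset"), n_trials >= 2)

  schedule <- preset$schedule
  phases <- preset$phases
  if (fast) {
    s <- as.data.frame(schedule)
    s$t_start_s <- s$t_start_s / 10
    s$t_end_s <- s$t_end_s / 10
    schedule <- pump_schedule(s)
    phases$t_start_s <- phases$t_start_s / 10
    phases$t_end_s <- phases$t_end_s / 10
    line$dead_volume_ml <- line$dead_volume_ml / 10
    window_s <- window_s / 10
  }

  wavelengths <- c(dyes$TZ$spectrum$peak_wavelength,
                   dyes$EG$spectrum$peak_wavelength)
  K <- build_cross_matrix(list(dyes$TZ, dyes$EG), geometry,
                          wavelengths = wavelengths, band_nm = band_nm)

  ts <- simulate_line(schedule, line, dyes, geometry, detector,
                      n_trials = n_trials, seed = seed,
                      wavelengths = wavelengths, band_nm = band_nm)

  conc <- lapply(ts, function(d) {
    I <- cbind(d[[paste0("I", wavelengths[1])]], d[[paste0("I", wavelengths[2])]])
    C <- recover_concentrations(I, K)
    N <- normalize_concentrations(C, K)
    data.frame(time_s = d$time_s,
               C_TZ_ug_ml = C[, "TZ"], C_EG_ug_ml = C[, "EG"],
               C_TZ_norm = N[, "TZ"], C_EG_norm = N[, "EG"])
  })

  report <- NULL
  stats_list <- list()
  for (i in seq_len(nrow(preset$expected))) {
    ph <- preset$expected$phase[i]
    sol <- preset$expected$solute[i]
    frac <- expected_steady_fraction(preset, ph, sol)   # exact, unrounded
    stock <- dyes[[sol]]$stock_concentration
    win <- c(max(phases$t_start_s[ph], phases$t_end_s[ph] - window_s),
             phases$t_end_s[ph])
    col <- paste0("C_", sol, "_ug_ml")
    st <- steady_state_stats(lapply(conc, `[[`, col), conc[[1]]$time_s,
                             window = win, expected = frac * stock)
    stats_list[[paste0(preset$name, "_p", ph, "_", sol)]] <- st
    report <- rbind(report, data.frame(
      experiment = preset$name, phase = ph, solute = sol,
      expected_fraction = frac, expected_ug_ml = frac * stock,
      mean_ug_ml = st$mean, mean_norm = st$mean / stock,
      accuracy_ug_ml = st$accuracy, accuracy_norm = st$accuracy / stock,
      sem_max_ug_ml = st$repeatability,
      window_start_s = win[1], window_end_s = win[2]
    ))
  }
  rownames(report) <- NULL

  structure(
    list(preset = preset, fast = fast, timeseries = ts, concentrations = conc,
         report = report, stats = stats_list, cross_matrix = K,
         line = line, dyes = dyes, geometry = geometry, detector = detector,
         n_trials = n_trials, seed = seed),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s%s: %d trial(s), seed %d\n",
              x$preset$name, if (x$fast) " (fast)" else "", x$n_trials, x$seed))
  print.data.frame(
    x$report[, c("phase", "solute", "expected_ug_ml", "mean_ug_ml",
                 "accuracy_ug_ml", "sem_max_ug_ml")],
    digits = 4
  )
  invisible(x)
}

#' Write experiment outputs to a directory
#'
#' Per-trial raw time-series CSVs (`trial<k>_timeseries.csv`), recovered
#' concentration CSVs (`trial<k>_concentrations.csv`), and the
#' steady-state report (`report.csv` and `report.json`).
#'
#' @param result An `experiment_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment_outputs <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (k in seq_along(result$timeseries)) {
    write_timeseries_csv(result$timeseries[[k]],
                         file.path(dir, sprintf("trial%d_timeseries.csv", k)))
    utils::write.csv(result$concentrations[[k]],
                     file.path(dir, sprintf("trial%d_concentrations.csv", k)),
                     row.names = FALSE)
  }
  utils::write.csv(result$report, file.path(dir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(result$report, file.path(dir, "report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
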