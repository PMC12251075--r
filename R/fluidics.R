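#' Piecewise-constant pump schedule
#'
#' One row per (pump, segment): the pump runs at `rate_ml_h` from
#' `t_start_s` (inclusive) to `t_end_s` (exclusive). Segments of one pump
#' must be contiguous and non-overlapping. Roles identify the saline
#' carrier and the two dye streams.
#'
#' @param segments data.frame with columns `role`, `t_start_s`, `t_end_s`,
#'   `rate_ml_h`. Roles are arbitrary labels; the presets use
#'   `"saline"`, `"EG"`, `"TZ"`.
#' @return A data.frame of class `pump_schedule`.
#' @export
pump_schedule <- function(segments) {
  need <- c("role", "t_start_s", "t_end_s", "rate_ml_h")
  if (!all(need %in% names(segments))) {
    stop("segments must have columns ", paste(need, collapse = ", "))
  }
  if (any(segments$rate_ml_h < 0)) stop("flow rates must be >= 0")
  if (any(segments$t_end_s <= segments$t_start_s)) stop("empty or inverted segment")
  for (r in unique(segments$role)) {
    s <- segments[segments$role == r, ]
    s <- s[order(s$t_start_s), ]
    if (nrow(s) > 1 && any(abs(s$t_end_s[-nrow(s)] - s$t_start_s[-1]) > 1e-9)) {
      stop("segments of pump '", r, "' must be contiguous and non-overlapping")
    }
  }
  out <- segments[order(segments$role, segments$t_start_s), need]
  rownames(out) <- NULL
  class(out) <- c("pump_schedule", "data.frame")
  out
}

#' Pump rates at a time point
#'
#' @param schedule A `pump_schedule`.
#' @param t Time in seconds (scalar). Times at a segment boundary take the
#'   right-hand (new) rate; times past the last segment hold the final rate
#'   of each pump at 0.
#' @return Named numeric vector of rates in mL/h, one per role.
#' @export
pump_rates <- function(schedule, t) {
  roles <- unique(schedule$role)
  out <- stats::setNames(numeric(length(roles)), roles)
  for (r in roles) {
    s <- schedule[schedule$role == r, ]
    hit <- which(t >= s$t_start_s & t < s$t_end_s)
    if (length(hit)) {
      out[r] <- s$rate_ml_h[hit[1]]
    } else if (isTRUE(all.equal(t, max(s$t_end_s)))) {
      out[r] <- s$rate_ml_h[which.max(s$t_end_s)]  # end point inclusive
    }
  }
  out
}

#' @export
print.pump_schedule <- function(x, ...) {
  cat(sprintf("<pump_schedule> %d segment(s), %d pump(s), duration %g s\n",
              nrow(x), length(unique(x$role)), schedule_duration(x)))
  print.data.frame(x)
  invisible(x)
}

#' Schedule duration
#' @param schedule A `pump_schedule`.
#' @return Latest segment end in seconds.
#' @export
schedule_duration <- function(schedule) max(schedule$t_end_s)

# Breakpoints where any pump rate changes (includes 0 and the end).
schedule_breaks <- function(schedule) {
  sort(unique(c(schedule$t_start_s, schedule$t_end_s)))
}

#' Cumulative pumped volume
#'
#' Exact closed-form integral of the piecewise-constant total flow rate.
#'
#' @param schedule A `pump_schedule`.
#' @param times Times in seconds.
#' @return Cumulative volume in mL at each time.
#' @export
cumulative_volume <- function(schedule, times) {
  v <- numeric(length(times))
  for (i in seq_len(nrow(schedule))) {
    ov <- pmin(pmax(times - schedule$t_start_s[i], 0),
               schedule$t_end_s[i] - schedule$t_start_s[i])
    v <- v + schedule$rate_ml_h[i] * ov / 3600
  }
  v
}

#' Infusion-line configuration
#'
#' Describes the common fluid pathway between the mixing manifold and the
#' flow cell. The dead volume of that pathway delays concentration changes
#' by roughly V/Q_tot; transport through it is modelled either as a chain
#' of `n_tanks` ideal well-mixed volumes (tanks-in-series; n = 1 is a
#' single mixing chamber, larger n approaches plug flow) or as pure plug
#' flow (an exact delay, useful for analytic tests).
#'
#' @param dead_volume_ml Line dead volume in mL (> 0, default 1.0).
#' @param n_tanks Number of tanks (>= 1, default 5).
#' @param transport `"tanks"` or `"plug"`.
#' @param fluid_density_g_ml Density in g/mL (default 1.0; dye mass
#'   fractions are <= 1e-4 so dilute-aqueous density is appropriate).
#' @return An object of class `line_config`.
#' @export
line_config <- function(dead_volume_ml = 1.0, n_tanks = 5,
                        transport = c("tanks", "plug"),
                        fluid_density_g_ml = 1.0) {
  transport <- match.arg(transport)
  stopifnot(dead_volume_ml > 0, n_tanks >= 1, fluid_density_g_ml > 0)
  structure(
    list(dead_volume_ml = dead_volume_ml, n_tanks = as.integer(n_tanks),
         transport = transport, fluid_density_g_ml = fluid_density_g_ml),
    class = "line_config"
  )
}

#' Mixed concentration at the manifold junction
#'
#' Ideal mixing of the pump streams: each solute enters through exactly one
#' syringe, so its concentration just downstream of the junction is
#' \eqn{C_i = Q_i C_{0,i} / Q_{tot}} — equivalently
#' \eqn{C_i / C_{0,i} = Q_i / Q_{tot}}, the solute stream's flow fraction.
#'
#' @param flows Named vector of pump flow rates in mL/h (names = roles).
#' @param stocks Named vector of stock concentrations in ug/mL, one per
#'   solute-carrying role (names must be a subset of `names(flows)`).
#' @return Named vector of mixed concentrations in ug/mL per solute.
#' @export
junction_concentration <- function(flows, stocks) {
  q_tot <- sum(flows)
  if (q_tot <= 0) stop("no_flow")
  if (!all(names(stocks) %in% names(flows))) {
    stop("every solute must map to a pump role")
  }
  flows[names(stocks)] * stocks / q_tot
}

#' Simulate the infusion line and detector
#'
#' Runs the digital twin: junction concentrations from the pump schedule
#' are advected through the line dead volume (tanks-in-series explicit
#' update, or plug-flow delay, at the detector sampling interval), the
#' flow-cell transmission at the 424 nm and 631 nm measurement bands is
#' computed from the dye spectra, detector noise is applied, and the
#' balance mass accumulates as \eqn{\rho \int Q_{tot}\,dt} with balance
#' noise and quantization. The line starts filled with saline (zero dye).
#'
#' @param schedule A `pump_schedule` with roles `saline`, `EG`, `TZ` (any
#'   role matching a dye name carries that dye; others carry plain saline).
#' @param line A `line_config`.
#' @param dyes Named list of `dye_definition` (names must match roles).
#' @param geometry A `flow_cell_geometry`.
#' @param detector A `detector_config`; its `measurement_interval_s` is the
#'   simulation/sampling step.
#' @param duration_s Simulation length (default: schedule duration).
#' @param n_trials Number of independent trials (default 1).
#' @param seed Master seed; per-trial noise seeds are derived from it
#'   deterministically.
#' @param wavelengths Measurement wavelengths in nm.
#' @param band_nm Averaging half-band per wavelength in nm.
#' @param balance_noise_sd_g,balance_resolution_g Balance noise SD and
#'   quantization step in grams (defaults 1e-5 g = 0.01 mg, the stated
#'   balance sensitivity).
#' @return List of `n_trials` data.frames (class `line_timeseries`) with
#'   columns `time_s`, `Q_sal`, `Q_eg`, `Q_tz`, `C_eg_true`, `C_tz_true`,
#'   `I424`, `I631`, `mass_g` (intensity columns named `I<wavelength>`).
#' @export
simulate_line <- function(schedule, line, dyes, geometry, detector,
                          duration_s = NULL, n_trials = 1, seed = 1,
                          wavelengths = c(424, 631), band_nm = 1,
                          balance_noise_sd_g = 1e-5,
                          balance_resolution_g = 1e-5) {
  stopifnot(inherits(schedule, "pump_schedule"), inherits(line, "line_config"),
            inherits(detector, "detector_config"), n_trials >= 1)
  if (is.null(duration_s)) duration_s <- schedule_duration(schedule)
  dt <- detector$measurement_interval_s
  times <- seq(0, duration_s, by = dt)
  roles <- unique(schedule$role)
  dye_roles <- intersect(roles, names(dyes))
  if (length(dye_roles) == 0) stop("no pump role matches a dye name")
  stocks <- vapply(dyes[dye_roles], function(d) d$stock_concentration, numeric(1))

  # piecewise-constant rates per role on the grid
  rate_mat <- vapply(times, function(t) pump_rates(schedule, t),
                     numeric(length(roles)))
  rate_mat <- matrix(rate_mat, nrow = length(roles),
                     dimnames = list(roles, NULL))
  q_tot <- colSums(rate_mat)                      # mL/h
  if (any(q_tot <= 0)) stop("no_flow")

  # junction concentration per solute over time (ug/mL)
  c_junction <- sweep(rate_mat[dye_roles, , drop = FALSE], 2, q_tot, `/`) * stocks

  # stability guard for the explicit tanks update
  if (line$transport == "tanks") {
    tau_min <- (line$dead_volume_ml / line$n_tanks) / max(q_tot) * 3600
    if (dt > tau_min / 2) stop("unstable_timestep")
  }

  vol <- cumulative_volume(schedule, times)       # exact, mL
  c_cell <- advect_dead_volume(c_junction, q_tot, times, line, vol = vol)
  mass_true <- line$fluid_density_g_ml * vol

  # per-band true transmission from the cell concentrations
  grid <- dyes[[dye_roles[1]]]$spectrum$wavelengths
  band_wl <- lapply(wavelengths, band_wavelengths, band_nm = band_nm, grid = grid)
  eps_band <- lapply(seq_along(wavelengths), function(w) {
    vapply(dye_roles, function(r) {
      absorptivity_at(dyes[[r]]$spectrum, band_wl[[w]], band_nm = 0)
    }, numeric(length(band_wl[[w]])))
  })

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max, n_trials)

  lapply(seq_len(n_trials), function(trial) {
    set.seed(trial_seeds[trial])
    I_meas <- vapply(seq_along(wavelengths), function(w) {
      eps <- eps_band[[w]]                         # band points x dyes
      A <- eps %*% c_cell                          # band points x time
      Tt <- 10^(-geometry$path_length_mm * A)
      if (detector$relative_noise_sd > 0) {
        Tt <- pmax(Tt * (1 + stats::rnorm(length(Tt),
                                          sd = detector$relative_noise_sd)), 0)
      }
      colMeans(Tt)
    }, numeric(length(times)))
    mass <- balance_readout(mass_true, noise_sd_g = balance_noise_sd_g,
                            resolution_g = balance_resolution_g)
    out <- data.frame(time_s = times)
    out$Q_sal <- if ("saline" %in% roles) rate_mat["saline", ] else 0
    out$Q_eg <- if ("EG" %in% roles) rate_mat["EG", ] else 0
    out$Q_tz <- if ("TZ" %in% roles) rate_mat["TZ", ] else 0
    if ("EG" %in% dye_roles) out$C_eg_true <- c_cell["EG", ]
    if ("TZ" %in% dye_roles) out$C_tz_true <- c_cell["TZ", ]
    for (w in seq_along(wavelengths)) {
      out[[paste0("I", wavelengths[w])]] <- I_meas[, w]
    }
    out$mass_g <- mass
    attr(out, "trial_seed") <- trial_seeds[trial]
    attr(out, "dye_roles") <- dye_roles
    class(out) <- c("line_timeseries", "data.frame")
    out
  })
}

# Advect junction concentrations through the dead volume.
# c_junction: solutes x time matrix; returns same shape at the flow cell.
advect_dead_volume <- function(c_junction, q_tot_ml_h, times, line, vol = NULL) {
  n_sol <- nrow(c_junction)
  n_t <- length(times)
  out <- matrix(0, n_sol, n_t, dimnames = dimnames(c_junction))
  if (line$transport == "plug") {
    # the cell sees the junction mix from the moment the intervening dead
    # volume was at the junction: invert the cumulative pumped volume
    if (is.null(vol)) {
      q_ml_s <- q_tot_ml_h / 3600
      vol <- c(0, cumsum((q_ml_s[-n_t] + q_ml_s[-1]) / 2 * diff(times)))
    }
    for (i in seq_len(n_t)) {
      target <- vol[i] - line$dead_volume_ml
      if (target < 0) next                        # still initial saline
      j <- findInterval(target, vol)
      t_src <- if (j >= n_t) times[n_t] else {
        span <- vol[j + 1] - vol[j]
        if (span <= 0) times[j] else
          times[j] + (target - vol[j]) / span * (times[j + 1] - times[j])
      }
      k <- findInterval(t_src, times)
      out[, i] <- c_junction[, max(1L, k)]
    }
  } else {
    v_tank <- line$dead_volume_ml / line$n_tanks
    state <- matrix(0, n_sol, line$n_tanks)
    out[, 1] <- 0
    for (i in 2:n_t) {
      dt_h <- (times[i] - times[i - 1]) / 3600
      k <- q_tot_ml_h[i - 1] * dt_h / v_tank       # fraction exchanged
      upstream <- cbind(c_junction[, i - 1], state[, -line$n_tanks, drop = FALSE])
      state <- state + k * (upstream - state)
      out[, i] <- state[, line$n_tanks]
    }
  }
  out
}

#' Gravimetric balance readout
#'
#' Additive Gaussian noise followed by quantization at the balance
#' resolution (round-half-even, the IEEE default). The modelled balance has
#' 0.01 mg sensitivity, hence the 1e-5 g defaults.
#'
#' @param mass_g True cumulative mass series in grams, monotone
#'   non-decreasing.
#' @param noise_sd_g Noise SD in grams.
#' @param resolution_g Quantization step in grams.
#' @param seed Optional seed for the noise draw.
#' @return Measured mass series in grams.
#' @export
balance_readout <- function(mass_g, noise_sd_g = 1e-5, resolution_g = 1e-5,
                            seed = NULL) {
  if (any(diff(mass_g) < -1e-12)) stop("true mass series must be non-decreasing")
  m <- if (noise_sd_g > 0) {
    mass_g + local_rnorm(length(mass_g), sd = noise_sd_g, seed = seed)
  } else mass_g
  round(m / resolution_g) * resolution_g
}

#' Write a simulated trial to tidy CSV
#'
#' @param ts A `line_timeseries` data.frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(ts, path) {
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE)
  invisible(path)
}
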