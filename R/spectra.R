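#' Default spectrometer wavelength grid
#'
#' The compact CCD spectrometer modelled here covers 350--700 nm at 0.5 nm
#' steps, which brackets both dye absorption peaks (424 nm and 631 nm) and
#' both LED emission lines (430 nm and 625 nm).
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
default_wavelength_grid <- function() {
  seq(350, 700, by = 0.5)
}

#' Construct an absorption spectrum
#'
#' Holds the specific absorptivity \eqn{\epsilon(\lambda)} of one dye on a
#' wavelength grid, in mL ug^-1 mm^-1, so that absorbance is
#' \eqn{A = \epsilon(\lambda) \, C \, L} for concentration C in ug/mL and
#' path length L in mm.
#'
#' @param dye_name Character label (e.g. "EG", "TZ").
#' @param wavelengths Strictly increasing grid in nm.
#' @param absorptivity Nonnegative values aligned to `wavelengths`.
#' @param peak_wavelength Nominal absorption peak in nm; must coincide with
#'   the argmax of `absorptivity` within one grid step.
#' @return An object of class `absorption_spectrum`.
#' @export
absorption_spectrum <- function(dye_name, wavelengths, absorptivity, peak_wavelength) {
  stopifnot(is.character(dye_name), length(dye_name) == 1L)
  wavelengths <- as.numeric(wavelengths)
  absorptivity <- as.numeric(absorptivity)
  if (length(wavelengths) < 2L || any(diff(wavelengths) <= 0)) {
    stop("wavelength grid must be strictly increasing")
  }
  if (length(absorptivity) != length(wavelengths)) {
    stop("absorptivity must align with the wavelength grid")
  }
  if (any(absorptivity < 0)) {
    stop("absorptivity must be nonnegative")
  }
  step <- max(diff(wavelengths))
  argmax <- wavelengths[which.max(absorptivity)]
  if (abs(argmax - peak_wavelength) > step + 1e-9) {
    stop("peak_wavelength must match the argmax of absorptivity within one grid step")
  }
  structure(
    list(
      dye_name = dye_name,
      wavelengths = wavelengths,
      absorptivity = absorptivity,
      peak_wavelength = peak_wavelength
    ),
    class = "absorption_spectrum"
  )
}

#' @export
print.absorption_spectrum <- function(x, ...) {
  cat(sprintf(
    "<absorption_spectrum> %s: peak %g nm, eps(peak) = %.4g mL/ug/mm, grid %g-%g nm (%d pts)\n",
    x$dye_name, x$peak_wavelength, max(x$absorptivity),
    min(x$wavelengths), max(x$wavelengths), length(x$wavelengths)
  ))
  invisible(x)
}

#' Synthesize a Gaussian dye absorption spectrum
#'
#' The true dye spectra are known only as single-peaked curves (blue dye
#' peaking near 631 nm, yellow near 424 nm), so each is modelled as a
#' Gaussian of configurable width plus an optional flat baseline floor. The
#' baseline is the explicit cross-absorption control: it sets how much one
#' dye absorbs at the other dye's measurement wavelength, which is what
#' exercises the off-diagonal terms of the two-wavelength unmixing solve.
#' The profile is scaled so the value at `peak_wavelength` equals
#' `peak_absorptivity` exactly regardless of baseline.
#'
#' @param dye_name Character label.
#' @param peak_wavelength Peak position in nm; must lie within the grid.
#' @param width Gaussian standard deviation in nm (> 0).
#' @param peak_absorptivity Value at the peak, mL ug^-1 mm^-1 (> 0).
#' @param grid Wavelength grid in nm.
#' @param baseline_absorptivity Flat absorptivity floor far from the peak
#'   (>= 0, < `peak_absorptivity`). Default 0 (no cross-absorption).
#' @return An `absorption_spectrum`.
#' @export
make_dye_spectrum <- function(dye_name, peak_wavelength, width, peak_absorptivity,
                              grid = default_wavelength_grid(),
                              baseline_absorptivity = 0) {
  stopifnot(width > 0, peak_absorptivity > 0,
            baseline_absorptivity >= 0, baseline_absorptivity < peak_absorptivity)
  if (peak_wavelength < min(grid) || peak_wavelength > max(grid)) {
    stop("peak_out_of_range")
  }
  shape <- exp(-((grid - peak_wavelength)^2) / (2 * width^2))
  eps <- baseline_absorptivity + (peak_absorptivity - baseline_absorptivity) * shape
  absorption_spectrum(dye_name, grid, eps, peak_wavelength)
}

#' Look up specific absorptivity at a wavelength
#'
#' Linear interpolation on the spectrum grid. With `band_nm > 0` the value
#' is the mean over the band `wavelength +/- band_nm`, sampled at the grid
#' resolution — mirroring a detector that averages a few CCD pixels around
#' the nominal measurement wavelength.
#'
#' @param spectrum An `absorption_spectrum`.
#' @param wavelength Query wavelength(s) in nm.
#' @param band_nm Half-width of the averaging band in nm (default 0).
#' @return Absorptivity in mL ug^-1 mm^-1 (vectorized over `wavelength`).
#' @export
absorptivity_at <- function(spectrum, wavelength, band_nm = 0) {
  stopifnot(inherits(spectrum, "absorption_spectrum"), band_nm >= 0)
  lookup <- function(w) {
    if (w < min(spectrum$wavelengths) || w > max(spectrum$wavelengths)) {
      stop("wavelength outside spectrum grid")
    }
    stats::approx(spectrum$wavelengths, spectrum$absorptivity, xout = w)$y
  }
  vapply(wavelength, function(w) {
    if (band_nm == 0) return(lookup(w))
    mean(vapply(band_wavelengths(w, band_nm, spectrum$wavelengths), lookup, numeric(1)))
  }, numeric(1))
}

# Band sample points at the grid resolution, clipped to the grid range.
band_wavelengths <- function(wavelength, band_nm, grid) {
  step <- min(diff(grid))
  w <- seq(wavelength - band_nm, wavelength + band_nm, by = step)
  w[w >= min(grid) & w <= max(grid)]
}

#' Define a dye stream
#'
#' Couples a dye's absorption spectrum with the stock concentration loaded
#' in its syringe. The stocks in the validation experiments are 25 ug/mL
#' for Erioglaucine (EG) and 100 ug/mL for Tartrazine (TZ).
#'
#' @param name Dye label.
#' @param spectrum An `absorption_spectrum`.
#' @param stock_concentration Syringe concentration C0 in ug/mL (> 0).
#' @return An object of class `dye_definition`.
#' @export
dye_definition <- function(name, spectrum, stock_concentration) {
  stopifnot(inherits(spectrum, "absorption_spectrum"),
            is.numeric(stock_concentration), length(stock_concentration) == 1L)
  if (stock_concentration <= 0) stop("stock_concentration must be > 0")
  structure(
    list(name = name, spectrum = spectrum, stock_concentration = stock_concentration),
    class = "dye_definition"
  )
}

#' @export
print.dye_definition <- function(x, ...) {
  cat(sprintf("<dye_definition> %s: C0 = %g ug/mL, peak %g nm\n",
              x$name, x$stock_concentration, x$spectrum$peak_wavelength))
  invisible(x)
}

#' Default Erioglaucine / Tartrazine dye pair
#'
#' Peak absorptivities are set so each stock concentration attenuates to
#' roughly I/I0 = 10^-1.2 (about 6%) at its own peak over the 10 mm cell,
#' keeping the calibration range informative, and each dye carries a small
#' baseline cross-absorption (1% of its peak absorptivity) so the
#' two-wavelength unmixing has nonzero off-diagonal terms.
#'
#' @param cross_fraction Baseline floor as a fraction of peak absorptivity.
#' @param grid Wavelength grid.
#' @return Named list with `dye_definition` elements `EG` and `TZ`.
#' @export
default_dyes <- function(cross_fraction = 0.01, grid = default_wavelength_grid()) {
  # A = eps * C0 * L = 1.2 at the peak with L = 10 mm
  eps_eg <- 1.2 / (25 * 10)   # 0.0048 mL/ug/mm
  eps_tz <- 1.2 / (100 * 10)  # 0.0012 mL/ug/mm
  list(
    EG = dye_definition(
      "EG",
      make_dye_spectrum("EG", 631, width = 40, peak_absorptivity = eps_eg,
                        grid = grid, baseline_absorptivity = cross_fraction * eps_eg),
      stock_concentration = 25
    ),
    TZ = dye_definition(
      "TZ",
      make_dye_spectrum("TZ", 424, width = 45, peak_absorptivity = eps_tz,
                        grid = grid, baseline_absorptivity = cross_fraction * eps_tz),
      stock_concentration = 100
    )
  )
}

#' Flow-cell geometry
#'
#' The Z-flow cell gives a 10 mm optical path with only 26 uL of internal
#' volume; both parameters are configurable.
#'
#' @param path_length_mm Optical path length L in mm (> 0).
#' @param internal_volume_ul Internal volume in uL (> 0).
#' @return An object of class `flow_cell_geometry`.
#' @export
flow_cell_geometry <- function(path_length_mm = 10, internal_volume_ul = 26) {
  stopifnot(path_length_mm > 0, internal_volume_ul > 0)
  structure(
    list(path_length_mm = path_length_mm, internal_volume_ul = internal_volume_ul),
    class = "flow_cell_geometry"
  )
}

#' Detector (spectrometer) configuration
#'
#' @param wavelengths Wavelength grid in nm.
#' @param relative_noise_sd Multiplicative Gaussian noise, SD as a fraction
#'   of signal (default 0.005).
#' @param measurement_interval_s Sampling interval in seconds; the hardware
#'   floor is 0.2 s.
#' @param rng_seed Optional integer seed for reproducible readouts.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(wavelengths = default_wavelength_grid(),
                            relative_noise_sd = 0.005,
                            measurement_interval_s = 1,
                            rng_seed = NULL) {
  stopifnot(relative_noise_sd >= 0)
  if (measurement_interval_s < 0.2) {
    stop("measurement_interval_s below the 0.2 s hardware floor")
  }
  structure(
    list(
      wavelengths = as.numeric(wavelengths),
      relative_noise_sd = relative_noise_sd,
      measurement_interval_s = measurement_interval_s,
      rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)
    ),
    class = "detector_config"
  )
}

#' Beer-Lambert absorbance of a dye mixture
#'
#' \eqn{A(\lambda) = \sum_i \epsilon_i(\lambda) \, c_i \, L}: additive over
#' dyes and linear in each concentration.
#'
#' @param dyes List of `dye_definition` objects.
#' @param concentrations Concentrations in ug/mL aligned with `dyes`, all >= 0.
#' @param geometry A `flow_cell_geometry`.
#' @param wavelength Wavelength(s) in nm.
#' @param band_nm Averaging half-band passed to [absorptivity_at()].
#' @return Dimensionless absorbance, vectorized over `wavelength`.
#' @export
absorbance <- function(dyes, concentrations, geometry, wavelength, band_nm = 0) {
  stopifnot(inherits(geometry, "flow_cell_geometry"))
  if (length(dyes) != length(concentrations)) {
    stop("concentrations must align with dyes")
  }
  if (any(concentrations < 0)) stop("negative_concentration")
  a <- rep(0, length(wavelength))
  for (i in seq_along(dyes)) {
    eps <- absorptivity_at(dyes[[i]]$spectrum, wavelength, band_nm = band_nm)
    a <- a + eps * concentrations[i] * geometry$path_length_mm
  }
  a
}

#' Normalized transmission from absorbance
#'
#' @param absorbance Dimensionless absorbance, >= 0.
#' @return I/I0 = 10^(-A), in (0, 1].
#' @export
transmission <- function(absorbance) {
  if (any(absorbance < 0)) stop("absorbance must be nonnegative")
  10^(-absorbance)
}

#' Noisy detector readout
#'
#' Applies multiplicative Gaussian noise (SD = `relative_noise_sd` of the
#' signal) per wavelength, clipped at zero. Seeded runs are reproducible;
#' the global RNG state is restored afterwards.
#'
#' @param true_transmission Transmission spectrum on the detector grid.
#' @param config A `detector_config`.
#' @return Measured spectrum, same length as the input.
#' @export
detector_readout <- function(true_transmission, config) {
  stopifnot(inherits(config, "detector_config"))
  if (length(true_transmission) != length(config$wavelengths)) {
    stop("grid mismatch between spectrum and detector config")
  }
  if (config$relative_noise_sd == 0) return(true_transmission)
  noise <- local_rnorm(length(true_transmission), sd = config$relative_noise_sd,
                       seed = config$rng_seed)
  pmax(true_transmission * (1 + noise), 0)
}

# Draw N(0, sd) deviates under an optional local seed, restoring the caller's
# RNG state so seeded readouts do not perturb unrelated randomness.
local_rnorm <- function(n, sd, seed = NULL) {
  if (is.null(seed)) return(stats::rnorm(n, sd = sd))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  stats::rnorm(n, sd = sd)
}

#' Write / read an absorption spectrum as two-column CSV
#'
#' Columns `wavelength_nm`, `absorptivity`.
#'
#' @param spectrum An `absorption_spectrum`.
#' @param path File path.
#' @param dye_name Dye label for the object read back.
#' @param peak_wavelength Optional peak; defaults to the argmax of the data.
#' @return `read_spectrum_csv` returns an `absorption_spectrum`;
#'   `write_spectrum_csv` returns `path` invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "absorption_spectrum"))
  utils::write.csv(
    data.frame(wavelength_nm = spectrum$wavelengths,
               absorptivity = spectrum$absorptivity),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path, dye_name = "dye", peak_wavelength = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("wavelength_nm", "absorptivity") %in% names(d))) {
    stop("spectrum CSV needs columns wavelength_nm, absorptivity")
  }
  if (is.null(peak_wavelength)) {
    peak_wavelength <- d$wavelength_nm[which.max(d$absorptivity)]
  }
  absorption_spectrum(dye_name, d$wavelength_nm, d$absorptivity, peak_wavelength)
}
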