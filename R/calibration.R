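#' Assemble calibration points
#'
#' A calibration point pairs a known dye concentration with the normalized
#' transmission I/I0 measured at a stated wavelength. Values of I/I0 above 1
#' are physically suspect (brighter than the blank) and are flagged in an
#' `out_of_range` column rather than silently clipped.
#'
#' @param concentration_ug_ml Concentrations, >= 0.
#' @param normalized_transmission I/I0 values, > 0.
#' @param wavelength_nm Measurement wavelength (recycled scalar allowed).
#' @return A data.frame of class `calibration_points`.
#' @export
calibration_points <- function(concentration_ug_ml, normalized_transmission,
                               wavelength_nm = NA_real_) {
  stopifnot(length(concentration_ug_ml) == length(normalized_transmission))
  if (any(concentration_ug_ml < 0)) stop("concentration must be >= 0")
  if (any(normalized_transmission <= 0)) stop("normalized_transmission must be > 0")
  out <- data.frame(
    concentration_ug_ml = as.numeric(concentration_ug_ml),
    normalized_transmission = as.numeric(normalized_transmission),
    wavelength_nm = rep_len(as.numeric(wavelength_nm), length(concentration_ug_ml)),
    out_of_range = normalized_transmission > 1
  )
  if (any(out$out_of_range)) {
    warning(sprintf("%d calibration point(s) have I/I0 > 1 (flagged, not clipped)",
                    sum(out$out_of_range)))
  }
  class(out) <- c("calibration_points", "data.frame")
  out
}

#' Simulate a single-dye calibration data set
#'
#' Forward-models the normalized transmission at the dye's peak wavelength
#' for each requested concentration level, averaging over a +/- `band_nm`
#' band, then applies one multiplicative detector-noise draw per replicate.
#' Deterministic under a fixed `detector$rng_seed`.
#'
#' @param dye A `dye_definition`.
#' @param levels Concentrations in ug/mL, all within `[0, C0]`.
#' @param geometry A `flow_cell_geometry`.
#' @param detector A `detector_config`; its `relative_noise_sd` and
#'   `rng_seed` drive the noise.
#' @param replicates Readouts per level (default 1).
#' @param band_nm Averaging half-band in nm (default 1).
#' @return A `calibration_points` data.frame with a `replicate` column.
#' @export
generate_calibration_set <- function(dye, levels, geometry, detector,
                                     replicates = 1, band_nm = 1) {
  stopifnot(inherits(dye, "dye_definition"), replicates >= 1)
  if (any(levels < 0)) stop("negative_concentration")
  if (any(levels > dye$stock_concentration)) stop("above_stock")
  wl <- dye$spectrum$peak_wavelength
  # noiseless transmission per level at the band-mean absorptivity
  eps <- absorptivity_at(dye$spectrum, wl, band_nm = band_nm)
  true_t <- 10^(-eps * levels * geometry$path_length_mm)

  conc <- rep(levels, each = replicates)
  truth <- rep(true_t, each = replicates)
  meas <- if (detector$relative_noise_sd == 0) {
    truth
  } else {
    noise <- local_rnorm(length(truth), sd = detector$relative_noise_sd,
                         seed = detector$rng_seed)
    pmax(truth * (1 + noise), .Machine$double.eps)
  }
  out <- calibration_points(conc, meas, wavelength_nm = wl)
  out$replicate <- rep(seq_len(replicates), times = length(levels))
  out
}

#' Fit a calibration curve
#'
#' Two model families are supported for concentration versus normalized
#' transmission:
#' \itemize{
#'   \item `single_exponential`: \eqn{I/I_0 = a \cdot 10^{-bC} + c} with
#'     a > 0, b > 0, c >= 0. This nests the pure Beer-Lambert law
#'     (a = 1, c = 0, b = eps * L) and allows a baseline offset.
#'   \item `linear`: \eqn{I/I_0 = slope \cdot C + intercept}.
#' }
#' The exponential fit is nonlinear least squares initialized at a = 1,
#' c = 0.5 * min(I/I0), and b from a log-linear regression of (I/I0 - c)
#' against C — a deterministic starting point. Fits whose predicted curve is
#' not strictly decreasing over the data range are refused.
#'
#' @param points A `calibration_points` data.frame (or any data.frame with
#'   columns `concentration_ug_ml`, `normalized_transmission`).
#' @param model_kind `"single_exponential"` or `"linear"`.
#' @param dye_name,wavelength_nm Metadata stored on the curve.
#' @return An object of class `calibration_curve`.
#' @export
fit_calibration <- function(points, model_kind = c("single_exponential", "linear"),
                            dye_name = NULL, wavelength_nm = NULL) {
  model_kind <- match.arg(model_kind)
  conc <- points$concentration_ug_ml
  tr <- points$normalized_transmission
  if (is.null(conc) || is.null(tr)) {
    stop("points must have concentration_ug_ml and normalized_transmission")
  }
  n_min <- if (model_kind == "single_exponential") 3L else 2L
  if (length(conc) < n_min) stop("insufficient points for ", model_kind, " fit")
  if (length(unique(conc)) < 2L) stop("concentrations must not all be equal")
  if (is.null(wavelength_nm)) {
    wavelength_nm <- if (!is.null(points$wavelength_nm)) points$wavelength_nm[1] else NA_real_
  }

  if (model_kind == "linear") {
    fit <- stats::lm(tr ~ conc)
    pars <- c(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]))
    resid_rms <- sqrt(mean(stats::residuals(fit)^2))
  } else {
    c0 <- 0.5 * min(tr)
    pos <- pmax(tr - c0, .Machine$double.eps)
    b0 <- -stats::coef(stats::lm(log10(pos) ~ conc))[2]
    if (!is.finite(b0) || b0 <= 0) b0 <- 1 / max(conc)
    start <- list(a = 1, b = unname(b0), c = c0)
    fit <- stats::nls(
      tr ~ a * 10^(-b * conc) + c,
      start = start,
      algorithm = "port",
      lower = c(a = .Machine$double.eps, b = .Machine$double.eps, c = 0),
      control = stats::nls.control(maxiter = 500, warnOnly = FALSE, scaleOffset = 1)
    )
    pars <- stats::coef(fit)
    resid_rms <- sqrt(mean(stats::residuals(fit)^2))
  }

  curve <- structure(
    list(
      dye_name = if (is.null(dye_name)) "dye" else dye_name,
      wavelength_nm = wavelength_nm,
      model_kind = model_kind,
      parameters = pars,
      valid_concentration_range = range(conc),
      fit_residual_rms = resid_rms
    ),
    class = "calibration_curve"
  )
  grid <- seq(min(conc), max(conc), length.out = 201)
  pred <- predict_calibration(curve, grid)
  if (any(diff(pred) >= 0)) stop("nonmonotone_calibration")
  curve
}

#' @export
print.calibration_curve <- function(x, ...) {
  p <- paste(sprintf("%s = %.6g", names(x$parameters), x$parameters), collapse = ", ")
  cat(sprintf("<calibration_curve> %s @ %g nm [%s]: %s; range %g-%g ug/mL, rms %.3g\n",
              x$dye_name, x$wavelength_nm, x$model_kind, p,
              x$valid_concentration_range[1], x$valid_concentration_range[2],
              x$fit_residual_rms))
  invisible(x)
}

#' Predict normalized transmission from a calibration curve
#'
#' @param curve A `calibration_curve`.
#' @param concentration Concentrations in ug/mL.
#' @return Predicted I/I0.
#' @export
predict_calibration <- function(curve, concentration) {
  stopifnot(inherits(curve, "calibration_curve"))
  p <- curve$parameters
  switch(curve$model_kind,
    single_exponential = p[["a"]] * 10^(-p[["b"]] * concentration) + p[["c"]],
    linear = p[["slope"]] * concentration + p[["intercept"]]
  )
}

#' Invert a calibration curve
#'
#' Closed-form inverse of [predict_calibration()]: unique on the valid range
#' because the fitted curve is strictly decreasing there. Measurements
#' outside the curve's predicted range (beyond `tol`) are refused rather
#' than extrapolated.
#'
#' @param curve A `calibration_curve`.
#' @param normalized_transmission Measured I/I0 value(s).
#' @param tol Tolerance on the range check (default 1e-6).
#' @return Concentration(s) in ug/mL.
#' @export
invert_calibration <- function(curve, normalized_transmission, tol = 1e-6) {
  stopifnot(inherits(curve, "calibration_curve"))
  rng <- curve$valid_concentration_range
  hi <- predict_calibration(curve, rng[1])
  lo <- predict_calibration(curve, rng[2])
  if (any(normalized_transmission > hi + tol) || any(normalized_transmission < lo - tol)) {
    stop("out_of_calibration_range")
  }
  x <- pmin(pmax(normalized_transmission, lo), hi)
  p <- curve$parameters
  switch(curve$model_kind,
    single_exponential = -log10((x - p[["c"]]) / p[["a"]]) / p[["b"]],
    linear = (x - p[["intercept"]]) / p[["slope"]]
  )
}

#' Serialize a calibration curve to JSON (and back)
#'
#' @param curve A `calibration_curve`.
#' @param path File path.
#' @return `read_calibration_curve_json` returns a `calibration_curve`;
#'   the writer returns `path` invisibly.
#' @export
write_calibration_curve_json <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  jsonlite::write_json(
    list(
      dye_name = curve$dye_name,
      wavelength_nm = curve$wavelength_nm,
      model_kind = curve$model_kind,
      parameters = as.list(curve$parameters),
      valid_concentration_range = curve$valid_concentration_range,
      fit_residual_rms = curve$fit_residual_rms
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_calibration_curve_json
#' @export
read_calibration_curve_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      dye_name = x$dye_name,
      wavelength_nm = x$wavelength_nm,
      model_kind = x$model_kind,
      parameters = unlist(x$parameters),
      valid_concentration_range = as.numeric(x$valid_concentration_range),
      fit_residual_rms = as.numeric(x$fit_residual_rms)
    ),
    class = "calibration_curve"
  )
}
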