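#' Total flow rate from the balance trace
#'
#' The analytical balance under the waste container provides an orthogonal
#' measurement of the total flow: \eqn{Q_{tot} \approx \Delta mass / (\rho
#' \Delta t)}. Implemented as a centered finite difference of the mass
#' series over a `window_s`-wide window, with optional moving-average
#' smoothing of the resulting rate. The window must span several samples so
#' balance quantization (1e-5 g) does not dominate at low flows.
#'
#' @param time_s Sample times in seconds (regular grid).
#' @param mass_g Measured cumulative mass in grams.
#' @param density_g_ml Fluid density (default 1.0).
#' @param window_s Differentiation window in seconds (default 30).
#' @param smooth_s Optional moving-average span for the rate series, in
#'   seconds (0 = off).
#' @return data.frame `time_s`, `Q_tot_ml_h` (NA within half a window of
#'   the ends), with attribute `nonmonotone` TRUE if the raw mass decreased
#'   by more than 5 quantization steps anywhere (also warns).
#' @export
total_flow_from_balance <- function(time_s, mass_g, density_g_ml = 1.0,
                                    window_s = 30, smooth_s = 0) {
  stopifnot(length(time_s) == length(mass_g), density_g_ml > 0, window_s > 0)
  dt <- stats::median(diff(time_s))
  h <- max(1L, round((window_s / 2) / dt))
  if (2 * h + 1 > length(time_s)) stop("window longer than the series")

  nonmono <- any(diff(mass_g) < -5e-5)
  if (nonmono) warning("mass series decreases beyond noise tolerance")

  n <- length(time_s)
  q <- rep(NA_real_, n)
  idx <- (h + 1):(n - h)
  q[idx] <- (mass_g[idx + h] - mass_g[idx - h]) /
    (time_s[idx + h] - time_s[idx - h]) / density_g_ml * 3600
  if (smooth_s > 0) {
    k <- max(1L, round(smooth_s / dt))
    kern <- rep(1 / k, k)
    sm <- stats::filter(q[idx], kern, sides = 2)
    q[idx] <- as.numeric(sm)
  }
  out <- data.frame(time_s = time_s, Q_tot_ml_h = q)
  attr(out, "nonmonotone") <- nonmono
  out
}

#' Saline (third-stream) fraction by conservation of mass
#'
#' With every solute exclusively in one syringe, the normalized
#' concentrations are flow fractions that must sum to one, so the
#' non-absorbing carrier's fraction is
#' \eqn{C/C_0|_{sal} = 1 - C/C_0|_{EG} - C/C_0|_{TZ}}. A result below
#' `-tol` means the measured dye fractions exceed unity — the mass balance
#' is violated, which happens transiently while dead-volume lag makes the
#' measured concentrations inconsistent with the instantaneous flows.
#'
#' @param eg_norm,tz_norm Normalized dye concentrations C/C0, each in
#'   `[0, 1 + tol]` (vectorized).
#' @param tol Tolerance (default 0.01).
#' @return Saline fraction(s), same length as the inputs.
#' @export
saline_fraction <- function(eg_norm, tz_norm, tol = 0.01) {
  if (any(eg_norm < -tol) || any(eg_norm > 1 + tol) ||
      any(tz_norm < -tol) || any(tz_norm > 1 + tol)) {
    stop("normalized concentrations must lie in [0, 1]")
  }
  out <- 1 - eg_norm - tz_norm
  if (any(out < -tol)) stop("mass_balance_violation")
  out
}

#' Back-calculate per-stream flow rates
#'
#' Given the total flow (from the balance) and the normalized dye
#' concentrations (from the spectroscopy), each dye stream's flow is
#' \eqn{Q_i = (C/C_0)_i \cdot Q_{tot}} and the saline stream takes the
#' remainder, so the three flows sum to `Q_tot` exactly by construction.
#'
#' @param fractions Named vector of normalized dye concentrations
#'   (e.g. `c(EG = 0.167, TZ = 0.333)`).
#' @param q_tot_ml_h Total flow rate in mL/h (> 0).
#' @param tol Passed to [saline_fraction()].
#' @return Named vector: one flow per dye plus `saline`, in mL/h.
#' @export
stream_flows <- function(fractions, q_tot_ml_h, tol = 0.01) {
  stopifnot(q_tot_ml_h > 0, !is.null(names(fractions)))
  if (length(fractions) == 2) {
    saline_fraction(fractions[1], fractions[2], tol = tol)   # validates
  } else if (1 - sum(fractions) < -tol) {
    stop("mass_balance_violation")
  }
  q <- fractions * q_tot_ml_h
  c(q, saline = q_tot_ml_h - sum(q))
}

#' Steady-state accuracy and repeatability statistics
#'
#' Across independent trials of the same experiment: at each time point the
#' cross-trial mean and SEM (sd / sqrt(n)) are computed; over the analysis
#' window the report gives repeatability = the maximum SEM and accuracy =
#' the maximum absolute difference between the expected steady-state value
#' and the cross-trial mean.
#'
#' @param trials List (length >= 2) of numeric series, one per trial, all
#'   aligned on `time_s`.
#' @param time_s Common time grid in seconds.
#' @param window Length-2 numeric, analysis window `[start, end]` in
#'   seconds; must lie within the series.
#' @param expected Expected steady-state value (same units as the trials).
#' @return An object of class `steady_state_stats`: list with `mean`
#'   (window-mean of the cross-trial mean), `accuracy`, `repeatability`
#'   (max SEM), `n_trials`, `window`, `expected`, and the per-time `series`
#'   data.frame (`time_s`, `mean`, `sem`).
#' @export
steady_state_stats <- function(trials, time_s, window, expected) {
  stopifnot(is.list(trials), length(window) == 2, window[1] < window[2])
  n <- length(trials)
  if (n < 2) stop("need >= 2 trials for SEM")
  if (any(vapply(trials, length, integer(1)) != length(time_s))) {
    stop("all trials must align with time_s")
  }
  if (window[2] < min(time_s) || window[1] > max(time_s)) {
    stop("window outside the series")
  }
  in_win <- time_s >= window[1] & time_s <= window[2]
  if (!any(in_win)) stop("window contains no samples")

  m <- do.call(cbind, trials)[in_win, , drop = FALSE]
  mu <- rowMeans(m)
  sem <- apply(m, 1, stats::sd) / sqrt(n)
  structure(
    list(
      mean = mean(mu),
      accuracy = max(abs(expected - mu)),
      repeatability = max(sem),
      n_trials = n,
      window = window,
      expected = expected,
      series = data.frame(time_s = time_s[in_win], mean = mu, sem = sem)
    ),
    class = "steady_state_stats"
  )
}

#' @export
print.steady_state_stats <- function(x, ...) {
  cat(sprintf(
    "<steady_state_stats> n=%d, window [%g, %g] s\n  expected %.4g | mean %.4g | accuracy (max |diff|) %.4g | repeatability (max SEM) %.4g\n",
    x$n_trials, x$window[1], x$window[2], x$expected, x$mean,
    x$accuracy, x$repeatability
  ))
  invisible(x)
}
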