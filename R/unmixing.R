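#' Build the cross-absorptivity matrix for joint unmixing
#'
#' Entry `K[w, d] = eps_d(lambda_w) * L` is the effective absorbance per
#' (ug/mL) of dye d at measurement wavelength w, so that the measured
#' absorbances satisfy the linear system `A = K %*% C`. Rows are
#' wavelengths (default 424 and 631 nm), columns are dyes. The matrix must
#' be well-conditioned: dyes whose spectra are indistinguishable at the
#' chosen wavelengths cannot be unmixed.
#'
#' The construction generalizes to n wavelengths x n dyes; the default
#' two-dye configuration is the one exercised throughout.
#'
#' @param dyes List of `dye_definition` objects (order fixes the column
#'   order of the recovered concentrations).
#' @param geometry A `flow_cell_geometry`.
#' @param wavelengths Measurement wavelengths in nm, one per dye.
#' @param band_nm Averaging half-band passed to [absorptivity_at()].
#' @return A `cross_matrix`: numeric matrix with dimnames, plus attributes
#'   `wavelengths` and `stocks` (per-dye C0, used for tolerance defaults).
#' @export
build_cross_matrix <- function(dyes, geometry,
                               wavelengths = c(424, 631), band_nm = 1) {
  stopifnot(inherits(geometry, "flow_cell_geometry"),
            length(dyes) == length(wavelengths))
  dye_names <- vapply(dyes, function(d) d$name, character(1))
  K <- matrix(0, nrow = length(wavelengths), ncol = length(dyes),
              dimnames = list(paste0("w", wavelengths), dye_names))
  for (j in seq_along(dyes)) {
    K[, j] <- absorptivity_at(dyes[[j]]$spectrum, wavelengths, band_nm = band_nm) *
      geometry$path_length_mm
  }
  if (any(diag(K) <= 0)) {
    # a dye must absorb at its own measurement wavelength
    stop("degenerate_spectra")
  }
  if (!all(is.finite(K)) || kappa(K, exact = TRUE) > 1e8) {
    stop("degenerate_spectra")
  }
  structure(K,
            wavelengths = wavelengths,
            stocks = vapply(dyes, function(d) d$stock_concentration, numeric(1)),
            class = c("cross_matrix", "matrix", "array"))
}

#' @export
print.cross_matrix <- function(x, ...) {
  cat("<cross_matrix> effective absorbance per (ug/mL):\n")
  print(unclass(x)[,, drop = FALSE])
  cat(sprintf("condition number: %.3g\n", kappa(unclass(x), exact = TRUE)))
  invisible(x)
}

#' Recover dye concentrations from dual-wavelength transmission
#'
#' Converts the measured normalized intensities to absorbances
#' `A_w = -log10(I_w)` and solves the square linear system `A = K C`
#' exactly. This makes the two-dye problem an exact 2x2 solve in absorbance
#' space. Small negative solutions (detector noise crossing zero) are
#' clipped to 0; components below `-neg_tol` indicate the intensities are
#' inconsistent with the spectral model and raise an error.
#'
#' @param intensities Normalized transmissions, one per matrix row; a
#'   vector for one time point or a matrix/data.frame with one column per
#'   wavelength (rows = time points).
#' @param K A `cross_matrix` from [build_cross_matrix()].
#' @param neg_tol Negative-concentration tolerance in ug/mL per dye;
#'   defaults to 0.5% of each dye's stock concentration.
#' @return Named concentration vector in ug/mL (or a matrix with one row
#'   per input row).
#' @export
recover_concentrations <- function(intensities, K, neg_tol = NULL) {
  stopifnot(inherits(K, "cross_matrix"))
  if (is.null(neg_tol)) {
    stocks <- attr(K, "stocks")
    neg_tol <- if (is.null(stocks)) rep(0.5, ncol(K)) else 0.005 * stocks
  }
  neg_tol <- rep_len(neg_tol, ncol(K))

  one_row <- is.null(dim(intensities))
  I <- if (one_row) matrix(intensities, nrow = 1) else as.matrix(intensities)
  if (ncol(I) != nrow(K)) stop("need one intensity per measurement wavelength")
  if (any(!is.finite(I)) || any(I <= 0)) stop("opaque_sample")

  A <- -log10(I)                       # rows: time, cols: wavelength
  C <- t(solve(unclass(K), t(A)))      # rows: time, cols: dye
  colnames(C) <- colnames(K)
  too_neg <- sweep(C, 2, -neg_tol, `<`)
  if (any(too_neg)) stop("inconsistent_intensities")
  C[C < 0] <- 0
  if (one_row) C[1, ] else C
}

#' Normalize recovered concentrations by stock
#'
#' C/C0 per dye; at steady state this equals the dye stream's flow
#' fraction Q_dye / Q_tot.
#'
#' @param concentrations Vector or matrix from [recover_concentrations()].
#' @param K The `cross_matrix` (carries the stock concentrations), or a
#'   named numeric vector of stocks.
#' @return Same shape as `concentrations`, dimensionless.
#' @export
normalize_concentrations <- function(concentrations, K) {
  stocks <- if (inherits(K, "cross_matrix")) attr(K, "stocks") else K
  if (is.null(dim(concentrations))) {
    concentrations / stocks
  } else {
    sweep(concentrations, 2, stocks, `/`)
  }
}
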