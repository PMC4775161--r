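# Extended pseudo-Voigt peak shapes: separable products of unit-area 1D
# pseudo-Voigts, one per reciprocal axis, with optional linear dependence of
# the widths on the reflection's |q|.

#' Extended pseudo-Voigt peak-shape parameters
#'
#' Six adjustable parameters describe the anisotropic separable peak shape:
#' per reciprocal axis a Gaussian/Lorentzian mixing weight `eta` in `[0, 1]`
#' and two FWHM widths (Gaussian `gamma_g`, Lorentzian `gamma_l`, both in
#' 1/Å). Optionally each width varies linearly with the peak's |q|
#' (`slopes`, per 1/Å of |q|; default 0 — defect-free ensembles are fitted
#' with one common parameter set).
#'
#' @param eta_x,eta_y mixing weights in `[0, 1]` (1 = pure Gaussian).
#' @param gamma_gx,gamma_lx,gamma_gy,gamma_ly FWHM widths in 1/Å, `> 0`.
#' @param slopes named numeric vector `c(gx=, lx=, gy=, ly=)` of linear
#'   |q|-dependence coefficients for the four widths.
#' @return an object of class `"peak_params"`.
#' @export
peak_params <- function(eta_x, eta_y, gamma_gx, gamma_lx, gamma_gy, gamma_ly,
                        slopes = c(gx = 0, lx = 0, gy = 0, ly = 0)) {
  etas <- c(eta_x, eta_y)
  gammas <- c(gamma_gx, gamma_lx, gamma_gy, gamma_ly)
  if (any(!is.finite(etas)) || any(etas < 0 | etas > 1))
    abort_invalid("eta must lie in [0, 1]")
  if (any(!is.finite(gammas)) || any(gammas <= 0))
    abort_invalid("widths must be positive")
  sl <- c(gx = 0, lx = 0, gy = 0, ly = 0)
  sl[names(slopes)] <- slopes
  structure(list(eta_x = eta_x, eta_y = eta_y,
                 gamma_gx = gamma_gx, gamma_lx = gamma_lx,
                 gamma_gy = gamma_gy, gamma_ly = gamma_ly,
                 slopes = sl),
            class = "peak_params")
}

#' @export
print.peak_params <- function(x, ...) {
  cat(sprintf(paste0("<peak_params> eta = (%.4f, %.4f); ",
                     "Gamma_G = (%.4g, %.4g), Gamma_L = (%.4g, %.4g) 1/A\n"),
              x$eta_x, x$eta_y, x$gamma_gx, x$gamma_gy,
              x$gamma_lx, x$gamma_ly))
  if (any(x$slopes != 0))
    cat("  width |q|-slopes:", paste(sprintf("%s=%.3g", names(x$slopes),
                                             x$slopes), collapse = ", "), "\n")
  invisible(x)
}

# Widths of one axis evaluated at a peak's |q| through the linear dependence.
widths_at <- function(p, axis, q_center_mag) {
  if (axis == "x") {
    g <- p$gamma_gx + p$slopes[["gx"]] * q_center_mag
    l <- p$gamma_lx + p$slopes[["lx"]] * q_center_mag
  } else {
    g <- p$gamma_gy + p$slopes[["gy"]] * q_center_mag
    l <- p$gamma_ly + p$slopes[["ly"]] * q_center_mag
  }
  if (any(g <= 0) || any(l <= 0))
    abort_invalid("width |q|-dependence drives a FWHM non-positive in range")
  list(g = g, l = l)
}

#' One-dimensional pseudo-Voigt density
#'
#' `eta * N(x; gamma_g) + (1 - eta) * C(x; gamma_l)` where `N` is the
#' unit-area Gaussian of FWHM `gamma_g` and `C` the unit-area Lorentzian of
#' FWHM `gamma_l`; integrates to 1 over the real line. `x` is the offset
#' from the peak center in 1/Å, so the density has units of Å.
#'
#' @param x offsets in 1/Å (vectorized).
#' @param eta mixing weight in `[0, 1]`.
#' @param gamma_g,gamma_l FWHM widths in 1/Å.
#' @return density values.
#' @export
pv1d <- function(x, eta, gamma_g, gamma_l) {
  if (!is.finite(eta) || eta < 0 || eta > 1)
    abort_invalid("eta must lie in [0, 1]")
  if (any(!is.finite(c(gamma_g, gamma_l))) || gamma_g <= 0 || gamma_l <= 0)
    abort_invalid("widths must be positive")
  g <- (2 / gamma_g) * sqrt(log(2) / pi) * exp(-4 * log(2) * (x / gamma_g)^2)
  l <- (gamma_l / (2 * pi)) / (x^2 + (gamma_l / 2)^2)
  eta * g + (1 - eta) * l
}

#' Two-dimensional extended pseudo-Voigt profile
#'
#' Separable product of two independent 1D pseudo-Voigts, one per reciprocal
#' axis, with the four widths evaluated at the peak's |q| through the linear
#' dependence. Even in each component and maximal at `dq = 0`; integrates
#' to 1 over the plane.
#'
#' @param dq offset from the peak center: a 2-vector or an n-by-2 matrix in
#'   1/Å.
#' @param p a [peak_params()].
#' @param q_center_mag |q| of the peak center in 1/Å (default 0).
#' @return density values in Å².
#' @export
profile2d <- function(dq, p, q_center_mag = 0) {
  stopifnot(inherits(p, "peak_params"))
  if (is.null(dim(dq))) dq <- matrix(dq, ncol = 2L)
  wx <- widths_at(p, "x", q_center_mag)
  wy <- widths_at(p, "y", q_center_mag)
  pv1d(dq[, 1L], p$eta_x, wx$g, wx$l) * pv1d(dq[, 2L], p$eta_y, wy$g, wy$l)
}

#' Peak maximum of the 2D profile
#'
#' `profile2d(c(0, 0), p, q_center_mag)` — the profile's value at its own
#' center, used for the P-matrix diagonal and for flat initialization of
#' extracted intensities.
#'
#' @inheritParams profile2d
#' @return the peak density in Å².
#' @export
peak_value <- function(p, q_center_mag = 0) {
  as.numeric(profile2d(c(0, 0), p, q_center_mag))
}

#' Serialize peak parameters to a plain list
#'
#' @param p a [peak_params()].
#' @return a named list suitable for the YAML config format.
#' @export
peak_params_to_list <- function(p) {
  list(eta_x = p$eta_x, eta_y = p$eta_y,
       gamma_gx = p$gamma_gx, gamma_lx = p$gamma_lx,
       gamma_gy = p$gamma_gy, gamma_ly = p$gamma_ly,
       slopes = as.list(p$slopes))
}

#' Build peak parameters from a plain list
#'
#' @param x a list as produced by [peak_params_to_list()] or parsed from a
#'   config file.
#' @return a [peak_params()].
#' @export
peak_params_from_list <- function(x) {
  sl <- unlist(x$slopes %||% list(gx = 0, lx = 0, gy = 0, ly = 0))
  peak_params(x$eta_x, x$eta_y, x$gamma_gx, x$gamma_lx, x$gamma_gy,
              x$gamma_ly, slopes = sl)
}

#' Write a peak-parameter report table
#'
#' One column per crystal-size set, rows for the two mixing weights and four
#' FWHM widths — the conventional way fitted profile parameters are reported
#' across ensembles.
#'
#' @param params_list list of [peak_params()].
#' @param labels column labels (e.g. mean crystal sizes).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_report <- function(params_list, labels, path) {
  stopifnot(length(params_list) == length(labels))
  rows <- c("eta_x", "eta_y", "gamma_gx", "gamma_lx", "gamma_gy", "gamma_ly")
  m <- vapply(params_list, function(p)
    c(p$eta_x, p$eta_y, p$gamma_gx, p$gamma_lx, p$gamma_gy, p$gamma_ly),
    numeric(6L))
  df <- data.frame(parameter = rows, m, check.names = FALSE)
  names(df)[-1L] <- as.character(labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
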