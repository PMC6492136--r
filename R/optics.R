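# 4F sample-arm geometry, Gaussian-beam derived quantities, and the
# source-spectrum wavelength/wavenumber bookkeeping.
#
# Unit convention: lengths in mm internally; wavelengths are accepted in nm
# and converted on construction. Wavenumbers are reported in rad/nm by the
# spectral functions (with rad/mm available via `k_grid_mm()`), matching how
# OCT source specifications are printed.

#' Construct the sample-arm beam geometry
#'
#' Describes the 4F focusing optics of the sample arm: a lens of focal
#' length `f` a distance `d` above the tissue surface, illuminated by a
#' collimated Gaussian beam of 1/e intensity radius `w0`. All derived
#' Gaussian-beam quantities are precomputed:
#'
#' * `wf` — focal-plane 1/e intensity radius in a medium of index `n`,
#'   \eqn{w_f = \lambda f / (2 n \pi w_0)};
#' * `wf_air` — the same quantity in air (`n = 1`), which is also the
#'   fiber-mode radius imaged at the p-plane;
#' * `ws` — beam radius where it crosses the tissue surface, evaluated with
#'   the in-air waist because the beam converges through air before entering
#'   the medium;
#' * `wfp` — in-medium focal-plane radius
#'   \eqn{w_f' = \lambda (f - d) / (2 n \pi w_s)};
#' * `zR` — in-medium Rayleigh length \eqn{z_R = 2 n \pi w_f'^2 / \lambda}.
#'
#' @param f_mm focal length of the focusing lens (mm).
#' @param d_mm distance from the lens to the tissue surface (mm); must
#'   satisfy `0 <= d < f`.
#' @param w0_mm 1/e intensity radius of the collimated beam at the lens (mm).
#' @param lambda_nm vacuum central wavelength (nm).
#' @param n refractive index of the first tissue layer.
#' @return An object of class `oct_beam` (a named list of the inputs in mm
#'   plus the derived quantities above).
#' @examples
#' geom <- beam_geometry(f_mm = 0.5, d_mm = 0, w0_mm = 0.1)
#' focal_waist(geom)
#' @export
beam_geometry <- function(f_mm, d_mm = 0, w0_mm, lambda_nm = 1300, n = 1) {
  bad <- character()
  if (!is.numeric(f_mm) || length(f_mm) != 1 || !is.finite(f_mm) || f_mm <= 0)
    bad <- c(bad, "f_mm must be a positive number")
  if (!is.numeric(w0_mm) || length(w0_mm) != 1 || !is.finite(w0_mm) || w0_mm <= 0)
    bad <- c(bad, "w0_mm must be a positive number")
  if (!is.numeric(lambda_nm) || length(lambda_nm) != 1 || lambda_nm <= 0)
    bad <- c(bad, "lambda_nm must be a positive number")
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    bad <- c(bad, "n must be >= 1")
  if (!is.numeric(d_mm) || length(d_mm) != 1 || d_mm < 0 ||
      (is.finite(f_mm) && f_mm > 0 && d_mm >= f_mm))
    bad <- c(bad, "d_mm must satisfy 0 <= d_mm < f_mm")
  if (length(bad) > 0)
    abort(paste0("invalid beam geometry: ", paste(bad, collapse = "; ")),
          class = "octmc_config_error")

  lambda <- lambda_nm * 1e-6 # mm
  wf     <- lambda * f_mm / (2 * n * pi * w0_mm)
  wf_air <- lambda * f_mm / (2 * pi * w0_mm)
  ws     <- wf_air * sqrt(1 + (lambda * (f_mm - d_mm) / (2 * pi * wf_air^2))^2)
  wfp    <- lambda * (f_mm - d_mm) / (2 * n * pi * ws)
  zR     <- 2 * n * pi * wfp^2 / lambda
  structure(
    list(f = f_mm, d = d_mm, w0 = w0_mm, lambda = lambda, lambda_nm = lambda_nm,
         n = n, wf = wf, wf_air = wf_air, ws = ws, wfp = wfp, zR = zR),
    class = "oct_beam"
  )
}

#' @export
print.oct_beam <- function(x, ...) {
  cat("<oct_beam> 4F sample-arm geometry\n")
  cat(sprintf("  f = %g mm, d = %g mm, w0 = %g mm, lambda = %g nm, n = %g\n",
              x$f, x$d, x$w0, x$lambda_nm, x$n))
  cat(sprintf("  wf = %.4g mm, ws = %.4g mm, wf' = %.4g mm, zR = %.4g mm\n",
              x$wf, x$ws, x$wfp, x$zR))
  invisible(x)
}

#' Focal-plane beam waist in the medium
#'
#' \eqn{w_f = \lambda f / (2 n \pi w_0)}.
#'
#' @param geom an [beam_geometry()] object.
#' @return 1/e intensity radius at the focal plane (mm).
#' @export
focal_waist <- function(geom) {
  stopifnot(inherits(geom, "oct_beam"))
  geom$wf
}

#' Beam radius at the tissue surface
#'
#' Radius of the incident Gaussian beam where it crosses the surface,
#' \eqn{w_s = w_f \sqrt{1 + (\lambda (f-d) / (2 \pi w_f^2))^2}} with the
#' in-air waist, from which surface-launched packets are sampled.
#'
#' @inheritParams focal_waist
#' @return 1/e intensity radius at `z = 0` (mm).
#' @export
surface_radius <- function(geom) {
  stopifnot(inherits(geom, "oct_beam"))
  geom$ws
}

#' Signed wavefront radius of curvature at depth z
#'
#' \eqn{R(z) = -(d - f + z/n)\,[1 + (z_R / (d - f + z/n))^2]}. Positive
#' before the focus (converging wavefronts), negative after. At the exact
#' focal depth `z* = n (f - d)` the wavefront is plane and a signed infinity
#' (`+Inf`) is returned; the direction formula degenerates gracefully there
#' because the trajectory tangent uses the smooth reciprocal
#' \eqn{1/R = -\zeta / (\zeta^2 + z_R^2)}.
#'
#' @inheritParams focal_waist
#' @param z depth(s) in the medium (mm).
#' @return signed radius of curvature (mm); vectorized over `z`.
#' @export
wavefront_radius <- function(geom, z) {
  stopifnot(inherits(geom, "oct_beam"))
  if (any(z < 0)) abort("z must be >= 0", class = "octmc_domain_error")
  zeta <- geom$d - geom$f + z / geom$n
  out <- ifelse(zeta == 0, Inf, -(zeta^2 + geom$zR^2) / zeta)
  out
}

#' Ballistic beam envelope at depth z
#'
#' The 1/e intensity radius of the unscattered beam at depth `z`, obtained by
#' integrating the wavefront-normal ray equation `d log w / dz = -1/R(z)`:
#' \eqn{w(z) = w_f' (1 + (\zeta/z_R)^2)^{n/2}} with
#' \eqn{\zeta = d - f + z/n}. For `n = 1` this is the usual Gaussian-beam
#' envelope; it equals `ws` at the surface and `wfp` at the focus.
#'
#' @inheritParams wavefront_radius
#' @return beam radius (mm); vectorized over `z`.
#' @export
beam_radius <- function(geom, z) {
  stopifnot(inherits(geom, "oct_beam"))
  zeta <- geom$d - geom$f + z / geom$n
  geom$wfp * (1 + (zeta / geom$zR)^2)^(geom$n / 2)
}

#' Unit tangent of the ballistic trajectory
#'
#' Direction normal to the Gaussian-beam wavefront at transverse position
#' `(x, y)` and depth `z`; `(0, 0, 1)` on the axis and at the focus.
#'
#' @inheritParams wavefront_radius
#' @param x,y transverse position (mm).
#' @return length-3 unit vector.
#' @export
beam_direction <- function(geom, x, y, z) {
  zeta <- geom$d - geom$f + z / geom$n
  invR <- -zeta / (zeta^2 + geom$zR^2)
  tx <- -x * invR
  ty <- -y * invR
  v <- c(tx, ty, 1)
  v / sqrt(sum(v^2))
}

# --- source spectrum ---------------------------------------------------------

#' Describe the light source spectrum
#'
#' FDOCT sources are specified on a wavelength grid: minimum wavelength,
#' central wavelength, spacing, FWHM bandwidth, and the number of spectral
#' cells. Defaults are a 1300 nm source with a 95 nm bandwidth sampled on
#' 2048 cells spaced 0.055 nm apart. (Equipment sheets sometimes quote a
#' larger "total" spectral span — here 2048 x 0.055 = 112.6 nm; the FWHM
#' bandwidth is what enters the Gaussian envelope.)
#'
#' @param lambda_c_nm central wavelength (nm).
#' @param bandwidth_nm FWHM wavelength bandwidth (nm).
#' @param n_cells number of spectral cells M (>= 2).
#' @param delta_lambda_nm wavelength spacing (nm).
#' @param lambda_min_nm minimum wavelength (nm); defaults to a grid centred
#'   on `lambda_c_nm`.
#' @return An object of class `oct_source`.
#' @export
source_spectrum <- function(lambda_c_nm = 1300, bandwidth_nm = 95,
                            n_cells = 2048, delta_lambda_nm = 0.055,
                            lambda_min_nm = NULL) {
  if (!is.numeric(n_cells) || n_cells < 2)
    abort("n_cells must be >= 2", class = "octmc_config_error")
  if (delta_lambda_nm <= 0 || bandwidth_nm <= 0 || lambda_c_nm <= 0)
    abort("wavelengths and spacings must be positive",
          class = "octmc_config_error")
  M <- as.integer(n_cells)
  if (is.null(lambda_min_nm))
    lambda_min_nm <- lambda_c_nm - (M - 1) * delta_lambda_nm / 2
  if (lambda_min_nm <= 0)
    abort("lambda_min_nm must be positive", class = "octmc_config_error")
  structure(
    list(lambda_min = lambda_min_nm,
         lambda_max = lambda_min_nm + (M - 1) * delta_lambda_nm,
         lambda_c = lambda_c_nm, delta_lambda = delta_lambda_nm,
         bandwidth = bandwidth_nm, M = M),
    class = "oct_source"
  )
}

#' @export
print.oct_source <- function(x, ...) {
  cat("<oct_source>\n")
  cat(sprintf("  lambda_c = %g nm, FWHM = %g nm, M = %d cells, spacing = %g nm\n",
              x$lambda_c, x$bandwidth, x$M, x$delta_lambda))
  cat(sprintf("  imaging depth D = %.3f mm\n", imaging_depth(x)))
  invisible(x)
}

#' Resample the wavelength grid to evenly spaced wavenumbers
#'
#' Spectrometer cells are evenly spaced in wavelength; the inverse Fourier
#' reconstruction needs even spacing in wavenumber. The interpolating factor
#' \eqn{s_i = [1/\lambda_{max} + (i/(M-1))(1/\lambda_{min} -
#' 1/\lambda_{max})]^{-1} - \lambda_{min}} defines resampled wavelengths
#' \eqn{\lambda_i = \lambda_{min} + s_i} running from \eqn{\lambda_{max}}
#' down to \eqn{\lambda_{min}}, so that \eqn{k_i = 2\pi/\lambda_i} increases
#' linearly from the smallest wavenumber \eqn{k_0 = 2\pi/\lambda_{max}}.
#'
#' @param src an [source_spectrum()] object.
#' @return numeric vector of wavenumbers (rad/nm), evenly spaced and
#'   increasing, with attributes `delta_k` (rad/nm) and `lambda_nm`.
#' @export
resample_wavenumbers <- function(src) {
  stopifnot(inherits(src, "oct_source"))
  M <- src$M
  i <- seq_len(M) - 1
  inv <- 1 / src$lambda_max + (i / (M - 1)) * (1 / src$lambda_min - 1 / src$lambda_max)
  s_i <- 1 / inv - src$lambda_min
  lambda_i <- src$lambda_min + s_i
  k <- 2 * pi / lambda_i
  attr(k, "delta_k") <- (k[M] - k[1]) / (M - 1)
  attr(k, "lambda_nm") <- lambda_i
  k
}

#' Wavenumber grid in rad/mm
#'
#' @inheritParams resample_wavenumbers
#' @return evenly spaced wavenumbers (rad/mm) with attribute `delta_k`
#'   (rad/mm).
#' @export
k_grid_mm <- function(src) {
  k <- resample_wavenumbers(src)
  out <- as.numeric(k) * 1e6
  attr(out, "delta_k") <- attr(k, "delta_k") * 1e6
  out
}

#' FWHM-derived wavenumber bandwidth
#'
#' Converts the FWHM wavelength bandwidth into the 1/e wavenumber half-width
#' of the Gaussian spectral envelope,
#' \eqn{\Delta k = (\pi/\sqrt{\ln 2})\, \Delta\lambda / \lambda_c^2}. This is
#' the convention under which a Gaussian
#' \eqn{G(k) = \exp[-((k - k_c)/\Delta k)^2]} has FWHM
#' \eqn{2\pi \Delta\lambda / \lambda_c^2} in k; `prefactor` can override it.
#'
#' @inheritParams resample_wavenumbers
#' @param prefactor multiplicative convention constant; default
#'   `pi / sqrt(log(2))`.
#' @return wavenumber bandwidth (rad/nm).
#' @export
wavenumber_bandwidth <- function(src, prefactor = pi / sqrt(log(2))) {
  stopifnot(inherits(src, "oct_source"))
  prefactor * src$bandwidth / src$lambda_c^2
}

#' Nyquist imaging depth of the spectral sampling
#'
#' \eqn{D = \lambda_c^2 / (4 \delta\lambda)}; the deepest depth the sampled
#' spectrum can encode without aliasing.
#'
#' @inheritParams resample_wavenumbers
#' @return imaging depth (mm).
#' @export
imaging_depth <- function(src) {
  stopifnot(inherits(src, "oct_source"))
  (src$lambda_c^2 / (4 * src$delta_lambda)) * 1e-6
}

# internal: geometry list handed to the C++ kernel
beam_to_cpp <- function(geom) {
  list(f = geom$f, d = geom$d, w0 = geom$w0, lambda = geom$lambda,
       n = geom$n, ws = geom$ws, wfp = geom$wfp, zR = geom$zR)
}
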