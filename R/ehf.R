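# Analytical extended-Huygens-Fresnel (EHF) forward model of the
# mean-squared heterodyne signal for a focused Gaussian beam in a single
# scattering layer. Serves both as the comparator for the Monte Carlo
# simulator and as the forward model of the inverse-fitting stage.

ehf_bounds <- function() {
  list(mu_s = c(1, 15), g = c(0.8, 1), p_b = c(0.001, 0.5), a = c(1e-3, 1e3))
}

#' EHF model parameters
#'
#' @param mu_s scattering coefficient (mm^-1).
#' @param g effective anisotropy factor.
#' @param p_b backscattering probability.
#' @param geometry an [beam_geometry()] object.
#' @param a multiplicative amplitude factor.
#' @param enforce_bounds check the inverse-fitting bounds
#'   (`1 <= mu_s <= 15`, `0.8 <= g <= 1`, `0.001 <= p_b <= 0.5`,
#'   `1e-3 <= a <= 1e3`); the forward model itself is defined for any
#'   `mu_s >= 0`.
#' @return object of class `ehf_params`.
#' @export
ehf_params <- function(mu_s, g, p_b, geometry, a = 1,
                       enforce_bounds = FALSE) {
  stopifnot(inherits(geometry, "oct_beam"))
  if (mu_s < 0 || g < 0 || g > 1 || p_b < 0 || p_b > 0.5 || a <= 0)
    abort("EHF parameters outside their physical domain",
          class = "octmc_config_error")
  if (enforce_bounds) {
    b <- ehf_bounds()
    ok <- mu_s >= b$mu_s[1] && mu_s <= b$mu_s[2] &&
      g >= b$g[1] && g <= b$g[2] &&
      p_b >= b$p_b[1] && p_b <= b$p_b[2] && a >= b$a[1] && a <= b$a[2]
    if (!ok) abort("EHF parameters outside the fitting bounds",
                   class = "octmc_config_error")
  }
  structure(list(mu_s = mu_s, g = g, p_b = p_b, geometry = geometry, a = a),
            class = "ehf_params")
}

# rms polar scattering angle of the small-angle forward lobe; the isotropic
# component is treated as loss from the forward-coherent channel, not as
# angular diffusion (see ehf_signal)
ehf_theta_rms <- function(g, p_b) {
  sqrt(2 * (1 - g))
}

#' Mean-squared heterodyne signal of the EHF model
#'
#' Single-layer EHF formulation for a focused Gaussian beam: the signal at
#' probing depth z is the product of the local backscattering strength
#' (proportional to `p_b`), the confocal geometric factor
#' \eqn{w_f^2 / w_H(z)^2}, and the heterodyne efficiency factor
#'
#' \deqn{\Psi(z) = B^2 + \frac{4 B F}{1 + w_S^2/w_H^2}
#'   + F^2 \frac{w_H^2}{w_S^2},}
#'
#' the sum of a ballistic, a cross and a multiple-forward-scattering term,
#' with \eqn{B = e^{-\mu_s z}} the ballistic survival amplitude and
#' \eqn{F = e^{-2 p_b \mu_s z} - e^{-\mu_s z}} the fraction of light that
#' has scattered at least once but only in the small-angle forward lobe:
#' the isotropic component of the phase function (probability `2 p_b` per
#' event) throws photons out of the forward-coherent channel and acts as
#' loss there, while supplying the local backscattering. For `p_b -> 0`
#' this reduces to the classic single-layer heterodyne efficiency factor.
#'
#' \eqn{w_H} is the 1/e irradiance radius of the probe beam at depth z in
#' the absence of scattering (ABCD propagation with reduced distance
#' `B = d + z/n`), and \eqn{w_S^2 = w_H^2 + (2B/(k\rho_0))^2} widens it by
#' the lateral coherence length
#' \eqn{\rho_0(z) = \sqrt{3/(\mu_s z)}\,(\lambda/(\pi\theta_{rms}))\,
#' (1 + n d / z)} of the multiply-forward-scattered light, with
#' \eqn{\theta_{rms} = \sqrt{2(1-g)}} the rms angle of the forward lobe;
#' the `1 + nd/z` factor is the shower-curtain lever arm (scattering far
#' from the observation plane degrades coherence less).
#'
#' @param params an [ehf_params()] object.
#' @param z depths (mm), strictly positive within the layer.
#' @return strictly positive signal values (linear scale), vectorized.
#' @export
ehf_signal <- function(params, z) {
  stopifnot(inherits(params, "ehf_params"))
  g <- params$geometry
  mu_s <- params$mu_s
  lambda <- g$lambda
  n <- g$n
  k <- 2 * pi * n / lambda # wavenumber in the medium (rad/mm)
  B <- g$d + z / n
  wH2 <- g$w0^2 * (1 - B / g$f)^2 + (B / (k * g$w0))^2
  if (mu_s > 0) {
    th <- ehf_theta_rms(params$g, params$p_b)
    rho0 <- sqrt(3 / (mu_s * z)) * (lambda / (pi * th)) * (1 + n * g$d / z)
    wS2 <- wH2 + (2 * B / (k * rho0))^2
    bal <- exp(-mu_s * z)
    fwd <- pmax(exp(-2 * params$p_b * mu_s * z) - bal, 0)
    psi <- bal^2 + 4 * bal * fwd / (1 + wS2 / wH2) + fwd^2 * wH2 / wS2
  } else {
    psi <- rep(1, length(z))
  }
  params$a * params$p_b * (g$wf^2 / wH2) * psi
}

#' Align a model curve to an A-scan in log space
#'
#' Finds the additive dB offset (equivalently the multiplicative factor a)
#' minimizing the mean squared error between `10 log10(model)` and the
#' A-scan; the least-squares offset is the mean residual.
#'
#' @param model linear-scale model values on the A-scan's depth grid.
#' @param ascan_db log A-scan values (dB).
#' @return list with `aligned` (dB), `offset_db`, and `mse`.
#' @export
align_to_ascan <- function(model, ascan_db) {
  if (length(model) != length(ascan_db))
    abort("model and A-scan must share a depth grid",
          class = "octmc_contract_error")
  if (any(model <= 0)) abort("model values must be positive",
                             class = "octmc_contract_error")
  mdb <- 10 * log10(model)
  if (sd(mdb) == 0 || sd(ascan_db) == 0)
    warn("degenerate (constant) input to alignment")
  offset <- mean(ascan_db - mdb)
  aligned <- mdb + offset
  list(aligned = aligned, offset_db = offset,
       mse = mean((aligned - ascan_db)^2))
}
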