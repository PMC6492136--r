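# Monte Carlo transport driver.

#' Run the Monte Carlo photon transport
#'
#' Launches `n_photons` packets from the Gaussian intensity profile of the
#' focused beam at the tissue surface, guides each along the wavefront
#' normals of the beam until its first scattering event, then propagates it
#' as a conventional layered Monte Carlo packet (exponential free paths,
#' weighted absorption, two-component small-angle phase function, Fresnel
#' boundaries, Russian roulette). Packets exiting the top surface are
#' returned as exit records for the detection stage.
#'
#' The photon-accounting tally is closed: launched weight equals the sum of
#' absorbed, bottom-transmitted, top-exited and roulette-terminated weight.
#' A relative gap above 1e-6 is a hard failure.
#'
#' @param config an [oct_config()] object.
#' @param seed optional seed overriding `config$run$seed`.
#' @param n_photons optional photon budget overriding `config$run$n_photons`.
#' @return object of class `oct_sim`: list with `exits` (tibble of exit
#'   records: weight, opl, path, x, y, ux, uy, uz — direction in air),
#'   `tally` (named numeric) and the `config`.
#' @examples
#' cfg <- oct_config(beam_geometry(0.5, 0, 0.1), source_spectrum(),
#'                   make_phantom("single_layer", mu_s = 5),
#'                   n_photons = 1000)
#' sim <- oct_simulate(cfg)
#' sim$tally
#' @export
oct_simulate <- function(config, seed = NULL, n_photons = NULL) {
  stopifnot(inherits(config, "oct_config"))
  seed <- as.integer(seed %||% config$run$seed)
  n <- as.integer(n_photons %||% config$run$n_photons)
  res <- cpp_run_transport(
    n_photons = n, seed = seed,
    layers = tissue_to_cpp(config$tissue),
    n_ambient = config$tissue$n_ambient,
    geom = beam_to_cpp(config$geometry),
    launch_mode = config$run$launch_mode,
    w_threshold = config$run$roulette_threshold,
    p_survive = config$run$survival_prob,
    h_max = config$run$rk_step_mm,
    mirror_z = config$tissue$mirror_z,
    mirror_refl = config$tissue$mirror_refl)
  tally <- res$tally
  gap <- abs(tally[["launched"]] -
               sum(tally[c("absorbed", "transmitted", "exited_top",
                           "rouletted")]))
  if (gap / tally[["launched"]] > 1e-6) {
    abort(paste0("photon tally does not close: ",
                 paste(sprintf("%s=%.8g", names(tally), tally),
                       collapse = ", ")),
          class = "octmc_conservation_error")
  }
  structure(list(exits = as_tibble(res$exits), tally = tally,
                 config = config, seed = seed),
            class = "oct_sim")
}

#' @export
print.oct_sim <- function(x, ...) {
  t <- x$tally
  cat(sprintf("<oct_sim> %d packets launched (seed %d)\n",
              as.integer(t[["launched"]]), x$seed))
  cat(sprintf("  exited top: %.4g  transmitted: %.4g  absorbed: %.4g  rouletted: %.4g\n",
              t[["exited_top"]], t[["transmitted"]], t[["absorbed"]],
              t[["rouletted"]]))
  cat(sprintf("  %d exit records\n", nrow(x$exits)))
  invisible(x)
}

#' Sample packet launch states
#'
#' Draws launch positions from the radially symmetric Gaussian intensity
#' with 1/e radius `ws` at the tissue surface, and directions along the
#' wavefront normal there. Exposed for distribution checks; the transport
#' kernel uses the same sampler.
#'
#' @param geom an [beam_geometry()] object.
#' @param n number of packets.
#' @param seed RNG seed.
#' @return tibble with `x`, `y`, `ux`, `uy`, `uz`.
#' @export
launch_photons <- function(geom, n, seed = 1) {
  as_tibble(cpp_launch(as.integer(n), beam_to_cpp(geom), as.integer(seed)))
}

#' Advance a ballistic packet along the curved beam trajectory
#'
#' Integrates the trajectory ODE (tangent = wavefront normal) with RK4
#' substeps no larger than `h_max` (refined near the focus) over a geometric
#' arc length `s`.
#'
#' @param geom an [beam_geometry()] object.
#' @param start numeric `c(x, y, z)` start position (mm).
#' @param s arc length to advance (mm).
#' @param h_max substep cap (mm).
#' @return list with `position` and `direction` (wavefront normal at the end
#'   point).
#' @export
ballistic_advance <- function(geom, start, s, h_max = 0.01) {
  stopifnot(s > 0)
  out <- cpp_ballistic_advance(as.numeric(start), s, beam_to_cpp(geom), h_max)
  list(position = out[1:3], direction = out[4:6])
}

#' Sample scattering angles from the two-component phase function
#'
#' With probability `2 p_b` the polar angle is uniform on `[0, pi]`
#' (isotropic backscattering component); otherwise `theta^2` is exponential
#' with mean `<theta^2> = 2 (1 - g)` truncated at `pi` (small-angle forward
#' lobe). The azimuth is uniform on `[0, 2 pi)`.
#'
#' @param n number of draws.
#' @param g anisotropy factor.
#' @param p_b backscattering probability.
#' @param seed RNG seed.
#' @return tibble with `theta`, `phi` (radians).
#' @export
sample_scattering_angles <- function(n, g, p_b, seed = 1) {
  as_tibble(cpp_sample_scatter(as.integer(n), g, p_b, as.integer(seed)))
}

#' MCML direction update
#'
#' Deflects unit direction(s) by polar angle `theta` with azimuth `phi`,
#' including the near-axial special case.
#'
#' @param dir numeric length-3 vector or n x 3 matrix of unit directions.
#' @param theta,phi deflection angles (radians), recycled.
#' @return matrix of rotated unit directions.
#' @export
rotate_direction <- function(dir, theta, phi) {
  if (is.null(dim(dir))) dir <- matrix(dir, nrow = 1)
  cpp_rotate_direction(dir, as.numeric(theta), as.numeric(phi))
}

#' Analytical density of the sampled polar scattering angle
#'
#' The density in theta implied by the sampler in
#' [sample_scattering_angles()]: a mixture of the uniform component
#' (weight `2 p_b`) and the truncated exponential-in-theta^2 forward lobe.
#' Used as the reference in goodness-of-fit tests.
#'
#' @inheritParams sample_scattering_angles
#' @param theta angles at which to evaluate (radians).
#' @return density values.
#' @export
phase_function_density <- function(theta, g, p_b) {
  s2 <- 2 * (1 - g)
  norm <- 1 - exp(-pi^2 / s2) # truncation mass of the forward lobe
  fwd <- (2 * theta / s2) * exp(-theta^2 / s2) / norm
  2 * p_b / pi + (1 - 2 * p_b) * fwd
}

#' @rdname phase_function_density
#' @export
phase_function_cdf <- function(theta, g, p_b) {
  s2 <- 2 * (1 - g)
  norm <- 1 - exp(-pi^2 / s2)
  fwd <- (1 - exp(-pmin(theta, pi)^2 / s2)) / norm
  2 * p_b * pmin(theta, pi) / pi + (1 - 2 * p_b) * fwd
}
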