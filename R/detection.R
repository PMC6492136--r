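# Photon detection: back-propagation of exiting packets through the 4F
# optics to the p'-plane conjugate to their scattering depth, and weight
# modulation by the reference-beam intensity there. A legacy acceptance-cone
# detector is provided for comparison.

#' Distance from the collimating lens to the p'-plane
#'
#' For a tissue discontinuity at geometric depth `z`, the plane in which the
#' back-propagated sample field is delta-correlated lies `2f - (d + z/n)` to
#' the left of the collimating lens L1 (the p'-to-q' separation is always
#' 4f). The scanned depth therefore cannot exceed `n (2f - d)`.
#'
#' @param geom an [beam_geometry()] object.
#' @param z geometric depth of the discontinuity (mm).
#' @return distance (mm).
#' @export
pprime_distance <- function(geom, z) {
  stopifnot(inherits(geom, "oct_beam"))
  dist <- 2 * geom$f - (geom$d + z / geom$n)
  if (any(z < 0) || any(dist < 0))
    abort(sprintf(
      "depth %g mm exceeds the p'-plane limit n(2f - d) = %g mm; use a larger f",
      max(z), geom$n * (2 * geom$f - geom$d)),
      class = "octmc_depth_limit_error")
  dist
}

#' Back-propagate exit rays to the p'-plane
#'
#' Traces each exiting ray through free space to the focusing lens, applies
#' the thin-lens ABCD transforms of the 4F telescope (two lenses of focal
#' length f separated by 2f) and propagates the remaining `2f - (d + z/n)`
#' to the p'-plane of effective depth `z_eff`. The composed ray transfer
#' matrix reduces to `[[-1, z/n], [0, -1]]`: the p'-plane is the unit
#' (inverted) conjugate of the depth-z plane.
#'
#' @param exits tibble with exit state columns `x`, `y`, `ux`, `uy`, `uz`
#'   (direction in air, `uz < 0` for upward travel).
#' @param geom an [beam_geometry()] object.
#' @param z_eff effective scattering depth(s) (mm), recycled.
#' @return tibble with transverse p'-plane coordinates `px`, `py` (mm).
#' @export
backpropagate_to_pprime <- function(exits, geom, z_eff) {
  stopifnot(inherits(geom, "oct_beam"))
  if (any(exits$uz >= 0))
    abort("exit directions must point upward (uz < 0)",
          class = "octmc_contract_error")
  # ray slope per unit distance travelled toward the detector
  tx <- exits$ux / (-exits$uz)
  ty <- exits$uy / (-exits$uz)
  zr <- z_eff / geom$n
  tibble(px = -exits$x + zr * tx, py = -exits$y + zr * ty)
}

#' Reference-beam intensity in the p'-plane
#'
#' \eqn{I_R(p) = (1/w_{p'}^2) \exp(-\|p\|^2 / w_{p'}^2)}; its integral over
#' the plane is \eqn{\pi} for any radius.
#'
#' @param px,py transverse position (mm).
#' @param w_pprime 1/e intensity radius of the reference beam in the
#'   p'-plane (mm).
#' @return intensity (mm^-2).
#' @export
reference_intensity <- function(px, py, w_pprime) {
  if (any(w_pprime <= 0))
    abort("w_pprime must be positive", class = "octmc_config_error")
  (1 / w_pprime^2) * exp(-(px^2 + py^2) / w_pprime^2)
}

#' Reference-beam radius in the p'-plane
#'
#' The reference beam arrives collimated with radius `w0` at the lens plane
#' and is focused by the collimating lens on its way back toward the fiber;
#' its waist there is the fiber-mode radius `wf_air = lambda f/(2 pi w0)` at
#' the p-plane. The p'-plane for depth `z` sits `Delta = d + z/n - f` beyond
#' that waist, so the reference radius there is the Gaussian-beam envelope
#' \eqn{w_{p'}(z) = w_f \sqrt{1 + (\Delta/z_{R,f})^2}} with
#' \eqn{z_{R,f} = 2\pi w_f^2/\lambda}. For an index-matched medium this
#' equals the ballistic sample-beam radius at depth z imaged onto its
#' conjugate plane, which is what makes the weight-modulated sum estimate
#' the heterodyne signal with the correct confocal depth dependence.
#'
#' @param geom an [beam_geometry()] object.
#' @param z_eff effective depth(s) (mm).
#' @return radius (mm), vectorized over `z_eff`.
#' @export
reference_waist <- function(geom, z_eff) {
  stopifnot(inherits(geom, "oct_beam"))
  delta <- geom$d + z_eff / geom$n - geom$f
  zRf <- 2 * pi * geom$wf_air^2 / geom$lambda
  geom$wf_air * sqrt(1 + (delta / zRf)^2)
}

#' Classify and weight exiting packets
#'
#' Applies the detection scheme to the exit records of [oct_simulate()].
#'
#' With `scheme = "pprime"` each packet's effective scattering depth
#' `z_eff` (half its geometric in-medium path length, i.e. the round-trip
#' depth implied by its optical path) selects the conjugate p'-plane; the
#' exit ray is back-propagated there and the packet weight is modulated by
#' the reference-beam intensity, normalized by its global (focal-plane,
#' on-axis) peak so that recorded weights never exceed the transport weight.
#' Packets whose `z_eff` exceeds the `n (2f - d)` limit are rejected and
#' counted.
#'
#' With `scheme = "mcml_cone"` a packet is detected, with unmodulated
#' weight, iff its exit radius is at most `fiber_radius_mm` (default: the
#' focal waist `wf_air`) and its exit angle at most `atan(w0 / f)`
#' (inclusive boundaries).
#'
#' @param exits exit-record tibble from [oct_simulate()] (or an `oct_sim`
#'   object).
#' @param geom an [beam_geometry()] object (taken from the sim when an
#'   `oct_sim` is given).
#' @param scheme `"pprime"` or `"mcml_cone"`.
#' @param w_pprime_mm optional fixed reference radius overriding the
#'   depth-dependent [reference_waist()].
#' @param fiber_radius_mm collection fiber radius for the cone scheme (mm).
#' @return tibble of detection records (`weight`, `opl`, `z_eff`) with
#'   attribute `counts`: named vector of `detected`, `rejected_depth`,
#'   `rejected_aperture` and `n_exits`.
#' @export
detect_photons <- function(exits, geom = NULL,
                           scheme = c("pprime", "mcml_cone"),
                           w_pprime_mm = NULL, fiber_radius_mm = NULL) {
  if (inherits(exits, "oct_sim")) {
    geom <- geom %||% exits$config$geometry
    exits <- exits$exits
  }
  stopifnot(inherits(geom, "oct_beam"))
  scheme <- match.arg(scheme)
  n_ex <- nrow(exits)
  if (n_ex == 0) {
    out <- tibble(weight = numeric(), opl = numeric(), z_eff = numeric())
    attr(out, "counts") <- c(detected = 0, rejected_depth = 0,
                             rejected_aperture = 0, n_exits = 0)
    return(out)
  }
  if (scheme == "pprime") {
    z_eff <- exits$path / 2
    z_max <- geom$n * (2 * geom$f - geom$d)
    ok <- z_eff <= z_max
    kept <- exits[ok, ]
    zk <- z_eff[ok]
    p <- backpropagate_to_pprime(kept, geom, zk)
    wp <- if (!is.null(w_pprime_mm) && is.finite(w_pprime_mm)) {
      rep(w_pprime_mm, nrow(kept))
    } else {
      reference_waist(geom, zk)
    }
    # Eq. 17 intensity normalized by its global on-axis peak 1/min(w_pprime)^2
    ir <- reference_intensity(p$px, p$py, wp) * min(wp)^2
    out <- tibble(weight = kept$weight * ir, opl = kept$opl, z_eff = zk)
    counts <- c(detected = nrow(kept), rejected_depth = sum(!ok),
                rejected_aperture = 0, n_exits = n_ex)
  } else {
    fr <- fiber_radius_mm %||% geom$wf_air
    theta_max <- atan(geom$w0 / geom$f)
    r_exit <- sqrt(exits$x^2 + exits$y^2)
    # inclusive angle cut, compared on the cosine scale for robustness at
    # the exact boundary
    ok <- (r_exit <= fr) & (-exits$uz >= cos(theta_max))
    kept <- exits[ok, ]
    out <- tibble(weight = kept$weight, opl = kept$opl,
                  z_eff = kept$path / 2)
    counts <- c(detected = sum(ok), rejected_depth = 0,
                rejected_aperture = sum(!ok), n_exits = n_ex)
  }
  attr(out, "counts") <- counts
  out
}

#' Detected-packet ratio of a simulation
#'
#' Fraction of launched packets that pass the detection scheme, as a
#' percentage.
#'
#' @param sim an `oct_sim` object.
#' @param ... passed to [detect_photons()].
#' @return percentage (scalar).
#' @export
detection_ratio <- function(sim, ...) {
  stopifnot(inherits(sim, "oct_sim"))
  det <- detect_photons(sim, ...)
  counts <- attr(det, "counts")
  100 * counts[["detected"]] / sim$tally[["launched"]]
}
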