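# Deterministic phantom generators used throughout the tests and examples.

#' Standard tissue phantoms
#'
#' * `single_layer`: one homogeneous 1 mm layer with the given optical
#'   properties (the workhorse of the parameter-recovery protocol);
#' * `two_layer`: 0.4 mm of (mu_s = 2, g = 0.95, p_b = 0.05) over 0.6 mm of
#'   (mu_s = 5, g = 0.98, p_b = 0.1), the layered demonstration phantom;
#' * `mirror_at`: a non-scattering, index-matched medium with a perfect
#'   specular reflector plane at `z0_mm` — not a biological phantom but a
#'   calibration fixture with an analytically known A-scan peak (every
#'   returned packet has optical path length `2 n z0`).
#'
#' @param kind one of `"single_layer"`, `"two_layer"`, `"mirror_at"`.
#' @param mu_s,g,p_b single-layer optical properties.
#' @param depth_mm total phantom depth (mm).
#' @param n refractive index.
#' @param z0_mm reflector depth for `mirror_at`.
#' @return an [tissue_model()] object.
#' @export
make_phantom <- function(kind = c("single_layer", "two_layer", "mirror_at"),
                         mu_s = 10, g = 0.95, p_b = 0.01, depth_mm = 1,
                         n = 1, z0_mm = 0.4) {
  kind <- match.arg(kind)
  switch(kind,
    single_layer = tissue_model(
      tissue_layer(mu_s = mu_s, g = g, p_b = p_b, n = n,
                   thickness_mm = depth_mm)),
    two_layer = tissue_model(
      tissue_layer(mu_s = 2, g = 0.95, p_b = 0.05, n = n, thickness_mm = 0.4),
      tissue_layer(mu_s = 5, g = 0.98, p_b = 0.1, n = n,
                   thickness_mm = depth_mm - 0.4)),
    mirror_at = tissue_model(
      tissue_layer(mu_s = 0, g = 0, p_b = 0, n = n, thickness_mm = depth_mm),
      mirror_z_mm = z0_mm)
  )
}

#' The 18-tissue parameter grid
#'
#' Enumerates the full crossing of mu_s in {1, 5, 10} mm^-1 (very low, low,
#' high scattering), g in {0.9, 0.95, 0.98} (wide-angle to highly forward
#' scattering) and p_b in {0.01, 0.1} (low / highly diffusive
#' backscattering) used by the recovery protocol.
#'
#' @return tibble with columns `mu_s`, `g`, `p_b` (18 rows).
#' @export
phantom_grid <- function() {
  tidyr::expand_grid(mu_s = c(1, 5, 10), g = c(0.9, 0.95, 0.98),
                     p_b = c(0.01, 0.1))
}
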