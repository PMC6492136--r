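# Multilayered tissue representation and Fresnel boundary physics.

#' Define one tissue layer
#'
#' @param mu_s scattering coefficient (mm^-1).
#' @param g anisotropy factor, `0 <= g < 1`.
#' @param p_b backscattering probability, `0 <= p_b <= 0.5` (weight of the
#'   isotropic component of the two-part small-angle phase function).
#' @param mu_a absorption coefficient (mm^-1); zero by default, matching the
#'   usual tissue regime where absorption is far weaker than scattering.
#' @param n refractive index (>= 1).
#' @param thickness_mm layer thickness (mm).
#' @return one-row tibble describing the layer.
#' @export
tissue_layer <- function(mu_s, g, p_b, mu_a = 0, n = 1, thickness_mm) {
  bad <- character()
  if (mu_s < 0) bad <- c(bad, "mu_s must be >= 0")
  if (mu_a < 0) bad <- c(bad, "mu_a must be >= 0")
  if (g < 0 || g >= 1) bad <- c(bad, "g must be in [0, 1)")
  if (p_b < 0 || p_b > 0.5) bad <- c(bad, "p_b must be in [0, 0.5]")
  if (n < 1) bad <- c(bad, "n must be >= 1")
  if (!is.finite(thickness_mm) || thickness_mm <= 0)
    bad <- c(bad, "thickness_mm must be > 0")
  if (length(bad) > 0)
    abort(paste0("invalid layer: ", paste(bad, collapse = "; ")),
          class = "octmc_config_error")
  tibble(mu_s = mu_s, mu_a = mu_a, g = g, p_b = p_b, n = n,
         thickness = thickness_mm)
}

#' Assemble a multilayered tissue model
#'
#' Layers are stacked top to bottom; `z = 0` is the top surface and z
#' increases downward. The lateral extent is infinite. An optional perfect
#' specular reflector plane (`mirror_z_mm`) may be embedded for calibration
#' phantoms.
#'
#' @param ... [tissue_layer()] rows (or a single tibble of layers).
#' @param n_ambient refractive index of the medium above (and below) the
#'   tissue.
#' @param mirror_z_mm optional depth of an embedded specular reflector plane
#'   (mm).
#' @param mirror_refl reflectivity of that plane in `[0, 1]`.
#' @return object of class `oct_tissue`: a list with the layers tibble
#'   (augmented with `z_top`/`z_bot` boundaries), `n_ambient`, and mirror
#'   fields.
#' @export
tissue_model <- function(..., n_ambient = 1, mirror_z_mm = NA_real_,
                         mirror_refl = 1) {
  parts <- list(...)
  layers <- dplyr::bind_rows(parts)
  if (nrow(layers) < 1)
    abort("a tissue model needs at least one layer",
          class = "octmc_config_error")
  layers$z_bot <- cumsum(layers$thickness)
  layers$z_top <- layers$z_bot - layers$thickness
  if (any(diff(c(0, layers$z_bot)) <= 0))
    abort("layer boundaries must be strictly increasing",
          class = "octmc_config_error")
  if (!is.na(mirror_z_mm) &&
      (mirror_z_mm <= 0 || mirror_z_mm >= max(layers$z_bot)))
    abort("mirror_z_mm must lie strictly inside the tissue",
          class = "octmc_config_error")
  structure(list(layers = layers, n_ambient = n_ambient,
                 mirror_z = mirror_z_mm, mirror_refl = mirror_refl,
                 depth = max(layers$z_bot)),
            class = "oct_tissue")
}

#' @export
print.oct_tissue <- function(x, ...) {
  cat(sprintf("<oct_tissue> %d layer(s), depth %.3g mm, ambient n = %g\n",
              nrow(x$layers), x$depth, x$n_ambient))
  print(x$layers)
  if (!is.na(x$mirror_z))
    cat(sprintf("  specular reflector at z = %g mm (R = %g)\n",
                x$mirror_z, x$mirror_refl))
  invisible(x)
}

#' Look up the layer containing a depth
#'
#' Layers occupy half-open intervals `[z_top, z_bot)`: at an interior
#' boundary the layer below is returned. `z` equal to the total depth is out
#' of domain (the photon has exited).
#'
#' @param tissue an [tissue_model()] object.
#' @param z depth (mm).
#' @return list with `layer` (one-row tibble), `index`, and signed distances
#'   `to_upper` (<= 0) and `to_lower` (> 0).
#' @export
layer_at <- function(tissue, z) {
  stopifnot(inherits(tissue, "oct_tissue"))
  if (length(z) != 1 || !is.finite(z) || z < 0 || z >= tissue$depth)
    abort(sprintf("depth z = %g outside [0, %g)", z, tissue$depth),
          class = "octmc_domain_error")
  i <- findInterval(z, c(0, tissue$layers$z_bot), rightmost.closed = FALSE)
  lay <- tissue$layers[i, ]
  list(layer = lay, index = i,
       to_upper = lay$z_top - z, to_lower = lay$z_bot - z)
}

#' Fresnel interaction at a refractive-index boundary
#'
#' Computes the unpolarized Fresnel reflectance (mean of the s and p
#' polarizations) for the incidence angle implied by `direction`, then either
#' reflects the packet (z-component negated) with that probability or
#' transmits it with the direction refracted by Snell's law. Beyond the
#' critical angle the packet always reflects.
#'
#' @param n1,n2 refractive indices on the incident and far side.
#' @param direction unit direction vector (its z-component must be nonzero).
#' @param u optional uniform deviate in `[0, 1)` deciding the branch (useful
#'   for deterministic tests); drawn from R's RNG when `NULL`.
#' @return list with `action` ("reflect" or "transmit"), the new unit
#'   `direction`, and the `reflectance` used.
#' @export
fresnel_interaction <- function(n1, n2, direction, u = NULL) {
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-9)
    abort("direction must be a unit vector", class = "octmc_contract_error")
  if (direction[3] == 0)
    abort("direction must have a nonzero z-component at a boundary",
          class = "octmc_contract_error")
  cos_i <- abs(direction[3])
  R <- cpp_fresnel_reflectance(n1, n2, cos_i)
  if (is.null(u)) u <- stats::runif(1)
  if (u < R) {
    list(action = "reflect",
         direction = c(direction[1], direction[2], -direction[3]),
         reflectance = R)
  } else {
    sin_i2 <- 1 - cos_i^2
    sin_t <- n1 / n2 * sqrt(sin_i2)
    scale <- if (sin_i2 < 1e-30) 0 else sin_t / sqrt(sin_i2)
    dir <- c(direction[1] * scale, direction[2] * scale,
             sign(direction[3]) * sqrt(max(0, 1 - sin_t^2)))
    list(action = "transmit", direction = dir, reflectance = R)
  }
}

# internal: layers matrix for the C++ kernel
tissue_to_cpp <- function(tissue) {
  L <- tissue$layers
  as.matrix(L[, c("mu_s", "mu_a", "g", "p_b", "n", "z_top", "z_bot")])
}
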