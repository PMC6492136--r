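# Run configuration: construction, YAML loading, validation.

default_run <- function() {
  list(n_photons = 1e5L, seed = 1L, n_ascans = 10L,
       roulette_threshold = 1e-4, survival_prob = 0.1,
       launch_mode = "surface", rk_step_mm = 0.01)
}

default_detection <- function() {
  list(scheme = "pprime", w_pprime_mm = NA_real_, fiber_radius_mm = NA_real_)
}

#' Assemble a validated simulation configuration
#'
#' Bundles the sample-arm optics, the light source, the tissue phantom, the
#' run controls and the detection scheme into one validated object consumed
#' by [oct_simulate()] and [oct_ascan()].
#'
#' @param geometry an [beam_geometry()] object (its `n` is overwritten by the
#'   first tissue layer's index).
#' @param source an [source_spectrum()] object.
#' @param tissue an [tissue_model()] object.
#' @param n_photons photon packets per A-scan.
#' @param seed base RNG seed (integer); every source of randomness in a run
#'   derives from it, and per-photon substreams make runs bit-reproducible.
#' @param n_ascans number of independent A-scans averaged into one profile.
#' @param scan_range_mm reconstructed depth range (mm); must not exceed the
#'   Nyquist imaging depth of the source.
#' @param roulette_threshold,survival_prob Russian-roulette controls.
#' @param launch_mode `"surface"` (default; packets sampled directly on the
#'   tissue surface) or `"lens"` (packets arrive through the air and are
#'   subject to specular surface reflection).
#' @param rk_step_mm cap on the Runge-Kutta substep of the ballistic
#'   trajectory integrator (further refined automatically near the focus).
#' @param detection list with `scheme` (`"pprime"` or `"mcml_cone"`) and
#'   optional overrides `w_pprime_mm`, `fiber_radius_mm`.
#' @return object of class `oct_config`.
#' @export
oct_config <- function(geometry, source, tissue,
                       n_photons = 1e5, seed = 1, n_ascans = 10,
                       scan_range_mm = 1,
                       roulette_threshold = 1e-4, survival_prob = 0.1,
                       launch_mode = c("surface", "lens"), rk_step_mm = 0.01,
                       detection = default_detection()) {
  stopifnot(inherits(geometry, "oct_beam"), inherits(source, "oct_source"),
            inherits(tissue, "oct_tissue"))
  launch_mode <- match.arg(launch_mode)
  errs <- character()
  if (n_photons < 1) errs <- c(errs, "run.n_photons must be >= 1")
  if (n_ascans < 1) errs <- c(errs, "run.n_ascans must be >= 1")
  if (survival_prob <= 0 || survival_prob > 1)
    errs <- c(errs, "run.survival_prob must be in (0, 1]")
  if (roulette_threshold < 0)
    errs <- c(errs, "run.roulette_threshold must be >= 0")
  if (rk_step_mm <= 0) errs <- c(errs, "run.rk_step_mm must be > 0")
  if (scan_range_mm <= 0) errs <- c(errs, "scan.range_mm must be > 0")
  D <- imaging_depth(source)
  n1 <- tissue$layers$n[1]
  if (scan_range_mm * n1 > D)
    errs <- c(errs, sprintf(
      "scan.range_mm (%g mm optical) exceeds the imaging depth D = %.3g mm",
      scan_range_mm * n1, D))
  if (!detection$scheme %in% c("pprime", "mcml_cone"))
    errs <- c(errs, "detection.scheme must be 'pprime' or 'mcml_cone'")
  if (length(errs) > 0)
    abort(paste0("invalid configuration:\n  - ",
                 paste(errs, collapse = "\n  - ")),
          class = "octmc_config_error")
  # the beam propagates in the first layer's medium
  geometry <- beam_geometry(geometry$f, geometry$d, geometry$w0,
                            geometry$lambda_nm, n = n1)
  structure(list(geometry = geometry, source = source, tissue = tissue,
                 run = list(n_photons = as.integer(n_photons),
                            seed = as.integer(seed),
                            n_ascans = as.integer(n_ascans),
                            roulette_threshold = roulette_threshold,
                            survival_prob = survival_prob,
                            launch_mode = launch_mode,
                            rk_step_mm = rk_step_mm),
                 scan_range = scan_range_mm,
                 detection = detection),
            class = "oct_config")
}

#' @export
print.oct_config <- function(x, ...) {
  cat("<oct_config>\n")
  print(x$geometry); print(x$source); print(x$tissue)
  cat(sprintf("  run: %d photons x %d A-scans, seed %d, %s launch, %s detection\n",
              x$run$n_photons, x$run$n_ascans, x$run$seed,
              x$run$launch_mode, x$detection$scheme))
  invisible(x)
}

#' Load a configuration from a YAML file
#'
#' Recognised blocks and keys (unknown keys are rejected):
#' `optics: f_mm, d_mm, w0_mm`;
#' `source: lambda_c_nm, bandwidth_nm, cells, delta_lambda_nm, lambda_min_nm`;
#' `tissue: layers: [{mu_s_mm, mu_a_mm, g, p_b, n, thickness_mm}, ...],
#'  ambient_n, mirror_z_mm, mirror_refl`;
#' `run: n_photons, seed, n_ascans, roulette_threshold, survival_prob,
#'  launch_mode, rk_step_mm`;
#' `scan: range_mm`;
#' `detection: scheme, w_pprime_mm, fiber_radius_mm`.
#'
#' @param path YAML file path.
#' @return an [oct_config()] object.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("optics", "source", "tissue", "run", "scan", "detection")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    abort(paste0("unknown config blocks: ", paste(extra, collapse = ", ")),
          class = "octmc_config_error")
  check_keys <- function(block, allowed, where) {
    extra <- setdiff(names(block), allowed)
    if (length(extra) > 0)
      abort(paste0("unknown keys in ", where, ": ",
                   paste(extra, collapse = ", ")),
            class = "octmc_config_error")
  }
  opt <- raw$optics %||% list()
  check_keys(opt, c("f_mm", "d_mm", "w0_mm"), "optics")
  src <- raw$source %||% list()
  check_keys(src, c("lambda_c_nm", "bandwidth_nm", "cells",
                    "delta_lambda_nm", "lambda_min_nm"), "source")
  tis <- raw$tissue %||% list()
  check_keys(tis, c("layers", "ambient_n", "mirror_z_mm", "mirror_refl"),
             "tissue")
  if (is.null(tis$layers) || length(tis$layers) == 0)
    abort("tissue.layers must list at least one layer",
          class = "octmc_config_error")
  layers <- purrr::map(tis$layers, function(l) {
    check_keys(l, c("mu_s_mm", "mu_a_mm", "g", "p_b", "n", "thickness_mm"),
               "tissue.layers[[i]]")
    tissue_layer(mu_s = l$mu_s_mm, mu_a = l$mu_a_mm %||% 0, g = l$g,
                 p_b = l$p_b, n = l$n %||% 1, thickness_mm = l$thickness_mm)
  })
  tissue <- tissue_model(dplyr::bind_rows(layers),
                         n_ambient = tis$ambient_n %||% 1,
                         mirror_z_mm = tis$mirror_z_mm %||% NA_real_,
                         mirror_refl = tis$mirror_refl %||% 1)
  run <- utils::modifyList(default_run(), raw$run %||% list())
  check_keys(raw$run %||% list(), names(default_run()), "run")
  det <- utils::modifyList(default_detection(), raw$detection %||% list())
  check_keys(raw$detection %||% list(), names(default_detection()),
             "detection")
  scan <- raw$scan %||% list()
  check_keys(scan, "range_mm", "scan")
  source <- source_spectrum(
    lambda_c_nm = src$lambda_c_nm %||% 1300,
    bandwidth_nm = src$bandwidth_nm %||% 95,
    n_cells = src$cells %||% 2048,
    delta_lambda_nm = src$delta_lambda_nm %||% 0.055,
    lambda_min_nm = src$lambda_min_nm)
  geometry <- beam_geometry(f_mm = opt$f_mm %||% 0.5, d_mm = opt$d_mm %||% 0,
                            w0_mm = opt$w0_mm %||% 0.1,
                            lambda_nm = src$lambda_c_nm %||% 1300)
  oct_config(geometry, source, tissue,
             n_photons = run$n_photons, seed = run$seed,
             n_ascans = run$n_ascans,
             scan_range_mm = scan$range_mm %||% 1,
             roulette_threshold = run$roulette_threshold,
             survival_prob = run$survival_prob,
             launch_mode = run$launch_mode, rk_step_mm = run$rk_step_mm,
             detection = det)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
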