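# High-level drivers: configuration -> A-scan(s).

#' Simulate one A-scan
#'
#' Full pipeline for a single depth profile: Monte Carlo transport,
#' detection, spectral accumulation on the resampled wavenumber grid,
#' interference with the reference spectrum, and inverse-Fourier
#' reconstruction.
#'
#' @param config an [oct_config()] object.
#' @param seed RNG seed for this A-scan (defaults to the config seed).
#' @param keep_records also return the detection records.
#' @return an `oct_ascan` tibble (see [reconstruct_ascan()]) with
#'   attributes `alpha`, `detected_ratio_pct`, `tally` and optionally
#'   `records`.
#' @export
simulate_ascan <- function(config, seed = NULL, keep_records = FALSE) {
  stopifnot(inherits(config, "oct_config"))
  sim <- oct_simulate(config, seed = seed)
  det <- detect_photons(sim, scheme = config$detection$scheme,
                        w_pprime_mm = config$detection$w_pprime_mm,
                        fiber_radius_mm = config$detection$fiber_radius_mm)
  k <- k_grid_mm(config$source)
  kc <- 2 * pi / (config$source$lambda_c * 1e-6)
  dk <- wavenumber_bandwidth(config$source) * 1e6
  G <- source_envelope(k, kc, dk)
  S <- accumulate_spectrum(det, k, G)
  ID <- interfere(S, G)
  asc <- reconstruct_ascan(ID, config$source,
                           scan_range_mm = config$scan_range,
                           n_medium = config$tissue$layers$n[1])
  attr(asc, "alpha") <- attr(ID, "alpha")
  attr(asc, "detected_ratio_pct") <-
    100 * attr(det, "counts")[["detected"]] / sim$tally[["launched"]]
  attr(asc, "tally") <- sim$tally
  if (keep_records) attr(asc, "records") <- det
  asc
}

# deterministic sub-seed for A-scan j of a run seeded with `seed`
subscan_seed <- function(seed, j) {
  as.integer((as.double(seed) * 131071 + j * 2654435) %% 2147483647)
}

#' Simulate an averaged A-scan
#'
#' Runs `n_ascans` independent A-scans (a B-scan's worth of laterally
#' adjacent profiles, here realized as independent seeds) and averages their
#' base-10 log intensities, the standard speckle-reduction protocol. This is
#' the profile the inverse-fitting stage consumes.
#'
#' @param config an [oct_config()] object.
#' @param seed base seed (defaults to the config seed); sub-scan j uses a
#'   seed derived deterministically from `(seed, j)`.
#' @param normalize subtract the z = 0 value (0 dB at the surface).
#' @param mode averaging mode passed to [average_bscan()]: `"log"` (mean of
#'   log profiles, the classic protocol) or `"intensity"` (log of the mean
#'   intensity, preferred at small photon budgets).
#' @return an `oct_ascan_avg` tibble with attribute `detected_ratio_pct`
#'   (mean over sub-scans) and `ascans` (the individual profiles).
#' @examples
#' \donttest{
#' cfg <- oct_config(beam_geometry(0.5, 0, 0.1), source_spectrum(),
#'                   make_phantom("single_layer", mu_s = 5),
#'                   n_photons = 2e4, n_ascans = 4)
#' avg <- oct_ascan(cfg)
#' }
#' @export
oct_ascan <- function(config, seed = NULL, normalize = FALSE,
                      mode = c("log", "intensity")) {
  stopifnot(inherits(config, "oct_config"))
  seed <- seed %||% config$run$seed
  ascans <- purrr::map(seq_len(config$run$n_ascans), function(j) {
    simulate_ascan(config, seed = subscan_seed(seed, j))
  })
  avg <- average_bscan(ascans, normalize = normalize, mode = mode)
  attr(avg, "detected_ratio_pct") <-
    mean(vapply(ascans, attr, numeric(1), "detected_ratio_pct"))
  attr(avg, "ascans") <- ascans
  avg
}

#' @export
autoplot.oct_ascan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth_mm,
                                       y = 10 * log10(.data$intensity))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (mm)", y = "intensity (dB)",
                  title = "Simulated A-scan")
}

#' @export
autoplot.oct_ascan_avg <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth_mm, y = .data$log_db)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (mm)", y = "mean 10 log10 intensity (dB)",
                  title = "Averaged A-scan")
}
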