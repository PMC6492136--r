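# FDOCT signal formation: spectral accumulation, interference, and A-scan
# reconstruction.

#' Gaussian spectral envelope of the source
#'
#' \eqn{G(k) = \exp[-((k - k_c)/\Delta k)^2]}, peak-normalized. In
#' swept-source mode the envelope is flat (all ones).
#'
#' @param k wavenumber grid (any consistent unit).
#' @param k_c central wavenumber (same unit).
#' @param delta_k wavenumber bandwidth (same unit).
#' @param ssoct if `TRUE`, return a flat (unit) envelope.
#' @return numeric vector of envelope values in `(0, 1]`.
#' @export
source_envelope <- function(k, k_c, delta_k, ssoct = FALSE) {
  if (ssoct) return(rep(1, length(k)))
  if (delta_k <= 0) abort("delta_k must be > 0", class = "octmc_config_error")
  exp(-((k - k_c) / delta_k)^2)
}

#' Accumulate the sample-arm spectrum from detection records
#'
#' \eqn{S(k) = G(k) \sum_i A_i \exp(2 i k z_i)} with \eqn{z_i} half the
#' optical path length of record i. By default the per-record amplitude is
#' the square root of the detected weight, so that the squared-magnitude
#' reconstruction estimates the weight sum per depth bin — the quantity the
#' detection scheme defines as the mean-squared heterodyne signal, and the
#' same quantity a time-domain simulation accumulates. Set
#' `amplitude = "weight"` to use the detected weight directly as the field
#' amplitude. Summation is compensated, so accumulation order does not
#' affect the result.
#'
#' @param records detection-record tibble (`weight`, `opl` in mm).
#' @param k wavenumber grid in rad/mm (see [k_grid_mm()]).
#' @param G spectral envelope on `k` (from [source_envelope()]), or `NULL`
#'   for flat.
#' @param amplitude `"sqrt_weight"` (default) or `"weight"`.
#' @return complex vector `S(k)`.
#' @export
accumulate_spectrum <- function(records, k, G = NULL,
                                amplitude = c("sqrt_weight", "weight")) {
  amplitude <- match.arg(amplitude)
  if (length(k) == 0) abort("empty wavenumber grid",
                            class = "octmc_contract_error")
  if (is.null(G)) G <- rep(1, length(k))
  if (nrow(records) == 0) {
    warn("no detection records; returning a zero spectrum")
    return(complex(real = numeric(length(k)), imaginary = numeric(length(k))))
  }
  amp <- switch(amplitude, sqrt_weight = sqrt(records$weight),
                weight = records$weight)
  S <- cpp_accumulate_spectrum(amp, records$opl / 2, as.numeric(k))
  G * S
}

#' Interfere sample and reference spectra
#'
#' \eqn{I_D(k) = |S + R|^2 - |S - R|^2}, algebraically equal to
#' \eqn{4\,\mathrm{Re}(S \bar R)}. The reference spectrum is
#' \eqn{R(k) = \alpha G(k)} with alpha solved so the total sample power
#' sits at the geometric midpoint of the admissible band
#' `power_band` (sample power between 0.001% and 0.01% of the reference
#' power); a caller-supplied `alpha` outside that band triggers a warning
#' with the computed ratio.
#'
#' @param S complex sample spectrum.
#' @param G real spectral envelope (same length).
#' @param alpha optional reference amplitude scale; solved when `NULL`.
#' @param power_band admissible `sum|S|^2 / sum|R|^2` interval.
#' @return numeric `I_D(k)` with attribute `alpha`.
#' @export
interfere <- function(S, G, alpha = NULL, power_band = c(1e-5, 1e-4)) {
  if (length(S) != length(G))
    abort("S and G must have the same length", class = "octmc_contract_error")
  pS <- sum(Mod(S)^2)
  pG <- sum(G^2)
  if (is.null(alpha)) {
    target <- sqrt(prod(power_band)) # midpoint of the band, log scale
    alpha <- if (pS > 0) sqrt(pS / (target * pG)) else 1
  }
  ratio <- pS / (alpha^2 * pG)
  if (pS > 0 && (ratio < power_band[1] || ratio > power_band[2]))
    warn(sprintf("sample/reference power ratio %.3g outside [%g, %g]",
                 ratio, power_band[1], power_band[2]))
  R <- alpha * G
  ID <- Mod(S + R)^2 - Mod(S - R)^2
  attr(ID, "alpha") <- alpha
  ID
}

#' Reconstruct an A-scan from the interference spectrum
#'
#' Multiplies `I_D(k)` by a Hamming window
#' (\eqn{0.54 - 0.46 \cos(2\pi m/(M-1))}), applies the inverse discrete
#' Fourier transform with k as the transform variable, and takes the squared
#' magnitude as the depth-resolved intensity. Bin m maps to optical depth
#' \eqn{z_m = \pi m / (M\,\delta k)}; the depth axis is divided by
#' `n_medium` to display geometric depth, and the profile is truncated to
#' `scan_range_mm` (which must not exceed the Nyquist imaging depth).
#'
#' @param I_D interference spectrum on the uniform k grid.
#' @param src an [source_spectrum()] object (defines `M` and `delta_k`).
#' @param scan_range_mm geometric depth range to keep (mm).
#' @param n_medium refractive index used to label geometric depth.
#' @return tibble of class `oct_ascan` with `depth_mm` and `intensity`;
#'   attributes `bin_mm` (depth bin width) and `n_medium`.
#' @export
reconstruct_ascan <- function(I_D, src, scan_range_mm = 1, n_medium = 1) {
  stopifnot(inherits(src, "oct_source"))
  M <- src$M
  if (length(I_D) != M)
    abort("I_D length must equal the number of spectral cells",
          class = "octmc_contract_error")
  if (scan_range_mm * n_medium > imaging_depth(src))
    abort("scan range exceeds the imaging depth of the source",
          class = "octmc_config_error")
  m <- 0:(M - 1)
  ham <- 0.54 - 0.46 * cos(2 * pi * m / (M - 1))
  a <- fft(I_D * ham, inverse = TRUE) / M
  intensity <- Mod(a)^2
  delta_k <- attr(k_grid_mm(src), "delta_k")
  z_opt <- pi * m / (M * delta_k)
  depth <- z_opt / n_medium
  keep <- depth <= scan_range_mm
  out <- tibble(depth_mm = depth[keep], intensity = intensity[keep])
  class(out) <- c("oct_ascan", class(out))
  attr(out, "bin_mm") <- depth[2] - depth[1]
  attr(out, "n_medium") <- n_medium
  out
}

#' Average log A-scans into one profile
#'
#' Combines independent A-scans into one speckle-reduced log profile.
#' `mode = "log"` takes the pointwise mean of `10 log10(intensity)` across
#' A-scans, the classic protocol. `mode = "intensity"` averages the linear
#' intensities first and takes the logarithm once; the two agree up to a
#' constant when every depth bin carries many independent contributions,
#' but at small photon budgets the log-then-mean estimate acquires a
#' depth-dependent small-sample bias (sparsely hit bins are dragged down),
#' so intensity averaging is preferred when profiles feed the inverse fit.
#' Zero-intensity bins are floored at `floor_eps` before the logarithm;
#' when `normalize = TRUE` the value at the first depth bin is subtracted
#' so the profile starts at 0 dB.
#'
#' @param ascans list of `oct_ascan` tibbles of identical length.
#' @param floor_eps intensity floor; defaults to the smallest positive
#'   intensity present (1e-12 of the maximum for `mode = "log"`).
#' @param normalize subtract the z = 0 value.
#' @param mode `"log"` (mean of logs) or `"intensity"` (log of mean).
#' @return tibble of class `oct_ascan_avg` with `depth_mm` and `log_db`.
#' @export
average_bscan <- function(ascans, floor_eps = NULL, normalize = FALSE,
                          mode = c("log", "intensity")) {
  mode <- match.arg(mode)
  if (length(ascans) < 1) abort("need at least one A-scan",
                                class = "octmc_contract_error")
  lens <- vapply(ascans, nrow, integer(1))
  if (length(unique(lens)) != 1)
    abort("A-scans differ in length", class = "octmc_contract_error")
  inten <- vapply(ascans, function(a) a$intensity, numeric(lens[1]))
  if (mode == "log") {
    if (is.null(floor_eps)) {
      mx <- max(inten)
      floor_eps <- if (mx > 0) 1e-12 * mx else .Machine$double.xmin
    }
    avg <- rowMeans(10 * log10(pmax(inten, floor_eps)))
  } else {
    mi <- rowMeans(inten)
    if (is.null(floor_eps)) {
      pos <- mi[mi > 0]
      floor_eps <- if (length(pos) > 0) min(pos) else .Machine$double.xmin
    }
    avg <- 10 * log10(pmax(mi, floor_eps))
  }
  if (normalize) avg <- avg - avg[1]
  out <- tibble(depth_mm = ascans[[1]]$depth_mm, log_db = avg)
  class(out) <- c("oct_ascan_avg", class(out))
  attr(out, "bin_mm") <- attr(ascans[[1]], "bin_mm")
  attr(out, "n_ascans") <- length(ascans)
  out
}
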