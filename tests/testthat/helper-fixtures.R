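# Shared fixtures: the standard instrument and small-budget configs.

std_geometry <- function(w0 = 0.1, n = 1) {
  beam_geometry(f_mm = 0.5, d_mm = 0, w0_mm = w0, lambda_nm = 1300, n = n)
}

std_source <- function() source_spectrum()

small_config <- function(tissue, n_photons = 2e4, seed = 1, ...) {
  oct_config(std_geometry(), std_source(), tissue,
             n_photons = n_photons, seed = seed, ...)
}
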