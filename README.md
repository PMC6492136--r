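# octmc

Monte Carlo simulation of frequency-domain optical coherence tomography
(FDOCT) in layered tissue, with a focusing Gaussian probe beam, a
conjugate-plane (p′-plane) photon detection scheme, an analytical
extended-Huygens-Fresnel (EHF) forward model, and genetic-algorithm
recovery of tissue optical properties from simulated depth scans.

## What it is for

OCT images encode the optical properties of tissue — the scattering
coefficient μs, the anisotropy factor g, the backscattering probability
p_b — but those properties are not directly visible in a scan. Estimating
them is an inverse problem: a forward model simulates the A-scan a
hypothesized tissue would produce, and an optimizer adjusts the tissue
parameters until simulation matches measurement. `octmc` provides both
halves for researchers studying this inversion:

* a **photon transport kernel** (Rcpp) for multilayered media with the
  two-component small-angle phase function
  x(θ) = (1 − 2p_b)·x₁(θ) + 2p_b, where x₁ is a forward lobe with
  ⟨θ²⟩ = 2(1 − g) and the isotropic part supplies direct backscatter;
* a **focusing Gaussian beam**: ballistic packets are launched from the
  surface intensity profile (1/e radius w_s) and follow wavefront-normal
  trajectories, so the unscattered photon density keeps the analytic
  envelope w(z) down to the diffraction-limited waist
  w_f = λf/(2nπw₀);
* a **p′-plane detector**: exiting packets are traced back through the 4F
  sample arm to the plane conjugate to their effective scattering depth
  (z_eff = half the in-medium path), where their weight is modulated by
  the reference-beam intensity I_R(p) ∝ exp(−‖p‖²/w_{p′}²); summed
  weights estimate the mean-squared heterodyne signal ⟨i²(z)⟩;
* the **FDOCT signal chain**: fringe accumulation
  S(k) = G(k) Σᵢ aᵢ e^{2ikzᵢ} on a wavenumber grid resampled to uniform
  spacing, interference I_D = |S+R|² − |S−R|², Hamming window, inverse
  FFT, squared magnitude, B-scan averaging in log scale;
* the **EHF comparator**: ⟨i²(z)⟩ ∝ p_b · (w_f²/w_H(z)²) · Ψ(z) with the
  ballistic/cross/multiple-scattering heterodyne efficiency factor and
  shower-curtain lateral coherence length;
* **inverse fitting**: a real-coded genetic algorithm (bounds
  1 ≤ μs ≤ 15 mm⁻¹, 0.8 ≤ g ≤ 1, 0.001 ≤ p_b ≤ 0.5, 10⁻³ ≤ a ≤ 10³)
  plus the linear-perturbation sensitivity bounds
  δu/u ≤ (1/N_z) Σᵢ |∂u/∂I(zᵢ)| (I/u)(δI/I).

Results come back as tibbles; fitted objects support `tidy()`, `glance()`
and `autoplot()`.

## Worked example

Simulate a speckle-averaged A-scan of a 1 mm phantom (μs = 5 mm⁻¹,
g = 0.95, p_b = 0.01) under a 1300 nm / 95 nm source focused by an
f = 0.5 mm lens, then recover the optical properties:

```r
library(octmc)

geom <- beam_geometry(f_mm = 0.5, d_mm = 0, w0_mm = 0.1, lambda_nm = 1300)
src  <- source_spectrum()   # 1300 nm centre, 95 nm FWHM, 2048 cells
cfg  <- oct_config(geom, src,
                   make_phantom("single_layer", mu_s = 5, g = 0.95, p_b = 0.01),
                   n_photons = 3e5, n_ascans = 10, seed = 31)

avg <- oct_ascan(cfg, mode = "intensity")
attr(avg, "detected_ratio_pct")
#> [1] 3.7528

fit <- fit_ehf(avg, geom, seed = 7)
fit
#> <oct_fit> EHF parameters fitted by genetic algorithm
#>   mu_s = 5.620 mm^-1, g = 0.9749, p_b = 0.0144, a = 0.635
#>   objective (SSD, dB^2) = 404.3 after 200 generations
```

About 3.75% of launched packets are detected (exit the top surface within
the p′-plane depth limit 2f − d). The fitted scattering coefficient
(5.62 mm⁻¹, true value 5) lands within the sampling spread expected at
this reduced photon budget; `autoplot(fit)` overlays the fitted EHF curve
on the simulated profile. A specular-mirror phantom (`make_phantom("mirror_at")`)
gives the analytic check: its A-scan peak localizes to the mirror depth
within one 7.5 µm depth bin.

`inst/cli/octmc.R` exposes the same pipeline as subcommands
(`simulate`, `ascan`, `ehf`, `fit`, `sensitivity`, `grid`) for shell use.

## Known limitations

The conjugate-plane detection estimator is unbiased but variance-starved
near the focal conjugate at small photon budgets; recovery of μs at
10 mm⁻¹ is correspondingly noisy at desk budgets and tightens only at
full-protocol budgets (~10⁸ packets per A-scan). See the methods
vignette (`vignettes/octmc-methods.Rmd`) for the full discussion of
modeling choices and limitations.
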