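# Beam geometry, Gaussian-beam derived quantities, spectral bookkeeping.

test_that("focal waist follows the lambda f / (2 n pi w0) closed form", {
  g <- beam_geometry(0.5, 0, 0.02, lambda_nm = 1300, n = 1)
  expect_equal(focal_waist(g), 1300e-6 * 0.5 / (2 * pi * 0.02),
               tolerance = 1e-12)
  # scaling identities
  g2 <- beam_geometry(0.5, 0, 0.04, lambda_nm = 1300, n = 1)
  expect_equal(focal_waist(g2), focal_waist(g) / 2, tolerance = 1e-12)
  gn <- beam_geometry(0.5, 0, 0.02, lambda_nm = 1300, n = 2)
  expect_equal(focal_waist(gn), focal_waist(g) / 2, tolerance = 1e-12)
})

test_that("invalid geometry is rejected with the offending field named", {
  expect_error(beam_geometry(-1, 0, 0.1), "f_mm", class = "octmc_config_error")
  expect_error(beam_geometry(0.5, 0.6, 0.1), "d_mm",
               class = "octmc_config_error")
  expect_error(beam_geometry(0.5, 0, -0.1), "w0_mm",
               class = "octmc_config_error")
  expect_error(beam_geometry(0.5, 0, 0.1, n = 0.9), "n",
               class = "octmc_config_error")
})

test_that("surface radius: d = f limit, collimated limit, monotone in d", {
  # d -> f would be rejected by the constructor; check continuity instead:
  # ws -> wf as d -> f
  g_near <- beam_geometry(0.5, 0.4999999, 0.1)
  expect_equal(surface_radius(g_near), g_near$wf_air, tolerance = 1e-4)
  # far-from-focus limit: ws ~ w0 (f - d)/f = w0 at d = 0
  g0 <- beam_geometry(0.5, 0, 0.1)
  expect_equal(surface_radius(g0), 0.1, tolerance = 0.01)
  # monotone nonincreasing in d
  ws <- vapply(seq(0, 0.45, by = 0.05),
               function(d) surface_radius(beam_geometry(0.5, d, 0.1)),
               numeric(1))
  expect_true(all(diff(ws) <= 1e-12))
})

test_that("wavefront radius: sign convention, focus sentinel, antisymmetry", {
  g <- beam_geometry(0.5, 0, 0.1)
  zf <- g$n * (g$f - g$d)
  expect_identical(wavefront_radius(g, zf), Inf)
  # direction at the focus is axial for any transverse position
  expect_equal(beam_direction(g, 0.05, -0.02, zf), c(0, 0, 1),
               tolerance = 1e-12)
  # converging (positive) before focus, diverging (negative) after
  expect_gt(wavefront_radius(g, zf - 0.1), 0)
  expect_lt(wavefront_radius(g, zf + 0.1), 0)
  # antisymmetry in u = d - f + z/n
  expect_equal(wavefront_radius(g, zf - 0.13),
               -wavefront_radius(g, zf + 0.13), tolerance = 1e-12)
  # R(0) = f (1 + (zR/f)^2) at d = 0, ~ f since zR << f
  expect_equal(wavefront_radius(g, 0), (g$f^2 + g$zR^2) / g$f,
               tolerance = 1e-12)
  expect_equal(wavefront_radius(g, 0), g$f, tolerance = 1e-3)
})

test_that("resampled wavenumber grid is uniform and spans the source", {
  src <- source_spectrum(1300, 95, 2048, 0.055)
  k <- resample_wavenumbers(src)
  expect_length(k, 2048)
  lam <- attr(k, "lambda_nm")
  # endpoints: lambda runs from lambda_max down to lambda_min
  expect_equal(lam[1], src$lambda_max, tolerance = 1e-9)
  expect_equal(lam[2048], src$lambda_min, tolerance = 1e-9)
  expect_equal(k[1], 2 * pi / src$lambda_max, tolerance = 1e-12)
  expect_equal(k[2048], 2 * pi / src$lambda_min, tolerance = 1e-12)
  # uniform spacing to 1e-9 relative
  dk <- diff(k)
  expect_lt(max(abs(dk - mean(dk))) / mean(dk), 1e-9)
  expect_true(all(dk > 0))
  # property holds for other (lambda_min, delta, M)
  for (M in c(2, 17, 301)) {
    ki <- resample_wavenumbers(source_spectrum(800, 40, M, 0.1))
    if (M > 2) {
      dki <- diff(ki)
      expect_lt(max(abs(dki - mean(dki))) / mean(dki), 1e-9)
    }
  }
  expect_error(source_spectrum(n_cells = 1), class = "octmc_config_error")
})

test_that("wavenumber bandwidth and imaging depth follow their closed forms", {
  src <- source_spectrum(1300, 95, 2048, 0.055)
  expect_equal(wavenumber_bandwidth(src),
               (pi / sqrt(log(2))) * 95 / 1300^2, tolerance = 1e-12)
  # lambda_c^-2 scaling
  src2 <- source_spectrum(2600, 95, 2048, 0.055)
  expect_equal(wavenumber_bandwidth(src2),
               wavenumber_bandwidth(src) / 4, tolerance = 1e-12)
  # D = lambda_c^2/(4 delta_lambda) ~ 7.68 mm
  expect_equal(imaging_depth(src), 1300^2 / (4 * 0.055) * 1e-6,
               tolerance = 1e-12)
  expect_equal(imaging_depth(src), 7.6818, tolerance = 1e-4)
  src3 <- source_spectrum(1300, 95, 2048, 0.0275)
  expect_equal(imaging_depth(src3), 2 * imaging_depth(src), tolerance = 1e-12)
})

test_that("beam envelope matches surface radius and focal waist", {
  # the surface value agrees with the two-step (air wf, then in-medium)
  # construction to within the small-angle approximation
  g <- beam_geometry(0.5, 0, 0.1)
  expect_equal(beam_radius(g, 0), g$ws, tolerance = 1e-3)
  expect_equal(beam_radius(g, g$n * (g$f - g$d)), g$wfp, tolerance = 1e-12)
})
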