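# p'-plane detection scheme and the legacy acceptance-cone detector.

test_that("p'-plane distance follows 2f - (d + z/n) with its depth limit", {
  g <- std_geometry()
  expect_equal(pprime_distance(g, 0), 2 * g$f)
  expect_equal(pprime_distance(g, 0.4), 0.6, tolerance = 1e-12)
  expect_equal(pprime_distance(g, g$n * (2 * g$f - g$d)), 0, tolerance = 1e-12)
  expect_error(pprime_distance(g, 1.2), "larger f",
               class = "octmc_depth_limit_error")
})

test_that("back-propagation reproduces the explicit ABCD matrix composition", {
  g <- beam_geometry(0.5, 0.1, 0.05)
  z_eff <- 0.37
  # oracle: explicit 2x2 ray-transfer composition
  Tm <- function(L) matrix(c(1, 0, L, 1), 2)
  Lf <- function(f) matrix(c(1, -1 / f, 0, 1), 2)
  M <- Tm(2 * g$f - (g$d + z_eff / g$n)) %*% Lf(g$f) %*% Tm(2 * g$f) %*%
    Lf(g$f) %*% Tm(g$d)
  for (i in 1:20) {
    x <- stats::runif(1, -0.3, 0.3); tx <- stats::runif(1, -0.5, 0.5)
    y <- stats::runif(1, -0.3, 0.3); ty <- stats::runif(1, -0.5, 0.5)
    nrm <- sqrt(1 + tx^2 + ty^2)
    exits <- tibble::tibble(x = x, y = y, ux = tx / nrm, uy = ty / nrm,
                            uz = -1 / nrm)
    p <- backpropagate_to_pprime(exits, g, z_eff)
    expect_equal(p$px, drop(M %*% c(x, tx))[1], tolerance = 1e-10)
    expect_equal(p$py, drop(M %*% c(y, ty))[1], tolerance = 1e-10)
  }
  # axial ray maps to the origin; mirror symmetry in the transverse angle
  ax <- backpropagate_to_pprime(
    tibble::tibble(x = 0, y = 0, ux = 0, uy = 0, uz = -1), g, z_eff)
  expect_equal(unlist(ax), c(px = 0, py = 0))
  pm <- backpropagate_to_pprime(
    tibble::tibble(x = c(0.1, 0.1), y = 0, ux = c(0.3, -0.3), uy = 0,
                   uz = -sqrt(1 - 0.09)), g, z_eff)
  expect_equal(pm$px[1] + pm$px[2], -0.2, tolerance = 1e-12)
})

test_that("reference intensity has peak 1/w^2 and plane integral pi", {
  w <- 0.037
  expect_equal(reference_intensity(0, 0, w), 1 / w^2)
  expect_equal(reference_intensity(w, 0, w), exp(-1) / w^2, tolerance = 1e-12)
  # radial integral oracle: int 2 pi r I(r) dr = pi
  val <- stats::integrate(function(r) 2 * pi * r *
                            reference_intensity(r, 0, w), 0, Inf)$value
  expect_equal(val, pi, tolerance = 1e-8)
})

test_that("pprime detection never increases weight and classifies every exit", {
  cfg <- small_config(make_phantom("single_layer", mu_s = 10, p_b = 0.1),
                      n_photons = 2e4, seed = 17)
  sim <- oct_simulate(cfg)
  det <- detect_photons(sim)
  counts <- attr(det, "counts")
  # mu_a = 0: transport weights are 1, so modulated weights stay in [0, 1]
  expect_true(all(det$weight <= 1 + 1e-12))
  expect_true(all(det$weight >= 0))
  expect_equal(counts[["detected"]] + counts[["rejected_depth"]] +
                 counts[["rejected_aperture"]], counts[["n_exits"]])
  expect_equal(counts[["n_exits"]], nrow(sim$exits))
  expect_true(all(det$z_eff <= 2 * 0.5 - 0))
})

test_that("single-backscatter packet from the mirror detects at full depth", {
  cfg <- small_config(make_phantom("mirror_at", z0_mm = 0.3),
                      n_photons = 2000)
  sim <- oct_simulate(cfg)
  det <- detect_photons(sim)
  # axial packets: opl = 2 z0, weight modulated by the on-axis reference
  expect_equal(min(det$opl), 0.6, tolerance = 1e-4)
  expect_equal(stats::median(det$z_eff), 0.3, tolerance = 0.02)
  expect_gt(max(det$weight), 0.1) # near-axis packets retain O(1) weight
})

test_that("mcml cone detector applies inclusive radius and angle cuts", {
  g <- std_geometry()
  theta_max <- atan(g$w0 / g$f)
  fr <- g$wf_air
  mk <- function(r, ang) {
    tibble::tibble(weight = 1, opl = 0.5, path = 0.5, x = r, y = 0,
                   ux = sin(ang), uy = 0, uz = -cos(ang))
  }
  on_edge <- detect_photons(mk(fr, theta_max), g, scheme = "mcml_cone")
  expect_equal(nrow(on_edge), 1) # inclusive boundary
  expect_equal(on_edge$weight, 1) # unmodulated
  off_r <- detect_photons(mk(fr * 1.01, 0), g, scheme = "mcml_cone")
  expect_equal(nrow(off_r), 0)
  expect_equal(attr(off_r, "counts")[["rejected_aperture"]], 1)
  off_a <- detect_photons(mk(0, theta_max * 1.01), g, scheme = "mcml_cone")
  expect_equal(nrow(off_a), 0)
})

test_that("reference waist is minimal at the focal depth", {
  g <- std_geometry()
  zf <- g$n * (g$f - g$d)
  z <- seq(0, 1, by = 0.05)
  w <- reference_waist(g, z)
  expect_equal(z[which.min(w)], zf, tolerance = 0.051)
  expect_equal(min(w), g$wf_air, tolerance = 1e-6)
  expect_equal(reference_waist(g, 0), g$w0, tolerance = 0.01)
})
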