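# FDOCT signal formation and A-scan reconstruction.

test_that("spectral envelope: peak, 1/e points, swept-source mode", {
  src <- std_source()
  k <- k_grid_mm(src)
  kc <- 2 * pi / (src$lambda_c * 1e-6)
  dk <- wavenumber_bandwidth(src) * 1e6
  expect_equal(source_envelope(kc, kc, dk), 1)
  expect_equal(source_envelope(kc + dk, kc, dk), exp(-1))
  expect_equal(source_envelope(kc - dk, kc, dk), exp(-1))
  expect_identical(source_envelope(k, kc, dk, ssoct = TRUE), rep(1, length(k)))
})

test_that("single-record spectrum is the modulated envelope; accumulation is linear", {
  src <- std_source()
  k <- k_grid_mm(src)
  kc <- 2 * pi / (src$lambda_c * 1e-6)
  dk <- wavenumber_bandwidth(src) * 1e6
  G <- source_envelope(k, kc, dk)
  one <- tibble::tibble(weight = 1, opl = 2 * 0.4)
  S <- accumulate_spectrum(one, k, G)
  expect_equal(Mod(S), G, tolerance = 1e-12)
  expect_equal(Arg(S[5]), (2 * k[5] * 0.4) %% (2 * pi) -
                 ifelse((2 * k[5] * 0.4) %% (2 * pi) > pi, 2 * pi, 0),
               tolerance = 1e-9)
  # two equal records double the spectrum
  two <- tibble::tibble(weight = c(1, 1), opl = c(0.8, 0.8))
  expect_equal(accumulate_spectrum(two, k, G), 2 * S, tolerance = 1e-12)
  # amplitude convention: "weight" uses W as the field amplitude
  half <- tibble::tibble(weight = 0.25, opl = 0.8)
  expect_equal(accumulate_spectrum(half, k, G, amplitude = "sqrt_weight"),
               0.5 * S, tolerance = 1e-12)
  expect_equal(accumulate_spectrum(half, k, G, amplitude = "weight"),
               0.25 * S, tolerance = 1e-12)
  expect_warning(accumulate_spectrum(tibble::tibble(weight = numeric(),
                                                    opl = numeric()), k, G),
                 "zero spectrum")
})

test_that("interference identity |S+R|^2 - |S-R|^2 = 4 Re(S conj(R))", {
  set.seed(8)
  M <- 256
  G <- exp(-seq(-2, 2, length.out = M)^2)
  S <- complex(real = stats::rnorm(M), imaginary = stats::rnorm(M)) * G
  ID <- interfere(S, G)
  alpha <- attr(ID, "alpha")
  expect_equal(as.numeric(ID), 4 * Re(S * Conj(alpha * G)),
               tolerance = 1e-12)
  # alpha puts the sample power at the midpoint of the admissible band
  ratio <- sum(Mod(S)^2) / (alpha^2 * sum(G^2))
  expect_equal(ratio, sqrt(1e-5 * 1e-4), tolerance = 1e-9)
  # zero sample arm
  expect_equal(as.numeric(interfere(S * 0, G, alpha = 1)), rep(0, M))
  # caller-supplied alpha outside the band warns with the ratio
  expect_warning(interfere(S, G, alpha = 1e9), "power ratio")
})

test_that("A-scan localizes reflectors and squares amplitude ratios", {
  src <- std_source()
  k <- k_grid_mm(src)
  kc <- 2 * pi / (src$lambda_c * 1e-6)
  dk <- wavenumber_bandwidth(src) * 1e6
  G <- source_envelope(k, kc, dk)
  for (z0 in c(0.2, 0.4, 0.8)) {
    rec <- tibble::tibble(weight = 1, opl = 2 * z0)
    ID <- interfere(accumulate_spectrum(rec, k, G), G)
    asc <- reconstruct_ascan(ID, src)
    pk <- asc$depth_mm[which.max(asc$intensity)]
    expect_lt(abs(pk - z0), attr(asc, "bin_mm"))
  }
  # two reflectors with weights W and 2W (amplitude ratio sqrt(2) under the
  # sqrt-weight convention): squared-magnitude peaks in ratio 2;
  # with amplitude = "weight" the peak ratio is 4
  rec2 <- tibble::tibble(weight = c(1, 2), opl = c(0.6, 1.4))
  ID2 <- interfere(accumulate_spectrum(rec2, k, G, amplitude = "weight"), G)
  asc2 <- reconstruct_ascan(ID2, src)
  # integrate over the peak windows to avoid bin-centering scalloping
  i1 <- sum(asc2$intensity[abs(asc2$depth_mm - 0.3) < 0.05])
  i2 <- sum(asc2$intensity[abs(asc2$depth_mm - 0.7) < 0.05])
  expect_equal(i2 / i1, 4, tolerance = 0.02)
  # all-zero spectrum reconstructs to zero
  asc0 <- reconstruct_ascan(rep(0, src$M), src)
  expect_true(all(asc0$intensity == 0))
  # scan range beyond the imaging depth is a configuration error
  expect_error(reconstruct_ascan(ID2, src, scan_range_mm = 10),
               class = "octmc_config_error")
})

test_that("FDOCT linearity: doubling record weights adds 6.02 dB", {
  src <- std_source()
  k <- k_grid_mm(src)
  kc <- 2 * pi / (src$lambda_c * 1e-6)
  dk <- wavenumber_bandwidth(src) * 1e6
  G <- source_envelope(k, kc, dk)
  set.seed(2)
  rec <- tibble::tibble(weight = stats::runif(50), opl = stats::runif(50, 0.1, 1.8))
  mk <- function(r) {
    S <- accumulate_spectrum(r, k, G)
    # fixed alpha so the two reconstructions share a reference scale; the
    # power-band advisory is expected and irrelevant here
    ID <- suppressWarnings(interfere(S, G, alpha = 5))
    reconstruct_ascan(ID, src)
  }
  a1 <- mk(rec)
  a2 <- mk(dplyr::mutate(rec, weight = 2 * weight))
  nz <- a1$intensity > max(a1$intensity) * 1e-9
  db_shift <- 10 * log10(a2$intensity[nz] / a1$intensity[nz])
  expect_equal(mean(db_shift), 10 * log10(2), tolerance = 1e-6)
  expect_lt(max(abs(db_shift - 10 * log10(2))), 1e-6)
})

test_that("B-scan averaging, flooring, and z = 0 normalization", {
  src <- std_source()
  asc <- reconstruct_ascan(rep(0, src$M), src)
  asc$intensity <- exp(seq(0, -5, length.out = nrow(asc)))
  avg1 <- average_bscan(list(asc, asc, asc))
  expect_equal(avg1$log_db, 10 * log10(asc$intensity), tolerance = 1e-12)
  expect_equal(attr(avg1, "n_ascans"), 3)
  # normalization puts the first bin at 0 dB
  avgn <- average_bscan(list(asc), normalize = TRUE)
  expect_equal(avgn$log_db[1], 0)
  # length mismatch is a contract violation
  short <- asc[1:10, ]
  expect_error(average_bscan(list(asc, short)),
               class = "octmc_contract_error")
  # speckle reduction: variance of the average drops ~ 1/N
  set.seed(3)
  mkasc <- function() {
    a <- asc
    a$intensity <- asc$intensity * stats::rexp(nrow(asc))
    a
  }
  reps1 <- replicate(40, average_bscan(list(mkasc()))$log_db[20])
  reps8 <- replicate(40, average_bscan(replicate(8, mkasc(),
                                                 simplify = FALSE))$log_db[20])
  expect_equal(var(reps1) / var(reps8), 8, tolerance = 0.6)
})
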