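make_strain_sweep <- function(strain_pct, storage_pa,
                              loss_pa = storage_pa * 0.03) {
  strain_sweep(sample_meta("a", "agarose", 0.4), strain_pct, storage_pa,
               loss_pa)
}

test_that("LVE limit detection handles plateau, softening and no-plateau", {
  grid <- 10^seq(-2, 1, length.out = 30)
  # perfectly flat: the maximum tested strain is returned
  flat <- make_strain_sweep(grid, rep(1000, 30))
  expect_equal(detect_lve_limit(flat), max(grid))

  # plateau then softening: agree with a brute-force scan of the same curve
  gc_pct <- 0.3
  g <- 1000 / (1 + (grid / gc_pct)^2)
  sweep <- make_strain_sweep(grid, g)
  # independent scan: walk up the curve, stop at the first 5% departure from
  # the low-strain mean
  ref <- mean(g[grid <= min(grid) * 10])
  expected <- grid[1]
  for (i in seq_along(grid)) {
    if (abs(g[i] - ref) > 0.05 * ref) break
    expected <- grid[i]
  }
  expect_equal(detect_lve_limit(sweep, 0.05), expected)
  # and the scan result is near the generator's closed-form departure strain
  expect_equal(expected, gc_pct * sqrt(0.05 / 0.95), tolerance = 0.3)

  # strictly decreasing from the start: the first strain is returned
  dec <- make_strain_sweep(grid[1:6], 1000 * 0.8^(0:5))
  expect_equal(detect_lve_limit(dec, 0.05), grid[1])

  expect_error(detect_lve_limit(make_strain_sweep(grid[1:3], rep(1, 3))),
               "4 strain")
  expect_error(detect_lve_limit(flat, 0.7), "tolerance_fraction")
})

test_that("inertial cutoff finds persistent collapses and ignores dips", {
  meta <- sample_meta("h", "heart")
  f <- c(0.1, 0.5, 1, 2, 5, 9.5, 11, 12, 14)
  rising <- frequency_sweep(meta, f, storage_pa = 100 * f^0.1,
                            loss_pa = 10 * f^0.1)
  expect_true(is.na(detect_inertial_cutoff(rising)))

  # peak at 9.5 Hz then collapse
  g <- 100 * f^0.1
  g[f > 9.5] <- g[f > 9.5] * c(0.7, 0.4, 0.1)
  collapsing <- frequency_sweep(meta, f, g, g * 0.1)
  expect_equal(detect_inertial_cutoff(collapsing, 0.1), 9.5)

  # single-point 5% dip that recovers is not a cutoff
  g2 <- rep(100, 9)
  g2[5] <- 95
  dip <- frequency_sweep(meta, f, g2, g2 * 0.1)
  expect_true(is.na(detect_inertial_cutoff(dip, 0.1)))

  # truncation keeps everything at or below the cutoff
  trunc <- truncate_at_cutoff(collapsing, 9.5)
  expect_equal(trunc$frequency_hz, f[f <= 9.5])
  expect_equal(trunc$storage_pa, g[f <= 9.5])
})

test_that("springpot fitting inverts the forward model", {
  f <- ten_freqs()
  for (conv in c("hz", "rad_s")) {
    truth <- springpot_params(1000, 0.1)
    spec <- springpot_moduli(truth, f, conv)
    fit <- fit_springpot(spec)
    expect_equal(fit$params$k_alpha, 1000, tolerance = 1e-6)
    expect_equal(fit$params$alpha, 0.1, tolerance = 1e-6)
    expect_gt(fit$correlation, 1 - 1e-9)
    expect_identical(fit$convention, conv)
  }

  # flat storage spectrum is a pure spring
  flat <- modulus_spectrum(c(0.1, 0.4, 1, 2), rep(2000, 4), rep(0, 4))
  fit <- fit_springpot(flat, channels = "storage_only")
  expect_equal(fit$params$alpha, 0, tolerance = 1e-8)
  expect_equal(fit$params$k_alpha, 2000, tolerance = 1e-6)

  expect_error(fit_springpot(modulus_spectrum(c(0.1, 1), c(1, 1), c(1, 1))),
               "3 frequencies")
  expect_error(fit_springpot(modulus_spectrum(c(0.1, 0.5, 1), c(1, 1, 1),
                                              c(0, 0, 0)),
                             channels = "joint"), "positive")
})

test_that("fitted alpha is scale-invariant and k_alpha scales linearly", {
  f <- ten_freqs()
  spec <- springpot_moduli(springpot_params(750, 0.25), f)
  scaled <- modulus_spectrum(f, spec$storage_pa * 13, spec$loss_pa * 13)
  fit1 <- fit_springpot(spec)
  fit2 <- fit_springpot(scaled)
  expect_equal(fit2$params$alpha, fit1$params$alpha, tolerance = 1e-7)
  expect_equal(fit2$params$k_alpha / fit1$params$k_alpha, 13,
               tolerance = 1e-7)
})

test_that("noisy recovery at the sweep protocol scale is accurate", {
  f <- ten_freqs()
  truth <- agarose_04()
  n_rep <- 100
  k_hat <- alpha_hat <- corr <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    sw <- gen_frequency_sweep(truth, f, noise = noise_spec(0.02, seed = i))
    fit <- fit_springpot(modulus_spectrum(sw$frequency_hz, sw$storage_pa,
                                          sw$loss_pa))
    k_hat[i] <- fit$params$k_alpha
    alpha_hat[i] <- fit$params$alpha
    corr[i] <- fit$correlation
  }
  expect_lt(abs(median(k_hat) - truth$k_alpha) / truth$k_alpha, 0.03)
  expect_lt(abs(median(alpha_hat) - truth$alpha), 0.01)
  expect_gt(median(corr), 0.99)
})

test_that("truncating an inertial drop materially changes the fit", {
  f <- c(ten_freqs(0.1, 1, 8), 1.2, 1.6, 2.2, 3)
  sw <- gen_frequency_sweep(agarose_04(), f, noise = NULL,
                            inertial_cutoff_hz = 1.2)
  cut <- detect_inertial_cutoff(sw, 0.1)
  expect_equal(cut, 1.2)
  full_fit <- fit_springpot(modulus_spectrum(sw$frequency_hz,
                                             pmax(sw$storage_pa, 1e-6),
                                             pmax(sw$loss_pa, 1e-9)))
  trunc <- truncate_at_cutoff(sw, cut)
  trunc_fit <- fit_springpot(modulus_spectrum(trunc$frequency_hz,
                                              trunc$storage_pa,
                                              trunc$loss_pa))
  expect_equal(trunc_fit$params$alpha, 0.019, tolerance = 1e-5)
  # the contaminated fit is pulled far off the generating order
  expect_gt(abs(full_fit$params$alpha - 0.019), 0.005)
})

test_that("Young modulus is the low-strain slope, offset-invariant", {
  meta <- sample_meta("u", "agarose", 2)
  strain <- seq(0, 0.02, length.out = 10)
  exact <- uniaxial_record(meta, strain, 4400 * strain)
  expect_equal(young_modulus(exact), 4400)

  stiff <- uniaxial_record(meta, strain, 297000 * strain)
  expect_equal(young_modulus(stiff), 297000)

  offset <- uniaxial_record(meta, strain, 4400 * strain + 10)
  expect_equal(young_modulus(offset), 4400)

  # points above max_strain are excluded from the slope
  wide <- uniaxial_record(meta, c(strain, 0.04, 0.06),
                          c(4400 * strain, 500, 600))
  expect_equal(young_modulus(wide, max_strain = 0.02), 4400)
  expect_error(young_modulus(wide, max_strain = 0.0001), "3 points")
})

test_that("contact force implies the axial strain offset", {
  o <- axial_strain_offset(0.1, 25, 4400)
  expect_equal(o$nominal_stress_pa, 0.1 / (pi * 0.0125^2))
  expect_equal(round(o$nominal_stress_pa), 204)
  expect_equal(o$offset_pct, 4.63, tolerance = 0.01)

  expect_equal(axial_strain_offset(0, 25, 4400)$offset_pct, 0)
  expect_equal(axial_strain_offset(0.2, 25, 4400)$offset_pct, 9.2599,
               tolerance = 1e-4)
  expect_error(axial_strain_offset(0.1, 25, 0), "positive")
})

test_that("pre-compression fit recovers the generating line", {
  strains <- c(4.6, 6.6, 8.6, 10.6, 12.6, 14.6)
  k <- 1.498 * (1 - 0.021 * strains)
  fit <- fit_precompression(strains, k, alpha = rep(0.019, 6))
  expect_equal(fit$k0, 1.498, tolerance = 1e-10)
  expect_equal(fit$b, 0.021, tolerance = 1e-10)
  expect_equal(fit$alpha, 0.019)

  const <- fit_precompression(strains, rep(0.7, 6))
  expect_equal(const$b, 0, tolerance = 1e-12)
  expect_equal(const$k0, 0.7, tolerance = 1e-12)

  # evaluating the 0.3% model at 10% axial strain
  m <- precompression_model(0.709, 0.017)
  expect_equal(predict_k_alpha(m, 10), 0.58847)

  expect_error(fit_precompression(c(1, 1, 1), c(1, 2, 3)), "distinct")
  # noisy residuals are zero-mean
  set.seed(42)
  noisy <- k + rnorm(6, 0, 0.005)
  fitn <- fit_precompression(strains, noisy)
  resid <- noisy - predict_k_alpha(fitn, strains)
  expect_equal(mean(resid), 0, tolerance = 1e-12)
  # a model predicting non-positive k over its range warns
  expect_warning(precompression_model(1, 0.2, strain_range_pct = c(1, 10)),
                 "non-positive")
})

test_that("concentration power law round-trips and degenerates sensibly", {
  conc <- c(0.25, 0.5, 1, 2)
  g <- 10.8 * conc^2.3
  law <- fit_concentration_power_law(conc, g)
  expect_equal(law$amplitude_kpa, 10.8, tolerance = 1e-10)
  expect_equal(law$exponent, 2.3, tolerance = 1e-10)

  flat <- fit_concentration_power_law(conc, rep(5, 4))
  expect_equal(flat$exponent, 0, tolerance = 1e-12)

  expect_equal(predict_power_law(concentration_power_law(10.8, 2.3), 0.4),
               1.3127, tolerance = 1e-4)
  expect_error(fit_concentration_power_law(c(1, 2), c(1, 2)), "distinct")
  expect_error(fit_concentration_power_law(conc, c(-1, 1, 1, 1)),
               "positive")
})
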