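test_that("generators are bit-reproducible under a fixed seed", {
  f <- ten_freqs()
  a <- gen_frequency_sweep(agarose_04(), f, noise_spec(0.02, seed = 11))
  b <- gen_frequency_sweep(agarose_04(), f, noise_spec(0.02, seed = 11))
  expect_identical(a, b)
  c <- gen_frequency_sweep(agarose_04(), f, noise_spec(0.02, seed = 12))
  expect_false(identical(a$storage_pa, c$storage_pa))

  s1 <- gen_study(study_config(seed = 5))
  s2 <- gen_study(study_config(seed = 5))
  expect_identical(s1, s2)
})

test_that("zero-noise frequency sweeps round-trip through the fitter", {
  f <- ten_freqs()
  sw <- gen_frequency_sweep(agarose_03(), f, noise = NULL)
  fit <- fit_springpot(modulus_spectrum(sw$frequency_hz, sw$storage_pa,
                                        sw$loss_pa))
  expect_equal(fit$params$k_alpha, 700, tolerance = 1e-6)
  expect_equal(fit$params$alpha, 0.020, tolerance = 1e-6)

  expect_error(gen_frequency_sweep(agarose_03(), f,
                                   inertial_cutoff_hz = 0.01),
               "below the first grid")
})

test_that("lognormal noise keeps all generated moduli strictly positive", {
  f <- ten_freqs()
  for (seed in 1:20) {
    sw <- gen_frequency_sweep(agarose_025(), f, noise_spec(0.3, seed = seed))
    expect_true(all(sw$storage_pa > 0))
    expect_true(all(sw$loss_pa > 0))
  }
})

test_that("strain sweep generator has the documented plateau and half-point", {
  grid <- c(0.01, 0.03, 0.1, 0.3, 1, 2, 3, 5, 10)
  sw <- gen_strain_sweep(1000, 30, critical_strain_pct = 2,
                         strain_pct = grid, noise = NULL)
  # below the critical strain the storage modulus sits at the plateau
  expect_equal(sw$storage_pa[1], 1000, tolerance = 1e-4)
  # at the critical strain it is exactly half the plateau
  expect_equal(sw$storage_pa[grid == 2], 500)
  # loss modulus rises above its plateau past the critical strain
  expect_gt(sw$loss_pa[grid == 2], 30)
  expect_error(gen_strain_sweep(1000, 30, critical_strain_pct = -1),
               "positive")
})

test_that("uniaxial generator recovers its Young modulus", {
  for (e_pa in c(4400, 297000)) {
    rec <- gen_uniaxial(e_pa, noise = NULL)
    expect_equal(young_modulus(rec), e_pa, tolerance = 1e-9)
  }
  expect_error(gen_uniaxial(4400, grid_points = 1), "at least 2")
})

test_that("relaxation generator reduces to the springpot and adds decay", {
  t <- 10^seq(-1, 1, length.out = 21)
  pure <- gen_relaxation(agarose_04(), t, noise = NULL)
  closed <- springpot_relaxation(agarose_04(), t)
  expect_equal(pure$relaxation_modulus_pa, closed$relaxation_modulus_pa)

  organ <- gen_relaxation(agarose_04(), c(t, 40, 60), noise = NULL,
                          extra_decay_fraction = 0.3, extra_decay_tau_s = 2)
  base <- springpot_relaxation(agarose_04(), c(t, 40, 60))
  ratio <- organ$relaxation_modulus_pa / base$relaxation_modulus_pa
  # far beyond tau the trace asymptotes to (1 - fraction) of the springpot
  expect_equal(tail(ratio, 1), 0.7, tolerance = 1e-4)
  expect_error(gen_relaxation(agarose_04(), t, extra_decay_fraction = 0.3,
                              extra_decay_tau_s = -1),
               "extra_decay_tau_s")
})

test_that("generated inertial drops are detected at the configured cutoff", {
  f <- c(ten_freqs(0.1, 1, 8), 1.2, 1.6, 2.2, 3)
  sw <- gen_frequency_sweep(agarose_04(), f, noise = NULL,
                            inertial_cutoff_hz = 1.2)
  expect_equal(detect_inertial_cutoff(sw, 0.1), 1.2)
})

test_that("the full synthetic study supports end-to-end parameter recovery", {
  cfg <- study_config(seed = 3, noise_sd = 0)
  study <- gen_study(cfg)
  res <- run_pipeline(list(seed = 3,
                           simulate = list(noise_sd = 0)),
                      verbose = FALSE)
  for (key in names(study$truth$agarose)) {
    truth <- study$truth$agarose[[key]]
    lvls <- res$fits[[key]]
    strains <- vapply(names(lvls), function(lvl) {
      res$data$frequency_sweeps[[key]][[lvl]]$axial_strain_pct
    }, 0)
    contact <- lvls[[which.min(strains)]]
    expect_equal(contact$params$alpha, cfg$alpha_agarose, tolerance = 1e-4)
    expect_equal(contact$params$k_alpha, truth$k_alpha_contact,
                 tolerance = 0.02)
    pre <- res$precompression[[key]]
    expect_equal(pre$k0, truth$k0, tolerance = 0.02)
    expect_equal(pre$b, truth$b, tolerance = 0.15)
  }
  expect_equal(res$power_law$amplitude_kpa, 10.8, tolerance = 0.05)
  expect_equal(res$power_law$exponent, 2.3, tolerance = 0.05)
  expect_equal(res$match$assignments,
               c(heart = 0.4, kidney = 0.3, liver = 0.25))
})
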