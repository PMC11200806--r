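test_that("springpot moduli reduce to the table-consistent values and limits", {
  # fitted 0.4% agarose parameters reproduce the printed storage modulus at
  # 0.1 Hz under the cyclic-Hz convention
  m <- springpot_moduli(agarose_04(), 0.1, convention = "hz")
  expect_equal(round(m$storage_pa / 1000, 1), 1.4)
  expect_equal(round(springpot_moduli(agarose_03(), 0.1)$storage_pa / 1000,
                     1), 0.7)
  expect_equal(round(springpot_moduli(agarose_025(), 0.1)$storage_pa / 1000,
                     1), 0.4)

  # spring limit: alpha = 0 gives a flat elastic response
  f <- c(0.1, 1, 10)
  spring <- springpot_moduli(springpot_params(2500, 0), f)
  expect_equal(spring$storage_pa, rep(2500, 3))
  expect_equal(spring$loss_pa, rep(0, 3))

  # dashpot limit: alpha = 1 gives a purely viscous response, G'' = eta*omega
  dash <- springpot_moduli(springpot_params(3, 1), f, convention = "rad_s")
  expect_equal(dash$storage_pa, rep(0, 3), tolerance = 1e-12)
  expect_equal(dash$loss_pa, 3 * 2 * pi * f)

  # alpha = 0.5 puts equal energy in both channels
  half <- springpot_moduli(springpot_params(1, 0.5), 1)
  expect_equal(half$storage_pa, half$loss_pa)
  expect_equal(half$storage_pa, cos(pi / 4))
})

test_that("the two frequency conventions differ by (2*pi)^alpha", {
  f <- ten_freqs()
  hz <- springpot_moduli(agarose_04(), f, "hz")
  rad <- springpot_moduli(agarose_04(), f, "rad_s")
  expect_equal(rad$storage_pa / hz$storage_pa,
               rep((2 * pi)^0.019, length(f)))
  expect_identical(hz$convention, "hz")
  expect_identical(rad$convention, "rad_s")
})

test_that("springpot phase and magnitude invariants hold at all frequencies", {
  f <- 10^seq(-2, 2, length.out = 30)
  for (alpha in c(0.019, 0.3, 0.5, 0.9)) {
    for (conv in c("hz", "rad_s")) {
      p <- springpot_params(1234, alpha)
      m <- springpot_moduli(p, f, conv)
      expect_equal(m$loss_pa / m$storage_pa,
                   rep(tan(alpha * pi / 2), length(f)),
                   tolerance = 1e-12)
      expect_equal(sqrt(m$storage_pa^2 + m$loss_pa^2),
                   1234 * angular_frequency(f, conv)^alpha)
      # G' non-decreasing in frequency
      expect_true(all(diff(m$storage_pa) >= 0))
    }
  }
})

test_that("classical elements give their textbook spectra and limits", {
  f <- c(0.05, 0.5, 5)
  kv <- classical_moduli(classical_params("kelvin_voigt", 1000, 0), f)
  expect_equal(kv$storage_pa, rep(1000, 3))
  expect_equal(kv$loss_pa, rep(0, 3))

  # Maxwell at omega*tau = 1 splits G equally
  mx <- classical_moduli(classical_params("maxwell", 1000, 1000),
                         c(0.05, 1 / (2 * pi), 2), convention = "rad_s")
  expect_equal(mx$storage_pa[2], 500)
  expect_equal(mx$loss_pa[2], 500)

  # high-frequency Maxwell limit recovers the spring
  hi <- classical_moduli(classical_params("maxwell", 1000, 1000), 1e6,
                         convention = "rad_s")
  expect_equal(hi$storage_pa, 1000, tolerance = 1e-10)

  # degenerate limits recover the pure elements
  spr <- classical_moduli(classical_params("spring", shear_modulus = 800), f)
  dp <- classical_moduli(classical_params("dashpot", viscosity = 2), f,
                         convention = "rad_s")
  expect_equal(spr$storage_pa, rep(800, 3))
  expect_equal(dp$loss_pa, 2 * 2 * pi * f)
  # Kelvin-Voigt with vanishing viscosity equals the spring
  kv0 <- classical_moduli(classical_params("kelvin_voigt", 800, 0), f)
  expect_equal(kv0$storage_pa, spr$storage_pa)
  expect_equal(kv0$loss_pa, spr$loss_pa)
})

test_that("relaxation modulus follows the power law with gamma-function scale", {
  # alpha = 0: constant at k_alpha (gamma(1) = 1)
  flat <- springpot_relaxation(springpot_params(900, 0), c(0.5, 1, 7))
  expect_equal(flat$relaxation_modulus_pa, rep(900, 3))

  # closed form with gamma(1/2) = sqrt(pi)
  r <- springpot_relaxation(springpot_params(1, 0.5), 4)
  expect_equal(r$relaxation_modulus_pa, 0.5 / sqrt(pi))

  # weak power law: 1.5 kPa / gamma(0.981) at t = 1 s
  r04 <- springpot_relaxation(agarose_04(), 1)
  expect_equal(r04$relaxation_modulus_pa, 1483.195, tolerance = 1e-6)

  # monotone non-increasing for alpha > 0
  tr <- springpot_relaxation(springpot_params(1500, 0.3),
                             10^seq(-1, 1, length.out = 25))
  expect_true(all(diff(tr$relaxation_modulus_pa) <= 0))
})

test_that("loss tangent is tan(alpha*pi/2), frequency- and k-independent", {
  expect_equal(loss_tangent(springpot_params(1, 0)), 0)
  expect_equal(loss_tangent(springpot_params(123, 0.5)), 1)
  expect_equal(loss_tangent(agarose_04()), 0.0298540, tolerance = 1e-6)
  expect_equal(loss_tangent(springpot_params(1, 0.3)),
               loss_tangent(springpot_params(1e6, 0.3)))
})

test_that("invalid inputs are rejected with informative errors", {
  expect_error(springpot_params(-1, 0.5), "positive")
  expect_error(springpot_params(1, 1.2), "0, 1")
  expect_error(springpot_moduli(agarose_04(), c(-1, 1)), "positive")
  expect_error(springpot_moduli(agarose_04(), c(1, 0.5)), "increasing")
  expect_error(springpot_relaxation(agarose_04(), c(0, 1)), "positive")
  expect_error(springpot_relaxation(springpot_params(1, 1), 1),
               "degenerates")
  expect_error(loss_tangent(springpot_params(1, 1)), "infinite")
  expect_error(classical_params("maxwell", shear_modulus = 1), "viscosity")
  expect_error(classical_params("kelvin_voigt", viscosity = 1),
               "shear_modulus")
})
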