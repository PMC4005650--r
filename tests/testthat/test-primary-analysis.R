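test_that("Guinier fit is exact on an ideal Guinier curve", {
  q <- q_default()
  p <- scattering_profile(q, 100 * exp(-q^2 * 50^2 / 3))
  g <- guinier_fit(p)
  expect_equal(g$rg, 50, tolerance = 0.01 / 50)
  expect_equal(g$i0, 100, tolerance = 0.1 / 100)
  expect_lte(g$qrg_window[2], 1.3)
})

test_that("Guinier Rg on a Debye-simulated sphere matches the analytic value", {
  p <- fx_sphere120()$profile
  g <- guinier_fit(p, qrg_max = 1.0, curvature = FALSE)
  expect_equal(g$rg, sqrt(3 / 5) * 60, tolerance = 0.015)
  gc <- guinier_fit(p, curvature = TRUE)
  expect_equal(gc$rg, sqrt(3 / 5) * 60, tolerance = 0.005)
})

test_that("Guinier fit errors on degenerate inputs", {
  q <- seq(0.2, 0.4, length.out = 20)  # window far above qRg 1.3 for Rg 50
  p <- scattering_profile(q, 100 * exp(-q^2 * 50^2 / 3))
  expect_error(guinier_fit(p), "fewer than 5|non-Guinier")
  # rising intensity has no Guinier regime
  p2 <- scattering_profile(q_default(20), exp(q_default(20)^2 * 100))
  expect_error(guinier_fit(p2), "non-Guinier")
})

test_that("mid-q exponents separate flat, rod-like and globular particles", {
  q <- rnpsaxs:::default_q_grid(400, 0.004, 0.35)
  oblate <- scattering_profile(q, ellipsoid_intensity(q, c(220, 220, 34),
                                                      n_quad = 48))
  w_ob <- c(1.5 * 2 * pi / 220, 0.6 * sqrt(12) / 34)
  expect_equal(powerlaw_exponent(oblate, w_ob), 2.0, tolerance = 0.3 / 2)
  prolate <- scattering_profile(q, ellipsoid_intensity(q, c(600, 40, 40),
                                                       n_quad = 48))
  w_pr <- c(1.5 * 2 * pi / 600, 0.7 / 20)
  expect_equal(powerlaw_exponent(prolate, w_pr), 1.0, tolerance = 0.3)
  # Porod envelope of a sphere
  qs <- rnpsaxs:::default_q_grid(200, 0.006, 0.5)
  sph <- scattering_profile(qs, ellipsoid_intensity(qs, c(100, 100, 100),
                                                    n_quad = 48))
  expect_equal(powerlaw_exponent(sph, c(6 / 50, 0.5), envelope = TRUE), 4.0,
               tolerance = 0.3 / 4)
  # scale invariance
  sc <- oblate; sc$intensity <- sc$intensity * 3.7e4
  expect_equal(powerlaw_exponent(sc, w_ob), powerlaw_exponent(oblate, w_ob),
               tolerance = 1e-9)
})

test_that("Kratky and Porod-Debye diagnostics separate compact from flexible", {
  qs <- rnpsaxs:::default_q_grid(200, 0.006, 0.5)
  sph <- scattering_profile(qs, ellipsoid_intensity(qs, c(100, 100, 100),
                                                    n_quad = 48))
  fr <- kratky_porod(sph)
  expect_false(fr$kratky_plateau)
  expect_true(fr$porod_debye_plateau)
  expect_identical(fr$verdict, "compact")
  # Debye chain with Rg 50
  x <- qs^2 * 2500
  chain <- scattering_profile(qs, 2 * (exp(-x) + x - 1) / x^2)
  fc <- kratky_porod(chain)
  expect_true(fc$kratky_plateau)
  expect_identical(fc$verdict, "flexible")
  # truncated support is refused
  short <- scattering_profile(qs[qs < 2 / 38.7],
                              ellipsoid_intensity(qs[qs < 2 / 38.7],
                                                  c(100, 100, 100)))
  expect_error(kratky_porod(short), "range error")
})

test_that("ellipsoid form-factor fit recovers its own forward model", {
  q <- q_default(80)
  truth <- c(220, 220, 40)
  I <- ellipsoid_intensity(q, truth, scale = 5e3)
  p <- scattering_profile(q, I, sigma = 0.01 * I)
  fit <- ellipsoid_form_fit(p)
  expect_equal(sort(fit$axes), sort(truth), tolerance = 0.05)
  expect_identical(fit$class, "oblate")
  expect_equal(fit$hydrated_volume, pi / 6 * prod(truth), tolerance = 0.1)
  # degenerate sphere case
  Is <- ellipsoid_intensity(q, c(100, 100, 100), scale = 10)
  fs <- ellipsoid_form_fit(scattering_profile(q, Is, sigma = 0.01 * Is))
  expect_equal(fs$axes, c(100, 100, 100), tolerance = 0.03)
  expect_identical(fs$class, "sphere-like")
})

test_that("ellipsoid fit chi is calibrated on data with matched noise", {
  q <- q_default(80)
  I <- ellipsoid_intensity(q, c(220, 220, 40), scale = 5e3)
  s <- 0.02 * I
  set.seed(5)
  p <- scattering_profile(q, I + rnorm(length(q), sd = s), sigma = s)
  fit <- ellipsoid_form_fit(p)
  expect_gt(fit$chi, 0.7)
  expect_lt(fit$chi, 1.5)
})

test_that("Flory prediction is an exact power law with the compact-RNA prefactor", {
  expect_equal(signif(flory_rg(902), 2), 53)
  expect_equal(flory_rg(1), 5.5)
  expect_equal(flory_rg(4096), 88)
  expect_equal(flory_rg(8 * 351), 2 * flory_rg(351))
  n <- c(10, 100, 500, 2000)
  expect_true(all(diff(flory_rg(n)) > 0))
})

test_that("composition arithmetic reproduces the printed masses and dn/dc", {
  comp <- composition()  # 2 x 70 kD + 902 nt at 323.7 Da
  expect_equal(signif(theoretical_mass(comp), 3), 432)
  expect_equal(theoretical_mass(composition(rna_nt = 0)), 140)
  expect_equal(theoretical_mass(composition(protein_copies = 0, rna_nt = 1000,
                                            nt_mass = 320)), 320)
  # mass-averaged dn/dc
  c5050 <- composition(protein_mass = 100, protein_copies = 1, rna_nt = 1,
                       nt_mass = 1e5, dndc_protein = 0.185,
                       dndc_nucleic = 0.170)
  expect_equal(mass_averaged_dndc(c5050), 0.1775)
  expect_equal(mass_averaged_dndc(composition(rna_nt = 0)),
               composition()$dndc_protein)
  # two-term weighted mean oracle at the 140/292 composition
  cc <- composition(dndc_protein = 0.185, dndc_nucleic = 0.180)
  expect_equal(mass_averaged_dndc(cc),
               (140 * 0.185 + cc$rna_mass * 0.180) / (140 + cc$rna_mass))
})
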