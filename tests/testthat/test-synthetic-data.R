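test_that("solvent electron density matches the pure-water oracle and is monotone", {
  # 0.9982 g/cm^3 * 10 e- / 18.015 g * NA, in e-/A^3
  expect_equal(solvent_electron_density(0), 0.334, tolerance = 0.001 / 0.334)
  # documented density fit at 65 % w/w
  expect_equal(solvent_electron_density(0.65), 0.4288, tolerance = 5e-3)
  w <- c(0.165, 0.325, 0.488)
  rho <- solvent_electron_density(w)
  expect_true(rho[1] < rho[2] && rho[2] < rho[3])
  expect_error(solvent_electron_density(0.75), "0.70")
})

test_that("contrast conditions compute deltas exactly and find match points", {
  cn <- contrast_condition(0, 0.425, 0.550)
  expect_equal(cn$delta_protein, 0.425 - cn$solvent_edensity)
  expect_equal(cn$delta_protein, 0.0913, tolerance = 2e-3 / 0.09)
  expect_equal(cn$delta_nucleic, 0.2163, tolerance = 2e-3 / 0.2)
  # protein match point: solvent density crosses 0.425 somewhere near 63 %
  wstar <- match_point_sucrose(0.425)
  expect_gt(wstar, 0.55); expect_lt(wstar, 0.70)
  cnm <- contrast_condition(wstar, 0.425, 0.550)
  expect_equal(cnm$delta_protein, 0, tolerance = 1e-9)
  # self-match: both deltas zero
  rho0 <- solvent_electron_density(0)
  cn0 <- contrast_condition(0, rho0, rho0)
  expect_equal(cn0$delta_protein, 0)
  expect_equal(cn0$delta_nucleic, 0)
})

test_that("phantom bead counts match the analytic volume on the HCP lattice", {
  m <- fx_sphere100()$model
  cell <- m$lattice$spacing^3 / sqrt(2)
  expect_equal(nrow(m$centers), (4 / 3) * pi * 50^3 / cell,
               tolerance = 0.05)
  expect_error(build_phantom(phantom_spec("sphere", 100, lattice_spacing = 30)),
               "resolution")
})

test_that("two-phase phantom honors the protein volume fraction and symmetry", {
  m <- build_phantom(phantom_spec("two-phase-RNP", c(244, 244, 79),
                                  protein_fraction_volume = 0.33,
                                  lattice_spacing = 79 / 7))
  frac <- mean(m$phases == "protein")
  expect_equal(frac, 0.33, tolerance = 0.02 / 0.33)
  pc <- rnpsaxs:::phase_centroid(m, "protein")
  mc <- colMeans(m$centers)
  expect_lt(sqrt(sum((pc - mc)^2)), m$lattice$spacing)
})

test_that("lobe variant extends the maximum intercenter distance", {
  pair <- fx_rnp_pair()
  dmax_base <- rnpsaxs:::cpp_pair_hist(pair$rnp$centers,
                                       rep(1, nrow(pair$rnp$centers)), 5)$rmax
  dmax_lobe <- rnpsaxs:::cpp_pair_hist(pair$lobe$centers,
                                       rep(1, nrow(pair$lobe$centers)), 5)$rmax
  expect_gte(dmax_lobe - dmax_base, 40)
})

test_that("Debye engine reproduces closed-form one- and two-bead intensities", {
  q <- q_default(60)
  cn <- water()
  phi2 <- ((3 * (sin(q * 5) - q * 5 * cos(q * 5)) / (q * 5)^3))^2
  m1 <- bead_model(matrix(0, 1, 3), 5, "nucleic", lattice = "free")
  I1 <- simulate_profile(m1, cn, q, exact = TRUE)$intensity
  expect_equal(I1 / I1[1], phi2 / phi2[1], tolerance = 1e-6)
  m2 <- bead_model(rbind(c(0, 0, 0), c(20, 0, 0)), 5, "nucleic",
                   lattice = "free")
  I2 <- simulate_profile(m2, cn, q, exact = TRUE)$intensity
  ref <- (1 + sin(q * 20) / (q * 20)) / 2 * phi2
  expect_equal(I2 / I2[1], ref / ref[1], tolerance = 1e-6)
})

test_that("forward intensity conserves I(0) and the contrast-weighted Rg", {
  m <- fx_sphere100()$model
  cn <- water()
  w <- cn$delta_nucleic * (4 / 3) * pi * m$bead_radius^3
  I0 <- rnpsaxs:::cpp_debye(m$centers, rep(w, nrow(m$centers)),
                            m$bead_radius, 1e-9, binw = m$bead_radius / 2,
                            exact = FALSE)
  expect_equal(I0, (w * nrow(m$centers))^2, tolerance = 1e-9)
  # low-q limit Rg vs coordinate Rg (bead form adds (3/5) rb^2)
  g <- guinier_fit(fx_sphere100()$profile, curvature = TRUE)
  rg_coord <- sqrt(rnpsaxs:::model_rg(m, cn)^2 + 0.6 * m$bead_radius^2)
  expect_equal(g$rg, rg_coord, tolerance = 0.01)
})

test_that("scattering is invariant under rigid motion of the model", {
  m <- build_phantom(phantom_spec("oblate", c(80, 80, 30),
                                  lattice_spacing = 5))
  q <- q_default(40)
  I_ref <- simulate_profile(m, water(), q, exact = TRUE)$intensity
  a <- 0.6
  R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  m2 <- m
  m2$centers <- m$centers %*% R +
    matrix(rep(c(17, -8, 31), each = nrow(m$centers)), ncol = 3)
  I_rot <- simulate_profile(m2, water(), q, exact = TRUE)$intensity
  expect_equal(I_rot, I_ref, tolerance = 1e-9)
})

test_that("a matched phase contributes nothing at its match point", {
  spec <- phantom_spec("concentric-shell", c(80, 80, 80),
                       lattice_spacing = 10)
  m <- build_phantom(spec)
  wstar <- match_point_sucrose(0.425)
  cn <- contrast_condition(wstar)
  q <- q_default(40)
  I_full <- simulate_profile(m, cn, q)$intensity
  shell <- bead_model(m$centers[m$phases == "nucleic", ], m$bead_radius,
                      "nucleic", m$lattice)
  I_shell <- simulate_profile(shell, cn, q)$intensity
  expect_equal(I_full, I_shell, tolerance = 1e-6)
  # all contrasts zero -> degenerate
  rho0 <- solvent_electron_density(0)
  expect_error(simulate_profile(m, contrast_condition(0, rho0, rho0), q),
               "degenerate")
})

test_that("seeded noise is reproducible and unbiased", {
  p <- fx_sphere100()$profile
  ns <- noise_spec(0.02, 2, seed = 99)
  n1 <- add_noise(p, ns)
  n2 <- add_noise(p, ns)
  expect_identical(n1$intensity, n2$intensity)
  expect_false(identical(add_noise(p, noise_spec(0.02, 2, seed = 100))$intensity,
                         n1$intensity))
  # zero noise: intensities unchanged, placeholder sigma attached
  n0 <- add_noise(p, noise_spec(0, 2, seed = 1))
  expect_identical(n0$intensity, p$intensity)
  expect_true(all(n0$sigma > 0))
  # z-scores across many points average out near zero
  q <- rnpsaxs:::default_q_grid(500)
  pfine <- simulate_profile(fx_sphere100()$model, water(), q)
  nz <- add_noise(pfine, noise_spec(0.02, 2, seed = 3))
  z <- (nz$intensity - pfine$intensity) / nz$sigma
  expect_lt(abs(mean(z)), 0.15)
})
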