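test_that("mean contrast is the volume-weighted phase contrast", {
  cn <- contrast_condition(0)
  cn$delta_protein <- 0.1; cn$delta_nucleic <- 0.2
  expect_equal(as.numeric(mean_contrast(cn, c(1, 1))), 0.15)
  cn$delta_protein <- 0; cn$delta_nucleic <- 0.216
  expect_equal(as.numeric(mean_contrast(cn, c(1, 2))), 0.144)
  cn$delta_protein <- 0.1; cn$delta_nucleic <- -0.05
  mp <- mean_contrast(cn, c(1, 2))
  expect_equal(as.numeric(mp), 0)
  expect_true(isTRUE(attr(mp, "match_point")))
})

test_that("a homogeneous particle gives a flat Stuhrmann plot", {
  spec <- phantom_spec("sphere", 100, lattice_spacing = 10)
  syn <- synthesize_series(spec, c(0, 0.165, 0.325, 0.488),
                           noise = noise_spec(0.01, 2, perturb = FALSE),
                           q_grid = q_default(100))
  ser <- contrast_series(syn$conditions, syn$profiles, c(1, 1e5),
                         guinier_args = list(curvature = TRUE))
  f <- stuhrmann_fit(ser)
  expect_equal(f$rc, syn$truth$shape_rg, tolerance = 0.01)
  # alpha and beta indistinguishable from zero at the Rg^2 scale
  expect_lt(abs(f$alpha_s) * max(abs(f$x)), 0.01 * f$rc^2)
  expect_lt(abs(f$beta_s) * max(f$x^2), 0.01 * f$rc^2)
})

test_that("a dense shell around a light core gives alpha > 0, beta near 0", {
  syn <- fx_series("concentric-shell", c(120, 120, 120))
  f <- stuhrmann_fit(syn$series)
  expect_gt(f$alpha_s, 0)
  expect_gt(f$alpha_s / sqrt(f$covariance[2, 2]), 5)      # decisively positive
  expect_lt(abs(f$beta_s) * max(f$x^2), 0.02 * f$rc^2)    # no displacement term
  expect_equal(f$rc, syn$truth$shape_rg, tolerance = 0.02)
  # apparent Rg grows as sucrose lowers the mean contrast (the sign anchor
  # for a low-density component at the centre of mass)
  rgs <- vapply(syn$series$entries, function(e) e$guinier$rg, 1)
  expect_true(all(diff(rgs) > 0))
})

test_that("a displaced core turns on the beta term", {
  syn <- fx_series("displaced-core", c(160, 120, 120), off = 40)
  f <- stuhrmann_fit(syn$series)
  expect_gt(f$beta_s, 0)
  expect_gt(f$beta_s / sqrt(f$covariance[3, 3]), 5)
  # and the F-test prefers the full model over beta = 0
  expect_lt(f$f_test$p, 0.05)
})

test_that("the closed-form two-phase Rg reproduces the simulated trend", {
  # oracle: Rg^2 = sum f_i (Rg_i^2 + d_i^2), f_i = drho_i V_i / sum
  syn <- fx_series("concentric-shell", c(120, 120, 120))
  m <- syn$model
  vb <- (4 / 3) * pi * m$bead_radius^3
  for (i in seq_along(syn$conditions)) {
    cn <- syn$conditions[[i]]
    dr <- rnpsaxs:::phase_contrasts(cn)
    parts <- lapply(c("protein", "nucleic"), function(ph) {
      sel <- m$phases == ph
      X <- m$centers[sel, , drop = FALSE]
      ctr <- colMeans(X)
      rg2 <- mean(rowSums(sweep(X, 2, ctr)^2)) + 0.6 * m$bead_radius^2
      w <- dr[[ph]] * vb * sum(sel)
      c(w = w, rg2 = rg2, d2 = sum(ctr^2))
    })
    w <- vapply(parts, `[[`, 1, "w")
    rg2 <- vapply(parts, `[[`, 1, "rg2")
    d2 <- vapply(parts, `[[`, 1, "d2")
    rg_oracle <- sqrt(sum(w * (rg2 + d2)) / sum(w))
    expect_equal(syn$series$entries[[i]]$guinier$rg, rg_oracle,
                 tolerance = 0.01)
  }
})

test_that("three points solve exactly and predict a held-out contrast", {
  syn4 <- fx_series("concentric-shell", c(120, 120, 120))
  ser3 <- contrast_series(syn4$conditions[1:3], syn4$profiles[1:3],
                          unname(syn4$truth$volumes),
                          guinier_args = list(curvature = TRUE))
  f3 <- stuhrmann_fit(ser3)
  expect_equal(f3$n_points, 3)
  # exact interpolation of the three fitted points
  pred <- sqrt(f3$rc^2 + f3$alpha_s * f3$x - f3$beta_s * f3$x^2)
  expect_equal(pred^2, f3$rg2, tolerance = 1e-8)
  # held-out 4th condition
  db4 <- as.numeric(mean_contrast(syn4$conditions[[4]],
                                  unname(syn4$truth$volumes)))
  g4 <- syn4$series$entries[[4]]$guinier
  expect_equal(predict_rg(f3, db4), g4$rg, tolerance = 0.01)
  # infinite-contrast limit returns rc
  expect_equal(predict_rg(f3, 1e9), f3$rc, tolerance = 1e-6)
})

test_that("the fit is invariant under uniform intensity rescaling", {
  syn <- fx_series("concentric-shell", c(120, 120, 120))
  prof2 <- lapply(syn$profiles, function(p) {
    p$intensity <- p$intensity * 2.3e5
    p$sigma <- p$sigma * 2.3e5
    p
  })
  ser2 <- contrast_series(syn$conditions, prof2, unname(syn$truth$volumes),
                          guinier_args = list(curvature = TRUE))
  f1 <- stuhrmann_fit(syn$series)
  f2 <- stuhrmann_fit(ser2)
  expect_equal(f2$rc, f1$rc, tolerance = 1e-8)
  expect_equal(f2$alpha_s, f1$alpha_s, tolerance = 1e-6)
})

test_that("match-point entries are excluded with a warning", {
  syn <- fx_series("concentric-shell", c(120, 120, 120))
  ser <- syn$series
  # rig one condition to the whole-particle match point
  e <- ser$entries[[2]]
  vol <- ser$volumes
  e$condition$delta_protein <- -vol[[2]] / vol[[1]] * e$condition$delta_nucleic
  ser$entries[[2]] <- e
  expect_warning(f <- stuhrmann_fit(ser), "match point")
  expect_equal(f$n_points, 3)
})
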