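# Reconstruction unit tests run on deliberately small grids; the full
# recovery study lives in test-acceptance.R and shares the cached ensemble.

small_setup <- function() fixture("recon_small", function() {
  spec <- phantom_spec("concentric-shell", c(84, 84, 84),
                       protein_fraction_volume = 0.3,
                       lattice_spacing = 12)
  syn <- synthesize_series(spec, c(0, 0.325, 0.65),
                           noise = noise_spec(0.01, 2, perturb = FALSE),
                           q_grid = rnpsaxs:::default_q_grid(50))
  vols <- unname(syn$truth$volumes)
  list(syn = syn, vols = vols,
       series = contrast_series(syn$conditions, syn$profiles, vols,
                                guinier_args = list(curvature = TRUE)))
})

test_that("search grid construction honors packing, determinism and limits", {
  g <- init_grid(240, 10, expected_volumes = c(3e5, 6e5), seed = 5)
  cell <- 20^3 / sqrt(2)
  expect_equal(nrow(g$centers), (4 / 3) * pi * 120^3 / cell, tolerance = 0.05)
  g2 <- init_grid(240, 10, expected_volumes = c(3e5, 6e5), seed = 5)
  expect_identical(g$phases, g2$phases)
  g3 <- init_grid(240, 10, expected_volumes = c(3e5, 6e5), seed = 6)
  expect_false(identical(g$phases, g3$phases))
  expect_error(init_grid(100, 10), "resolution")
})

test_that("the phantom scores near-optimally against its own data", {
  st <- small_setup()
  cfg <- anneal_config(110, st$syn$model$bead_radius,
                       expected_volumes = st$vols, seed = 1)
  sc <- model_score(st$syn$model, st$series, cfg)
  expect_true(all(sc$chi < 0.05))
  expect_equal(sc$penalties$phase_volume, 0, tolerance = 1e-3)
  expect_equal(sc$penalties$disconnect, 0)
  # randomly deleting beads always scores worse
  set.seed(31)
  worse <- replicate(20, {
    m <- st$syn$model
    drop <- sample(nrow(m$centers), round(0.1 * nrow(m$centers)))
    m$phases[drop] <- "solvent"
    model_score(m, st$series, cfg)$total
  })
  expect_true(all(worse > sc$total))
})

test_that("disconnected phases pay the component penalty", {
  st <- small_setup()
  cfg <- anneal_config(110, st$syn$model$bead_radius,
                       expected_volumes = st$vols, seed = 1)
  m <- st$syn$model
  # split the protein core: convert a slab through its middle (thicker than
  # the first neighbour shell) to nucleic
  sel <- m$phases == "protein" & abs(m$centers[, 1]) < 8
  m2 <- m
  m2$phases[sel] <- "nucleic"
  s0 <- model_score(m, st$series, cfg)
  s2 <- model_score(m2, st$series, cfg)
  expect_gt(s2$penalties$disconnect, 0)
})

test_that("annealing recovers a protein-core phantom deterministically", {
  st <- small_setup()
  cfg <- anneal_config(110, st$syn$model$bead_radius,
                       expected_volumes = st$vols, seed = 7)
  res <- anneal(st$series, cfg)
  expect_true(all(is.finite(res$chi_per_profile)))
  expect_true(all(res$chi_per_profile < 1.5))
  pc <- rnpsaxs:::phase_centroid(res$model, "protein")
  expect_lt(sqrt(sum(pc^2)), 2.5 * res$model$bead_radius)
  # bitwise reproducibility from the seed
  res2 <- anneal(st$series, cfg)
  expect_identical(res$model$phases, res2$model$phases)
  expect_identical(res$chi_per_profile, res2$chi_per_profile)
})

test_that("greedy mode decreases the score monotonically", {
  st <- small_setup()
  cfg <- anneal_config(110, st$syn$model$bead_radius,
                       expected_volumes = st$vols, seed = 3)
  res <- anneal(st$series, cfg, greedy = TRUE)
  expect_true(all(diff(res$trace) <= 1e-8))
})

test_that("a zero-information series raises the divergence warning", {
  st <- small_setup()
  # all profiles at the whole-particle match point: flat ~zero intensity
  q <- rnpsaxs:::default_q_grid(50)
  flat <- lapply(1:3, function(i)
    scattering_profile(q, rep(1e-12, 50), rep(1, 50)))
  conds <- lapply(c(0, 0.1, 0.2), contrast_condition)
  ser <- contrast_series(conds, flat, st$vols, guinier = vector("list", 3))
  cfg <- anneal_config(110, st$syn$model$bead_radius,
                       expected_volumes = st$vols, seed = 2,
                       moves_per_temperature = 500)
  expect_warning(anneal(ser, cfg), "divergence")
})

test_that("NSD obeys its closed form, symmetry and identity", {
  m <- small_setup()$syn$model
  expect_equal(as.numeric(nsd(m, m)), 0)
  lat <- list(spacing = 10, packing = "hcp")
  a <- bead_model(matrix(0, 1, 3), 5, "protein", lat)
  b <- bead_model(matrix(c(10, 0, 0), 1, 3), 5, "protein", lat)
  expect_equal(as.numeric(nsd(a, b)), 1)
  set.seed(8)
  r1 <- bead_model(matrix(runif(30, -40, 40), 10), 5, "protein", "free")
  r2 <- bead_model(matrix(runif(36, -40, 40), 12), 5, "nucleic", "free")
  expect_equal(as.numeric(nsd(r1, r2)), as.numeric(nsd(r2, r1)))
})

test_that("alignment recovers a rigidly transformed anisotropic model", {
  m <- build_phantom(phantom_spec("oblate", c(120, 90, 40),
                                  lattice_spacing = 6))
  a <- 0.8
  R <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3)
  m2 <- m
  m2$centers <- m$centers %*% R +
    matrix(rep(c(25, -40, 10), each = nrow(m$centers)), ncol = 3)
  al <- align(list(m, m2))
  expect_lt(as.numeric(nsd(al[[1]], al[[2]])), 0.05)
  # mirror image of a chiral model is only recovered with mirror search:
  # three unequal orthogonal arms meeting at a corner have no improper
  # symmetry, so their reflection is a genuine enantiomorph
  lat <- list(spacing = 10, packing = "hcp")
  arms <- rbind(cbind(10 * (0:6), 0, 0),
                cbind(0, 10 * (1:4), 0),
                cbind(0, 0, 10 * (1:2)))
  chir <- bead_model(arms, 5, "nucleic", lat)
  mm <- chir
  mm$centers[, 1] <- -mm$centers[, 1]
  al_no <- align(list(chir, mm))
  al_yes <- align(list(chir, mm), mirror = TRUE)
  expect_lt(as.numeric(nsd(al_yes[[1]], al_yes[[2]])) + 0.05,
            as.numeric(nsd(al_no[[1]], al_no[[2]])))
})

test_that("spherically symmetric models trigger the alignment ambiguity path", {
  m <- build_phantom(phantom_spec("sphere", 80, lattice_spacing = 8))
  expect_warning(align(list(m, m)), "ambiguous")
})

test_that("averaging identical models returns the model; deletions average out", {
  m <- small_setup()$syn$model
  av <- average_filter(list(m, m, m))
  expect_equal(av$nsd_mean_sd[["mean"]], 0)
  expect_equal(sort(table(av$filtered$phases)),
               sort(table(m$phases[m$phases != "solvent"])))
  # ten 5%-deleted copies filter back to the phantom volume
  set.seed(12)
  dels <- lapply(1:10, function(i) {
    mi <- m
    drop <- sample(nrow(m$centers), round(0.05 * nrow(m$centers)))
    mi$phases[drop] <- "solvent"
    mi
  })
  vc <- rnpsaxs:::cell_volume(m)
  avd <- average_filter(dels, expected_volumes =
                          c(sum(m$phases == "protein"),
                            sum(m$phases == "nucleic")) * vc)
  v_target <- sum(m$phases != "solvent")
  expect_equal(nrow(avd$filtered$centers), v_target, tolerance = 0.05)
  # mismatched lattices are refused
  m2 <- m; m2$lattice$spacing <- 7
  expect_error(average_filter(list(m, m2)), "grid error")
})
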