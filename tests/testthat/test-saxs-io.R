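test_that("profile containers validate their invariants", {
  q <- seq(0.01, 0.3, length.out = 20)
  expect_s3_class(scattering_profile(q, exp(-q^2)), "scattering_profile")
  expect_error(scattering_profile(q[1:7], exp(-q[1:7]^2)), "at least 8")
  expect_error(scattering_profile(c(-0.01, q[-1]), exp(-q^2)), "positive")
  expect_error(scattering_profile(rep(q[1], 20), exp(-q^2)), "increasing")
  expect_error(scattering_profile(q, exp(-q^2), sigma = rep(0, 20)), "sigma")
})

test_that("profile write/read round trip preserves data to 6 significant figures", {
  q <- seq(0.006, 0.3, length.out = 100)
  p <- scattering_profile(q, 1e4 * exp(-q^2 * 900), 50 * exp(-q^2 * 450),
                          label = "rt")
  f <- withr::local_tempfile(fileext = ".dat")
  write_profile(p, f)
  lines <- readLines(f)
  expect_length(lines, 101)  # header + 100 rows
  p2 <- read_profile(f)
  expect_equal(p2$q, p$q, tolerance = 1e-6)
  expect_equal(p2$intensity, p$intensity, tolerance = 1e-6)
  expect_equal(p2$sigma, p$sigma, tolerance = 1e-6)
})

test_that("2-column profiles read with sigma absent and a warning", {
  q <- seq(0.01, 0.2, length.out = 30)
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# q I", sprintf("%.6e %.6e", q, exp(-q^2 * 400))), f)
  expect_warning(p <- read_profile(f), "sigma")
  expect_null(p$sigma)
  # placeholder sigma kicks in for weighted work
  expect_true(all(rnpsaxs:::profile_sigma(p) > 0))
})

test_that("malformed profile files are rejected", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(sprintf("%g %g", c(1:4, 4, 5:9) / 100, 1:10), f)  # repeated q
  expect_error(read_profile(f), "increasing")
  writeLines(c("# hdr", "0.01 1.0", "0.02 2.0"), f)
  expect_error(read_profile(f), "fewer than 8")
  expect_error(read_profile(file.path(tempdir(), "no-such-file.dat")),
               "cannot read")
})

test_that("nm^-1 unit flag rescales q on read", {
  q_nm <- seq(0.1, 3, length.out = 20)  # nm^-1
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(sprintf("%.6e %.6e %.6e", q_nm, exp(-q_nm), 0.01 + 0 * q_nm), f)
  p <- read_profile(f, q_unit = "nm^-1")
  expect_equal(p$q, q_nm / 10, tolerance = 1e-6)
})

test_that("bead model write/read round trips through the PDB dialect", {
  m <- build_phantom(phantom_spec("concentric-shell", c(60, 60, 60),
                                  lattice_spacing = 10))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_bead_model(m, f)
  m2 <- read_bead_model(f)
  expect_equal(m2$centers, m$centers, tolerance = 1e-3)  # fixed width, 3 dp
  expect_identical(m2$phases, m$phases)
  expect_equal(m2$bead_radius, m$bead_radius)
  expect_equal(m2$lattice$spacing, m$lattice$spacing)
  # two phases -> two chain identifiers
  rec <- readLines(f)
  rec <- rec[grepl("^ATOM", rec)]
  expect_setequal(unique(substr(rec, 22, 22)), c("A", "B"))
})

test_that("bead model reader errors and fallbacks behave as documented", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK 265 BEAD RADIUS : 5.0", f)
  expect_error(read_bead_model(f), "no ATOM")
  # unknown residue name names the offender
  writeLines(c(
    "ATOM      1  CA  XXX A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  XXX A   2      10.000   0.000   0.000  1.00  0.00"), f)
  expect_error(read_bead_model(f), "XXX")
  # missing radius REMARK -> inferred from minimum spacing, with warning
  writeLines(c(
    "ATOM      1  CA  PRO A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  RNA B   2      10.000   0.000   0.000  1.00  0.00"), f)
  expect_warning(m <- read_bead_model(f), "inferred")
  expect_equal(m$bead_radius, 5)
})

test_that("coordinates beyond the PDB fixed-width range are refused", {
  m <- bead_model(rbind(c(0, 0, 0), c(10500, 0, 0)), 5,
                  c("protein", "nucleic"), lattice = "free")
  expect_error(write_bead_model(m, withr::local_tempfile(fileext = ".pdb")),
               "fixed-width")
})

test_that("written bead models parse with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  m <- fx_sphere100()$model
  f <- withr::local_tempfile(fileext = ".pdb")
  write_bead_model(m, f)
  pdb <- bio3d::read.pdb(f)
  expect_equal(nrow(pdb$atom), nrow(m$centers))
  expect_equal(unname(as.matrix(pdb$atom[, c("x", "y", "z")])),
               unname(m$centers), tolerance = 1e-3)
})
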