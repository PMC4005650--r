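# Shared fixtures. Heavy objects (bead phantoms, Debye profiles, annealing
# ensembles) are built once per test run and cached in this environment.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx)) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

q_default <- function(n = 120) rnpsaxs:::default_q_grid(n)

water <- function() contrast_condition(0)

# Debye-simulated solid sphere, diameter 100 A, 4 A lattice
fx_sphere100 <- function() fixture("sphere100", function() {
  model <- build_phantom(phantom_spec("sphere", 100, lattice_spacing = 4))
  list(model = model,
       profile = simulate_profile(model, water(), q_default()))
})

# fine-bead sphere for the acceptance sphere suite: radius 60 A, 5 A lattice
fx_sphere120 <- function() fixture("sphere120", function() {
  model <- build_phantom(phantom_spec("sphere", 120, lattice_spacing = 5))
  list(model = model,
       profile = simulate_profile(model, water(), q_default(150)))
})

# 4-contrast noiseless series from a phantom kind (1 % sigma band attached)
fx_series <- function(kind, dims, off = 0,
                      sucrose = c(0, 0.165, 0.325, 0.488),
                      spacing = min(dims) / 8, nq = 100) {
  key <- paste("series", kind, paste(dims, collapse = "x"), off,
               paste(sucrose, collapse = "_"), sep = "|")
  fixture(key, function() {
    spec <- phantom_spec(kind, dims, core_offset = off,
                         lattice_spacing = spacing)
    syn <- synthesize_series(spec, sucrose,
                             noise = noise_spec(0.01, 2, perturb = FALSE),
                             q_grid = rnpsaxs:::default_q_grid(nq))
    vols <- unname(syn$truth$volumes)
    vols[vols == 0] <- 1
    syn$series <- contrast_series(syn$conditions, syn$profiles, vols,
                                  guinier_args = list(curvature = TRUE))
    syn
  })
}

# reconstruction study conditions: protein-core shell phantom, wide-spread
# sucrose subset, search grid commensurate with the phantom lattice
fx_recon_setup <- function() fixture("recon_setup", function() {
  spec <- phantom_spec("concentric-shell", c(100, 100, 100),
                       protein_fraction_volume = 0.3,
                       lattice_spacing = 100 / 9)
  syn <- synthesize_series(spec, c(0, 0.325, 0.65),
                           noise = noise_spec(0.01, 2, perturb = FALSE),
                           q_grid = rnpsaxs:::default_q_grid(60))
  vols <- unname(syn$truth$volumes)
  list(syn = syn,
       series = contrast_series(syn$conditions, syn$profiles, vols,
                                guinier_args = list(curvature = TRUE)),
       vols = vols, rb = spec$lattice_spacing / 2, search = 130)
})

recon_config <- function(setup, seed) {
  anneal_config(setup$search, setup$rb, expected_volumes = setup$vols,
                seed = seed, q_max_fit = 0.15)
}

# ensemble of annealing replicates (the expensive fixture, built once and
# shared by the reconstruction-recovery and ensemble-stability tests)
fx_recon_ensemble <- function(n = 5) fixture("recon_ensemble", function() {
  setup <- fx_recon_setup()
  lapply(seq_len(n), function(s) anneal(setup$series, recon_config(setup, s)))
})

# bow-tie RNP phantom and its lobe-added variant (shared geometry)
fx_rnp_pair <- function() fixture("rnp_pair", function() {
  base <- phantom_spec("two-phase-RNP", c(244, 244, 79),
                       lattice_spacing = 79 / 7)
  lobe <- phantom_spec("RNP-plus-lobe", c(244, 244, 79),
                       lattice_spacing = 79 / 7,
                       lobe = list(offset = 140, diameter = 60))
  list(rnp = build_phantom(base), lobe = build_phantom(lobe))
})

# analytic sphere pair-distance distribution, diameter D
sphere_pr <- function(r, D) {
  p <- r^2 * (1 - 3 * r / (2 * D) + r^3 / (2 * D^3))
  p[r > D] <- 0
  p
}
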