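# Shared fixtures, memoised so expensive constructions run once per suite.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# adult sphere phantom at 2.5 mm voxels, with surface and full 10-5 montage
adult_phantom <- function() fixture("adult_phantom", {
  make_layered_head_phantom("adult", voxel_size = 2.5)
})

adult_surface <- function() fixture("adult_surface", {
  extract_scalp_surface(adult_phantom()$volume)
})

adult_montage10 <- function() fixture("adult_montage10", {
  construct_10_10(adult_surface(), adult_phantom()$fiducials)
})

adult_montage5 <- function() fixture("adult_montage5", {
  construct_10_5(adult_surface(), adult_montage10())
})

adult_all_pairs <- function() fixture("adult_all_pairs", {
  enumerate_all_pairs(adult_montage5())
})

# homogeneous gray-matter half-space and the Monte Carlo run validated
# against the diffusion oracle (the suite's most expensive simulation)
gm_halfspace <- function() fixture("gm_halfspace", {
  make_slab_phantom(list(list(tissue = "GM", thickness = 45)),
                    lateral_extent = 90, voxel_size = 1)
})

gm_halfspace_run <- function() fixture("gm_halfspace_run", {
  vol <- gm_halfspace()
  cfg <- simulation_config(n_photons = 1e6, seed = 11, keep_gates = FALSE)
  launch <- c(46, 46, 1.0)
  fl <- simulate_fluence(vol, default_media_table(), launch, c(0, 0, 1), cfg)
  list(volume = vol, fluence = fl, launch = launch)
}
)

# desk-scale separation experiment on the adult sphere (similarity media)
desk_experiment <- function() fixture("desk_experiment", {
  cfg <- experiment_config(phantom = "adult", voxel_size = 2, photons = 1e5,
                           seed = 5, n_meridians = 4,
                           out_dir = file.path(tempdir(), "dotsens_desk"))
  run_experiment(cfg, quiet = TRUE)
})

# infant-preset run at 20 and 50 mm with log-scale channel averaging
infant_experiment <- function() fixture("infant_experiment", {
  cfg <- experiment_config(phantom = "infant_3mo", voxel_size = 2,
                           photons = 1e5, seed = 9, targets = c(20, 50),
                           n_meridians = 4, average = "log",
                           out_dir = file.path(tempdir(), "dotsens_infant"))
  run_experiment(cfg, quiet = TRUE)
})

# small absorbing-only slab for ballistic attenuation checks
ballistic_run <- function() fixture("ballistic_run", {
  vol <- make_slab_phantom(list(list(tissue = "GM", thickness = 40)),
                           lateral_extent = 40, voxel_size = 1)
  med <- default_media_table()
  med$mu_s[med$name == "GM"] <- 1e-9
  med$mu_a[med$name == "GM"] <- 0.1
  cfg <- simulation_config(n_photons = 2e4, seed = 7)
  fl <- simulate_fluence(vol, med, c(21, 21, 1.0), c(0, 0, 1), cfg)
  list(volume = vol, media = med, fluence = fl, config = cfg)
})

# reciprocity runs: top-face vs side-face pencil sources in a GM block
reciprocity_runs <- function() fixture("reciprocity_runs", {
  vol <- make_slab_phantom(list(list(tissue = "GM", thickness = 30)),
                           lateral_extent = 50, voxel_size = 1)
  med <- default_media_table()
  A <- c(26, 26, 1.0); dA <- c(0, 0, 1)
  B <- c(1.0, 26, 16); dB <- c(1, 0, 0)
  getv <- function(cw, p) {
    mean(cw[(p[1] - 1):(p[1] + 1), (p[2] - 1):(p[2] + 1), (p[3] - 1):(p[3] + 1)])
  }
  res <- sapply(1:4, function(s) {
    cfgA <- simulation_config(n_photons = 8e4, seed = 100 + s,
                              boundary = "matched", keep_gates = FALSE)
    cfgB <- simulation_config(n_photons = 8e4, seed = 200 + s,
                              boundary = "matched", keep_gates = FALSE)
    fA <- sum_time_gates(simulate_fluence(vol, med, A, dA, cfgA))
    fB <- sum_time_gates(simulate_fluence(vol, med, B, dB, cfgB))
    c(AtoB = getv(fA, c(2, 26, 16)), BtoA = getv(fB, c(26, 26, 2)))
  })
  res
})

# mirror pairing of the 81 labels across the sagittal plane
mirror_pairs_1010 <- function() {
  grid <- dotsens:::ten10_grid()
  key <- paste(grid$row, 10 - grid$col)
  data.frame(label = grid$label,
             mirror = grid$label[match(paste(grid$row, grid$col), key)],
             stringsAsFactors = FALSE)
}
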