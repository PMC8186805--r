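#' Experiment configuration
#'
#' Describes an end-to-end depth-sensitivity run: phantom, media, optode
#' scheme, photon budget, seeds and separation targets.  The same
#' configuration and base seed always reproduce identical outputs.
#'
#' @param phantom an [age_preset()] name (sphere phantom) or `"slab"`.
#' @param voxel_size voxel edge length in mm.
#' @param photons photons per optode (>= 1e3).
#' @param seed base integer seed; optode `i` (in stable label order)
#'   simulates with seed `seed + i`, so adding optodes never perturbs
#'   existing simulations.
#' @param targets target separations, a subset of 10, 15, ..., 60 mm.
#' @param window selection half-window in mm.
#' @param scheme `"meridian"` (reduced optode subset: an apex source with
#'   detector arcs along meridians, desk scale), `"montage_centered"`
#'   (251 channels centred on 10-10 positions) or `"montage_all_pairs"`
#'   (full 358-optode enumeration; cluster scale at full photon counts).
#' @param n_meridians number of meridian arcs for the `"meridian"` scheme.
#' @param media `"default"`, a media table path (CSV/YAML), or a
#'   `media_table`.
#' @param similarity apply [similarity_scale()] to the media (desk-scale
#'   acceleration; see the methods vignette).
#' @param average `"linear"` or `"log"` profile averaging.
#' @param out_dir output directory.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(phantom = "adult", voxel_size = 2,
                              photons = 1e5, seed = 1L,
                              targets = seq(10, 60, by = 5), window = 2.5,
                              scheme = c("meridian", "montage_centered",
                                         "montage_all_pairs"),
                              n_meridians = 4, media = "default",
                              similarity = TRUE,
                              average = c("linear", "log"),
                              out_dir = tempfile("dotsens_run_")) {
  scheme <- match.arg(scheme)
  average <- match.arg(average)
  if (photons < 1e3) stop("photon count must be at least 1e3")
  if (!all(targets %in% seq(10, 60, by = 5))) {
    stop("targets must be a subset of 10, 15, ..., 60 mm")
  }
  structure(list(phantom = phantom, voxel_size = voxel_size,
                 photons = photons, seed = as.integer(seed),
                 targets = targets, window = window, scheme = scheme,
                 n_meridians = n_meridians, media = media,
                 similarity = similarity, average = average,
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Demonstration configurations at three scales
#'
#' `"smoke"` finishes in well under a minute on one CPU (tiny phantom,
#' 1e4 photons); `"desk"` is the workstation scale used throughout the
#' package's own experiments (sphere preset, 1e5 photons per optode,
#' reduced optode subset, minutes on one CPU); `"cluster"` is the
#' cluster-scale reference configuration (full 358-optode montage,
#' 1e8 photons per optode, 1 mm voxels) and is not intended to run on a
#' laptop.
#'
#' @param scale `"smoke"`, `"desk"` or `"cluster"`.
#' @param out_dir output directory.
#' @return An `experiment_config`.
#' @export
make_demo_config <- function(scale = c("smoke", "desk", "cluster"),
                             out_dir = tempfile("dotsens_run_")) {
  scale <- match.arg(scale)
  switch(scale,
    smoke = experiment_config(phantom = "neonate", voxel_size = 3,
                              photons = 1e4, targets = c(10, 20, 30),
                              n_meridians = 2, out_dir = out_dir),
    desk = experiment_config(phantom = "adult", voxel_size = 2,
                             photons = 1e5, out_dir = out_dir),
    cluster = experiment_config(phantom = "adult", voxel_size = 1,
                              photons = 1e8, scheme = "montage_all_pairs",
                              similarity = FALSE, out_dir = out_dir))
}

# stable FNV-1a hash of a configuration (cache key)
config_hash <- function(config, extra = NULL) {
  x <- config[setdiff(names(config), "out_dir")]
  s <- paste(deparse(c(x, extra)), collapse = "\n")
  bytes <- utf8ToInt(s)
  # 31-bit polynomial rolling hash (deterministic across sessions)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# apex + meridian-arc optode set on a (near-)spherical phantom surface
meridian_optode_set <- function(surface, targets, n_meridians) {
  ctr <- colMeans(surface$points)
  rad <- mean(sqrt(rowSums(sweep(surface$points, 2, ctr)^2)))
  on_sphere <- function(theta, phi) {
    ctr + rad * c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  }
  apex <- surface_nearest(surface, on_sphere(0, 0))
  labs <- "apex"; idxs <- apex
  for (m in seq_len(n_meridians)) {
    phi <- 2 * pi * (m - 1) / n_meridians
    for (d in targets) {
      theta <- d / rad
      idxs <- c(idxs, surface_nearest(surface, on_sphere(theta, phi)))
      labs <- c(labs, sprintf("m%d_d%d", m, d))
    }
  }
  data.frame(label = labs, index = idxs,
             x = surface$points[idxs, 1], y = surface$points[idxs, 2],
             z = surface$points[idxs, 3], stringsAsFactors = FALSE)
}

#' Run a depth-sensitivity experiment end to end
#'
#' Builds (or loads) the phantom, places optodes, simulates one fluence
#' volume per optode (cached on disk and reused when the configuration
#' hash matches), enumerates channels, computes the separation-resolved
#' depth profiles and writes tidy CSV outputs plus a run manifest.
#'
#' @param config an [experiment_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `experiment` (a `profile_experiment`),
#'   `channels`, `optodes`, `volume` and `out_dir`.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cache <- file.path(out, "cache")
  dir.create(cache, showWarnings = FALSE)

  media <- if (inherits(config$media, "media_table")) config$media
           else if (identical(config$media, "default")) default_media_table()
           else read_media_table(config$media)
  if (config$similarity) media <- similarity_scale(media)

  if (identical(config$phantom, "slab")) {
    vol <- make_slab_phantom(list(list(tissue = "skin", thickness = 4),
                                  list(tissue = "skull", thickness = 6),
                                  list(tissue = "CSF", thickness = 2),
                                  list(tissue = "GM", thickness = 30)),
                             lateral_extent = 80,
                             voxel_size = config$voxel_size)
    fiducials <- NULL
  } else {
    ph <- make_layered_head_phantom(config$phantom, voxel_size = config$voxel_size)
    vol <- ph$volume; fiducials <- ph$fiducials
  }
  say("phantom: %s voxels", paste(dim(vol$labels), collapse = "x"))
  surf <- extract_scalp_surface(vol)
  say("surface: %d points", nrow(surf$points))

  if (config$scheme == "meridian") {
    optodes <- meridian_optode_set(surf, config$targets, config$n_meridians)
  } else {
    mt <- construct_10_10(surf, fiducials)
    mt5 <- construct_10_5(surf, mt)
    optodes <- mt5$optodes
  }
  say("optodes: %d", nrow(optodes))

  hash <- config_hash(config)
  fluences <- list()
  n_sim <- 0L
  for (i in seq_len(nrow(optodes))) {
    lab <- optodes$label[i]
    f_nii <- file.path(cache, paste0("fluence_", lab, ".nii.gz"))
    f_meta <- paste0(f_nii, ".json")
    if (file.exists(f_nii) && file.exists(f_meta)) {
      meta <- jsonlite::read_json(f_meta)
      if (!identical(meta$hash, hash)) {
        stop("fluence cache at ", cache, " was produced by a different ",
             "configuration (hash ", meta$hash, " != ", hash,
             "); clear the cache directory to re-run")
      }
      fluences[[lab]] <- as.array(RNifti::readNifti(f_nii))
      next
    }
    idx <- optodes$index[i]
    cfg <- simulation_config(n_photons = config$photons,
                             seed = config$seed + i, keep_gates = FALSE)
    fl <- simulate_fluence(vol, media, surf$points[idx, ],
                           -surf$normals[idx, ], cfg)
    cw <- sum_time_gates(fl)
    attr(cw, "pixdim") <- rep(vol$voxel_size, 3)
    RNifti::writeNifti(RNifti::asNifti(cw, datatype = "double"), f_nii)
    attr(cw, "pixdim") <- NULL
    jsonlite::write_json(list(hash = hash, label = lab, seed = config$seed + i,
                              photons = config$photons),
                         f_meta, auto_unbox = TRUE, digits = NA)
    fluences[[lab]] <- cw
    n_sim <- n_sim + 1L
  }
  say("simulated %d optodes (%d from cache)", n_sim, nrow(optodes) - n_sim)

  channels <- if (config$scheme == "montage_centered") {
    centered_adjacent_channels(mt5, tier = "10-5")
  } else if (config$scheme == "montage_all_pairs") {
    enumerate_all_pairs(mt5)
  } else {
    enumerate_all_pairs(optodes, surf)
  }
  say("channels: %d", nrow(channels))
  write_channels(channels, file.path(out, "channels.csv"))

  exp <- profile_experiment(vol, fluences, channels,
                            targets = config$targets, window = config$window,
                            average = config$average)
  write_profiles(exp, out, group = as.character(config$phantom)[1])

  manifest <- list(hash = hash,
                   config = config[setdiff(names(config), "out_dir")],
                   optode_seeds = stats::setNames(config$seed + seq_len(nrow(optodes)),
                                                  optodes$label),
                   counts = list(optodes = nrow(optodes),
                                 channels = nrow(channels),
                                 separations = nrow(exp$hwhm)),
                   version = as.character(utils::packageVersion("dotsens")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  say("outputs written to %s", out)
  invisible(list(experiment = exp, channels = channels, optodes = optodes,
                 volume = vol, out_dir = out))
}
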