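#' Simulation configuration
#'
#' Bundles the Monte Carlo run parameters.  The reference configuration
#' follows the simulated study design: photons tracked over a 0-5 ns
#' window resolved into 50 time gates of 0.1 ns, at 690 nm.  The default
#' photon count here is a desk-scale 1e5; the cluster-scale reference
#' count of 1e8 is available through `n_photons`.
#'
#' @param n_photons number of photons to launch (>= 1).
#' @param t_max_ns time window in ns.
#' @param n_gates number of time gates (gate width `t_max_ns / n_gates`).
#' @param seed integer RNG seed; identical seed + config gives bit-identical output.
#' @param roulette_threshold photon weight below which Russian roulette triggers.
#' @param survival_prob roulette survival probability (surviving photons
#'   have their weight divided by this, keeping the estimator unbiased).
#' @param boundary `"fresnel"` (reflect at tissue-air interfaces with the
#'   unpolarised Fresnel probability) or `"matched"` (always escape).
#' @param wavelength_nm carried as metadata only.
#' @param keep_gates keep the per-gate 4-D fluence array; set `FALSE` to
#'   accumulate the continuous-wave sum directly (saves memory on large grids).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_photons = 1e5, t_max_ns = 5, n_gates = 50,
                              seed = 1L, roulette_threshold = 1e-4,
                              survival_prob = 0.1,
                              boundary = c("fresnel", "matched"),
                              wavelength_nm = 690, keep_gates = TRUE) {
  boundary <- match.arg(boundary)
  if (n_photons < 1) stop("n_photons must be at least 1")
  if (t_max_ns <= 0 || n_gates < 1) stop("invalid time gating")
  if (survival_prob <= 0 || survival_prob >= 1) stop("survival_prob must be in (0,1)")
  structure(list(n_photons = n_photons, t_max_ns = t_max_ns, n_gates = n_gates,
                 seed = as.integer(seed), roulette_threshold = roulette_threshold,
                 survival_prob = survival_prob, boundary = boundary,
                 wavelength_nm = wavelength_nm, keep_gates = keep_gates),
            class = "simulation_config")
}

#' Sample the cosine of the Henyey-Greenstein deflection angle
#'
#' Inverse-transform sampling of the Henyey-Greenstein phase function.
#' For `g = 0` this reduces to `2u - 1` (isotropic scattering); the first
#' moment of the sampled cosine equals `g`.  The azimuthal angle is drawn
#' separately, uniform on [0, 2 pi).
#'
#' @param g anisotropy, -1 < g < 1.
#' @param u uniform variate(s) in [0, 1).
#' @return Cosine(s) in [-1, 1].
#' @export
sample_scatter_cos <- function(g, u) {
  if (abs(g) >= 1) stop("anisotropy |g| must be < 1")
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  .mc_hg_cos(g, as.numeric(u))
}

#' Unpolarised Fresnel reflectance
#'
#' Average of the s- and p-polarised reflectances at a planar interface;
#' returns 1 beyond the critical angle when `n_in > n_out`.
#'
#' @param n_in,n_out refractive indices on the incident and far side.
#' @param cos_incident cosine of the incidence angle, in [0, 1].
#' @return Reflectance in [0, 1].
#' @export
fresnel_reflectance <- function(n_in, n_out, cos_incident) {
  if (n_in <= 0 || n_out <= 0) stop("refractive indices must be positive")
  if (any(cos_incident < 0 | cos_incident > 1)) stop("cos_incident must lie in [0, 1]")
  vapply(cos_incident, function(ci) .mc_fresnel(n_in, n_out, ci), 0)
}

#' Simulate a photon fluence volume (2-point Green's function)
#'
#' Launches photons at one optode position, pointing into the tissue, and
#' accumulates time-gated fluence in every voxel with a track-length
#' estimator (weight x path length, per launched photon, per voxel
#' volume).  Each photon is followed until it escapes through the scalp,
#' is terminated by Russian roulette, or reaches the end of the time
#' window.  Identical seed and configuration reproduce the output
#' bit-for-bit.
#'
#' @param volume a `labeled_volume`.
#' @param media a `media_table` covering every code in `volume`.
#' @param launch_position mm coordinates on (or just inside) the scalp surface.
#' @param launch_direction unit 3-vector pointing into the tissue.
#' @param config a [simulation_config()].
#' @return An object of class `fluence_volume`: per-gate (or gate-summed)
#'   fluence array plus energy-bookkeeping totals in photon-weight units
#'   (`absorbed`, `escaped`, `alive_at_tmax`, `roulette_killed`,
#'   `roulette_boost`).
#' @export
simulate_fluence <- function(volume, media, launch_position, launch_direction,
                             config = simulation_config()) {
  stopifnot(inherits(volume, "labeled_volume"), inherits(media, "media_table"),
            inherits(config, "simulation_config"))
  codes <- sort(unique(as.vector(volume$labels)))
  missing <- setdiff(codes, media$code)
  if (length(missing)) stop("media table lacks tissue code(s): ", paste(missing, collapse = ", "))
  maxcode <- max(media$code)
  mua <- mus <- gg <- numeric(maxcode + 1)
  nn <- rep(1, maxcode + 1)
  mua[media$code + 1] <- media$mu_a
  mus[media$code + 1] <- media$mu_s
  gg[media$code + 1] <- media$g
  nn[media$code + 1] <- media$n

  p0 <- as.numeric(launch_position) - volume$origin
  res <- .mc_simulate(as.integer(volume$labels), dim(volume$labels),
                      volume$voxel_size, mua, mus, gg, nn,
                      p0, as.numeric(launch_direction),
                      config$n_photons, config$t_max_ns, config$n_gates,
                      as.numeric(config$seed), config$roulette_threshold,
                      config$survival_prob, config$boundary == "fresnel",
                      config$keep_gates)
  d <- dim(volume$labels)
  fl <- res$fluence
  dim(fl) <- if (config$keep_gates) c(d, config$n_gates) else d
  structure(list(
    fluence = fl, gate_totals = res$gate_totals,
    per_gate = config$keep_gates,
    dims = d, voxel_size = volume$voxel_size, origin = volume$origin,
    n_photons = res$n_photons, seed = config$seed,
    t_max_ns = config$t_max_ns, n_gates = config$n_gates,
    launch_position = as.numeric(launch_position),
    launch_direction = as.numeric(launch_direction),
    absorbed = res$absorbed, escaped = res$escaped,
    alive_at_tmax = res$alive_at_tmax,
    roulette_killed = res$roulette_killed,
    roulette_boost = res$roulette_boost), class = "fluence_volume")
}

#' @export
print.fluence_volume <- function(x, ...) {
  cat(sprintf("Fluence volume: %s voxels, %s photons, seed %d%s\n",
              paste(x$dims, collapse = "x"), format(x$n_photons, big.mark = ","),
              x$seed, if (x$per_gate) sprintf(", %d gates", x$n_gates) else " (gate-summed)"))
  bal <- energy_balance(x)
  cat(sprintf("  escaped %.1f%%, absorbed %.1f%%, residual %.2e\n",
              100 * x$escaped / x$n_photons, 100 * x$absorbed / x$n_photons,
              bal$relative_residual))
  invisible(x)
}

#' Photon-weight conservation check
#'
#' `absorbed + escaped + alive_at_tmax + roulette_killed - roulette_boost`
#' must equal the launched photon count up to floating-point rounding.
#'
#' @param fluence a `fluence_volume`.
#' @return List with `total`, `launched` and `relative_residual`.
#' @export
energy_balance <- function(fluence) {
  tot <- fluence$absorbed + fluence$escaped + fluence$alive_at_tmax +
    fluence$roulette_killed - fluence$roulette_boost
  list(total = tot, launched = fluence$n_photons,
       relative_residual = abs(tot - fluence$n_photons) / fluence$n_photons)
}

#' Sum fluence over time gates (continuous-wave fluence)
#'
#' @param fluence a `fluence_volume`.
#' @return 3-D array of gate-summed fluence (mm^-2 per launched photon).
#' @export
sum_time_gates <- function(fluence) {
  stopifnot(inherits(fluence, "fluence_volume"))
  if (!fluence$per_gate) return(fluence$fluence)
  d <- fluence$dims
  cw <- fluence$fluence
  dim(cw) <- c(prod(d), fluence$n_gates)
  out <- rowSums(cw)
  dim(out) <- d
  out
}

#' Log-scaled sensitivity grid
#'
#' Base-10 logarithm of the fluence, floored at `floor`; voxels at or
#' below the floor are flagged as below detection.
#'
#' @param cw_fluence numeric array of non-negative fluence values.
#' @param floor positive detection floor.
#' @return List with `log10` (array) and `below_floor` (logical array).
#' @export
log_sensitivity <- function(cw_fluence, floor = 1e-12) {
  if (floor <= 0) stop("floor must be positive")
  below <- cw_fluence <= floor
  out <- log10(pmax(cw_fluence, floor))
  dim(out) <- dim(cw_fluence); dim(below) <- dim(cw_fluence)
  list(log10 = out, below_floor = below)
}

#' Closed-form diffusion oracle for a semi-infinite medium
#'
#' Extrapolated-boundary dipole solution for the continuous-wave surface
#' fluence of a pencil source on a homogeneous half-space:
#' an isotropic source at depth `z0 = 1/(mu_a + mu_s')` and a negative
#' image source mirrored about the extrapolated boundary at
#' `zb = 2 A D`, with `D = 1/(3 (mu_a + mu_s'))`,
#' `mu_eff = sqrt(3 mu_a (mu_a + mu_s'))` and the internal-reflection
#' parameter `A` from Groenhuis' polynomial in the relative index.
#' Used as an independent validation target for the Monte Carlo kernel;
#' valid in the diffusive regime (`mu_s' >> mu_a`, distance beyond a few
#' transport lengths).
#'
#' @param mu_a absorption coefficient, mm^-1.
#' @param mu_s_prime reduced scattering coefficient, mm^-1.
#' @param rho source-detector distance(s) along the surface, mm.
#' @param n_relative tissue/ambient refractive index ratio.
#' @return Fluence value(s) at the surface (arbitrary source strength).
#' @export
diffusion_cw_oracle <- function(mu_a, mu_s_prime, rho, n_relative = 1.37) {
  if (mu_s_prime < 10 * mu_a || any(rho < 3 / mu_s_prime)) {
    warning("parameters outside the diffusive regime; oracle value may be inaccurate")
  }
  mut <- mu_a + mu_s_prime
  D <- 1 / (3 * mut)
  mu_eff <- sqrt(3 * mu_a * mut)
  z0 <- 1 / mut
  Reff <- -1.440 / n_relative^2 + 0.710 / n_relative + 0.668 + 0.0636 * n_relative
  A <- (1 + Reff) / (1 - Reff)
  zb <- 2 * A * D
  r1 <- sqrt(rho^2 + z0^2)
  r2 <- sqrt(rho^2 + (z0 + 2 * zb)^2)
  (exp(-mu_eff * r1) / r1 - exp(-mu_eff * r2) / r2) / (4 * pi * D)
}
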