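#' Photon measurement density function (S-D channel sensitivity)
#'
#' Voxelwise product of the source-optode and detector-optode
#' continuous-wave fluence distributions (the 3-point Green's function).
#' No normalisation by the source fluence near the detector is applied;
#' the product is symmetric under swapping source and detector.
#'
#' @param source_fluence,detector_fluence gate-summed fluence arrays of
#'   identical dimensions (see [sum_time_gates()]), or `fluence_volume`s.
#' @param channel optional one-row channel data frame carried as metadata.
#' @return An object of class `pmdf_volume`: `values` (array), `channel`.
#' @export
pmdf <- function(source_fluence, detector_fluence, channel = NULL) {
  if (inherits(source_fluence, "fluence_volume")) source_fluence <- sum_time_gates(source_fluence)
  if (inherits(detector_fluence, "fluence_volume")) detector_fluence <- sum_time_gates(detector_fluence)
  if (!identical(dim(source_fluence), dim(detector_fluence))) {
    stop("source and detector fluence grids are not congruent: ",
         paste(dim(source_fluence), collapse = "x"), " vs ",
         paste(dim(detector_fluence), collapse = "x"))
  }
  structure(list(values = source_fluence * detector_fluence, channel = channel),
            class = "pmdf_volume")
}

#' Sampling-depth map for a channel
#'
#' Euclidean distance (mm) from the channel location (the halfway point
#' of the scalp path between the two optodes) to every voxel centre.
#'
#' @param channel one-row channel data frame with `channel_x/y/z`, or a
#'   length-3 mm coordinate.
#' @param volume a `labeled_volume` defining the grid.
#' @return 3-D array of distances in mm.
#' @export
sampling_depth_map <- function(channel, volume) {
  stopifnot(inherits(volume, "labeled_volume"))
  p <- if (is.data.frame(channel)) {
    c(channel$channel_x[1], channel$channel_y[1], channel$channel_z[1])
  } else as.numeric(channel)
  cc <- voxel_centres(volume)
  dx2 <- (cc$x - p[1])^2; dy2 <- (cc$y - p[2])^2; dz2 <- (cc$z - p[3])^2
  d <- dim(volume$labels)
  sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
}

#' Depth-binned sensitivity profile of one channel
#'
#' Bins head voxels (air excluded) by sampling depth into 1 mm bins
#' `(k-1, k]` for k = 1..`max_depth` and averages the channel sensitivity
#' within each bin.
#'
#' @param pmdf a `pmdf_volume` (or a plain array).
#' @param depth_map array from [sampling_depth_map()].
#' @param volume the `labeled_volume` (identifies air voxels).
#' @param max_depth deepest bin in mm (default 100).
#' @param statistic `"mean"` (default) or `"sum"` of voxel values per bin.
#' @return Object of class `depth_profile`: data frame with `depth_mm`
#'   (bin upper edge), `value`, `n_voxels`.
#' @export
depth_profile <- function(pmdf, depth_map, volume, max_depth = 100,
                          statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  vals <- if (inherits(pmdf, "pmdf_volume")) pmdf$values else pmdf
  if (!identical(dim(vals), dim(depth_map))) stop("grids are not congruent")
  head_vox <- volume$labels != 0L
  keep <- head_vox & depth_map <= max_depth
  b <- ceiling(depth_map[keep])
  b[b < 1] <- 1L
  v <- vals[keep]
  n <- tabulate(b, nbins = max_depth)
  s <- numeric(max_depth)
  agg <- tapply(v, b, sum)
  s[as.integer(names(agg))] <- agg
  value <- if (statistic == "mean") ifelse(n > 0, s / n, NA_real_) else s
  structure(data.frame(depth_mm = seq_len(max_depth), value = value,
                       n_voxels = n),
            class = c("depth_profile", "data.frame"), statistic = statistic)
}

#' Average sensitivity profiles across channels
#'
#' Per-bin mean and standard error of the mean over a set of congruent
#' depth profiles.
#'
#' @param profiles list of `depth_profile`s with identical bins.
#' @param label optional group label.
#' @return Object of class `profile_summary`: data frame with `depth_mm`,
#'   `mean`, `se`, `n_channels`.
#' @export
average_over_channels <- function(profiles, label = NULL) {
  if (length(profiles) == 0) stop("at least one profile is required")
  depths <- profiles[[1]]$depth_mm
  for (p in profiles) {
    if (!identical(p$depth_mm, depths)) stop("profiles have incongruent bins")
  }
  m <- vapply(profiles, function(p) p$value, numeric(length(depths)))
  m <- matrix(m, nrow = length(depths))
  n <- ncol(m)
  mu <- rowMeans(m)
  se <- if (n == 1) rep(0, length(depths)) else apply(m, 1, stats::sd) / sqrt(n)
  structure(data.frame(depth_mm = depths, mean = mu, se = se, n_channels = n),
            class = c("profile_summary", "data.frame"), label = label)
}

#' Half-width-half-maximum location of a depth profile
#'
#' Scans bins of increasing depth from the profile peak and returns the
#' first bin whose value is strictly below half of the maximum.  An exact
#' half value does not trigger; if no bin qualifies within the profile
#' range, the result is flagged as not crossing.
#'
#' @param profile a `depth_profile` (or `profile_summary`, using `mean`).
#' @return List of class `hwhm_result`: `hwhm_mm` (NA when no crossing),
#'   `peak_value`, `peak_depth_mm`, `crossed`.
#' @export
hwhm_location <- function(profile) {
  v <- if ("mean" %in% names(profile)) profile$mean else profile$value
  d <- profile$depth_mm
  ok <- !is.na(v)
  v <- v[ok]; d <- d[ok]
  if (!length(v) || max(v) <= 0) stop("profile has no positive maximum")
  ipk <- which.max(v)
  half <- v[ipk] / 2
  rest <- which(seq_along(v) > ipk & v < half)
  crossed <- length(rest) > 0
  structure(list(hwhm_mm = if (crossed) d[rest[1]] else NA_real_,
                 peak_value = v[ipk], peak_depth_mm = d[ipk],
                 crossed = crossed), class = "hwhm_result")
}

#' @export
print.hwhm_result <- function(x, ...) {
  cat(sprintf("HWHM location: %s mm (peak %.3g at %g mm)\n",
              if (x$crossed) format(x$hwhm_mm) else "not crossed",
              x$peak_value, x$peak_depth_mm))
  invisible(x)
}

#' Depth-sensitivity profiles by source-detector separation
#'
#' End-to-end sensitivity experiment on one head model: for each target
#' separation distance, takes the selected channels, multiplies the
#' source and detector fluence volumes into channel sensitivity (PMDF)
#' volumes, bins them by sampling depth, and summarises across channels
#' (per-bin mean, standard error, and HWHM locations).  Profiles are
#' computed on the linear fluence scale by default; `average = "log"`
#' summarises the base-10 log profiles instead (the scale on which
#' sensitivity is conventionally displayed).
#'
#' @param volume a `labeled_volume`.
#' @param fluences named list of `fluence_volume`s (or gate-summed
#'   arrays), one per optode label appearing in `channels`.
#' @param channels channel data frame (with `source`, `detector`,
#'   `separation_mm`, `channel_x/y/z`).
#' @param targets target separations in mm.
#' @param window selection half-window in mm.
#' @param max_depth deepest bin in mm.
#' @param average `"linear"` or `"log"`.
#' @param hwhm_per_channel compute HWHM per channel then average
#'   (default); otherwise on the channel-averaged profile.
#' @param log_floor detection floor used when `average = "log"`.
#' @param max_channels cap on channels per target (deterministic order);
#'   `Inf` for all.
#' @return List of class `profile_experiment`: `summaries` (tidy data
#'   frame over separation x depth), `hwhm` (per separation), `profiles`
#'   (list of per-channel profiles per separation).
#' @export
profile_experiment <- function(volume, fluences, channels,
                               targets = seq(10, 60, by = 5), window = 2.5,
                               max_depth = 100,
                               average = c("linear", "log"),
                               hwhm_per_channel = TRUE,
                               log_floor = 1e-30, max_channels = Inf) {
  average <- match.arg(average)
  cw <- lapply(fluences, function(f) {
    if (inherits(f, "fluence_volume")) sum_time_gates(f) else f
  })
  summaries <- list(); hwhm_rows <- list(); prof_store <- list()
  for (tg in targets) {
    sel <- suppressWarnings(select_by_target_separation(channels, tg, window))
    if (nrow(sel) == 0) next
    if (nrow(sel) > max_channels) sel <- sel[seq_len(max_channels), ]
    need <- unique(c(sel$source, sel$detector))
    miss <- setdiff(need, names(cw))
    if (length(miss)) stop("missing fluence volume(s) for optode(s): ",
                           paste(miss, collapse = ", "))
    profs <- vector("list", nrow(sel))
    for (i in seq_len(nrow(sel))) {
      pv <- pmdf(cw[[sel$source[i]]], cw[[sel$detector[i]]], sel[i, ])
      dm <- sampling_depth_map(sel[i, ], volume)
      profs[[i]] <- depth_profile(pv, dm, volume, max_depth = max_depth)
    }
    # HWHM always acts on the linear profiles; the log option only
    # changes the scale on which channels are averaged and spread
    profs_avg <- if (average == "log") {
      lapply(profs, function(p) { p$value <- log10(pmax(p$value, log_floor)); p })
    } else profs
    sm <- average_over_channels(profs_avg, label = paste0(tg, "mm"))
    sm$separation_mm <- tg
    summaries[[length(summaries) + 1L]] <- as.data.frame(sm)
    if (hwhm_per_channel) {
      hh <- vapply(profs, function(p) hwhm_location(p)$hwhm_mm, 0)
      pk <- vapply(profs, function(p) hwhm_location(p)$peak_value, 0)
      hwhm_rows[[length(hwhm_rows) + 1L]] <- data.frame(
        separation_mm = tg, hwhm_mm = mean(hh, na.rm = TRUE),
        peak = mean(pk), n_channels = length(profs),
        n_crossed = sum(!is.na(hh)))
    } else {
      hx <- hwhm_location(sm)
      hwhm_rows[[length(hwhm_rows) + 1L]] <- data.frame(
        separation_mm = tg, hwhm_mm = hx$hwhm_mm, peak = hx$peak_value,
        n_channels = nrow(sel), n_crossed = as.integer(hx$crossed))
    }
    prof_store[[paste0(tg, "mm")]] <- profs
  }
  structure(list(summaries = do.call(rbind, summaries),
                 hwhm = do.call(rbind, hwhm_rows),
                 profiles = prof_store, average = average),
            class = "profile_experiment")
}

#' @export
print.profile_experiment <- function(x, ...) {
  cat("Depth-sensitivity profile experiment\n")
  print(x$hwhm, row.names = FALSE)
  invisible(x)
}

#' Write profile experiment outputs as tidy CSVs
#'
#' @param experiment a `profile_experiment`.
#' @param dir output directory.
#' @param group group label recorded in the CSVs.
#' @return The two file paths, invisibly.
#' @export
write_profiles <- function(experiment, dir, group = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sm <- experiment$summaries
  sm <- data.frame(group = group, separation_mm = sm$separation_mm,
                   depth_bin_mm = sm$depth_mm, mean_fluence = sm$mean,
                   se_fluence = sm$se, n_channels = sm$n_channels)
  f1 <- file.path(dir, "profiles.csv")
  utils::write.csv(sm, f1, row.names = FALSE)
  hw <- data.frame(group = group, experiment$hwhm)
  f2 <- file.path(dir, "hwhm.csv")
  utils::write.csv(hw, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
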