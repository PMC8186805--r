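#' Construct a labeled volume
#'
#' The basic head-model container: a 3-D integer array of tissue codes on
#' an isotropic voxel grid, with a physical origin in mm.  Voxel
#' `[i, j, k]` (1-based) has its centre at
#' `origin + (c(i, j, k) - 0.5) * voxel_size`.
#'
#' @param labels 3-D integer array of tissue codes (0 = air).
#' @param voxel_size voxel edge length in mm (isotropic).
#' @param origin mm offset of the corner of voxel `[1,1,1]` (length 3).
#' @return An object of class `labeled_volume`.
#' @export
labeled_volume <- function(labels, voxel_size = 1, origin = c(0, 0, 0)) {
  stopifnot(length(dim(labels)) == 3, length(origin) == 3)
  if (voxel_size <= 0) stop("voxel_size must be positive")
  storage.mode(labels) <- "integer"
  known <- tissue_labels()$code
  bad <- setdiff(unique(as.vector(labels)), known)
  if (length(bad)) stop("unknown tissue code(s) in volume: ", paste(sort(bad), collapse = ", "))
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("Labeled volume: %d x %d x %d voxels @ %g mm\n", d[1], d[2], d[3], x$voxel_size))
  tab <- table(factor(tissue_name(as.vector(x$labels)), levels = tissue_labels()$name))
  tab <- tab[tab > 0]
  cat("  ", paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  invisible(x)
}

#' Voxel centre coordinates
#'
#' @param volume a `labeled_volume`.
#' @return A list with numeric vectors `x`, `y`, `z` of voxel-centre
#'   coordinates (mm) along each axis.
#' @keywords internal
voxel_centres <- function(volume) {
  d <- dim(volume$labels); h <- volume$voxel_size; o <- volume$origin
  list(x = o[1] + (seq_len(d[1]) - 0.5) * h,
       y = o[2] + (seq_len(d[2]) - 0.5) * h,
       z = o[3] + (seq_len(d[3]) - 0.5) * h)
}

#' Layered slab phantom
#'
#' Stacks tissue layers along the z axis (depth), starting at depth 0;
#' the deepest layer fills the remaining grid depth and a one-voxel air
#' margin surrounds the block on all sides.  Layer boundaries are
#' quantised to the nearest voxel edge, so with 1 mm voxels integer
#' thicknesses are reproduced exactly.
#'
#' @param layers list of `list(tissue, thickness)` pairs, outermost first.
#'   `tissue` is a name from [tissue_labels()]; `thickness` in mm.
#' @param lateral_extent lateral block size in mm (x and y).
#' @param voxel_size voxel edge length in mm.
#' @param depth total tissue depth in mm; defaults to the summed layer
#'   thicknesses. Must be at least their sum.
#' @return A `labeled_volume`.  Depth 0 (the outer tissue surface) lies at
#'   the z position of one voxel size (below the air margin).
#' @export
make_slab_phantom <- function(layers, lateral_extent = 60, voxel_size = 1,
                              depth = NULL) {
  th <- vapply(layers, function(l) as.numeric(l$thickness), 0)
  nm <- vapply(layers, function(l) as.character(l$tissue), "")
  bad <- which(!(th > 0))
  if (length(bad)) stop("layer '", nm[bad[1]], "' has non-positive thickness")
  codes <- tissue_code(nm)
  total <- sum(th)
  if (is.null(depth)) depth <- total
  if (depth < total - 1e-9) stop("total layer thickness exceeds grid depth")
  h <- voxel_size
  nl <- max(1L, round(lateral_extent / h))
  nz <- max(1L, round(depth / h))
  labels <- array(0L, dim = c(nl + 2L, nl + 2L, nz + 2L))
  # voxel edge indices (in tissue depth units) of the layer boundaries
  bnd <- round(cumsum(th) / h)
  bnd[length(bnd)] <- nz  # deepest layer fills remaining depth
  lo <- c(0L, bnd[-length(bnd)])
  for (k in seq_along(codes)) {
    if (bnd[k] > lo[k]) {
      zset <- (lo[k] + 1L):bnd[k]
      labels[2L:(nl + 1L), 2L:(nl + 1L), zset + 1L] <- codes[k]
    }
  }
  labeled_volume(labels, voxel_size = h)
}

#' Age presets for spherical head phantoms
#'
#' Layer thicknesses (mm) for the extracerebral tissues and the gray
#' matter shell, plus the outer (scalp) radius.  The scalp-to-cortex
#' distance (skin + skull + dura + CSF) is 8 mm for the 3-month preset and
#' 13 mm for the adult preset, the two values with direct literature
#' anchors; the remaining presets interpolate plausibly and are
#' configurable rather than claimed as anatomical ground truth.
#'
#' @param name one of `"neonate"`, `"infant_3mo"`, `"toddler_2yr"`,
#'   `"adult"`, or `NULL` to list all presets.
#' @return A list with fields `name`, `radius`, `skin`, `skull`, `dura`,
#'   `CSF`, `GM`, `scalp_to_cortex`; or a data frame of all presets.
#' @export
age_preset <- function(name = NULL) {
  presets <- list(
    neonate     = list(radius = 55, skin = 2, skull = 2, dura = 1, CSF = 2, GM = 3),
    infant_3mo  = list(radius = 65, skin = 2, skull = 3, dura = 1, CSF = 2, GM = 3),
    toddler_2yr = list(radius = 75, skin = 3, skull = 4, dura = 1, CSF = 2, GM = 4),
    adult       = list(radius = 85, skin = 4, skull = 6, dura = 1, CSF = 2, GM = 4)
  )
  if (is.null(name)) {
    return(do.call(rbind, lapply(names(presets), function(nm) {
      p <- presets[[nm]]
      data.frame(name = nm, radius = p$radius, skin = p$skin, skull = p$skull,
                 dura = p$dura, CSF = p$CSF, GM = p$GM,
                 scalp_to_cortex = p$skin + p$skull + p$dura + p$CSF)
    })))
  }
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ", paste(names(presets), collapse = ", "))
  }
  p <- presets[[name]]
  p$name <- name
  p$scalp_to_cortex <- p$skin + p$skull + p$dura + p$CSF
  p
}

#' Spherical layered head phantom with fiducials
#'
#' Concentric spheres centred in the grid: a white-matter core wrapped in
#' gray matter, CSF, dura, skull and skin shells.  Seven cranial fiducials
#' are returned at canonical surface points: Vz at the top pole (+z);
#' Nz (+y), Iz (-y), LPA (-x), RPA (+x) on the equatorial great circle;
#' LMa and RMa 10 mm below LPA and RPA along their meridians.
#'
#' @param preset an [age_preset()] list (or a preset name).
#' @param voxel_size voxel edge length in mm.
#' @return A list with components `volume` (a `labeled_volume`) and
#'   `fiducials` (data frame: name, x, y, z in mm).
#' @export
make_layered_head_phantom <- function(preset = "adult", voxel_size = 1) {
  if (is.character(preset)) preset <- age_preset(preset)
  th <- c(skin = preset$skin, skull = preset$skull, dura = preset$dura,
          CSF = preset$CSF, GM = preset$GM)
  if (any(th <= 0)) stop("layer '", names(th)[which(th <= 0)[1]], "' has non-positive thickness")
  R <- preset$radius
  if (R <= sum(th)) stop("outer radius must exceed the summed shell thicknesses")
  h <- voxel_size
  n <- 2L * ceiling(R / h) + 5L          # air margin of >= 2 voxels
  ctr <- rep((n / 2) * h, 3)             # sphere centre in mm
  ax <- (seq_len(n) - 0.5) * h - ctr[1]
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  r <- sqrt(r2)
  # shell outer radii, outermost first
  shells <- R - cumsum(c(0, th))
  codes <- tissue_code(c("skin", "skull", "dura", "CSF", "GM", "WM"))
  labels <- array(0L, dim = c(n, n, n))
  labels[r <= R] <- codes[1]
  for (k in seq_along(th)) labels[r <= shells[k + 1]] <- codes[k + 1]
  vol <- labeled_volume(labels, voxel_size = h)

  on_sphere <- function(u) ctr + R * u / sqrt(sum(u^2))
  phi <- 10 / R  # 10 mm of arc below the preauricular points
  fid <- rbind(
    Nz  = on_sphere(c(0,  1, 0)),
    Iz  = on_sphere(c(0, -1, 0)),
    Vz  = on_sphere(c(0, 0, 1)),
    LPA = on_sphere(c(-1, 0, 0)),
    RPA = on_sphere(c(1, 0, 0)),
    LMa = on_sphere(c(-cos(phi), 0, -sin(phi))),
    RMa = on_sphere(c(cos(phi), 0, -sin(phi)))
  )
  fiducials <- data.frame(name = rownames(fid), x = fid[, 1], y = fid[, 2],
                          z = fid[, 3], row.names = NULL, stringsAsFactors = FALSE)
  list(volume = vol, fiducials = fiducials, preset = preset)
}

#' Tabulate voxel counts per tissue
#'
#' @param volume a `labeled_volume`.
#' @return A data frame with columns `code`, `name`, `voxels`.
#' @export
label_counts <- function(volume) {
  stopifnot(inherits(volume, "labeled_volume"))
  tab <- table(as.vector(volume$labels))
  data.frame(code = as.integer(names(tab)),
             name = tissue_name(as.integer(names(tab))),
             voxels = as.integer(tab))
}
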