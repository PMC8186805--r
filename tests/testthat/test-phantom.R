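test_that("slab layers occupy the stated depth intervals", {
  vol <- make_slab_phantom(list(list(tissue = "skin", thickness = 3),
                                list(tissue = "skull", thickness = 3),
                                list(tissue = "CSF", thickness = 2),
                                list(tissue = "GM", thickness = 20)),
                           lateral_extent = 20, voxel_size = 1)
  code <- function(nm) dotsens:::tissue_code(nm)
  mid <- 11  # lateral centre (1-voxel air margin)
  # tissue depth d mm occupies array slice d + 1 (air margin at slice 1)
  expect_true(all(vol$labels[mid, mid, 2:4] == code("skin")))
  expect_true(all(vol$labels[mid, mid, 5:7] == code("skull")))
  expect_true(all(vol$labels[mid, mid, 8:9] == code("CSF")))
  expect_true(all(vol$labels[mid, mid, 10:29] == code("GM")))
  # everything outside the block is air
  expect_true(all(vol$labels[1, , ] == 0))
  expect_true(all(vol$labels[, , 1] == 0))
})

test_that("single-layer slab is a homogeneous block", {
  vol <- make_slab_phantom(list(list(tissue = "GM", thickness = 50)),
                           lateral_extent = 30, voxel_size = 1)
  inner <- vol$labels[2:31, 2:31, 2:51]
  expect_true(all(inner == dotsens:::tissue_code("GM")))
})

test_that("layer boundaries quantise to the nearest voxel edge", {
  # independent oracle: direct rounding arithmetic over thicknesses 1-5 mm
  h <- 2
  for (th in 1:5) {
    vol <- make_slab_phantom(list(list(tissue = "skin", thickness = th),
                                  list(tissue = "GM", thickness = 20)),
                             lateral_extent = 10, voxel_size = h)
    got <- sum(vol$labels == dotsens:::tissue_code("skin")) /
      sum(vol$labels[, , 2] != 0)  # skin voxels per lateral column
    expect_equal(got, round(th / h), info = paste("thickness", th))
    # realised thickness within one voxel of requested
    expect_lte(abs(got * h - th), h)
  }
})

test_that("slab rejects non-positive thickness, naming the layer", {
  expect_error(make_slab_phantom(list(list(tissue = "skin", thickness = 0),
                                      list(tissue = "GM", thickness = 10))),
               "skin")
})

test_that("every voxel carries exactly one label (partition)", {
  vol <- adult_phantom()$volume
  lc <- label_counts(vol)
  expect_equal(sum(lc$voxels), prod(dim(vol$labels)))
})

test_that("sphere presets reproduce the stated scalp-to-cortex distances", {
  dist_to_gm <- function(preset, h) {
    ph <- make_layered_head_phantom(preset, voxel_size = h)
    lab <- ph$volume$labels
    n <- dim(lab)[1]; mid <- ceiling(n / 2)
    col <- lab[mid, mid, ]          # axial column through the centre
    top <- max(which(col != 0))     # scalp surface voxel (from above)
    gm <- max(which(col == dotsens:::tissue_code("GM")))
    (top - gm) * h
  }
  expect_lte(abs(dist_to_gm("adult", 1) - 13), 1)
  expect_lte(abs(dist_to_gm("infant_3mo", 1) - 8), 1)
  expect_equal(age_preset("adult")$scalp_to_cortex, 13)
  expect_equal(age_preset("infant_3mo")$scalp_to_cortex, 8)
})

test_that("Nz-to-Iz geodesic over the vertex is half the great circle", {
  ph <- adult_phantom()
  surf <- adult_surface()
  fid <- ph$fiducials
  idx <- surface_nearest(surf, as.matrix(fid[match(c("Nz", "Vz", "Iz"), fid$name),
                                             c("x", "y", "z")]))
  path <- dotsens:::geodesic_polyline(surf, idx)
  expect_lt(abs(path$length / (pi * ph$preset$radius) - 1), 0.05)
})

test_that("phantom generation is deterministic and validates inputs", {
  a <- make_layered_head_phantom("neonate", voxel_size = 3)
  b <- make_layered_head_phantom("neonate", voxel_size = 3)
  expect_identical(a$volume$labels, b$volume$labels)
  expect_identical(a$fiducials, b$fiducials)
  bad <- age_preset("neonate"); bad$radius <- 5
  expect_error(make_layered_head_phantom(bad), "radius")
})

test_that("fiducials sit on the outer surface within half a voxel", {
  ph <- make_layered_head_phantom("toddler_2yr", voxel_size = 1)
  r <- sqrt(rowSums(sweep(as.matrix(ph$fiducials[, c("x", "y", "z")]), 2,
                          rep(dim(ph$volume$labels)[1] / 2 * 1, 3))^2))
  expect_true(all(abs(r - ph$preset$radius) < 0.5))
})
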