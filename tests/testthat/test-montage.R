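# Montage construction counts are forced by the shipped curve tables and
# must hold on any phantom that resolves the montage spacing.

test_that("the 10-10 construction yields 81 distinct on-surface positions", {
  m10 <- adult_montage10()
  surf <- adult_surface()
  expect_equal(nrow(m10$optodes), 81L)
  expect_equal(length(unique(m10$optodes$index)), 81L)
  expect_true(all(m10$optodes$index >= 1 & m10$optodes$index <= nrow(surf$points)))
})

test_that("Cz from the sagittal and coronal curves coincide", {
  m10 <- adult_montage10()
  surf <- adult_surface()
  cor <- dotsens:::geodesic_polyline(surf, m10$fiducial_idx[c("LPA", "Vz", "RPA")])
  cz_cor <- dotsens:::path_point_at(cor, 0.5, surf)
  pos <- stats::setNames(m10$optodes$index, m10$optodes$label)
  off <- sqrt(sum((surf$points[pos["Cz"], ] - surf$points[cz_cor, ])^2))
  expect_lte(off, 2 * surf$voxel_size)
})

test_that("positions are left-right mirror symmetric on a symmetric phantom", {
  m10 <- adult_montage10()
  surf <- adult_surface()
  pos <- stats::setNames(m10$optodes$index, m10$optodes$label)
  mp <- mirror_pairs_1010()
  ctrx <- mean(surf$points[, 1])
  offs <- vapply(seq_len(nrow(mp)), function(i) {
    p <- surf$points[pos[mp$label[i]], ]
    q <- surf$points[pos[mp$mirror[i]], ]
    sqrt(sum((c(2 * ctrx - p[1], p[2], p[3]) - q)^2))
  }, 0)
  expect_lte(max(offs), 2 * surf$voxel_size)
})

test_that("the 10-5 refinement yields 358 positions including all parents", {
  m10 <- adult_montage10()
  m5 <- adult_montage5()
  expect_equal(nrow(m5$optodes), 358L)
  expect_equal(length(unique(m5$optodes$index)), 358L)
  expect_equal(sum(m5$optodes$tier == "10-10"), 81L)
  # all 81 parents appear unchanged
  parents <- m5$optodes[match(m10$optodes$label, m5$optodes$label), ]
  expect_equal(parents$index, m10$optodes$index)
  expect_error(construct_10_5(adult_surface(), m5), "81")
})

test_that("inserted curve midpoints are arc-equidistant from their parents", {
  m5 <- adult_montage5()
  surf <- adult_surface()
  p5 <- stats::setNames(m5$optodes$index, m5$optodes$label)
  mids <- grep("-", m5$optodes$label[m5$optodes$tier == "10-5"], value = TRUE)
  eq <- vapply(mids, function(m) {
    ab <- strsplit(m, "-")[[1]]
    d <- surface_distances(surf, p5[m], p5[ab])
    abs(d[1] - d[2])
  }, 0)
  # equidistant up to the surface-graph resolution (~1 voxel, with a
  # half-voxel allowance for snapping both the midpoint and its parents)
  expect_lte(max(eq), 1.5 * surf$voxel_size)
})

test_that("all-pairs enumeration counts n(n-1)/2 channels", {
  ch <- adult_all_pairs()
  expect_equal(nrow(ch), 63903L)           # choose(358, 2)
  expect_true(all(ch$path_mm > 0))
  expect_equal(ch$separation_mm, ch$path_mm)
  # half-path convention
  m5 <- adult_montage5()
  three <- m5$optodes[m5$optodes$label %in% c("Cz", "Fpz", "Oz"), ]
  ch3 <- enumerate_all_pairs(three, adult_surface())
  expect_equal(nrow(ch3), 3L)
  ch3h <- enumerate_all_pairs(three, adult_surface(), separation = "half")
  expect_equal(ch3h$separation_mm, ch3$path_mm / 2)
})

test_that("channel locations sit halfway along the scalp path", {
  surf <- adult_surface()
  m5 <- adult_montage5()
  set.seed(2)
  ch <- adult_all_pairs()[sample(63903, 40), ]
  pos <- stats::setNames(m5$optodes$index, m5$optodes$label)
  for (i in seq_len(nrow(ch))) {
    mid <- surface_nearest(surf, c(ch$channel_x[i], ch$channel_y[i], ch$channel_z[i]))
    d <- surface_distances(surf, mid, pos[c(ch$source[i], ch$detector[i])])
    # the recorded midpoint is a path vertex: equidistant up to the
    # local edge length of the surface graph
    expect_lte(abs(d[1] - d[2]), 1.6 * surf$voxel_size)
  }
})

test_that("duplicate optode positions are rejected by name", {
  m5 <- adult_montage5()
  two <- m5$optodes[m5$optodes$label %in% c("Cz", "Fpz"), ]
  dup <- rbind(two, two[1, ])
  dup$label[3] <- "Cz2"
  expect_error(enumerate_all_pairs(dup, adult_surface()), "Cz")
})

test_that("centred-adjacent channels number 251 per tier", {
  m5 <- adult_montage5()
  ch10 <- centered_adjacent_channels(m5, "10-10")
  ch5 <- centered_adjacent_channels(m5, "10-5")
  expect_equal(nrow(ch10), 251L)
  expect_equal(nrow(ch5), 251L)
  # the 10-5 tier halves the flanking span
  expect_lt(mean(ch5$separation_mm) / mean(ch10$separation_mm), 0.55)
  expect_gt(mean(ch5$separation_mm) / mean(ch10$separation_mm), 0.45)
  # no channel pair repeats; all centres are 10-10 positions
  expect_equal(anyDuplicated(paste(ch10$source, ch10$detector)), 0L)
  lab10 <- m5$optodes$label[m5$optodes$tier == "10-10"]
  expect_true(all(ch10$center %in% lab10))
  # fiducial-centred combinations (nasion, preauricular) are excluded
  expect_false(any(ch10$center %in% c("Nz", "T9", "T10")))
  # arm equidistance: combinatorial centring deviates from geometric
  # centring by at most 25% of the scalp path on a spherical head
  expect_lte(max(ch10$midpoint_offset_mm / ch10$path_mm), 0.25)
  expect_lte(max(ch5$midpoint_offset_mm / ch5$path_mm), 0.25)
})

test_that("centred channels can be filtered by a strict midpoint tolerance", {
  m5 <- adult_montage5()
  expect_warning(strict <- centered_adjacent_channels(m5, "10-10", tolerance = 2),
                 "dropped")
  expect_lt(nrow(strict), 251L)
  expect_true(all(strict$midpoint_offset_mm <= 2))
})

test_that("separation selection windows behave as specified", {
  ch <- adult_all_pairs()
  # contiguous +/-2.5 mm windows partition the 10-60 mm range
  sel <- lapply(seq(10, 60, 5), function(tg)
    select_by_target_separation(ch, tg, 2.5))
  ids <- unlist(lapply(sel, function(s) paste(s$source, s$detector)))
  in_range <- ch[ch$separation_mm >= 7.5 & ch$separation_mm <= 62.5, ]
  expect_gte(length(ids), nrow(in_range))   # boundary channels may repeat
  expect_equal(length(unique(ids)), nrow(in_range))
  # empty selection warns and returns zero rows
  tiny <- ch[ch$separation_mm >= 20, ]
  expect_warning(out <- select_by_target_separation(tiny, 10, 2.5), "no channels")
  expect_equal(nrow(out), 0L)
  # count is monotone in the window width
  counts <- vapply(seq(0.5, 5, by = 0.5), function(w)
    nrow(suppressWarnings(select_by_target_separation(ch, 30, w))), 0L)
  expect_true(all(diff(counts) >= 0))
  expect_error(select_by_target_separation(ch, 12, 2.5), "target")
})

test_that("optode and channel tables round-trip through CSV", {
  m5 <- adult_montage5()
  f <- tempfile(fileext = ".csv")
  write_optodes(m5, f)
  back <- read_optodes(f, adult_surface())
  expect_equal(nrow(back), 358L)
  expect_equal(back$index, m5$optodes$index)
  f2 <- tempfile(fileext = ".csv")
  ch <- centered_adjacent_channels(m5, "10-10")
  write_channels(ch, f2)
  expect_equal(nrow(read.csv(f2)), 251L)
})
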