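test_that("channel sensitivity is a commutative voxelwise product", {
  a <- array(runif(27), c(3, 3, 3)); b <- array(runif(27), c(3, 3, 3))
  expect_identical(pmdf(a, b)$values, pmdf(b, a)$values)  # bitwise
  ones <- array(1, c(3, 3, 3))
  expect_equal(pmdf(a, ones)$values, a)
  expect_equal(pmdf(a, array(0, c(3, 3, 3)))$values, array(0, c(3, 3, 3)))
  expect_error(pmdf(a, array(0, c(2, 3, 3))), "congruent")
})

test_that("sampling depth is the Euclidean distance to the channel location", {
  vol <- make_slab_phantom(list(list(tissue = "GM", thickness = 20)),
                           lateral_extent = 20, voxel_size = 1)
  p <- c(10.5, 10.5, 1.5)  # a voxel centre at the slab surface
  dm <- sampling_depth_map(p, vol)
  expect_equal(dm[11, 11, 2], 0)
  expect_equal(dm[11, 11, 12], 10)
  # mirror symmetry about the channel location
  expect_equal(dm[11 + 3, 11, 2], dm[11 - 3, 11, 2])
  expect_equal(dm[11, 11 + 5, 7], dm[11, 11 - 5, 7])
})

test_that("depth profiles bin head voxels into (k-1, k] mm shells", {
  vol <- make_slab_phantom(list(list(tissue = "GM", thickness = 20)),
                           lateral_extent = 20, voxel_size = 1)
  dm <- sampling_depth_map(c(10.5, 10.5, 1.5), vol)
  # uniform sensitivity: every populated bin has that value
  u <- array(0.7, dim(vol$labels))
  pr <- depth_profile(u, dm, vol, max_depth = 15)
  expect_true(all(abs(pr$value[pr$n_voxels > 0] - 0.7) < 1e-12))
  # sensitivity confined to one shell leaves the others at zero
  v <- array(0, dim(vol$labels))
  v[dm > 4 & dm <= 5 & vol$labels != 0] <- 2
  pr2 <- depth_profile(v, dm, vol, max_depth = 15)
  expect_true(all(pr2$value[pr2$n_voxels > 0][-5] == 0))
  expect_gt(pr2$value[5], 0)
  # partition identity: bin populations count every head voxel in range
  expect_equal(sum(pr$n_voxels), sum(vol$labels != 0 & dm <= 15))
  # mass identity: sum(mean x count) equals the total over the region
  pr3 <- depth_profile(v, dm, vol, max_depth = 15)
  expect_equal(sum(pr3$value * pr3$n_voxels), sum(v[vol$labels != 0 & dm <= 15]))
})

test_that("channel averaging gives the closed-form mean and standard error", {
  mk <- function(vals) structure(data.frame(depth_mm = seq_along(vals),
                                            value = vals,
                                            n_voxels = rep(1, length(vals))),
                                 class = c("depth_profile", "data.frame"))
  one <- average_over_channels(list(mk(c(2, 4))))
  expect_equal(one$mean, c(2, 4))
  expect_equal(one$se, c(0, 0))
  two <- average_over_channels(list(mk(c(2, 2)), mk(c(4, 4))))
  expect_equal(two$mean, c(3, 3))
  expect_equal(two$se, c(1, 1))      # sd(2,4)/sqrt(2) = sqrt(2)/sqrt(2)
  expect_error(average_over_channels(list()), "at least one")
})

test_that("standard error shrinks as 1/sqrt(n) for replicated profiles", {
  mk <- function(vals) structure(data.frame(depth_mm = seq_along(vals),
                                            value = vals, n_voxels = 1),
                                 class = c("depth_profile", "data.frame"))
  set.seed(99)
  base <- replicate(64, mk(rnorm(5, mean = 10)), simplify = FALSE)
  se16 <- mean(average_over_channels(base[1:16])$se)
  se64 <- mean(average_over_channels(base)$se)
  expect_lt(abs(se16 / se64 - 2), 0.8)  # ratio ~ sqrt(64/16) = 2
})

test_that("HWHM location scans strictly below half maximum", {
  mk <- function(vals) data.frame(depth_mm = seq_along(vals), value = vals)
  r <- hwhm_location(mk(c(10, 8, 6, 4, 3, 2)))
  expect_equal(r$hwhm_mm, 4)           # first value strictly below 5
  expect_equal(r$peak_value, 10)
  expect_equal(r$peak_depth_mm, 1)
  # flat profile never crosses
  flat <- hwhm_location(mk(rep(5, 6)))
  expect_false(flat$crossed)
  expect_true(is.na(flat$hwhm_mm))
  # an exact half value does not trigger; the next lower bin does
  r2 <- hwhm_location(mk(c(10, 7, 5, 4)))
  expect_equal(r2$hwhm_mm, 4)
  expect_error(hwhm_location(mk(c(0, 0))), "positive")
})
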