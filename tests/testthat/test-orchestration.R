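smoke_cfg <- function(dir, seed = 3) {
  experiment_config(phantom = "neonate", voxel_size = 3, photons = 1e4,
                    seed = seed, targets = c(10, 20, 30), n_meridians = 2,
                    out_dir = dir)
}

test_that("identical configurations reproduce byte-identical outputs", {
  d1 <- file.path(tempdir(), "dotsens_smoke1")
  d2 <- file.path(tempdir(), "dotsens_smoke2")
  unlink(c(d1, d2), recursive = TRUE)
  r1 <- run_experiment(smoke_cfg(d1), quiet = TRUE)
  r2 <- run_experiment(smoke_cfg(d2), quiet = TRUE)
  for (f in c("profiles.csv", "hwhm.csv", "channels.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_true(file.exists(file.path(d1, "manifest.json")))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$counts$optodes, nrow(r1$optodes))
})

test_that("the fluence cache is reused and selectively rebuilt", {
  d <- file.path(tempdir(), "dotsens_smoke_cache")
  unlink(d, recursive = TRUE)
  run_experiment(smoke_cfg(d), quiet = TRUE)
  # second run: everything cached
  msgs <- capture_messages(run_experiment(smoke_cfg(d)))
  expect_true(any(grepl("simulated 0 optodes", msgs)))
  # delete one cached volume: only that optode is resimulated
  one <- list.files(file.path(d, "cache"), pattern = "\\.nii.gz$", full.names = TRUE)[1]
  unlink(c(one, paste0(one, ".json")))
  msgs <- capture_messages(run_experiment(smoke_cfg(d)))
  expect_true(any(grepl("simulated 1 optodes", msgs)))
})

test_that("a cache from a different configuration is refused", {
  d <- file.path(tempdir(), "dotsens_smoke_hash")
  unlink(d, recursive = TRUE)
  run_experiment(smoke_cfg(d), quiet = TRUE)
  cfg2 <- smoke_cfg(d, seed = 4)
  expect_error(run_experiment(cfg2, quiet = TRUE), "clear the cache")
})

test_that("invalid configurations are rejected up front", {
  expect_error(experiment_config(targets = c(10, 12)), "targets")
  expect_error(experiment_config(photons = 100), "photon")
  expect_error(run_experiment(list()), "experiment_config")
})

test_that("demo configurations encode the three scales", {
  expect_equal(make_demo_config("smoke")$photons, 1e4)
  desk <- make_demo_config("desk")
  expect_equal(desk$photons, 1e5)
  expect_equal(desk$targets, seq(10, 60, by = 5))
  big <- make_demo_config("cluster")
  expect_equal(big$photons, 1e8)
  expect_equal(big$scheme, "montage_all_pairs")
  expect_false(big$similarity)
  expect_equal(big$voxel_size, 1)
})
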