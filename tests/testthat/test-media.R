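test_that("shipped optical properties match the 690 nm reference table", {
  med <- default_media_table()
  expect_equal(unlist(media_lookup(med, "WM")), c(mu_a = 0.07, mu_s = 40.1, g = 0.85, n = 1.37))
  expect_equal(unlist(media_lookup(med, "CSF")), c(mu_a = 4e-4, mu_s = 1, g = 0.99, n = 1.37))
  expect_equal(unlist(media_lookup(med, "skull")), c(mu_a = 0.0101, mu_s = 100, g = 0.99, n = 1.37))
  expect_equal(unlist(media_lookup(med, "GM")), c(mu_a = 0.02, mu_s = 8.4, g = 0.90, n = 1.37))
  # eyes mimic CSF; non-myelinated axons mimic white matter
  expect_equal(media_lookup(med, "eyes"), media_lookup(med, "CSF"), ignore_attr = TRUE)
  expect_equal(media_lookup(med, "NMA"), media_lookup(med, "WM"), ignore_attr = TRUE)
  expect_true(all(med$n[med$code != 0] == 1.37))
  expect_equal(med$mu_a[med$name == "air"], 0)
  expect_equal(med$mu_s[med$name == "air"], 0)
  expect_equal(attr(med, "wavelength_nm"), 690)
})

test_that("reduced scattering is mu_s (1 - g); CSF is water-like", {
  musp <- reduced_scattering(default_media_table())
  expect_equal(unname(musp["CSF"]), 1 * (1 - 0.99))
  expect_equal(unname(musp["GM"]), 8.4 * 0.1)
  expect_true(all(musp >= 0))
})

test_that("lookups fail informatively for unknown tissues", {
  med <- default_media_table()
  expect_error(media_lookup(med, "bone"), "bone")
  expect_error(media_lookup(med, 42L), "42")
})

test_that("similarity scaling preserves mu_s' and zeroes anisotropy", {
  med <- default_media_table()
  sc <- similarity_scale(med)
  expect_equal(reduced_scattering(sc), reduced_scattering(med))
  expect_true(all(sc$g[sc$code != 0] == 0))
  # shipped defaults must not be mutated
  expect_equal(default_media_table()$g[default_media_table()$name == "GM"], 0.90)
})

test_that("media overrides replace named tissues and keep the rest", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(tissue = "GM", mu_a = 0.03, mu_s = 9, g = 0.9, n = 1.4),
            f, row.names = FALSE)
  ov <- read_media_table(f)
  expect_equal(media_lookup(ov, "GM")$mu_a, 0.03)
  expect_equal(media_lookup(ov, "WM")$mu_a, 0.07)
  f2 <- tempfile(fileext = ".yaml")
  writeLines("skull:\n  mu_a: 0.02\n  mu_s: 90\n  g: 0.95\n  n: 1.37", f2)
  ov2 <- read_media_table(f2)
  expect_equal(media_lookup(ov2, "skull")$mu_s, 90)
  writeLines("unknown_tissue:\n  mu_a: 1\n  mu_s: 1\n  g: 0\n  n: 1", f2)
  expect_error(read_media_table(f2), "unknown_tissue")
})
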