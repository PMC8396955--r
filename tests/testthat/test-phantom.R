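# Ground-truth field generation and the CCD forward model.

test_that("zero-variance fields are constant at the group mean", {
  acq <- tiny_acq(16, 32)
  geom <- default_geometry(acq, "heart")
  grp <- group_spec("g", 1, rr_mean = 1.0, rr_between_sd = 0, rr_within_sd = 0)
  truth <- generate_rr_field(geom, grp, acq, seed = 11)
  expect_true(all(truth$rr_field[truth$tissue_mask] == 1.0))
  expect_true(all(is.na(truth$rr_field[!truth$tissue_mask])))
  expect_equal(truth$sample_true_mean_rr, 1.0)
  expect_equal(truth$sample_true_mean_rr,
               mean(truth$rr_field[truth$tissue_mask]), tolerance = 1e-12)
})

test_that("kidney medulla offset produces the two-compartment field", {
  acq <- tiny_acq(16, 32)
  geom <- default_geometry(acq, "kidney")
  grp <- group_spec("g", 1, rr_mean = 0.9, rr_between_sd = 0,
                    rr_within_sd = 0, medulla_rr_offset = 0.4)
  truth <- generate_rr_field(geom, grp, acq, seed = 5)
  expect_true(all(truth$rr_field[truth$region_labels == 1L] == 0.9))
  expect_true(all(truth$rr_field[truth$region_labels == 2L] == 1.3))
  expect_gt(sum(truth$region_labels == 2L), 0)
})

test_that("per-animal means follow the configured sampling distribution", {
  # Monte-Carlo over 200 seeds; tolerance 0.03 ~ 4 standard errors of the
  # mean of 200 draws with SD 0.1.
  acq <- tiny_acq(12, 24)
  geom <- default_geometry(acq, "heart")
  grp <- group_spec("g", 1, rr_mean = 1.2, rr_between_sd = 0.1,
                    rr_within_sd = 0)
  means <- vapply(1:200, function(s)
    generate_rr_field(geom, grp, acq, seed = s)$sample_true_mean_rr,
    numeric(1))
  expect_lt(abs(mean(means) - 1.2), 0.03)
  expect_true(all(means > 0))
})

test_that("field generation is deterministic in the seed and validates inputs", {
  acq <- tiny_acq(12, 24)
  geom <- default_geometry(acq, "heart")
  grp <- group_spec("g", 1, rr_mean = 1.1, rr_between_sd = 0.1)
  a <- generate_rr_field(geom, grp, acq, seed = 99)
  b <- generate_rr_field(geom, grp, acq, seed = 99)
  c <- generate_rr_field(geom, grp, acq, seed = 100)
  expect_identical(a$rr_field, b$rr_field)
  expect_false(identical(a$rr_field, c$rr_field))

  too_big <- organ_geometry("heart", semi_axes_vox = c(20, 20, 10),
                            center_vox = c(12, 12, 6))
  expect_error(generate_rr_field(too_big, grp, acq, seed = 1),
               class = "cryoredox_dim_error")
  neg <- group_spec("g", 1, rr_mean = 0.5, rr_between_sd = 0,
                    rr_within_sd = 0, medulla_rr_offset = -0.6)
  expect_error(
    generate_rr_field(default_geometry(acq, "kidney"), neg, acq, seed = 1),
    class = "cryoredox_param_error")
})

test_that("noiseless rendering reproduces the exact forward model", {
  acq <- tiny_acq(14, 28)
  geom <- default_geometry(acq, "heart")
  grp <- group_spec("g", 1, rr_mean = 2, rr_between_sd = 0, rr_within_sd = 0)
  truth <- generate_rr_field(geom, grp, acq, seed = 2)
  pair <- render_channels(truth, noiseless_spec(1000), acq, seed = 3)
  tissue <- truth$tissue_mask
  expect_true(all(pair$nadh$voxels[tissue] == 2000))
  expect_true(all(pair$fad$voxels[tissue] == 1000))
  expect_true(all(pair$nadh$voxels[!tissue] == 0))
  expect_true(all(pair$fad$voxels[!tissue] == 0))

  bg <- noise_spec(fad_base_intensity = 1000, background_offset = 100,
                   read_noise_sd = 0, shot_noise = FALSE)
  pair2 <- render_channels(truth, bg, acq, seed = 3)
  expect_true(all(pair2$nadh$voxels[!tissue] == 100))
  expect_true(all(pair2$fad$voxels[!tissue] == 100))
  expect_true(all(pair2$fad$voxels[tissue] == 1100))
})

test_that("shot noise has Poisson variance in the FAD channel", {
  # Poisson(1000): sample variance over ~1e4 in-tissue voxels must fall in
  # [900, 1100], comfortably inside the chi-square 99.9% band.
  acq <- tiny_acq(24, 48)
  geom <- default_geometry(acq, "heart")
  grp <- group_spec("g", 1, rr_mean = 1, rr_between_sd = 0, rr_within_sd = 0)
  truth <- generate_rr_field(geom, grp, acq, seed = 4)
  expect_gt(sum(truth$tissue_mask), 1e4)
  shot <- noise_spec(fad_base_intensity = 1000, background_offset = 0,
                     read_noise_sd = 0, shot_noise = TRUE)
  pair <- render_channels(truth, shot, acq, seed = 8)
  v <- stats::var(pair$fad$voxels[truth$tissue_mask])
  expect_gt(v, 900)
  expect_lt(v, 1100)
})

test_that("default rendering neither saturates nor tolerates saturation-prone settings", {
  acq <- tiny_acq(16, 32)
  geom <- default_geometry(acq, "heart")
  grp <- group_spec("g", 1, rr_mean = 1.185, rr_between_sd = 0.19)
  truth <- generate_rr_field(geom, grp, acq, seed = 21)
  pair <- render_channels(truth, noise_spec(), acq, seed = 22)
  maxval <- 2^16 - 1
  frac_clipped <- mean(pair$nadh$voxels == maxval | pair$fad$voxels == maxval)
  expect_lt(frac_clipped, 0.001)
  expect_error(
    render_channels(truth, noise_spec(fad_base_intensity = 60000), acq,
                    seed = 1),
    class = "cryoredox_param_error")
})

test_that("noiseless render-then-divide round trip recovers the field to quantization", {
  acq <- tiny_acq(16, 32)
  geom <- default_geometry(acq, "heart")
  grp <- group_spec("g", 1, rr_mean = 1.1, rr_between_sd = 0, rr_within_sd = 0.1)
  for (seed in 1:5) {
    truth <- generate_rr_field(geom, grp, acq, seed = seed)
    pair <- render_channels(truth, noiseless_spec(1000), acq, seed = seed + 50)
    tissue <- truth$tissue_mask
    rr_hat <- pair$nadh$voxels[tissue] / pair$fad$voxels[tissue]
    rel_err <- abs(rr_hat - truth$rr_field[tissue]) / truth$rr_field[tissue]
    expect_lte(max(rel_err), 1 / 1000)
  }
})

test_that("generate_cohort writes the full study layout deterministically", {
  acq <- tiny_acq(12, 24)
  geom <- default_geometry(acq, "heart")
  groups <- list(group_spec("control", 2, rr_mean = 1.185, rr_between_sd = 0.19),
                 group_spec("severe", 3, rr_mean = 0.835, rr_between_sd = 0.054))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_cohort(groups, geom, noise_spec(), acq, d1, master_seed = 31)
  m2 <- generate_cohort(groups, geom, noise_spec(), acq, d2, master_seed = 31)
  expect_equal(nrow(m1), 5)
  expect_equal(length(list.files(d1, pattern = "_(NADH|FAD)\\.tif$")), 10)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  expect_identical(m1$true_mean_rr, m2$true_mean_rr)
  # stacks are byte-identical under the same master seed
  expect_identical(
    readBin(file.path(d1, "control_s01_NADH.tif"), "raw", 1e6),
    readBin(file.path(d2, "control_s01_NADH.tif"), "raw", 1e6))
  expect_error(group_spec("empty", 0, rr_mean = 1),
               class = "cryoredox_config_error")
})

test_that("paper-sized cohorts carry 6 + 11 hearts and 5 + 12 kidneys", {
  heart <- default_groups("heart")
  kidney <- default_groups("kidney")
  expect_equal(vapply(heart, `[[`, integer(1), "n_samples"), c(6L, 11L))
  expect_equal(vapply(kidney, `[[`, integer(1), "n_samples"), c(5L, 12L))
  expect_equal(heart[[1]]$rr_mean, (0.943 + 1.427) / 2)
  expect_equal(heart[[2]]$rr_mean, (0.75 + 0.92) / 2)
})
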