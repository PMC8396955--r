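# Ratio volumes, volumetric means, histograms, regional means, effect size.

make_mask <- function(dims, value = TRUE) array(value, dim = dims)

test_that("ratio_volume divides voxel by voxel inside the mask", {
  dims <- c(10, 10, 4)
  pair <- manual_pair(array(2000, dims), array(1000, dims))
  vol <- ratio_volume(pair, make_mask(dims))
  expect_true(all(vol$rr == 2.0))
  expect_equal(vol$n_valid, prod(dims))

  # a zero-FAD voxel is excluded, not an exception
  fad <- array(1000, dims); fad[3, 3, 2] <- 0
  vol2 <- ratio_volume(manual_pair(array(2000, dims), fad), make_mask(dims))
  expect_equal(vol2$n_valid, prod(dims) - 1)
  expect_true(is.na(vol2$rr[3, 3, 2]))

  # joint channel scaling leaves the ratio untouched
  vol3 <- ratio_volume(manual_pair(array(6000, dims), array(3000, dims)),
                       make_mask(dims))
  expect_identical(vol3$rr, vol$rr)

  expect_error(ratio_volume(pair, make_mask(dims), fad_floor = -1),
               class = "cryoredox_param_error")
  expect_error(ratio_volume(pair, make_mask(dims, FALSE)),
               class = "cryoredox_empty_ratio")
})

test_that("swapping the channels reciprocates the ratio", {
  dims <- c(8, 8, 3)
  a <- withr::with_seed(2, array(sample(500:4000, prod(dims), TRUE), dims))
  b <- withr::with_seed(3, array(sample(500:4000, prod(dims), TRUE), dims))
  fwd <- ratio_volume(manual_pair(a, b), make_mask(dims))
  rev <- ratio_volume(manual_pair(b, a), make_mask(dims))
  expect_equal(rev$rr, 1 / fwd$rr, tolerance = 1e-15)
})

test_that("background subtraction is clamped and changes validity, not shape", {
  dims <- c(8, 8, 2)
  pair <- manual_pair(array(2100, dims), array(1100, dims))
  vol <- ratio_volume(pair, make_mask(dims),
                      background = c(nadh = 100, fad = 100))
  expect_true(all(vol$rr == 2.0))
  # subtracting more than the FAD signal empties the volume
  expect_error(
    ratio_volume(pair, make_mask(dims), background = c(nadh = 0, fad = 2000)),
    class = "cryoredox_empty_ratio")
})

test_that("the volumetric mean equals the triple-loop accumulation", {
  dims <- c(8, 8, 1)
  nadh <- array(0, dims)
  nadh[1:4] <- c(1, 2, 3, 4) * 100
  mask <- array(FALSE, dims)
  mask[1:4] <- TRUE
  vol <- ratio_volume(manual_pair(nadh, array(100, dims)), mask)
  expect_equal(volumetric_mean(vol), 2.5)

  for (seed in 1:4) {
    rv <- random_rr_volume(c(12, 10, 6), seed = seed)
    expect_equal(volumetric_mean(rv), triple_loop_mean(rv$rr, rv$valid),
                 tolerance = 1e-12)
  }
  # full-grid audit mode divides the same sum by Nx*Ny*Nz
  rv <- random_rr_volume(c(8, 8, 4), seed = 9)
  expect_equal(volumetric_mean(rv, "grid"),
               sum(rv$rr[rv$valid]) / prod(dim(rv$rr)))
})

test_that("increasing a valid FAD voxel never increases the volumetric mean", {
  dims <- c(8, 8, 3)
  nadh <- withr::with_seed(4, array(sample(1000:3000, prod(dims), TRUE), dims))
  fad <- withr::with_seed(5, array(sample(800:1500, prod(dims), TRUE), dims))
  base <- volumetric_mean(ratio_volume(manual_pair(nadh, fad), make_mask(dims)))
  for (i in c(1, 17, 80)) {
    fad2 <- fad
    fad2[i] <- fad2[i] + 500
    expect_lte(
      volumetric_mean(ratio_volume(manual_pair(nadh, fad2), make_mask(dims))),
      base)
  }
})

test_that("histograms conserve mass and report overflow explicitly", {
  dims <- c(10, 10, 2)
  vol <- ratio_volume(manual_pair(array(1000, dims), array(1000, dims)),
                      make_mask(dims))
  h <- rr_histogram(vol, seq(0, 3, by = 0.25))
  expect_equal(sum(h$rel_freq), 1, tolerance = 1e-12)
  expect_equal(h$rel_freq[5], 1)  # all mass in [1.0, 1.25)
  expect_equal(h$mean_rr, 1)

  rv <- random_rr_volume(c(10, 10, 5), seed = 3)
  h2 <- rr_histogram(rv, seq(0.5, 2, length.out = 31))
  expect_equal(sum(h2$rel_freq), 1, tolerance = 1e-12)
  expect_equal(sum(h2$counts) + h2$n_below + h2$n_above, rv$n_valid)
  expect_equal(h2$mean_rr, mean(rv$rr[rv$valid]))
  expect_error(rr_histogram(rv, c(1, 0.5, 2)),
               class = "cryoredox_param_error")
})

test_that("bin-midpoint means track the voxel mean to within half a bin", {
  edges <- seq(0, 3, length.out = 101)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  for (seed in 1:5) {
    rv <- random_rr_volume(c(14, 14, 6), seed = seed)
    h <- rr_histogram(rv, edges)
    binned_mean <- sum(mids * h$rel_freq)
    expect_lt(abs(binned_mean - h$mean_rr), diff(edges)[1] / 2)
  }
})

test_that("tidy() turns a histogram into a plot-ready tibble", {
  dims <- c(8, 8, 2)
  vol <- ratio_volume(manual_pair(array(1000, dims), array(1000, dims)),
                      make_mask(dims))
  tb <- tidy(rr_histogram(vol, seq(0, 3, by = 0.5)))
  expect_s3_class(tb, "tbl_df")
  expect_named(tb, c("sample_id", "bin_left", "bin_right", "rel_freq"))
  expect_equal(nrow(tb), 6)
})

test_that("regional means resolve the cortex/medulla contrast by construction", {
  acq <- tiny_acq(16, 32)
  geom <- default_geometry(acq, "kidney")
  grp <- group_spec("g", 1, rr_mean = 0.9, rr_between_sd = 0,
                    rr_within_sd = 0, medulla_rr_offset = 0.4)
  sim <- simulate_sample(geom, grp, noiseless_spec(), acq, seed = 12)
  vol <- ratio_volume(sim$pair, sim$truth$tissue_mask, fad_floor = 1)
  rm <- regional_means(vol, sim$truth$region_labels)
  expect_equal(rm$mean_rr[rm$region == "cortex"], 0.9, tolerance = 1e-3)
  expect_equal(rm$mean_rr[rm$region == "medulla"], 1.3, tolerance = 1e-3)

  # a label with no valid voxels is absent, not zero
  labels2 <- sim$truth$region_labels
  labels2[labels2 == 2L] <- 1L
  rm2 <- regional_means(vol, labels2)
  expect_false(2L %in% rm2$label)
  # all-background labels are an error
  expect_error(regional_means(vol, array(0L, dim = dim(vol$rr))),
               class = "cryoredox_empty_ratio")
})

test_that("percent decrease matches its defining formula", {
  expect_equal(percent_decrease(1.0, 0.6810), 31.90)
  expect_equal(percent_decrease(1.0, 1.0), 0)
  expect_equal(percent_decrease(100.0, 87.68), 12.32)
  expect_lt(percent_decrease(1.0, 1.2), 0)  # increases are negative
  expect_error(percent_decrease(0, 1), class = "cryoredox_param_error")
})

test_that("the noiseless pipeline mean matches the generator truth", {
  acq <- tiny_acq(16, 32)
  geom <- default_geometry(acq, "heart")
  grp <- group_spec("g", 1, rr_mean = 1.1, rr_between_sd = 0.1,
                    rr_within_sd = 0.1)
  cfg <- pipeline_config("heart", acq = acq, geometry = geom,
                         groups = list(grp), noise = noiseless_spec())
  for (seed in 1:3) {
    sim <- simulate_sample(geom, grp, noiseless_spec(), acq, seed = seed)
    est <- cryoredox:::process_pair(sim$pair, cfg)
    expect_lt(abs(est$summary$mean_rr - sim$truth$sample_true_mean_rr), 1e-3)
  }
})
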