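test_that("segmentation matches a brute-force labeling oracle", {
  set.seed(42)
  centers <- cbind(c(10, 10, 30, 45, 52), c(8, 40, 25, 50, 10))
  raster <- disk_raster(c(64, 64), centers, radius = 3, value = 500,
                        background = 50)
  img <- make_channel(raster)
  objs <- segment_channel(img, segmentation_params(), pixel_size_um = 0.1)
  expect_length(objs, 5)

  # oracle: BFS labeling of the same thresholded raster
  thr <- median(raster) + 5 * mad(raster)
  lab <- bfs_label(raster > thr, 8)
  expect_equal(max(lab), 5)
  oracle_masks <- lapply(seq_len(max(lab)), function(l) which(lab == l))
  impl_masks <- lapply(objs, `[[`, "mask")
  key <- function(ms) paste(vapply(ms, function(m) paste(sort(m), collapse = ","),
                                   character(1)))
  expect_setequal(key(impl_masks), key(oracle_masks))

  # segmentation is idempotent / deterministic
  objs2 <- segment_channel(img, segmentation_params(), pixel_size_um = 0.1)
  expect_identical(impl_masks, lapply(objs2, `[[`, "mask"))
})

test_that("labeling respects 4- vs 8-connectivity on diagonal bridges", {
  m <- matrix(0, 16, 16)
  m[2, 2] <- 1; m[3, 3] <- 1   # touching only diagonally
  m[6, 6] <- 1; m[6, 7] <- 1   # edge-adjacent
  img <- make_channel(m * 1000)
  p8 <- segmentation_params(min_area_um2 = 0.005, connectivity = 8)
  p4 <- segmentation_params(min_area_um2 = 0.005, connectivity = 4)
  expect_length(segment_channel(img, p8, 0.1), 2)
  expect_length(segment_channel(img, p4, 0.1), 3)
  expect_equal(max(bfs_label(m > 0, 8)), 2)
  expect_equal(max(bfs_label(m > 0, 4)), 3)
})

test_that("size filter drops objects outside the area bounds", {
  raster <- disk_raster(c(64, 64), cbind(20, 20), radius = 5, value = 500)
  raster <- raster + disk_raster(c(64, 64), cbind(50, 50), radius = 1, value = 500)
  img <- make_channel(raster)
  # radius-1 disk = 5 px = 0.05 um^2 at 0.1 um pixels -> below min_area 0.1
  objs <- segment_channel(img, segmentation_params(min_area_um2 = 0.1), 0.1)
  expect_length(objs, 1)
  expect_gt(objs[[1]]$area_um2, 0.5)

  blank <- make_channel(matrix(0, 32, 32))
  expect_length(segment_channel(blank, segmentation_params(), 0.1), 0)
})

test_that("signal-to-background ratio is mean over mask divided by background", {
  raster <- matrix(100, 32, 32)
  raster[5:8, 5:8] <- 200
  img <- make_channel(raster)
  obj_mask <- which(raster == 200)
  expect_equal(signal_background_ratio(obj_mask, img, 100), 2.0)
  raster[5:8, 5:8] <- 50
  img <- make_channel(raster)
  expect_equal(signal_background_ratio(which(raster == 50), img, 100), 0.5)
  expect_equal(signal_background_ratio(seq_len(1024), make_channel(matrix(7, 32, 32)), 7), 1.0)
  expect_error(signal_background_ratio(obj_mask, img, 0),
               class = "flaps_degenerate_background_error")
})

test_that("background estimate is the median of non-object pixels", {
  raster <- matrix(100, 32, 32)
  raster[1:4, 1:4] <- 4000
  img <- make_channel(raster)
  expect_equal(estimate_background(img, list(which(raster == 4000))), 100)

  # a tiled 1..9 background has median 5
  vals <- matrix(rep(1:9, length.out = 15 * 15), 15, 15)
  expect_equal(estimate_background(make_channel(vals), list()), 5)

  # masks covering (almost) everything leave too few background pixels
  expect_error(estimate_background(img, list(seq_len(1024 - 50))),
               class = "flaps_degenerate_background_error")
})

test_that("exposure merging keeps the longest unsaturated representative", {
  dims <- c(32, 32); px <- 0.1
  m <- mask_of(disk_raster(dims, cbind(16, 16), 3, 1))
  o10 <- stub_obj(m, id = 1, sbr = 1.2, exposure = 10, dims = dims)
  o35 <- stub_obj(m, id = 1, sbr = 3.5, exposure = 35, dims = dims)
  o140 <- stub_obj(m, id = 1, sbr = 9.0, exposure = 140, dims = dims)

  merged <- merge_exposures(list(list(o10), list(o35), list(o140)))
  expect_length(merged, 1)
  expect_equal(merged[[1]]$exposure_ms, 140)

  # saturated at 140 ms -> fall back to 35 ms statistics
  o140s <- o140; o140s$saturated <- TRUE
  merged <- merge_exposures(list(list(o10), list(o35), list(o140s)))
  expect_equal(merged[[1]]$exposure_ms, 35)
  expect_equal(merged[[1]]$sbr, 3.5)

  # saturated everywhere -> shortest exposure
  o10s <- o10; o10s$saturated <- TRUE; o35s <- o35; o35s$saturated <- TRUE
  merged <- merge_exposures(list(list(o10s), list(o35s), list(o140s)))
  expect_equal(merged[[1]]$exposure_ms, 10)

  # object seen only at the longest exposure is retained
  merged <- merge_exposures(list(list(), list(), list(o140)))
  expect_length(merged, 1)
  expect_equal(merged[[1]]$exposure_ms, 140)

  expect_length(merge_exposures(list(list(), list())), 0)

  # two distant objects never merge; merged count <= sum of inputs
  far <- stub_obj(mask_of(disk_raster(dims, cbind(5, 5), 2, 1)), id = 2,
                  exposure = 35, dims = dims)
  merged <- merge_exposures(list(list(o10), list(o35, far)))
  expect_length(merged, 2)
})

test_that("crosstalk correction subtracts scaled FISH signal and clips at zero", {
  flaps <- make_channel(matrix(100, 16, 16), "FLAPS", 35)
  fish <- make_channel(matrix(900, 16, 16), "FISH", 300)
  corr <- correct_crosstalk(flaps, fish, 0.05)
  expect_true(all(corr$raster == 55))
  corr <- correct_crosstalk(flaps, fish, 0.2)
  expect_true(all(corr$raster == 0))
  expect_identical(correct_crosstalk(flaps, fish, 0), flaps)
})

test_that("noise-free DAPI detection recovers the exact truth count", {
  sim <- simulate_field(sim_field_config(n_cells = 40, dims = c(176, 176),
                                         noise_sd = 0, seed = 31))
  objs <- segment_channel(fov_channels(sim$fov, "DAPI"),
                          segmentation_params(), 0.1)
  expect_length(objs, 40)
})
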