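test_that("overlap fraction is intersection over the DAPI reference", {
  ref <- 1:10
  expect_equal(overlap_fraction(ref, 1:10), 1.0)
  expect_equal(overlap_fraction(ref, 11:20), 0.0)
  expect_equal(overlap_fraction(ref, c(1, 2, 3, 50, 60)), 0.3)
  # asymmetric: denominator is the reference, not the query
  expect_equal(overlap_fraction(1:4, 1:100), 1.0)
  expect_equal(overlap_fraction(1:100, 1:4), 0.04)
  expect_error(overlap_fraction(integer(0), 1:3),
               class = "flaps_degenerate_object_error")
})

test_that("classification truth table covers all evidence combinations", {
  dims <- c(32, 32)
  dapi_mask <- mask_of(disk_raster(dims, cbind(16, 16), 4, 1))
  dapi <- stub_obj(dapi_mask, id = 1, dims = dims)
  th <- phenotype_thresholds()
  full <- function(sbr = 2) list(stub_obj(dapi_mask, id = 9, sbr = sbr, dims = dims))
  none <- list()

  # every (flaps, fish, auto) evidence combination maps to its class
  cases <- expand.grid(flaps = c(FALSE, TRUE), fish = c(FALSE, TRUE),
                       auto = c(FALSE, TRUE))
  for (k in seq_len(nrow(cases))) {
    rec <- classify_cell(dapi,
                         if (cases$flaps[k]) full() else none,
                         if (cases$fish[k]) full() else none,
                         if (cases$auto[k]) full() else none, th)
    want <- if (cases$flaps[k] && cases$auto[k]) "cyanobacterium"
      else if (cases$flaps[k] && cases$fish[k]) "flaps_fish_cell"
      else if (cases$flaps[k]) "flaps_cell"
      else "unstained_cell"
    expect_equal(rec$phenotype, want, info = paste(cases[k, ], collapse = "/"))
  }
})

test_that("overlap and SBR thresholds are inclusive minima", {
  dims <- c(32, 32)
  dapi_mask <- which(disk_raster(dims, cbind(16, 16), 4, 1) > 0)
  n <- length(dapi_mask)
  dapi <- stub_obj(dapi_mask, id = 1, dims = dims)
  th <- phenotype_thresholds(min_overlap = 0.30, min_sbr = 1.0)
  # build query masks with exact overlap fractions (n = 49 px: use 0.30
  # boundary via a reference sized to make 30% an integer)
  ref <- 1:10
  dapi10 <- stub_obj(ref, id = 1, dims = dims)
  at_30 <- list(stub_obj(c(1:3, 200:206), id = 2, sbr = 1.0, dims = dims))
  below_30 <- list(stub_obj(c(1:2, 200:207), id = 2, sbr = 5.0, dims = dims))
  expect_equal(classify_cell(dapi10, at_30, th = th)$phenotype, "flaps_cell")
  expect_equal(classify_cell(dapi10, below_30, th = th)$phenotype,
               "unstained_cell")
  # SBR just below 1 fails even with full overlap
  low_sbr <- list(stub_obj(ref, id = 2, sbr = 0.999, dims = dims))
  expect_equal(classify_cell(dapi10, low_sbr, th = th)$phenotype,
               "unstained_cell")
  expect_equal(classify_cell(dapi10, list(stub_obj(ref, id = 2, sbr = 1.0,
                                                   dims = dims)),
                             th = th)$phenotype, "flaps_cell")
})

test_that("FLAPS objects without DAPI overlap become background particles", {
  dims <- c(48, 48)
  dapi <- stub_obj(mask_of(disk_raster(dims, cbind(12, 12), 4, 1)), dims = dims)
  on_cell <- stub_obj(mask_of(disk_raster(dims, cbind(12, 12), 5, 1)), id = 2,
                      dims = dims)
  free <- stub_obj(mask_of(disk_raster(dims, cbind(36, 36), 3, 1)), id = 3,
                   dims = dims)
  bg <- reject_background(list(on_cell, free), list(dapi))
  expect_length(bg$particles, 1)
  expect_equal(bg$particles[[1]]$object_id, 3)
  expect_length(bg$cell_associated, 1)
  expect_length(reject_background(list(), list(dapi))$particles, 0)
})

test_that("sample quantification implements the stated arithmetic", {
  mk_rec <- function(phenos) data.frame(fov_id = rep(1, length(phenos)),
                                        phenotype = phenos,
                                        stringsAsFactors = FALSE)
  meta <- acquisition_meta(pixel_size_um = 0.1, filter_area_um2 = 1e8,
                           volume_filtered_L = 0.01, sample_id = "s",
                           timepoint_h = 1)
  meta$fov_area_um2 <- 1e4   # filter:FOV ratio = 1e4
  recs <- mk_rec(c(rep("flaps_cell", 16), rep("unstained_cell", 84)))
  q <- quantify_sample(recs, meta, n_fov = 1)
  expect_equal(q$total_cells, 100)
  expect_equal(q$frac_flaps_pos, 0.16)
  expect_equal(q$cells_per_L, 100 * 1e4 / 0.01)  # = 1e8
  expect_equal(q$n_cyanobacteria, 0)
  # Wilson interval brackets the point estimate
  expect_lt(q$ci95_frac[1], 0.16)
  expect_gt(q$ci95_frac[2], 0.16)

  # cyanobacteria stay in total_cells but leave both fraction terms
  recs <- mk_rec(c(rep("flaps_cell", 16), rep("cyanobacterium", 20),
                   rep("unstained_cell", 64)))
  q <- quantify_sample(recs, meta, n_fov = 1)
  expect_equal(q$total_cells, 100)
  expect_equal(q$frac_flaps_pos, 16 / 80)

  # zero cells: fraction flagged missing, not an error
  q <- quantify_sample(mk_rec(character(0)), meta, n_fov = 1)
  expect_equal(q$total_cells, 0)
  expect_true(is.na(q$frac_flaps_pos))

  # class partition: flaps_pos + cyanobacteria + unstained = total
  recs <- mk_rec(c(rep("flaps_cell", 10), rep("flaps_fish_cell", 5),
                   rep("cyanobacterium", 3), rep("unstained_cell", 82)))
  q <- quantify_sample(recs, meta, n_fov = 1)
  expect_equal(q$n_flaps_pos + q$n_cyanobacteria +
                 sum(recs$phenotype == "unstained_cell"), q$total_cells)
})

test_that("timecourse summary flags fluorescence dilution by division", {
  quants <- list(quant_stub(0.2, 1e9, 0), quant_stub(0.1, 2e9, 24))
  tc <- timecourse_summary(quants)
  expect_true(tc$dilution_flag)

  # constant series: no flags
  quants <- list(quant_stub(0.2, 1e9, 0), quant_stub(0.2, 1e9, 24),
                 quant_stub(0.2, 1e9, 48))
  expect_true(!any(timecourse_summary(quants)$dilution_flag))

  # rising fraction never flags, whatever the counts do
  quants <- list(quant_stub(0.1, 1e9, 0), quant_stub(0.3, 3e9, 24))
  expect_true(!any(timecourse_summary(quants)$dilution_flag))

  expect_error(timecourse_summary(quants[1]), class = "flaps_input_error")
  expect_error(timecourse_summary(list(quant_stub(0.1, 1, 24),
                                       quant_stub(0.1, 1, 0))),
               class = "flaps_input_error")
})

test_that("raising thresholds never increases the positive count", {
  sim <- simulate_field(sim_field_config(n_cells = 60, dims = c(220, 220),
                                         frac_selfish = 0.4, seed = 17))
  last <- Inf
  for (ov in seq(0.05, 0.95, length.out = 10)) {
    res <- analyze_field(sim$fov, th = phenotype_thresholds(min_overlap = ov))
    n_pos <- res$counts[["n_flaps_pos"]]
    expect_lte(n_pos, last)
    last <- n_pos
  }
  last <- Inf
  for (sbr in seq(0.5, 8, length.out = 10)) {
    res <- analyze_field(sim$fov, th = phenotype_thresholds(min_sbr = sbr))
    n_pos <- res$counts[["n_flaps_pos"]]
    expect_lte(n_pos, last)
    last <- n_pos
  }
})
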