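test_that("two-point calibration gives the exact line; degenerate inputs fail", {
  cal <- calibrate_mw(data.frame(elution_vol = c(10, 20), mw = c(1e5, 1e3)))
  expect_equal(cal$slope, -0.2)
  expect_equal(cal$intercept, 7)
  expect_equal(mw_at(cal, 10), 1e5)
  expect_equal(mw_at(cal, 20), 1e3)

  expect_error(calibrate_mw(data.frame(elution_vol = 10, mw = 1e5)),
               class = "flaps_calibration_error")
  expect_error(calibrate_mw(data.frame(elution_vol = c(10, 10), mw = c(1, 2))),
               class = "flaps_calibration_error")

  # collinear standards: zero residuals
  cal3 <- calibrate_mw(data.frame(elution_vol = c(10, 15, 20),
                                  mw = c(1e5, 1e4, 1e3)))
  expect_equal(max(abs(cal3$residuals)), 0, tolerance = 1e-12)

  expect_warning(calibrate_mw(data.frame(elution_vol = c(10, 20),
                                         mw = c(1e3, 1e5))),
                 "elute earlier")
})

test_that("class binning integrates signal per molecular-weight class", {
  cal <- calibrate_mw(data.frame(elution_vol = c(10, 20), mw = c(1e5, 1e3)))
  ev <- seq(8, 24, length.out = 800)
  bounds <- c(Inf, 1e4, 3e3, 1e2)

  # single peak entirely inside class 1 (MW 5e4 elutes at ~11.5 mL)
  mu1 <- (log10(5e4) - 7) / -0.2
  sig <- exp(-0.5 * ((ev - mu1) / 0.3)^2)
  prof <- bin_chromatogram(chromatogram(ev, sig, 0), cal, bounds)
  expect_equal(prof$fractions, c(1, 0, 0), tolerance = 1e-6)

  # equal-area peaks in classes 1 and 3 -> (0.5, 0, 0.5)
  mu3 <- (log10(5e2) - 7) / -0.2
  sig2 <- sig + exp(-0.5 * ((ev - mu3) / 0.3)^2)
  prof2 <- bin_chromatogram(chromatogram(ev, sig2, 0), cal, bounds)
  expect_equal(prof2$fractions, c(0.5, 0, 0.5), tolerance = 1e-3)
  # oracle: analytic Gaussian masses inside each class's elution window
  a <- 0.3 * sqrt(2 * pi)
  cls_edges <- (log10(bounds) - 7) / -0.2   # Inf -> -Inf on elution axis
  m1 <- gauss_mass(a, mu1, 0.3, -Inf, cls_edges[2]) +
        gauss_mass(a, mu3, 0.3, -Inf, cls_edges[2])
  m3 <- gauss_mass(a, mu1, 0.3, cls_edges[3], Inf) +
        gauss_mass(a, mu3, 0.3, cls_edges[3], Inf)
  total <- 2 * a
  expect_equal(prof2$fractions[1], m1 / total, tolerance = 1e-3)
  expect_equal(prof2$fractions[3], m3 / total, tolerance = 1e-3)

  expect_error(bin_chromatogram(chromatogram(ev, sig * 0, 0), cal, bounds),
               class = "flaps_degenerate_chromatogram_error")
})

test_that("hydrolysis rate is monomer-equivalent product gain per hour", {
  bounds <- c(Inf, 3000, 800, 250, 0)
  p0 <- mw_class_profile(bounds, c(1, 0, 0, 0), 0)
  p24 <- mw_class_profile(bounds, c(0.9, 0.04, 0.03, 0.03), 24)

  res <- hydrolysis_rate(list(p0, p24), substrate_conc_monomer = 3500)
  expect_equal(nrow(res), 2)  # t0 basis and consecutive coincide here
  expect_equal(res$rate_nmol_L_h,
               rep(0.10 * 3500 / 24, 2), tolerance = 1e-12)

  # identical profiles -> zero rate
  res0 <- hydrolysis_rate(list(p0, mw_class_profile(bounds, c(1, 0, 0, 0), 24)))
  expect_true(all(res0$rate_nmol_L_h == 0))

  # killed control showing the same shift cancels the signal entirely
  resk <- hydrolysis_rate(list(p0, p24), substrate_conc_monomer = 3500,
                          killed_profiles = list(p0, p24))
  expect_true(all(resk$rate_nmol_L_h == 0))
  expect_true(all(resk$control_corrected))

  # mismatched killed timepoints are rejected
  expect_error(hydrolysis_rate(list(p0, p24),
                               killed_profiles = list(p0,
                                 mw_class_profile(bounds, c(1, 0, 0, 0), 48))),
               class = "flaps_input_error")
})

test_that("rates are invariant to uniform rescaling of the raw signal", {
  series <- simulate_chromatogram_series(transfer_fracs = c(0, 0.25, 0.5),
                                         timepoints_h = c(0, 24, 48))
  cal <- default_mw_calibration()
  bounds <- c(Inf, 3000, 800, 250, 0)
  prof_a <- lapply(series, bin_chromatogram, cal = cal, class_bounds = bounds)
  scaled <- lapply(series, function(ch)
    chromatogram(ch$elution_vol, ch$signal * 37.5, ch$timepoint_h))
  prof_b <- lapply(scaled, bin_chromatogram, cal = cal, class_bounds = bounds)
  ra <- hydrolysis_rate(prof_a)
  rb <- hydrolysis_rate(prof_b)
  expect_equal(ra$rate_nmol_L_h, rb$rate_nmol_L_h, tolerance = 1e-12)
  # non-negative always; consecutive intervals of a monotone series positive
  expect_true(all(ra$rate_nmol_L_h >= 0))
})

test_that("rate recovery from simulated series matches the planted transfer", {
  series <- simulate_chromatogram_series(transfer_fracs = c(0, 0.5),
                                         timepoints_h = c(0, 24))
  cal <- default_mw_calibration()
  bounds <- c(Inf, 3000, 800, 250, 0)
  prof <- lapply(series, bin_chromatogram, cal = cal, class_bounds = bounds)
  res <- hydrolysis_rate(prof, substrate_conc_monomer = 3500)
  expected <- 0.5 * 3500 / 24
  expect_equal(res$rate_nmol_L_h[1], expected, tolerance = 0.01)
})

test_that("carbon addition converts monomer equivalents to carbon", {
  expect_equal(carbon_added(3.5, 6), 21)
  expect_equal(carbon_added(3.5, 5), 17.5)
  expect_error(carbon_added(-1), class = "flaps_config_error")
})
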