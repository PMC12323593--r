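# Ground-truthed synthetic data: fields of view with selfish / autofluorescent
# / FISH-positive cells and non-cell substrate particles, gel-permeation
# chromatogram timecourses, and bimodal cytometry event tables.

#' Configuration for a simulated field of view
#'
#' Defaults emulate a coastal seawater incubation imaged at 63x on a 12-bit
#' CCD: ~0.1 um pixels, rod-shaped cells ~1.5 x 0.7 um, a FLAPS substrate
#' channel acquired at 10/35/140 ms so that dim cells need the long exposure
#' while the brightest cells saturate it, plus non-cell substrate particles
#' that lack a DAPI counterstain.
#'
#' @param n_cells number of cells to place.
#' @param frac_selfish proportion of cells with periplasmic FLAPS staining.
#' @param frac_autofluorescent proportion of cells with pigment
#'   autofluorescence (cyanobacteria-like: positive in AUTO and FLAPS).
#'   Drawn from the non-selfish pool so truth classes are disjoint.
#' @param frac_fish_positive proportion of cells hybridized by the FISH probe.
#' @param pattern_mix named proportions of `halo` and `polar` staining among
#'   selfish cells; must sum to 1. Halo: substrate over the whole periplasm,
#'   rendered as the cell ellipse dilated by one pixel. Polar: substrate
#'   caps at one or both cell poles.
#' @param cell_length_um,cell_width_um cell ellipse axes (um).
#' @param dims raster dimensions `c(rows, cols)`.
#' @param pixel_size_um physical pixel size (um).
#' @param flaps_exposures_ms strictly increasing FLAPS exposure series (ms).
#' @param dapi_level DAPI deposit intensity (counts above background).
#' @param flaps_rate_meanlog,flaps_rate_sdlog log-normal law for per-cell
#'   FLAPS brightness in counts per ms of exposure.
#' @param fish_level,auto_level absolute deposit intensities for the FISH and
#'   AUTO channels.
#' @param auto_flaps_rate pigment bleed-through of autofluorescent cells into
#'   the FLAPS channel (counts per ms).
#' @param particle_rate_meanlog,particle_rate_sdlog log-normal law for
#'   background-particle brightness (counts per ms).
#' @param background_mean,noise_sd additive Gaussian camera background.
#' @param n_background_particles number of non-cell FLAPS particles.
#' @param crosstalk_coeff fraction of the FISH deposit leaking into every
#'   FLAPS exposure (0 = the optical setup fully separates the dyes).
#' @param bit_max camera saturation level (4095 = 12-bit).
#' @param fish_exposure_ms,auto_exposure_ms,dapi_exposure_ms exposure
#'   metadata for the single-exposure channels.
#' @param sample_id,timepoint_h sample labels.
#' @param volume_filtered_L,filter_area_um2 filtration bookkeeping used for
#'   cells-per-litre conversion (10 mL onto a 20 mm effective-diameter
#'   polycarbonate filter by default).
#' @param seed integer seed; identical seeds give bit-identical fields.
#' @return object of class `sim_field_config`.
#' @export
sim_field_config <- function(n_cells = 100, frac_selfish = 0.16,
                             frac_autofluorescent = 0.02,
                             frac_fish_positive = 0,
                             pattern_mix = c(halo = 0.5, polar = 0.5),
                             cell_length_um = 1.5, cell_width_um = 0.7,
                             dims = c(256, 256), pixel_size_um = 0.1,
                             flaps_exposures_ms = c(10, 35, 140),
                             dapi_level = 1500,
                             flaps_rate_meanlog = log(20),
                             flaps_rate_sdlog = 0.5,
                             fish_level = 1200, auto_level = 1500,
                             auto_flaps_rate = 25,
                             particle_rate_meanlog = log(25),
                             particle_rate_sdlog = 0.5,
                             background_mean = 60, noise_sd = 5,
                             n_background_particles = 10,
                             crosstalk_coeff = 0,
                             bit_max = 4095,
                             fish_exposure_ms = 300, auto_exposure_ms = 300,
                             dapi_exposure_ms = 50,
                             sample_id = "sim", timepoint_h = 0,
                             volume_filtered_L = 0.01,
                             filter_area_um2 = 3.1e8,
                             seed = NULL) {
  cfg <- as.list(environment())
  for (p in c("frac_selfish", "frac_autofluorescent", "frac_fish_positive"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1)
      stopf("%s must lie in [0, 1]", p, class = "flaps_config_error")
  if (crosstalk_coeff < 0 || crosstalk_coeff >= 1)
    stopf("crosstalk_coeff must lie in [0, 1)", class = "flaps_config_error")
  if (abs(sum(pattern_mix) - 1) > 1e-9 ||
      !all(c("halo", "polar") %in% names(pattern_mix)))
    stopf("pattern_mix must be named proportions of halo and polar summing to 1",
          class = "flaps_config_error")
  if (n_cells < 0 || n_background_particles < 0)
    stopf("counts must be non-negative", class = "flaps_config_error")
  if (any(diff(flaps_exposures_ms) <= 0))
    stopf("flaps_exposures_ms must be strictly increasing",
          class = "flaps_config_error")
  if (noise_sd < 0 || background_mean < 0)
    stopf("background_mean and noise_sd must be non-negative",
          class = "flaps_config_error")
  structure(cfg, class = "sim_field_config")
}

# Pixels of a filled, rotated ellipse; returns linear (column-major) indices.
ellipse_pixels <- function(cr, cc, a_px, b_px, theta, dims, grow = 0) {
  a <- a_px + grow; b <- b_px + grow
  r0 <- max(1L, floor(cr - a)); r1 <- min(dims[1], ceiling(cr + a))
  c0 <- max(1L, floor(cc - a)); c1 <- min(dims[2], ceiling(cc + a))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc_ <- c0:c1
  dr <- outer(rr - cr, rep(1, length(cc_)))
  dc <- outer(rep(1, length(rr)), cc_ - cc)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside)
  (rep(cc_, each = length(rr))[idx] - 1L) * dims[1] +
    rep(rr, length(cc_))[idx]
}

disk_pixels <- function(cr, cc, radius, dims) {
  ellipse_pixels(cr, cc, radius, radius, 0, dims)
}

# Dilate a pixel-index set by one pixel (8-neighbourhood), clipped to bounds.
dilate1 <- function(idx, dims) {
  if (!length(idx)) return(idx)
  r <- ((idx - 1L) %% dims[1]) + 1L
  c <- ((idx - 1L) %/% dims[1]) + 1L
  off <- expand.grid(dr = -1:1, dc = -1:1)
  rr <- rep(r, each = 9L) + off$dr
  cc <- rep(c, each = 9L) + off$dc
  keep <- rr >= 1 & rr <= dims[1] & cc >= 1 & cc <= dims[2]
  unique((cc[keep] - 1L) * dims[1] + rr[keep])
}

mask_centroid <- function(idx, dims) {
  r <- ((idx - 1L) %% dims[1]) + 1L
  c <- ((idx - 1L) %/% dims[1]) + 1L
  c(mean(r), mean(c))
}

#' Simulate one multi-channel field of view with ground truth
#'
#' Renders DAPI, FLAPS (one raster per exposure), and - when the
#' configuration plants such cells - FISH and AUTO channels. Selfish cells
#' carry a periplasmic FLAPS deposit (halo or polar caps); background
#' particles carry FLAPS but no DAPI; autofluorescent cells are positive in
#' AUTO, DAPI and FLAPS (the cyanobacterium signature). FLAPS deposits scale
#' linearly with exposure time and clip at `bit_max`, so bright cells
#' saturate the 140 ms exposure. A fraction `crosstalk_coeff` of the FISH
#' deposit is added to every FLAPS exposure.
#'
#' Objects are placed uniformly at random without contact (a guard margin
#' keeps segmented masks disjoint); placement failure after bounded retries
#' raises an error rather than overlapping objects.
#'
#' @param config a [sim_field_config()].
#' @return list with elements `fov` ([field_of_view()]) and `truth`
#'   (class `ground_truth`: data frame `objects` with per-object flags and
#'   centroids, plus `masks`, a list of pixel-index vectors).
#' @export
simulate_field <- function(config) {
  stopifnot(inherits(config, "sim_field_config"))
  with_seed(config$seed, simulate_field_impl(config))
}

simulate_field_impl <- function(cfg) {
  dims <- as.integer(cfg$dims)
  px <- cfg$pixel_size_um
  a_px <- cfg$cell_length_um / 2 / px
  b_px <- cfg$cell_width_um / 2 / px
  margin <- 3  # keeps masks (incl. 1-px halo dilation) 8-disconnected

  n <- cfg$n_cells
  n_selfish <- as.integer(round_half_away(cfg$frac_selfish * n))
  n_auto <- as.integer(round_half_away(cfg$frac_autofluorescent * n))
  n_fish <- as.integer(round_half_away(cfg$frac_fish_positive * n))
  if (n_selfish + n_auto > n)
    stopf("frac_selfish + frac_autofluorescent exceed the cell count",
          class = "flaps_config_error")

  perm <- if (n > 0) sample.int(n) else integer(0)
  is_selfish <- is_auto <- is_fish <- logical(n)
  is_selfish[perm[seq_len(n_selfish)]] <- TRUE
  if (n_auto > 0) is_auto[perm[n_selfish + seq_len(n_auto)]] <- TRUE
  if (n_fish > 0) is_fish[sample.int(n, n_fish)] <- TRUE
  pattern <- rep("none", n)
  if (n_selfish > 0) {
    n_halo <- as.integer(round_half_away(cfg$pattern_mix[["halo"]] * n_selfish))
    sel_idx <- which(is_selfish)
    pattern[sel_idx] <- c(rep("halo", n_halo), rep("polar", n_selfish - n_halo))
  }

  occupied <- matrix(FALSE, dims[1], dims[2])
  place <- function(fp_fun) {
    for (try in 1:500) {
      cr <- runif(1, a_px + margin + 1, dims[1] - a_px - margin)
      cc <- runif(1, a_px + margin + 1, dims[2] - a_px - margin)
      theta <- runif(1, 0, pi)
      fp <- fp_fun(cr, cc, theta, grow = margin)
      if (!any(occupied[fp])) {
        occupied[fp] <<- TRUE
        return(list(cr = cr, cc = cc, theta = theta))
      }
    }
    stopf("could not place all objects without overlap; reduce n_cells or enlarge dims",
          class = "flaps_placement_error")
  }

  cell_fp <- function(cr, cc, theta, grow)
    ellipse_pixels(cr, cc, a_px, b_px, theta, dims, grow = grow)

  n_obj_max <- n + cfg$n_background_particles
  masks <- vector("list", n_obj_max)
  t_kind <- character(n_obj_max); t_row <- t_col <- numeric(n_obj_max)
  t_selfish <- t_auto <- t_fish <- logical(n_obj_max)
  t_pattern <- character(n_obj_max)
  oid <- 0L
  flaps_rate <- matrix(0, dims[1], dims[2])
  dapi_base <- matrix(0, dims[1], dims[2])
  fish_base <- matrix(0, dims[1], dims[2])
  auto_base <- matrix(0, dims[1], dims[2])

  cell_rates <- rlnorm(n, cfg$flaps_rate_meanlog, cfg$flaps_rate_sdlog)
  for (i in seq_len(n)) {
    pos <- place(cell_fp)
    body <- ellipse_pixels(pos$cr, pos$cc, a_px, b_px, pos$theta, dims)
    dapi_base[body] <- cfg$dapi_level
    if (is_fish[i]) fish_base[body] <- cfg$fish_level
    if (is_auto[i]) {
      auto_base[body] <- cfg$auto_level
      flaps_rate[body] <- pmax(flaps_rate[body], cfg$auto_flaps_rate)
    }
    if (is_selfish[i]) {
      if (pattern[i] == "halo") {
        # periplasmic shell seen in projection: covers the cell and extends
        # one pixel beyond it
        deposit <- dilate1(body, dims)
      } else {
        # cap(s) at the cell pole(s), inside the cell footprint
        n_ends <- sample(1:2, 1)
        d <- a_px - b_px
        ends <- list(c(pos$cr + d * cos(pos$theta), pos$cc + d * sin(pos$theta)),
                     c(pos$cr - d * cos(pos$theta), pos$cc - d * sin(pos$theta)))
        deposit <- unique(unlist(lapply(ends[seq_len(n_ends)], function(e)
          disk_pixels(e[1], e[2], b_px, dims))))
      }
      flaps_rate[deposit] <- pmax(flaps_rate[deposit], cell_rates[i])
    }
    oid <- oid + 1L
    ctr <- mask_centroid(body, dims)
    masks[[oid]] <- body
    t_kind[oid] <- "cell"; t_row[oid] <- ctr[1] - 1; t_col[oid] <- ctr[2] - 1
    t_selfish[oid] <- is_selfish[i]; t_auto[oid] <- is_auto[i]
    t_fish[oid] <- is_fish[i]; t_pattern[oid] <- pattern[i]
  }

  part_rates <- rlnorm(cfg$n_background_particles, cfg$particle_rate_meanlog,
                       cfg$particle_rate_sdlog)
  for (i in seq_len(cfg$n_background_particles)) {
    radius <- runif(1, 2.5, 4)
    fp_fun <- function(cr, cc, theta, grow)
      disk_pixels(cr, cc, radius + grow, dims)
    pos <- place(fp_fun)
    body <- disk_pixels(pos$cr, pos$cc, radius, dims)
    flaps_rate[body] <- pmax(flaps_rate[body], part_rates[i])
    oid <- oid + 1L
    ctr <- mask_centroid(body, dims)
    masks[[oid]] <- body
    t_kind[oid] <- "particle"; t_row[oid] <- ctr[1] - 1; t_col[oid] <- ctr[2] - 1
    t_pattern[oid] <- "none"
  }

  render <- function(base) {
    img <- base + cfg$background_mean
    if (cfg$noise_sd > 0) img <- img + rnorm(length(img), 0, cfg$noise_sd)
    matrix(as.integer(pmin(pmax(round(img), 0), cfg$bit_max)), dims[1], dims[2])
  }

  channels <- list(channel_image(render(dapi_base), "DAPI",
                                 cfg$dapi_exposure_ms, cfg$bit_max))
  for (e in cfg$flaps_exposures_ms) {
    base <- flaps_rate * e + cfg$crosstalk_coeff * fish_base
    channels[[length(channels) + 1L]] <-
      channel_image(render(base), "FLAPS", e, cfg$bit_max)
  }
  if (any(fish_base > 0) || cfg$frac_fish_positive > 0)
    channels[[length(channels) + 1L]] <-
      channel_image(render(fish_base), "FISH", cfg$fish_exposure_ms, cfg$bit_max)
  if (any(auto_base > 0) || cfg$frac_autofluorescent > 0)
    channels[[length(channels) + 1L]] <-
      channel_image(render(auto_base), "AUTO", cfg$auto_exposure_ms, cfg$bit_max)

  meta <- acquisition_meta(pixel_size_um = px,
                           filter_area_um2 = cfg$filter_area_um2,
                           volume_filtered_L = cfg$volume_filtered_L,
                           sample_id = cfg$sample_id,
                           timepoint_h = cfg$timepoint_h)
  truth_df <- data.frame(object_id = seq_len(oid), kind = t_kind[seq_len(oid)],
                         centroid_row = t_row[seq_len(oid)],
                         centroid_col = t_col[seq_len(oid)],
                         is_selfish = t_selfish[seq_len(oid)],
                         is_autofluorescent = t_auto[seq_len(oid)],
                         is_fish_positive = t_fish[seq_len(oid)],
                         pattern = t_pattern[seq_len(oid)],
                         stringsAsFactors = FALSE)
  truth <- structure(list(objects = truth_df, masks = masks[seq_len(oid)],
                          dim = dims),
                     class = "ground_truth")
  list(fov = field_of_view(channels, meta), truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  o <- x$objects
  cat(sprintf(
    "ground_truth: %d cells (%d selfish, %d autofluorescent, %d FISH+), %d particles\n",
    sum(o$kind == "cell"), sum(o$is_selfish), sum(o$is_autofluorescent),
    sum(o$is_fish_positive), sum(o$kind == "particle")))
  invisible(x)
}

#' Default gel-permeation molecular-weight calibration for simulations
#'
#' Two-point log-linear calibration spanning 100 kDa at 8 mL to 100 Da at
#' 18 mL (slope -0.3 log10(Da)/mL).
#' @return an `mw_calibration` (see [calibrate_mw()]).
#' @export
default_mw_calibration <- function() {
  calibrate_mw(data.frame(elution_vol = c(8, 18), mw = c(1e5, 1e2)))
}

#' Simulate a chromatogram timecourse with mass transfer to product classes
#'
#' Each chromatogram is a sum of Gaussian peaks on the elution axis: one
#' parent-polysaccharide peak plus one peak per product molecular-weight
#' class, centred at the class's geometric-mean MW mapped through the
#' calibration. At timepoint `t`, a fraction `transfer_fracs[t]` of the
#' parent's integrated signal has moved to the product classes in the
#' proportions of `product_profile`; total integrated signal is conserved by
#' construction (to well within 0.1%).
#'
#' @param parent_mw parent polysaccharide molecular weight (Da).
#' @param product_profile proportions over the product classes (classes below
#'   the parent class, in descending MW order); must sum to 1.
#' @param transfer_fracs non-decreasing fractions in `[0, 1]`, one per
#'   timepoint.
#' @param timepoints_h increasing incubation times (h).
#' @param peak_width Gaussian peak standard deviation on the elution axis (mL).
#' @param class_bounds descending MW class boundaries (Da), first class =
#'   parent range; used to place product peaks.
#' @param calibration [calibrate_mw()] result mapping MW to elution volume.
#' @param elution_grid elution axis (mL).
#' @param total_signal integrated signal of the parent peak at t = 0.
#' @param noise_sd additive signal noise (default 0: conservation is exact).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @return list of [chromatogram()], one per timepoint.
#' @export
simulate_chromatogram_series <- function(parent_mw = 6000,
                                         product_profile = c(0.2, 0.4, 0.4),
                                         transfer_fracs,
                                         timepoints_h,
                                         peak_width = 0.35,
                                         class_bounds = c(Inf, 3000, 800, 250, 0),
                                         calibration = default_mw_calibration(),
                                         elution_grid = seq(5, 25, length.out = 600),
                                         total_signal = 1000,
                                         noise_sd = 0, seed = NULL) {
  if (length(transfer_fracs) != length(timepoints_h))
    stopf("transfer_fracs and timepoints_h lengths differ",
          class = "flaps_config_error")
  if (any(transfer_fracs < 0 | transfer_fracs > 1))
    stopf("transfer_fracs must lie in [0, 1]", class = "flaps_config_error")
  if (any(diff(transfer_fracs) < 0))
    stopf("transfer_fracs must be non-decreasing (hydrolysis is irreversible)",
          class = "flaps_config_error")
  if (any(diff(timepoints_h) <= 0))
    stopf("timepoints_h must be strictly increasing", class = "flaps_config_error")
  k <- length(class_bounds) - 1L
  if (length(product_profile) != k - 1L)
    stopf("product_profile needs one proportion per product class (%d)", k - 1L,
          class = "flaps_config_error")
  if (abs(sum(product_profile) - 1) > 1e-9)
    stopf("product_profile must sum to 1", class = "flaps_config_error")
  if (parent_mw <= class_bounds[2])
    stopf("parent_mw must fall in the first (parent) class",
          class = "flaps_config_error")

  mw_to_ev <- function(mw)
    (log10(mw) - calibration$intercept) / calibration$slope
  # product peak centres: geometric mean of class bounds (fallback for the
  # open-ended lowest class: a tenth of its upper bound)
  centers_mw <- vapply(seq_len(k - 1L), function(i) {
    hi <- class_bounds[i + 1L]; lo <- class_bounds[i + 2L]
    if (lo <= 0) hi / 10 else sqrt(hi * lo)
  }, numeric(1))
  centers_ev <- mw_to_ev(centers_mw)
  parent_ev <- mw_to_ev(parent_mw)

  gauss <- function(mu, area)
    area * exp(-0.5 * ((elution_grid - mu) / peak_width)^2) /
      (peak_width * sqrt(2 * pi))

  with_seed(seed, lapply(seq_along(timepoints_h), function(ti) {
    f <- transfer_fracs[ti]
    sig <- gauss(parent_ev, total_signal * (1 - f))
    for (i in seq_len(k - 1L))
      sig <- sig + gauss(centers_ev[i], total_signal * f * product_profile[i])
    if (noise_sd > 0) sig <- pmax(sig + rnorm(length(sig), 0, noise_sd), 0)
    chromatogram(elution_grid, sig, timepoints_h[ti])
  }))
}

#' Simulate a flow-cytometry event table with planted positives
#'
#' Events are drawn from a two-component log-normal mixture in FL1-H (a
#' FLAPS-negative background population and a brighter FLAPS-stained
#' population) with log-normal forward and side scatter independent of
#' staining. The number of planted positives is `round(frac_positive *
#' n_events)` (half away from zero), so truth counts are deterministic.
#'
#' @param n_events number of events (> 0).
#' @param frac_positive proportion of FLAPS-positive events in `[0, 1]`.
#' @param neg_fl1_law,pos_fl1_law `c(meanlog, sdlog)` of the FL1-H components.
#' @param fsc_law,ssc_law `c(meanlog, sdlog)` of the scatter channels.
#' @param seed integer seed.
#' @return list with `events` ([event_table()] with columns FSC-H, SSC-H,
#'   FL1-H) and `truth` (logical vector, `TRUE` for planted positives).
#' @export
simulate_event_table <- function(n_events, frac_positive,
                                 neg_fl1_law = c(log(200), 0.5),
                                 pos_fl1_law = c(log(5000), 0.6),
                                 fsc_law = c(log(50000), 0.4),
                                 ssc_law = c(log(30000), 0.5),
                                 seed = NULL) {
  if (n_events <= 0)
    stopf("n_events must be positive", class = "flaps_config_error")
  if (frac_positive < 0 || frac_positive > 1)
    stopf("frac_positive must lie in [0, 1]", class = "flaps_config_error")
  n_pos <- as.integer(round_half_away(frac_positive * n_events))
  with_seed(seed, {
    truth <- logical(n_events)
    if (n_pos > 0) truth[sample.int(n_events, n_pos)] <- TRUE
    fl1 <- rlnorm(n_events, neg_fl1_law[1], neg_fl1_law[2])
    if (n_pos > 0)
      fl1[truth] <- rlnorm(n_pos, pos_fl1_law[1], pos_fl1_law[2])
    df <- data.frame(`FSC-H` = rlnorm(n_events, fsc_law[1], fsc_law[2]),
                     `SSC-H` = rlnorm(n_events, ssc_law[1], ssc_law[2]),
                     `FL1-H` = fl1, check.names = FALSE)
    list(events = event_table(df), truth = truth)
  })
}
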