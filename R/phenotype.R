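# Cell classification by multi-channel co-localization, background-particle
# rejection, and sample / timecourse quantification.

PHENOTYPE_CLASSES <- c("unstained_cell", "flaps_cell", "flaps_fish_cell",
                       "cyanobacterium", "background_particle")

#' Classification thresholds
#'
#' A cell is scored FLAPS-positive when a FLAPS object overlaps at least
#' `min_overlap` of the cell's DAPI mask and that object's signal-to-
#' background ratio is at least `min_sbr`. Both thresholds are inclusive:
#' "minimum" is read literally, so overlap = 0.30 and SBR = 1.0 qualify.
#'
#' @param min_overlap minimum overlap fraction in `(0, 1]`, default 0.30.
#' @param min_sbr minimum signal-to-background ratio (> 0), default 1.0.
#' @return object of class `phenotype_thresholds`.
#' @export
phenotype_thresholds <- function(min_overlap = 0.30, min_sbr = 1.0) {
  if (min_overlap <= 0 || min_overlap > 1)
    stopf("min_overlap must lie in (0, 1]", class = "flaps_config_error")
  if (min_sbr <= 0)
    stopf("min_sbr must be positive", class = "flaps_config_error")
  structure(list(min_overlap = min_overlap, min_sbr = min_sbr),
            class = "phenotype_thresholds")
}

#' Overlap of a query mask with a reference (DAPI) mask
#'
#' Cell-centric overlap: the intersection size divided by the *reference*
#' size, the reference being the DAPI-defined cell. With this convention, a
#' substrate deposit covering 30% of a cell counts the same regardless of
#' how large the deposit itself is.
#'
#' @param reference_mask non-empty pixel-index vector (the DAPI object).
#' @param query_mask pixel-index vector (e.g. a FLAPS object).
#' @return proportion in `[0, 1]`.
#' @export
overlap_fraction <- function(reference_mask, query_mask) {
  if (!length(reference_mask))
    stopf("reference mask is empty", class = "flaps_degenerate_object_error")
  sum(reference_mask %in% query_mask) / length(reference_mask)
}

best_overlap <- function(dapi_mask, objs) {
  if (!length(objs)) return(list(overlap = 0, obj = NULL))
  ov <- vapply(objs, function(o) overlap_fraction(dapi_mask, o$mask), numeric(1))
  i <- which.max(ov)
  list(overlap = ov[i], obj = objs[[i]])
}

#' Classify one DAPI-defined cell by channel co-localization
#'
#' Evidence rules: a cell is FLAPS-positive when the best-overlapping FLAPS
#' object covers at least `min_overlap` of the DAPI mask *and* that object's
#' SBR is at least `min_sbr`; FISH- and AUTO-positivity use the same overlap
#' rule on their channels. The phenotype is then, in order of precedence:
#' `cyanobacterium` when AUTO- and FLAPS-positive (pigment autofluorescence,
#' excluded from selfish-uptake calculations), `flaps_fish_cell` when FLAPS-
#' and FISH-positive (all three signals overlap), `flaps_cell` when only
#' FLAPS-positive, else `unstained_cell`.
#'
#' @param dapi_obj detected DAPI object (see [segment_channel()]).
#' @param flaps_objs merged FLAPS objects ([merge_exposures()]).
#' @param fish_objs,auto_objs detected objects from the optional channels
#'   (empty list when the channel was not acquired).
#' @param th [phenotype_thresholds()].
#' @return one-row data frame: `cell_id`, `area_um2`, `centroid_row`,
#'   `centroid_col`, `flaps_overlap`, `flaps_sbr`, `fish_overlap`,
#'   `auto_positive`, `phenotype`.
#' @export
classify_cell <- function(dapi_obj, flaps_objs, fish_objs = list(),
                          auto_objs = list(), th = phenotype_thresholds()) {
  rec <- classify_cell_core(dapi_obj, flaps_objs, fish_objs, auto_objs, th)
  as.data.frame(rec, stringsAsFactors = FALSE)
}

classify_cell_core <- function(dapi_obj, flaps_objs, fish_objs, auto_objs, th) {
  if (is.null(dapi_obj) || !length(dapi_obj$mask))
    stopf("DAPI object is empty", class = "flaps_degenerate_object_error")
  fl <- best_overlap(dapi_obj$mask, flaps_objs)
  flaps_sbr <- if (is.null(fl$obj)) NA_real_ else fl$obj$sbr
  flaps_pos <- fl$overlap >= th$min_overlap && !is.na(flaps_sbr) &&
    flaps_sbr >= th$min_sbr
  fish_ov <- best_overlap(dapi_obj$mask, fish_objs)$overlap
  fish_pos <- fish_ov >= th$min_overlap
  auto_pos <- best_overlap(dapi_obj$mask, auto_objs)$overlap >= th$min_overlap
  phenotype <- if (flaps_pos && auto_pos) "cyanobacterium"
    else if (flaps_pos && fish_pos) "flaps_fish_cell"
    else if (flaps_pos) "flaps_cell"
    else "unstained_cell"
  list(cell_id = dapi_obj$object_id,
       area_um2 = dapi_obj$area_um2,
       centroid_row = dapi_obj$centroid[1],
       centroid_col = dapi_obj$centroid[2],
       flaps_overlap = fl$overlap, flaps_sbr = flaps_sbr,
       fish_overlap = fish_ov, auto_positive = auto_pos,
       phenotype = phenotype)
}

#' Reject non-cell FLAPS signals as background particles
#'
#' FLAPS signals without a nucleic-acid counterstain are background noise:
#' any FLAPS object whose overlap with every DAPI object stays below
#' `min_overlap` (overlap measured against each DAPI mask) is labeled a
#' background particle and excluded from all cell counts.
#'
#' @param flaps_objs merged FLAPS objects.
#' @param dapi_objs detected DAPI objects.
#' @param th [phenotype_thresholds()].
#' @return list with `particles` and `cell_associated` (disjoint sublists of
#'   `flaps_objs`).
#' @export
reject_background <- function(flaps_objs, dapi_objs,
                              th = phenotype_thresholds()) {
  if (!length(flaps_objs))
    return(list(particles = list(), cell_associated = list()))
  is_bg <- vapply(flaps_objs, function(fo) {
    for (d in dapi_objs)
      if (overlap_fraction(d$mask, fo$mask) >= th$min_overlap) return(FALSE)
    TRUE
  }, logical(1))
  list(particles = flaps_objs[is_bg], cell_associated = flaps_objs[!is_bg])
}

#' Detect and classify every cell in a field of view
#'
#' End-to-end per-field analysis: segments the DAPI channel (cell objects),
#' segments each FLAPS exposure (after optional FISH crosstalk subtraction)
#' and consolidates the series with [merge_exposures()], segments FISH and
#' AUTO channels when present, rejects non-DAPI FLAPS objects as background
#' particles, and classifies each cell with [classify_cell()]. FLAPS objects
#' are matched to a cell only within a centroid radius of 5 um, which bounds
#' the quadratic matching cost without affecting co-localization (masks
#' further apart cannot overlap).
#'
#' @param fov a [field_of_view()].
#' @param params a [segmentation_params()].
#' @param th [phenotype_thresholds()].
#' @param crosstalk_coeff FISH-into-FLAPS correction coefficient (see
#'   [correct_crosstalk()]); 0 disables the correction.
#' @param fov_id identifier copied into the output rows.
#' @return list: `cells` (data frame, one row per DAPI object), `particles`
#'   (data frame of background particles), `counts` (named totals), plus the
#'   detected object lists.
#' @export
analyze_field <- function(fov, params = segmentation_params(),
                          th = phenotype_thresholds(), crosstalk_coeff = 0,
                          fov_id = 1L) {
  px <- fov$meta$pixel_size_um
  dapi_objs <- segment_channel(fov_channels(fov, "DAPI"), params, px)
  fish_ch <- fov_channels(fov, "FISH")
  fish_objs <- if (is.null(fish_ch)) list() else
    segment_channel(fish_ch, params, px)
  auto_ch <- fov_channels(fov, "AUTO")
  auto_objs <- if (is.null(auto_ch)) list() else
    segment_channel(auto_ch, params, px)
  per_expo <- lapply(fov_channels(fov, "FLAPS"), function(ch) {
    if (crosstalk_coeff > 0 && !is.null(fish_ch))
      ch <- correct_crosstalk(ch, fish_ch, crosstalk_coeff)
    segment_channel(ch, params, px)
  })
  flaps_objs <- merge_exposures(per_expo)
  bg <- reject_background(flaps_objs, dapi_objs, th)

  near <- function(objs, ctr, radius_um = 5) {
    if (!length(objs)) return(list())
    d <- vapply(objs, function(o) sqrt(sum((o$centroid - ctr)^2)) * px,
                numeric(1))
    objs[d <= radius_um]
  }
  rows <- lapply(dapi_objs, function(d)
    classify_cell_core(d, near(flaps_objs, d$centroid),
                       near(fish_objs, d$centroid),
                       near(auto_objs, d$centroid), th))
  cells <- if (length(rows)) {
    pull <- function(fld, mode) vapply(rows, `[[`, vector(mode, 1), fld)
    cbind(data.frame(fov_id = fov_id, sample_id = fov$meta$sample_id,
                     timepoint_h = fov$meta$timepoint_h,
                     cell_id = pull("cell_id", "integer"),
                     area_um2 = pull("area_um2", "numeric"),
                     centroid_row = pull("centroid_row", "numeric"),
                     centroid_col = pull("centroid_col", "numeric"),
                     flaps_overlap = pull("flaps_overlap", "numeric"),
                     flaps_sbr = pull("flaps_sbr", "numeric"),
                     fish_overlap = pull("fish_overlap", "numeric"),
                     auto_positive = pull("auto_positive", "logical"),
                     phenotype = pull("phenotype", "character"),
                     stringsAsFactors = FALSE))
  } else {
    cbind(data.frame(fov_id = integer(0), sample_id = character(0),
                     timepoint_h = numeric(0)), classify_cell_empty_frame())
  }
  particles <- if (length(bg$particles)) {
    data.frame(fov_id = fov_id,
               particle_id = vapply(bg$particles, `[[`, numeric(1), "object_id"),
               area_um2 = vapply(bg$particles, `[[`, numeric(1), "area_um2"),
               centroid_row = vapply(bg$particles, function(o) o$centroid[1],
                                     numeric(1)),
               centroid_col = vapply(bg$particles, function(o) o$centroid[2],
                                     numeric(1)),
               phenotype = "background_particle", stringsAsFactors = FALSE)
  } else {
    data.frame(fov_id = integer(0), particle_id = numeric(0),
               area_um2 = numeric(0), centroid_row = numeric(0),
               centroid_col = numeric(0), phenotype = character(0))
  }
  counts <- c(n_cells = length(dapi_objs),
              n_flaps_pos = sum(cells$phenotype %in%
                                  c("flaps_cell", "flaps_fish_cell")),
              n_flaps_fish = sum(cells$phenotype == "flaps_fish_cell"),
              n_cyanobacteria = sum(cells$phenotype == "cyanobacterium"),
              n_background_particles = length(bg$particles))
  list(cells = cells, particles = particles, counts = counts,
       dapi_objects = dapi_objs, flaps_objects = flaps_objs,
       fish_objects = fish_objs, auto_objects = auto_objs)
}

classify_cell_empty_frame <- function() {
  data.frame(cell_id = integer(0), area_um2 = numeric(0),
             centroid_row = numeric(0), centroid_col = numeric(0),
             flaps_overlap = numeric(0), flaps_sbr = numeric(0),
             fish_overlap = numeric(0), auto_positive = logical(0),
             phenotype = character(0), stringsAsFactors = FALSE)
}

#' Quantify a sample from per-cell records over one or more fields of view
#'
#' `total_cells` counts every DAPI object (cyanobacteria included, background
#' particles excluded by construction). The selfish-uptake fraction excludes
#' cyanobacteria from both numerator and denominator:
#' `frac_flaps_pos = n_flaps_pos / (total_cells - n_cyanobacteria)`.
#' Volumetric abundance scales the mean per-field count up to the filter:
#' `cells_per_L = mean cells per FOV x (filter_area / fov_area) / volume`.
#' The 95% confidence interval on the pooled proportion is the Wilson score
#' interval.
#'
#' @param records data frame of cell records (with `fov_id`, `phenotype`).
#' @param meta [acquisition_meta()] with `fov_area_um2` set (as produced by
#'   [field_of_view()] / [simulate_field()]).
#' @param n_fov number of fields pooled; default: distinct `fov_id`s.
#' @param probe FISH probe label for the per-probe count column.
#' @return object of class `sample_quant`.
#' @export
quantify_sample <- function(records, meta, n_fov = NULL, probe = "probe") {
  if (is.null(meta$fov_area_um2))
    stopf("meta$fov_area_um2 is unset; quantification needs the imaged area",
          class = "flaps_config_error")
  if (meta$volume_filtered_L <= 0)
    stopf("volume_filtered_L must be positive", class = "flaps_config_error")
  if (is.null(n_fov)) n_fov <- max(1L, length(unique(records$fov_id)))
  total_cells <- nrow(records)
  n_flaps_pos <- sum(records$phenotype %in% c("flaps_cell", "flaps_fish_cell"))
  n_flaps_fish <- sum(records$phenotype == "flaps_fish_cell")
  n_cyano <- sum(records$phenotype == "cyanobacterium")
  denom <- total_cells - n_cyano
  frac <- if (denom > 0) n_flaps_pos / denom else NA_real_
  ci <- if (denom > 0) wilson_ci(n_flaps_pos, denom) else c(NA_real_, NA_real_)
  cells_per_L <- (total_cells / n_fov) *
    (meta$filter_area_um2 / meta$fov_area_um2) / meta$volume_filtered_L
  structure(list(sample_id = meta$sample_id, timepoint_h = meta$timepoint_h,
                 n_fov = n_fov, total_cells = total_cells,
                 cells_per_L = cells_per_L, n_flaps_pos = n_flaps_pos,
                 frac_flaps_pos = frac,
                 n_flaps_fish = stats::setNames(n_flaps_fish, probe),
                 n_cyanobacteria = n_cyano,
                 ci95_frac = ci),
            class = "sample_quant")
}

#' @export
as.data.frame.sample_quant <- function(x, ...) {
  data.frame(sample_id = x$sample_id, timepoint_h = x$timepoint_h,
             n_fov = x$n_fov, total_cells = x$total_cells,
             cells_per_L = x$cells_per_L, n_flaps_pos = x$n_flaps_pos,
             frac_flaps_pos = x$frac_flaps_pos,
             n_flaps_fish = unname(x$n_flaps_fish),
             probe = names(x$n_flaps_fish),
             n_cyanobacteria = x$n_cyanobacteria,
             ci95_lower = x$ci95_frac[1], ci95_upper = x$ci95_frac[2],
             stringsAsFactors = FALSE)
}

#' @export
print.sample_quant <- function(x, ...) {
  cat(sprintf("sample %s @ %g h: %d cells over %d FOV (%.3g cells/L)\n",
              x$sample_id, x$timepoint_h, x$total_cells, x$n_fov, x$cells_per_L))
  cat(sprintf("  FLAPS-positive: %d (%.1f%%, 95%% CI %.1f-%.1f%%); FISH+FLAPS: %d; cyanobacteria: %d\n",
              x$n_flaps_pos, 100 * x$frac_flaps_pos, 100 * x$ci95_frac[1],
              100 * x$ci95_frac[2], unname(x$n_flaps_fish), x$n_cyanobacteria))
  invisible(x)
}

#' Timecourse summary with fluorescence-dilution flags
#'
#' Per-interval changes of the stained fraction and of the cell abundance. A
#' drop in the stained fraction that coincides with an increase in cell
#' numbers is flagged: substrate distributed to daughter cells dilutes the
#' per-cell fluorescence after division, so such intervals should not be
#' read as a loss of selfish activity without checking the total counts.
#'
#' @param quants list of [quantify_sample()] results ordered by time.
#' @return data frame with one row per interval: `t_a`, `t_b`,
#'   `delta_frac_flaps_pos`, `delta_cells_per_L`, `dilution_flag`.
#' @export
timecourse_summary <- function(quants) {
  if (length(quants) < 2)
    stopf("timecourse needs >= 2 timepoints", class = "flaps_input_error")
  tp <- vapply(quants, `[[`, numeric(1), "timepoint_h")
  if (any(diff(tp) <= 0))
    stopf("timepoints must be strictly increasing", class = "flaps_input_error")
  fr <- vapply(quants, `[[`, numeric(1), "frac_flaps_pos")
  cl <- vapply(quants, `[[`, numeric(1), "cells_per_L")
  n <- length(quants)
  data.frame(t_a = tp[-n], t_b = tp[-1],
             delta_frac_flaps_pos = diff(fr),
             delta_cells_per_L = diff(cl),
             dilution_flag = diff(fr) < 0 & diff(cl) > 0)
}
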