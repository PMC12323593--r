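# Channel segmentation, signal-to-background scoring and consolidation of the
# multi-exposure FLAPS series into one object set per field of view.

#' Segmentation parameters
#'
#' @param threshold_method `"robust_background"` (default: image median +
#'   `k_mad` median absolute deviations, suited to sparse-cell fields) or
#'   `"otsu"`.
#' @param k_mad non-negative MAD multiplier for the robust threshold.
#' @param min_area_um2,max_area_um2 object size filter (square micrometres).
#' @param connectivity pixel connectivity for component labeling, 4 or 8.
#' @return object of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_method = c("robust_background", "otsu"),
                                k_mad = 5, min_area_um2 = 0.1,
                                max_area_um2 = 20, connectivity = 8) {
  threshold_method <- match.arg(threshold_method)
  if (k_mad < 0)
    stopf("k_mad must be non-negative", class = "flaps_config_error")
  if (min_area_um2 <= 0 || max_area_um2 <= min_area_um2)
    stopf("need 0 < min_area_um2 < max_area_um2", class = "flaps_config_error")
  if (!connectivity %in% c(4, 8))
    stopf("connectivity must be 4 or 8", class = "flaps_config_error")
  structure(list(threshold_method = threshold_method, k_mad = k_mad,
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 connectivity = connectivity),
            class = "segmentation_params")
}

# Connected-component labeling (compiled two-pass union-find; 4- or
# 8-connectivity). EBImage's labeller is fixed 4-connectivity, so the
# configurable kernel lives in src/.
label_components <- function(binary, connectivity = 8) {
  .label_cc(binary, as.integer(connectivity))
}

#' Segment one channel into candidate objects
#'
#' Thresholds the raster (foreground strictly above the threshold), labels
#' connected components, filters them by area, and scores each object's
#' signal-to-background ratio against the median intensity of non-object
#' pixels. An object is flagged `saturated` when at least 1% of its pixels
#' lie at or above 98% of `bit_max`.
#'
#' @param img a [channel_image()].
#' @param params a [segmentation_params()].
#' @param pixel_size_um physical pixel size (um).
#' @return list of detected objects; each has `object_id`, `channel_role`,
#'   `exposure_ms`, `mask` (pixel indices), `area_um2`, `centroid` (0-based
#'   `(row, col)`), `mean_intensity`, `sbr`, `saturated`, `pixel_size_um`.
#'   The background estimate is attached as attribute `background`.
#' @export
segment_channel <- function(img, params = segmentation_params(),
                            pixel_size_um) {
  stopifnot(inherits(img, "channel_image"))
  raster <- img$raster
  if (length(raster) == 0)
    stopf("raster has zero size", class = "flaps_input_error")
  thr <- switch(params$threshold_method,
    robust_background = stats::median(raster) + params$k_mad * stats::mad(raster),
    otsu = EBImage::otsu(EBImage::Image(raster / img$bit_max),
                         range = c(0, 1)) * img$bit_max)
  binary <- raster > thr
  lab <- label_components(binary, params$connectivity)
  objects <- list()
  if (max(lab) > 0) {
    fg <- which(lab > 0L)
    by_lab <- split(fg, lab[fg])
    px_area <- pixel_size_um^2
    min_px <- params$min_area_um2 / px_area
    max_px <- params$max_area_um2 / px_area
    dims <- dim(raster)
    keep <- Filter(function(ix) length(ix) >= min_px && length(ix) <= max_px,
                   by_lab)
    bg <- estimate_background(img, keep)
    oid <- 0L
    for (ix in keep) {
      oid <- oid + 1L
      vals <- raster[ix]
      ctr <- mask_centroid(ix, dims)
      objects[[oid]] <- list(
        object_id = oid, channel_role = img$channel_role,
        exposure_ms = img$exposure_ms, mask = ix,
        area_um2 = length(ix) * px_area,
        centroid = c(ctr[1] - 1, ctr[2] - 1),
        mean_intensity = mean(vals),
        # a zero background (possible in blank synthetic channels) makes any
        # signal unambiguously positive
        sbr = if (bg > 0) signal_background_ratio(ix, img, bg) else Inf,
        saturated = mean(vals >= 0.98 * img$bit_max) >= 0.01,
        pixel_size_um = pixel_size_um)
    }
    attr(objects, "background") <- bg
  } else {
    attr(objects, "background") <- estimate_background(img, list())
  }
  objects
}

#' Estimate the background intensity of a channel
#'
#' Median intensity over pixels outside the union of object masks. Requires
#' at least 100 background pixels so the estimate is not driven by a handful
#' of residual pixels.
#'
#' @param img a [channel_image()].
#' @param object_masks list of pixel-index vectors to exclude.
#' @return positive background intensity.
#' @export
estimate_background <- function(img, object_masks) {
  excl <- unique(unlist(object_masks))
  n_bg <- length(img$raster) - length(excl)
  if (n_bg < 100)
    stopf("fewer than 100 background pixels outside object masks (%d)",
          n_bg, class = "flaps_degenerate_background_error")
  vals <- if (length(excl)) img$raster[-excl] else as.vector(img$raster)
  stats::median(vals)
}

#' Signal-to-background ratio of an object
#'
#' Mean intensity inside the mask divided by the background estimate; a
#' minimum ratio of 1 is the positivity floor used by [classify_cell()].
#'
#' @param obj_mask pixel-index vector.
#' @param img a [channel_image()].
#' @param background_estimate positive background intensity.
#' @return non-negative ratio.
#' @export
signal_background_ratio <- function(obj_mask, img, background_estimate) {
  if (!is.numeric(background_estimate) || background_estimate <= 0)
    stopf("background estimate must be positive",
          class = "flaps_degenerate_background_error")
  mean(img$raster[obj_mask]) / background_estimate
}

#' Consolidate the FLAPS exposure series into one object set
#'
#' Objects detected at different exposures are considered the same physical
#' object when their centroids lie within `merge_dist_um` or their masks
#' intersect (transitively, via union-find). Each group is represented by the
#' detection from the longest exposure that did not saturate - the exposure
#' series exists to cover dim and bright cells alike - falling back to the
#' shortest exposure when every detection saturated.
#'
#' @param per_exposure_objects list (one entry per exposure) of
#'   [segment_channel()] outputs.
#' @param merge_dist_um centroid distance below which objects merge (um).
#' @return list of detected objects, one per physical object, re-numbered.
#' @export
merge_exposures <- function(per_exposure_objects, merge_dist_um = 0.5) {
  objs <- do.call(c, lapply(per_exposure_objects, unclass))
  attributes(objs) <- NULL
  n <- length(objs)
  if (n == 0) return(list())
  px <- objs[[1]]$pixel_size_um
  ctr <- t(vapply(objs, `[[`, numeric(2), "centroid")) * px
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  dmat <- as.matrix(stats::dist(ctr))
  cand <- which(dmat < 5 & upper.tri(dmat), arr.ind = TRUE)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    same <- dmat[i, j] < merge_dist_um ||
      any(objs[[j]]$mask %in% objs[[i]]$mask)
    if (same) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- lapply(split(seq_len(n), root), function(grp) {
    members <- objs[grp]
    unsat <- Filter(function(o) !o$saturated, members)
    rep <- if (length(unsat)) {
      unsat[[which.max(vapply(unsat, `[[`, numeric(1), "exposure_ms"))]]
    } else {
      members[[which.min(vapply(members, `[[`, numeric(1), "exposure_ms"))]]
    }
    rep
  })
  out <- unname(out)
  for (i in seq_along(out)) out[[i]]$object_id <- i
  out
}

#' Subtract FISH crosstalk from a FLAPS channel
#'
#' Red-excited FISH staining can bleed into the FLAPS channel and create
#' false-positive substrate signals; this subtracts `coeff` times the FISH
#' raster from the FLAPS raster, clipping at zero.
#'
#' @param flaps_img FLAPS [channel_image()].
#' @param fish_img FISH [channel_image()] (same shape).
#' @param coeff crosstalk coefficient in `[0, 1)`; 0 returns the input.
#' @return corrected [channel_image()].
#' @export
correct_crosstalk <- function(flaps_img, fish_img, coeff = 0) {
  if (coeff == 0) return(flaps_img)
  if (!identical(dim(flaps_img$raster), dim(fish_img$raster)))
    stopf("FLAPS and FISH rasters differ in shape", class = "flaps_registration_error")
  corrected <- pmax(flaps_img$raster - coeff * fish_img$raster, 0)
  channel_image(matrix(corrected, nrow(flaps_img$raster)), "FLAPS",
                flaps_img$exposure_ms, flaps_img$bit_max)
}
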