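# Readers, writers and domain-type constructors for external data:
# multi-channel TIFF stacks, gel-permeation chromatogram tables and
# flow-cytometry event tables.

CHANNEL_ROLES <- c("DAPI", "FLAPS", "FISH", "AUTO")

#' Single-channel image with acquisition role
#'
#' A `channel_image` couples one intensity raster with its role in the
#' staining scheme (DAPI nucleic-acid counterstain, FLAPS substrate channel,
#' FISH probe channel, or pigment autofluorescence) and the exposure used to
#' acquire it. Rasters are integer matrices indexed `(row, col)`, 0-based
#' pixel coordinates are used wherever coordinates are reported.
#'
#' @param raster numeric/integer matrix of non-negative intensities.
#' @param channel_role one of `"DAPI"`, `"FLAPS"`, `"FISH"`, `"AUTO"`.
#' @param exposure_ms positive exposure time in milliseconds.
#' @param bit_max maximum representable intensity (e.g. 4095 for a 12-bit
#'   camera). Not inferred from the data: it is acquisition metadata.
#' @return object of class `channel_image`.
#' @export
channel_image <- function(raster, channel_role, exposure_ms, bit_max) {
  if (!is.matrix(raster) || length(raster) == 0)
    stopf("raster must be a non-empty matrix", class = "flaps_input_error")
  channel_role <- match.arg(channel_role, CHANNEL_ROLES)
  if (!is.numeric(exposure_ms) || exposure_ms <= 0)
    stopf("exposure_ms must be positive", class = "flaps_input_error")
  if (!is.numeric(bit_max) || bit_max <= 0)
    stopf("bit_max must be positive", class = "flaps_input_error")
  if (any(raster < 0))
    stopf("%s raster contains negative intensities", channel_role,
          class = "flaps_input_error")
  if (any(raster > bit_max))
    stopf("%s raster exceeds bit_max = %g", channel_role, bit_max,
          class = "flaps_input_error")
  structure(list(raster = raster, channel_role = channel_role,
                 exposure_ms = as.numeric(exposure_ms),
                 bit_max = as.numeric(bit_max)),
            class = "channel_image")
}

#' Acquisition metadata for a field of view
#'
#' Carries the geometry and filtration bookkeeping needed to convert per-field
#' cell counts into volumetric abundances (cells per litre): counted cells are
#' scaled from the imaged area up to the effective filtration area and divided
#' by the filtered volume.
#'
#' @param pixel_size_um physical pixel edge length in micrometres.
#' @param filter_area_um2 effective filtration area of the membrane in square
#'   micrometres.
#' @param volume_filtered_L volume of sample filtered, in litres.
#' @param sample_id sample label.
#' @param timepoint_h incubation time in hours (non-negative).
#' @param fov_area_um2 imaged area; if `NULL`, computed from raster
#'   dimensions when the metadata is attached to a field of view.
#' @return object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(pixel_size_um, filter_area_um2, volume_filtered_L,
                             sample_id = "sample", timepoint_h = 0,
                             fov_area_um2 = NULL) {
  for (v in c(pixel_size_um, filter_area_um2, volume_filtered_L))
    if (!is.numeric(v) || v <= 0)
      stopf("pixel_size_um, filter_area_um2 and volume_filtered_L must be positive",
            class = "flaps_input_error")
  if (timepoint_h < 0)
    stopf("timepoint_h must be non-negative", class = "flaps_input_error")
  structure(list(pixel_size_um = pixel_size_um,
                 fov_area_um2 = fov_area_um2,
                 filter_area_um2 = filter_area_um2,
                 volume_filtered_L = volume_filtered_L,
                 sample_id = sample_id, timepoint_h = timepoint_h),
            class = "acquisition_meta")
}

#' Field of view: registered channel set plus metadata
#'
#' Bundles the channels acquired at one microscope stage position. Exactly one
#' DAPI channel is required (it defines cell objects); at least one FLAPS
#' exposure; FISH and AUTO channels are optional. All channels share one
#' raster shape — the instrument acquires every channel through a multi-filter
#' module without moving the sample, so no registration is computed.
#'
#' @param channels list of [channel_image()] objects.
#' @param meta [acquisition_meta()] for the position.
#' @return object of class `field_of_view`.
#' @export
field_of_view <- function(channels, meta) {
  if (!length(channels))
    stopf("a field of view needs at least one channel", class = "flaps_config_error")
  roles <- vapply(channels, function(ch) ch$channel_role, character(1))
  if (sum(roles == "DAPI") != 1)
    stopf("exactly one DAPI channel is required (found %d)", sum(roles == "DAPI"),
          class = "flaps_config_error")
  if (!any(roles == "FLAPS"))
    stopf("at least one FLAPS exposure is required", class = "flaps_config_error")
  dims <- vapply(channels, function(ch) dim(ch$raster), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("channel rasters differ in shape: channels must be co-registered",
          class = "flaps_registration_error")
  expo <- sort(vapply(channels[roles == "FLAPS"], function(ch) ch$exposure_ms,
                      numeric(1)))
  if (anyDuplicated(expo))
    stopf("FLAPS exposures must be unique", class = "flaps_config_error")
  npix_area <- prod(dims[, 1]) * meta$pixel_size_um^2
  if (is.null(meta$fov_area_um2)) {
    meta$fov_area_um2 <- npix_area
  } else if (abs(meta$fov_area_um2 - npix_area) > 0.01 * npix_area) {
    stopf("fov_area_um2 (%g) inconsistent with raster dimensions x pixel size (%g)",
          meta$fov_area_um2, npix_area, class = "flaps_config_error")
  }
  if (meta$fov_area_um2 > meta$filter_area_um2)
    stopf("fov_area_um2 exceeds filter_area_um2", class = "flaps_config_error")
  structure(list(channels = channels, meta = meta), class = "field_of_view")
}

#' @export
print.field_of_view <- function(x, ...) {
  d <- dim(x$channels[[1]]$raster)
  cat(sprintf("field_of_view: %d x %d px, %d channels (%s)\n", d[1], d[2],
              length(x$channels),
              paste(vapply(x$channels, function(ch)
                sprintf("%s@%gms", ch$channel_role, ch$exposure_ms),
                character(1)), collapse = ", ")))
  invisible(x)
}

#' Extract channels from a field of view by role
#'
#' @param fov a [field_of_view()].
#' @param role channel role to select.
#' @return list of `channel_image` (FLAPS, sorted by increasing exposure), or
#'   a single `channel_image`/`NULL` for the singleton roles.
#' @export
fov_channels <- function(fov, role) {
  role <- match.arg(role, CHANNEL_ROLES)
  sel <- Filter(function(ch) ch$channel_role == role, fov$channels)
  if (role == "FLAPS") {
    sel[order(vapply(sel, function(ch) ch$exposure_ms, numeric(1)))]
  } else if (length(sel)) sel[[1]] else NULL
}

#' Load a multi-channel field of view from TIFF files
#'
#' Reads single-page TIFFs (8/12/16-bit unsigned) without any rescaling:
#' stored integer sample values are preserved bit-exactly.
#'
#' @param image_paths character vector of TIFF paths.
#' @param meta [acquisition_meta()].
#' @param channel_map data frame with columns `file`, `role`, `exposure_ms`
#'   assigning each file a channel role and exposure; `file` entries are
#'   matched against `basename(image_paths)` (or full paths).
#' @param bit_max maximum representable intensity; default `NULL` derives it
#'   from the TIFF bits-per-sample tag.
#' @return validated [field_of_view()].
#' @export
load_field_of_view <- function(image_paths, meta, channel_map, bit_max = NULL) {
  stopifnot(is.data.frame(channel_map))
  need <- c("file", "role", "exposure_ms")
  if (!all(need %in% names(channel_map)))
    stopf("channel_map needs columns: %s", paste(need, collapse = ", "),
          class = "flaps_config_error")
  if (!any(toupper(channel_map$role) == "DAPI"))
    stopf("channel_map assigns no DAPI channel", class = "flaps_config_error")
  channels <- vector("list", length(image_paths))
  for (i in seq_along(image_paths)) {
    p <- image_paths[i]
    if (!file.exists(p))
      stopf("image file not found: '%s'", p, class = "flaps_io_error")
    j <- match(basename(p), channel_map$file)
    if (is.na(j)) j <- match(p, channel_map$file)
    if (is.na(j))
      stopf("channel_map has no entry for '%s'", basename(p),
            class = "flaps_config_error")
    img <- tryCatch(tiff::readTIFF(p, as.is = TRUE, info = TRUE),
                    error = function(e)
                      stopf("cannot read TIFF '%s': %s", p, conditionMessage(e),
                            class = "flaps_io_error"))
    bm <- bit_max
    if (is.null(bm)) {
      bits <- attr(img, "bits.per.sample")
      bm <- if (is.null(bits)) max(img) else 2^bits - 1
    }
    channels[[i]] <- channel_image(raster = unclass(img)[, , drop = TRUE],
                                   channel_role = toupper(channel_map$role[j]),
                                   exposure_ms = channel_map$exposure_ms[j],
                                   bit_max = bm)
  }
  field_of_view(channels, meta)
}

#' Write a field of view to single-page TIFF files
#'
#' One 16-bit TIFF per channel, named `<prefix>_<role>_<exposure>ms.tif`.
#' Raw integer counts are stored against the 16-bit full scale, so any
#' intensity up to 65535 survives a write/read cycle bit-exactly regardless
#' of the camera's bit depth.
#'
#' @param fov a [field_of_view()].
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @return data frame (`file`, `role`, `exposure_ms`) usable as a
#'   `channel_map` for [load_field_of_view()].
#' @export
write_field_of_view <- function(fov, dir, prefix = "fov") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(fov$channels, function(ch) {
    fn <- sprintf("%s_%s_%gms.tif", prefix, ch$channel_role, ch$exposure_ms)
    tiff::writeTIFF(ch$raster / 65535, file.path(dir, fn),
                    bits.per.sample = 16)
    data.frame(file = fn, role = ch$channel_role, exposure_ms = ch$exposure_ms,
               stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, rows))
}

#' Gel-permeation chromatogram
#'
#' Fluorescence signal versus elution volume for one filtrate sample. The
#' elution axis must be strictly increasing and the signal non-negative.
#'
#' @param elution_vol strictly increasing elution volumes (mL).
#' @param signal non-negative fluorescence per point.
#' @param timepoint_h incubation time of the sample (hours).
#' @return object of class `chromatogram`.
#' @export
chromatogram <- function(elution_vol, signal, timepoint_h = NA_real_) {
  if (length(elution_vol) != length(signal))
    stopf("elution_vol and signal lengths differ", class = "flaps_format_error")
  if (length(elution_vol) < 2 || any(diff(elution_vol) <= 0))
    stopf("elution axis must be strictly increasing", class = "flaps_format_error")
  if (any(signal < 0))
    stopf("chromatogram signal must be non-negative", class = "flaps_format_error")
  structure(list(elution_vol = as.numeric(elution_vol),
                 signal = as.numeric(signal),
                 timepoint_h = as.numeric(timepoint_h)),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("chromatogram: %d points, %.3g-%.3g mL, t = %g h\n",
              length(x$signal), min(x$elution_vol), max(x$elution_vol),
              x$timepoint_h))
  invisible(x)
}

#' Plot a chromatogram (or overlay several)
#'
#' @param x a `chromatogram`.
#' @param ... further chromatograms to overlay.
#' @export
plot.chromatogram <- function(x, ...) {
  extra <- Filter(function(o) inherits(o, "chromatogram"), list(...))
  all_c <- c(list(x), extra)
  ylim <- c(0, max(vapply(all_c, function(ch) max(ch$signal), numeric(1))))
  graphics::plot(x$elution_vol, x$signal, type = "l", ylim = ylim,
                 xlab = "elution volume (mL)", ylab = "fluorescence")
  if (length(extra))
    for (i in seq_along(extra))
      graphics::lines(extra[[i]]$elution_vol, extra[[i]]$signal, col = i + 1)
  invisible(x)
}

#' Read a chromatogram from a delimited table
#'
#' Accepts comma- or tab-delimited files with a header. Columns named
#' `elution_vol` and `signal` are used when present, otherwise the first two
#' columns; an optional `timepoint_h` column (constant) is carried along.
#'
#' @param path file path.
#' @param timepoint_h override for the timepoint label.
#' @return [chromatogram()].
#' @export
read_chromatogram <- function(path, timepoint_h = NULL) {
  df <- read_delim_auto(path)
  if (ncol(df) < 2)
    stopf("chromatogram table needs >= 2 columns", class = "flaps_format_error")
  ev <- if ("elution_vol" %in% names(df)) df$elution_vol else df[[1]]
  sg <- if ("signal" %in% names(df)) df$signal else df[[2]]
  tp <- if (!is.null(timepoint_h)) timepoint_h
        else if ("timepoint_h" %in% names(df)) df$timepoint_h[1] else NA_real_
  chromatogram(ev, sg, tp)
}

#' Write a chromatogram to a tab-delimited table
#' @param chrom a [chromatogram()].
#' @param path output path.
#' @export
write_chromatogram <- function(chrom, path) {
  df <- data.frame(elution_vol = chrom$elution_vol, signal = chrom$signal)
  if (!is.na(chrom$timepoint_h)) df$timepoint_h <- chrom$timepoint_h
  write_exact_table(df, path)
}

#' Flow-cytometry event table
#'
#' Per-event pulse-height measurements. `FSC-H` (forward scatter, size proxy)
#' and `FL1-H` (green fluorescence, 530/30 nm) are required for gating;
#' `SSC-H` (side scatter) is carried when present.
#'
#' @param df data frame of per-event measurements.
#' @param required_columns canonical column names that must resolve.
#' @return object of class `event_table` (a data frame).
#' @export
event_table <- function(df, required_columns = c("FSC-H", "FL1-H")) {
  nm <- names(df)
  for (want in unique(c(required_columns, "SSC-H"))) {
    hit <- which(tolower(gsub("[^[:alnum:]]", "", nm)) ==
                 tolower(gsub("[^[:alnum:]]", "", want)))
    if (length(hit)) {
      names(df)[hit[1]] <- want
    } else if (want %in% required_columns) {
      stopf("event table lacks required column '%s'", want,
            class = "flaps_format_error")
    }
  }
  for (cc in intersect(c("FSC-H", "SSC-H", "FL1-H"), names(df)))
    if (nrow(df) && any(df[[cc]] < 0))
      stopf("column '%s' contains negative values", cc, class = "flaps_format_error")
  class(df) <- c("event_table", "data.frame")
  df
}

#' Read a flow-cytometry event table
#'
#' Reads a delimited event export (comma or tab, header row) with
#' case-insensitive column matching. Binary FCS files are detected by their
#' magic number and rejected with a pointer to the delimited fallback: export
#' events as text (one row per event) from the acquisition software.
#'
#' @param path file path.
#' @param required_columns columns that must be present.
#' @return [event_table()]. An empty table (0 events) is valid; gating
#'   errors out later.
#' @export
read_event_table <- function(path, required_columns = c("FSC-H", "FL1-H")) {
  if (!file.exists(path))
    stopf("file not found: '%s'", path, class = "flaps_io_error")
  magic <- readBin(path, "raw", n = 6)
  if (identical(rawToChar(magic[1:3]), "FCS"))
    stopf(paste0("'%s' is a binary FCS file; export events as a delimited ",
                 "table (header row with FSC-H, SSC-H, FL1-H) and retry"),
          path, class = "flaps_format_error")
  first <- readLines(path, n = 2L)
  if (length(first) < 2L) {
    hdr <- strsplit(first[1], "[,\t]")[[1]]
    df <- stats::setNames(as.data.frame(rep(list(numeric(0)), length(hdr))), hdr)
  } else {
    df <- read_delim_auto(path)
  }
  event_table(df, required_columns)
}

#' Write an event table to a tab-delimited file
#' @param events an [event_table()].
#' @param path output path.
#' @export
write_event_table <- function(events, path) {
  write_exact_table(as.data.frame(events), path)
}

#' Write a per-cell classification table
#'
#' Tab-delimited, stable column order; numeric values survive a read/write
#' cycle exactly.
#'
#' @param records data frame of cell records (see [classify_cell()]).
#' @param path output path.
#' @export
write_cell_table <- function(records, path) {
  cols <- c("cell_id", "fov_id", "sample_id", "timepoint_h", "area_um2",
            "centroid_row", "centroid_col", "flaps_overlap", "flaps_sbr",
            "fish_overlap", "auto_positive", "phenotype")
  keep <- intersect(cols, names(records))
  write_exact_table(records[, c(keep, setdiff(names(records), keep)), drop = FALSE],
                    path)
}

#' Read back a per-cell classification table
#' @param path file path.
#' @return data frame.
#' @export
read_cell_table <- function(path) read_delim_auto(path)

#' Write a sample summary table
#' @param quant a `sample_quant` (see [quantify_sample()]) or a data frame of
#'   several.
#' @param path output path.
#' @export
write_summary <- function(quant, path) {
  df <- if (inherits(quant, "sample_quant")) as.data.frame(quant) else quant
  write_exact_table(df, path)
}
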