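# End-to-end workflow: configuration, staging, and the `run` entry point
# used by the command-line wrapper. Stages: simulate (optional) -> detect ->
# phenotype, plus hydrolysis and cytometry when their inputs are present.

#' Read and validate a run configuration
#'
#' The configuration is one YAML file holding per-stage blocks (`simulate`,
#' `detect`, `phenotype`, `hydrolysis`, `cytometry`), a `seed`, and an
#' `output_dir`. Unknown top-level keys are rejected so typos fail before any
#' work is done.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path))
      stopf("config file not found: '%s'", path, class = "flaps_config_error")
    yaml::read_yaml(path)
  }
  known <- c("seed", "output_dir", "simulate", "detect", "phenotype",
             "hydrolysis", "cytometry")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stopf("unknown config keys: %s", paste(extra, collapse = ", "),
          class = "flaps_config_error")
  if (!is.null(cfg$seed) && cfg$seed != as.integer(cfg$seed))
    stopf("seed must be an integer", class = "flaps_config_error")
  if (is.null(cfg$simulate) && !is.null(cfg$detect) &&
      is.null(cfg$detect$fov_dirs))
    stopf("detect stage without simulate block needs detect$fov_dirs",
          class = "flaps_config_error")
  if (!is.null(cfg$detect$fov_dirs) && is.null(cfg$detect$channel_map))
    stopf("detect$fov_dirs requires detect$channel_map", class = "flaps_config_error")
  structure(cfg, class = "run_config")
}

cfg_seg_params <- function(cfg) {
  do.call(segmentation_params, cfg$detect$segmentation %||% list())
}

cfg_thresholds <- function(cfg) {
  do.call(phenotype_thresholds, cfg$phenotype$thresholds %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full phenotyping workflow
#'
#' Executes the configured stages in order and writes all outputs below
#' `output_dir`: simulated TIFFs and truth tables, per-cell and per-particle
#' classification tables, sample summaries, hydrolysis rate tables, gating
#' results, and a run manifest (config echo, package version, seeds).
#' Identical configuration and seed give byte-identical output tables.
#'
#' @param config path to a YAML config, or a config list (see
#'   [read_run_config()]).
#' @param seed overrides the config seed.
#' @param out_dir overrides the config `output_dir`.
#' @param force overwrite a non-empty output directory.
#' @return (invisibly) list of in-memory stage results.
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL, force = FALSE) {
  cfg <- read_run_config(config)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  out_dir <- out_dir %||% cfg$output_dir %||% "flaps_run"
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stopf("output directory '%s' is not empty (use force = TRUE to overwrite)",
          out_dir, class = "flaps_config_error")
  if (dir.exists(out_dir) && force) unlink(out_dir, recursive = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(seed = seed)

  # ---- simulate + detect + phenotype -----------------------------------
  fovs <- list(); truths <- list()
  if (!is.null(cfg$simulate)) {
    sim_dir <- file.path(out_dir, "sim")
    n_fov <- cfg$simulate$n_fov %||% 1L
    field_args <- cfg$simulate$field %||% list()
    truth_rows <- list()
    for (i in seq_len(n_fov)) {
      fc <- do.call(sim_field_config, c(field_args, list(seed = seed + i - 1L)))
      sim <- simulate_field(fc)
      fovs[[i]] <- sim$fov; truths[[i]] <- sim$truth
      cmap <- write_field_of_view(sim$fov, file.path(sim_dir, sprintf("fov_%03d", i)),
                                  prefix = sprintf("fov_%03d", i))
      write_exact_table(cmap, file.path(sim_dir, sprintf("fov_%03d", i),
                                        "channel_map.tsv"))
      tr <- sim$truth$objects
      if (nrow(tr)) truth_rows[[i]] <- cbind(fov_id = i, tr)
    }
    if (length(truth_rows))
      write_exact_table(do.call(rbind, truth_rows),
                        file.path(sim_dir, "truth.tsv"))
    results$truths <- truths
  } else if (!is.null(cfg$detect$fov_dirs)) {
    cmap <- read_delim_auto(cfg$detect$channel_map)
    meta_args <- cfg$detect$meta %||% list()
    for (i in seq_along(cfg$detect$fov_dirs)) {
      d <- cfg$detect$fov_dirs[[i]]
      paths <- file.path(d, cmap$file)
      fovs[[i]] <- load_field_of_view(paths, do.call(acquisition_meta, meta_args),
                                      cmap)
    }
  }

  if (length(fovs)) {
    params <- cfg_seg_params(cfg)
    th <- cfg_thresholds(cfg)
    ct <- cfg$detect$crosstalk_coeff %||% 0
    analyses <- lapply(seq_along(fovs), function(i)
      analyze_field(fovs[[i]], params, th, crosstalk_coeff = ct, fov_id = i))
    cells <- do.call(rbind, lapply(analyses, `[[`, "cells"))
    particles <- do.call(rbind, lapply(analyses, `[[`, "particles"))
    write_cell_table(cells, file.path(out_dir, "cells.tsv"))
    write_exact_table(particles, file.path(out_dir, "particles.tsv"))
    quant <- quantify_sample(cells, fovs[[1]]$meta, n_fov = length(fovs))
    write_summary(quant, file.path(out_dir, "summary.tsv"))
    results$cells <- cells; results$particles <- particles
    results$quant <- quant; results$analyses <- analyses
  }

  # ---- hydrolysis -------------------------------------------------------
  if (!is.null(cfg$hydrolysis)) {
    hy <- cfg$hydrolysis
    cal <- if (!is.null(hy$standards)) calibrate_mw(read_delim_auto(hy$standards))
           else default_mw_calibration()
    bounds <- unlist(hy$class_bounds) %||% c(Inf, 3000, 800, 250, 0)
    chroms <- if (!is.null(hy$files)) {
      tps <- unlist(hy$timepoints_h %||% rep(NA_real_, length(hy$files)))
      Map(function(f, tp) read_chromatogram(f, timepoint_h = tp),
          hy$files, tps)
    } else {
      sim_args <- hy$simulate %||% list()
      do.call(simulate_chromatogram_series,
              c(sim_args, list(calibration = cal, class_bounds = bounds,
                               seed = seed)))
    }
    profiles <- lapply(chroms, bin_chromatogram, cal = cal, class_bounds = bounds)
    killed <- NULL
    if (!is.null(hy$killed_files)) {
      tps <- unlist(hy$timepoints_h %||% rep(NA_real_, length(hy$killed_files)))
      kc <- Map(function(f, tp) read_chromatogram(f, timepoint_h = tp),
                hy$killed_files, tps)
      killed <- lapply(kc, bin_chromatogram, cal = cal, class_bounds = bounds)
    }
    rates <- hydrolysis_rate(profiles,
                             substrate_conc_monomer = hy$substrate_conc_monomer %||% 3500,
                             killed_profiles = killed)
    write_exact_table(as.data.frame(rates), file.path(out_dir, "hydrolysis_rates.tsv"))
    fr <- do.call(rbind, lapply(profiles, function(p)
      data.frame(timepoint_h = p$timepoint_h,
                 t(stats::setNames(p$fractions,
                                   paste0("class", seq_along(p$fractions)))))))
    write_exact_table(fr, file.path(out_dir, "mw_class_fractions.tsv"))
    results$hydrolysis <- rates
  }

  # ---- cytometry --------------------------------------------------------
  if (!is.null(cfg$cytometry)) {
    cy <- cfg$cytometry
    q <- cy$quantile %||% 0.999
    fsc <- cy$fsc_threshold %||% 17000
    if (!is.null(cy$control)) {
      control <- read_event_table(cy$control)
      samples <- lapply(cy$samples, read_event_table)
      nms <- basename(unlist(cy$samples))
    } else {
      sim_args <- cy$simulate %||% list(n_events = 10000, frac_positive = 0.3)
      control <- simulate_event_table(sim_args$n_events %||% 10000, 0,
                                      seed = seed)$events
      samples <- list(do.call(simulate_event_table,
                              c(sim_args, list(seed = seed + 1L)))$events)
      nms <- "simulated"
    }
    thr <- control_threshold(control, quantile = q, fsc_threshold = fsc)
    gates <- lapply(samples, gate_flaps_positive, fl1_threshold = thr,
                    fsc_threshold = fsc)
    gdf <- do.call(rbind, lapply(gates, as.data.frame))
    gdf <- cbind(sample = nms, gdf)
    write_exact_table(gdf, file.path(out_dir, "cytometry_gates.tsv"))
    results$cytometry <- gates
  }

  manifest <- list(package = "flapsphenotyper",
                   version = as.character(utils::packageVersion("flapsphenotyper")),
                   seed = seed,
                   config = cfg[order(names(cfg))])
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
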