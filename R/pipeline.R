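## Configuration handling and the end-to-end pipeline commands.

#' Default run configuration
#'
#' Nested list with one section per pipeline stage. Written to / read from
#' JSON; unknown keys are rejected on read so typos fail loudly.
#'
#' @param seed global seed; per-stage streams are derived from it by
#'   stable hashing.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synthetic_microscopy = list(
      wells = c("A1", "A2"),
      fields_per_well = 4L,
      field = unclass(field_spec())[setdiff(names(unclass(field_spec())),
                                            "seed")]),
    translocation_assay = list(
      cellline_profile = "a549",
      min_area_px = 30L,
      gates = list(perimeter = c(0, Inf), circularity = c(0, Inf),
                   intensity = c(0, Inf), sd_gfp = c(0, Inf),
                   theta_nc = 1.5, intercept = 0)),
    oscillator_model = list(
      params = unclass(oscillator_params()),
      stimulus = list(kind = "sustained", onset_min = 0,
                      duration_min = NA_real_, amplitude = 1),
      t_end_min = 400, dt_min = 0.5),
    population_model = unclass(population_config())[
      setdiff(names(unclass(population_config())), "seed")],
    trace_analysis = list(smooth_window = 3L, min_prominence = 0.2,
                          min_separation_min = 20))
}

merge_config <- function(base, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(base))
      stop("unknown config key: ", paste0(path, nm), call. = FALSE)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("config key ", paste0(path, nm), " must be a section",
             call. = FALSE)
      base[[nm]] <- merge_config(base[[nm]], user[[nm]],
                                 paste0(path, nm, "."))
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Read and validate a run configuration
#'
#' Reads a JSON config file and merges it over [default_run_config()];
#' unknown keys raise an error naming the offending path.
#'
#' @param path JSON file, or `NULL` for pure defaults.
#' @param seed overrides the config seed when not `NULL`.
#' @return validated configuration list.
#' @export
read_run_config <- function(path = NULL, seed = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    cfg <- merge_config(cfg, user)
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

config_field_spec <- function(cfg, seed) {
  do.call(field_spec, c(cfg$synthetic_microscopy$field, list(seed = seed)))
}

config_oscillator_params <- function(cfg) {
  do.call(oscillator_params, cfg$oscillator_model$params)
}

config_population <- function(cfg, moi = NULL) {
  pm <- cfg$population_model
  if (!is.null(moi)) pm$moi <- moi
  do.call(population_config, c(pm, list(seed = cfg$seed)))
}

write_manifest <- function(out_dir, command, cfg, files) {
  files <- files[file.exists(files)]
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("nfkbosc")),
    seed = cfg$seed,
    config = cfg,
    artifacts = data.frame(file = basename(files),
                           md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run a pipeline command
#'
#' Commands:
#' \describe{
#'   \item{`simulate-images`}{generate a synthetic plate and write TIFF
#'     channels plus ground truth.}
#'   \item{`quantify`}{segment, gate and classify every field of an image
#'     directory; writes `cells.csv` and `wells.csv`.}
#'   \item{`simulate-cell`}{single-cell oscillator trace; writes
#'     `trace.csv` (`t_min`, `x_ikba`, `n_p65`).}
#'   \item{`simulate-population`}{population percentage curve at the
#'     configured MOI; writes `population.csv`.}
#'   \item{`analyze-traces`}{peak detection and interval statistics for a
#'     trace CSV (column `t_min` plus one column per cell); writes
#'     `peaks.csv`, `intervals.csv`, `histogram.csv`.}
#'   \item{`replay-moi-contrast`}{population simulations at MOI 100 and
#'     MOI 1 with shared seed; writes both curves and their oscillation
#'     visibility scores.}
#' }
#' Every command writes a `manifest.json` with the config, seed and md5
#' checksums of its artifacts.
#'
#' @param command one of the commands above.
#' @param config path to a JSON config file, or a config list, or `NULL`
#'   for defaults.
#' @param out_dir output directory.
#' @param images_dir input image directory (for `quantify`).
#' @param traces_csv input trace table (for `analyze-traces`).
#' @param moi MOI override (for `simulate-population`).
#' @param cellline_profile profile override (for `quantify`).
#' @param seed seed override.
#' @return list of written artifact paths, invisibly.
#' @export
run_pipeline <- function(command, config = NULL, out_dir = ".",
                         images_dir = NULL, traces_csv = NULL, moi = NULL,
                         cellline_profile = NULL, seed = NULL) {
  commands <- c("simulate-images", "quantify", "simulate-cell",
                "simulate-population", "analyze-traces",
                "replay-moi-contrast")
  if (!is.character(command) || length(command) != 1L ||
      !command %in% commands)
    stop("unknown command '", paste(command, collapse = " "),
         "'; expected one of: ", paste(commands, collapse = ", "))
  cfg <- if (is.list(config)) merge_config(default_run_config(), config)
         else read_run_config(config, seed = seed)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- switch(command,
    "simulate-images" = {
      sm <- cfg$synthetic_microscopy
      spec <- config_field_spec(cfg, seed = 0L)
      plate <- generate_plate(
        stats::setNames(rep(list(spec), length(sm$wells)), sm$wells),
        fields_per_well = sm$fields_per_well, plate_seed = cfg$seed)
      write_plate(plate, out_dir)
      list.files(out_dir, full.names = TRUE)
    },
    "quantify" = {
      if (is.null(images_dir)) stop("'images_dir' is required for quantify")
      if (!dir.exists(images_dir)) stop("missing input: ", images_dir)
      prof_name <- cellline_profile %||%
        cfg$translocation_assay$cellline_profile
      profile <- cellline_profile(prof_name)
      g <- cfg$translocation_assay$gates
      gates <- gate_spec(perimeter = g$perimeter,
                         circularity = g$circularity,
                         intensity = g$intensity, sd_gfp = g$sd_gfp,
                         theta_nc = g$theta_nc, intercept = g$intercept)
      stains <- sort(list.files(images_dir, "_stain\\.tif$"))
      if (!length(stains)) stop("missing input: no *_stain.tif in ",
                                images_dir)
      cells <- list()
      for (f in stains) {
        gfp_name <- sub("_stain\\.tif$", "_gfp.tif", f)
        gfp_path <- file.path(images_dir, gfp_name)
        if (!file.exists(gfp_path)) stop("missing input: ", gfp_name)
        stain <- read_tiff16(file.path(images_dir, f))
        gfp <- read_tiff16(gfp_path)
        feats <- quantify_field(stain, gfp, gates = gates,
                                profile = profile,
                                min_area_px =
                                  cfg$translocation_assay$min_area_px)
        m <- regmatches(f, regexec("^([A-H][0-9]+)_f([0-9]+)_", f))[[1]]
        message(sprintf("%s: %d cells, %d excluded by gates", f,
                        nrow(feats),
                        sum(feats$classification == "excluded")))
        if (nrow(feats))
          cells[[f]] <- cbind(well = m[2], field = as.integer(m[3]), feats)
      }
      cells <- do.call(rbind, cells)
      rownames(cells) <- NULL
      wells <- well_percentage(cells)
      write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
      write.csv(wells, file.path(out_dir, "wells.csv"), row.names = FALSE)
      file.path(out_dir, c("cells.csv", "wells.csv"))
    },
    "simulate-cell" = {
      om <- cfg$oscillator_model
      stim <- stimulus_profile(om$stimulus$kind,
                               onset_min = om$stimulus$onset_min,
                               duration_min =
                                 if (is.na(om$stimulus$duration_min)) NULL
                                 else om$stimulus$duration_min,
                               amplitude = om$stimulus$amplitude)
      tr <- simulate_cell(config_oscillator_params(cfg), stim,
                          t_end_min = om$t_end_min, dt_min = om$dt_min)
      write.csv(tr, file.path(out_dir, "trace.csv"), row.names = FALSE)
      file.path(out_dir, "trace.csv")
    },
    "simulate-population" = {
      pc <- config_population(cfg, moi = moi)
      res <- simulate_population(pc, config_oscillator_params(cfg))
      out <- data.frame(t_min = res$t_min, pct_nuclear = res$pct_nuclear,
                        n_activated = res$n_activated)
      write.csv(out, file.path(out_dir, "population.csv"),
                row.names = FALSE)
      file.path(out_dir, "population.csv")
    },
    "analyze-traces" = {
      if (is.null(traces_csv)) stop("'traces_csv' is required")
      if (!file.exists(traces_csv)) stop("missing input: ", traces_csv)
      ta <- cfg$trace_analysis
      tab <- read.csv(traces_csv)
      if (!"t_min" %in% names(tab)) stop("trace CSV needs a t_min column")
      tcol <- tab$t_min
      ids <- setdiff(names(tab), "t_min")
      peaks <- list(); ivals <- list()
      for (id in ids) {
        y <- normalize_trace(tab[[id]], smooth_window = ta$smooth_window)
        pk <- detect_peaks(y, t_min = tcol,
                           min_prominence = ta$min_prominence,
                           min_separation_min = ta$min_separation_min)
        if (length(pk$peak_times_min))
          peaks[[id]] <- data.frame(cell = id,
                                    peak_time_min = pk$peak_times_min,
                                    peak_height = pk$peak_heights)
        if (length(pk$intervals_min))
          ivals[[id]] <- data.frame(cell = id,
                                    interval_min = pk$intervals_min)
      }
      peaks <- do.call(rbind, peaks); ivals <- do.call(rbind, ivals)
      write.csv(peaks, file.path(out_dir, "peaks.csv"), row.names = FALSE)
      write.csv(ivals, file.path(out_dir, "intervals.csv"),
                row.names = FALSE)
      if (!is.null(ivals) && nrow(ivals)) {
        hh <- interval_histogram(ivals$interval_min)
        hist_df <- data.frame(bin = names(hh$counts),
                              count = as.integer(hh$counts))
        write.csv(hist_df, file.path(out_dir, "histogram.csv"),
                  row.names = FALSE)
      }
      file.path(out_dir, c("peaks.csv", "intervals.csv", "histogram.csv"))
    },
    "replay-moi-contrast" = {
      params <- config_oscillator_params(cfg)
      curves <- lapply(c(high = 100, low = 1), function(m) {
        res <- simulate_population(config_population(cfg, moi = m), params)
        data.frame(t_min = res$t_min, pct_nuclear = res$pct_nuclear,
                   n_activated = res$n_activated)
      })
      scores <- vapply(curves, function(d)
        oscillation_visibility(d$pct_nuclear), numeric(1))
      write.csv(curves$high, file.path(out_dir, "population_moi100.csv"),
                row.names = FALSE)
      write.csv(curves$low, file.path(out_dir, "population_moi1.csv"),
                row.names = FALSE)
      jsonlite::write_json(
        list(moi100 = scores[["high"]], moi1 = scores[["low"]]),
        file.path(out_dir, "visibility.json"), auto_unbox = TRUE,
        digits = NA)
      message(sprintf("oscillation visibility: MOI 100 = %.3f, MOI 1 = %.3f",
                      scores[["high"]], scores[["low"]]))
      file.path(out_dir, c("population_moi100.csv", "population_moi1.csv",
                           "visibility.json"))
    })
  write_manifest(out_dir, command, cfg, unlist(files))
  invisible(c(unlist(files), file.path(out_dir, "manifest.json")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
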