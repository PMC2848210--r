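#' Specification of a synthetic microscopy field
#'
#' Describes one two-channel field of view: roughly circular nuclei
#' (Hoechst-like stain channel) surrounded by a cytoplasmic annulus carrying
#' GFP signal. Each cell is in one of two ground-truth states: "nuclear"
#' (p65-GFP translocated, most GFP inside the nucleus) or "cytoplasmic"
#' (resting, most GFP in the cytoplasm). Geometry is in pixels; intensities
#' are arbitrary units written 1:1 as 16-bit counts.
#'
#' @param width_px,height_px field size in pixels.
#' @param n_cells number of cells to place (non-overlapping).
#' @param nucleus_radius_px mean nucleus radius; per-cell radii are drawn
#'   uniformly in `nucleus_radius_px +/- nucleus_radius_spread_px`.
#' @param nucleus_radius_spread_px half-width of the radius range.
#' @param cytoplasm_extent_px width of the cytoplasmic annulus around the
#'   nucleus.
#' @param fraction_nuclear probability that a cell is in the translocated
#'   ("nuclear") state.
#' @param background additive background level of the stain channel.
#' @param stain_level nuclear stain intensity above background.
#' @param gfp_background additive background of the GFP channel (default 0 so
#'   that compartment intensity ratios equal the configured state ratios).
#' @param gfp_total per-cell GFP budget; the nuclear and cytoplasmic levels
#'   of a cell in state with nuclear:cytoplasmic ratio `r` are
#'   `gfp_total * r / (1 + r)` and `gfp_total / (1 + r)`.
#' @param ratio_nuclear nuclear:cytoplasmic GFP ratio of translocated cells.
#' @param ratio_cytoplasmic same ratio for resting cells (< 1).
#' @param noise_sd standard deviation of additive Gaussian noise (clipped at
#'   zero) applied to both channels.
#' @param seed integer seed; fields are bit-reproducible.
#' @return object of class `field_spec`.
#' @export
field_spec <- function(width_px = 900L, height_px = 900L, n_cells = 125L,
                       nucleus_radius_px = 5, nucleus_radius_spread_px = 1,
                       cytoplasm_extent_px = 4, fraction_nuclear = 0.5,
                       background = 100, stain_level = 500,
                       gfp_background = 0, gfp_total = 200,
                       ratio_nuclear = 4, ratio_cytoplasmic = 0.5,
                       noise_sd = 10, seed = 1L) {
  check_number(width_px, "width_px", lower = 8)
  check_number(height_px, "height_px", lower = 8)
  check_number(n_cells, "n_cells", lower = 0)
  check_number(nucleus_radius_px, "nucleus_radius_px", lower = 0,
               strict_lower = TRUE)
  check_number(nucleus_radius_spread_px, "nucleus_radius_spread_px",
               lower = 0)
  if (nucleus_radius_spread_px >= nucleus_radius_px)
    stop("radius spread must be smaller than the mean radius")
  check_number(cytoplasm_extent_px, "cytoplasm_extent_px", lower = 0,
               strict_lower = TRUE)
  check_number(fraction_nuclear, "fraction_nuclear", lower = 0, upper = 1)
  for (nm in c("background", "stain_level", "gfp_background", "gfp_total"))
    check_number(get(nm), nm, lower = 0)
  check_number(ratio_nuclear, "ratio_nuclear", lower = 0, strict_lower = TRUE)
  check_number(ratio_cytoplasmic, "ratio_cytoplasmic", lower = 0,
               strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  spec <- list(width_px = as.integer(width_px),
               height_px = as.integer(height_px),
               n_cells = as.integer(n_cells),
               nucleus_radius_px = nucleus_radius_px,
               nucleus_radius_spread_px = nucleus_radius_spread_px,
               cytoplasm_extent_px = cytoplasm_extent_px,
               fraction_nuclear = fraction_nuclear,
               background = background, stain_level = stain_level,
               gfp_background = gfp_background, gfp_total = gfp_total,
               ratio_nuclear = ratio_nuclear,
               ratio_cytoplasmic = ratio_cytoplasmic,
               noise_sd = noise_sd, seed = as.integer(seed))
  class(spec) <- "field_spec"
  spec
}

#' Generate one synthetic two-channel field
#'
#' Places non-overlapping cells (nucleus disk plus cytoplasmic annulus) by
#' rejection sampling, assigns each a ground-truth translocation state with
#' probability `fraction_nuclear`, paints both channels, and adds clipped
#' Gaussian noise. The whole cell footprint is kept disjoint between cells
#' and away from the image border so that every compartment is sampled from
#' its own cytoplasm.
#'
#' @param spec a [field_spec()].
#' @return object of class `synthetic_field`: list with `stain` and `gfp`
#'   intensity matrices and a `truth` data frame
#'   (`cell_id`, `x`, `y`, `radius_px`, `state`). `x` is the column and `y`
#'   the row of the nucleus centre, 1-based.
#' @export
generate_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  w <- spec$width_px; h <- spec$height_px
  ext <- spec$cytoplasm_extent_px

  cx <- cy <- rad <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- max(100L * n, 100L)
  while (placed < n) {
    if (attempts >= max_attempts)
      stop("could not place ", n, " cells in a ", w, "x", h,
           " field after ", max_attempts,
           " attempts; reduce n_cells or enlarge the field")
    attempts <- attempts + 1L
    r <- spec$nucleus_radius_px +
      runif(1, -1, 1) * spec$nucleus_radius_spread_px
    margin <- r + ext + 1
    x <- runif(1, margin, w - margin + 1)
    y <- runif(1, margin, h - margin + 1)
    if (placed > 0L) {
      i <- seq_len(placed)
      # full cell disks stay disjoint (nuclei a fortiori)
      if (any((cx[i] - x)^2 + (cy[i] - y)^2 <
              (rad[i] + r + 2 * ext + 1)^2)) next
    }
    placed <- placed + 1L
    cx[placed] <- x; cy[placed] <- y; rad[placed] <- r
  }

  state <- if (n > 0L) {
    ifelse(runif(n) < spec$fraction_nuclear, "nuclear", "cytoplasmic")
  } else character(0)

  stain <- matrix(spec$background, h, w)
  gfp <- matrix(spec$gfp_background, h, w)
  if (n > 0L) {
    stain <- .paint_annuli(stain, cx, cy, rep(0, n), rad,
                           rep(spec$background + spec$stain_level, n))
    ratio <- ifelse(state == "nuclear", spec$ratio_nuclear,
                    spec$ratio_cytoplasmic)
    cyt_level <- spec$gfp_background + spec$gfp_total / (1 + ratio)
    nuc_level <- spec$gfp_background + spec$gfp_total * ratio / (1 + ratio)
    gfp <- .paint_annuli(gfp, cx, cy, rad, rad + ext, cyt_level)
    gfp <- .paint_annuli(gfp, cx, cy, rep(0, n), rad, nuc_level)
  }
  if (spec$noise_sd > 0) {
    stain <- pmax(stain + matrix(rnorm(h * w, 0, spec$noise_sd), h, w), 0)
    gfp <- pmax(gfp + matrix(rnorm(h * w, 0, spec$noise_sd), h, w), 0)
  }
  truth <- data.frame(cell_id = seq_len(n), x = cx, y = cy, radius_px = rad,
                      state = state, stringsAsFactors = FALSE)
  structure(list(stain = stain, gfp = gfp, truth = truth, spec = spec),
            class = "synthetic_field")
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf("<synthetic_field> %dx%d px, %d cells (%d nuclear-state)\n",
              ncol(x$stain), nrow(x$stain), nrow(x$truth),
              sum(x$truth$state == "nuclear")))
  invisible(x)
}

#' Generate a synthetic plate
#'
#' Generates `fields_per_well` fields for each well, with per-field seeds
#' derived deterministically from the plate seed, the well label and the
#' field index, so any field can be regenerated in isolation.
#'
#' @param well_specs named list mapping 96-well labels (`A1`..`H12`) to
#'   [field_spec()] objects.
#' @param fields_per_well number of fields imaged per well.
#' @param plate_seed integer master seed for the plate.
#' @return object of class `synthetic_plate`: nested list
#'   `plate[[well]][[field]]` of `synthetic_field` objects.
#' @export
generate_plate <- function(well_specs, fields_per_well = 4L, plate_seed = 1L) {
  stopifnot(is.list(well_specs), length(well_specs) > 0)
  wells <- names(well_specs)
  if (is.null(wells) || any(!nzchar(wells)))
    stop("well_specs must be a named list of field_spec objects")
  if (anyDuplicated(wells)) stop("duplicate well labels: ",
                                 paste(unique(wells[duplicated(wells)]),
                                       collapse = ", "))
  bad <- setdiff(wells, well_labels_96())
  if (length(bad)) stop("invalid 96-well labels: ",
                        paste(bad, collapse = ", "))
  check_number(fields_per_well, "fields_per_well", lower = 0)
  plate <- lapply(wells, function(wl) {
    spec <- well_specs[[wl]]
    stopifnot(inherits(spec, "field_spec"))
    lapply(seq_len(fields_per_well), function(f) {
      fs <- spec
      fs$seed <- seed_stream(plate_seed, "field", wl, f)
      generate_field(fs)
    })
  })
  names(plate) <- wells
  structure(plate, class = "synthetic_plate",
            plate_seed = as.integer(plate_seed),
            fields_per_well = as.integer(fields_per_well))
}

#' Write a synthetic plate to disk
#'
#' Writes `<dir>/<well>_f<field>_<channel>.tif` (channels `stain` and `gfp`)
#' plus a `truth.csv` ground-truth table with columns
#' `well, field, cell_id, x, y, radius_px, state`.
#'
#' @param plate a `synthetic_plate`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_plate <- function(plate, dir) {
  stopifnot(inherits(plate, "synthetic_plate"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- list()
  for (wl in names(plate)) {
    for (f in seq_along(plate[[wl]])) {
      fld <- plate[[wl]][[f]]
      write_tiff16(fld$stain, file.path(dir, sprintf("%s_f%d_stain.tif",
                                                     wl, f)))
      write_tiff16(fld$gfp, file.path(dir, sprintf("%s_f%d_gfp.tif", wl, f)))
      if (nrow(fld$truth))
        truth[[length(truth) + 1L]] <-
          cbind(well = wl, field = f, fld$truth)
    }
  }
  if (length(truth))
    write.csv(do.call(rbind, truth), file.path(dir, "truth.csv"),
              row.names = FALSE)
  invisible(dir)
}
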