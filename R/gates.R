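## R01-R04 gating cascade and the per-well percentage statistic.
##
## R01 gates nuclei on perimeter and circularity (size/shape), R02 on
## overall GFP intensity and its standard deviation (expression level and
## homogeneity). Cells passing both are classified nuclear (R03) or
## cytoplasmic (R04) by an oblique decision boundary in the
## (nuclear, cytoplasmic) mean-intensity plane:
## nuclear iff mean_nuc_gfp > theta_nc * mean_cyt_gfp + intercept.

#' Gate specification
#'
#' @param perimeter,circularity numeric `c(lower, upper)` bounds for the
#'   R01 morphology gate.
#' @param intensity,sd_gfp numeric `c(lower, upper)` bounds for the R02
#'   expression/homogeneity gate (`intensity` gates the mean GFP over the
#'   nuclear+ring pixels).
#' @param theta_nc slope of the nuclear/cytoplasmic decision boundary
#'   (> 0). The default 1.5 asks for clearly more nuclear than cytoplasmic
#'   signal and is scale invariant when `intercept = 0`.
#' @param intercept optional intercept of the boundary.
#' @return object of class `gate_spec`.
#' @export
gate_spec <- function(perimeter = c(0, Inf), circularity = c(0, Inf),
                      intensity = c(0, Inf), sd_gfp = c(0, Inf),
                      theta_nc = 1.5, intercept = 0) {
  for (nm in c("perimeter", "circularity", "intensity", "sd_gfp")) {
    b <- get(nm)
    if (length(b) != 2L || any(is.na(b)) || b[1] >= b[2])
      stop("'", nm, "' must be c(lower, upper) with lower < upper")
  }
  check_number(theta_nc, "theta_nc", lower = 0, strict_lower = TRUE)
  check_number(intercept, "intercept")
  structure(list(perimeter = perimeter, circularity = circularity,
                 intensity = intensity, sd_gfp = sd_gfp,
                 theta_nc = theta_nc, intercept = intercept),
            class = "gate_spec")
}

#' Calibrate R01/R02 gate bounds from a control plate
#'
#' Region definitions are optimised per cell line in practice; this helper
#' reproduces that calibration by taking central percentile bands of the
#' morphology and intensity features of an unstimulated control population.
#'
#' @param control_features a `cell_features` data frame from an
#'   unstimulated plate.
#' @param probs lower/upper percentiles used as bounds.
#' @param theta_nc,intercept classification boundary, passed through.
#' @return a [gate_spec()].
#' @export
calibrate_gates <- function(control_features, probs = c(0.01, 0.99),
                            theta_nc = 1.5, intercept = 0) {
  stopifnot(nrow(control_features) > 0)
  b <- function(col) unname(quantile(control_features[[col]], probs))
  gate_spec(perimeter = b("perimeter_px"), circularity = b("circularity"),
            intensity = b("mean_gfp"), sd_gfp = c(0, b("sd_gfp")[2]),
            theta_nc = theta_nc, intercept = intercept)
}

#' Per-cell-line compartment profiles
#'
#' Erosion and ring-placement defaults per cell line: the epithelial lines
#' (`a549`, `ags`) use 2 px erosion and a ring distanced by 1 px; the
#' fibroblast line (`l929`) has larger, flatter nuclei and uses 3 px
#' erosion with a 2 px ring distance.
#'
#' @param name one of `"a549"`, `"ags"`, `"l929"`.
#' @return list with `erosion_px`, `ring_distance_px`, `ring_width_px`.
#' @export
cellline_profile <- function(name = c("a549", "ags", "l929")) {
  name <- match.arg(tolower(name), c("a549", "ags", "l929"))
  switch(name,
         a549 = list(erosion_px = 2, ring_distance_px = 1, ring_width_px = 1),
         ags = list(erosion_px = 2, ring_distance_px = 1, ring_width_px = 1),
         l929 = list(erosion_px = 3, ring_distance_px = 2, ring_width_px = 1))
}

#' Apply the gating cascade
#'
#' Cells failing the R01 (morphology) or R02 (intensity/homogeneity) gate
#' are excluded; cells passing both are classified `nuclear` when
#' `mean_nuc_gfp > theta_nc * mean_cyt_gfp + intercept` (R03), else
#' `cytoplasmic` (R04). A pure function of the features.
#'
#' @param features a `cell_features` data frame.
#' @param gates a [gate_spec()].
#' @return character vector (`"nuclear"`, `"cytoplasmic"`, `"excluded"`)
#'   aligned with the rows of `features`.
#' @export
apply_gates <- function(features, gates) {
  stopifnot(inherits(gates, "gate_spec"))
  inb <- function(x, b) x >= b[1] & x <= b[2]
  pass <- inb(features$perimeter_px, gates$perimeter) &
    inb(features$circularity, gates$circularity) &
    inb(features$mean_gfp, gates$intensity) &
    inb(features$sd_gfp, gates$sd_gfp)
  nuclear <- features$mean_nuc_gfp >
    gates$theta_nc * features$mean_cyt_gfp + gates$intercept
  out <- rep("excluded", nrow(features))
  out[pass & nuclear] <- "nuclear"
  out[pass & !nuclear] <- "cytoplasmic"
  out
}

#' Per-well percentage of cells with nuclear p65
#'
#' `pct_nuclear = 100 * n_nuclear / (n_nuclear + n_cytoplasmic)`; excluded
#' cells do not enter the denominator. Wells without any classified cell
#' get `NA` (undefined), not 0.
#'
#' @param classified data frame with columns `well` and `classification`.
#' @return data frame with one row per well: `well`, `n_nuclear`,
#'   `n_cytoplasmic`, `n_excluded`, `pct_nuclear`.
#' @export
well_percentage <- function(classified) {
  stopifnot(all(c("well", "classification") %in% names(classified)))
  wells <- unique(classified$well)
  out <- do.call(rbind, lapply(wells, function(wl) {
    cl <- classified$classification[classified$well == wl]
    n_nuc <- sum(cl == "nuclear")
    n_cyt <- sum(cl == "cytoplasmic")
    data.frame(well = wl, n_nuclear = n_nuc, n_cytoplasmic = n_cyt,
               n_excluded = sum(cl == "excluded"),
               pct_nuclear = if (n_nuc + n_cyt > 0)
                 100 * n_nuc / (n_nuc + n_cyt) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Distribution of the nuclear:cytoplasmic ratio
#'
#' Histogram of `nc_ratio` over the gated cells, a distribution readout of
#' intermediate translocation states that the binary classification
#' collapses.
#'
#' @param features a `cell_features` data frame.
#' @param bins number of equal-width bins over the observed range.
#' @return list with `breaks`, `counts`, `mids`.
#' @export
ratio_distribution <- function(features, bins = 30L) {
  stopifnot(nrow(features) >= 1L)
  check_number(bins, "bins", lower = 1)
  r <- features$nc_ratio
  rng <- range(r)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  counts <- tabulate(findInterval(r, breaks, all.inside = TRUE), bins)
  list(breaks = breaks, counts = counts,
       mids = (breaks[-1L] + breaks[-length(breaks)]) / 2)
}

#' Quantify one two-channel field
#'
#' Convenience wrapper running segmentation, compartment construction,
#' feature extraction and gating on one (stain, GFP) image pair.
#'
#' @param stain_channel,gfp_channel intensity matrices.
#' @param gates a [gate_spec()].
#' @param profile compartment geometry, e.g. from [cellline_profile()].
#' @param min_area_px passed to [segment_nuclei()].
#' @return `cell_features` data frame with an extra `classification`
#'   column.
#' @export
quantify_field <- function(stain_channel, gfp_channel,
                           gates = gate_spec(),
                           profile = cellline_profile("a549"),
                           min_area_px = 30L) {
  labels <- segment_nuclei(stain_channel, min_area_px = min_area_px)
  comp <- define_compartments(labels, profile$erosion_px,
                              profile$ring_distance_px,
                              profile$ring_width_px)
  feats <- extract_features(comp, gfp_channel)
  feats$classification <- apply_gates(feats, gates)
  feats
}
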