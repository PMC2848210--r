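## The automated p65-translocation readout: nucleus segmentation from the
## stain channel, eroded-nucleus / cytoplasmic-ring compartments, per-cell
## features, R01-R04 gating and the per-well percentage statistic.

# Otsu threshold on a 256-bin histogram of the intensity range.
otsu_threshold <- function(img, n_bins = 256L) {
  rng <- range(img)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(img, breaks, all.inside = TRUE), n_bins)
  w <- h / sum(h)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Segment nuclei from the stain channel
#'
#' Thresholds the nuclear-stain image (Otsu on a 256-bin histogram, or a
#' fixed threshold), labels 8-connected foreground components and drops
#' components below a minimum area. A minimum-contrast guard returns zero
#' labels for near-uniform images, where Otsu would split noise.
#'
#' @param stain_channel intensity matrix.
#' @param min_area_px minimum nucleus area in pixels.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold value (for `threshold_method="fixed"`).
#' @param min_contrast minimum intensity range required before any
#'   foreground is declared under Otsu.
#' @return integer label matrix (0 = background), labels consecutive in
#'   raster order of first appearance.
#' @export
segment_nuclei <- function(stain_channel, min_area_px = 30L,
                           threshold_method = c("otsu", "fixed"),
                           threshold = NULL, min_contrast = 10) {
  if (!is.matrix(stain_channel) || length(stain_channel) == 0)
    stop("'stain_channel' must be a non-empty matrix")
  if (any(!is.finite(stain_channel)))
    stop("'stain_channel' contains non-finite pixels")
  threshold_method <- match.arg(threshold_method)
  thr <- if (threshold_method == "fixed") {
    if (is.null(threshold)) stop("fixed thresholding needs 'threshold'")
    threshold
  } else {
    if (diff(range(stain_channel)) < min_contrast)
      return(matrix(0L, nrow(stain_channel), ncol(stain_channel)))
    otsu_threshold(stain_channel)
  }
  lab <- .cc_label(stain_channel > thr)
  if (min_area_px > 0L && max(lab) > 0L) {
    sizes <- tabulate(lab, max(lab))
    drop <- which(sizes < min_area_px)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      # relabel consecutively, preserving raster order
      keep <- sort(unique(lab[lab > 0L]))
      lab[] <- match(lab, keep, nomatch = 0L)
    }
  }
  lab
}

#' Build eroded-nucleus and cytoplasmic-ring compartments
#'
#' For every labelled nucleus the nuclear compartment is the set of pixels
#' whose Euclidean distance to the nearest background pixel exceeds
#' `erosion_px`, and the cytoplasmic ring is the set of background pixels
#' whose distance `d` to the (un-eroded) nucleus satisfies
#' `ring_distance_px < d <= ring_distance_px + ring_width_px`. Ring pixels
#' claimed by two nuclei go to the nearer one, ties to the lower label id.
#' A nucleus fully erased by erosion is dropped and recorded.
#'
#' The defaults (erode 2 px, ring distanced by 1 px, 1 px wide) are the
#' standard epithelial-line setup of the assay; a fibroblast profile uses
#' erosion 3 px and ring distance 2 px (see [cellline_profile()]).
#'
#' @param labels integer label matrix from [segment_nuclei()].
#' @param erosion_px nucleus erosion depth (px).
#' @param ring_distance_px gap between nucleus boundary and ring (px).
#' @param ring_width_px ring thickness (px).
#' @return object of class `compartment_map`: list with `labels` (input),
#'   `nuclear` and `ring` label matrices, `params`, `cell_ids` (surviving)
#'   and `dropped` (erased by erosion).
#' @export
define_compartments <- function(labels, erosion_px = 2, ring_distance_px = 1,
                                ring_width_px = 1) {
  stopifnot(is.matrix(labels))
  for (nm in c("erosion_px", "ring_distance_px", "ring_width_px"))
    check_number(get(nm), nm, lower = 0)
  storage.mode(labels) <- "integer"
  masks <- .compartment_masks(labels, erosion_px, ring_distance_px,
                              ring_width_px)
  all_ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  kept <- setdiff(sort(unique(as.vector(masks$nuclear))), 0L)
  dropped <- setdiff(all_ids, kept)
  ring <- masks$ring
  ring[!(ring %in% kept)] <- 0L  # rings of erased nuclei are void
  structure(list(labels = labels, nuclear = masks$nuclear, ring = ring,
                 params = list(erosion_px = erosion_px,
                               ring_distance_px = ring_distance_px,
                               ring_width_px = ring_width_px),
                 cell_ids = kept, dropped = dropped),
            class = "compartment_map")
}

# Crofton perimeter (4 directions) of a logical mask, via the 2x2 pixel
# configuration histogram. Standard integral-geometry estimator; close to
# the true perimeter for convex discrete shapes.
crofton_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  M <- matrix(0L, nr + 3L, nc + 3L)
  M[2:(nr + 1L), 2:(nc + 1L)] <- mask * 1L
  a <- M[-1L, -1L]
  b <- M[-(nr + 3L), -1L]          # shifted down: pixel above
  cc <- M[-1L, -(nc + 3L)]         # shifted right: pixel to the left
  d <- M[-(nr + 3L), -(nc + 3L)]   # diagonal
  XF <- a + 2L * b + 4L * cc + 8L * d
  h <- tabulate(XF + 1L, nbins = 16L)
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2), 0,
             pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2), pi / 4, pi / 2,
             pi / (4 * s2), pi / (4 * s2), pi / 4, pi / 2, 0, 0)
  sum(coefs * h)
}

#' Extract per-cell features
#'
#' One record per surviving cell: nucleus area and Crofton perimeter
#' (measured on the un-eroded nucleus), circularity `4*pi*A/P^2`, mean GFP
#' in the eroded nucleus and in the cytoplasmic ring, the standard
#' deviation of GFP over the union of the two compartments (homogeneity
#' readout), their mean (overall GFP intensity), and the
#' nuclear:cytoplasmic ratio. Cells with an empty ring and cells whose
#' ring region could be truncated by the image border are excluded, with
#' the reason recorded in the `excluded` attribute.
#'
#' @param compartments a [define_compartments()] result.
#' @param gfp_channel GFP intensity matrix, same size as the label image.
#' @return data frame of class `cell_features` with columns `cell_id`,
#'   `nucleus_area_px`, `perimeter_px`, `circularity`, `mean_nuc_gfp`,
#'   `mean_cyt_gfp`, `mean_gfp`, `sd_gfp`, `nc_ratio`; attribute `excluded`
#'   is a data frame (`cell_id`, `reason`).
#' @export
extract_features <- function(compartments, gfp_channel) {
  stopifnot(inherits(compartments, "compartment_map"),
            is.matrix(gfp_channel),
            all(dim(gfp_channel) == dim(compartments$labels)))
  labels <- compartments$labels
  nuc <- compartments$nuclear
  ring <- compartments$ring
  nr <- nrow(labels); ncl <- ncol(labels)
  border_margin <- compartments$params$ring_distance_px +
    compartments$params$ring_width_px
  excluded <- data.frame(cell_id = integer(0), reason = character(0))
  if (length(compartments$dropped))
    excluded <- rbind(excluded,
                      data.frame(cell_id = compartments$dropped,
                                 reason = "erased_by_erosion"))
  # one pass per matrix: pixel index lists keyed by label id
  pix_of <- function(m) {
    i <- which(m > 0L)
    split(i, m[i])
  }
  lab_pix <- pix_of(labels)
  nuc_pix_all <- pix_of(nuc)
  ring_pix_all <- pix_of(ring)
  rows <- list()
  for (id in compartments$cell_ids) {
    pix <- lab_pix[[as.character(id)]]
    ri <- (pix - 1L) %% nr + 1L
    ci <- (pix - 1L) %/% nr + 1L
    if (min(ri) - 1 <= border_margin || nr - max(ri) <= border_margin ||
        min(ci) - 1 <= border_margin || ncl - max(ci) <= border_margin) {
      excluded <- rbind(excluded,
                        data.frame(cell_id = id, reason = "border"))
      next
    }
    nuc_pix <- nuc_pix_all[[as.character(id)]]
    ring_pix <- ring_pix_all[[as.character(id)]]
    if (is.null(ring_pix) || !length(ring_pix)) {
      excluded <- rbind(excluded,
                        data.frame(cell_id = id, reason = "empty_ring"))
      next
    }
    # perimeter on the un-eroded nucleus, over its bounding box
    sub <- labels[min(ri):max(ri), min(ci):max(ci), drop = FALSE] == id
    per <- crofton_perimeter(sub)
    area <- length(pix)
    v_nuc <- gfp_channel[nuc_pix]
    v_ring <- gfp_channel[ring_pix]
    v_all <- c(v_nuc, v_ring)
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = id, nucleus_area_px = area, perimeter_px = per,
      circularity = 4 * pi * area / per^2,
      mean_nuc_gfp = mean(v_nuc), mean_cyt_gfp = mean(v_ring),
      mean_gfp = mean(v_all),
      sd_gfp = if (length(v_all) > 1L) sd(v_all) else 0,
      nc_ratio = mean(v_nuc) / mean(v_ring))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(0), nucleus_area_px = integer(0),
               perimeter_px = numeric(0), circularity = numeric(0),
               mean_nuc_gfp = numeric(0), mean_cyt_gfp = numeric(0),
               mean_gfp = numeric(0), sd_gfp = numeric(0),
               nc_ratio = numeric(0))
  class(out) <- c("cell_features", "data.frame")
  attr(out, "excluded") <- excluded
  out
}
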