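# A noise-free single-cell field for exact intensity checks
exact_field <- function(state_ratio = 4, fraction = 1) {
  spec <- field_spec(width_px = 120L, height_px = 120L, n_cells = 1L,
                     noise_sd = 0, fraction_nuclear = fraction,
                     ratio_nuclear = state_ratio, seed = 8L)
  generate_field(spec)
}

test_that("circularity of a rasterised disk matches the frozen estimate", {
  # frozen from the Crofton estimator (verified against an independent
  # integral-geometry implementation during development): disk r = 10
  mask <- disk_mask(25, 25, 13, 13, 10)
  lab <- matrix(0L, 25, 25); lab[mask] <- 1L
  # use erosion/ring 0/0/1 so nothing is dropped; perimeter is measured
  # on the un-eroded nucleus either way
  comp <- define_compartments(lab, 0, 0, 1)
  feats <- extract_features(comp, matrix(1, 25, 25))
  expect_equal(feats$perimeter_px, 65.19762, tolerance = 1e-6)
  expect_equal(feats$circularity, 4 * pi * 317 / 65.19762^2,
               tolerance = 1e-6)
  expect_gt(feats$circularity, 0.85) # discretisation band for disks
  expect_lt(feats$circularity, 1.1)
  expect_equal(feats$nucleus_area_px, 317)
})

test_that("uniform GFP gives sd 0 and unit ratio", {
  f <- exact_field()
  lab <- segment_nuclei(f$stain)
  comp <- define_compartments(lab, 2, 1, 1)
  feats <- extract_features(comp, matrix(7.5, 120, 120))
  expect_equal(feats$sd_gfp, 0)
  expect_equal(feats$nc_ratio, 1)
})

test_that("noise-free translocated cells show the configured 4:1 ratio", {
  f <- exact_field(state_ratio = 4, fraction = 1)
  feats <- quantify_field(f$stain, f$gfp)
  expect_equal(nrow(feats), 1)
  expect_equal(feats$nc_ratio, 4, tolerance = 1e-10)
  expect_equal(feats$classification, "nuclear")
})

test_that("feature extraction mirrors the generator levels per compartment", {
  spec <- field_spec(width_px = 400L, height_px = 400L, n_cells = 20L,
                     noise_sd = 0, fraction_nuclear = 0.5, seed = 31L)
  f <- generate_field(spec)
  feats <- quantify_field(f$stain, f$gfp)
  expect_equal(nrow(feats), 20)
  # noise-free: each cell's measured ratio equals its state's ratio
  got <- ifelse(feats$nc_ratio > 1, "nuclear", "cytoplasmic")
  # match features to truth by nearest centroid is overkill: states are
  # recoverable from the ratios alone here
  expect_equal(sort(table(got)), sort(table(f$truth$state)),
               ignore_attr = TRUE)
  expect_true(all(abs(feats$nc_ratio - 4) < 1e-9 |
                    abs(feats$nc_ratio - 0.5) < 1e-9))
})

test_that("cells touching the border are excluded with a reason", {
  lab <- compartment_fixtures()$border_disk
  comp <- define_compartments(lab, 2, 1, 1)
  feats <- extract_features(comp, matrix(1, 32, 32))
  expect_equal(nrow(feats), 0)
  excl <- attr(feats, "excluded")
  expect_equal(excl$reason, "border")
})

test_that("gating cascade classifies and excludes as specified", {
  feats <- data.frame(cell_id = 1:4,
                      nucleus_area_px = 100, perimeter_px = 36,
                      circularity = c(0.9, 0.2, 0.9, 0.9),
                      mean_nuc_gfp = c(40, 40, 10, 30),
                      mean_cyt_gfp = c(10, 10, 40, 30),
                      mean_gfp = 25, sd_gfp = 5,
                      nc_ratio = c(4, 4, 0.25, 1))
  gates <- gate_spec(circularity = c(0.5, 1.2), theta_nc = 1)
  cls <- apply_gates(feats, gates)
  expect_equal(cls, c("nuclear", "excluded", "cytoplasmic", "cytoplasmic"))
  # infinite bounds, theta 1: ratio 4 cell is nuclear
  cls2 <- apply_gates(feats, gate_spec(theta_nc = 1))
  expect_equal(cls2[1], "nuclear")
})

test_that("raising the ratio threshold never increases nuclear calls", {
  set.seed(4)
  feats <- data.frame(cell_id = 1:200, nucleus_area_px = 100,
                      perimeter_px = 36, circularity = 0.9,
                      mean_nuc_gfp = runif(200, 5, 50),
                      mean_cyt_gfp = runif(200, 5, 50),
                      mean_gfp = 25, sd_gfp = 5, nc_ratio = 1)
  n_nuc <- vapply(c(0.5, 1, 1.5, 2, 4), function(th)
    sum(apply_gates(feats, gate_spec(theta_nc = th)) == "nuclear"),
    numeric(1))
  expect_true(all(diff(n_nuc) <= 0))
})

test_that("well percentages follow the printed formula and conserve", {
  cls <- data.frame(
    well = rep(c("A1", "A2", "A3"), c(105, 50, 15)),
    classification = c(rep("nuclear", 30), rep("cytoplasmic", 70),
                       rep("excluded", 5),
                       rep("cytoplasmic", 50),
                       rep("nuclear", 10), rep("excluded", 5)))
  res <- well_percentage(cls)
  expect_equal(res$pct_nuclear[res$well == "A1"], 30)
  expect_equal(res$pct_nuclear[res$well == "A2"], 0)
  expect_equal(res$pct_nuclear[res$well == "A3"], 100)
  expect_equal(res$n_excluded[res$well == "A1"], 5)
  # conservation: nuclear + cytoplasmic percentages sum to exactly 100
  pct_cyt <- 100 * res$n_cytoplasmic / (res$n_nuclear + res$n_cytoplasmic)
  expect_equal(res$pct_nuclear + pct_cyt, rep(100, 3))
  # a well with only excluded cells is undefined, not zero
  res2 <- well_percentage(data.frame(well = "B1",
                                     classification = "excluded"))
  expect_true(is.na(res2$pct_nuclear))
})

test_that("ratio distribution histograms behave at the edges", {
  feats <- data.frame(nc_ratio = rep(2, 10))
  h <- ratio_distribution(feats, bins = 5)
  expect_equal(sum(h$counts), 10)
  expect_equal(sum(h$counts > 0), 1)
  h1 <- ratio_distribution(data.frame(nc_ratio = runif(40, 0.3, 5)),
                           bins = 1)
  expect_equal(h1$counts, 40)
  # bimodal mixture: modes near 0.5 and 4 land in distinct occupied bins
  set.seed(9)
  mix <- data.frame(nc_ratio = c(rnorm(100, 0.5, 0.05), rnorm(100, 4, 0.2)))
  hm <- ratio_distribution(mix, bins = 12)
  occ <- which(hm$counts > 10)
  expect_gt(max(hm$mids[occ]) - min(hm$mids[occ]), 2)
})

test_that("gate calibration brackets a control population", {
  spec <- field_spec(width_px = 650L, height_px = 650L, n_cells = 100L,
                     fraction_nuclear = 0, noise_sd = 5, seed = 6L)
  f <- generate_field(spec)
  feats <- quantify_field(f$stain, f$gfp)
  gates <- calibrate_gates(feats)
  cls <- apply_gates(feats, gates)
  # nearly all control cells pass their own calibration gates
  expect_gte(mean(cls != "excluded"), 0.9)
  expect_true(all(cls[cls != "excluded"] == "cytoplasmic"))
})
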