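make_masks <- function(axon, dendrite) list(list(axon = axon,
                                                 dendrite = dendrite))

full_area <- function(nx, ny, px, name = "all") {
  target_area(name, rbind(c(0, 0), c(nx * px, 0), c(nx * px, ny * px),
                          c(0, ny * px)))
}

test_that("areas are pixel counts times pixel area; intersections bounded", {
  ax <- matrix(FALSE, 20, 20); ax[1:10, 1:10] <- TRUE   # 100 px
  dd <- matrix(FALSE, 20, 20); dd[11:20, 11:20] <- TRUE # disjoint 100 px
  tr <- list(affine2d(a = 0.31, d = 0.31, tx = 0.155, ty = 0.155))
  out <- measure_areas(make_masks(ax, dd), list(full_area(20, 20, 0.31)),
                       tr, 0.31)
  expect_equal(out$axon_area_um2, 100 * 0.31^2)     # 9.61
  expect_equal(out$dendrite_area_um2, 9.61)
  expect_equal(out$intersection_area_um2, 0)
  ov <- measure_areas(make_masks(ax, ax), list(full_area(20, 20, 0.31)),
                      tr, 0.31)
  expect_equal(ov$intersection_area_um2, ov$axon_area_um2)
})

test_that("areas over disjoint target areas add up to their union", {
  set.seed(5)
  ax <- matrix(runif(900) < 0.3, 30, 30)
  dd <- matrix(runif(900) < 0.3, 30, 30)
  px <- 0.5
  tr <- list(affine2d(a = px, d = px, tx = px / 2, ty = px / 2))
  left <- target_area("left", rbind(c(0, 0), c(7.5, 0), c(7.5, 15), c(0, 15)))
  right <- target_area("right", rbind(c(7.5, 0), c(15, 0), c(15, 15), c(7.5, 15)))
  both <- target_area("both", rbind(c(0, 0), c(15, 0), c(15, 15), c(0, 15)))
  out <- measure_areas(make_masks(ax, dd), list(left, right, both), tr, px)
  for (col in c("dendrite_area_um2", "axon_area_um2", "intersection_area_um2"))
    expect_equal(out[[col]][1] + out[[col]][2], out[[col]][3])
})

test_that("rasterized tube area agrees with the analytic projection", {
  th <- 0.09; r <- 0.62; zc <- 0.7; px <- 0.31; len <- 8
  truth <- list(neurites = data.frame(
    id = 1L, channel = "dendrite",
    x0 = 3, y0 = 6, z0 = zc, x1 = 3 + len, y1 = 6, z1 = zc, radius_um = r))
  stack <- structure(list(dim = c(ny = 45L, nx = 48L), pixel_size_um = px,
                          section_thickness_um = th, n_sections = 16L),
                     class = "section_stack")
  measured <- sum(vapply(1:16, function(k)
    sum(truth_tube_mask(truth, stack, k, "dendrite")), numeric(1))) * px^2
  # oracle: the capsule's slab projection at the closest in-slab depth dz is
  # a stadium of halfwidth w = sqrt(r^2 - dz^2): area = len * 2w + pi w^2
  analytic <- 0
  for (k in 1:16) {
    dz <- max(0, (k - 1) * th - zc, zc - k * th)
    if (dz < r) {
      w <- sqrt(r^2 - dz^2)
      analytic <- analytic + len * 2 * w + pi * w^2
    }
  }
  expect_lt(abs(measured - analytic) / analytic, 0.05)
})

test_that("densities and fold ratios reproduce the layer comparison", {
  areas <- data.frame(area = c("L4", "L5"),
                      dendrite_area_um2 = c(7777.5, 83857),
                      axon_area_um2 = c(2497.6, 13813),
                      intersection_area_um2 = c(279, 4830))
  rep <- density_and_folds(areas, c(L4 = 17, L5 = 447), reference = "L4")
  l5 <- rep[rep$area == "L5", ]
  expect_identical(trunc(l5$fold_count), 26)
  expect_equal(round(l5$fold_intersection, 1), 17.3)
  expect_equal(round(l5$fold_axon, 1), 5.5)
  expect_gte(l5$fold_dendrite, 10)
  expect_equal(l5$density_per_100um2_dendrite, 100 * 447 / 83857)
  fmt <- format_quant_report(rep)
  expect_identical(fmt$fold_count[fmt$area == "L5"], "26")
  expect_identical(fmt$fold_intersection[fmt$area == "L5"], "17.3")
})

test_that("fold ratios are invariant under pixel-size rescaling and guard zeros", {
  areas <- data.frame(area = c("A", "B"),
                      dendrite_area_um2 = c(10, 10),
                      axon_area_um2 = c(4, 4),
                      intersection_area_um2 = c(2, 2))
  rep <- density_and_folds(areas, c(A = 3, B = 3))
  expect_true(all(c(rep$fold_count[2], rep$fold_dendrite[2],
                    rep$fold_axon[2], rep$fold_intersection[2]) == 1))
  scaled <- areas
  scaled[, -1] <- scaled[, -1] * 4  # pixel size x2
  rep2 <- density_and_folds(scaled, c(A = 3, B = 3))
  expect_equal(rep2$fold_dendrite, rep$fold_dendrite)
  zero <- data.frame(area = c("A", "B"), dendrite_area_um2 = c(0, 5),
                     axon_area_um2 = c(1, 1), intersection_area_um2 = c(0, 1))
  rz <- density_and_folds(zero, c(A = 1, B = 1))
  expect_true(is.na(rz$density_per_100um2_dendrite[1]))
  expect_true(is.na(rz$fold_dendrite[2]))
  expect_false(is.infinite(rz$fold_dendrite[2]))
})

test_that("imaging-time arithmetic reproduces the worked example", {
  plan <- imaging_plan(1300, 1450, fov_um = 33, n_sections = 35,
                       minutes_per_tile = 3, targeted_tiles = 3268)
  expect_identical(plan$grid, c(40L, 44L))
  expect_identical(plan$full$n_tiles, 61600L)
  expect_equal(plan$full$total_hours, 3080)
  expect_equal(plan$targeted$total_hours, 163.4)
  expect_identical(plan$percent_saved, 95)
  expect_error(imaging_plan(10, 10, fov_um = 0, n_sections = 1), "> 0")
})

test_that("FWHM matches the Gaussian closed form and basic invariances", {
  for (sigma in c(52.2, 64.1, 69.6)) {
    x <- seq(-400, 400, by = 10)
    prof <- exp(-x^2 / (2 * sigma^2))
    expect_equal(fwhm(prof, 10), 2 * sqrt(2 * log(2)) * sigma,
                 tolerance = 0.01)
    expect_equal(fwhm(prof * 37 + 5, 10), fwhm(prof, 10), tolerance = 1e-9)
  }
  # symmetric triangle: width at half height equals half the base
  tri <- c(0, 1, 2, 3, 4, 3, 2, 1, 0)
  expect_equal(fwhm(tri, 1), 4)
  expect_error(fwhm(rep(1, 10)), "flat")
})

test_that("line profiles sample channels bilinearly at unit spacing", {
  planes <- list(dendrite = matrix(5, 20, 20),
                 axon = matrix(rep(0:19, each = 20), 20, 20),
                 marker = matrix(0, 20, 20))
  out <- line_profile(planes, 1, p0 = c(2, 7), p1 = c(12, 7))
  expect_identical(nrow(out), 11L)
  expect_true(all(out$dendrite == 5))
  # axis-aligned line equals the direct row slice (axon varies along x)
  expect_equal(out$axon, 2:12, tolerance = 1e-12)
  diag <- line_profile(planes, 1, p0 = c(0, 0), p1 = c(9, 9))
  expect_identical(nrow(diag), as.integer(ceiling(sqrt(2) * 9)) + 1L)
  expect_error(line_profile(planes, 1, c(3, 3), c(3, 3)), "zero-length")
  expect_error(line_profile(planes, 1, c(-1, 3), c(3, 3)), "outside")
})

test_that("the density extrapolation helper reproduces the printed arithmetic", {
  est <- synapse_share_estimate(0.5, area_correction_factor = 1.6,
                                reference_density_per_100um2 = 50)
  expect_equal(est$corrected_density_per_100um2, 0.8)
  expect_equal(est$percent_of_reference, 1.6)
})
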