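test_that("affine transforms invert exactly and handle the trivial cases", {
  p <- c(3.2, -1.5)
  expect_equal(to_global(p, affine2d()), p)
  expect_equal(to_global(p, affine2d(tx = 2, ty = -7)), p + c(2, -7))
  set.seed(6)
  for (i in 1:25) {
    tr <- affine2d(a = runif(1, 0.5, 2), b = runif(1, -0.5, 0.5),
                   c = runif(1, -0.5, 0.5), d = runif(1, 0.5, 2),
                   tx = runif(1, -100, 100), ty = runif(1, -100, 100))
    pts <- matrix(runif(20, -50, 50), ncol = 2)
    back <- to_local(to_global(pts, tr), tr)
    expect_lt(max(abs(back - pts)), 1e-6)
  }
  expect_error(affine2d(a = 1, b = 2, c = 2, d = 4), "singular")
})

test_that("overlap detection matches a flood-fill oracle with 8-connectivity", {
  # diagonal-only touching pixels form one component
  a <- matrix(TRUE, 6, 6)
  d <- matrix(FALSE, 6, 6); d[2, 2] <- TRUE; d[3, 3] <- TRUE
  comps <- detect_overlaps(a, d)
  expect_length(comps, 1L)
  expect_identical(nrow(comps[[1]]$pixels), 2L)
  # disjoint masks give an empty list
  expect_length(detect_overlaps(matrix(c(TRUE, FALSE), 4, 4),
                                matrix(c(FALSE, TRUE), 4, 4)), 0L)
  expect_error(detect_overlaps(matrix(TRUE, 3, 3), matrix(TRUE, 4, 4)),
               "mismatch")
  set.seed(12)
  for (i in 1:25) {
    m1 <- matrix(runif(15 * 17) < 0.4, 15, 17)
    m2 <- matrix(runif(15 * 17) < 0.4, 15, 17)
    comps <- detect_overlaps(m1, m2)
    lab <- flood_fill_label(m1 & m2)
    expect_length(comps, max(lab))
    for (cc in comps) {
      labs <- lab[cbind(cc$pixels[, 2] + 1L, cc$pixels[, 1] + 1L)]
      expect_identical(length(unique(labs)), 1L)  # one oracle component each
      expect_identical(nrow(cc$pixels), sum(lab == labs[1]))
    }
  }
})

test_that("field-of-view boxes center on components and clamp at borders", {
  dims <- c(ny = 200L, nx = 200L)
  comp <- function(x, y) list(section = 1L, area = "a",
                              pixels = cbind(x = x, y = y),
                              centroid = c(x = mean(x), y = mean(y)))
  b <- make_fov_boxes(list(comp(100, 100)), 32, dims)
  expect_identical(unlist(b[1, ], use.names = FALSE), c(84L, 84L, 116L, 116L))
  b0 <- make_fov_boxes(list(comp(0, 0)), 32, dims)
  expect_identical(unlist(b0[1, ], use.names = FALSE), c(0L, 0L, 32L, 32L))
  # deterministic, stable order follows the component order
  two <- make_fov_boxes(list(comp(10, 10), comp(150, 90)), 32, dims)
  expect_identical(two$x0, c(0L, 134L))
  expect_error(make_fov_boxes(list(comp(1, 1)), 500, dims), "exceeds")
})

test_that("box merging covers everything with near-minimal boxes", {
  dims <- c(ny = 200L, nx = 200L)
  close_px <- cbind(x = c(100L, 105L), y = c(50L, 50L))
  m1 <- merge_fov_boxes(NULL, close_px, 32, dims)
  expect_identical(nrow(m1), 1L)
  expect_true(box_cover_complete(m1, close_px))
  far_px <- cbind(x = c(10L, 100L), y = c(50L, 50L))
  m2 <- merge_fov_boxes(NULL, far_px, 32, dims)
  expect_identical(nrow(m2), 2L)
  expect_true(box_cover_complete(m2, far_px))
  expect_error(merge_fov_boxes(NULL, cbind(x = 500L, y = 1L), 32, dims),
               "uncoverable")
  set.seed(4)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    pix <- cbind(x = sample(0:199, n, replace = TRUE),
                 y = sample(0:199, n, replace = TRUE))
    got <- merge_fov_boxes(NULL, pix, 32, dims)
    expect_true(box_cover_complete(got, pix))
    opt <- min_cover_oracle(pix, 32, 200L, 200L)
    expect_lte(nrow(got), opt + 1L)
  }
})

test_that("interior-overlap candidates are rejected, surface contacts kept", {
  # a big blob present in both channels: its center overlap is interior
  a <- matrix(FALSE, 40, 40); a[5:35, 5:35] <- TRUE
  d <- a
  center <- list(section = 1L, area = "x",
                 pixels = cbind(x = 19L, y = 19L),
                 centroid = c(x = 19, y = 19))
  expect_true(reject_interior(center, a, d, interior_margin = 5))
  # a contact at the surface of both structures stays
  edge <- list(section = 1L, area = "x",
               pixels = cbind(x = 5L, y = 19L),
               centroid = c(x = 5, y = 19))
  expect_false(reject_interior(edge, a, d, interior_margin = 5))
  # limit behavior: an unbounded margin flags nothing, margin 0 flags any
  # foreground candidate
  expect_false(reject_interior(center, a, d, interior_margin = 1e9))
  expect_true(reject_interior(center, a, d, interior_margin = 0))
})

test_that("continuity keeps spanning structures and drops one-section speckle", {
  dims <- 30L
  blank <- matrix(FALSE, dims, dims)
  blob <- function(x, y) { m <- blank; m[y + (0:1), x + (0:1)] <- TRUE; m }
  transforms <- replicate(3, affine2d(), simplify = FALSE)
  # structures present on all three sections at (10, 10)
  masks <- list(
    list(axon = blob(10, 10), dendrite = blob(10, 10)),
    list(axon = blob(10, 10) | blob(20, 20), dendrite = blob(10, 10) | blob(20, 20)),
    list(axon = blob(10, 10), dendrite = blob(10, 10)))
  spanning <- list(section = 2L, centroid = c(x = 10.5, y = 10.5))
  speckle <- list(section = 2L, centroid = c(x = 20.5, y = 20.5))
  keep <- continuity_filter(list(spanning, speckle), masks, transforms,
                            match_radius = 3)
  expect_identical(keep, c(TRUE, FALSE))
  # channels reappearing in different neighbors still count as continuity...
  masks2 <- list(
    list(axon = blank, dendrite = blob(10, 10)),
    list(axon = blob(10, 10), dendrite = blob(10, 10)),
    list(axon = blob(10, 10), dendrite = blank))
  expect_true(continuity_filter(list(spanning), masks2, transforms)[1])
  # ...unless the stricter same-neighbor rule is requested
  expect_false(continuity_filter(list(spanning), masks2, transforms,
                                 require_same_neighbor = TRUE)[1])
  # first/last sections use their single neighbor
  first <- list(section = 1L, centroid = c(x = 10.5, y = 10.5))
  expect_true(continuity_filter(list(first), masks, transforms)[1])
  # a single-section stack removes everything, with a warning
  expect_warning(
    out <- continuity_filter(list(spanning), masks[2], transforms[2]),
    "single-section")
  expect_identical(out, FALSE)
})

test_that("series binding yields 3-5 consecutive sections around the anchor", {
  transforms <- replicate(10, affine2d(), simplify = FALSE)
  dims <- c(ny = 100L, nx = 100L)
  cand <- function(s) list(section = s, centroid = c(x = 50, y = 50))
  s1 <- bind_series(cand(5L), 1, 10L, transforms, 32, dims)
  expect_identical(s1$section, 4:6)
  s2 <- bind_series(cand(5L), 2, 10L, transforms, 32, dims)
  expect_identical(s2$section, 3:7)
  # truncation at the stack start, extended to keep three images
  s3 <- bind_series(cand(1L), 2, 10L, transforms, 32, dims)
  expect_identical(s3$section, 1:3)
  s4 <- bind_series(cand(1L), 1, 10L, transforms, 32, dims)
  expect_identical(s4$section, 1:3)
  s5 <- bind_series(cand(10L), 1, 10L, transforms, 32, dims)
  expect_identical(s5$section, 8:10)
  expect_error(bind_series(cand(5L), 3, 10L, transforms, 32, dims),
               "n_neighbors")
  # every entry carries the same global coordinate
  tr2 <- lapply(1:10, function(k) affine2d(tx = k, ty = -k))
  s6 <- bind_series(cand(5L), 1, 10L, tr2, 32, dims)
  g <- attr(s6, "global")
  for (j in seq_len(nrow(s6))) {
    loc <- to_local(g, tr2[[s6$section[j]]])
    expect_equal(c(s6$x[j], s6$y[j]), unname(loc), tolerance = 1e-9)
  }
})

test_that("target areas validate, rasterize and restrict detection", {
  expect_error(target_area("bad", rbind(c(0, 0), c(1, 0))), "n >= 3")
  expect_error(target_area("bow", rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))),
               "self-intersecting")
  sq <- target_area("L4", rbind(c(2, 2), c(8, 2), c(8, 8), c(2, 8)))
  m <- area_mask(sq, c(ny = 12L, nx = 12L), affine2d())
  expect_true(m[5, 5])    # (4, 4) inside
  expect_false(m[11, 11]) # (10, 10) outside
  # restriction: overlap outside the area is not reported
  a <- matrix(TRUE, 12, 12)
  comps <- detect_overlaps(a, a, target_mask = m, section = 1L,
                           area_name = "L4")
  pix <- do.call(rbind, lapply(comps, `[[`, "pixels"))
  expect_true(all(pix[, 1] >= 2 & pix[, 1] <= 8))
  # geojson round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_target_areas(list(sq), path)
  back <- read_target_areas(path)
  expect_identical(back[[1]]$name, "L4")
  expect_equal(back[[1]]$polygon, sq$polygon, ignore_attr = TRUE)
})
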