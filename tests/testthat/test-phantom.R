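test_that("section count follows ceil(z extent / thickness)", {
  cfg <- phantom_config(volume_size_um = c(10, 10, 3.15),
                        section_thickness_um = 0.09,
                        n_synapses = 0, n_near_misses = 0,
                        n_dendrites = 0, n_axons = 0)
  ph <- generate_phantom(cfg)
  expect_identical(ph$stack$n_sections, 35L)
  cfg2 <- phantom_config(volume_size_um = c(10, 10, 0.91),
                         n_synapses = 0, n_near_misses = 0,
                         n_dendrites = 0, n_axons = 0)
  expect_identical(generate_phantom(cfg2)$stack$n_sections, 11L)
})

test_that("degenerate volume and invalid parameters are rejected", {
  expect_error(phantom_config(volume_size_um = c(10, 0, 1)), "degenerate")
  expect_error(phantom_config(n_synapses = -1), "counts")
  expect_error(phantom_config(tile_brightness_cv = 1), "tile_brightness_cv")
  expect_error(phantom_config(section_thickness_um = 0), ">")
})

test_that("a forced crossing with gap 0 yields one true synapse on >= 1 section", {
  ph <- generate_phantom(phantom_config(
    volume_size_um = c(18, 18, 0.9), n_synapses = 1, n_near_misses = 0,
    n_dendrites = 0, n_axons = 0, seed = 5))
  syn <- ph$truth$synapses
  expect_identical(nrow(syn), 1L)
  expect_true(syn$is_true_synapse)
  expect_identical(syn$gap_um, 0)
  # the rendered contact produces overlapping binarized signal near the
  # synapse on at least one section
  res <- run_detect(ph$stack, run_config())
  rec <- phantom_recall(res, ph$truth, ph$stack, radius_px = 3)
  expect_identical(rec$n_found, 1L)
})

test_that("empty axon channel leads to zero overlaps downstream", {
  ph <- generate_phantom(phantom_config(
    volume_size_um = c(20, 20, 0.45), n_synapses = 0, n_near_misses = 0,
    n_dendrites = 3, n_axons = 0, seed = 9))
  res <- run_detect(ph$stack, run_config())
  expect_identical(res$counts$detected, 0L)
  expect_identical(nrow(res$candidates), 0L)
})

test_that("identical seed and config give identical output, different seeds differ", {
  cfg <- phantom_config(volume_size_um = c(12, 12, 0.27), n_synapses = 1,
                        n_near_misses = 1, n_dendrites = 1, n_axons = 1,
                        seed = 1)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$stack, b$stack)
  expect_identical(a$truth$synapses, b$truth$synapses)
  cfg2 <- phantom_config(volume_size_um = c(12, 12, 0.27), n_synapses = 1,
                         n_near_misses = 1, n_dendrites = 1, n_axons = 1,
                         seed = 2)
  c <- generate_phantom(cfg2)
  expect_false(identical(a$stack$sections, c$stack$sections))
  expect_identical(dim(a$stack$sections[[1]]$axon),
                   dim(c$stack$sections[[1]]$axon))
  expect_identical(a$stack$n_sections, c$stack$n_sections)
})

test_that("phantom write/read round-trips pixels, truth and metadata", {
  ph <- small_phantom()
  dir <- withr::local_tempdir()
  write_phantom(ph$stack, ph$truth, dir)
  back <- read_phantom(dir)
  expect_identical(back$stack$n_sections, ph$stack$n_sections)
  for (k in seq_len(ph$stack$n_sections))
    for (ch in ph$stack$channels)
      expect_equal(back$stack$sections[[k]][[ch]],
                   ph$stack$sections[[k]][[ch]], ignore_attr = TRUE)
  expect_identical(nrow(back$truth$synapses),
                   ph$truth$config$n_synapses + ph$truth$config$n_near_misses)
  expect_equal(back$stack$pixel_size_um, ph$stack$pixel_size_um)
})

test_that("marker signal above background occurs only near true synapses", {
  ph <- generate_phantom(phantom_config(
    volume_size_um = c(22, 22, 0.9), n_synapses = 3, n_near_misses = 3,
    n_dendrites = 2, n_axons = 2, tile_brightness_cv = 0,
    background_gradient_amplitude = 0, seed = 21))
  cfg <- ph$truth$config
  syn <- ph$truth$synapses
  px <- ph$stack$pixel_size_um
  # anything clearly above background + shot/read noise must be a punctum
  lim <- cfg$background_level + 8 * sqrt(cfg$background_level +
                                         cfg$noise_read_sd^2)
  for (k in seq_len(ph$stack$n_sections)) {
    m <- ph$stack$sections[[k]]$marker
    idx <- which(m > lim)
    if (!length(idx)) next
    iy <- ((idx - 1) %% nrow(m))
    ix <- ((idx - 1) %/% nrow(m))
    tru <- syn[syn$is_true_synapse, ]
    dmin <- vapply(seq_along(idx), function(j) {
      min(sqrt((tru$x_um / px - 0.5 - ix[j])^2 +
               (tru$y_um / px - 0.5 - iy[j])^2))
    }, numeric(1))
    expect_true(all(dmin <= 3), label = sprintf("section %d puncta localized", k))
  }
  # and near-misses carry no punctum: marker is at background near them
  nm <- syn[!syn$is_true_synapse, ]
  for (i in seq_len(nrow(nm))) {
    k <- nm$section[i]
    m <- ph$stack$sections[[k]]$marker
    cx <- round(nm$x_um[i] / px + 0.5); cy <- round(nm$y_um[i] / px + 0.5)
    win <- m[max(1, cy - 1):min(nrow(m), cy + 1),
             max(1, cx - 1):min(ncol(m), cx + 1)]
    expect_lt(max(win), lim)
  }
})

test_that("a tube appears in exactly the sections its geometry crosses", {
  # hand-built horizontal tube at a known depth
  th <- 0.09; r <- 0.3; zc <- 0.5
  truth <- list(neurites = data.frame(
    id = 1L, channel = "dendrite",
    x0 = 1, y0 = 5, z0 = zc, x1 = 9, y1 = 5, z1 = zc, radius_um = r))
  stack <- structure(list(dim = c(ny = 33L, nx = 33L), pixel_size_um = 0.31,
                          section_thickness_um = th, n_sections = 12L),
                     class = "section_stack")
  present <- vapply(1:12, function(k)
    sum(truth_tube_mask(truth, stack, k, "dendrite")) > 0, logical(1))
  # slab k = [(k-1) th, k th] intersects [zc - r, zc + r]
  expected <- vapply(1:12, function(k)
    (k - 1) * th < zc + r && k * th > zc - r, logical(1))
  expect_identical(present, expected)
})

test_that("true synapses touch both tube surfaces; near-misses keep a gap", {
  ph <- small_phantom()
  syn <- ph$truth$synapses
  nr <- ph$truth$neurites
  for (i in seq_len(nrow(syn))) {
    s <- syn[i, ]
    a <- nr[nr$id == s$axon_id, ]
    d <- nr[nr$id == s$dendrite_id, ]
    dist_line <- function(t, p) {
      # distance from point p to segment of neurite row t
      p0 <- c(t$x0, t$y0, t$z0); p1 <- c(t$x1, t$y1, t$z1)
      dd <- p1 - p0
      tt <- max(0, min(1, sum((p - p0) * dd) / sum(dd^2)))
      sqrt(sum((p - p0 - tt * dd)^2))
    }
    p <- c(s$x_um, s$y_um, s$z_um)
    if (s$is_true_synapse) {
      expect_equal(dist_line(a, p), a$radius_um, tolerance = 1e-6)
      expect_equal(dist_line(d, p), d$radius_um, tolerance = 1e-6)
    } else {
      gap <- dist_line(a, p) - a$radius_um + dist_line(d, p) - d$radius_um
      expect_gt(gap, 0)
      expect_equal(gap, s$gap_um, tolerance = 1e-6)
    }
  }
})
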