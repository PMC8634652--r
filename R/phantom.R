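#' Configuration for a synthetic serial-section phantom
#'
#' Describes a fluorescently labeled tissue block cut into ultrathin serial
#' sections and surveyed at low magnification. Dendrites and axons are capsule
#' tubes with Gaussian cross-sectional intensity; true synapses are rendered
#' as axon-dendrite surface contacts (gap 0) carrying a sub-diffraction
#' synaptic-marker punctum, while near-misses are bypassing tube pairs with a
#' small gap and no punctum. Per-tile multiplicative brightness variation, a
#' planar background gradient, Poisson shot noise, and Gaussian read noise
#' emulate the artifacts the preprocessing stage must cancel.
#'
#' @param volume_size_um Numeric length-3, (x, y, z) extents in micrometres.
#' @param section_thickness_um Section thickness in micrometres (90 nm
#'   default, the axial resolution of the method).
#' @param pixel_size_um Lateral pixel size of the survey magnification in
#'   micrometres per pixel.
#' @param n_dendrites,n_axons Counts of unpaired distractor neurites, in
#'   addition to the tubes created for synapse/near-miss pairs.
#' @param neurite_radius_um Length-2 range of tube radii in micrometres.
#' @param n_synapses Number of true axon-dendrite contacts with puncta.
#' @param n_near_misses Number of bypassing pairs (no punctum).
#' @param near_miss_gap_um Length-2 range of inter-tube surface gaps for
#'   near-misses, micrometres.
#' @param tile_grid Integer length-2, (rows, cols) of the survey tile grid.
#' @param tile_brightness_cv Coefficient of variation of the per-tile
#'   multiplicative brightness factor; must lie in [0, 1).
#' @param background_gradient_amplitude Peak-to-trough amplitude of the
#'   planar background gradient, intensity units.
#' @param background_level Mean background intensity.
#' @param neurite_amplitude Peak tube intensity above background.
#' @param punctum_amplitude Peak punctum intensity above background.
#' @param punctum_fwhm_um Full width at half maximum of the rendered punctum.
#' @param noise_read_sd Gaussian read-noise standard deviation.
#' @param noise_poisson_gain Photons per intensity unit for shot noise
#'   (larger = less relative noise); 0 disables Poisson noise.
#' @param seed Integer seed; identical seed and config give byte-identical
#'   output.
#' @return An object of class \code{phantom_config}.
#' @export
phantom_config <- function(volume_size_um = c(57.66, 57.66, 3.15),
                           section_thickness_um = 0.09,
                           pixel_size_um = 0.31,
                           n_dendrites = 10,
                           n_axons = 10,
                           neurite_radius_um = c(0.25, 0.45),
                           n_synapses = 25,
                           n_near_misses = 25,
                           near_miss_gap_um = c(0.1, 0.3),
                           tile_grid = c(3L, 3L),
                           tile_brightness_cv = 0.1,
                           background_gradient_amplitude = 20,
                           background_level = 100,
                           neurite_amplitude = 600,
                           punctum_amplitude = 900,
                           punctum_fwhm_um = 0.3,
                           noise_read_sd = 4,
                           noise_poisson_gain = 1,
                           seed = 1L) {
  if (length(volume_size_um) != 3L || any(!is.finite(volume_size_um)) ||
      any(volume_size_um <= 0))
    stop("degenerate volume: all extents must be > 0", call. = FALSE)
  stopifnot_scalar_num(section_thickness_um, "section_thickness_um", TRUE)
  stopifnot_scalar_num(pixel_size_um, "pixel_size_um", TRUE)
  counts <- c(n_dendrites, n_axons, n_synapses, n_near_misses)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (tile_brightness_cv < 0 || tile_brightness_cv >= 1)
    stop("tile_brightness_cv must lie in [0, 1)", call. = FALSE)
  if (length(neurite_radius_um) == 1L)
    neurite_radius_um <- rep(neurite_radius_um, 2L)
  structure(list(
    volume_size_um = as.numeric(volume_size_um),
    section_thickness_um = section_thickness_um,
    pixel_size_um = pixel_size_um,
    n_dendrites = as.integer(n_dendrites),
    n_axons = as.integer(n_axons),
    neurite_radius_um = as.numeric(neurite_radius_um),
    n_synapses = as.integer(n_synapses),
    n_near_misses = as.integer(n_near_misses),
    near_miss_gap_um = as.numeric(near_miss_gap_um),
    tile_grid = as.integer(tile_grid),
    tile_brightness_cv = tile_brightness_cv,
    background_gradient_amplitude = background_gradient_amplitude,
    background_level = background_level,
    neurite_amplitude = neurite_amplitude,
    punctum_amplitude = punctum_amplitude,
    punctum_fwhm_um = punctum_fwhm_um,
    noise_read_sd = noise_read_sd,
    noise_poisson_gain = noise_poisson_gain,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  n_sec <- ceiling_safe(x$volume_size_um[3] / x$section_thickness_um)
  cat(sprintf(
    "phantom_config: %.1f x %.1f x %.2f um, %d sections @ %d nm, %.2f um/px\n",
    x$volume_size_um[1], x$volume_size_um[2], x$volume_size_um[3],
    n_sec, round(x$section_thickness_um * 1000), x$pixel_size_um))
  cat(sprintf("  %d synapses, %d near-misses, %d+%d distractor neurites, seed %d\n",
              x$n_synapses, x$n_near_misses, x$n_dendrites, x$n_axons, x$seed))
  invisible(x)
}

# random unit direction with bounded z component, so tubes run mostly
# in-plane and persist across sections (axons/dendrites traverse the block)
rand_direction <- function(max_dz = 0.25) {
  th <- stats::runif(1, 0, 2 * pi)
  dz <- stats::runif(1, -max_dz, max_dz)
  v <- c(cos(th), sin(th), dz)
  v / sqrt(sum(v^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# squared distance from points (n x 3) to segment [p0, p1]
dist2_to_segment <- function(pts, p0, p1) {
  d <- p1 - p0
  L2 <- sum(d^2)
  rel <- sweep(pts, 2L, p0)
  tt <- if (L2 > 0) pmin(1, pmax(0, as.vector(rel %*% d) / L2)) else 0
  dx <- rel[, 1] - tt * d[1]
  dy <- rel[, 2] - tt * d[2]
  dz <- rel[, 3] - tt * d[3]
  dx * dx + dy * dy + dz * dz
}

make_neurite_row <- function(id, channel, p0, p1, radius) {
  data.frame(id = id, channel = channel,
             x0 = p0[1], y0 = p0[2], z0 = p0[3],
             x1 = p1[1], y1 = p1[2], z1 = p1[3],
             radius_um = radius)
}

#' Generate a synthetic serial-section stack with ground truth
#'
#' Renders the phantom described by `config` into an ordered stack of
#' sections, each with three channel planes (dendrite, axon, synaptic
#' marker), and returns the ground-truth tables needed to score every
#' downstream stage.
#'
#' @param config A [phantom_config()].
#' @return A list with elements `stack` (class `section_stack`: `sections`
#'   is a list of per-section channel matrices, plus pixel/section metadata)
#'   and `truth` (class `phantom_truth`: `synapses` and `neurites` tables).
#' @examples
#' ph <- generate_phantom(phantom_config(
#'   volume_size_um = c(15, 15, 0.45), n_synapses = 2, n_near_misses = 1,
#'   n_dendrites = 1, n_axons = 1, seed = 7))
#' ph$truth$synapses
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, generate_phantom_impl(config))
}

generate_phantom_impl <- function(cfg) {
  px <- cfg$pixel_size_um
  nx <- max(1L, as.integer(round(cfg$volume_size_um[1] / px)))
  ny <- max(1L, as.integer(round(cfg$volume_size_um[2] / px)))
  n_sec <- ceiling_safe(cfg$volume_size_um[3] / cfg$section_thickness_um)
  z_ext <- cfg$volume_size_um[3]

  neurites <- list()
  syn_rows <- list()
  nid <- 0L
  margin_xy <- min(3, cfg$volume_size_um[1] / 4)
  zpad <- min(0.25, z_ext / 4)

  n_pairs <- cfg$n_synapses + cfg$n_near_misses
  for (i in seq_len(n_pairs)) {
    is_true <- i <= cfg$n_synapses
    gap <- if (is_true) 0 else
      stats::runif(1, cfg$near_miss_gap_um[1], cfg$near_miss_gap_um[2])
    p <- c(stats::runif(1, margin_xy, cfg$volume_size_um[1] - margin_xy),
           stats::runif(1, margin_xy, cfg$volume_size_um[2] - margin_xy),
           stats::runif(1, zpad, z_ext - zpad))
    r_d <- stats::runif(1, cfg$neurite_radius_um[1], cfg$neurite_radius_um[2])
    r_a <- stats::runif(1, cfg$neurite_radius_um[1], cfg$neurite_radius_um[2])
    if (is_true) {
      # crossing contact: the separation of two crossing, mostly in-plane
      # tubes lies along their common normal (mostly axial)
      repeat {
        d1 <- rand_direction()
        d2 <- rand_direction()
        u <- cross3(d1, d2)
        nu <- sqrt(sum(u^2))
        if (nu > 0.3) { u <- u / nu; break }  # reject near-parallel pairs
      }
    } else {
      # bypass: tubes running in parallel with a small lateral gap -- the
      # geometry the survey magnification cannot resolve (an axial gap is
      # already resolved by the 90 nm sectioning itself)
      d1 <- rand_direction()
      d2 <- if (stats::runif(1) < 0.5) d1 else -d1
      h <- c(-d1[2], d1[1], 0)
      h <- h / sqrt(sum(h^2))
      zax <- cross3(d1, h)
      zax <- zax / sqrt(sum(zax^2))
      phi <- stats::runif(1, -pi / 4, pi / 4)
      u <- cos(phi) * h + sin(phi) * zax
    }
    c_d <- p - u * (r_d + gap / 2)
    c_a <- p + u * (r_a + gap / 2)
    L <- stats::runif(2, 8, 14)
    nid <- nid + 1L; dend_id <- nid
    neurites[[nid]] <- make_neurite_row(nid, "dendrite",
                                        c_d - d1 * L[1] / 2, c_d + d1 * L[1] / 2, r_d)
    nid <- nid + 1L; axon_id <- nid
    neurites[[nid]] <- make_neurite_row(nid, "axon",
                                        c_a - d2 * L[2] / 2, c_a + d2 * L[2] / 2, r_a)
    syn_rows[[i]] <- data.frame(
      id = i, x_um = p[1], y_um = p[2], z_um = p[3],
      section = min(n_sec, as.integer(floor(p[3] / cfg$section_thickness_um)) + 1L),
      axon_id = axon_id, dendrite_id = dend_id,
      gap_um = gap, is_true_synapse = is_true)
  }
  for (ch in c("dendrite", "axon")) {
    n_extra <- if (ch == "dendrite") cfg$n_dendrites else cfg$n_axons
    for (i in seq_len(n_extra)) {
      p <- c(stats::runif(1, 0, cfg$volume_size_um[1]),
             stats::runif(1, 0, cfg$volume_size_um[2]),
             stats::runif(1, 0, z_ext))
      d <- rand_direction()
      L <- stats::runif(1, 8, 14)
      r <- stats::runif(1, cfg$neurite_radius_um[1], cfg$neurite_radius_um[2])
      nid <- nid + 1L
      neurites[[nid]] <- make_neurite_row(nid, ch, p - d * L / 2, p + d * L / 2, r)
    }
  }
  neurites <- if (length(neurites)) do.call(rbind, neurites) else
    data.frame(id = integer(0), channel = character(0),
               x0 = numeric(0), y0 = numeric(0), z0 = numeric(0),
               x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
               radius_um = numeric(0))
  synapses <- if (length(syn_rows)) do.call(rbind, syn_rows) else
    data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
               z_um = numeric(0), section = integer(0), axon_id = integer(0),
               dendrite_id = integer(0), gap_um = numeric(0),
               is_true_synapse = logical(0))

  # per-(section, tile) brightness factors and the fixed gradient direction
  tg <- cfg$tile_grid
  tile_factors <- array(1, dim = c(n_sec, tg[1], tg[2]))
  if (cfg$tile_brightness_cv > 0)
    tile_factors[] <- pmax(0.2, stats::rnorm(length(tile_factors), 1,
                                             cfg$tile_brightness_cv))
  grad_dir <- rand_direction(0)[1:2]

  xs <- (seq_len(nx) - 0.5) * px
  ys <- (seq_len(ny) - 0.5) * px
  grad <- cfg$background_gradient_amplitude *
    (outer(ys, xs, function(y, x)
      (grad_dir[1] * x / cfg$volume_size_um[1] +
       grad_dir[2] * y / cfg$volume_size_um[2])))

  tile_row <- pmin(tg[1], 1L + (seq_len(ny) - 1L) %/% ceiling(ny / tg[1]))
  tile_col <- pmin(tg[2], 1L + (seq_len(nx) - 1L) %/% ceiling(nx / tg[2]))

  sections <- vector("list", n_sec)
  punct_sd <- cfg$punctum_fwhm_um / (2 * sqrt(2 * log(2)))
  truth_syn <- synapses[synapses$is_true_synapse, , drop = FALSE]

  for (k in seq_len(n_sec)) {
    z_lo <- (k - 1) * cfg$section_thickness_um
    z_hi <- k * cfg$section_thickness_um
    z_c <- (z_lo + z_hi) / 2
    base <- cfg$background_level + grad
    planes <- list(dendrite = base, axon = base, marker = base)
    for (j in seq_len(nrow(neurites))) {
      nr <- neurites[j, ]
      add <- render_tube_section(nr, z_lo, z_hi, nx, ny, px,
                                 cfg$neurite_amplitude)
      if (is.null(add)) next
      ch <- nr$channel
      planes[[ch]][add$idx] <- planes[[ch]][add$idx] + add$val
    }
    if (nrow(truth_syn) > 0) {
      for (j in seq_len(nrow(truth_syn))) {
        s <- truth_syn[j, ]
        zq <- z_lo + (seq_len(5L) - 0.5) / 5 * (z_hi - z_lo)
        zfac <- mean(exp(-(zq - s$z_um)^2 / (2 * punct_sd^2)))
        if (zfac < 1e-3) next
        add <- render_punctum(s$x_um, s$y_um, nx, ny, px, punct_sd,
                              cfg$punctum_amplitude * zfac)
        if (!is.null(add))
          planes$marker[add$idx] <- planes$marker[add$idx] + add$val
      }
    }
    tfm <- matrix(tile_factors[k, , ], tg[1], tg[2])
    tf_img <- matrix(tfm[cbind(rep(tile_row, times = nx),
                               rep(tile_col, each = ny))],
                     ny, nx)
    for (ch in names(planes)) {
      img <- planes[[ch]] * tf_img
      if (cfg$noise_poisson_gain > 0) {
        lam <- pmax(img * cfg$noise_poisson_gain, 0)
        img <- stats::rpois(length(lam), lam) / cfg$noise_poisson_gain
        img <- matrix(img, ny, nx)
      }
      if (cfg$noise_read_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, cfg$noise_read_sd),
                            ny, nx)
      planes[[ch]] <- matrix(pmin(65535, pmax(0, round(img))), ny, nx)
    }
    sections[[k]] <- planes
  }

  stack <- structure(list(
    sections = sections,
    n_sections = n_sec,
    dim = c(ny = ny, nx = nx),
    channels = c("dendrite", "axon", "marker"),
    pixel_size_um = px,
    section_thickness_um = cfg$section_thickness_um
  ), class = "section_stack")
  truth <- structure(list(synapses = synapses, neurites = neurites,
                          config = cfg), class = "phantom_truth")
  list(stack = stack, truth = truth)
}

# Additive tube intensity for one section slab [z_lo, z_hi]. The label is
# cytosolic, so the cross-section profile is flat inside the tube with a
# Gaussian shoulder (edge softness ~ lateral PSF) outside; the imaged
# intensity is the fluorophore content of the physical slab, so the profile
# is averaged over `nz` z-samples through the slab (a contact slab genuinely
# contains both apposed structures). Returns NULL when the tube does not
# approach the slab, else list(idx, val).
render_tube_section <- function(nr, z_lo, z_hi, nx, ny, px, amplitude,
                                nz = 5L, edge_um = 0.08) {
  w <- nr$radius_um + 3 * edge_um
  p0 <- c(nr$x0, nr$y0, nr$z0); p1 <- c(nr$x1, nr$y1, nr$z1)
  dz <- p1[3] - p0[3]
  if (abs(dz) < 1e-12) {
    if (p0[3] < z_lo - w || p0[3] > z_hi + w) return(NULL)
    t0 <- 0; t1 <- 1
  } else {
    ta <- (z_lo - w - p0[3]) / dz
    tb <- (z_hi + w - p0[3]) / dz
    t0 <- max(0, min(ta, tb)); t1 <- min(1, max(ta, tb))
    if (t0 > t1) return(NULL)
  }
  a <- p0 + t0 * (p1 - p0)
  b <- p0 + t1 * (p1 - p0)
  mpx <- ceiling(w / px) + 1L
  ix0 <- max(1L, as.integer(floor(min(a[1], b[1]) / px + 0.5)) - mpx)
  ix1 <- min(nx, as.integer(ceiling(max(a[1], b[1]) / px + 0.5)) + mpx)
  iy0 <- max(1L, as.integer(floor(min(a[2], b[2]) / px + 0.5)) - mpx)
  iy1 <- min(ny, as.integer(ceiling(max(a[2], b[2]) / px + 0.5)) + mpx)
  if (ix0 > ix1 || iy0 > iy1) return(NULL)
  ixs <- ix0:ix1; iys <- iy0:iy1
  xy <- cbind(rep((ixs - 0.5) * px, each = length(iys)),
              rep((iys - 0.5) * px, times = length(ixs)))
  zs <- z_lo + (seq_len(nz) - 0.5) / nz * (z_hi - z_lo)
  val <- 0
  r <- nr$radius_um
  for (z_s in zs) {
    d <- sqrt(dist2_to_segment(cbind(xy, z_s), p0, p1))
    excess <- pmax(0, d - r)
    val <- val + exp(-excess^2 / (2 * edge_um^2))
  }
  val <- amplitude * val / nz
  keep <- val > 1e-3
  if (!any(keep)) return(NULL)
  idx <- as.vector(outer(iys, (ixs - 1L) * ny, `+`))
  list(idx = idx[keep], val = val[keep])
}

render_punctum <- function(x_um, y_um, nx, ny, px, sd_um, amplitude) {
  r <- 3 * sd_um
  ix0 <- max(1L, as.integer(floor((x_um - r) / px + 0.5)))
  ix1 <- min(nx, as.integer(ceiling((x_um + r) / px + 0.5)))
  iy0 <- max(1L, as.integer(floor((y_um - r) / px + 0.5)))
  iy1 <- min(ny, as.integer(ceiling((y_um + r) / px + 0.5)))
  if (ix0 > ix1 || iy0 > iy1) return(NULL)
  ixs <- ix0:ix1; iys <- iy0:iy1
  dx <- (rep(ixs, each = length(iys)) - 0.5) * px - x_um
  dy <- (rep(iys, times = length(ixs)) - 0.5) * px - y_um
  val <- amplitude * exp(-(dx^2 + dy^2) / (2 * sd_um^2))
  idx <- as.vector(outer(iys, (ixs - 1L) * ny, `+`))
  keep <- val > 1e-3
  if (!any(keep)) return(NULL)
  list(idx = idx[keep], val = val[keep])
}

#' @export
print.section_stack <- function(x, ...) {
  cat(sprintf("section_stack: %d sections of %d x %d px, channels %s\n",
              x$n_sections, x$dim[["ny"]], x$dim[["nx"]],
              paste(x$channels, collapse = "/")))
  cat(sprintf("  %.2f um/px lateral, %d nm sections\n",
              x$pixel_size_um, round(x$section_thickness_um * 1000)))
  invisible(x)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %d synapse rows (%d true), %d neurites\n",
              nrow(x$synapses), sum(x$synapses$is_true_synapse),
              nrow(x$neurites)))
  invisible(x)
}

#' Rasterize the ground-truth tube footprint of one channel on one section
#'
#' A pixel is foreground when its 3-D distance to any centerline of the
#' channel is at most that tube's radius, evaluated at the section mid-plane.
#' Used to score segmentation recall against known geometry.
#'
#' @param truth A `phantom_truth`.
#' @param stack The matching `section_stack`.
#' @param section Section index (1-based).
#' @param channel `"dendrite"` or `"axon"`.
#' @return Logical matrix of the section's dimensions.
#' @export
truth_tube_mask <- function(truth, stack, section, channel) {
  ny <- stack$dim[["ny"]]; nx <- stack$dim[["nx"]]
  px <- stack$pixel_size_um
  th <- stack$section_thickness_um
  z_lo <- (section - 1) * th; z_hi <- section * th
  mask <- matrix(FALSE, ny, nx)
  nr_all <- truth$neurites[truth$neurites$channel == channel, , drop = FALSE]
  if (nrow(nr_all) == 0) return(mask)
  xs <- (seq_len(nx) - 0.5) * px
  ys <- (seq_len(ny) - 0.5) * px
  zq <- z_lo + (seq_len(9L) - 0.5) / 9 * th
  for (j in seq_len(nrow(nr_all))) {
    nr <- nr_all[j, ]
    add <- render_tube_section(nr, z_lo, z_hi, nx, ny, px, 1)
    if (is.null(add)) next
    # foreground iff the pixel's z-column through the slab meets the tube
    iy <- ((add$idx - 1L) %% ny) + 1L
    ix <- ((add$idx - 1L) %/% ny) + 1L
    d2min <- rep(Inf, length(add$idx))
    for (z_s in zq) {
      d2 <- dist2_to_segment(cbind(xs[ix], ys[iy], z_s),
                             c(nr$x0, nr$y0, nr$z0), c(nr$x1, nr$y1, nr$z1))
      d2min <- pmin(d2min, d2)
    }
    mask[add$idx[d2min <= nr$radius_um^2]] <- TRUE
  }
  mask
}
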