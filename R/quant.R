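#' Measure per-area structure areas across sections
#'
#' For each target area, sums foreground pixel counts of the *undilated*
#' dendrite and axon masks over all sections inside the area (dilation
#' exists only to protect detection recall, so areas are measured on the
#' raw binarization), converts to square micrometres with the pixel size,
#' and measures the per-section axon-and-dendrite intersection the same
#' way. A z-projected variant (pixels counted once if foreground on any
#' section) is available via `projected = TRUE`.
#'
#' @param masks_by_section List (one per section) of lists with logical
#'   (or `binary_mask`) entries `axon` and `dendrite` (undilated).
#' @param areas List of [target_area()] objects.
#' @param transforms Per-section [affine2d()] transforms.
#' @param pixel_size_um Lateral pixel size, micrometres per pixel (> 0).
#' @param projected If TRUE, count each pixel once across sections.
#' @return data.frame, one row per area: `area` (name), `dendrite_area_um2`,
#'   `axon_area_um2`, `intersection_area_um2`.
#' @export
measure_areas <- function(masks_by_section, areas, transforms, pixel_size_um,
                          projected = FALSE) {
  stopifnot_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (length(areas) == 0L) stop("empty target area list", call. = FALSE)
  n_sec <- length(masks_by_section)
  px2 <- pixel_size_um^2
  rows <- lapply(areas, function(ar) {
    stopifnot(inherits(ar, "target_area"))
    dend <- 0; axon <- 0; inter <- 0
    proj <- NULL
    for (k in seq_len(n_sec)) {
      a <- mask_matrix(masks_by_section[[k]]$axon)
      d <- mask_matrix(masks_by_section[[k]]$dendrite)
      am <- area_mask(ar, c(ny = nrow(a), nx = ncol(a)), transforms[[k]])
      if (!any(am)) next
      if (projected) {
        if (is.null(proj))
          proj <- list(a = a & am, d = d & am, i = a & d & am)
        else {
          proj$a <- proj$a | (a & am)
          proj$d <- proj$d | (d & am)
          proj$i <- proj$i | (a & d & am)
        }
      } else {
        axon <- axon + sum(a & am)
        dend <- dend + sum(d & am)
        inter <- inter + sum(a & d & am)
      }
    }
    if (projected && !is.null(proj)) {
      axon <- sum(proj$a); dend <- sum(proj$d); inter <- sum(proj$i)
    }
    data.frame(area = ar$name,
               dendrite_area_um2 = dend * px2,
               axon_area_um2 = axon * px2,
               intersection_area_um2 = inter * px2)
  })
  do.call(rbind, rows)
}

#' Complete a quantification report with densities and fold ratios
#'
#' Adds confirmed synapse counts, per-structure densities (synapses per 100
#' square micrometres of dendrite, axon, and intersection area), and fold
#' ratios of every area against a reference area (e.g. L5 relative to L4).
#' Zero-area denominators yield `NA` densities (undefined, not infinite).
#' Values are kept at full precision; rounding happens only in
#' [format_quant_report()].
#'
#' @param areas_df Output of [measure_areas()].
#' @param counts Named integer vector of confirmed synapse counts, names
#'   matching `areas_df$area`.
#' @param reference Name of the denominator area for fold ratios (default:
#'   the first area).
#' @return A `quant_report`: the input data.frame with columns
#'   `synapse_count`, `density_per_100um2_dendrite` (headline), `_axon`,
#'   `_intersection`, and `fold_count`, `fold_dendrite`, `fold_axon`,
#'   `fold_intersection` relative to the reference area.
#' @export
density_and_folds <- function(areas_df, counts, reference = NULL) {
  if (nrow(areas_df) < 2L)
    stop("two or more target areas are required for fold ratios",
         call. = FALSE)
  if (is.null(names(counts)) || !all(areas_df$area %in% names(counts)))
    stop("'counts' must be named by target area", call. = FALSE)
  reference <- reference %||% areas_df$area[1]
  if (!reference %in% areas_df$area)
    stop("unknown reference area: ", reference, call. = FALSE)
  df <- areas_df
  df$synapse_count <- as.numeric(counts[df$area])
  dens <- function(cnt, a) ifelse(a > 0, 100 * cnt / a, NA_real_)
  df$density_per_100um2_dendrite <- dens(df$synapse_count, df$dendrite_area_um2)
  df$density_per_100um2_axon <- dens(df$synapse_count, df$axon_area_um2)
  df$density_per_100um2_intersection <-
    dens(df$synapse_count, df$intersection_area_um2)
  ref <- df[df$area == reference, ]
  fold <- function(num, den) {
    if (length(den) == 1L && is.finite(den) && den > 0) num / den
    else rep(NA_real_, length(num))
  }
  df$fold_count <- fold(df$synapse_count, ref$synapse_count)
  df$fold_dendrite <- fold(df$dendrite_area_um2, ref$dendrite_area_um2)
  df$fold_axon <- fold(df$axon_area_um2, ref$axon_area_um2)
  df$fold_intersection <- fold(df$intersection_area_um2,
                               ref$intersection_area_um2)
  attr(df, "reference") <- reference
  class(df) <- c("quant_report", class(df))
  df
}

#' Presentation rounding for a quantification report
#'
#' Count folds are truncated to integers and area folds rounded to one
#' decimal, matching the precision these ratios are conventionally printed
#' at; raw values remain in the report.
#'
#' @param report A `quant_report`.
#' @return data.frame of formatted character columns.
#' @export
format_quant_report <- function(report) {
  data.frame(
    area = report$area,
    dendrite_um2 = sprintf("%.1f", report$dendrite_area_um2),
    axon_um2 = sprintf("%.1f", report$axon_area_um2),
    intersection_um2 = sprintf("%.1f", report$intersection_area_um2),
    count = sprintf("%d", as.integer(report$synapse_count)),
    density_dendrite = sprintf("%.3f", report$density_per_100um2_dendrite),
    fold_count = sprintf("%d", trunc(report$fold_count)),
    fold_dendrite = sprintf("%.1f", report$fold_dendrite),
    fold_axon = sprintf("%.1f", report$fold_axon),
    fold_intersection = sprintf("%.1f", report$fold_intersection))
}

#' @export
print.quant_report <- function(x, ...) {
  cat("quant_report (reference area:", attr(x, "reference"), ")\n")
  print(format_quant_report(x), row.names = FALSE)
  invisible(x)
}

#' Imaging-time arithmetic for full-grid versus targeted acquisition
#'
#' Full-grid mode tiles the whole target area on every section:
#' `ceil(width/fov) * ceil(height/fov)` tiles per section times
#' `n_sections`. Targeted mode images only the scheduled ROI-series tiles.
#' Hours are `tiles * minutes_per_tile / 60` exactly; the percentage saved
#' is rounded to the nearest integer.
#'
#' @param width_um,height_um Target-area extents, micrometres.
#' @param fov_um Field-of-view side, micrometres (> 0).
#' @param n_sections Number of serial sections.
#' @param minutes_per_tile Acquisition minutes per tile (default 3).
#' @param targeted_tiles Number of tiles in the targeted plan (ROI series
#'   entries), or NULL for a full-grid-only plan.
#' @return An `imaging_plan`: list with `full` and (optionally) `targeted`
#'   tile counts and hours, and `percent_saved`.
#' @examples
#' imaging_plan(1300, 1450, fov_um = 33, n_sections = 35,
#'              targeted_tiles = 3268)
#' @export
imaging_plan <- function(width_um, height_um, fov_um, n_sections,
                         minutes_per_tile = 3, targeted_tiles = NULL) {
  stopifnot_scalar_num(fov_um, "fov_um", positive = TRUE)
  stopifnot_scalar_num(width_um, "width_um", positive = TRUE)
  stopifnot_scalar_num(height_um, "height_um", positive = TRUE)
  stopifnot_scalar_num(n_sections, "n_sections", positive = TRUE)
  stopifnot_scalar_num(minutes_per_tile, "minutes_per_tile", positive = TRUE)
  tiles_per_section <- ceiling_safe(width_um / fov_um) *
    ceiling_safe(height_um / fov_um)
  full_tiles <- as.integer(round(tiles_per_section * n_sections))
  out <- list(
    fov_um = fov_um, minutes_per_tile = minutes_per_tile,
    n_sections = n_sections,
    grid = c(ceiling_safe(width_um / fov_um), ceiling_safe(height_um / fov_um)),
    full = list(n_tiles = full_tiles,
                total_hours = full_tiles * minutes_per_tile / 60))
  if (!is.null(targeted_tiles)) {
    stopifnot_scalar_num(targeted_tiles, "targeted_tiles")
    out$targeted <- list(
      n_tiles = targeted_tiles,
      total_hours = targeted_tiles * minutes_per_tile / 60)
    out$percent_saved <- round((1 - targeted_tiles / full_tiles) * 100)
  }
  class(out) <- "imaging_plan"
  out
}

#' @export
print.imaging_plan <- function(x, ...) {
  cat(sprintf("imaging_plan: %d x %d tiles/section x %d sections @ %g min\n",
              x$grid[1], x$grid[2], x$n_sections, x$minutes_per_tile))
  cat(sprintf("  full grid: %d tiles, %.1f h\n",
              x$full$n_tiles, x$full$total_hours))
  if (!is.null(x$targeted))
    cat(sprintf("  targeted : %d tiles, %.1f h (%d%% saved)\n",
                x$targeted$n_tiles, x$targeted$total_hours, x$percent_saved))
  invisible(x)
}

#' Full width at half maximum of a 1-D intensity profile
#'
#' The resolution metric for bead point-spread-function profiles: the
#' profile's half-height is `baseline + (max - baseline) / 2` with the
#' baseline at the profile minimum; crossings on each side of the peak are
#' located by linear interpolation. Scaling the profile leaves the width
#' unchanged.
#'
#' @param profile Numeric vector, unimodal with a defined maximum.
#' @param sample_spacing Distance between samples (e.g. nm); the width is
#'   returned in the same unit.
#' @return Width at half maximum.
#' @examples
#' x <- seq(-300, 300, by = 5)
#' fwhm(exp(-x^2 / (2 * 52.2^2)), sample_spacing = 5)  # ~123 nm
#' @export
fwhm <- function(profile, sample_spacing = 1) {
  stopifnot_scalar_num(sample_spacing, "sample_spacing", positive = TRUE)
  if (length(profile) < 3L || any(!is.finite(profile)))
    stop("profile must be a finite vector of length >= 3", call. = FALSE)
  lo <- min(profile); hi <- max(profile)
  if (hi == lo) stop("flat profile: FWHM undefined", call. = FALSE)
  half <- lo + (hi - lo) / 2
  pk <- which.max(profile)
  if (pk == 1L || pk == length(profile))
    stop("peak at profile edge: FWHM undefined", call. = FALSE)
  cross <- function(i0, i1) {
    # linear interpolation of the half-height crossing between samples
    i0 + (half - profile[i0]) / (profile[i1] - profile[i0]) * (i1 - i0)
  }
  i <- pk
  while (i > 1L && profile[i - 1L] >= half) i <- i - 1L
  if (i == 1L) stop("no left half-height crossing", call. = FALSE)
  left <- cross(i - 1L, i)
  j <- pk
  while (j < length(profile) && profile[j + 1L] >= half) j <- j + 1L
  if (j == length(profile)) stop("no right half-height crossing", call. = FALSE)
  right <- cross(j + 1L, j)
  (right - left) * sample_spacing
}

bilinear_sample <- function(plane, x, y) {
  # x, y: 0-based continuous pixel-center coordinates
  nx <- ncol(plane); ny <- nrow(plane)
  x <- clamp(x, 0, nx - 1); y <- clamp(y, 0, ny - 1)
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  fx <- x - x0; fy <- y - y0
  i <- cbind(y0 + 1, x0 + 1)
  v00 <- plane[i]
  v10 <- plane[cbind(y0 + 1, x0 + 2)]
  v01 <- plane[cbind(y0 + 2, x0 + 1)]
  v11 <- plane[cbind(y0 + 2, x0 + 2)]
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}

#' Per-channel intensity profile along a line segment
#'
#' Bilinearly samples every channel of one section at unit-pixel spacing
#' along the segment from `p0` to `p1` (0-based pixel coordinates);
#' `ceil(length) + 1` samples are taken.
#'
#' @param stack A `section_stack` (or a named list of channel matrices).
#' @param section Section index (ignored when `stack` is a plain list).
#' @param p0,p1 Numeric length-2 endpoints (x, y), inside the image.
#' @return data.frame with `distance_px` and one column per channel.
#' @export
line_profile <- function(stack, section, p0, p1) {
  planes <- if (inherits(stack, "section_stack"))
    stack$sections[[section]] else stack
  dims <- dim(planes[[1]])
  L <- sqrt(sum((p1 - p0)^2))
  if (L == 0) stop("zero-length line", call. = FALSE)
  if (any(c(p0, p1) < 0) || p0[1] > dims[2] - 1 || p1[1] > dims[2] - 1 ||
      p0[2] > dims[1] - 1 || p1[2] > dims[1] - 1)
    stop("line endpoints outside the image", call. = FALSE)
  n <- ceiling_safe(L) + 1L
  tt <- seq(0, 1, length.out = n)
  xs <- p0[1] + tt * (p1[1] - p0[1])
  ys <- p0[2] + tt * (p1[2] - p0[2])
  out <- data.frame(distance_px = tt * L)
  for (ch in names(planes))
    out[[ch]] <- bilinear_sample(planes[[ch]], xs, ys)
  out
}

#' Density extrapolation helper
#'
#' Converts a measured synapse density over the whole postsynaptic-neuron
#' area into an expected density after correcting for the areal fraction of
#' unmyelinated axons and dendrites, and expresses it as a percentage of a
#' reference total synapse density from stereological EM.
#'
#' @param density_per_100um2 Measured synapses per 10 x 10 um^2 of
#'   postsynaptic neuron area.
#' @param area_correction_factor Areal correction factor (default 1.6).
#' @param reference_density_per_100um2 Reference total density (default 50
#'   synapses per 10 x 10 um^2 of neuropil).
#' @return List with `corrected_density_per_100um2` and
#'   `percent_of_reference`.
#' @examples
#' synapse_share_estimate(0.5)  # 0.8 per 100 um^2, 1.6%
#' @export
synapse_share_estimate <- function(density_per_100um2,
                                   area_correction_factor = 1.6,
                                   reference_density_per_100um2 = 50) {
  corrected <- density_per_100um2 * area_correction_factor
  list(corrected_density_per_100um2 = corrected,
       percent_of_reference = 100 * corrected / reference_density_per_100um2)
}
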