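#' Named polygonal target area in global coordinates
#'
#' Detection and quantification are restricted to named target areas (for
#' example cortical layers L4 and L5) drawn as simple polygons in global
#' slide coordinates (micrometres).
#'
#' @param name Area name, e.g. `"L4"`.
#' @param polygon n x 2 matrix of (x, y) vertices in global micrometres;
#'   must be simple (non-self-intersecting) with nonzero area.
#' @param sections Optional integer range of sections the area applies to.
#' @return An object of class `target_area`.
#' @export
target_area <- function(name, polygon, sections = NULL) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("'polygon' must be an n x 2 matrix with n >= 3", call. = FALSE)
  if (!polygon_is_simple(polygon))
    stop("polygon is self-intersecting", call. = FALSE)
  if (abs(polygon_area(polygon)) < 1e-9)
    stop("polygon has zero area", call. = FALSE)
  structure(list(name = name, polygon = polygon, sections = sections),
            class = "target_area")
}

# shoelace signed area
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

segments_cross <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

polygon_is_simple <- function(p) {
  n <- nrow(p)
  for (i in seq_len(n)) {
    a1 <- p[i, ]; a2 <- p[i %% n + 1L, ]
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1L || abs(i - j) == n - 1L) next
      b1 <- p[j, ]; b2 <- p[j %% n + 1L, ]
      if (segments_cross(a1, a2, b1, b2)) return(FALSE)
    }
  }
  TRUE
}

#' Rasterize a target area onto a section's pixel grid
#'
#' Pixel centers are mapped through the section transform to global
#' coordinates and tested against the polygon.
#'
#' @param area A [target_area()].
#' @param dim Named integer vector `c(ny = , nx = )` of the section plane.
#' @param transform The section's [affine2d()] local-to-global transform.
#' @return Logical matrix, TRUE inside the area.
#' @export
area_mask <- function(area, dim, transform) {
  stopifnot(inherits(area, "target_area"))
  ny <- dim[["ny"]]; nx <- dim[["nx"]]
  # restrict the point-in-polygon test to the polygon's local bounding box
  corners_l <- to_local(area$polygon, transform)
  ix0 <- max(0L, floor(min(corners_l[, 1])))
  ix1 <- min(nx - 1L, ceiling(max(corners_l[, 1])))
  iy0 <- max(0L, floor(min(corners_l[, 2])))
  iy1 <- min(ny - 1L, ceiling(max(corners_l[, 2])))
  mask <- matrix(FALSE, ny, nx)
  if (ix0 > ix1 || iy0 > iy1) return(mask)
  ixs <- ix0:ix1; iys <- iy0:iy1
  loc <- cbind(rep(ixs, each = length(iys)), rep(iys, times = length(ixs)))
  glob <- to_global(loc, transform)
  inside <- pracma::inpolygon(glob[, 1], glob[, 2],
                              area$polygon[, 1], area$polygon[, 2],
                              boundary = TRUE)
  mask[cbind(loc[, 2] + 1L, loc[, 1] + 1L)] <- inside
  mask
}

#' Detect axon-dendrite overlap components on one section
#'
#' Putative synapse sites are connected components (8-connectivity) of the
#' conjunction of the dilated axon and dendrite masks, optionally restricted
#' to a rasterized target area. Components are returned in stable raster
#' order of their topmost-then-leftmost pixel.
#'
#' @param axon_mask,dendrite_mask `binary_mask` objects or logical matrices
#'   of equal dimensions (dilated).
#' @param target_mask Optional logical matrix restricting detection.
#' @param section Section index recorded on each component.
#' @param area_name Target-area name recorded on each component.
#' @return List of components; each has `section`, `area`, `pixels`
#'   (n x 2 matrix of 0-based (x, y)), and `centroid` (x, y).
#' @export
detect_overlaps <- function(axon_mask, dendrite_mask, target_mask = NULL,
                            section = NA_integer_, area_name = NA_character_) {
  a <- mask_matrix(axon_mask)
  d <- mask_matrix(dendrite_mask)
  if (!all(dim(a) == dim(d)))
    stop("mask shape mismatch", call. = FALSE)
  ov <- a & d
  if (!is.null(target_mask)) {
    if (!all(dim(target_mask) == dim(a)))
      stop("target mask shape mismatch", call. = FALSE)
    ov <- ov & target_mask
  }
  lab <- label_components8(ov)
  n <- max(lab)
  if (n == 0L) return(list())
  comps <- vector("list", n)
  idx <- which(lab > 0)
  iy <- ((idx - 1L) %% nrow(lab))        # 0-based y
  ix <- ((idx - 1L) %/% nrow(lab))       # 0-based x
  for (i in seq_len(n)) {
    sel <- lab[idx] == i
    px <- cbind(x = ix[sel], y = iy[sel])
    comps[[i]] <- list(section = section, area = area_name, pixels = px,
                       centroid = c(x = mean(px[, 1]), y = mean(px[, 2])))
  }
  # stable order by topmost, then leftmost pixel
  key <- t(vapply(comps, function(cc)
    c(min(cc$pixels[, 2]), min(cc$pixels[, 1])), numeric(2)))
  comps[order(key[, 1], key[, 2])]
}

clamp <- function(v, lo, hi) pmin(hi, pmax(lo, v))

#' Center a fixed-size field-of-view box on each overlap component
#'
#' One box per component, centered at the rounded component centroid with
#' the configured SIM field-of-view dimensions; boxes at the image border
#' are shifted inward (never shrunk). Boxes are half-open pixel intervals
#' `[x0, x1) x [y0, y1)`, 0-based.
#'
#' @param components List from [detect_overlaps()].
#' @param fov_size Box side in pixels (> 0).
#' @param dim Named `c(ny = , nx = )` plane dimensions.
#' @return data.frame with `x0, y0, x1, y1` (one row per component).
#' @export
make_fov_boxes <- function(components, fov_size, dim) {
  stopifnot_scalar_num(fov_size, "fov_size", positive = TRUE)
  ny <- dim[["ny"]]; nx <- dim[["nx"]]
  if (fov_size > nx || fov_size > ny)
    stop("fov_size exceeds image dimensions", call. = FALSE)
  if (length(components) == 0L)
    return(data.frame(x0 = integer(0), y0 = integer(0),
                      x1 = integer(0), y1 = integer(0)))
  ctr <- t(vapply(components, function(cc) round(cc$centroid), numeric(2)))
  x0 <- clamp(ctr[, 1] - fov_size %/% 2L, 0L, nx - fov_size)
  y0 <- clamp(ctr[, 2] - fov_size %/% 2L, 0L, ny - fov_size)
  data.frame(x0 = as.integer(x0), y0 = as.integer(y0),
             x1 = as.integer(x0 + fov_size), y1 = as.integer(y0 + fov_size))
}

#' Merge field-of-view boxes into a minimal-overlap cover
#'
#' Re-tiles the section with as few field-of-view boxes as practical.
#' Small instances (up to 12 overlap pixels) are solved to optimality by a
#' deterministic depth-limited search; larger instances use a greedy rule:
#' repeatedly place a box at the position covering the maximum number of
#' still-uncovered overlap pixels (ties broken topmost, then leftmost)
#' until every pixel is covered. In both regimes candidate positions are
#' anchored so a box edge touches an overlap pixel (sliding a box until its
#' left/top edge reaches a covered pixel never loses coverage), which
#' preserves attainable optima while keeping the search finite. If the
#' computed cover ever needs more boxes than supplied, the de-duplicated
#' input boxes are returned instead, so the output never exceeds the input
#' in size.
#'
#' @param boxes Optional data.frame of input boxes (for the size guarantee
#'   and the coverage precondition check).
#' @param pixels n x 2 matrix of 0-based (x, y) overlap pixels to cover.
#' @param fov_size Box side in pixels.
#' @param dim Named `c(ny = , nx = )` plane dimensions.
#' @return data.frame with `x0, y0, x1, y1`; covers every input pixel.
#' @export
merge_fov_boxes <- function(boxes = NULL, pixels, fov_size, dim) {
  stopifnot_scalar_num(fov_size, "fov_size", positive = TRUE)
  ny <- dim[["ny"]]; nx <- dim[["nx"]]
  if (fov_size > nx || fov_size > ny)
    stop("fov_size exceeds image dimensions", call. = FALSE)
  empty <- data.frame(x0 = integer(0), y0 = integer(0),
                      x1 = integer(0), y1 = integer(0))
  if (is.null(pixels) || nrow(pixels) == 0L) return(empty)
  px <- pixels[, 1]; py <- pixels[, 2]
  if (any(px < 0 | px >= nx | py < 0 | py >= ny))
    stop("uncoverable pixel outside the image", call. = FALSE)
  if (!is.null(boxes) && nrow(boxes) > 0) {
    cov_in <- rep(FALSE, length(px))
    for (b in seq_len(nrow(boxes)))
      cov_in <- cov_in | (px >= boxes$x0[b] & px < boxes$x1[b] &
                          py >= boxes$y0[b] & py < boxes$y1[b])
    if (!all(cov_in))
      stop("precondition: every overlap pixel must be covered by an input box",
           call. = FALSE)
  }
  pos <- if (length(px) <= 12L)
    exact_box_cover(px, py, fov_size, nx, ny)
  else
    greedy_box_cover(px, py, fov_size, nx, ny)
  res <- data.frame(x0 = as.integer(pos[, 1]), y0 = as.integer(pos[, 2]),
                    x1 = as.integer(pos[, 1] + fov_size),
                    y1 = as.integer(pos[, 2] + fov_size))
  if (!is.null(boxes) && nrow(res) > nrow(boxes)) {
    res <- unique(boxes[, c("x0", "y0", "x1", "y1")])
    rownames(res) <- NULL
  }
  res
}

# Greedy max-new-coverage placement with topmost-then-leftmost tie-breaks.
# Returns a matrix of (x0, y0) box anchors.
greedy_box_cover <- function(px, py, fov, nx, ny) {
  cand_x <- sort(unique(clamp(px, 0L, nx - fov)))
  cand_y <- sort(unique(clamp(py, 0L, ny - fov)))
  uncovered <- rep(TRUE, length(px))
  out <- list()
  while (any(uncovered)) {
    ux <- px[uncovered]; uy <- py[uncovered]
    best <- c(-1L, NA_integer_, NA_integer_)
    for (y0 in cand_y) {
      in_y <- uy >= y0 & uy < y0 + fov
      if (!any(in_y)) next
      for (x0 in cand_x) {
        cnt <- sum(in_y & ux >= x0 & ux < x0 + fov)
        if (cnt > best[1]) best <- c(cnt, x0, y0)
      }
    }
    out[[length(out) + 1L]] <- c(best[2], best[3])
    uncovered[uncovered] <- !(ux >= best[2] & ux < best[2] + fov &
                              uy >= best[3] & uy < best[3] + fov)
  }
  do.call(rbind, out)
}

# Minimum box cover by iterative-deepening search over pixel-anchored
# candidate positions; deterministic (candidates scanned topmost, then
# leftmost; the first optimal cover found wins). Intended for small pixel
# sets; the greedy cover bounds the search depth.
exact_box_cover <- function(px, py, fov, nx, ny) {
  n <- length(px)
  cand_x <- sort(unique(clamp(px, 0L, nx - fov)))
  cand_y <- sort(unique(clamp(py, 0L, ny - fov)))
  cand <- cbind(x0 = rep(cand_x, times = length(cand_y)),
                y0 = rep(cand_y, each = length(cand_x)))
  cand <- cand[order(cand[, 2], cand[, 1]), , drop = FALSE]
  cover <- lapply(seq_len(nrow(cand)), function(i)
    which(px >= cand[i, 1] & px < cand[i, 1] + fov &
          py >= cand[i, 2] & py < cand[i, 2] + fov))
  nonempty <- lengths(cover) > 0L
  cand <- cand[nonempty, , drop = FALSE]
  cover <- cover[nonempty]
  # keep the first (topmost-leftmost) of identical coverage patterns
  keys <- vapply(cover, paste, character(1), collapse = ",")
  first <- !duplicated(keys)
  cand <- cand[first, , drop = FALSE]
  cover <- cover[first]
  ub <- nrow(greedy_box_cover(px, py, fov, nx, ny))
  # raster order of pixels drives the branching
  ord <- order(py, px)
  dfs <- function(uncovered, depth) {
    if (length(uncovered) == 0L) return(integer(0))
    if (depth == 0L) return(NULL)
    target <- ord[ord %in% uncovered][1]
    for (i in seq_along(cover)) {
      if (!(target %in% cover[[i]])) next
      sub <- dfs(setdiff(uncovered, cover[[i]]), depth - 1L)
      if (!is.null(sub)) return(c(i, sub))
    }
    NULL
  }
  for (k in seq_len(ub)) {
    sel <- dfs(seq_len(n), k)
    if (!is.null(sel)) {
      pos <- cand[sel, , drop = FALSE]
      return(pos[order(pos[, 2], pos[, 1]), , drop = FALSE])
    }
  }
  greedy_box_cover(px, py, fov, nx, ny)  # unreachable; defensive
}

#' Flag overlap components buried inside large structures
#'
#' A component is flagged (and excluded from the shortlist) when every one
#' of its pixels lies strictly deeper than `interior_margin` pixels from
#' the background of *both* masks: such overlaps sit in the middle of large
#' double-labeled structures rather than at an axon-dendrite apposition.
#'
#' @param component A single component from [detect_overlaps()].
#' @param axon_mask,dendrite_mask The (dilated) masks the component was
#'   detected on.
#' @param interior_margin Depth threshold in pixels (default 5, >= 1).
#' @return TRUE if the component should be rejected as interior.
#' @export
reject_interior <- function(component, axon_mask, dendrite_mask,
                            interior_margin = 5) {
  flag_interior(list(component), mask_matrix(axon_mask),
                mask_matrix(dendrite_mask), interior_margin)[1]
}

flag_interior <- function(components, axon, dendrite, interior_margin,
                          dist_a = NULL, dist_d = NULL) {
  if (length(components) == 0L) return(logical(0))
  if (is.null(dist_a)) dist_a <- distance_to_background(axon)
  if (is.null(dist_d)) dist_d <- distance_to_background(dendrite)
  vapply(components, function(cc) {
    ij <- cbind(cc$pixels[, 2] + 1L, cc$pixels[, 1] + 1L)
    all(dist_a[ij] > interior_margin & dist_d[ij] > interior_margin)
  }, logical(1))
}

# any foreground pixel within `radius` px of local point (x, y)?
disk_hit <- function(mask, x, y, radius) {
  ny <- nrow(mask); nx <- ncol(mask)
  ix0 <- max(0L, floor(x - radius)); ix1 <- min(nx - 1L, ceiling(x + radius))
  iy0 <- max(0L, floor(y - radius)); iy1 <- min(ny - 1L, ceiling(y + radius))
  if (ix0 > ix1 || iy0 > iy1) return(FALSE)
  sub <- mask[(iy0:iy1) + 1L, (ix0:ix1) + 1L, drop = FALSE]
  if (!any(sub)) return(FALSE)
  dx2 <- (ix0:ix1 - x)^2
  dy2 <- (iy0:iy1 - y)^2
  any(sub & outer(dy2, dx2, `+`) <= radius^2)
}

#' Shortlist candidates by cross-section continuity
#'
#' Neuronal processes are continuous, so the structures forming a genuine
#' axon-dendrite contact must reappear at the same or adjacent global
#' coordinates on neighboring sections, while one-section staining speckle
#' does not. A candidate is kept when axon-channel foreground reappears in
#' at least one neighboring section (within `neighbor_range`) AND
#' dendrite-channel foreground reappears in at least one neighboring
#' section, each within `match_radius` pixels of the candidate centroid
#' mapped through the global frame. The two channels may reappear in
#' different neighbors: at a contact whose apposition plane is parallel to
#' the cutting plane the dendrite continues below and the axon above, so
#' demanding both channels in the same neighbor would reject exactly the
#' commonest contact geometry (`require_same_neighbor = TRUE` restores the
#' stricter rule). Candidates on a single-section stack cannot show
#' continuity and are all removed (with a warning).
#'
#' @param candidates List of components (with `section` set).
#' @param masks_by_section List (one per section) of lists with dilated
#'   logical masks `axon` and `dendrite`.
#' @param transforms List of per-section [affine2d()] local-to-global
#'   transforms.
#' @param match_radius Pixel tolerance (default 3: dilation radius + 2).
#' @param neighbor_range 1 (adjacent sections only) or 2.
#' @param require_same_neighbor If TRUE, both channels must reappear in the
#'   same neighboring section.
#' @return Logical vector: TRUE for candidates passing the filter.
#' @export
continuity_filter <- function(candidates, masks_by_section, transforms,
                              match_radius = 3, neighbor_range = 1,
                              require_same_neighbor = FALSE) {
  n_sec <- length(masks_by_section)
  if (length(candidates) == 0L) return(logical(0))
  if (n_sec < 2L) {
    warning("single-section stack: continuity cannot be established, ",
            "all candidates removed")
    return(rep(FALSE, length(candidates)))
  }
  vapply(candidates, function(cc) {
    s <- cc$section
    glob <- to_global(unname(cc$centroid), transforms[[s]])
    nb <- setdiff(seq(s - neighbor_range, s + neighbor_range), s)
    nb <- nb[nb >= 1L & nb <= n_sec]
    axon_seen <- FALSE; dend_seen <- FALSE
    for (k in nb) {
      loc <- to_local(glob, transforms[[k]])
      a <- disk_hit(masks_by_section[[k]]$axon, loc[1], loc[2], match_radius)
      d <- disk_hit(masks_by_section[[k]]$dendrite, loc[1], loc[2],
                    match_radius)
      if (require_same_neighbor && a && d) return(TRUE)
      axon_seen <- axon_seen || a
      dend_seen <- dend_seen || d
      if (!require_same_neighbor && axon_seen && dend_seen) return(TRUE)
    }
    FALSE
  }, logical(1))
}

#' Bind a shortlisted candidate to a serial image series
#'
#' The shortlisted coordinate is imaged together with the same global
#' coordinate on the one or two preceding and following sections (3-5
#' serial images), so continuity can be judged at super-resolution. Series
#' are truncated at stack ends and, when possible, extended on the
#' available side to keep at least 3 entries.
#'
#' @param candidate A shortlisted component (with `section`, `centroid`).
#' @param n_neighbors 1 or 2 sections on each side.
#' @param n_sections Total sections in the stack.
#' @param transforms Per-section [affine2d()] transforms.
#' @param fov_size Field-of-view side in pixels.
#' @param dim Named `c(ny = , nx = )` plane dimensions.
#' @return An `roi_series`: data.frame with `section`, local center
#'   `x, y`, and box `x0, y0, x1, y1` per entry, plus attributes
#'   `anchor_section` and `global` (x, y in global coordinates).
#' @export
bind_series <- function(candidate, n_neighbors = 1, n_sections, transforms,
                        fov_size, dim) {
  if (!n_neighbors %in% c(1L, 2L))
    stop("n_neighbors must be 1 or 2", call. = FALSE)
  s <- candidate$section
  secs <- seq(s - n_neighbors, s + n_neighbors)
  secs <- secs[secs >= 1L & secs <= n_sections]
  # extend on the open side to keep >= 3 images when the stack allows
  while (length(secs) < min(3L, n_sections)) {
    lo <- min(secs); hi <- max(secs)
    if (hi < n_sections) secs <- c(secs, hi + 1L)
    else if (lo > 1L) secs <- c(lo - 1L, secs)
    else break
  }
  glob <- to_global(unname(candidate$centroid), transforms[[s]])
  ny <- dim[["ny"]]; nx <- dim[["nx"]]
  rows <- lapply(sort(secs), function(k) {
    loc <- to_local(glob, transforms[[k]])
    cx <- round(loc[1]); cy <- round(loc[2])
    x0 <- clamp(cx - fov_size %/% 2L, 0L, nx - fov_size)
    y0 <- clamp(cy - fov_size %/% 2L, 0L, ny - fov_size)
    data.frame(section = k, x = loc[1], y = loc[2],
               x0 = as.integer(x0), y0 = as.integer(y0),
               x1 = as.integer(x0 + fov_size), y1 = as.integer(y0 + fov_size))
  })
  out <- do.call(rbind, rows)
  attr(out, "anchor_section") <- s
  attr(out, "global") <- glob
  class(out) <- c("roi_series", class(out))
  out
}
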