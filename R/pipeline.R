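#' Run configuration for the detection pipeline
#'
#' Collects every tunable of the pipeline stages with their defaults.
#' Configurations round-trip through YAML or JSON files; flags of the
#' command-line entry point mirror these keys 1:1.
#'
#' @param target_mean,target_sd Brightness normalization targets.
#' @param background_sigma Background-flattening blur scale, pixels.
#' @param alpha Renyi entropy order for thresholding.
#' @param n_bins Histogram bins for thresholding.
#' @param noise_guard_k Background-only guard of [binarize_channel()].
#' @param fov_px SIM field-of-view side, pixels of the survey image.
#' @param interior_margin Interior-rejection depth, pixels.
#' @param match_radius Continuity matching tolerance, pixels.
#' @param neighbor_range Continuity neighbor range (1 or 2 sections).
#' @param n_neighbors Series binding: sections added on each side (1 or 2).
#' @param minutes_per_tile SIM acquisition minutes per tile.
#' @param seed Integer seed for any stochastic stage.
#' @param channel_roles Named character vector mapping the stack's channel
#'   names onto the roles dendrite/axon/marker (each exactly once).
#' @return A `run_config` list.
#' @export
run_config <- function(target_mean = 100, target_sd = 20,
                       background_sigma = 50,
                       alpha = 2, n_bins = 256L,
                       noise_guard_k = 2,
                       fov_px = 32L,
                       interior_margin = 5,
                       match_radius = 3,
                       neighbor_range = 1L,
                       n_neighbors = 1L,
                       minutes_per_tile = 3,
                       seed = 1L,
                       channel_roles = c(dendrite = "dendrite",
                                         axon = "axon",
                                         marker = "marker")) {
  roles <- names(channel_roles)
  if (!setequal(roles, c("dendrite", "axon", "marker")) ||
      anyDuplicated(roles))
    stop("channel_roles must cover dendrite/axon/marker exactly once",
         call. = FALSE)
  if (!neighbor_range %in% c(1L, 2L))
    stop("neighbor_range must be 1 or 2", call. = FALSE)
  if (!n_neighbors %in% c(1L, 2L))
    stop("n_neighbors must be 1 or 2", call. = FALSE)
  structure(list(
    target_mean = target_mean, target_sd = target_sd,
    background_sigma = background_sigma,
    alpha = alpha, n_bins = as.integer(n_bins),
    noise_guard_k = noise_guard_k,
    fov_px = as.integer(fov_px),
    interior_margin = interior_margin,
    match_radius = match_radius,
    neighbor_range = as.integer(neighbor_range),
    n_neighbors = as.integer(n_neighbors),
    minutes_per_tile = minutes_per_tile,
    seed = as.integer(seed),
    channel_roles = as.list(channel_roles)
  ), class = "run_config")
}

#' @rdname run_config
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- run_config()
  keep <- intersect(names(vals), names(defaults))
  args <- unclass(defaults)
  args[keep] <- vals[keep]
  args$channel_roles <- unlist(args$channel_roles)
  do.call(run_config, args)
}

#' @rdname run_config
#' @param config A `run_config` to write.
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(unclass(config), path)
  else jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                            digits = NA)
  invisible(path)
}

#' Default local-to-global transforms for a stack
#'
#' Pixel-center coordinates map to global micrometres by pure scaling:
#' `global = (local_px + 0.5) * pixel_size_um`.
#'
#' @param stack A `section_stack`.
#' @return List of [affine2d()] transforms, one per section.
#' @export
default_transforms <- function(stack) {
  px <- stack$pixel_size_um
  replicate(stack$n_sections,
            affine2d(a = px, d = px, tx = px / 2, ty = px / 2),
            simplify = FALSE)
}

#' Detect, schedule and shortlist ROIs on a section stack
#'
#' Executes the full detection chain on every section: brightness
#' normalization and background flattening per channel, Renyi-entropy
#' binarization and 3x3 dilation, axon-dendrite overlap detection inside
#' each target area, interior rejection, minimal-overlap field-of-view
#' merging, cross-section continuity shortlisting, series binding, and
#' global-coordinate export.
#'
#' @param stack A `section_stack`.
#' @param config A [run_config()].
#' @param areas List of [target_area()] polygons; NULL means one implicit
#'   area covering the whole image.
#' @param transforms Per-section [affine2d()] transforms; default pixel
#'   scaling.
#' @return An `roi_result`: list with `candidates` (data.frame, one row per
#'   detected component with status flags and global coordinates), `series`
#'   (list of `roi_series` for shortlisted candidates), `plan_boxes`
#'   (merged acquisition boxes per section/area), `masks` (per-section
#'   dilated and undilated masks), `counts` (per-stage bookkeeping), and
#'   the inputs used.
#' @export
run_detect <- function(stack, config = run_config(), areas = NULL,
                       transforms = NULL) {
  stopifnot(inherits(stack, "section_stack"))
  stopifnot(inherits(config, "run_config"))
  transforms <- transforms %||% default_transforms(stack)
  n_sec <- stack$n_sections
  if (is.null(areas)) {
    ext <- (stack$dim[c("nx", "ny")]) * stack$pixel_size_um
    areas <- list(target_area("all", rbind(c(0, 0), c(ext[1], 0),
                                           ext, c(0, ext[2]))))
  }
  roles <- config$channel_roles

  masks <- vector("list", n_sec)
  dilated <- vector("list", n_sec)
  thresholds <- vector("list", n_sec)
  for (k in seq_len(n_sec)) {
    pl <- stack$sections[[k]]
    mk <- list(); dk <- list(); th <- list()
    for (role in c("dendrite", "axon", "marker")) {
      plane <- pl[[roles[[role]]]]
      if (is.null(plane))
        stop("stage segment: channel for role '", role, "' not found",
             call. = FALSE)
      pre <- preprocess_plane(plane, config$target_mean, config$target_sd,
                              config$background_sigma)
      bm <- binarize_channel(pre, alpha = config$alpha,
                             n_bins = config$n_bins,
                             noise_guard_k = config$noise_guard_k,
                             section = k, channel = role)
      mk[[role]] <- bm$mask
      dk[[role]] <- dilate3x3(bm$mask)
      th[[role]] <- bm$threshold
    }
    masks[[k]] <- mk
    dilated[[k]] <- dk
    thresholds[[k]] <- th
  }

  candidates <- list()
  plan_boxes <- list()
  for (k in seq_len(n_sec)) {
    dist_a <- distance_to_background(dilated[[k]]$axon)
    dist_d <- distance_to_background(dilated[[k]]$dendrite)
    for (ar in areas) {
      if (!is.null(ar$sections) &&
          !(k >= min(ar$sections) && k <= max(ar$sections))) next
      am <- area_mask(ar, stack$dim, transforms[[k]])
      comps <- detect_overlaps(dilated[[k]]$axon, dilated[[k]]$dendrite,
                               target_mask = am, section = k,
                               area_name = ar$name)
      if (length(comps) == 0L) next
      interior <- flag_interior(comps, dilated[[k]]$axon,
                                dilated[[k]]$dendrite,
                                config$interior_margin,
                                dist_a = dist_a, dist_d = dist_d)
      for (i in seq_along(comps)) comps[[i]]$interior <- interior[i]
      candidates <- c(candidates, comps)
      pix <- do.call(rbind, lapply(comps, `[[`, "pixels"))
      # components can outgrow one field of view, so the cover is computed
      # from the pixels directly rather than from the per-component boxes
      merged <- merge_fov_boxes(NULL, pix, config$fov_px, stack$dim)
      # cover completeness is asserted on every run
      stopifnot(all(vapply(seq_len(nrow(pix)), function(j)
        any(pix[j, 1] >= merged$x0 & pix[j, 1] < merged$x1 &
            pix[j, 2] >= merged$y0 & pix[j, 2] < merged$y1), logical(1))))
      if (nrow(merged) > 0) {
        merged$section <- k
        merged$area <- ar$name
        plan_boxes[[length(plan_boxes) + 1L]] <- merged
      }
    }
  }

  n_detected <- length(candidates)
  interior_flags <- vapply(candidates, `[[`, logical(1), "interior")
  survivors <- candidates[!interior_flags]
  keep <- continuity_filter(survivors, dilated, transforms,
                            match_radius = config$match_radius,
                            neighbor_range = config$neighbor_range)
  shortlisted <- survivors[keep]

  series <- lapply(shortlisted, function(cc)
    bind_series(cc, n_neighbors = config$n_neighbors,
                n_sections = n_sec, transforms = transforms,
                fov_size = config$fov_px, dim = stack$dim))

  cand_df <- candidates_to_df(candidates, transforms, config, stack$dim)
  if (nrow(cand_df) > 0) {
    cand_df$continuity_rejected <- FALSE
    surv_ids <- cand_df$id[!cand_df$interior_rejected]
    cand_df$continuity_rejected[match(surv_ids[!keep], cand_df$id)] <- TRUE
    cand_df$shortlisted <- !cand_df$interior_rejected &
      !cand_df$continuity_rejected
    cand_df$series_id <- NA_integer_
    cand_df$series_id[cand_df$shortlisted] <- seq_along(series)
  }

  counts <- list(detected = n_detected,
                 interior_rejected = sum(interior_flags),
                 continuity_rejected = sum(!keep),
                 shortlisted = length(shortlisted))
  structure(list(candidates = cand_df, components = candidates,
                 series = series,
                 plan_boxes = if (length(plan_boxes))
                   do.call(rbind, plan_boxes) else NULL,
                 masks = list(raw = masks, dilated = dilated,
                              thresholds = thresholds),
                 counts = counts, config = config, areas = areas,
                 transforms = transforms,
                 pixel_size_um = stack$pixel_size_um,
                 n_sections = n_sec),
            class = "roi_result")
}

candidates_to_df <- function(candidates, transforms, config, dim) {
  if (length(candidates) == 0L)
    return(data.frame(id = integer(0), section = integer(0),
                      area = character(0), local_x = numeric(0),
                      local_y = numeric(0), global_x_um = numeric(0),
                      global_y_um = numeric(0), x0 = integer(0),
                      y0 = integer(0), x1 = integer(0), y1 = integer(0),
                      n_pixels = integer(0), interior_rejected = logical(0)))
  rows <- lapply(seq_along(candidates), function(i) {
    cc <- candidates[[i]]
    glob <- to_global(unname(cc$centroid), transforms[[cc$section]])
    cx <- round(cc$centroid[["x"]]); cy <- round(cc$centroid[["y"]])
    x0 <- clamp(cx - config$fov_px %/% 2L, 0L, dim[["nx"]] - config$fov_px)
    y0 <- clamp(cy - config$fov_px %/% 2L, 0L, dim[["ny"]] - config$fov_px)
    data.frame(id = i, section = cc$section, area = cc$area,
               local_x = cc$centroid[["x"]], local_y = cc$centroid[["y"]],
               global_x_um = glob[1], global_y_um = glob[2],
               x0 = as.integer(x0), y0 = as.integer(y0),
               x1 = as.integer(x0 + config$fov_px),
               y1 = as.integer(y0 + config$fov_px),
               n_pixels = nrow(cc$pixels),
               interior_rejected = cc$interior)
  })
  do.call(rbind, rows)
}

#' @export
print.roi_result <- function(x, ...) {
  cat(sprintf(
    "roi_result: %d detected, %d interior-rejected, %d continuity-rejected, %d shortlisted\n",
    x$counts$detected, x$counts$interior_rejected,
    x$counts$continuity_rejected, x$counts$shortlisted))
  invisible(x)
}

#' Export ROI detections and the acquisition plan
#'
#' Writes the candidate table as CSV and JSON, the acquisition-plan CSV
#' (one row per scheduled series entry, the stand-in for a microscope
#' macro's coordinate list), the per-stage counts log, and a
#' machine-readable run manifest (config echo and hash, package version,
#' seed). Identical inputs produce byte-identical files.
#'
#' @param result An `roi_result` from [run_detect()].
#' @param directory Output directory.
#' @return Invisibly, the directory.
#' @export
write_roi_result <- function(result, directory) {
  stopifnot(inherits(result, "roi_result"))
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory, call. = FALSE)
  utils::write.csv(result$candidates, file.path(directory, "rois.csv"),
                   row.names = FALSE)
  jsonlite::write_json(result$candidates, file.path(directory, "rois.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  plan <- series_plan(result)
  utils::write.csv(plan, file.path(directory, "acquisition_plan.csv"),
                   row.names = FALSE)
  counts <- data.frame(stage = names(result$counts),
                       n = unlist(result$counts, use.names = FALSE))
  utils::write.csv(counts, file.path(directory, "stage_counts.csv"),
                   row.names = FALSE)
  cfg_path <- file.path(directory, "config.json")
  write_run_config(result$config, cfg_path)
  manifest <- list(package = "simtarget",
                   version = as.character(utils::packageVersion("simtarget")),
                   seed = result$config$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   n_sections = result$n_sections,
                   counts = result$counts)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

#' Acquisition plan: one row per scheduled series entry
#'
#' @param result An `roi_result`.
#' @return data.frame with `series_id`, `section`, box bounds, and the
#'   global anchor coordinates in micrometres.
#' @export
series_plan <- function(result) {
  if (length(result$series) == 0L)
    return(data.frame(series_id = integer(0), section = integer(0),
                      x0 = integer(0), y0 = integer(0), x1 = integer(0),
                      y1 = integer(0), global_x_um = numeric(0),
                      global_y_um = numeric(0)))
  rows <- lapply(seq_along(result$series), function(i) {
    s <- result$series[[i]]
    g <- attr(s, "global")
    data.frame(series_id = i, section = s$section,
               x0 = s$x0, y0 = s$y0, x1 = s$x1, y1 = s$y1,
               global_x_um = g[1], global_y_um = g[2])
  })
  do.call(rbind, rows)
}

#' Quantify confirmed synapses per target area
#'
#' Joins a confirmation table (the stand-in for visual verification of the
#' super-resolution series: `id`, `confirmed`) onto the shortlisted
#' candidates, counts confirmed synapses per target area, measures
#' structure areas on the undilated masks, and completes the report with
#' densities, fold ratios and the targeted imaging plan.
#'
#' @param result An `roi_result` from [run_detect()].
#' @param confirmations data.frame with columns `id` (candidate ids from
#'   the ROI export) and `confirmed` (logical). Unknown ids are rejected.
#' @param reference Reference area for fold ratios (default first area).
#' @return List with `report` (a `quant_report`, when >= 2 areas are
#'   present, else the areas/counts data.frame), `confirmed_ids`, and
#'   `plan` (an `imaging_plan` for the targeted acquisition).
#' @export
run_quant <- function(result, confirmations, reference = NULL) {
  stopifnot(inherits(result, "roi_result"))
  if (!all(c("id", "confirmed") %in% names(confirmations)))
    stop("confirmations must have columns id, confirmed", call. = FALSE)
  unknown <- setdiff(confirmations$id, result$candidates$id)
  if (length(unknown))
    stop("unknown ROI ids: ", paste(utils::head(unknown, 5), collapse = ", "),
         call. = FALSE)
  cand <- result$candidates
  conf_ids <- confirmations$id[as.logical(confirmations$confirmed)]
  confirmed <- cand[cand$id %in% conf_ids & cand$shortlisted, , drop = FALSE]
  area_names <- vapply(result$areas, `[[`, character(1), "name")
  counts <- vapply(area_names, function(a) sum(confirmed$area == a),
                   numeric(1))
  undil <- lapply(result$masks$raw, function(mk)
    list(axon = mk$axon, dendrite = mk$dendrite))
  areas_df <- measure_areas(undil, result$areas, result$transforms,
                            result$pixel_size_um)
  report <- if (nrow(areas_df) >= 2L)
    density_and_folds(areas_df, counts, reference = reference)
  else {
    areas_df$synapse_count <- as.numeric(counts[areas_df$area])
    areas_df
  }
  n_tiles <- if (length(result$series))
    sum(vapply(result$series, nrow, integer(1))) else 0L
  plan <- imaging_plan(
    width_um = ncol(result$masks$raw[[1]]$axon) * result$pixel_size_um,
    height_um = nrow(result$masks$raw[[1]]$axon) * result$pixel_size_um,
    fov_um = result$config$fov_px * result$pixel_size_um,
    n_sections = result$n_sections,
    minutes_per_tile = result$config$minutes_per_tile,
    targeted_tiles = n_tiles)
  list(report = report, confirmed_ids = conf_ids, plan = plan,
       counts = counts)
}

#' Write quantification outputs
#'
#' @param quant Output of [run_quant()].
#' @param directory Output directory.
#' @return Invisibly, the directory.
#' @export
write_quant <- function(quant, directory) {
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory: ", directory, call. = FALSE)
  rep_df <- as.data.frame(quant$report)
  jsonlite::write_json(list(report = rep_df,
                            plan = unclass(quant$plan)),
                       file.path(directory, "quant_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  tbl <- utils::capture.output({
    if (inherits(quant$report, "quant_report")) print(quant$report)
    else print(rep_df)
    print(quant$plan)
  })
  writeLines(tbl, file.path(directory, "quant_report.txt"))
  invisible(directory)
}

#' Recall of ground-truth synapses among shortlisted ROIs
#'
#' A true synapse counts as recovered when a shortlisted candidate on its
#' section (or an adjacent one) has an overlap pixel within `radius_px` of
#' the synapse position.
#'
#' @param result An `roi_result`.
#' @param truth A `phantom_truth`.
#' @param stack The `section_stack` the result came from.
#' @param radius_px Matching radius, pixels (default: the config's
#'   `match_radius`).
#' @return List with `recall` (fraction in [0, 1]), `n_true`, `n_found`.
#' @export
phantom_recall <- function(result, truth, stack, radius_px = NULL) {
  radius_px <- radius_px %||% result$config$match_radius
  short_ids <- result$candidates$id[result$candidates$shortlisted]
  comps <- result$components[short_ids]
  tru <- truth$synapses[truth$synapses$is_true_synapse, , drop = FALSE]
  px <- stack$pixel_size_um
  found <- vapply(seq_len(nrow(tru)), function(i) {
    sx <- tru$x_um[i] / px - 0.5
    sy <- tru$y_um[i] / px - 0.5
    sec <- tru$section[i]
    for (cc in comps) {
      if (abs(cc$section - sec) > 1L) next
      if (min((cc$pixels[, 1] - sx)^2 + (cc$pixels[, 2] - sy)^2) <=
          radius_px^2) return(TRUE)
    }
    FALSE
  }, logical(1))
  list(recall = if (nrow(tru)) mean(found) else NA_real_,
       n_true = nrow(tru), n_found = sum(found))
}
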