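#' Run one software-emulating preset on a stack
#'
#' Executes the preset's documented operator chain on every intensity
#' channel present (nuclei required; insle / alpha optional), derives
#' the spheroid mask and core/mantle partition when the preset defines a
#' core fraction, processes the ECM channel and counts cell-ECM
#' contacts when the preset defines a contact distance.  The chain is
#' assembled from the configuration fields, so a custom
#' [pipeline_config()] runs the same way as a published preset.  Every
#' stage appends its resolved voxel-unit parameters to the returned log.
#'
#' @param stack A [channel_stack()].
#' @param cfg A [pipeline_config()], e.g. from [preset()].
#' @return A list with `objects` (per-channel object tables), `labels`
#'   (per-channel label maps; spots have none), `counts` (named counts),
#'   `partition` (or `NULL`), `contacts` (or `NULL`) and `log`
#'   (character).
#' @export
run_preset <- function(stack, cfg) {
  stopifnot(inherits(stack, "channel_stack"),
            inherits(cfg, "pipeline_config"))
  if (!"nuclei" %in% names(stack$channels))
    stop("stack is missing required channel role 'nuclei'")
  geometry <- stack$geometry
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  intensity_roles <- intersect(c("nuclei", "insle", "alpha"),
                               names(stack$channels))
  objects <- list(); labels <- list()
  for (role in intensity_roles) {
    g <- stack$channels[[role]]
    if (cfg$rescale) { g <- rescale_intensity(g); say("[%s] rescale to [0,1]", role) }
    if (!is.na(cfg$rolling_ball_radius)) {
      g <- rolling_ball_subtract(g, cfg$rolling_ball_radius,
                                 cfg$rolling_ball_unit, geometry)
      say("[%s] rolling ball r=%g %s", role, cfg$rolling_ball_radius,
          cfg$rolling_ball_unit)
    }
    if (cfg$z_equalize) { g <- equalize_z(g); say("[%s] equalize z", role) }
    if (!is.na(cfg$median_size)) {
      g <- median_filter(g, cfg$median_size)
      say("[%s] median filter size=%d", role, as.integer(cfg$median_size))
    }
    bgl <- cfg$bg_gauss_length[[role]]
    if (!is.null(bgl) && !is.na(bgl)) {
      g <- gaussian_background_subtract(g, bgl, geometry)
      say("[%s] gaussian background subtract %g um", role, bgl)
    }
    if (!is.na(cfg$spot_diameter) && role == "nuclei") {
      tab <- detect_spots(g, cfg$spot_diameter, NULL, geometry, role)
      say("[%s] spot detection d=%g um -> %d spots", role,
          cfg$spot_diameter, nrow(tab))
      objects[[role]] <- tab
      next
    }
    if (!is.na(cfg$surface_smoothness)) {
      lm <- detect_surfaces(g, cfg$surface_smoothness,
                            cfg$surface_bg_diameter, NULL, geometry,
                            cfg$split_diameter, cfg$min_area,
                            cfg$connectivity)
      say("[%s] surfaces smooth=%g bg=%g split=%g min_area=%g -> %d objects",
          role, cfg$surface_smoothness, cfg$surface_bg_diameter,
          cfg$split_diameter, cfg$min_area, lm$n_objects)
    } else {
      if (!is.na(cfg$log_sigma)) {
        g <- gaussian_laplace(g, cfg$log_sigma)
        say("[%s] gaussian laplace sigma=%g px", role, cfg$log_sigma)
      }
      binary <- binarize(g, cfg)
      say("[%s] threshold (%s)", role,
          if (!is.na(cfg$manual_threshold)) "manual" else cfg$otsu_mode)
      lm <- if (!is.na(cfg$split_diameter))
        watershed_split(binary, cfg$split_diameter, geometry,
                        cfg$connectivity)
      else label_components(binary, cfg$connectivity, geometry)
      lm <- size_filter(lm, cfg$min_voxels, cfg$min_area, geometry)
      say("[%s] label conn=%d, size filter >%d voxels / >=%g um^2 -> %d objects",
          role, cfg$connectivity, as.integer(cfg$min_voxels),
          cfg$min_area, lm$n_objects)
    }
    labels[[role]] <- lm
    objects[[role]] <- measure_objects(lm, stack$channels[[role]], role)
  }
  partition <- NULL
  if (!is.na(cfg$core_fraction)) {
    mask <- tryCatch(spheroid_mask(stack$channels$nuclei, geometry),
                     error = function(e) NULL)
    if (!is.null(mask)) {
      partition <- core_mantle_partition(mask, cfg$core_fraction, geometry)
      say("[spheroid] partition target=%g achieved=%.3f", cfg$core_fraction,
          partition$achieved_core_fraction)
      for (role in names(objects))
        objects[[role]] <- assign_regions(objects[[role]], partition)
    }
  }
  contacts <- NULL
  if (!is.na(cfg$contact_max_distance) && "ecm" %in% names(stack$channels) &&
      "insle" %in% names(labels)) {
    e <- stack$channels$ecm
    bgl <- cfg$bg_gauss_length$ecm
    if (!is.null(bgl) && !is.na(bgl))
      e <- gaussian_background_subtract(e, bgl, geometry)
    else e <- gaussian_smooth(e, 1, geometry)
    ecm_labels <- if (max(e) > min(e))
      label_components(threshold_otsu(e, "global"), cfg$connectivity,
                       geometry)
    else label_map(array(0L, dim = dim(e)), geometry)
    contacts <- object_contacts(labels$insle, ecm_labels,
                                cfg$contact_max_distance, geometry)
    say("[ecm] contacts at <=%g um: %d / %d children interacting",
        cfg$contact_max_distance, attr(contacts, "n_interacting"),
        nrow(contacts))
  }
  counts <- vapply(objects, nrow, integer(1))
  list(objects = objects, labels = labels, counts = counts,
       partition = partition, contacts = contacts, log = log)
}

binarize <- function(g, cfg) {
  if (!is.na(cfg$manual_threshold))
    return(threshold_manual(g, cfg$manual_threshold))
  if (max(g) == min(g))   # blank channel: nothing to segment
    return(array(FALSE, dim = dim(g)))
  threshold_otsu(g, cfg$otsu_mode, cfg$adaptive_block)
}

#' Match detections to ground truth
#'
#' Globally optimal one-to-one assignment minimising total centroid
#' distance among pairs closer than `match_radius` (Hungarian
#' algorithm; pairs beyond the radius are forbidden, and the solution
#' first maximises the number of matches, then minimises total
#' distance).
#'
#' @param detected Object table with centroid columns, µm.
#' @param truth Ground-truth table with centre columns, µm.
#' @param match_radius Maximum pairing distance, µm; the default is one
#'   nucleus diameter.
#' @return `list(pairs = data.frame(detected_id, truth_id, distance),
#'   unmatched_detected, unmatched_truth)`.
#' @export
match_objects <- function(detected, truth, match_radius = 6) {
  if (match_radius <= 0) stop("`match_radius` must be strictly positive")
  nd <- nrow(detected); nt <- nrow(truth)
  empty <- data.frame(detected_id = integer(0), truth_id = integer(0),
                      distance = numeric(0))
  if (nd == 0 || nt == 0)
    return(list(pairs = empty, unmatched_detected = seq_len(nd),
                unmatched_truth = seq_len(nt)))
  pd <- table_positions_um(detected)
  pt <- table_positions_um(truth)
  dm <- sqrt(outer(rowSums(pd^2), rep(1, nt)) +
             outer(rep(1, nd), rowSums(pt^2)) - 2 * pd %*% t(pt))
  dm[!is.finite(dm)] <- 0
  big <- (max(dm) + match_radius + 1) * (max(nd, nt) + 1)
  cost <- ifelse(dm <= match_radius, dm, big)
  transposed <- nd > nt
  m <- if (transposed) t(cost) else cost
  assign <- hungarian_cpp(m)
  rows <- seq_len(nrow(m))
  pairs <- data.frame(
    detected_id = if (transposed) assign else rows,
    truth_id = if (transposed) rows else assign)
  pairs$distance <- dm[cbind(pairs$detected_id, pairs$truth_id)]
  pairs <- pairs[!is.na(pairs$truth_id) & !is.na(pairs$detected_id) &
                   pairs$distance <= match_radius, , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unmatched_detected = setdiff(seq_len(nd), pairs$detected_id),
       unmatched_truth = setdiff(seq_len(nt), pairs$truth_id))
}

#' Relative count change versus a reference
#'
#' `100 * (count - reference) / reference`, the over/underestimation
#' metric used to compare each software count against the reference
#' count.
#'
#' @param count Measured count.
#' @param reference Reference count (> 0).
#' @return Signed percentage.
#' @examples
#' relative_change(113, 100)  # +13
#' relative_change(17, 100)   # -83
#' @export
relative_change <- function(count, reference) {
  if (any(reference <= 0)) stop("`reference` must be strictly positive")
  100 * (count - reference) / reference
}

#' Study-condition simulation regimes
#'
#' Fixed simulation settings for the two benchmark regimes: `"easy"`
#' (200 well-separated cells, no attenuation, no PSF, no background, no
#' noise — the regime in which every preset should recover the nucleus
#' count) and `"hard"` (200 compressed, touching cells with depth
#' attenuation, PSF blur, smooth background and Poisson + Gaussian
#' noise — the paper-like regime in which preset counts diverge).
#'
#' @param regime `"easy"` or `"hard"`.
#' @param seed Simulation seed.
#' @return A [simulation_config()].
#' @export
regime_config <- function(regime = c("easy", "hard"), seed = 0) {
  regime <- match.arg(regime)
  if (regime == "easy")
    simulation_config(
      n_cells = 200, aggregate_radius = 36, contact_fraction = 1.0,
      attenuation_length = Inf, psf_sigma_xy = 0, psf_sigma_z = 0,
      background_amplitude = 0, noise_photons = Inf, noise_read_sd = 0,
      ecm_fibre_count = 12, seed = seed)
  else
    simulation_config(
      n_cells = 200, aggregate_radius = 28, contact_fraction = 0.75,
      attenuation_length = 40, psf_sigma_xy = 0.35, psf_sigma_z = 1.0,
      background_amplitude = 0.1, noise_photons = 150,
      noise_read_sd = 0.01, ecm_fibre_count = 12, seed = seed)
}

#' Default benchmark acquisition geometry
#'
#' 0.55 µm lateral pixels (a 2x2-binned 11 µm camera pixel behind a 40x
#' objective) and 0.7 µm z-steps.
#'
#' @return A [voxel_geometry()].
#' @export
benchmark_geometry <- function() voxel_geometry(0.55, 0.7)

#' Benchmark presets against ground truth
#'
#' Runs every preset on every dataset and reports, per dataset x preset
#' x channel: detected count, ground-truth reference count, relative
#' change, core/mantle counts and the ECM-contact count.  The
#' per-preset, per-channel mean relative change across datasets is
#' attached as `attr(report, "summary")`.
#'
#' @param datasets List of `list(stack =, truth =)` entries (e.g. from
#'   [simulate_pseudoislet()]); names become dataset ids.
#' @param presets Character vector of preset names or a list of
#'   [pipeline_config()] objects.
#' @return A `data.frame` of class `benchmark_report`.
#' @export
benchmark_report <- function(datasets,
                             presets = c("fiji", "cellprofiler", "ga3",
                                         "imaris")) {
  if (length(datasets) == 0) stop("at least one dataset is required")
  if (length(presets) == 0) stop("at least one preset is required")
  if (is.null(names(datasets)))
    names(datasets) <- sprintf("dataset%02d", seq_along(datasets))
  if (is.character(presets)) {
    presets <- lapply(presets, preset)
  }
  preset_names <- vapply(presets, function(p) p$preset_name, character(1))
  rows <- list()
  for (di in seq_along(datasets)) {
    ds <- datasets[[di]]
    truth <- ds$truth
    refs <- c(nuclei = nrow(truth),
              insle = sum(truth$cell_type == "insle"),
              alpha = sum(truth$cell_type == "alpha"))
    for (pi in seq_along(presets)) {
      res <- run_preset(ds$stack, presets[[pi]])
      for (role in names(res$objects)) {
        tab <- res$objects[[role]]
        rc <- attr(tab, "region_counts")
        rows[[length(rows) + 1]] <- data.frame(
          dataset_id = names(datasets)[di],
          preset_name = preset_names[pi],
          channel = role,
          count = nrow(tab),
          reference_count = refs[[role]],
          relative_change_pct = relative_change(nrow(tab), refs[[role]]),
          core_count = if (is.null(rc)) NA_integer_ else rc[["core"]],
          mantle_count = if (is.null(rc)) NA_integer_ else rc[["mantle"]],
          ecm_contact_count = if (role == "insle" && !is.null(res$contacts))
            attr(res$contacts, "n_interacting") else NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  summ <- aggregate(relative_change_pct ~ preset_name + channel, report,
                    mean)
  names(summ)[3] <- "mean_relative_change_pct"
  attr(report, "summary") <- summ
  class(report) <- c("benchmark_report", "data.frame")
  report
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Benchmark report (", length(unique(x$dataset_id)), " dataset(s) x ",
      length(unique(x$preset_name)), " preset(s))\n", sep = "")
  print.data.frame(x, ...)
  cat("\nMean relative change across datasets:\n")
  print(attr(x, "summary"))
  invisible(x)
}
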