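PIPELINE_FIELDS <- c(
  "preset_name", "rolling_ball_radius", "rolling_ball_unit", "rescale",
  "median_size", "log_sigma", "z_equalize", "bg_gauss_length", "otsu_mode",
  "adaptive_block", "manual_threshold", "min_voxels", "min_area",
  "spot_diameter", "surface_smoothness", "surface_bg_diameter",
  "split_diameter", "core_fraction", "contact_max_distance", "connectivity")

#' Pipeline configuration
#'
#' Holds every tunable parameter of the quantification chain.  Lengths are
#' in µm unless the field carries an explicit unit tag
#' (`rolling_ball_unit`), sizes in voxels.  A stage is disabled by leaving
#' its parameter `NA`.  Binarisation is driven by exactly one of
#' `manual_threshold` (a fixed cutoff) or `otsu_mode`
#' (`"global"`/`"adaptive"`).
#'
#' @param ... Field values overriding the defaults; see
#'   [preset()] for the four published parameter sets.
#' @return A validated object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    preset_name = "custom",
    rolling_ball_radius = NA_real_, rolling_ball_unit = "um",
    rescale = FALSE,
    median_size = NA_real_,
    log_sigma = NA_real_,
    z_equalize = FALSE,
    bg_gauss_length = list(nuclei = NA_real_, insle = NA_real_,
                           alpha = NA_real_, ecm = NA_real_),
    otsu_mode = "global",
    adaptive_block = 32,
    manual_threshold = NA_real_,
    min_voxels = 0,
    min_area = 0,
    spot_diameter = NA_real_,
    surface_smoothness = NA_real_,
    surface_bg_diameter = NA_real_,
    split_diameter = NA_real_,
    core_fraction = NA_real_,
    contact_max_distance = 0,
    connectivity = 26)
  over <- list(...)
  bad <- setdiff(names(over), PIPELINE_FIELDS)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  if ("bg_gauss_length" %in% names(over) && is.numeric(over$bg_gauss_length) &&
      is.null(names(over$bg_gauss_length))) {
    over$bg_gauss_length <- as.list(setNames(
      rep(over$bg_gauss_length[1], 4), names(cfg$bg_gauss_length)))
  }
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  problems <- character(0)
  pos <- function(field, value) {
    if (!is.na(value) && (!is.numeric(value) || value <= 0))
      problems <<- c(problems, paste0(field, " must be strictly positive"))
  }
  pos("rolling_ball_radius", cfg$rolling_ball_radius)
  pos("median_size", cfg$median_size)
  pos("log_sigma", cfg$log_sigma)
  pos("adaptive_block", cfg$adaptive_block)
  pos("spot_diameter", cfg$spot_diameter)
  pos("surface_smoothness", cfg$surface_smoothness)
  pos("surface_bg_diameter", cfg$surface_bg_diameter)
  pos("split_diameter", cfg$split_diameter)
  for (role in names(cfg$bg_gauss_length))
    pos(paste0("bg_gauss_length$", role), cfg$bg_gauss_length[[role]])
  if (!cfg$rolling_ball_unit %in% c("um", "pixels"))
    problems <- c(problems, "rolling_ball_unit must be 'um' or 'pixels'")
  if (!is.na(cfg$median_size) && cfg$median_size %% 2 != 1)
    problems <- c(problems, "median_size must be odd")
  if (!is.na(cfg$core_fraction) &&
      (cfg$core_fraction <= 0 || cfg$core_fraction >= 1))
    problems <- c(problems, "core_fraction must lie in (0, 1)")
  if (!is.na(cfg$min_voxels) && cfg$min_voxels < 0)
    problems <- c(problems, "min_voxels must be >= 0")
  if (!is.na(cfg$min_area) && cfg$min_area < 0)
    problems <- c(problems, "min_area must be >= 0")
  if (!is.na(cfg$contact_max_distance) && cfg$contact_max_distance < 0)
    problems <- c(problems, "contact_max_distance must be >= 0")
  if (!cfg$connectivity %in% c(6, 18, 26))
    problems <- c(problems, "connectivity must be 6, 18 or 26")
  manual <- !is.na(cfg$manual_threshold)
  otsu <- !is.null(cfg$otsu_mode) && !is.na(cfg$otsu_mode)
  if (manual && otsu)
    problems <- c(problems, paste0(
      "exactly one of manual_threshold / otsu_mode may drive binarisation ",
      "(set otsu_mode to NA when using a manual threshold)"))
  if (!manual && !otsu)
    problems <- c(problems, "one of manual_threshold / otsu_mode is required")
  if (otsu && !cfg$otsu_mode %in% c("global", "adaptive"))
    problems <- c(problems, "otsu_mode must be 'global' or 'adaptive'")
  if (length(problems))
    stop("invalid pipeline configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config> preset '%s'\n", x$preset_name))
  for (f in setdiff(PIPELINE_FIELDS, "preset_name")) {
    v <- x[[f]]
    if (is.list(v)) v <- paste(names(v), unlist(v), sep = "=", collapse = ", ")
    cat(sprintf("  %-22s %s\n", f, paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

#' Published per-software parameter presets
#'
#' Returns the pipeline configuration matching one of the four published
#' analysis chains:
#'
#' * `"fiji"` — rolling-ball background subtraction of radius 50 pixels,
#'   3D connected-component counting, object filter `> 250` voxels.
#'   (The published chain thresholds each channel manually; the preset
#'   defaults to a global Otsu threshold so runs are unattended, and
#'   `manual_threshold` can be set to reproduce a hand-picked cutoff.)
#' * `"cellprofiler"` — intensity rescaling to `[0, 1]`, median filter of
#'   size 5, adaptive two-class Otsu thresholding.
#' * `"ga3"` — rolling ball of 27 µm, z-intensity equalisation, Gaussian
#'   Laplace filter (sigma 2 px), 60 % core / 40 % mantle partition,
#'   parent-child ECM contact counting at 0 µm.
#' * `"imaris"` — Gaussian background subtraction over 60 µm (20 µm for
#'   the collagen-IV channel), 6 µm spot detection for nuclei, surfaces
#'   with 0.6 µm smoothness and 16 µm background diameter, 8 µm touching-
#'   object splitting, 353 µm² size filter, 80 % core / 20 % mantle,
#'   cell-matrix contact at a maximum distance of 0 µm.
#'
#' @param name One of `"fiji"`, `"cellprofiler"`, `"ga3"`, `"imaris"`.
#' @return A `pipeline_config`.
#' @examples
#' preset("ga3")$rolling_ball_radius   # 27 (um)
#' preset("imaris")$split_diameter     # 8 (um)
#' @export
preset <- function(name) {
  switch(name,
    fiji = pipeline_config(
      preset_name = "fiji",
      rolling_ball_radius = 50, rolling_ball_unit = "pixels",
      otsu_mode = "global",
      min_voxels = 250,
      contact_max_distance = NA_real_),
    cellprofiler = pipeline_config(
      preset_name = "cellprofiler",
      rescale = TRUE,
      median_size = 5,
      otsu_mode = "adaptive", adaptive_block = 32,
      contact_max_distance = NA_real_),
    ga3 = pipeline_config(
      preset_name = "ga3",
      rolling_ball_radius = 27, rolling_ball_unit = "um",
      z_equalize = TRUE,
      log_sigma = 2.0,
      otsu_mode = "global",
      min_voxels = 250,
      core_fraction = 0.60,
      contact_max_distance = 0),
    imaris = pipeline_config(
      preset_name = "imaris",
      bg_gauss_length = list(nuclei = 60, insle = 60, alpha = 60, ecm = 20),
      spot_diameter = 6,
      surface_smoothness = 0.6,
      surface_bg_diameter = 16,
      split_diameter = 8,
      min_area = 353,
      otsu_mode = "global",
      core_fraction = 0.80,
      contact_max_distance = 0),
    stop("unknown preset '", name,
         "'; available: fiji, cellprofiler, ga3, imaris"))
}

#' Load / save a pipeline configuration
#'
#' Flat `key: value` text (YAML mapping).  A `preset_name` key seeds the
#' configuration from [preset()] before the remaining keys override it;
#' unknown keys are an error, not a warning, so a preset file cannot
#' silently drift.
#'
#' @param path Config file path.
#' @param cfg A `pipeline_config` (for saving).
#' @return A validated `pipeline_config`; `save_config()` returns `path`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a flat key: value mapping")
  bad <- setdiff(names(raw), PIPELINE_FIELDS)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  base <- if (!is.null(raw$preset_name) && raw$preset_name != "custom")
    preset(raw$preset_name) else pipeline_config()
  raw$preset_name <- NULL
  if (!is.null(raw$bg_gauss_length) && !is.list(raw$bg_gauss_length))
    raw$bg_gauss_length <- as.list(setNames(rep(raw$bg_gauss_length[1], 4),
                                            CHANNEL_ROLES))
  for (f in names(raw)) base[[f]] <- raw[[f]]
  validate_config(base)
  base
}

#' @rdname load_config
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
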