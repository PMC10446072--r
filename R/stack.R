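#' Channel roles understood by the pipelines
#' @export
CHANNEL_ROLES <- c("nuclei", "insle", "alpha", "ecm")

#' Multi-channel 3D image stack
#'
#' A named set of 3D voxel grids (one per fluorescence channel role) that
#' share dimensions and acquisition geometry.  Grids are numeric arrays of
#' dimension `(ny, nx, nz)` with finite, non-negative intensities.
#'
#' @param channels Named list of 3D numeric arrays; names must be channel
#'   roles among `r paste(CHANNEL_ROLES, collapse = ", ")`.
#' @param geometry A [voxel_geometry()].
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(channels, geometry) {
  if (!is.list(channels) || length(channels) == 0)
    stop("`channels` must be a non-empty named list of 3D arrays")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("every channel must be named by its role")
  bad <- setdiff(names(channels), CHANNEL_ROLES)
  if (length(bad))
    stop("unknown channel role(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(CHANNEL_ROLES, collapse = ", "), ")")
  dims <- lapply(channels, function(ch) {
    if (!is.array(ch) || length(dim(ch)) != 3)
      stop("each channel must be a 3D array")
    dim(ch)
  })
  d0 <- dims[[1]]
  if (!all(vapply(dims, function(d) all(d == d0), logical(1))))
    stop("all channel grids must have identical dimensions")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!all(is.finite(ch)))
      stop("channel '", nm, "' contains non-finite intensities")
    if (min(ch) < 0)
      stop("channel '", nm, "' contains negative intensities")
  }
  if (!inherits(geometry, "voxel_geometry"))
    stop("`geometry` must be a voxel_geometry")
  structure(list(channels = channels, geometry = geometry),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<channel_stack> %d channel(s) [%s], %d x %d x %d voxels\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3]))
  print(x$geometry)
  invisible(x)
}

#' @export
dim.channel_stack <- function(x) dim(x$channels[[1]])

#' Labeled 3D object map
#'
#' An integer 3D grid where 0 is background and each positive value
#' identifies one discrete object, paired with the acquisition geometry.
#'
#' @param labels 3D array of non-negative integers.
#' @param geometry A [voxel_geometry()].
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, geometry) {
  if (!is.array(labels) || length(dim(labels)) != 3)
    stop("`labels` must be a 3D array")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || min(labels) < 0)
    stop("labels must be non-negative integers")
  if (!inherits(geometry, "voxel_geometry"))
    stop("`geometry` must be a voxel_geometry")
  structure(list(labels = labels, geometry = geometry,
                 n_objects = n_distinct_labels(labels)),
            class = "label_map")
}

n_distinct_labels <- function(labels) {
  u <- unique(as.integer(labels))
  length(u[u > 0L])
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_map> %d object(s), %d x %d x %d voxels\n",
              x$n_objects, d[1], d[2], d[3]))
  invisible(x)
}

# ---- TIFF I/O ---------------------------------------------------------------

#' Write a channel stack to a multi-page TIFF
#'
#' One page per z-slice, channels interleaved within each slice (page
#' `k = (z - 1) * n_channels + c`).  Integer-valued stacks in
#' `[0, 65535]` are stored as 16-bit samples (bit-exact round trip);
#' other stacks must lie in `[0, 1]` and are stored as 32-bit floats
#' (round trip to single precision).  Geometry is not embedded in the
#' file and must be supplied again on reading.
#'
#' @param stack A [channel_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  if (!inherits(stack, "channel_stack")) stop("`stack` must be a channel_stack")
  if (length(stack$channels) == 0) stop("empty channel map")
  d <- dim(stack$channels[[1]])
  vals <- unlist(lapply(stack$channels, range), use.names = FALSE)
  integerish <- all(vapply(stack$channels,
                           function(ch) all(ch == floor(ch)), logical(1)))
  bits <- if (integerish && max(vals) <= 65535) 16L else 32L
  if (bits == 32L && (max(vals) > 1 || min(vals) < 0))
    stop("float stacks must have intensities in [0, 1] for TIFF storage; ",
         "rescale (e.g. rescale_intensity()) before writing")
  pages <- vector("list", d[3] * length(stack$channels))
  k <- 1L
  for (z in seq_len(d[3])) {
    for (ch in stack$channels) {
      page <- ch[, , z, drop = TRUE]
      if (bits == 16L) page <- page / 65535
      pages[[k]] <- page
      k <- k + 1L
    }
  }
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = bits,
                                 compression = "deflate", reduce = FALSE),
                 error = function(e) stop("cannot write TIFF at '", path,
                                          "': ", conditionMessage(e)))
  invisible(path)
}

#' Read a channel stack from a multi-page TIFF
#'
#' Inverse of [write_stack()]: pages are interpreted as z-slices with the
#' given channel roles interleaved within each slice.
#'
#' @param path TIFF file written by [write_stack()] (or any multi-page
#'   greyscale TIFF with the same layout).
#' @param channel_roles Character vector of roles in page order within a
#'   slice.
#' @param geometry A [voxel_geometry()]; TIFF carries no trusted pixel
#'   size here, so the acquisition geometry is always caller-supplied.
#' @return A [channel_stack()].
#' @export
read_stack <- function(path, channel_roles, geometry) {
  if (!file.exists(path)) stop("file not found: ", path)
  nch <- length(channel_roles)
  if (nch == 0) stop("`channel_roles` must name at least one channel")
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  np <- length(pages)
  if (np %% nch != 0)
    stop("format error: ", np, " page(s) not divisible by ", nch,
         " channel role(s); expected slices interleaved as ",
         "(z1 c1, z1 c2, ..., z2 c1, ...)")
  nz <- np %/% nch
  d2 <- dim(pages[[1]])
  bits <- attr(pages[[1]], "bits.per.sample")
  int_stored <- !is.null(bits) && bits <= 16
  channels <- lapply(seq_len(nch), function(c) {
    arr <- array(0, dim = c(d2[1], d2[2], nz))
    for (z in seq_len(nz)) {
      page <- pages[[(z - 1L) * nch + c]]
      if (length(dim(page)) == 3) page <- page[, , 1]
      arr[, , z] <- page
    }
    if (int_stored) {
      # integer samples come back scaled to [0, 1]; restore the counts
      arr <- round(arr * (2^bits - 1))
    } else {
      # float compression can introduce ~1e-10 undershoot below zero
      arr[arr < 0] <- 0
    }
    arr
  })
  names(channels) <- channel_roles
  channel_stack(channels, geometry)
}

# ---- CSV I/O for tables -----------------------------------------------------

OBJECT_TABLE_COLS <- c("object_id", "channel", "centroid_x", "centroid_y",
                       "centroid_z", "voxel_count", "volume",
                       "max_slice_area", "mean_intensity", "region")

GROUND_TRUTH_COLS <- c("cell_id", "cell_type", "centre_x", "centre_y",
                       "centre_z", "nucleus_radius", "cell_radius",
                       "region", "ecm_contact")

#' Write / read per-object measurement tables
#'
#' Plain CSV with a fixed header (`r paste(OBJECT_TABLE_COLS, collapse=", ")`),
#' centroids in µm, volumes in µm³ and areas in µm².
#'
#' @param objects Object table (`data.frame`).
#' @param path CSV path.
#' @return `path` invisibly; `read_object_table()` returns the data frame.
#' @export
write_object_table <- function(objects, path) {
  stopifnot(is.data.frame(objects))
  missing <- setdiff(OBJECT_TABLE_COLS, names(objects))
  if (length(missing))
    stop("object table lacks column(s): ", paste(missing, collapse = ", "))
  write.csv(objects[OBJECT_TABLE_COLS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_object_table
#' @export
read_object_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(OBJECT_TABLE_COLS, names(df))
  if (length(missing))
    stop("not an object table; missing column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Write / read simulator ground truth
#'
#' Plain CSV with a fixed header (`r paste(GROUND_TRUTH_COLS, collapse=", ")`),
#' centres and radii in µm.
#'
#' @param truth Ground-truth table (`data.frame`).
#' @param path CSV path.
#' @return `path` invisibly; `read_ground_truth()` returns the data frame.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(is.data.frame(truth))
  missing <- setdiff(GROUND_TRUTH_COLS, names(truth))
  if (length(missing))
    stop("ground truth lacks column(s): ", paste(missing, collapse = ", "))
  write.csv(truth[GROUND_TRUTH_COLS], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(GROUND_TRUTH_COLS, names(df))
  if (length(missing))
    stop("not a ground-truth table; missing column(s): ",
         paste(missing, collapse = ", "))
  df$ecm_contact <- as.logical(df$ecm_contact)
  df
}
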