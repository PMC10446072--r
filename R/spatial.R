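#' Whole-spheroid mask from the nuclei channel
#'
#' Global Otsu threshold, morphological closing with a Euclidean ball
#' (physical radius, anisotropy-aware, via distance transforms),
#' per-slice hole filling, and retention of the largest connected
#' component, giving one solid aggregate mask.
#'
#' @param nuclei 3D numeric array (nuclei channel).
#' @param geometry A [voxel_geometry()].
#' @param closing_radius Closing ball radius, µm.
#' @return Logical 3D array.
#' @export
spheroid_mask <- function(nuclei, geometry, closing_radius = 10) {
  nuclei <- as_grid3(nuclei)
  if (max(nuclei) == min(nuclei))
    stop("empty foreground: nuclei channel is constant")
  binary <- threshold_otsu(nuclei, "global")
  if (!any(binary)) stop("empty foreground after Otsu thresholding")
  d <- dim(binary)
  sp <- voxel_spacing(geometry)
  # closing = erosion of the dilation, both with a Euclidean ball
  dil <- array(sqrt(edt_sq3_cpp(as.logical(binary), d, sp)$dist_sq) <=
                 closing_radius, dim = d)
  clo <- array(sqrt(edt_sq3_cpp(!dil, d, sp)$dist_sq) > closing_radius,
               dim = d)
  clo <- (clo & dil) | binary  # closing is extensive: never lose mask voxels
  # fill holes slice by slice: background not reachable from the border
  for (z in seq_len(d[3])) {
    sl <- clo[, , z, drop = TRUE]
    bglab <- cc_label3_cpp(array(!sl, dim = c(d[1], d[2], 1L)),
                           c(d[1], d[2], 1L), 6L)
    bglab <- matrix(bglab, d[1], d[2])
    border <- unique(c(bglab[1, ], bglab[d[1], ], bglab[, 1], bglab[, d[2]]))
    border <- border[border > 0L]
    hole <- !sl & !(bglab %in% border)
    if (any(hole)) clo[, , z] <- sl | matrix(hole, d[1], d[2])
  }
  lab <- cc_label3_cpp(clo, d, 26L)
  n <- attr(lab, "n_objects")
  if (n == 0) stop("empty foreground after closing")
  if (n > 1) {
    counts <- tabulate(lab[lab > 0L], nbins = n)
    keep <- which.max(counts)
    clo <- array(lab == keep, dim = d)
  }
  clo
}

#' Volumetric core/mantle partition
#'
#' Implements the erode-to-a-volume-fraction rule: the core is the set
#' of mask voxels whose physical distance to the mask surface exceeds a
#' cutoff chosen so that the achieved core-volume fraction is as close
#' as possible to `core_fraction` (continuous erosion via the Euclidean
#' distance transform, so shells have uniform µm thickness despite
#' anisotropic voxels, with sub-voxel refinement by distance
#' thresholding).  The mantle is the remainder of the mask.
#'
#' @param mask Logical 3D array (spheroid mask).
#' @param core_fraction Target core-volume fraction in (0, 1).
#' @param geometry A [voxel_geometry()].
#' @return A `region_partition`: `core_mask`, `mantle_mask`,
#'   `achieved_core_fraction`, `geometry`.
#' @export
core_mantle_partition <- function(mask, core_fraction, geometry) {
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1))
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("mask is empty")
  if (core_fraction <= 0 || core_fraction >= 1)
    stop("core_fraction must lie in (0, 1)")
  n <- sum(mask)
  if (n < 2) stop("mask too small to partition")
  d <- dim(mask)
  sp <- voxel_spacing(geometry)
  dist <- array(sqrt(edt_sq3_cpp(!mask, d, sp)$dist_sq), dim = d)
  k <- min(max(round(core_fraction * n), 1), n - 1)
  # continuous erosion: keep the k deepest voxels.  Ties at the cutoff
  # distance are broken deterministically in scan order so the achieved
  # fraction equals k / n up to one voxel.
  idx <- which(mask)
  dv <- dist[idx]
  ds <- sort(dv, decreasing = TRUE)
  t <- ds[k]
  deep <- idx[dv > t]
  ties <- idx[dv == t]
  need <- k - length(deep)
  core_idx <- c(deep, ties[seq_len(max(need, 0))])
  core <- array(FALSE, dim = d)
  core[core_idx] <- TRUE
  achieved <- length(core_idx) / n
  structure(list(core_mask = core, mantle_mask = mask & !core,
                 achieved_core_fraction = achieved, geometry = geometry),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf(
    "<region_partition> achieved core fraction %.3f (%d core / %d mantle voxels)\n",
    x$achieved_core_fraction, sum(x$core_mask), sum(x$mantle_mask)))
  invisible(x)
}

table_positions_um <- function(tab) {
  if (all(c("centroid_x", "centroid_y", "centroid_z") %in% names(tab)))
    cbind(tab$centroid_x, tab$centroid_y, tab$centroid_z)
  else if (all(c("centre_x", "centre_y", "centre_z") %in% names(tab)))
    cbind(tab$centre_x, tab$centre_y, tab$centre_z)
  else stop("table has neither centroid_* nor centre_* columns")
}

#' Assign objects to core or mantle by centroid
#'
#' @param objects Object table (or ground truth) with centroid/centre
#'   columns in µm.
#' @param partition A `region_partition` from [core_mantle_partition()].
#' @return `objects` with `region` set to core / mantle / unassigned;
#'   per-region counts in `attr(, "region_counts")`.
#' @export
assign_regions <- function(objects, partition) {
  stopifnot(inherits(partition, "region_partition"))
  d <- dim(partition$core_mask)
  if (nrow(objects) == 0) {
    objects$region <- character(0)
    attr(objects, "region_counts") <-
      c(core = 0L, mantle = 0L, unassigned = 0L)
    return(objects)
  }
  idx <- um_to_voxel_index(table_positions_um(objects), d,
                           partition$geometry)
  lin <- idx[, 1] + d[1] * (idx[, 2] - 1) + d[1] * d[2] * (idx[, 3] - 1)
  region <- ifelse(partition$core_mask[lin], "core",
                   ifelse(partition$mantle_mask[lin], "mantle",
                          "unassigned"))
  objects$region <- region
  attr(objects, "region_counts") <- c(
    core = sum(region == "core"), mantle = sum(region == "mantle"),
    unassigned = sum(region == "unassigned"))
  objects
}

#' Layer-based (manual-style) core/mantle assignment
#'
#' Emulates the manual convention: an object is mantle when its centroid
#' lies within `n_layers * cell_diameter` of the mask surface, core
#' otherwise.
#'
#' @param objects Object or ground-truth table with positions in µm.
#' @param mask Logical 3D spheroid mask.
#' @param n_layers Number of peripheral cell layers counted as mantle.
#' @param cell_diameter One cell layer's thickness, µm.
#' @param geometry A [voxel_geometry()].
#' @return Character vector of region labels, one per row.
#' @export
layer_based_regions <- function(objects, mask, n_layers, cell_diameter,
                                geometry) {
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1))
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  if (!any(mask)) stop("mask is empty")
  if (nrow(objects) == 0) return(character(0))
  d <- dim(mask)
  sp <- voxel_spacing(geometry)
  dist <- sqrt(edt_sq3_cpp(!array(as.logical(mask), dim = d), d,
                           sp)$dist_sq)
  idx <- um_to_voxel_index(table_positions_um(objects), d, geometry)
  lin <- idx[, 1] + d[1] * (idx[, 2] - 1) + d[1] * d[2] * (idx[, 3] - 1)
  ifelse(dist[lin] <= n_layers * cell_diameter, "mantle", "core")
}

#' Object-based cell-ECM contact counting
#'
#' For every child object the minimum voxel-centre distance to any
#' parent voxel is computed from one Euclidean distance transform of the
#' parent foreground.  With `adjacency = TRUE` (default) the
#' surface-to-surface distance is taken as that minimum minus one voxel
#' diagonal, floored at zero, so at `max_distance = 0` a child counts as
#' interacting when it overlaps *or touches* (26-adjacency) a parent;
#' with `adjacency = FALSE` the raw voxel-centre distance is used and
#' `max_distance = 0` demands actual voxel overlap.
#'
#' @param children A [label_map()] of child objects (cells).
#' @param parents A [label_map()] of parent objects (ECM).
#' @param max_distance Maximum surface distance, µm (default 0).
#' @param geometry A [voxel_geometry()]; defaults to the children's.
#' @param adjacency Count touching (26-adjacent) voxels as contact at
#'   distance 0.
#' @return `data.frame(child_id, nearest_parent, distance, interacting)`
#'   with the interacting-children count in `attr(, "n_interacting")`.
#' @export
object_contacts <- function(children, parents, max_distance = 0,
                            geometry = children$geometry,
                            adjacency = TRUE) {
  stopifnot(inherits(children, "label_map"), inherits(parents, "label_map"))
  d <- dim(children$labels)
  if (!all(d == dim(parents$labels)))
    stop("children and parents label maps must share dimensions")
  nch <- max(children$labels)
  if (nch == 0) {
    out <- data.frame(child_id = integer(0), nearest_parent = integer(0),
                      distance = numeric(0), interacting = logical(0))
    attr(out, "n_interacting") <- 0L
    return(out)
  }
  sp <- voxel_spacing(geometry)
  voxel_diag <- sqrt(sum(sp^2))
  if (max(parents$labels) == 0) {
    out <- data.frame(child_id = seq_len(nch),
                      nearest_parent = NA_integer_,
                      distance = Inf, interacting = FALSE)
    attr(out, "n_interacting") <- 0L
    return(out)
  }
  ed <- edt_sq3_cpp(parents$labels > 0L, d, sp)
  res <- child_min_dist_cpp(children$labels, ed$dist_sq, ed$nearest,
                            as.integer(parents$labels), as.integer(nch))
  surf <- if (adjacency) pmax(sqrt(res$min_dist_sq) - voxel_diag, 0)
          else sqrt(res$min_dist_sq)
  interacting <- surf <= max_distance
  out <- data.frame(child_id = seq_len(nch),
                    nearest_parent = res$nearest_parent,
                    distance = surf, interacting = interacting)
  attr(out, "n_interacting") <- sum(interacting)
  out
}
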