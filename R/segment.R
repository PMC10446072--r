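# scalar Otsu threshold over a numeric vector: 256-bin histogram between
# min and max, exhaustive between-class variance maximisation, ties broken
# toward the lower threshold.  Returns a value t; foreground is >= t.
otsu_threshold_values <- function(v, n_bins = 256L) {
  rng <- range(v)
  if (diff(rng) == 0)
    stop("constant grid: no Otsu threshold exists")
  h <- tabulate(pmin(as.integer((v - rng[1]) / diff(rng) * n_bins) + 1L,
                     n_bins), nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  k <- which.max(sb2)  # first (lowest) maximiser
  rng[1] + k / n_bins * diff(rng)  # upper edge of bin k
}

#' Otsu thresholding (global or adaptive)
#'
#' Global mode computes a single threshold by exhaustive between-class
#' variance maximisation over a 256-bin histogram.  Adaptive mode
#' computes a local Otsu threshold per `block`-voxel cube, clips block
#' thresholds into `[0.7, 1.5]` times the global threshold (so blocks
#' containing only background cannot invent foreground), and
#' interpolates thresholds trilinearly between block centres.
#' Foreground is `grid >= threshold`.
#'
#' @param grid 3D numeric array with at least two distinct values.
#' @param mode `"global"` or `"adaptive"`.
#' @param block Adaptive block edge length in voxels.
#' @return Logical array of the grid's dimensions.
#' @export
threshold_otsu <- function(grid, mode = c("global", "adaptive"), block = 32) {
  grid <- as_grid3(grid)
  mode <- match.arg(mode)
  t_global <- otsu_threshold_values(as.vector(grid))
  if (mode == "global") return(array(grid >= t_global, dim = dim(grid)))
  d <- dim(grid)
  nb <- pmax(1L, as.integer(ceiling(d / block)))
  starts <- lapply(1:3, function(a) floor(seq(0, d[a], length.out = nb[a] + 1)))
  centres <- lapply(1:3, function(a)
    (head(starts[[a]], -1) + starts[[a]][-1] + 1) / 2)
  tb <- array(NA_real_, dim = nb)
  for (i in seq_len(nb[1])) for (j in seq_len(nb[2])) for (k in seq_len(nb[3])) {
    sub <- grid[(starts[[1]][i] + 1):starts[[1]][i + 1],
                (starts[[2]][j] + 1):starts[[2]][j + 1],
                (starts[[3]][k] + 1):starts[[3]][k + 1]]
    tb[i, j, k] <- tryCatch(otsu_threshold_values(as.vector(sub)),
                            error = function(e) NA_real_)
  }
  tb[is.na(tb)] <- t_global
  tb <- pmin(pmax(tb, 0.7 * t_global), 1.5 * t_global)
  thr <- interp_block_grid(tb, centres, d)
  array(grid >= thr, dim = d)
}

# trilinear interpolation of block-centre values to every voxel
interp_block_grid <- function(tb, centres, d) {
  w <- lapply(1:3, function(a) {
    cc <- centres[[a]]
    pos <- seq_len(d[a])
    if (length(cc) == 1)
      return(list(lo = rep(1L, d[a]), hi = rep(1L, d[a]),
                  t = rep(0, d[a])))
    lo <- pmin(pmax(findInterval(pos, cc), 1L), length(cc) - 1L)
    t <- (pos - cc[lo]) / (cc[lo + 1] - cc[lo])
    list(lo = lo, hi = lo + 1L, t = pmin(pmax(t, 0), 1))
  })
  out <- array(0, dim = d)
  # interpolate along z for each (by, bx) plane first, then y, then x
  nzb <- dim(tb)[3]
  tz <- array(0, dim = c(dim(tb)[1], dim(tb)[2], d[3]))
  for (z in seq_len(d[3])) {
    lo <- w[[3]]$lo[z]; hi <- w[[3]]$hi[z]; t <- w[[3]]$t[z]
    tz[, , z] <- (1 - t) * tb[, , lo] + t * tb[, , hi]
  }
  ty <- array(0, dim = c(d[1], dim(tb)[2], d[3]))
  for (y in seq_len(d[1])) {
    lo <- w[[1]]$lo[y]; hi <- w[[1]]$hi[y]; t <- w[[1]]$t[y]
    ty[y, , ] <- (1 - t) * tz[lo, , ] + t * tz[hi, , ]
  }
  for (x in seq_len(d[2])) {
    lo <- w[[2]]$lo[x]; hi <- w[[2]]$hi[x]; t <- w[[2]]$t[x]
    out[, x, ] <- (1 - t) * ty[, lo, ] + t * ty[, hi, ]
  }
  out
}

#' Manual threshold
#'
#' @param grid 3D numeric array.
#' @param value Cutoff; foreground is `grid >= value`.
#' @return Logical array.
#' @export
threshold_manual <- function(grid, value) {
  grid <- as_grid3(grid)
  array(grid >= value, dim = dim(grid))
}

#' 3D connected-component labeling
#'
#' Maximal connected foreground components are labeled 1..K in scan
#' order (column-major order of first encounter).
#'
#' @param binary Logical 3D array.
#' @param connectivity 6, 18 or 26 (default 26, matching common 3D
#'   object-counter behaviour).
#' @param geometry A [voxel_geometry()].
#' @return A [label_map()].
#' @export
label_components <- function(binary, connectivity = 26,
                             geometry = voxel_geometry(1, 1)) {
  if (is.matrix(binary)) binary <- array(binary, dim = c(dim(binary), 1))
  stopifnot(is.array(binary), length(dim(binary)) == 3)
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  lab <- cc_label3_cpp(as.logical(binary), dim(binary),
                       as.integer(connectivity))
  label_map(array(lab, dim = dim(binary)), geometry)
}

#' Remove objects below size cutoffs
#'
#' An object survives when its voxel count is strictly greater than
#' `min_voxels` (the published "filter size > 250" is a strict
#' inequality) and its largest single-slice cross-sectional area is at
#' least `min_area` µm² (the published "filtered out any object size
#' below 353 µm²" removes only areas strictly below the cutoff).
#' Survivors are relabeled 1..K preserving order.
#'
#' @param labels A [label_map()].
#' @param min_voxels Voxel-count cutoff (strict >; 0 keeps everything).
#' @param min_area Maximum-cross-section cutoff in µm² (>=; 0 keeps
#'   everything).
#' @param geometry Geometry used for the area conversion; defaults to
#'   the label map's own.
#' @return A filtered [label_map()].
#' @export
size_filter <- function(labels, min_voxels = 0, min_area = 0,
                        geometry = labels$geometry) {
  stopifnot(inherits(labels, "label_map"))
  k <- max(labels$labels)
  if (k == 0) return(labels)
  st <- object_stats_cpp(labels$labels, array(0, dim = dim(labels$labels)),
                         dim(labels$labels), as.integer(k))
  area <- st$max_slice_count * geometry$pixel_size_xy^2
  keep <- st$count > min_voxels & area >= min_area
  remap <- integer(k)
  remap[keep] <- seq_len(sum(keep))
  new_lab <- labels$labels
  pos <- new_lab > 0L
  new_lab[pos] <- remap[new_lab[pos]]
  label_map(new_lab, geometry)
}

#' Split touching objects with a distance-transform watershed
#'
#' Seeds are local maxima of the Euclidean distance transform (computed
#' with physical spacing), with maxima closer than `seed_diameter / 2`
#' (one expected-object radius) suppressed in favour of the deeper one;
#' fused blobs are flooded from those seeds along increasing negative
#' distance.  Two objects of diameter `seed_diameter` whose centres
#' overlap by 25% are therefore still split, while a single convex
#' object keeps one seed.  Connected components that receive no seed
#' remain whole.
#'
#' @param binary Logical 3D array.
#' @param seed_diameter Minimum seed separation, µm.
#' @param geometry A [voxel_geometry()].
#' @param connectivity Flooding/labeling connectivity.
#' @return A [label_map()].
#' @export
watershed_split <- function(binary, seed_diameter, geometry,
                            connectivity = 26) {
  if (is.matrix(binary)) binary <- array(binary, dim = c(dim(binary), 1))
  stopifnot(is.array(binary), length(dim(binary)) == 3)
  if (seed_diameter <= 0) stop("`seed_diameter` must be strictly positive")
  d <- dim(binary)
  mask <- as.logical(binary)
  if (!any(mask)) return(label_map(array(0L, dim = d), geometry))
  sp <- voxel_spacing(geometry)
  ed <- edt_sq3_cpp(!mask, d, sp)   # distance of foreground to background
  dist <- sqrt(ed$dist_sq)
  dist[!mask] <- 0
  maxima <- local_max3_cpp(dist, d, 26L, 0)
  # collapse plateau maxima to one candidate per connected maxima cluster
  clus <- cc_label3_cpp(maxima, d, 26L)
  nclus <- attr(clus, "n_objects")
  seeds_idx <- integer(0)
  if (nclus > 0) {
    idx <- which(clus > 0L)
    reps <- idx[!duplicated(clus[idx])]
    ord <- order(-dist[reps])
    reps <- reps[ord]
    coords <- arrayInd(reps, d)
    pos <- cbind((coords[, 2] - 0.5) * sp[2], (coords[, 1] - 0.5) * sp[1],
                 (coords[, 3] - 0.5) * sp[3])
    kept <- integer(0)
    for (i in seq_along(reps)) {
      if (length(kept) == 0) { kept <- i; next }
      dd <- sqrt(rowSums((pos[kept, , drop = FALSE] -
                          matrix(pos[i, ], length(kept), 3,
                                 byrow = TRUE))^2))
      if (all(dd >= seed_diameter / 2)) kept <- c(kept, i)
    }
    seeds_idx <- reps[kept]
  }
  seeds <- array(0L, dim = d)
  seeds[seeds_idx] <- seq_along(seeds_idx)
  lab <- watershed3_cpp(-dist, seeds, mask, d, as.integer(connectivity))
  lab <- array(lab, dim = d)
  # components without any seed keep their identity
  left <- mask & lab == 0L
  if (any(left)) {
    extra <- cc_label3_cpp(left, d, as.integer(connectivity))
    nex <- attr(extra, "n_objects")
    sel <- extra > 0L
    lab[sel] <- length(seeds_idx) + extra[sel]
  }
  # relabel consecutively in scan order of first encounter
  u <- unique(as.integer(lab[lab > 0L]))
  remap <- integer(max(u))
  remap[u] <- seq_along(u)
  pos <- lab > 0L
  lab[pos] <- remap[lab[pos]]
  label_map(lab, geometry)
}

#' Detect blob-like spots (nucleus counting)
#'
#' Laplacian-of-Gaussian blob detection at the physical scale
#' `sigma = diameter / (2 * sqrt(2))`, applied with anisotropy-corrected
#' voxel sigmas.  Local response maxima above `quality_threshold` become
#' spot records; when `quality_threshold` is `NULL` an automatic cutoff
#' of 10% of the peak response is used.  Duplicates closer than
#' `diameter / 2` are suppressed, keeping the higher response.
#'
#' @param grid 3D numeric array.
#' @param diameter Expected spot diameter, µm.
#' @param quality_threshold Minimum LoG response, or `NULL` for auto.
#' @param geometry A [voxel_geometry()].
#' @param channel Channel role recorded in the returned table.
#' @return An object table with one row per spot (`mean_intensity`
#'   holds the LoG response).
#' @export
detect_spots <- function(grid, diameter, quality_threshold = NULL,
                         geometry, channel = NA_character_) {
  grid <- as_grid3(grid)
  if (diameter <= 0) stop("`diameter` must be strictly positive")
  d <- dim(grid)
  sp <- voxel_spacing(geometry)
  sigma_um <- diameter / (2 * sqrt(2))
  sm <- gaussian_smooth_vox(grid, sigma_um / sp)
  resp <- -sigma_um^2 * laplacian_3d(sm, sp)
  maxima <- which(local_max3_cpp(resp, d, 26L, 0))
  if (length(maxima) == 0) return(empty_object_table(channel))
  vals <- resp[maxima]
  # auto mode keeps every maxima whose response reaches 10% of the peak:
  # permissive enough to count attenuated deep spots, strict enough to
  # reject low-amplitude ripple maxima
  cut <- if (!is.null(quality_threshold)) quality_threshold
         else 0.1 * max(vals)
  keep <- vals >= cut
  maxima <- maxima[keep]; vals <- vals[keep]
  if (length(maxima) == 0) return(empty_object_table(channel))
  ord <- order(-vals)
  maxima <- maxima[ord]; vals <- vals[ord]
  coords <- arrayInd(maxima, d)
  pos <- cbind(x = (coords[, 2] - 0.5) * sp[2],
               y = (coords[, 1] - 0.5) * sp[1],
               z = (coords[, 3] - 0.5) * sp[3])
  kept <- integer(0)
  for (i in seq_along(maxima)) {
    ok <- TRUE
    if (length(kept)) {
      dd <- sqrt(rowSums((pos[kept, , drop = FALSE] -
                          matrix(pos[i, ], length(kept), 3,
                                 byrow = TRUE))^2))
      ok <- all(dd >= diameter / 2)
    }
    if (ok) kept <- c(kept, i)
  }
  data.frame(object_id = seq_along(kept), channel = channel,
             centroid_x = pos[kept, 1], centroid_y = pos[kept, 2],
             centroid_z = pos[kept, 3],
             voxel_count = NA_integer_, volume = NA_real_,
             max_slice_area = NA_real_, mean_intensity = vals[kept],
             region = "unassigned", stringsAsFactors = FALSE)
}

empty_object_table <- function(channel = NA_character_) {
  data.frame(object_id = integer(0), channel = character(0),
             centroid_x = numeric(0), centroid_y = numeric(0),
             centroid_z = numeric(0), voxel_count = integer(0),
             volume = numeric(0), max_slice_area = numeric(0),
             mean_intensity = numeric(0), region = character(0),
             stringsAsFactors = FALSE)
}

#' Surface (cell-body) detection pipeline
#'
#' The documented composition used for cell surfaces: Gaussian smoothing
#' at `smoothness`, Gaussian background subtraction over `bg_diameter`,
#' thresholding (Otsu unless `threshold` is given), connected-component
#' labeling, optional watershed splitting of touching objects, and
#' optional size filtering on the maximum cross-sectional area.
#'
#' @param grid 3D numeric array.
#' @param smoothness Detail smoothness sigma, µm.
#' @param bg_diameter Background subtraction width, µm.
#' @param threshold Manual cutoff or `NULL` for a global Otsu.
#' @param geometry A [voxel_geometry()].
#' @param split_diameter Touching-object seed separation, µm (`NA`
#'   disables splitting).
#' @param min_area Minimum largest-slice area, µm² (0 disables).
#' @param connectivity Labeling connectivity.
#' @return A [label_map()].
#' @export
detect_surfaces <- function(grid, smoothness, bg_diameter, threshold = NULL,
                            geometry, split_diameter = NA, min_area = 0,
                            connectivity = 26) {
  grid <- as_grid3(grid)
  g <- gaussian_smooth(grid, smoothness, geometry)
  g <- gaussian_background_subtract(g, bg_diameter, geometry)
  if (max(g) == min(g))
    return(label_map(array(0L, dim = dim(g)), geometry))
  binary <- if (is.null(threshold)) threshold_otsu(g, "global")
            else threshold_manual(g, threshold)
  if (!any(binary)) return(label_map(array(0L, dim = dim(g)), geometry))
  lm <- if (!is.na(split_diameter))
    watershed_split(binary, split_diameter, geometry, connectivity)
  else label_components(binary, connectivity, geometry)
  if (min_area > 0) lm <- size_filter(lm, 0, min_area, geometry)
  lm
}

#' Measure labeled objects
#'
#' One row per label with intensity-weighted centroid (µm), voxel count,
#' physical volume, maximum single-slice cross-sectional area and mean
#' intensity.  Objects with zero total intensity fall back to the
#' unweighted (geometric) centroid.
#'
#' @param labels A [label_map()].
#' @param intensity 3D numeric array sharing the label map's shape.
#' @param channel Channel role recorded in the table.
#' @return An object table `data.frame`.
#' @export
measure_objects <- function(labels, intensity, channel = NA_character_) {
  stopifnot(inherits(labels, "label_map"))
  intensity <- as_grid3(intensity)
  if (!all(dim(intensity) == dim(labels$labels)))
    stop("intensity grid and label map dimensions differ")
  k <- max(labels$labels)
  if (k == 0) return(empty_object_table(channel))
  g <- labels$geometry
  st <- object_stats_cpp(labels$labels, intensity, dim(intensity),
                         as.integer(k))
  sp <- voxel_spacing(g)
  wsum <- st$sum_intensity
  use_w <- wsum > 0
  my <- ifelse(use_w, st$wsum_y / wsum, st$sum_y / st$count)
  mx <- ifelse(use_w, st$wsum_x / wsum, st$sum_x / st$count)
  mz <- ifelse(use_w, st$wsum_z / wsum, st$sum_z / st$count)
  data.frame(object_id = seq_len(k), channel = channel,
             centroid_x = (mx + 0.5) * sp[2],
             centroid_y = (my + 0.5) * sp[1],
             centroid_z = (mz + 0.5) * sp[3],
             voxel_count = st$count,
             volume = st$count * voxel_volume(g),
             max_slice_area = st$max_slice_count * g$pixel_size_xy^2,
             mean_intensity = st$sum_intensity / st$count,
             region = "unassigned", stringsAsFactors = FALSE)
}
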