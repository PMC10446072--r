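as_grid3 <- function(grid) {
  if (inherits(grid, "channel_stack"))
    stop("pass a single 3D channel grid, e.g. stack$channels$nuclei")
  if (is.matrix(grid)) grid <- array(grid, dim = c(dim(grid), 1))
  if (!is.array(grid) || length(dim(grid)) != 3)
    stop("`grid` must be a 3D numeric array")
  storage.mode(grid) <- "double"
  grid
}

#' Rescale intensities to the full [0, 1] range
#'
#' Affine map sending the grid minimum to 0 and maximum to 1; a constant
#' grid maps to all zeros.
#'
#' @param grid 3D numeric array.
#' @return Rescaled array of the same dimensions.
#' @export
rescale_intensity <- function(grid) {
  grid <- as_grid3(grid)
  if (!all(is.finite(grid))) stop("grid contains non-finite values")
  rng <- range(grid)
  if (diff(rng) == 0) return(array(0, dim = dim(grid)))
  (grid - rng[1]) / diff(rng)
}

#' 3D median filter
#'
#' Replaces every voxel by the median of its `size`^3 neighbourhood;
#' edges use reflected padding.
#'
#' @param grid 3D numeric array.
#' @param size Odd window edge length in voxels.
#' @return Filtered array.
#' @export
median_filter <- function(grid, size) {
  grid <- as_grid3(grid)
  if (size < 1 || size %% 2 != 1) stop("`size` must be an odd integer >= 1")
  if (size == 1) return(grid)
  array(median3_cpp(grid, dim(grid), as.integer(size)), dim = dim(grid))
}

# per-axis separable Gaussian; sigma in voxels (y, x, z); 0 skips the axis.
# Very large sigmas (> 8 voxels) run on a block-mean pyramid: downsample,
# blur at the reduced sigma (compensating the box variance of the block
# mean), then linearly upsample -- accurate to well under a percent for
# the smooth backgrounds such sigmas are used on, and orders of magnitude
# faster than direct convolution.
gaussian_smooth_vox <- function(grid, sigma_vox) {
  d <- dim(grid)
  sigma_vox[is.na(sigma_vox)] <- 0
  f <- ifelse(sigma_vox > 8, pmax(1L, floor(sigma_vox / 3)), 1L)
  if (any(f > 1)) {
    small <- downsample_mean3(grid, f)
    s_red <- sqrt(pmax(sigma_vox^2 - f^2 / 12, 0)) / f
    small <- gaussian_smooth_vox(small, pmin(s_red, 8))
    return(upsample_linear3(small, f, d))
  }
  out <- grid
  for (axis in 0:2) {
    s <- sigma_vox[axis + 1]
    if (s <= 0) next
    r <- max(1L, as.integer(ceiling(4 * s)))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    out <- array(conv1_axis_cpp(out, d, k, axis), dim = d)
  }
  out
}

# block-mean downsample by integer factors (y, x, z), edge-replicated
downsample_mean3 <- function(g, f) {
  d <- dim(g)
  for (a in 1:3) {
    if (f[a] == 1) next
    n2 <- ceiling(d[a] / f[a])
    pad <- n2 * f[a] - d[a]
    if (pad > 0) {
      idx <- lapply(dim(g), seq_len)
      idx[[a]] <- c(seq_len(d[a]), rep(d[a], pad))
      g <- do.call("[", c(list(g), idx, list(drop = FALSE)))
    }
    dd <- dim(g)
    perm <- c(a, setdiff(1:3, a))
    g <- aperm(g, perm)
    g <- array(colMeans(array(g, dim = c(f[a], n2 * prod(dd[-a])))),
               dim = c(n2, dd[perm][-1]))
    g <- aperm(g, order(perm))
    d <- dim(g)
  }
  g
}

# linear upsample of a block-mean pyramid back to dimensions d_out
upsample_linear3 <- function(g, f, d_out) {
  for (a in 1:3) {
    if (f[a] == 1) next
    centres <- (seq_len(dim(g)[a]) - 0.5) * f[a] + 0.5
    pos <- seq_len(d_out[a])
    if (length(centres) == 1) {
      idx <- lapply(dim(g), seq_len)
      idx[[a]] <- rep(1L, d_out[a])
      g <- do.call("[", c(list(g), idx, list(drop = FALSE)))
      next
    }
    lo <- pmin(pmax(findInterval(pos, centres), 1L), length(centres) - 1L)
    t <- pmin(pmax((pos - centres[lo]) / (centres[lo + 1] - centres[lo]),
                   0), 1)
    w <- matrix(0, d_out[a], dim(g)[a])
    w[cbind(pos, lo)] <- 1 - t
    w[cbind(pos, lo + 1L)] <- w[cbind(pos, lo + 1L)] + t
    perm <- c(a, setdiff(1:3, a))
    gp <- aperm(g, perm)
    dd <- dim(gp)
    gp <- w %*% array(gp, dim = c(dd[1], prod(dd[-1])))
    gp <- array(gp, dim = c(d_out[a], dd[-1]))
    g <- aperm(gp, order(perm))
  }
  g
}

#' Gaussian smoothing with a physical sigma
#'
#' Isotropic in physical units: the µm sigma is converted to voxels per
#' axis through the geometry, so anisotropic voxels receive anisotropic
#' voxel sigmas.
#'
#' @param grid 3D numeric array.
#' @param sigma_um Gaussian sigma in µm.
#' @param geometry A [voxel_geometry()].
#' @return Smoothed array.
#' @export
gaussian_smooth <- function(grid, sigma_um, geometry) {
  grid <- as_grid3(grid)
  sp <- voxel_spacing(geometry)
  gaussian_smooth_vox(grid, sigma_um / sp)
}

#' Rolling-ball background subtraction (slice-wise)
#'
#' For each z-slice the background is estimated as the grayscale opening
#' with a ball-shaped (non-flat) structuring element of the given radius
#' and subtracted, clipping at zero, so output <= input everywhere.
#' Large radii use the classic shrink / roll / enlarge scheme (block
#' minimum downscale, opening at reduced radius, bilinear upscale) for
#' speed.
#'
#' @param grid 3D numeric array.
#' @param radius Ball radius, in the unit given by `unit`.
#' @param unit `"pixels"` or `"um"` (µm are converted through the
#'   geometry's lateral pixel size).
#' @param geometry Required when `unit = "um"`.
#' @return Background-subtracted array.
#' @export
rolling_ball_subtract <- function(grid, radius, unit = c("pixels", "um"),
                                  geometry = NULL) {
  grid <- as_grid3(grid)
  unit <- match.arg(unit)
  if (radius <= 0) stop("`radius` must be strictly positive")
  radius_px <- if (unit == "um") {
    if (is.null(geometry)) stop("`geometry` is required for a radius in um")
    radius / geometry$pixel_size_xy
  } else radius
  if (radius_px < 1)
    stop("rolling-ball radius is smaller than one pixel after conversion (",
         signif(radius_px, 3), " px)")
  shrink <- if (radius_px <= 10) 1L else if (radius_px <= 30) 2L
            else if (radius_px <= 100) 4L else 8L
  d <- dim(grid)
  bg <- array(0, dim = d)
  for (z in seq_len(d[3])) {
    sl <- grid[, , z, drop = TRUE]
    if (shrink == 1L) {
      bg[, , z] <- ball_opening_2d(sl, radius_px)
    } else {
      small <- block_min(sl, shrink)
      opened <- ball_opening_2d(small, radius_px / shrink)
      bg[, , z] <- pmin(enlarge_bilinear(opened, shrink, d[1], d[2]), sl)
    }
  }
  pmax(grid - bg, 0)
}

ball_opening_2d <- function(slice, radius_px) {
  d3 <- c(dim(slice), 1L)
  er <- ball_morph2_cpp(array(slice, dim = d3), d3, radius_px, FALSE)
  op <- ball_morph2_cpp(array(er, dim = d3), d3, radius_px, TRUE)
  matrix(op, nrow = d3[1])
}

block_min <- function(m, s) {
  ny <- nrow(m); nx <- ncol(m)
  by <- ceiling(ny / s); bx <- ceiling(nx / s)
  out <- matrix(Inf, by, bx)
  for (a in seq_len(s)) {
    ys <- seq(a, ny, by = s)
    for (b in seq_len(s)) {
      xs <- seq(b, nx, by = s)
      sub <- m[ys, xs, drop = FALSE]
      out[seq_along(ys), seq_along(xs)] <-
        pmin(out[seq_along(ys), seq_along(xs)], sub)
    }
  }
  out
}

enlarge_bilinear <- function(small, s, ny, nx) {
  cy <- (seq_len(nrow(small)) - 0.5) * s + 0.5
  cx <- (seq_len(ncol(small)) - 0.5) * s + 0.5
  tmp <- matrix(0, ny, ncol(small))
  for (j in seq_len(ncol(small)))
    tmp[, j] <- stats::approx(cy, small[, j], xout = seq_len(ny),
                              rule = 2)$y
  out <- matrix(0, ny, nx)
  for (i in seq_len(ny))
    out[i, ] <- stats::approx(cx, tmp[i, ], xout = seq_len(nx), rule = 2)$y
  out
}

#' Equalise intensity across z
#'
#' Rescales each slice so that its robust foreground centre (the median
#' of voxels above the slice's Otsu threshold) matches that of the
#' brightest slice, compensating depth-dependent signal loss.  Slices
#' with no separable foreground are left unscaled and flagged in the
#' attached report (`attr(result, "equalize_report")`: columns `slice`,
#' `scale`, `flagged`).
#'
#' @param grid 3D numeric array.
#' @return Equalised array with a per-slice report attribute.
#' @export
equalize_z <- function(grid) {
  grid <- as_grid3(grid)
  nz <- dim(grid)[3]
  centres <- rep(NA_real_, nz)
  for (z in seq_len(nz)) {
    v <- as.vector(grid[, , z])
    thr <- tryCatch(otsu_threshold_values(v), error = function(e) NA_real_)
    if (!is.na(thr)) {
      fg <- v[v >= thr]
      if (length(fg) > 0 && median(fg) > 0) centres[z] <- median(fg)
    }
  }
  flagged <- is.na(centres)
  if (all(flagged)) {
    report <- data.frame(slice = seq_len(nz), scale = 1, flagged = flagged)
    attr(grid, "equalize_report") <- report
    return(grid)
  }
  ref <- max(centres, na.rm = TRUE)
  scale <- ifelse(flagged, 1, ref / centres)
  for (z in seq_len(nz))
    if (scale[z] != 1) grid[, , z] <- grid[, , z] * scale[z]
  attr(grid, "equalize_report") <-
    data.frame(slice = seq_len(nz), scale = scale, flagged = flagged)
  grid
}

#' Laplacian-of-Gaussian filter (slice-wise)
#'
#' Smooths each z-slice with a 2D Gaussian of the given pixel sigma and
#' applies the negated discrete Laplacian, so bright blobs become
#' positive peaks; the response is multiplied by `sigma^2` for scale
#' normalisation.
#'
#' @param grid 3D numeric array.
#' @param sigma Gaussian sigma in pixels.
#' @return LoG response array.
#' @export
gaussian_laplace <- function(grid, sigma) {
  grid <- as_grid3(grid)
  if (sigma <= 0) stop("`sigma` must be strictly positive")
  sm <- gaussian_smooth_vox(grid, c(sigma, sigma, 0))
  -sigma^2 * laplacian_xy(sm)
}

# discrete 2D Laplacian per slice, reflect edges (pixel units)
laplacian_xy <- function(g) {
  d <- dim(g)
  shift <- function(a, by, axis) {
    idx <- lapply(d, seq_len)
    i <- pmin(pmax(seq_len(d[axis]) + by, 1), d[axis])
    idx[[axis]] <- i
    do.call("[", c(list(a), idx, list(drop = FALSE)))
  }
  shift(g, 1, 1) + shift(g, -1, 1) + shift(g, 1, 2) + shift(g, -1, 2) - 4 * g
}

# 3D Laplacian with physical spacing (µm^-2 units)
laplacian_3d <- function(g, sp) {
  d <- dim(g)
  shift <- function(a, by, axis) {
    idx <- lapply(d, seq_len)
    i <- pmin(pmax(seq_len(d[axis]) + by, 1), d[axis])
    idx[[axis]] <- i
    do.call("[", c(list(a), idx, list(drop = FALSE)))
  }
  (shift(g, 1, 1) + shift(g, -1, 1) - 2 * g) / sp[1]^2 +
  (shift(g, 1, 2) + shift(g, -1, 2) - 2 * g) / sp[2]^2 +
  (shift(g, 1, 3) + shift(g, -1, 3) - 2 * g) / sp[3]^2
}

#' Gaussian (large-structure) background subtraction
#'
#' High-pass filter in the Imaris style: subtracts a Gaussian blur of
#' the image with sigma = `length_um / 2` per axis, clipping at zero, so
#' structures larger than the filter width are removed.  When the sigma
#' falls below half a voxel on the lateral axes the blur degenerates to
#' the identity and the result is all zeros (with a warning).
#'
#' @param grid 3D numeric array.
#' @param length_um Filter width in µm.
#' @param geometry A [voxel_geometry()].
#' @return Background-subtracted array.
#' @export
gaussian_background_subtract <- function(grid, length_um, geometry) {
  grid <- as_grid3(grid)
  if (length_um <= 0) stop("`length_um` must be strictly positive")
  sigma_um <- length_um / 2
  if (sigma_um / geometry$pixel_size_xy < 0.5) {
    warning("background length ", length_um, " um gives a sub-voxel sigma; ",
            "the blur is the identity and the output is all zeros")
    return(array(0, dim = dim(grid)))
  }
  pmax(grid - gaussian_smooth(grid, sigma_um, geometry), 0)
}
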