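#' Synthetic pseudoislet simulation settings
#'
#' Describes one simulated pseudoislet: a spherical aggregate of three
#' cell types (alpha : INS1E : HUVEC seeded at 1:9:5, 1500 cells total by
#' default), imaged as a multi-channel z-stack with depth-dependent signal
#' loss, an anisotropic Gaussian PSF, a smooth background and
#' Poisson-then-Gaussian camera noise.  HUVEC cells carry no cytoplasmic
#' label and appear in the nuclei channel only, so the nucleus count
#' always exceeds the labelled-cell count, as in the real aggregates.
#'
#' @param n_cells Total cells in the aggregate (default 1500).
#' @param type_ratio Positive integer seeding ratio alpha:insle:huvec
#'   (default `c(1, 9, 5)`).
#' @param aggregate_radius Aggregate sphere radius, µm.
#' @param nucleus_radius Nucleus radius, µm (default 3, i.e. 6 µm
#'   diameter).
#' @param cell_radius Whole-cell radius, µm.
#' @param contact_fraction In `(0, 1]`: pairwise centre distances are kept
#'   at or above `contact_fraction * 2 * cell_radius`; 1 means cells just
#'   touch, smaller values compress them into contact.
#' @param mantle_layers Number of peripheral cell layers counted as
#'   mantle in the ground truth (layer thickness = one cell diameter).
#' @param ecm_fibre_count Number of collagen-like fibres.
#' @param fibre_radius Fibre tube radius, µm.
#' @param attenuation_length Depth constant tau of the `exp(-z / tau)`
#'   signal decay, µm; `Inf` disables attenuation.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF sigmas, µm; 0 disables
#'   blurring.
#' @param background_amplitude Smooth background level as a fraction of
#'   the peak signal.
#' @param noise_photons Photon budget at unit intensity for the Poisson
#'   stage; `Inf` disables shot noise.
#' @param noise_read_sd Gaussian read-noise standard deviation (intensity
#'   units); 0 disables it.
#' @param packing_limit Maximum allowed packing density of effective cell
#'   spheres inside the aggregate (random close packing bound).
#' @param seed Integer seed making every simulation stage deterministic.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_cells = 1500,
                              type_ratio = c(alpha = 1, insle = 9, huvec = 5),
                              aggregate_radius = 70,
                              nucleus_radius = 3,
                              cell_radius = 5,
                              contact_fraction = 0.9,
                              mantle_layers = 1,
                              ecm_fibre_count = 40,
                              fibre_radius = 0.8,
                              attenuation_length = 40,
                              psf_sigma_xy = 0.3,
                              psf_sigma_z = 0.9,
                              background_amplitude = 0.1,
                              noise_photons = 150,
                              noise_read_sd = 0.01,
                              packing_limit = 0.64,
                              seed = 0) {
  cfg <- list(n_cells = as.integer(n_cells), type_ratio = type_ratio,
              aggregate_radius = aggregate_radius,
              nucleus_radius = nucleus_radius, cell_radius = cell_radius,
              contact_fraction = contact_fraction,
              mantle_layers = mantle_layers,
              ecm_fibre_count = as.integer(ecm_fibre_count),
              fibre_radius = fibre_radius,
              attenuation_length = attenuation_length,
              psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
              background_amplitude = background_amplitude,
              noise_photons = noise_photons, noise_read_sd = noise_read_sd,
              packing_limit = packing_limit, seed = as.integer(seed))
  if (cfg$n_cells < 0) stop("n_cells must be >= 0")
  if (length(cfg$type_ratio) != 3 || any(cfg$type_ratio <= 0) ||
      any(cfg$type_ratio != floor(cfg$type_ratio)))
    stop("type_ratio must be three positive integers (alpha, insle, huvec)")
  if (cfg$nucleus_radius > cfg$cell_radius)
    stop("nucleus_radius must not exceed cell_radius")
  for (f in c("aggregate_radius", "nucleus_radius", "cell_radius",
              "fibre_radius", "attenuation_length"))
    if (!(cfg[[f]] > 0)) stop(f, " must be strictly positive")
  if (cfg$contact_fraction <= 0 || cfg$contact_fraction > 1)
    stop("contact_fraction must lie in (0, 1]")
  if (cfg$mantle_layers < 0) stop("mantle_layers must be >= 0")
  if (cfg$background_amplitude < 0)
    stop("background_amplitude must be >= 0")
  class(cfg) <- "simulation_config"
  cfg
}

# evaluate expr with a fixed RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# n apportioned by positive integer ratio, largest-remainder rounding;
# ties broken in ratio order
apportion <- function(n, ratio) {
  q <- n * ratio / sum(ratio)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    frac_order <- order(-(q - base), seq_along(q))
    base[frac_order[seq_len(rem)]] <- base[frac_order[seq_len(rem)]] + 1
  }
  as.integer(base)
}

empty_truth <- function() {
  data.frame(cell_id = integer(0), cell_type = character(0),
             centre_x = numeric(0), centre_y = numeric(0),
             centre_z = numeric(0), nucleus_radius = numeric(0),
             cell_radius = numeric(0), region = character(0),
             ecm_contact = logical(0), stringsAsFactors = FALSE)
}

#' Place cells inside the aggregate sphere
#'
#' Cell centres are the `n_cells` sites of a face-centred-cubic lattice
#' closest to the aggregate centre, with the lattice constant chosen so
#' the sphere holds exactly the requested number of cells, each site
#' jittered uniformly within the spacing slack.  This produces the dense,
#' touching, slightly disordered packing of a centrifuged aggregate while
#' guaranteeing all pairwise centre distances respect
#' `contact_fraction * 2 * cell_radius`.  A short repulsive relaxation
#' cleans up any residual violation.  Cell types are apportioned to the
#' seeding ratio by largest-remainder rounding and assigned to positions
#' at random.  Deterministic given `cfg$seed`.
#'
#' Centres are returned in the aggregate frame (aggregate centre at the
#' origin); [simulate_pseudoislet()] shifts them into image coordinates.
#'
#' @param cfg A [simulation_config()].
#' @return A ground-truth `data.frame` (one row per cell) with columns
#'   `cell_id, cell_type, centre_x/y/z, nucleus_radius, cell_radius,
#'   region, ecm_contact`.
#' @export
place_cells <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n <- cfg$n_cells
  if (n == 0) return(empty_truth())
  eff_r <- cfg$contact_fraction * cfg$cell_radius
  max_feasible <- floor(cfg$packing_limit * (cfg$aggregate_radius / eff_r)^3)
  if (n > max_feasible)
    stop("infeasible packing: at most ", max_feasible, " cells of radius ",
         cfg$cell_radius, " um (contact fraction ", cfg$contact_fraction,
         ") fit in an aggregate of radius ", cfg$aggregate_radius, " um")
  R <- cfg$aggregate_radius
  min_d <- cfg$contact_fraction * 2 * cfg$cell_radius
  pts <- with_seed(cfg$seed, {
    # fcc lattice with nearest-neighbour spacing sized so the aggregate
    # sphere holds n sites (fcc density = sqrt(2) / a_nn^3)
    vol <- 4 / 3 * pi * R^3
    a_nn <- max((sqrt(2) * vol / n)^(1 / 3), min_d)
    offs <- matrix(c(0, 0, 0, 0, .5, .5, .5, 0, .5, .5, .5, 0),
                   ncol = 3, byrow = TRUE)
    make_sites <- function(a_nn) {
      a_c <- sqrt(2) * a_nn
      m <- ceiling(R / a_c) + 1
      base <- as.matrix(expand.grid(i = -m:m, j = -m:m, k = -m:m))
      do.call(rbind, lapply(seq_len(4), function(b)
        sweep(base, 2, offs[b, ], "+"))) * a_c
    }
    p <- NULL
    repeat {
      jit <- max(min(0.49 * (a_nn - min_d), 0.3 * a_nn), 0)
      sites <- make_sites(a_nn)
      r2 <- rowSums(sites^2)
      inside <- r2 <= (R - jit)^2
      if (sum(inside) >= n || a_nn <= min_d * 1.0001) {
        sites <- sites[inside, , drop = FALSE]
        if (nrow(sites) < n)
          stop("infeasible packing: lattice placement cannot fit ", n,
               " cells in an aggregate of radius ", R, " um")
        p <- sites[order(rowSums(sites^2))[seq_len(n)], , drop = FALSE]
        break
      }
      a_nn <- max(a_nn * 0.985, min_d)
    }
    if (jit > 0) {
      u <- matrix(rnorm(3 * n), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      p <- p + u * jit * runif(n)^(1 / 3)
    }
    # cleanup relaxation for any residual violation
    for (iter in seq_len(50)) {
      dm <- as.matrix(stats::dist(p))
      dm[upper.tri(dm, diag = TRUE)] <- Inf
      viol <- which(dm < min_d, arr.ind = TRUE)
      if (nrow(viol) == 0) break
      i <- viol[, 1]; j <- viol[, 2]
      v <- p[i, , drop = FALSE] - p[j, , drop = FALSE]
      d <- pmax(sqrt(rowSums(v^2)), 1e-9)
      push <- 0.6 * (min_d - pmin(d, min_d)) / d * v
      disp <- rowsum(rbind(push, -push), c(i, j), reorder = FALSE)
      who <- as.integer(rownames(disp))
      p[who, ] <- p[who, ] + disp
    }
    p
  })
  dm <- as.matrix(stats::dist(pts))
  diag(dm) <- Inf
  if (min(dm) < min_d * (1 - 1e-9))
    stop("packing relaxation failed to converge; lower n_cells or ",
         "contact_fraction")
  counts <- apportion(n, cfg$type_ratio)
  types <- rep(c("alpha", "insle", "huvec"), counts)
  types <- with_seed(cfg$seed + 1L, sample(types))
  data.frame(cell_id = seq_len(n), cell_type = types,
             centre_x = pts[, 1], centre_y = pts[, 2], centre_z = pts[, 3],
             nucleus_radius = cfg$nucleus_radius,
             cell_radius = cfg$cell_radius,
             region = NA_character_, ecm_contact = FALSE,
             stringsAsFactors = FALSE)
}

#' Label ground-truth cells as core or mantle
#'
#' A cell is mantle when its centre lies within
#' `mantle_layers * 2 * cell_radius` (i.e. that many cell diameters) of
#' the aggregate surface, core otherwise.  Operates in the aggregate
#' frame produced by [place_cells()].
#'
#' @param truth Ground truth from [place_cells()].
#' @param cfg The [simulation_config()] used to generate it.
#' @return `truth` with the `region` column filled.
#' @export
assign_truth_regions <- function(truth, cfg) {
  if (nrow(truth) == 0) stop("empty ground truth")
  r <- sqrt(truth$centre_x^2 + truth$centre_y^2 + truth$centre_z^2)
  depth <- cfg$aggregate_radius - r
  thickness <- cfg$mantle_layers * 2 * cfg$cell_radius
  truth$region <- ifelse(depth <= thickness, "mantle", "core")
  truth
}

#' Synthesize the fibrous ECM channel and set contact flags
#'
#' Fibres are random polyline tubes of radius `fibre_radius` confined to
#' the aggregate sphere, rasterised onto the voxel grid.  A cell is in
#' contact with the ECM when its cell sphere reaches at least one fibre
#' voxel centre (surface distance <= 0 µm, the object-based
#' co-localization rule at maximum distance 0).
#'
#' @param truth Ground truth in the aggregate frame.
#' @param cfg A [simulation_config()].
#' @param geometry A [voxel_geometry()].
#' @param dim3 Grid dimensions `(ny, nx, nz)`; defaults to a grid that
#'   contains the aggregate with a small margin.
#' @return `list(fibre_grid = <3D array>, truth = <truth with
#'   ecm_contact set>)`; the fibre grid lives in image coordinates with
#'   the aggregate at the grid centre.
#' @export
synthesize_ecm <- function(truth, cfg, geometry, dim3 = NULL) {
  if (is.null(dim3)) dim3 <- default_grid_dim(cfg, geometry)
  grid <- array(0, dim = dim3)
  truth$ecm_contact <- FALSE
  if (cfg$ecm_fibre_count == 0 || nrow(truth) == 0)
    return(list(fibre_grid = grid, truth = truth))
  sp <- voxel_spacing(geometry)
  centre_um <- grid_centre_um(dim3, geometry)
  R <- cfg$aggregate_radius
  pts <- with_seed(cfg$seed + 2L, {
    out <- list()
    step <- min(sp) / 2
    for (f in seq_len(cfg$ecm_fibre_count)) {
      p <- rnorm(3); p <- p / sqrt(sum(p^2)) * R * runif(1)^(1 / 3)
      dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
      seg <- list(p)
      for (s in seq_len(6)) {
        dirv <- dirv + 0.6 * rnorm(3)
        dirv <- dirv / sqrt(sum(dirv^2))
        q <- seg[[length(seg)]] + dirv * R / 4
        rr <- sqrt(sum(q^2))
        if (rr > R - cfg$fibre_radius) q <- q * ((R - cfg$fibre_radius) / rr)
        seg[[length(seg) + 1]] <- q
      }
      seg <- do.call(rbind, seg)
      for (s in seq_len(nrow(seg) - 1)) {
        a <- seg[s, ]; b <- seg[s + 1, ]
        L <- sqrt(sum((b - a)^2))
        tt <- seq(0, 1, by = step / max(L, step))
        out[[length(out) + 1]] <-
          cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]),
                a[3] + tt * (b[3] - a[3]))
      }
    }
    do.call(rbind, out)
  })
  # centreline voxels, then inflate to tubes with a distance transform
  pix <- um_to_voxel_index(sweep(pts, 2, -centre_um), dim3, geometry)
  centreline <- array(FALSE, dim = dim3)
  centreline[pix] <- TRUE
  ed <- edt_sq3_cpp(as.logical(centreline), as.integer(dim3), sp)
  tube <- array(sqrt(ed$dist_sq) <= cfg$fibre_radius, dim = dim3)
  grid[tube] <- 1
  # exact contact flags: min distance from each cell centre to any fibre
  # voxel centre, searched in a local bounding box
  fib_idx <- which(tube)
  if (length(fib_idx)) {
    reach <- cfg$cell_radius
    for (i in seq_len(nrow(truth))) {
      cpos <- c(truth$centre_x[i], truth$centre_y[i], truth$centre_z[i]) +
        centre_um
      lo <- um_to_voxel_index(matrix(cpos - reach - sp, nrow = 1), dim3,
                              geometry)
      hi <- um_to_voxel_index(matrix(cpos + reach + sp, nrow = 1), dim3,
                              geometry)
      sub <- tube[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      if (!any(sub)) next
      w <- which(sub, arr.ind = TRUE)
      vy <- (w[, 1] + lo[1] - 1 - 0.5) * sp[1]
      vx <- (w[, 2] + lo[2] - 1 - 0.5) * sp[2]
      vz <- (w[, 3] + lo[3] - 1 - 0.5) * sp[3]
      d2 <- (vx - cpos[1])^2 + (vy - cpos[2])^2 + (vz - cpos[3])^2
      if (min(d2) <= reach^2) truth$ecm_contact[i] <- TRUE
    }
  }
  list(fibre_grid = grid, truth = truth)
}

default_grid_dim <- function(cfg, geometry) {
  margin <- 2 * cfg$cell_radius
  side <- 2 * (cfg$aggregate_radius + margin)
  c(ceiling(side / geometry$pixel_size_xy),
    ceiling(side / geometry$pixel_size_xy),
    ceiling(side / geometry$z_step))
}

grid_centre_um <- function(dim3, geometry) {
  sp <- voxel_spacing(geometry)
  c(dim3[2] * sp[2] / 2, dim3[1] * sp[1] / 2, dim3[3] * sp[3] / 2) # x, y, z
}

# stamp value into grid for voxels within radius of centre (physical um)
stamp_sphere <- function(grid, centre_um_xyz, r_in, r_out, geometry, value) {
  d <- dim(grid)
  sp <- voxel_spacing(geometry)
  lo <- um_to_voxel_index(matrix(centre_um_xyz - r_out - sp, 1), d, geometry)
  hi <- um_to_voxel_index(matrix(centre_um_xyz + r_out + sp, 1), d, geometry)
  ys <- lo[1]:hi[1]; xs <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dy <- (ys - 0.5) * sp[1] - centre_um_xyz[2]
  dx <- (xs - 0.5) * sp[2] - centre_um_xyz[1]
  dz <- (zs - 0.5) * sp[3] - centre_um_xyz[3]
  d2 <- outer(outer(dy^2, dx^2, "+"), dz^2, "+")
  sel <- d2 <= r_out^2 & d2 >= r_in^2
  sub <- grid[ys, xs, zs, drop = FALSE]
  sub[sel] <- sub[sel] + value
  grid[ys, xs, zs] <- sub
  grid
}

#' Render a simulated pseudoislet into a multi-channel stack
#'
#' The nuclei channel is the sum of spherical nucleus indicators for all
#' cells; the INS1E and alpha channels are cytoplasmic shells (between
#' nucleus and cell radius) of their respective cell types; the ECM
#' channel is the fibre grid.  Each channel is attenuated with depth by
#' `exp(-z / attenuation_length)`, blurred with the anisotropic Gaussian
#' PSF, offset by a smooth low-frequency background and corrupted with
#' Poisson-then-Gaussian noise; every stage is deterministic given
#' `cfg$seed` and disabled by its neutral parameter (`Inf`, `0`).
#' Channels are finally normalised to peak 1 for storage.
#'
#' @param truth Ground truth in the aggregate frame.
#' @param cfg A [simulation_config()].
#' @param geometry A [voxel_geometry()].
#' @param dim3 Grid dimensions; default fits the aggregate.
#' @param fibre_grid Optional ECM channel from [synthesize_ecm()].
#' @return A [channel_stack()] with channels nuclei, insle, alpha and
#'   (when `fibre_grid` is given) ecm.
#' @export
render <- function(truth, cfg, geometry, dim3 = NULL, fibre_grid = NULL) {
  if (is.null(dim3)) dim3 <- default_grid_dim(cfg, geometry)
  sp <- voxel_spacing(geometry)
  if (cfg$nucleus_radius < max(sp))
    stop("geometry too coarse: nucleus radius ", cfg$nucleus_radius,
         " um is smaller than one voxel (",
         paste(signif(sp, 3), collapse = " x "), " um)")
  centre_um <- grid_centre_um(dim3, geometry)
  nuc <- array(0, dim = dim3)
  ins <- array(0, dim = dim3)
  alp <- array(0, dim = dim3)
  for (i in seq_len(nrow(truth))) {
    cpos <- c(truth$centre_x[i], truth$centre_y[i], truth$centre_z[i]) +
      centre_um
    nuc <- stamp_sphere(nuc, cpos, 0, truth$nucleus_radius[i], geometry, 1)
    if (truth$cell_type[i] == "insle")
      ins <- stamp_sphere(ins, cpos, truth$nucleus_radius[i],
                          truth$cell_radius[i], geometry, 1)
    else if (truth$cell_type[i] == "alpha")
      alp <- stamp_sphere(alp, cpos, truth$nucleus_radius[i],
                          truth$cell_radius[i], geometry, 1)
  }
  channels <- list(nuclei = nuc, insle = ins, alpha = alp)
  if (!is.null(fibre_grid)) channels$ecm <- fibre_grid
  channels <- lapply(seq_along(channels), function(k) {
    g <- channels[[k]]
    if (is.finite(cfg$attenuation_length)) {
      depth <- (seq_len(dim3[3]) - 0.5) * sp[3]
      fac <- exp(-depth / cfg$attenuation_length)
      g <- sweep(g, 3, fac, "*")
    }
    if (cfg$psf_sigma_xy > 0 || cfg$psf_sigma_z > 0)
      g <- gaussian_smooth_vox(g, c(cfg$psf_sigma_xy / sp[1],
                                    cfg$psf_sigma_xy / sp[2],
                                    cfg$psf_sigma_z / sp[3]))
    if (cfg$background_amplitude > 0) {
      bg <- with_seed(cfg$seed + 10L + k, smooth_background(dim3)) *
        cfg$background_amplitude
      g <- g + replicate(dim3[3], bg)
    }
    if (is.finite(cfg$noise_photons))
      g <- with_seed(cfg$seed + 20L + k, {
        array(rpois(length(g), g * cfg$noise_photons) / cfg$noise_photons,
              dim = dim3)
      })
    if (cfg$noise_read_sd > 0)
      g <- with_seed(cfg$seed + 30L + k, {
        pmax(g + array(rnorm(length(g), sd = cfg$noise_read_sd), dim = dim3),
             0)
      })
    m <- max(g)
    if (m > 1) g <- g / m
    g
  })
  names(channels) <- c("nuclei", "insle", "alpha",
                       if (!is.null(fibre_grid)) "ecm")
  channel_stack(channels, geometry)
}

# low-order polynomial background in (x, y), scaled to [0.5, 1]
smooth_background <- function(dim3) {
  xs <- seq(-1, 1, length.out = dim3[2])
  ys <- seq(-1, 1, length.out = dim3[1])
  cf <- rnorm(5, sd = 0.5)
  f <- outer(ys, xs, function(y, x)
    cf[1] * x + cf[2] * y + cf[3] * x * y + cf[4] * x^2 + cf[5] * y^2)
  rng <- range(f)
  if (diff(rng) < 1e-12) return(matrix(0.75, dim3[1], dim3[2]))
  0.5 + 0.5 * (f - rng[1]) / diff(rng)
}

#' Simulate one complete pseudoislet dataset
#'
#' Runs [place_cells()], [assign_truth_regions()], [synthesize_ecm()] and
#' [render()] and returns the stack together with ground truth shifted
#' into image coordinates (aggregate at the grid centre), ready for
#' benchmarking against detections.
#'
#' @inheritParams render
#' @param cfg A [simulation_config()].
#' @return `list(stack = channel_stack, truth = data.frame)`.
#' @export
simulate_pseudoislet <- function(cfg, geometry, dim3 = NULL) {
  if (is.null(dim3)) dim3 <- default_grid_dim(cfg, geometry)
  truth <- place_cells(cfg)
  if (nrow(truth) > 0) truth <- assign_truth_regions(truth, cfg)
  ecm <- synthesize_ecm(truth, cfg, geometry, dim3)
  stack <- render(ecm$truth, cfg, geometry, dim3, fibre_grid = ecm$fibre_grid)
  truth <- ecm$truth
  centre_um <- grid_centre_um(dim3, geometry)
  truth$centre_x <- truth$centre_x + centre_um[1]
  truth$centre_y <- truth$centre_y + centre_um[2]
  truth$centre_z <- truth$centre_z + centre_um[3]
  list(stack = stack, truth = truth)
}
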