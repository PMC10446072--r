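# Independent brute-force oracles and small fixture builders.  Each oracle
# is deliberately written as plain, slow R so it shares no code path with
# the implementation it checks.

# flood-fill (BFS) connected-component labeling
oracle_label <- function(binary, connectivity) {
  d <- dim(binary)
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, ]
  lab <- array(0L, dim = d)
  k <- 0L
  for (start in which(binary)) {
    if (lab[start] != 0L) next
    k <- k + 1L
    queue <- start
    lab[start] <- k
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      pos <- arrayInd(cur, d)
      for (o in seq_len(nrow(offs))) {
        p <- pos + c(offs$dy[o], offs$dx[o], offs$dz[o])
        if (any(p < 1) || any(p > d)) next
        i <- p[1] + d[1] * (p[2] - 1) + d[1] * d[2] * (p[3] - 1)
        if (binary[i] && lab[i] == 0L) { lab[i] <- k; queue <- c(queue, i) }
      }
    }
  }
  lab
}

# two labelings are equal up to renaming of labels
same_partitioning <- function(a, b) {
  if (!all((a > 0) == (b > 0))) return(FALSE)
  fg <- a > 0
  key <- paste(a[fg], b[fg])
  map_ab <- tapply(b[fg], a[fg], function(x) length(unique(x)))
  map_ba <- tapply(a[fg], b[fg], function(x) length(unique(x)))
  all(map_ab == 1) && all(map_ba == 1)
}

# exhaustive neighbourhood median with reflected padding
oracle_median <- function(grid, size) {
  d <- dim(grid)
  r <- size %/% 2
  refl <- function(i, n) {
    period <- 2 * n
    i <- ((i %% period) + period) %% period
    ifelse(i >= n, period - 1 - i, i)
  }
  out <- array(0, dim = d)
  for (z in seq_len(d[3])) for (x in seq_len(d[2])) for (y in seq_len(d[1])) {
    vals <- numeric(0)
    for (c in -r:r) for (b in -r:r) for (a in -r:r) {
      yy <- refl(y - 1 + a, d[1]) + 1
      xx <- refl(x - 1 + b, d[2]) + 1
      zz <- refl(z - 1 + c, d[3]) + 1
      vals <- c(vals, grid[yy, xx, zz])
    }
    out[y, x, z] <- sort(vals)[length(vals) %/% 2 + 1]
  }
  out
}

# exhaustive non-flat ball opening of one slice (clamped edges)
oracle_ball_opening <- function(slice, radius) {
  ny <- nrow(slice); nx <- ncol(slice)
  r <- floor(radius)
  offs <- expand.grid(a = -r:r, b = -r:r)
  offs <- offs[offs$a^2 + offs$b^2 <= radius^2, ]
  offs$h <- sqrt(radius^2 - offs$a^2 - offs$b^2) - radius
  clamp <- function(i, n) pmin(pmax(i, 1), n)
  er <- matrix(0, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx))
    er[y, x] <- min(slice[cbind(clamp(y + offs$a, ny),
                                clamp(x + offs$b, nx))] - offs$h)
  di <- matrix(0, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx))
    di[y, x] <- max(er[cbind(clamp(y + offs$a, ny),
                             clamp(x + offs$b, nx))] + offs$h)
  di
}

# exhaustive global Otsu over 256 histogram levels (between-class variance)
oracle_otsu <- function(v, n_bins = 256) {
  rng <- range(v)
  bin <- pmin(floor((v - rng[1]) / diff(rng) * n_bins) + 1, n_bins)
  h <- tabulate(bin, nbins = n_bins)
  best_k <- NA; best <- -Inf
  n <- length(v)
  for (k in 1:(n_bins - 1)) {
    w0 <- sum(h[1:k]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:k] * (1:k)) / sum(h[1:k])
    mu1 <- sum(h[(k + 1):n_bins] * ((k + 1):n_bins)) / sum(h[(k + 1):n_bins])
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best + 1e-12) { best <- sb; best_k <- k }
  }
  rng[1] + best_k / n_bins * diff(rng)
}

# all-pairs min voxel-centre distance between child and parent objects
oracle_child_distances <- function(child_lab, parent_lab, sp) {
  d <- dim(child_lab)
  coord_um <- function(idx) {
    w <- arrayInd(idx, d)
    cbind(w[, 1] * sp[1] - sp[1] / 2, w[, 2] * sp[2] - sp[2] / 2,
          w[, 3] * sp[3] - sp[3] / 2)
  }
  pcoord <- coord_um(which(parent_lab > 0))
  vapply(seq_len(max(child_lab)), function(ci) {
    cc <- coord_um(which(child_lab == ci))
    if (nrow(pcoord) == 0) return(Inf)
    min(apply(cc, 1, function(p)
      min(sqrt(colSums((t(pcoord) - p)^2)))))
  }, numeric(1))
}

# exhaustive optimal one-to-one matching over all permutations (n <= 8)
oracle_match <- function(pd, pt, radius) {
  nd <- nrow(pd); nt <- nrow(pt)
  dm <- as.matrix(stats::dist(rbind(pd, pt)))[seq_len(nd),
                                              nd + seq_len(nt), drop = FALSE]
  small <- if (nd <= nt) seq_len(nd) else seq_len(nt)
  best <- NULL; best_cost <- Inf; best_n <- -1
  perm_all <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perm_all(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  big_side <- max(nd, nt)
  for (sel in utils::combn(big_side, length(small), simplify = FALSE)) {
    for (perm in perm_all(sel)) {
      pairs <- if (nd <= nt) cbind(seq_len(nd), perm)
               else cbind(perm, seq_len(nt))
      dd <- dm[pairs]
      ok <- dd <= radius
      cost <- sum(dd[ok])
      if (sum(ok) > best_n ||
          (sum(ok) == best_n && cost < best_cost - 1e-12)) {
        best_n <- sum(ok); best_cost <- cost
        best <- pairs[ok, , drop = FALSE]
      }
    }
  }
  list(n = best_n, cost = best_cost, pairs = best)
}

# greedy matching by increasing distance (upper bound on optimal cost)
greedy_match_cost <- function(pd, pt, radius) {
  nd <- nrow(pd); nt <- nrow(pt)
  dm <- as.matrix(stats::dist(rbind(pd, pt)))[seq_len(nd),
                                              nd + seq_len(nt), drop = FALSE]
  cand <- which(dm <= radius, arr.ind = TRUE)
  cand <- cand[order(dm[cand]), , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt)
  n <- 0; cost <- 0
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_d[i] || used_t[j]) next
    used_d[i] <- TRUE; used_t[j] <- TRUE
    n <- n + 1; cost <- cost + dm[i, j]
  }
  list(n = n, cost = cost)
}

# voxelized solid sphere mask of physical radius (µm), centred in the grid
sphere_mask <- function(radius_um, geometry, margin_um = 2) {
  sp <- voxel_spacing(geometry)
  d <- ceiling(2 * (radius_um + margin_um) / sp)
  cen <- d * sp / 2
  ys <- (seq_len(d[1]) - 0.5) * sp[1] - cen[1]
  xs <- (seq_len(d[2]) - 0.5) * sp[2] - cen[2]
  zs <- (seq_len(d[3]) - 0.5) * sp[3] - cen[3]
  array(outer(outer(ys^2, xs^2, "+"), zs^2, "+") <= radius_um^2, dim = d)
}

# grid with hard spheres of radius r at given centres (µm, grid frame)
spheres_grid <- function(centres, r, geometry, dim3) {
  g <- array(0, dim = dim3)
  sp <- voxel_spacing(geometry)
  ys <- (seq_len(dim3[1]) - 0.5) * sp[1]
  xs <- (seq_len(dim3[2]) - 0.5) * sp[2]
  zs <- (seq_len(dim3[3]) - 0.5) * sp[3]
  for (i in seq_len(nrow(centres))) {
    d2 <- outer(outer((ys - centres[i, 2])^2, (xs - centres[i, 1])^2, "+"),
                (zs - centres[i, 3])^2, "+")
    g[d2 <= r^2] <- g[d2 <= r^2] + 1
  }
  g
}

tiny_geometry <- function() voxel_geometry(1, 1)
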