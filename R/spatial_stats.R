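# Point-cloud spatial statistics: border strength, Ripley's L,
# lateral-diffusion profiling and the optical-crowding simulation.

#' Border strength and angle field
#'
#' At each grid point, molecules within `radius_um` are split in half by
#' `n_angles` equally spaced lines through the point; for each split the
#' per-gene count vectors of the two half-disks are compared by Euclidean
#' distance. The border strength is the maximum distance over angles and
#' the border angle is the orientation of the maximizing split line
#' (degrees in [0, 180)). Large strengths mark sharp changes in local
#' expression composition -- candidate anatomical borders.
#'
#' @param molecules data.frame with `gene`, `x`, `y` (microns).
#' @param grid_spacing spacing of the evaluation grid (microns).
#' @param radius_um disk radius.
#' @param n_angles number of split orientations.
#' @param min_molecules disks with fewer molecules are flagged
#'   low-support and get strength 0.
#' @param normalize divide the count distance by the number of molecules
#'   in the disk (off by default: the raw count distance is the metric).
#' @return data.frame x, y, strength, angle_deg, n_molecules, low_support.
#' @export
border_field <- function(molecules, grid_spacing = 50, radius_um = 200,
                         n_angles = 12L, min_molecules = 10L,
                         normalize = FALSE) {
  genes <- sort(unique(molecules$gene))
  if (length(genes) < 2L) stop("need at least 2 genes")
  gi <- match(molecules$gene, genes)
  gx <- seq(min(molecules$x), max(molecules$x), by = grid_spacing)
  gy <- seq(min(molecules$y), max(molecules$y), by = grid_spacing)
  pts <- expand.grid(x = gx, y = gy)
  thetas <- (seq_len(n_angles) - 1L) * pi / n_angles
  out <- data.frame(pts, strength = 0, angle_deg = NA_real_,
                    n_molecules = 0L, low_support = TRUE)
  for (p in seq_len(nrow(pts))) {
    dx <- molecules$x - pts$x[p]
    dy <- molecules$y - pts$y[p]
    sel <- which(dx * dx + dy * dy <= radius_um^2)
    out$n_molecules[p] <- length(sel)
    if (length(sel) < min_molecules) next
    out$low_support[p] <- FALSE
    phi <- atan2(dy[sel], dx[sel])
    g <- gi[sel]
    best <- -Inf; best_th <- NA_real_
    for (k in seq_along(thetas)) {
      # side of the split line with orientation theta
      side <- sin(phi - thetas[k]) > 0
      c1 <- tabulate(g[side], nbins = length(genes))
      c2 <- tabulate(g[!side], nbins = length(genes))
      d <- sqrt(sum((c1 - c2)^2))
      if (normalize) d <- d / length(sel)
      if (d > best) { best <- d; best_th <- thetas[k] }
    }
    out$strength[p] <- best
    out$angle_deg[p] <- best_th * 180 / pi
  }
  out
}

#' Ripley's K and L functions
#'
#' Deviation from complete spatial randomness in a rectangular window:
#' `K(r) = area / n^2 * sum of edge-corrected pair indicators within r`,
#' reported through the variance-stabilized `L(r) = sqrt(K / pi)`.
#' `L(r) - r > 0` indicates clustering at scale r; cell-sized clusters of
#' molecules produce a peak near the typical cell diameter.
#'
#' @param points 2-column matrix / data.frame of coordinates (microns).
#' @param radii radii at which to evaluate (each < half the window size).
#' @param extent c(width, height) of the observation rectangle (origin 0).
#' @param correction edge correction: `"isotropic"` (fraction of the pair
#'   circle inside the window), `"toroidal"`, or `"none"`.
#' @return data.frame r, K, L, L_minus_r.
#' @export
ripley_l <- function(points, radii, extent,
                     correction = c("isotropic", "toroidal", "none")) {
  correction <- match.arg(correction)
  xy <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(xy)
  stopifnot(n >= 2L, all(radii < min(extent) / 2))
  area <- prod(extent)
  if (correction == "toroidal") {
    dx <- abs(outer(xy[, 1L], xy[, 1L], "-"))
    dy <- abs(outer(xy[, 2L], xy[, 2L], "-"))
    dx <- pmin(dx, extent[1L] - dx)
    dy <- pmin(dy, extent[2L] - dy)
    D <- sqrt(dx^2 + dy^2)
  } else {
    D <- as.matrix(stats::dist(xy))
  }
  diag(D) <- Inf
  K <- vapply(radii, function(r) {
    ind <- D <= r
    if (!any(ind)) return(0)
    if (correction == "isotropic") {
      w <- matrix(1, n, n)
      ij <- which(ind, arr.ind = TRUE)
      w[ij] <- 1 / circle_frac_inside(xy[ij[, 1L], 1L], xy[ij[, 1L], 2L],
                                      D[ij], extent)
      sum(w[ind])
    } else sum(ind)
  }, numeric(1L)) * area / n^2
  L <- sqrt(K / pi)
  data.frame(r = radii, K = K, L = L, L_minus_r = L - radii)
}

# Fraction of the circle of radius t centred at (x, y) lying inside the
# rectangle [0, a] x [0, b]. With t < min(a, b) / 2 a circle can cross at
# most one vertical and one horizontal edge; the doubly exterior arc near
# a corner is removed once.
circle_frac_inside <- function(x, y, t, extent) {
  d1 <- pmin(x, extent[1L] - x)
  d2 <- pmin(y, extent[2L] - y)
  a1 <- ifelse(t > d1, acos(pmin(d1 / t, 1)), 0)
  a2 <- ifelse(t > d2, acos(pmin(d2 / t, 1)), 0)
  overlap <- pmax(0, a1 + a2 - pi / 2)
  # corner region is outside both edges: subtract the double count
  ext <- 2 * a1 + 2 * a2 - ifelse(d1^2 + d2^2 < t^2, overlap, 0)
  pmax(1 - ext / (2 * pi), 1e-6)
}

# Plain DBSCAN on 2D points (Euclidean eps-neighbourhoods): core points
# have >= min_samples neighbours (self included); clusters are the
# connected components of core points plus their border points. Returns 0
# for noise.
dbscan_points <- function(x, y, eps, min_samples) {
  n <- length(x)
  pr <- pairs_within(x, y, eps)
  nb <- vector("list", n)
  for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1L]; j <- pr[k, 2L]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  deg <- vapply(nb, length, integer(1L)) + 1L
  core <- deg >= min_samples
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i; labels[i] <- cl
    while (length(queue) > 0L) {
      p <- queue[1L]; queue <- queue[-1L]
      for (q in nb[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Lateral-diffusion profile of a marker gene
#'
#' Clusters the molecules of a cell-type marker with DBSCAN (clusters =
#' putative cells), computes each cluster's centroid, and pools the
#' distances of molecules to their cluster centroid. The radius containing
#' half the molecules summarizes how far molecules spread from their
#' source cell.
#'
#' @param molecules data.frame with `gene`, `x`, `y`.
#' @param marker_gene gene to profile.
#' @param dbscan_eps DBSCAN neighbourhood radius (microns).
#' @param dbscan_min_samples DBSCAN core-point threshold.
#' @param probs CDF probabilities reported.
#' @return list with `n_clusters`, `median_radius` (50% radius),
#'   `radius_cdf` (data.frame prob, radius), `distances`, `cluster`
#'   (per-molecule cluster id, 0 = noise).
#' @export
diffusion_profile <- function(molecules, marker_gene, dbscan_eps = 8,
                              dbscan_min_samples = 5L,
                              probs = seq(0.1, 0.9, by = 0.1)) {
  m <- molecules[molecules$gene == marker_gene, , drop = FALSE]
  if (nrow(m) == 0L) stop("marker gene absent")
  labels <- dbscan_points(m$x, m$y, dbscan_eps, dbscan_min_samples)
  if (all(labels == 0L)) {
    warning("no clusters found")
    return(list(n_clusters = 0L, median_radius = NA_real_,
                radius_cdf = data.frame(prob = probs, radius = NA_real_),
                distances = numeric(0), cluster = labels))
  }
  dists <- numeric(0)
  for (cl in seq_len(max(labels))) {
    idx <- labels == cl
    cx <- mean(m$x[idx]); cy <- mean(m$y[idx])
    dists <- c(dists, sqrt((m$x[idx] - cx)^2 + (m$y[idx] - cy)^2))
  }
  list(n_clusters = max(labels),
       median_radius = stats::median(dists),
       radius_cdf = data.frame(
         prob = probs,
         radius = stats::quantile(dists, probs, names = FALSE)),
       distances = dists, cluster = labels)
}

#' Optical-crowding simulation
#'
#' Scatters an increasing number of points uniformly in a small area and
#' counts how many are resolvable under the diffraction limit: a point is
#' resolvable iff its nearest neighbour is at least `lambda / (2 NA)`
#' away. In the sparse limit the expected resolvable fraction approaches
#' the Poisson nearest-neighbour void probability
#' `exp(-n pi d^2 / A)`.
#'
#' @param n_points_grid vector of point counts to simulate.
#' @param wavelength_nm emission wavelength.
#' @param numerical_aperture objective NA.
#' @param area_um c(width, height) of the simulated area in microns.
#' @param n_rep replicates per point count.
#' @param seed RNG seed.
#' @return data.frame n, fraction_resolvable (mean over replicates),
#'   fraction_sd, d_limit_um.
#' @export
optical_crowding <- function(n_points_grid, wavelength_nm = 660,
                             numerical_aperture = 1.4,
                             area_um = c(10, 10), n_rep = 20L, seed = 1L) {
  stopifnot(numerical_aperture > 0)
  d <- wavelength_nm / (2 * numerical_aperture) / 1000   # um
  set.seed(seed)
  res <- lapply(n_points_grid, function(n) {
    fr <- vapply(seq_len(n_rep), function(rep) {
      x <- stats::runif(n, 0, area_um[1L])
      y <- stats::runif(n, 0, area_um[2L])
      if (n == 1L) return(1)
      D <- as.matrix(stats::dist(cbind(x, y)))
      diag(D) <- Inf
      mean(apply(D, 1L, min) >= d)
    }, numeric(1L))
    data.frame(n = n, fraction_resolvable = mean(fr),
               fraction_sd = stats::sd(fr), d_limit_um = d)
  })
  do.call(rbind, res)
}
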