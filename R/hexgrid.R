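# Hexagonal binning of molecules and connectivity-constrained
# regionalization of the binned expression.

#' Bin molecules into a hexagonal lattice
#'
#' Pointy-top hexagonal lattice in axial coordinates with centre-to-centre
#' spacing `spacing_um`; every molecule is assigned to the nearest hex
#' centre (cube rounding) and hexes receiving no molecules are dropped, so
#' the total binned count equals the number of molecules exactly.
#'
#' @param molecules data.frame with `gene`, `x`, `y` (or `x_um`, `y_um`)
#'   in microns.
#' @param spacing_um distance between adjacent hex centres.
#' @return object of class `hexgrid`: `centers` (data.frame q, r, x, y),
#'   `counts` (sparse genes x hexes matrix), `adjacency` (2-column matrix
#'   of neighbouring hex indices), `spacing`.
#' @export
hexbin_molecules <- function(molecules, spacing_um = 100) {
  stopifnot(spacing_um > 0)
  x <- if ("x" %in% names(molecules)) molecules$x else molecules$x_um
  y <- if ("y" %in% names(molecules)) molecules$y else molecules$y_um
  size <- spacing_um / sqrt(3)          # centre-to-corner size
  qf <- (sqrt(3) / 3 * x - 1 / 3 * y) / size
  rf <- (2 / 3 * y) / size
  ax <- cube_round(qf, rf)
  key <- paste(ax$q, ax$r)
  uk <- unique(key)
  hex_idx <- match(key, uk)
  qr <- do.call(rbind, strsplit(uk, " "))
  q <- as.integer(qr[, 1L]); r <- as.integer(qr[, 2L])
  centers <- data.frame(
    q = q, r = r,
    x = size * (sqrt(3) * q + sqrt(3) / 2 * r),
    y = size * (3 / 2 * r))
  genes <- sort(unique(molecules$gene))
  counts <- Matrix::sparseMatrix(
    i = match(molecules$gene, genes), j = hex_idx, x = 1,
    dims = c(length(genes), length(uk)),
    dimnames = list(genes, uk))
  # axial neighbours of a pointy-top hex
  nb <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1), c(-1, 1))
  adj_i <- integer(0); adj_j <- integer(0)
  pos <- stats::setNames(seq_along(uk), uk)
  for (k in seq_len(nrow(nb))) {
    nk <- paste(q + nb[k, 1L], r + nb[k, 2L])
    hit <- !is.na(pos[nk])
    adj_i <- c(adj_i, which(hit))
    adj_j <- c(adj_j, unname(pos[nk[hit]]))
  }
  keep <- adj_i < adj_j
  structure(list(centers = centers, counts = counts,
                 adjacency = cbind(adj_i[keep], adj_j[keep]),
                 spacing = spacing_um),
            class = "hexgrid")
}

cube_round <- function(qf, rf) {
  sf <- -qf - rf
  q <- round(qf); r <- round(rf); s <- round(sf)
  dq <- abs(q - qf); dr <- abs(r - rf); ds <- abs(s - sf)
  fix_q <- dq > dr & dq > ds
  fix_r <- !fix_q & dr > ds
  q[fix_q] <- -r[fix_q] - s[fix_q]
  r[fix_r] <- -q[fix_r] - s[fix_r]
  list(q = as.integer(q), r = as.integer(r))
}

#' @export
print.hexgrid <- function(x, ...) {
  cat(sprintf("hexgrid: %d hexes (spacing %g um), %d genes, %d molecules\n",
              nrow(x$centers), x$spacing, nrow(x$counts), sum(x$counts)))
  invisible(x)
}

# Per-hex normalization: totals scaled to the median hex total, log1p.
normalize_hex_counts <- function(counts) {
  tot <- Matrix::colSums(counts)
  tot[tot == 0] <- 1
  target <- stats::median(tot)
  log1p(t(as.matrix(counts)) * (target / tot))   # hexes x genes
}

# Ward agglomeration restricted to merges between clusters adjacent in
# the hex graph (Lance-Williams on centroids: cost = n_i n_j / (n_i + n_j)
# * squared centroid distance). Falls back to unconstrained merges only
# if the adjacency graph is disconnected.
constrained_ward <- function(X, adjacency, n_regions) {
  n <- nrow(X)
  stopifnot(n_regions >= 1L, n_regions <= n)
  cl <- seq_len(n)                      # cluster id per element
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  centroid <- X
  adj <- vector("list", n)
  for (k in seq_len(nrow(adjacency))) {
    i <- adjacency[k, 1L]; j <- adjacency[k, 2L]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  n_active <- n
  while (n_active > n_regions) {
    best <- c(NA_integer_, NA_integer_); best_cost <- Inf
    for (i in which(active)) {
      for (j in adj[[i]]) {
        if (j <= i || !active[j]) next
        cost <- size[i] * size[j] / (size[i] + size[j]) *
          sum((centroid[i, ] - centroid[j, ])^2)
        if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
      }
    }
    if (is.na(best[1L])) {
      # disconnected graph: merge the globally cheapest active pair
      act <- which(active)
      for (ii in seq_along(act)) for (jj in seq_len(ii - 1L)) {
        i <- act[jj]; j <- act[ii]
        cost <- size[i] * size[j] / (size[i] + size[j]) *
          sum((centroid[i, ] - centroid[j, ])^2)
        if (cost < best_cost) { best_cost <- cost; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    centroid[i, ] <- (size[i] * centroid[i, ] + size[j] * centroid[j, ]) /
      (size[i] + size[j])
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    cl[cl == j] <- i
    adj[[i]] <- setdiff(unique(c(adj[[i]], adj[[j]])), c(i, j))
    for (k in adj[[j]]) adj[[k]] <- unique(c(setdiff(adj[[k]], j), i))
    n_active <- n_active - 1L
  }
  as.integer(factor(cl))
}

#' Regionalize a hex grid by constrained Ward clustering
#'
#' Per-hex counts are depth-normalized (scaled to the median hex total,
#' log1p), reduced by PCA or a small latent Dirichlet allocation topic
#' model, and clustered by Ward agglomeration constrained to merge only
#' hexes that are neighbours in the lattice, so every region is spatially
#' connected. Region colours are assigned along a 1D spectral embedding of
#' the region-similarity graph (correlation of region mean expression), so
#' transcriptionally similar regions receive similar hues.
#'
#' @param grid a `hexgrid`.
#' @param n_regions number of regions.
#' @param n_components dimensionality of the reduction.
#' @param reduction `"pca"` or `"lda"`.
#' @param seed RNG seed (used by the LDA sampler).
#' @return the grid with `region_labels` (per hex), `region_colors`
#'   (n_regions x 3 RGB in [0,1]) and `region_means` (genes x regions mean
#'   normalized expression) added.
#' @export
regionalize <- function(grid, n_regions, n_components = 10L,
                        reduction = c("pca", "lda"), seed = 1L) {
  reduction <- match.arg(reduction)
  n_hex <- nrow(grid$centers)
  if (n_regions > n_hex) stop("more regions than hexes")
  Xn <- normalize_hex_counts(grid$counts)
  n_components <- min(n_components, ncol(Xn), n_hex)
  if (reduction == "pca") {
    X <- stats::prcomp(Xn, center = TRUE, scale. = FALSE)$x
    X <- X[, seq_len(min(n_components, ncol(X))), drop = FALSE]
  } else {
    X <- lda_topics(as.matrix(grid$counts), n_topics = n_components,
                    seed = seed)
  }
  labels <- constrained_ward(X, grid$adjacency, n_regions)
  means <- sapply(seq_len(n_regions), function(rg)
    colMeans(Xn[labels == rg, , drop = FALSE]))
  means <- matrix(means, ncol = n_regions,
                  dimnames = list(colnames(Xn), NULL))
  grid$region_labels <- labels
  grid$region_colors <- spectral_region_colors(means)
  grid$region_means <- means
  grid
}

# Collapsed-Gibbs latent Dirichlet allocation on the genes x hexes count
# matrix (hexes = documents, genes = words); returns hexes x topics
# proportions. Small fixed iteration budget -- the reduction only feeds a
# clustering, not inference on the topics themselves.
lda_topics <- function(counts, n_topics, alpha = 0.5, beta = 0.1,
                       n_iter = 150L, seed = 1L) {
  set.seed(seed)
  n_genes <- nrow(counts); n_docs <- ncol(counts)
  idx <- which(counts > 0, arr.ind = TRUE)
  gene <- rep(idx[, 1L], counts[idx])
  doc <- rep(idx[, 2L], counts[idx])
  n_tok <- length(gene)
  z <- sample.int(n_topics, n_tok, replace = TRUE)
  ndk <- matrix(0L, n_docs, n_topics)
  nkw <- matrix(0L, n_topics, n_genes)
  nk <- integer(n_topics)
  for (t in seq_len(n_tok)) {
    ndk[doc[t], z[t]] <- ndk[doc[t], z[t]] + 1L
    nkw[z[t], gene[t]] <- nkw[z[t], gene[t]] + 1L
    nk[z[t]] <- nk[z[t]] + 1L
  }
  for (it in seq_len(n_iter)) {
    for (t in seq_len(n_tok)) {
      k <- z[t]; d <- doc[t]; w <- gene[t]
      ndk[d, k] <- ndk[d, k] - 1L; nkw[k, w] <- nkw[k, w] - 1L
      nk[k] <- nk[k] - 1L
      p <- (ndk[d, ] + alpha) * (nkw[, w] + beta) / (nk + n_genes * beta)
      k <- sample.int(n_topics, 1L, prob = p)
      z[t] <- k
      ndk[d, k] <- ndk[d, k] + 1L; nkw[k, w] <- nkw[k, w] + 1L
      nk[k] <- nk[k] + 1L
    }
  }
  theta <- (ndk + alpha) / (rowSums(ndk) + n_topics * alpha)
  theta
}

# Hues along the Fiedler vector of the region-similarity graph so that
# transcriptionally similar regions get similar colours.
spectral_region_colors <- function(region_means, s = 0.65, v = 0.9) {
  k <- ncol(region_means)
  if (k == 1L) return(matrix(grDevices::col2rgb(
    grDevices::hsv(0, s, v)) / 255, 1L, 3L))
  W <- (stats::cor(region_means) + 1) / 2
  diag(W) <- 0
  D <- diag(rowSums(W))
  L <- D - W
  ev <- eigen(L, symmetric = TRUE)
  fiedler <- ev$vectors[, k - 1L]
  ord <- rank(fiedler, ties.method = "first")
  hue <- (ord - 1) / k * 0.85           # stay short of wrapping red->red
  cols <- t(grDevices::col2rgb(grDevices::hsv(hue, s, v)) / 255)
  unname(cols)
}

#' Mix region colours by classifier probability
#'
#' Trains a random-forest classifier on the normalized hex expression with
#' the region labels, then colours each hex by the probability-weighted
#' mixture of region colours, `sum_r P(r | hex) * color_r`. Hexes firmly
#' inside a region keep its colour; hexes along expression gradients
#' blend, revealing gradual transitions that hard labels hide.
#'
#' @param grid a regionalized `hexgrid`.
#' @param n_trees random-forest size.
#' @param seed RNG seed for the forest.
#' @return n_hex x 3 matrix of RGB values in [0, 1].
#' @export
mix_region_colors <- function(grid, n_trees = 100L, seed = 1L) {
  labels <- grid$region_labels
  if (is.null(labels)) stop("grid has no region labels; run regionalize()")
  colors <- grid$region_colors
  if (length(unique(labels)) == 1L) {
    warning("single region: returning flat colour")
    return(matrix(colors[1L, ], nrow(grid$centers), 3L, byrow = TRUE))
  }
  X <- normalize_hex_counts(grid$counts)
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = factor(labels),
                                   ntree = n_trees)
  P <- stats::predict(rf, X, type = "prob")
  lv <- as.integer(colnames(P))        # factor levels back to region ids
  unname(P %*% colors[lv, , drop = FALSE])
}

#' Link regions between two sections by expression correlation
#'
#' Pearson-correlates region mean-expression vectors across two
#' regionalized grids over their shared gene panel, then greedily pairs
#' best matches above `threshold`.
#'
#' @param grid_a,grid_b regionalized `hexgrid`s.
#' @param threshold minimum correlation for a match.
#' @return data.frame region_a, region_b, correlation (best matches,
#'   descending).
#' @export
link_regions <- function(grid_a, grid_b, threshold = 0.7) {
  ma <- grid_a$region_means; mb <- grid_b$region_means
  shared <- intersect(rownames(ma), rownames(mb))
  if (length(shared) == 0L) stop("no shared genes between grids")
  cc <- stats::cor(ma[shared, , drop = FALSE], mb[shared, , drop = FALSE])
  out <- data.frame(region_a = integer(0), region_b = integer(0),
                    correlation = numeric(0))
  while (TRUE) {
    best <- which(cc == max(cc), arr.ind = TRUE)[1L, , drop = FALSE]
    if (!is.finite(cc[best]) || cc[best] < threshold) break
    out <- rbind(out, data.frame(region_a = best[1L], region_b = best[2L],
                                 correlation = cc[best]))
    cc[best[1L], ] <- -Inf
    cc[, best[2L]] <- -Inf
    if (all(!is.finite(cc))) break
  }
  rownames(out) <- NULL
  out
}
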