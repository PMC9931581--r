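test_that("hex binning conserves counts and matches Poisson density", {
  one <- hexbin_molecules(data.frame(gene = "g", x = 3, y = 4), 100)
  expect_identical(nrow(one$centers), 1L)
  expect_identical(sum(one$counts), 1)

  set.seed(2)
  mols <- data.frame(gene = sample(c("a", "b"), 1e5, TRUE),
                     x = runif(1e5, 0, 2000), y = runif(1e5, 0, 2000))
  g <- hexbin_molecules(mols, spacing_um = 100)
  expect_identical(sum(g$counts), 1e5)
  # adjacency is symmetric-by-construction pairs with <= 6 neighbours
  deg <- tabulate(c(g$adjacency), nbins = nrow(g$centers))
  expect_lte(max(deg), 6L)
  # interior hex occupancy approximates density x hex area
  lam <- 1e5 / 2000^2
  hex_area <- sqrt(3) / 2 * 100^2
  tot <- Matrix::colSums(g$counts)
  interior <- g$centers$x > 150 & g$centers$x < 1850 &
    g$centers$y > 150 & g$centers$y < 1850
  expect_lt(abs(mean(tot[interior]) - lam * hex_area),
            2 * sd(tot[interior]) / sqrt(sum(interior)) + 3)
})

test_that("regionalization splits two disjoint-usage domains exactly", {
  mols <- two_domain_molecules(seed = 1L)
  g <- hexbin_molecules(mols, spacing_um = 50)
  for (red in c("pca", "lda")) {
    rg <- regionalize(g, n_regions = 2L, n_components = 3L,
                      reduction = red, seed = 2L)
    a_tot <- Matrix::colSums(g$counts[c("A1", "A2", "A3"), , drop = FALSE])
    b_tot <- Matrix::colSums(g$counts[c("B1", "B2", "B3"), , drop = FALSE])
    truth <- ifelse(a_tot > b_tot, 1L, 2L)
    expect_equal(ari_from_table(table(rg$region_labels, truth)), 1)
  }
  # regions are connected in the hex adjacency graph
  rg <- regionalize(g, n_regions = 4L, n_components = 3L)
  el <- rg$adjacency
  for (lab in unique(rg$region_labels)) {
    hexes <- which(rg$region_labels == lab)
    sub <- el[el[, 1L] %in% hexes & el[, 2L] %in% hexes, , drop = FALSE]
    gr <- igraph::graph_from_edgelist(
      matrix(as.character(sub), ncol = 2L), directed = FALSE)
    gr <- igraph::add_vertices(
      gr, length(setdiff(as.character(hexes), igraph::V(gr)$name)))
    expect_equal(igraph::components(gr)$no, 1)
  }
  expect_error(regionalize(g, n_regions = nrow(g$centers) + 1L), "regions")
})

test_that("probability colour mixing interpolates between region colours", {
  mols <- two_domain_molecules(seed = 3L)
  g <- hexbin_molecules(mols, spacing_um = 50)
  rg <- regionalize(g, n_regions = 2L, n_components = 3L)
  mix <- mix_region_colors(rg, seed = 4L)
  expect_identical(dim(mix), c(nrow(g$centers), 3L))
  expect_true(all(mix >= 0 & mix <= 1))
  # hexes deep inside a domain take (essentially) the pure region colour
  deep <- which(g$centers$x < 300)
  lab_deep <- rg$region_labels[deep[1L]]
  expect_lt(max(abs(mix[deep[1L], ] - rg$region_colors[lab_deep, ])), 0.15)

  flat <- rg
  flat$region_labels <- rep(1L, nrow(g$centers))
  flat$region_colors <- matrix(c(1, 0, 0), 1L)
  expect_warning(m2 <- mix_region_colors(flat), "single region")
  expect_true(all(m2[, 1L] == 1))
})

test_that("border field peaks on the boundary with the correct angle", {
  set.seed(5)
  n <- 6000
  mols <- rbind(
    data.frame(gene = "a", x = runif(n / 2, 0, 400),
               y = runif(n / 2, 0, 400)),
    data.frame(gene = "b", x = runif(n / 2, 400, 800),
               y = runif(n / 2, 0, 400)))
  bf <- border_field(mols, grid_spacing = 50, radius_um = 100,
                     n_angles = 12L)
  best <- bf[which.max(bf$strength), ]
  expect_lt(abs(best$x - 400), 51)
  expect_identical(best$angle_deg, 90)
  # interior points far from the boundary sit near the noise floor
  # (points near the data edge are excluded: their disks are asymmetric)
  far <- bf[abs(bf$x - 400) > 150 & bf$x > 120 & bf$x < 680 &
              bf$y > 120 & bf$y < 280 & !bf$low_support, ]
  expect_gt(nrow(far), 0L)
  expect_lt(max(far$strength), best$strength / 2)

  # empty disk -> zero strength, flagged
  sparse <- data.frame(gene = c("a", "b"), x = c(0, 1000), y = c(0, 1000))
  bf2 <- border_field(sparse, grid_spacing = 500, radius_um = 50,
                      n_angles = 4L)
  expect_true(all(bf2$strength[bf2$low_support] == 0))
})

test_that("border strength is translation invariant and angle equivariant", {
  set.seed(6)
  mols <- rbind(
    data.frame(gene = "a", x = runif(800, 0, 200), y = runif(800, 0, 400)),
    data.frame(gene = "b", x = runif(800, 200, 400), y = runif(800, 0, 400)))
  bf <- border_field(mols, grid_spacing = 100, radius_um = 80, n_angles = 12L)
  shifted <- mols; shifted$x <- shifted$x + 37; shifted$y <- shifted$y - 11
  bf_sh <- border_field(shifted, grid_spacing = 100, radius_um = 80,
                        n_angles = 12L)
  expect_equal(bf_sh$strength, bf$strength)
  expect_equal(bf_sh$angle_deg, bf$angle_deg)

  # rotate all molecules by one angle step (15 deg) about the grid origin:
  # the reported angles shift by the same step (mod 180)
  th <- pi / 12
  rot <- mols
  rot$x <- cos(th) * mols$x - sin(th) * mols$y
  rot$y <- sin(th) * mols$x + cos(th) * mols$y
  p0 <- c(200, 200)
  p0r <- c(cos(th) * p0[1L] - sin(th) * p0[2L],
           sin(th) * p0[1L] + cos(th) * p0[2L])
  b1 <- border_field(mols, grid_spacing = 400, radius_um = 80, n_angles = 12L)
  b1 <- b1[b1$x == 200 & b1$y == 200, ]
  b2 <- border_field(rot, grid_spacing = 400, radius_um = 80, n_angles = 12L)
  # nearest rotated grid point to the rotated probe location
  d2 <- (b2$x - p0r[1L])^2 + (b2$y - p0r[2L])^2
  b2 <- b2[which.min(d2), ]
  if (nrow(b1) == 1L && !b1$low_support && !b2$low_support) {
    expect_equal((b2$angle_deg - b1$angle_deg) %% 180, 15,
                 tolerance = 1e-6)
  }
})

test_that("Ripley's L agrees with theory on CSR and flags clustering", {
  radii <- c(5, 10, 20, 40)
  # Monte-Carlo envelope under CSR
  set.seed(7)
  env <- replicate(30, {
    pts <- cbind(runif(1500, 0, 500), runif(1500, 0, 500))
    ripley_l(pts, radii, c(500, 500))$L_minus_r
  })
  lo <- apply(env, 1L, function(v) mean(v) - 5 * sd(v))
  hi <- apply(env, 1L, function(v) mean(v) + 5 * sd(v))
  set.seed(99)
  test_pts <- cbind(runif(1500, 0, 500), runif(1500, 0, 500))
  lr <- ripley_l(test_pts, radii, c(500, 500))$L_minus_r
  expect_true(all(lr >= lo - 1e-9 & lr <= hi + 1e-9))

  # cell-mimicking clusters: peak near the cluster diameter (~10 um)
  prof <- matrix(25, 1L, 1L, dimnames = list("g", "t"))
  cl <- simulate_scene(prof, n_cells = 80L, extent = c(500, 500),
                       cell_radius_um = 5, bead_density = 0, seed = 8L)
  rr <- seq(2, 30, by = 2)
  lrc <- ripley_l(cbind(cl$molecules$x, cl$molecules$y), rr, c(500, 500))
  peak_r <- rr[which.max(lrc$L_minus_r)]
  expect_gte(peak_r, 5); expect_lte(peak_r, 15)
  expect_gt(max(lrc$L_minus_r), 5)
})

test_that("two-point K matches the hand-evaluated estimator", {
  # n = 2 points at distance d in the window interior, no edge effects:
  # K(r >= d) = area / n^2 * 2 = area / 2
  pts <- rbind(c(50, 50), c(53, 50))
  ext <- c(200, 200)
  kk <- ripley_l(pts, c(2, 5), ext, correction = "none")
  expect_equal(kk$K[1L], 0)
  expect_equal(kk$K[2L], prod(ext) / 4 * 2)
})

test_that("uncorrected K matches direct pair counting", {
  set.seed(11)
  n <- 400L
  xs <- runif(n, 0, 1); ys <- runif(n, 0, 1)
  ours <- ripley_l(cbind(xs, ys), radii = c(0.05, 0.1), extent = c(1, 1),
                   correction = "none")
  # estimator definition evaluated independently: area / n^2 * pair count
  D <- as.matrix(stats::dist(cbind(xs, ys))); diag(D) <- Inf
  for (k in 1:2) {
    K_ref <- sum(D <= ours$r[k]) / n^2
    expect_equal(ours$K[k], K_ref)
  }
})

test_that("diffusion profile recovers the Rayleigh median", {
  prof <- matrix(40, 1L, 1L, dimnames = list("Vip", "t"))
  meds <- vapply(1:3, function(s) {
    sc <- simulate_scene(prof, n_cells = 60L, extent = c(600, 600),
                         cell_radius_um = 15, bead_density = 0, seed = s)
    # emit all molecules at the cell centroid, then diffuse
    sc$molecules$x <- sc$cells$x[sc$molecules$cell_id]
    sc$molecules$y <- sc$cells$y[sc$molecules$cell_id]
    scd <- apply_lateral_diffusion(sc, 3, seed = s + 10L)
    diffusion_profile(scd$molecules, "Vip")$median_radius
  }, numeric(1L))
  expect_lt(abs(mean(meds) / (3 * sqrt(2 * log(2))) - 1), 0.05)

  # two well-separated cells -> two clusters; single tight cluster -> ~0
  two <- data.frame(gene = "Vip",
                    x = c(rnorm(30, 50, 0.5), rnorm(30, 500, 0.5)),
                    y = c(rnorm(30, 50, 0.5), rnorm(30, 500, 0.5)))
  dp2 <- diffusion_profile(two, "Vip")
  expect_identical(dp2$n_clusters, 2L)
  expect_lt(dp2$median_radius, 1)
})

test_that("optical crowding follows the void-probability approximation", {
  oc <- optical_crowding(c(1, 25, 50, 100, 200), n_rep = 40L, seed = 12L)
  expect_identical(oc$fraction_resolvable[1L], 1)
  expect_true(all(diff(oc$fraction_resolvable) <= 0))
  d <- 660 / (2 * 1.4) / 1000
  analytic <- exp(-100 * pi * d^2 / 100)
  got <- oc$fraction_resolvable[oc$n == 100]
  expect_lt(abs(got - analytic), 0.02)
})

test_that("region linking matches identical profiles and rejects orthogonal", {
  ga <- regionalize(hexbin_molecules(two_domain_molecules(seed = 13L), 50),
                    n_regions = 2L, n_components = 3L)
  gb <- regionalize(hexbin_molecules(two_domain_molecules(seed = 14L), 50),
                    n_regions = 2L, n_components = 3L)
  lk <- link_regions(ga, gb)
  expect_identical(nrow(lk), 2L)
  expect_true(all(lk$correlation > 0.95))
  # each linked pair shares the dominant gene family
  for (i in seq_len(nrow(lk))) {
    ma <- ga$region_means[, lk$region_a[i]]
    mb <- gb$region_means[, lk$region_b[i]]
    expect_identical(names(which.max(ma)) %in% c("A1", "A2", "A3"),
                     names(which.max(mb)) %in% c("A1", "A2", "A3"))
  }
  gc <- ga
  rownames(gc$region_means) <- paste0("zz", seq_len(nrow(gc$region_means)))
  expect_error(link_regions(ga, gc), "shared genes")
})
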