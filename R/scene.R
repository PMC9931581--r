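# Ground-truth scene generation and simulation of the multi-round
# barcoded acquisition. Every downstream stage (detection, registration,
# decoding, assignment, spatial statistics) is benchmarked against scenes
# with known molecules, cells, beads and per-round drift.

#' Default per-type gene expression profiles
#'
#' Log-normal per-cell Poisson rates with cell-type structure: every type
#' shares a low baseline and overexpresses a disjoint block of marker
#' genes. Rates are scaled so the expected molecule count per cell is
#' `mean_total`, matching the sparse per-cell transcript loads of
#' surface-captured panels (tens of molecules per cell, spanning roughly
#' two orders of magnitude across genes).
#'
#' @param n_genes panel size.
#' @param n_types number of cell types.
#' @param mean_total expected molecules per cell.
#' @param seed RNG seed.
#' @return genes x types rate matrix.
#' @export
example_profiles <- function(n_genes = 20L, n_types = 4L, mean_total = 4,
                             seed = 11L) {
  set.seed(seed)
  base <- stats::rlnorm(n_genes, meanlog = -1.5, sdlog = 1)
  prof <- matrix(rep(base, n_types), n_genes, n_types)
  marker_block <- split(seq_len(n_genes),
                        rep(seq_len(n_types), length.out = n_genes))
  for (t in seq_len(n_types))
    prof[marker_block[[t]], t] <- prof[marker_block[[t]], t] * 8
  prof <- prof * mean_total / mean(colSums(prof))
  dimnames(prof) <- list(sprintf("Gene%02d", seq_len(n_genes)),
                         sprintf("type%d", seq_len(n_types)))
  prof
}

#' Simulate a ground-truth tissue scene
#'
#' Cells are placed uniformly with rejection sampling so that cell disks do
#' not overlap; per-cell molecule counts are Poisson with the cell type's
#' per-gene rates and molecule positions are uniform in the cell disk.
#' Ambient (extracellular) molecules form a homogeneous Poisson background
#' and fiducial beads are uniform over the extent.
#'
#' @param profiles genes x types matrix of expected molecules per cell
#'   (rownames = genes, colnames = types). A vector is taken as a single
#'   type.
#' @param n_cells number of cells.
#' @param extent c(width, height) in microns.
#' @param ambient_rate ambient molecules per square micron (split uniformly
#'   over genes).
#' @param bead_density beads per square micron.
#' @param cell_radius_um cell disk radius.
#' @param type_probs sampling probabilities over cell types (default
#'   uniform).
#' @param seed RNG seed.
#' @param max_tries rejection-sampling budget per cell.
#' @return object of class `scene`: list with `extent`, `cells`
#'   (data.frame id, x, y, radius, type), `molecules` (data.frame mol_id,
#'   gene, x, y, cell_id with `NA` for ambient), `beads` (data.frame x, y).
#' @export
simulate_scene <- function(profiles, n_cells, extent = c(200, 200),
                           ambient_rate = 0, bead_density = 0.005,
                           cell_radius_um = 5, type_probs = NULL,
                           seed = 1L, max_tries = 2000L) {
  if (is.null(dim(profiles)))
    profiles <- matrix(profiles, ncol = 1L,
                       dimnames = list(names(profiles), "type1"))
  stopifnot(all(profiles >= 0), all(extent > 0))
  genes <- rownames(profiles)
  types <- colnames(profiles)
  set.seed(seed)

  # non-overlapping cell centroids by rejection
  cx <- numeric(0); cy <- numeric(0)
  r <- cell_radius_um
  for (i in seq_len(n_cells)) {
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      x <- stats::runif(1L, r, extent[1L] - r)
      y <- stats::runif(1L, r, extent[2L] - r)
      if (length(cx) == 0L || min((cx - x)^2 + (cy - y)^2) >= (2 * r)^2) {
        cx <- c(cx, x); cy <- c(cy, y); placed <- TRUE; break
      }
    }
    if (!placed)
      stop("could not place ", n_cells, " non-overlapping cells; ",
           "reduce n_cells or cell_radius_um")
  }
  type <- if (n_cells > 0L)
    sample(types, n_cells, replace = TRUE, prob = type_probs)
  else character(0)
  cells <- data.frame(id = seq_len(n_cells), x = cx, y = cy,
                      radius = rep(r, n_cells), type = type,
                      stringsAsFactors = FALSE)

  # per-cell molecules
  mol <- list()
  for (i in seq_len(n_cells)) {
    lam <- profiles[, cells$type[i]]
    counts <- stats::rpois(length(lam), lam)
    n <- sum(counts)
    if (n == 0L) next
    rad <- r * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    mol[[length(mol) + 1L]] <- data.frame(
      gene = rep(genes, counts),
      x = cells$x[i] + rad * cos(th),
      y = cells$y[i] + rad * sin(th),
      cell_id = i, stringsAsFactors = FALSE)
  }
  # ambient molecules
  n_amb <- stats::rpois(1L, ambient_rate * prod(extent))
  if (n_amb > 0L) {
    mol[[length(mol) + 1L]] <- data.frame(
      gene = sample(genes, n_amb, replace = TRUE),
      x = stats::runif(n_amb, 0, extent[1L]),
      y = stats::runif(n_amb, 0, extent[2L]),
      cell_id = NA_integer_, stringsAsFactors = FALSE)
  }
  molecules <- if (length(mol) > 0L) do.call(rbind, mol) else
    data.frame(gene = character(0), x = numeric(0), y = numeric(0),
               cell_id = integer(0), stringsAsFactors = FALSE)
  if (nrow(molecules) > 0L)
    molecules <- cbind(mol_id = seq_len(nrow(molecules)), molecules)
  else molecules <- cbind(mol_id = integer(0), molecules)
  rownames(molecules) <- NULL

  n_beads <- stats::rpois(1L, bead_density * prod(extent))
  beads <- data.frame(x = stats::runif(n_beads, 0, extent[1L]),
                      y = stats::runif(n_beads, 0, extent[2L]))

  structure(list(extent = extent, cells = cells, molecules = molecules,
                 beads = beads),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("scene: %g x %g um, %d cells, %d molecules, %d beads\n",
              x$extent[1L], x$extent[2L], nrow(x$cells),
              nrow(x$molecules), nrow(x$beads)))
  invisible(x)
}

#' Apply lateral diffusion to scene molecules
#'
#' Each molecule is displaced by an isotropic 2D Gaussian N(0, sigma^2 I),
#' emulating lateral dispersion of molecules away from their source cell
#' during capture. The pre-diffusion position is retained in `x0`, `y0` so
#' diffusion profiling can be scored against ground truth.
#'
#' @param scene a `scene`.
#' @param sigma_um diffusion scale in microns (>= 0).
#' @param seed RNG seed.
#' @return the scene with displaced molecules.
#' @export
apply_lateral_diffusion <- function(scene, sigma_um, seed = 1L) {
  stopifnot(sigma_um >= 0)
  set.seed(seed)
  m <- scene$molecules
  if (nrow(m) == 0L) return(scene)
  m$x0 <- m$x; m$y0 <- m$y
  m$x <- m$x + stats::rnorm(nrow(m), 0, sigma_um)
  m$y <- m$y + stats::rnorm(nrow(m), 0, sigma_um)
  scene$molecules <- m
  scene
}

#' Acquisition configuration
#'
#' Bundles the imaging and error-model parameters of a simulated
#' multi-round acquisition.
#'
#' @param pixel_size microns per pixel (default 0.18, an 11-um camera pixel
#'   behind a 60x objective).
#' @param psf_sigma point-spread-function sigma in pixels.
#' @param drift named list of per-round `similarity` transforms (names =
#'   round index); rounds absent from the list use the identity.
#' @param p_dropout probability an "on" bit yields no spot.
#' @param p_gain probability per "off" round of a spurious spot colocated
#'   with the molecule (probe cross-talk model).
#' @param sigma_loc localization jitter sd in microns.
#' @param spot_amplitude,bead_amplitude mean rendered peak intensities.
#' @param background,noise_sd constant background level and Gaussian read
#'   noise sd (camera counts).
#' @param shot_noise apply Poisson shot noise when rendering.
#' @param seed RNG seed.
#' @return list of class `acq_config`.
#' @export
acquisition_config <- function(pixel_size = 0.18, psf_sigma = 1.2,
                               drift = list(), p_dropout = 0,
                               p_gain = 0, sigma_loc = 0.05,
                               spot_amplitude = 800, bead_amplitude = 4000,
                               background = 100, noise_sd = 10,
                               shot_noise = TRUE, seed = 1L) {
  stopifnot(pixel_size > 0, p_dropout >= 0, p_dropout <= 1,
            p_gain >= 0, p_gain <= 1)
  structure(list(pixel_size = pixel_size, psf_sigma = psf_sigma,
                 drift = drift, p_dropout = p_dropout, p_gain = p_gain,
                 sigma_loc = sigma_loc, spot_amplitude = spot_amplitude,
                 bead_amplitude = bead_amplitude, background = background,
                 noise_sd = noise_sd, shot_noise = shot_noise, seed = seed),
            class = "acq_config")
}

#' Simulate the cyclic readout of a scene
#'
#' For every molecule and every "on" bit of its gene's codeword, a spot is
#' emitted in that round with probability `1 - p_dropout`; each "off"
#' round gains a spurious spot with probability `p_gain`, colocated with
#' the molecule. Spot positions are jittered by N(0, sigma_loc^2) and each
#' round's spots and beads are mapped through that round's drift transform.
#'
#' @param scene a `scene` (all molecule genes must be assigned in the
#'   codebook).
#' @param codebook a gene-labelled `codebook` (from [assign_genes()]).
#' @param config an `acq_config`.
#' @return list with `spots` (data.frame round, x_um, y_um, intensity,
#'   is_bead, mol_id) and `truth` (the scene molecule table).
#' @export
simulate_readout <- function(scene, codebook, config = acquisition_config()) {
  m <- scene$molecules
  genes <- unique(m$gene)
  missing <- setdiff(genes, rownames(codebook$codes))
  if (length(missing) > 0L)
    stop("scene genes missing from codebook: ",
         paste(missing, collapse = ", "))
  set.seed(config$seed)
  n_bits <- codebook$n_bits
  words <- codebook$codes[m$gene, , drop = FALSE]

  rows <- list()
  for (r in seq_len(n_bits) - 1L) {
    on <- words[, r + 1L] == 1L
    emit_on <- on & stats::runif(nrow(m)) >= config$p_dropout
    emit_gain <- !on & stats::runif(nrow(m)) < config$p_gain
    emit <- which(emit_on | emit_gain)
    if (length(emit) == 0L && nrow(scene$beads) == 0L) next
    n <- length(emit)
    sp <- data.frame(
      round = rep(r, n),
      x_um = m$x[emit] + stats::rnorm(n, 0, config$sigma_loc),
      y_um = m$y[emit] + stats::rnorm(n, 0, config$sigma_loc),
      intensity = config$spot_amplitude *
        exp(stats::rnorm(n, 0, 0.2)),
      is_bead = rep(FALSE, n), mol_id = m$mol_id[emit])
    if (nrow(scene$beads) > 0L) {
      nb <- nrow(scene$beads)
      bd <- data.frame(
        round = r,
        x_um = scene$beads$x + stats::rnorm(nb, 0, config$sigma_loc),
        y_um = scene$beads$y + stats::rnorm(nb, 0, config$sigma_loc),
        intensity = config$bead_amplitude * exp(stats::rnorm(nb, 0, 0.1)),
        is_bead = TRUE, mol_id = NA_integer_)
      sp <- rbind(sp, bd)
    }
    tf <- config$drift[[as.character(r)]]
    if (!is.null(tf)) {
      xy <- apply_transform(tf, as.matrix(sp[, c("x_um", "y_um")]))
      sp$x_um <- xy[, 1L]; sp$y_um <- xy[, 2L]
    }
    rows[[length(rows) + 1L]] <- sp
  }
  spots <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(round = integer(0), x_um = numeric(0), y_um = numeric(0),
               intensity = numeric(0), is_bead = logical(0),
               mol_id = integer(0))
  rownames(spots) <- NULL
  list(spots = spots, truth = m)
}

#' Render one round as a 2D image
#'
#' Sums Gaussian point-spread kernels at spot and bead positions over a
#' constant background, then applies Poisson shot noise and Gaussian read
#' noise, and quantizes to 16-bit counts. The pixel convention is shared
#' repo-wide: origin at the image top-left, y increasing downward, pixel
#' index `floor(coord / pixel_size)` (0-based); `image[row, col]`
#' corresponds to pixel (col - 1, row - 1).
#'
#' @param spots data.frame with `x_um`, `y_um`, `intensity` (beads included
#'   as rows like any spot, typically brighter).
#' @param extent c(width, height) microns of the field of view.
#' @param config an `acq_config`.
#' @param seed RNG seed for the noise draws.
#' @return integer matrix (rows = y pixels, cols = x pixels), 0..65535.
#' @export
render_round_image <- function(spots, extent, config = acquisition_config(),
                               seed = 1L) {
  ps <- config$pixel_size
  nx <- ceiling(extent[1L] / ps); ny <- ceiling(extent[2L] / ps)
  img <- matrix(0, ny, nx)
  sig <- config$psf_sigma
  halfw <- ceiling(4 * sig)
  for (i in seq_len(nrow(spots))) {
    px <- spots$x_um[i] / ps - 0.5   # pixel-center coordinates, 0-based
    py <- spots$y_um[i] / ps - 0.5
    x0 <- max(0L, floor(px) - halfw); x1 <- min(nx - 1L, floor(px) + halfw)
    y0 <- max(0L, floor(py) - halfw); y1 <- min(ny - 1L, floor(py) + halfw)
    if (x1 < x0 || y1 < y0) next
    gx <- exp(-((x0:x1) - px)^2 / (2 * sig^2))
    gy <- exp(-((y0:y1) - py)^2 / (2 * sig^2))
    img[(y0:y1) + 1L, (x0:x1) + 1L] <-
      img[(y0:y1) + 1L, (x0:x1) + 1L] + spots$intensity[i] * outer(gy, gx)
  }
  img <- img + config$background
  set.seed(seed)
  if (config$shot_noise) img <- matrix(stats::rpois(length(img), img),
                                       ny, nx)
  if (config$noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, config$noise_sd)
  img <- round(pmin(pmax(img, 0), 65535))
  storage.mode(img) <- "integer"
  img
}
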