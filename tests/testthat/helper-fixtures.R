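# Shared fixtures: the default codebook is expensive enough to build once.

default_cb <- local({
  cb <- NULL
  function() {
    if (is.null(cb)) cb <<- generate_codebook(16L, 6L, 4L)
    cb
  }
})

# Adjusted Rand index from a contingency table (closed form, used as an
# independent scoring of cluster agreement).
ari_from_table <- function(tab) {
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  e <- b * cc / choose(n, 2)
  (a - e) / ((b + cc) / 2 - e)
}

# Two expression domains separated by a molecule-free gap wider than a hex,
# so every occupied hex has single-domain content (emulates two nuclei
# separated by a fibre tract).
two_domain_molecules <- function(n = 3000, seed = 1L) {
  set.seed(seed)
  rbind(
    data.frame(gene = sample(c("A1", "A2", "A3"), n / 2, TRUE),
               x = runif(n / 2, 0, 460), y = runif(n / 2, 0, 500)),
    data.frame(gene = sample(c("B1", "B2", "B3"), n / 2, TRUE),
               x = runif(n / 2, 540, 1000), y = runif(n / 2, 0, 500)))
}

# Per-round drift transforms within the calibration-level ranges: scale
# 0.99-1.01, rotation up to 2 degrees, shifts up to 5 um.
make_drift <- function(n_rounds = 16L, seed = 99L) {
  set.seed(seed)
  drift <- lapply(seq_len(n_rounds) - 1L, function(r)
    similarity_transform(1 + runif(1, -0.01, 0.01),
                         runif(1, -2, 2) * pi / 180,
                         runif(1, -5, 5), runif(1, -5, 5)))
  names(drift) <- as.character(seq_len(n_rounds) - 1L)
  drift[["0"]] <- similarity_transform()
  drift
}

# Label image with one disk per row of `centers` (matrix px, py, radius px).
disk_labels <- function(dim_px, centers) {
  lab <- matrix(0L, dim_px[1L], dim_px[2L])
  for (k in seq_len(nrow(centers))) {
    for (i in seq_len(dim_px[1L])) {
      dy2 <- (i - centers[k, 2L])^2
      if (dy2 > centers[k, 3L]^2) next
      dx <- sqrt(centers[k, 3L]^2 - dy2)
      j0 <- max(1L, ceiling(centers[k, 1L] - dx))
      j1 <- min(dim_px[2L], floor(centers[k, 1L] + dx))
      if (j1 >= j0) lab[i, j0:j1] <- k
    }
  }
  lab
}
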