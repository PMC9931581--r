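# Segmentation-mask expansion and molecule-to-cell assignment.

#' Expand segmentation masks without overlap
#'
#' Grows every label outward by up to `distance_um`: each background pixel
#' within that distance of at least one label takes the label of its
#' nearest labelled pixel (Euclidean distance transform); equidistant ties
#' go to the smaller label id, and original labelled pixels are never
#' reassigned. Nuclear masks expanded this way approximate cell bodies
#' while staying disjoint.
#'
#' @param label_image integer matrix; 0 = background, positive = labels.
#' @param distance_um expansion distance in microns.
#' @param pixel_size microns per pixel (isotropic; anisotropic pixels are
#'   not supported).
#' @return expanded integer label matrix.
#' @export
expand_masks <- function(label_image, distance_um = 8, pixel_size = 0.5) {
  if (length(pixel_size) > 1L && pixel_size[1L] != pixel_size[2L])
    stop("anisotropic pixels are not supported")
  pixel_size <- pixel_size[1L]
  stopifnot(all(label_image >= 0))
  if (distance_um <= 0) return(label_image)
  d_px <- distance_um / pixel_size
  labels <- sort(unique(label_image[label_image > 0]))
  out <- label_image
  best <- matrix(Inf, nrow(label_image), ncol(label_image))
  best[label_image > 0] <- 0
  for (L in labels) {
    # distance of every pixel to the nearest pixel of label L
    m <- matrix(1, nrow(label_image), ncol(label_image))
    m[label_image == L] <- 0
    dist_L <- EBImage::distmap(m, metric = "euclidean")
    take <- label_image == 0 & dist_L <= d_px & dist_L < best
    out[take] <- L
    best[take] <- dist_L[take]      # strict < keeps smaller label on ties
  }
  out
}

#' Assign decoded molecules to cells
#'
#' Each molecule position is mapped (through the inverse of
#' `stain_to_mol`, when the stain image lives in a different frame) into
#' the label image; the molecule receives the label of the pixel it falls
#' in, with label 0 or out-of-bounds counted as unassigned. Gene counts
#' are aggregated into a cells x genes matrix; blank calls are excluded
#' from the matrix but reported.
#'
#' @param molecules decoded molecule table (`label`, `x_um`, `y_um`).
#' @param labels expanded label image (integer matrix).
#' @param stain_to_mol optional `similarity` mapping the stain-image frame
#'   into the molecule frame (e.g. from [register_magnifications()]).
#' @param pixel_size microns per pixel of the label image.
#' @return list of class `cell_matrix`: `counts` (sparse cells x genes
#'   matrix, dimnames cell id / gene), `cells` (data.frame id, x, y,
#'   area_px for labels present in the image), `n_unassigned`,
#'   `blank_counts` (named), `cell_id` (per input molecule; NA if
#'   unassigned).
#' @export
assign_to_cells <- function(molecules, labels, stain_to_mol = NULL,
                            pixel_size = 0.5) {
  xy <- as.matrix(molecules[, c("x_um", "y_um")])
  if (!is.null(stain_to_mol))
    xy <- apply_transform(invert_transform(stain_to_mol), xy)
  px <- floor(xy[, 1L] / pixel_size)    # 0-based
  py <- floor(xy[, 2L] / pixel_size)
  inside <- px >= 0L & px < ncol(labels) & py >= 0L & py < nrow(labels)
  cell <- rep(NA_integer_, nrow(molecules))
  cell[inside] <- labels[cbind(py[inside] + 1L, px[inside] + 1L)]
  cell[!is.na(cell) & cell == 0L] <- NA_integer_

  is_blank <- startsWith(molecules$label, "Blank-")
  blank_counts <- table(molecules$label[is_blank])

  ids <- sort(unique(labels[labels > 0]))
  genes <- sort(unique(molecules$label[!is_blank]))
  use <- !is.na(cell) & !is_blank
  counts <- Matrix::sparseMatrix(
    i = match(cell[use], ids),
    j = match(molecules$label[use], genes),
    x = 1, dims = c(length(ids), length(genes)),
    dimnames = list(as.character(ids), genes))

  # cell centroids and areas from the label image
  pos <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[pos]
  cx <- tapply((pos[, 2L] - 0.5) * pixel_size, lab, mean)
  cy <- tapply((pos[, 1L] - 0.5) * pixel_size, lab, mean)
  area <- tapply(lab, lab, length)
  cells <- data.frame(id = ids,
                      x = as.numeric(cx[as.character(ids)]),
                      y = as.numeric(cy[as.character(ids)]),
                      area_px = as.integer(area[as.character(ids)]))

  structure(list(counts = counts, cells = cells,
                 n_unassigned = sum(is.na(cell)),
                 blank_counts = blank_counts,
                 cell_id = cell),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d cells x %d genes, %d molecules assigned, %d unassigned\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts),
              x$n_unassigned))
  invisible(x)
}

#' Quality-control filter on the cell matrix
#'
#' Drops cells with fewer than `min_counts` total molecules or fewer than
#' `min_genes` detected genes.
#'
#' @param cm a `cell_matrix` (or a bare counts matrix).
#' @param min_counts,min_genes thresholds (>= 0).
#' @return list with `counts` (filtered), `n_dropped`, `kept` (logical per
#'   cell).
#' @export
qc_cells <- function(cm, min_counts = 0, min_genes = 0) {
  stopifnot(min_counts >= 0, min_genes >= 0)
  counts <- if (inherits(cm, "cell_matrix")) cm$counts else cm
  tot <- Matrix::rowSums(counts)
  ngene <- Matrix::rowSums(counts > 0)
  kept <- tot >= min_counts & ngene >= min_genes
  list(counts = counts[kept, , drop = FALSE],
       n_dropped = sum(!kept), kept = kept)
}

#' Export a cell matrix as MatrixMarket + TSV sidecars
#'
#' Writes `matrix.mtx` (genes x cells, MatrixMarket), `features.tsv` and
#' `cells.tsv` into `dir`.
#'
#' @param cm a `cell_matrix`.
#' @param dir output directory (created if needed).
#' @export
write_cell_matrix <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::t(cm$counts), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(cm$counts), file.path(dir, "features.tsv"))
  utils::write.table(cm$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
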