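# Similarity transforms and fiducial-bead registration.
#
# Rounds drift relative to each other by a small scaling, rotation and
# shift; bright photostable beads present in every round anchor a
# similarity transform back to a reference frame. Low- and high-
# magnification acquisitions are registered the same way.

#' Create a 2D similarity transform
#'
#' Maps a point p to `scale * R(rotation) p + (dx, dy)`.
#'
#' @param scale scale factor (> 0).
#' @param rotation rotation in radians, counter-clockwise.
#' @param dx,dy translation in microns.
#' @return object of class `similarity`.
#' @export
similarity_transform <- function(scale = 1, rotation = 0, dx = 0, dy = 0) {
  stopifnot(scale > 0)
  structure(list(scale = unname(scale), rotation = unname(rotation),
                 dx = unname(dx), dy = unname(dy)),
            class = "similarity")
}

#' @export
print.similarity <- function(x, ...) {
  cat(sprintf("similarity: scale %.6f, rotation %.4f deg, shift (%.3f, %.3f)\n",
              x$scale, x$rotation * 180 / pi, x$dx, x$dy))
  invisible(x)
}

#' Apply a similarity transform to points
#'
#' @param tf a `similarity`.
#' @param xy 2-column matrix (or data.frame) of x, y coordinates.
#' @return transformed 2-column matrix.
#' @export
apply_transform <- function(tf, xy) {
  xy <- as.matrix(xy)
  R <- matrix(c(cos(tf$rotation), sin(tf$rotation),
                -sin(tf$rotation), cos(tf$rotation)), 2L)
  out <- tf$scale * (xy %*% t(R))
  out[, 1L] <- out[, 1L] + tf$dx
  out[, 2L] <- out[, 2L] + tf$dy
  colnames(out) <- c("x", "y")
  out
}

#' Invert a similarity transform
#'
#' @param tf a `similarity`.
#' @return the inverse `similarity`.
#' @export
invert_transform <- function(tf) {
  s <- 1 / tf$scale
  th <- -tf$rotation
  t_inv <- -s * c(cos(th) * tf$dx - sin(th) * tf$dy,
                  sin(th) * tf$dx + cos(th) * tf$dy)
  similarity_transform(s, th, t_inv[1L], t_inv[2L])
}

#' Compose two similarity transforms
#'
#' `compose_transforms(a, b)` applies `b` first, then `a`.
#'
#' @param a,b `similarity` transforms.
#' @return the composed `similarity`.
#' @export
compose_transforms <- function(a, b) {
  th <- a$rotation + b$rotation
  t_new <- apply_transform(a, matrix(c(b$dx, b$dy), 1L))
  similarity_transform(a$scale * b$scale, th, t_new[1L], t_new[2L])
}

# Closed-form least-squares similarity fit (Procrustes / Umeyama, 2D,
# no reflection) mapping src -> dst.
fit_similarity <- function(src, dst) {
  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  xs <- sweep(src, 2L, mu_s); xd <- sweep(dst, 2L, mu_d)
  S <- crossprod(xd, xs) / nrow(src)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, d))
  R <- sv$u %*% D %*% t(sv$v)
  var_s <- mean(rowSums(xs^2))
  scale <- sum(diag(D) * sv$d) / var_s
  t_vec <- mu_d - scale * as.vector(R %*% mu_s)
  similarity_transform(scale, atan2(R[2L, 1L], R[1L, 1L]),
                       t_vec[1L], t_vec[2L])
}

# Mutual (symmetric) nearest-neighbor pairs within radius; returns an
# index matrix (src row, dst row). Distance matrices are fine at bead
# counts (hundreds of points).
mutual_nn <- function(a, b, radius) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  nn_ab <- max.col(-d2, ties.method = "first")
  nn_ba <- max.col(-t(d2), ties.method = "first")
  i <- seq_len(nrow(a))
  keep <- nn_ba[nn_ab] == i & d2[cbind(i, nn_ab)] <= radius^2
  cbind(src = i[keep], dst = nn_ab[keep])
}

#' Estimate a similarity transform between two point sets
#'
#' Iterative nearest-neighbor alignment: starting from a centroid-shift
#' initialization, alternate (1) mutual nearest-neighbor matching within
#' `match_radius` between the transformed source and the destination and
#' (2) a closed-form least-squares similarity fit on the matches, until the
#' transform parameters change by less than `tol` or `max_iter` is reached.
#' Mutual matching suppresses false pairs from unmatched points and
#' outliers.
#'
#' When the two point sets are already in known one-to-one correspondence
#' (row i of `src_points` corresponds to row i of `dst_points`), set
#' `paired = TRUE` to apply the closed-form fit directly without matching.
#' `init` seeds the iteration, e.g. with the expected magnification ratio
#' when registering across objectives; by default the translation is
#' initialized from the coordinate medians (robust to outliers).
#'
#' @param src_points,dst_points 2-column matrices / data.frames of x, y in
#'   microns (at least 3 points each).
#' @param max_iter maximum iterations.
#' @param match_radius matching radius in microns.
#' @param tol convergence tolerance on parameter change.
#' @param paired points are in known row correspondence; fit directly.
#' @param init optional initial `similarity` transform.
#' @return list with `transform` (mapping src to dst), `rms` residual over
#'   the final matches, `n_matches`, `n_iter`.
#' @export
estimate_similarity <- function(src_points, dst_points, max_iter = 50L,
                                match_radius = 2, tol = 1e-6,
                                paired = FALSE, init = NULL) {
  src <- as.matrix(src_points)[, 1:2, drop = FALSE]
  dst <- as.matrix(dst_points)[, 1:2, drop = FALSE]
  if (nrow(src) < 3L || nrow(dst) < 3L)
    stop("need at least 3 points in each set")
  if (paired) {
    if (nrow(src) != nrow(dst))
      stop("paired fit needs equally sized point sets")
    tf <- fit_similarity(src, dst)
    res <- apply_transform(tf, src) - dst
    return(list(transform = tf, rms = sqrt(mean(rowSums(res^2))),
                n_matches = nrow(src), n_iter = 0L))
  }
  tf <- if (!is.null(init)) init else similarity_transform()
  if (is.null(init)) {
    tf$dx <- stats::median(dst[, 1L]) - stats::median(src[, 1L])
    tf$dy <- stats::median(dst[, 2L]) - stats::median(src[, 2L])
  }
  n_matches <- 0L
  for (it in seq_len(max_iter)) {
    moved <- apply_transform(tf, src)
    m <- mutual_nn(moved, dst, match_radius)
    if (nrow(m) < 3L)
      stop(sprintf("convergence error: only %d matches at iteration %d",
                   nrow(m), it))
    new_tf <- fit_similarity(src[m[, "src"], , drop = FALSE],
                             dst[m[, "dst"], , drop = FALSE])
    delta <- max(abs(new_tf$scale - tf$scale),
                 abs(new_tf$rotation - tf$rotation),
                 abs(new_tf$dx - tf$dx), abs(new_tf$dy - tf$dy))
    tf <- new_tf
    n_matches <- nrow(m)
    if (delta < tol) break
  }
  moved <- apply_transform(tf, src)
  m <- mutual_nn(moved, dst, match_radius)
  res <- moved[m[, "src"], , drop = FALSE] - dst[m[, "dst"], , drop = FALSE]
  list(transform = tf, rms = sqrt(mean(rowSums(res^2))),
       n_matches = nrow(m), n_iter = it)
}

#' Register all readout rounds to a reference round using beads
#'
#' @param spots a spot table (data.frame with `round`, `x_um`, `y_um`,
#'   `is_bead`); only bead rows are used for estimation.
#' @param reference_round round whose frame the others are mapped into.
#' @param ... passed to [estimate_similarity()].
#' @return named list of `similarity` transforms, one per round present
#'   (the reference round maps to the identity).
#' @export
register_rounds <- function(spots, reference_round = 0L, ...) {
  beads <- spots[spots$is_bead, , drop = FALSE]
  rounds <- sort(unique(spots$round))
  if (!(reference_round %in% rounds))
    stop("reference round ", reference_round, " absent from spot table")
  ref <- beads[beads$round == reference_round, c("x_um", "y_um")]
  out <- list()
  for (r in rounds) {
    if (r == reference_round) {
      out[[as.character(r)]] <- similarity_transform()
      next
    }
    b <- beads[beads$round == r, c("x_um", "y_um")]
    if (nrow(b) < 3L)
      stop("round ", r, " has fewer than 3 beads")
    fit <- tryCatch(estimate_similarity(b, ref, ...),
                    error = function(e)
                      stop("registration failed for round ", r, ": ",
                           conditionMessage(e)))
    out[[as.character(r)]] <- fit$transform
  }
  out
}

#' Map all spots into the reference frame
#'
#' @param spots spot table with `round`, `x_um`, `y_um`.
#' @param transforms per-round transforms from [register_rounds()].
#' @return the spot table with coordinates replaced by registered ones.
#' @export
apply_round_transforms <- function(spots, transforms) {
  out <- spots
  for (r in names(transforms)) {
    idx <- spots$round == as.integer(r)
    if (!any(idx)) next
    xy <- apply_transform(transforms[[r]],
                          as.matrix(spots[idx, c("x_um", "y_um")]))
    out$x_um[idx] <- xy[, 1L]
    out$y_um[idx] <- xy[, 2L]
  }
  out
}

#' Register two magnifications via shared beads
#'
#' Same estimator as [estimate_similarity()], with the recovered scale
#' expected near the magnification ratio; used to carry nucleus-stain
#' segmentation into the RNA-signal frame.
#'
#' @param beads_lowmag,beads_highmag 2-column bead coordinates (microns in
#'   each objective's frame).
#' @param scale_hint expected scale ratio between the frames (known from
#'   the objectives); used to initialize the iteration.
#' @param ... passed to [estimate_similarity()].
#' @return list as returned by [estimate_similarity()] (transform maps the
#'   low-magnification frame into the high-magnification frame).
#' @export
register_magnifications <- function(beads_lowmag, beads_highmag,
                                    scale_hint = 1, ...) {
  src <- as.matrix(beads_lowmag)[, 1:2, drop = FALSE]
  dst <- as.matrix(beads_highmag)[, 1:2, drop = FALSE]
  init <- similarity_transform(
    scale_hint, 0,
    stats::median(dst[, 1L]) - scale_hint * stats::median(src[, 1L]),
    stats::median(dst[, 2L]) - scale_hint * stats::median(src[, 2L]))
  estimate_similarity(src, dst, init = init, ...)
}

#' Write per-round transforms as CSV
#'
#' @param transforms named list from [register_rounds()].
#' @param path output CSV (columns round, scale, rotation_rad, dx, dy).
#' @export
write_transforms <- function(transforms, path) {
  df <- do.call(rbind, lapply(names(transforms), function(r) {
    tf <- transforms[[r]]
    data.frame(round = as.integer(r), scale = tf$scale,
               rotation_rad = tf$rotation, dx = tf$dx, dy = tf$dy)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
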