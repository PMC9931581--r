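# Aggregation of registered spots into candidate molecules, codebook
# decoding, and blank-based false-positive estimation.

# All pairs of points within `radius`, found via a uniform grid hash so
# dense spot tables stay tractable. Returns a 2-column index matrix.
pairs_within <- function(x, y, radius) {
  n <- length(x)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  cx <- floor(x / radius) - min(floor(x / radius)) + 1L
  cy <- floor(y / radius) - min(floor(y / radius)) + 1L
  ncx <- max(cx) + 1L
  key <- cy * ncx + cx
  ord <- order(key)
  ukey <- unique(key[ord])
  bucket_of <- match(key, ukey)
  buckets <- split(seq_len(n), bucket_of)
  # neighbour buckets covering each adjacent pair once: self, right, down,
  # down-right, down-left
  offs <- c(0L, 1L, ncx, ncx + 1L, ncx - 1L)
  out_i <- vector("list", 5L * length(buckets)); oo <- 0L
  r2 <- radius^2
  for (k in seq_along(offs)) {
    nb_idx <- match(ukey + offs[k], ukey)
    for (b in which(!is.na(nb_idx) | offs[k] == 0L)) {
      pts_a <- buckets[[b]]
      if (offs[k] == 0L) {
        if (length(pts_a) < 2L) next
        cmb <- utils::combn(pts_a, 2L)
        ii <- cmb[1L, ]; jj <- cmb[2L, ]
      } else {
        pts_b <- buckets[[nb_idx[b]]]
        ii <- rep(pts_a, times = length(pts_b))
        jj <- rep(pts_b, each = length(pts_a))
      }
      d2 <- (x[ii] - x[jj])^2 + (y[ii] - y[jj])^2
      sel <- d2 <= r2
      if (any(sel)) {
        oo <- oo + 1L
        out_i[[oo]] <- cbind(ii[sel], jj[sel])
      }
    }
  }
  if (oo == 0L) return(matrix(integer(0), 0L, 2L))
  do.call(rbind, out_i[seq_len(oo)])
}

#' Aggregate registered spots into candidate molecules
#'
#' Spots from different rounds lying within `match_radius_um` of each other
#' are joined into a graph; connected components become candidate
#' molecules. A component's observed word has bit r set iff it contains at
#' least one spot from round r. Components carrying several spots from the
#' same round are deduplicated by keeping, per round, the spot closest to
#' the component centroid (two real molecules closer than the match radius
#' merge into one candidate -- a documented resolution limit).
#'
#' @param spots registered spot table (`round`, `x_um`, `y_um`,
#'   `is_bead`); beads are ignored.
#' @param match_radius_um linking radius in microns.
#' @param n_bits word length (number of rounds).
#' @return list with `words` (candidates x n_bits 0/1 matrix), `x`, `y`
#'   (component centroids over kept spots), `n_spots` (kept spots per
#'   candidate) and `members` (list of spot row indices).
#' @export
aggregate_rounds <- function(spots, match_radius_um = 0.75, n_bits = 16L) {
  sp <- spots[!spots$is_bead, , drop = FALSE]
  n <- nrow(sp)
  if (n == 0L)
    return(list(words = matrix(0L, 0L, n_bits), x = numeric(0),
                y = numeric(0), n_spots = integer(0), members = list()))
  pr <- pairs_within(sp$x_um, sp$y_um, match_radius_um)
  if (nrow(pr) > 0L)
    pr <- pr[sp$round[pr[, 1L]] != sp$round[pr[, 2L]], , drop = FALSE]
  g <- igraph::graph_from_edgelist(matrix(as.character(pr), ncol = 2L),
                                   directed = FALSE)
  g <- igraph::add_vertices(
    g, length(setdiff(as.character(seq_len(n)),
                      igraph::V(g)$name)),
    name = setdiff(as.character(seq_len(n)), igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  comp <- comp[order(as.integer(names(comp)))]

  words <- matrix(0L, max(comp), n_bits)
  xs <- numeric(max(comp)); ys <- numeric(max(comp))
  n_spots <- integer(max(comp)); members <- split(seq_len(n), comp)
  for (ci in seq_len(max(comp))) {
    rows <- members[[ci]]
    cx <- mean(sp$x_um[rows]); cy <- mean(sp$y_um[rows])
    # per-round dedup: keep the spot nearest the component centroid
    keep <- rows
    rds <- sp$round[rows]
    if (anyDuplicated(rds)) {
      d2 <- (sp$x_um[rows] - cx)^2 + (sp$y_um[rows] - cy)^2
      keep <- rows[unlist(lapply(split(seq_along(rows), rds),
                                 function(ii) ii[which.min(d2[ii])]))]
    }
    words[ci, sp$round[keep] + 1L] <- 1L
    xs[ci] <- mean(sp$x_um[keep]); ys[ci] <- mean(sp$y_um[keep])
    n_spots[ci] <- length(keep)
  }
  list(words = words, x = xs, y = ys, n_spots = n_spots, members = members)
}

#' Decode candidate molecules against the codebook
#'
#' Applies nearest-neighbour decoding ([decode_words()]) to every
#' candidate; no-calls are dropped from the molecule table but counted.
#'
#' @param candidates result of [aggregate_rounds()].
#' @param codebook gene-labelled `codebook`.
#' @param max_correct maximum correctable bit errors.
#' @return list with `molecules` (data.frame label, x_um, y_um, n_on_bits,
#'   bit_errors), `n_nocall`, `nocall_reasons` (table) and `per_label`
#'   (named decoded counts over all codebook labels).
#' @export
decode_molecules <- function(candidates, codebook, max_correct = 1L) {
  if (nrow(candidates$words) == 0L) {
    per <- stats::setNames(integer(nrow(codebook$codes)),
                           rownames(codebook$codes))
    return(list(molecules = data.frame(label = character(0),
                                       x_um = numeric(0), y_um = numeric(0),
                                       n_on_bits = integer(0),
                                       bit_errors = integer(0)),
                n_nocall = 0L, nocall_reasons = table(character(0)),
                per_label = per))
  }
  dec <- decode_words(candidates$words, codebook, max_correct)
  called <- !is.na(dec$label)
  molecules <- data.frame(
    label = dec$label[called],
    x_um = candidates$x[called], y_um = candidates$y[called],
    n_on_bits = rowSums(candidates$words)[called],
    bit_errors = dec$bit_errors[called],
    stringsAsFactors = FALSE)
  per <- table(factor(molecules$label, levels = rownames(codebook$codes)))
  list(molecules = molecules,
       n_nocall = sum(!called),
       nocall_reasons = table(dec$reason[!called]),
       per_label = stats::setNames(as.integer(per), names(per)))
}

#' Blank-based false-positive rate
#'
#' Codewords assigned to no gene ("blanks") should never be decoded; their
#' decoded counts estimate the per-barcode false-positive rate. For each
#' blank the rate is its count over the total number of decoded molecules;
#' the mean and sd are taken across blanks.
#'
#' @param decoded result of [decode_molecules()].
#' @param codebook the `codebook` used (must contain blanks).
#' @return list with `per_blank` (named rates), `mean`, `sd`, `n_decoded`.
#' @export
blank_fpr <- function(decoded, codebook) {
  blanks <- grep("^Blank-", rownames(codebook$codes), value = TRUE)
  if (length(blanks) == 0L)
    stop("codebook contains no blank codewords")
  total <- nrow(decoded$molecules)
  counts <- decoded$per_label[blanks]
  rate <- if (total > 0L) counts / total else counts * 0
  list(per_blank = rate,
       mean = mean(rate),
       sd = if (length(rate) > 1L) stats::sd(rate) else 0,
       n_decoded = total)
}
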