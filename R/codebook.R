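#' Construct a constant-weight error-correcting barcode codebook
#'
#' Builds the set of binary codewords used to encode genes over cyclic
#' readout rounds: each codeword has `n_bits` bits (one per round), exactly
#' `weight` of them set, and every pair of codewords differs in at least
#' `min_distance` bits. The default parameters (16 bits, weight 6, distance
#' 4) support correcting a single dropped or gained bit per molecule while
#' detecting two-bit errors.
#'
#' For `min_distance = 4` the construction is the checksum-class code:
#' enumerate all weight-`weight` words, compute the position checksum
#' \eqn{s(x) = \sum_i i x_i \bmod n}{s(x) = sum(i * x_i) mod n} with 0-based
#' positions, and keep the largest residue class (ties broken toward the
#' smallest residue). Two distinct equal-weight words in the same class
#' cannot differ in only two bits -- a single position swap i -> j changes
#' the checksum by (j - i) mod n != 0 -- so the class has minimum distance 4.
#' For other distances a greedy lexicographic accept/reject scan is used.
#'
#' @param n_bits total number of bits (readout rounds), e.g. 16.
#' @param weight number of "on" bits per codeword, e.g. 6.
#' @param min_distance required minimum pairwise Hamming distance (even,
#'   >= 2).
#' @return An object of class `codebook`: a list with `n_bits`, `weight`,
#'   `min_distance` and `codes`, a 0/1 integer matrix (one codeword per row,
#'   rows in lexicographic order of the bit string, bit 0 in column 1).
#'   Row names are placeholder labels until [assign_genes()] is called.
#' @examples
#' cb <- generate_codebook(16, 6, 4)
#' nrow(cb$codes)   # >= 448 codewords
#' @export
generate_codebook <- function(n_bits = 16L, weight = 6L, min_distance = 4L) {
  n_bits <- as.integer(n_bits)
  weight <- as.integer(weight)
  min_distance <- as.integer(min_distance)
  if (weight <= 0L || weight >= n_bits)
    stop("infeasible parameters: need 0 < weight < n_bits")
  if (min_distance < 2L || min_distance %% 2L != 0L)
    stop("min_distance must be even and >= 2")

  combs <- utils::combn(n_bits, weight)        # 1-based positions
  words <- matrix(0L, ncol(combs), n_bits)
  words[cbind(rep(seq_len(ncol(combs)), each = weight), as.vector(combs))] <- 1L

  if (min_distance == 2L) {
    codes <- words   # distinct equal-weight words always differ in >= 2 bits
  } else if (min_distance == 4L) {
    s <- (colSums(combs - 1L) %% n_bits)       # 0-based position checksum
    tab <- table(s)
    best <- as.integer(names(tab)[tab == max(tab)])
    codes <- words[s == min(best), , drop = FALSE]
  } else {
    ord <- do.call(order, as.data.frame(words))
    words <- words[ord, , drop = FALSE]
    keep <- integer(0)
    for (i in seq_len(nrow(words))) {
      if (length(keep) == 0L) { keep <- i; next }
      d <- hamming_to_set(words[i, ], words[keep, , drop = FALSE])
      if (min(d) >= min_distance) keep <- c(keep, i)
    }
    codes <- words[keep, , drop = FALSE]
  }

  codes <- codes[do.call(order, as.data.frame(codes)), , drop = FALSE]
  rownames(codes) <- sprintf("Code-%d", seq_len(nrow(codes)))
  structure(
    list(n_bits = n_bits, weight = weight, min_distance = min_distance,
         codes = codes),
    class = "codebook")
}

# Hamming distances from one 0/1 word to the rows of a 0/1 matrix.
hamming_to_set <- function(word, codes) {
  as.vector(codes %*% (1L - word) + (1L - codes) %*% word)
}

#' @export
print.codebook <- function(x, ...) {
  n_blank <- sum(startsWith(rownames(x$codes), "Blank-"))
  cat(sprintf(
    "codebook: %d codewords (%d bits, weight %d, min distance %d)\n",
    nrow(x$codes), x$n_bits, x$weight, x$min_distance))
  if (n_blank > 0)
    cat(sprintf("  %d gene(s), %d blank(s)\n",
                nrow(x$codes) - n_blank, n_blank))
  invisible(x)
}

#' Take the first n codewords of a codebook
#'
#' The checksum-class construction typically yields more codewords than an
#' experiment uses (504 at 16 bits / weight 6 / distance 4); a panel is
#' built on a deterministic subset -- the first `n` codewords in
#' lexicographic order -- so that e.g. a 440-gene panel on a 448-codeword
#' book carries exactly 8 blank controls. Subsetting cannot reduce the
#' minimum pairwise distance.
#'
#' @param cb a `codebook`.
#' @param n number of codewords to keep (<= codebook size).
#' @return the truncated `codebook`.
#' @export
subset_codebook <- function(cb, n) {
  stopifnot(inherits(cb, "codebook"), n >= 1L, n <= nrow(cb$codes))
  cb$codes <- cb$codes[seq_len(n), , drop = FALSE]
  cb
}

#' Validate a codebook by exhaustive pairwise comparison
#'
#' @param cb a `codebook`.
#' @return list with `min_distance` (observed minimum pairwise Hamming
#'   distance), `weight_table` (table of codeword weights), `n_duplicates`
#'   (codewords appearing more than once, counted as extra copies) and `ok`
#'   (all invariants hold).
#' @export
validate_codebook <- function(cb) {
  stopifnot(inherits(cb, "codebook"), nrow(cb$codes) > 0L)
  codes <- cb$codes
  w <- rowSums(codes)
  key <- apply(codes, 1L, paste, collapse = "")
  n_dup <- length(key) - length(unique(key))
  min_d <- if (nrow(codes) < 2L) Inf else {
    # cross-products give pairwise distances in two matrix multiplies
    d <- codes %*% t(1L - codes)
    d <- d + t(d)
    min(d[upper.tri(d)])
  }
  list(min_distance = min_d,
       weight_table = table(w),
       n_duplicates = n_dup,
       ok = n_dup == 0L && all(w == cb$weight) && min_d >= cb$min_distance)
}

#' Assign genes to codewords, leaving leftover codewords as blanks
#'
#' Each gene receives a unique codeword; codewords left unassigned become
#' empty-barcode ("blank") controls, labelled `Blank-1 ..` in lexicographic
#' codeword order. Blank counts in decoded data estimate the false-positive
#' rate.
#'
#' When `coexpression_groups` is supplied, the assignment minimises, summed
#' over readout rounds, the number of same-group gene pairs that are both
#' "on" in a round (genes detected in the same round compete for optical
#' space, so co-expressed genes should not share decoding cycles). The
#' optimiser is greedy insertion followed by pairwise-swap hill climbing
#' under a fixed seed. Without groups the assignment is deterministic in
#' input order: gene i gets codeword i.
#'
#' @param cb a `codebook` from [generate_codebook()].
#' @param genes character vector of gene symbols.
#' @param coexpression_groups optional named vector/list mapping gene ->
#'   group id; genes absent from the map are unconstrained.
#' @param seed integer seed for the swap phase.
#' @param max_passes maximum hill-climbing sweeps.
#' @return list with `codebook` (relabelled), `assignment` (data.frame
#'   gene/code/row), `blanks` (blank labels) and `collision_score`.
#' @export
assign_genes <- function(cb, genes, coexpression_groups = NULL, seed = 1L,
                         max_passes = 20L) {
  stopifnot(inherits(cb, "codebook"))
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene symbols")
  n_codes <- nrow(cb$codes)
  if (length(genes) > n_codes)
    stop(sprintf("capacity error: %d genes but only %d codewords",
                 length(genes), n_codes))

  slot <- seq_along(genes)                 # gene i -> codeword row slot[i]
  if (!is.null(coexpression_groups) && length(genes) > 1L) {
    grp <- unlist(coexpression_groups)[genes]
    names(grp) <- genes
    slot <- optimize_assignment(cb$codes, genes, grp, seed, max_passes)
  }

  labels <- rownames(cb$codes)
  labels[slot] <- genes
  blank_rows <- setdiff(seq_len(n_codes), slot)
  labels[blank_rows] <- sprintf("Blank-%d", seq_along(blank_rows))
  out <- cb
  rownames(out$codes) <- labels

  assignment <- data.frame(
    gene = genes,
    code = apply(cb$codes[slot, , drop = FALSE], 1L, paste, collapse = ""),
    row = slot, stringsAsFactors = FALSE)
  list(codebook = out,
       assignment = assignment,
       blanks = labels[blank_rows],
       collision_score = collision_score(cb$codes, slot, genes,
                                         coexpression_groups))
}

# Rounds-summed count of same-group gene pairs sharing an "on" bit.
collision_score <- function(codes, slot, genes, groups) {
  if (is.null(groups) || length(genes) < 2L) return(0L)
  grp <- unlist(groups)[genes]
  keep <- !is.na(grp)
  if (sum(keep) < 2L) return(0L)
  m <- codes[slot[keep], , drop = FALSE]
  g <- grp[keep]
  score <- 0L
  for (r in seq_len(ncol(m))) {
    on <- g[m[, r] == 1L]
    if (length(on) > 1L) {
      tab <- table(on)
      score <- score + sum(choose(tab, 2L))
    }
  }
  as.integer(score)
}

optimize_assignment <- function(codes, genes, grp, seed, max_passes) {
  n <- length(genes)
  n_codes <- nrow(codes)
  # greedy: each gene takes the free codeword adding fewest collisions
  slot <- integer(n)
  used <- logical(n_codes)
  for (i in seq_len(n)) {
    free <- which(!used)
    if (is.na(grp[i])) { slot[i] <- free[1L]; used[free[1L]] <- TRUE; next }
    mates <- which(!is.na(grp[seq_len(i - 1L)]) &
                     grp[seq_len(i - 1L)] == grp[i])
    if (length(mates) == 0L) { slot[i] <- free[1L]; used[free[1L]] <- TRUE; next }
    mate_on <- colSums(codes[slot[mates], , drop = FALSE])
    cost <- as.vector(codes[free, , drop = FALSE] %*% mate_on)
    best <- free[which.min(cost)]
    slot[i] <- best; used[best] <- TRUE
  }
  # pairwise-swap hill climbing over gene/gene and gene/blank swaps
  score <- collision_score(codes, slot, genes, grp)
  if (score == 0L) return(slot)
  rng <- local({ set.seed(seed); NULL })
  set.seed(seed)
  for (pass in seq_len(max_passes)) {
    improved <- FALSE
    order_i <- sample.int(n)
    for (i in order_i) {
      if (is.na(grp[i])) next
      cands <- c(setdiff(which(!is.na(grp)), i), which(!used))
      for (j in cands) {
        new_slot <- slot
        if (j <= n && j >= 1 && !is.na(grp[j]) && j != i) {
          new_slot[c(i, j)] <- slot[c(j, i)]
        } else next
        s2 <- collision_score(codes, new_slot, genes, grp)
        if (s2 < score) { slot <- new_slot; score <- s2; improved <- TRUE }
      }
      # try moving gene i onto any unused codeword
      for (f in which(!used)) {
        new_slot <- slot; new_slot[i] <- f
        s2 <- collision_score(codes, new_slot, genes, grp)
        if (s2 < score) {
          used[slot[i]] <- FALSE; used[f] <- TRUE
          slot <- new_slot; score <- s2; improved <- TRUE
        }
      }
      if (score == 0L) return(slot)
    }
    if (!improved) break
  }
  slot
}

#' Decode an observed bit word against a codebook
#'
#' Nearest-neighbour decoding with bounded correction: the word is called
#' as the unique codeword within Hamming distance `max_correct`; if no
#' codeword is close enough, or two are equally close, the result is a
#' no-call (never an arbitrary pick -- ambiguous calls would bias the
#' blank-based false-positive rate).
#'
#' @param observed 0/1 vector of length `cb$n_bits`.
#' @param cb a `codebook` (labels from [assign_genes()] if genes assigned).
#' @param max_correct maximum correctable bit errors (default 1; with
#'   minimum distance 4 one error is corrected while two are detected).
#' @return list with `label` (codeword label or `NA` for no-call),
#'   `bit_errors` (distance to the called codeword) and `reason`
#'   (`"ok"`, `"distance"` or `"tie"`).
#' @export
decode_word <- function(observed, cb, max_correct = 1L) {
  stopifnot(length(observed) == cb$n_bits)
  res <- decode_words(matrix(as.integer(observed), 1L), cb, max_correct)
  list(label = res$label[1L], bit_errors = res$bit_errors[1L],
       reason = res$reason[1L])
}

#' Decode many observed words at once
#'
#' Vectorised form of [decode_word()] used by the molecule decoder.
#'
#' @param words 0/1 integer matrix, one observed word per row.
#' @inheritParams decode_word
#' @return data.frame with columns `label`, `bit_errors`, `reason`.
#' @export
decode_words <- function(words, cb, max_correct = 1L) {
  stopifnot(ncol(words) == cb$n_bits)
  codes <- cb$codes
  storage.mode(words) <- "double"
  storage.mode(codes) <- "double"
  # Hamming distance is |w| + |c| - 2 <w, c>; per row, minimising it is
  # maximising <w, c> - |c| / 2 (just <w, c> for a constant-weight code)
  s <- tcrossprod(words, codes)
  cw <- rowSums(codes)
  adj <- if (length(unique(cw)) == 1L) s else
    s - rep(cw / 2, each = nrow(s))
  best <- max.col(adj, ties.method = "first")
  ii <- cbind(seq_len(nrow(s)), best)
  dmin <- rowSums(words) + cw[best] - 2 * s[ii]
  # a tie exists if another codeword attains the same minimal distance
  n_at_min <- rowSums(adj == adj[ii])
  label <- rownames(codes)[best]
  reason <- rep("ok", nrow(words))
  bad_d <- dmin > max_correct
  bad_t <- !bad_d & n_at_min > 1L
  label[bad_d | bad_t] <- NA_character_
  reason[bad_d] <- "distance"
  reason[bad_t] <- "tie"
  bit_errors <- ifelse(is.na(label), NA_integer_, dmin)
  data.frame(label = label, bit_errors = bit_errors, reason = reason,
             stringsAsFactors = FALSE)
}

#' Write a codebook to CSV
#'
#' Format: header `label,code`; `code` is an `n_bits`-character string of
#' 0/1 with bit 0 leftmost.
#'
#' @param cb a `codebook`.
#' @param path output file.
#' @export
write_codebook <- function(cb, path) {
  df <- data.frame(
    label = rownames(cb$codes),
    code = apply(cb$codes, 1L, paste, collapse = ""),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a codebook from CSV
#'
#' @param path CSV with columns `label,code` as written by
#'   [write_codebook()].
#' @param min_distance distance the codebook claims; re-verified with
#'   [validate_codebook()] by callers as needed.
#' @return a `codebook`.
#' @export
read_codebook <- function(path, min_distance = 4L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character"))
  codes <- do.call(rbind, lapply(strsplit(df$code, ""), as.integer))
  rownames(codes) <- df$label
  structure(
    list(n_bits = ncol(codes), weight = as.integer(rowSums(codes)[1L]),
         min_distance = as.integer(min_distance), codes = codes),
    class = "codebook")
}

#' "On" bits of a labelled codeword
#'
#' @param cb a `codebook`.
#' @param label a codeword label (gene or blank).
#' @return integer vector of 0-based round indices where the bit is set.
#' @export
on_bits <- function(cb, label) {
  row <- cb$codes[label, ]
  which(row == 1L) - 1L
}
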