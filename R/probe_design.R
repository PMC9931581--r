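# Encoding-probe design: thermodynamic scoring, composition and structure
# filters, off-target screening, transcript tiling and oligo assembly.

.nn_env <- new.env(parent = emptyenv())

# Unified DNA/DNA nearest-neighbor free energies at 37 degC, shipped as a
# CSV data asset. Values are kcal/mol per stacked dimer, plus terminal
# initiation penalties and the self-complementarity correction.
nn_table <- function() {
  if (is.null(.nn_env$tab)) {
    path <- system.file("extdata", "nn_dg37_unified.csv", package = "spotcode")
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    .nn_env$tab <- stats::setNames(df$dg37_kcal_mol, df$term)
  }
  .nn_env$tab
}

#' G+C content of a sequence
#'
#' @param seq DNA sequence (character scalar, A/C/G/T, case-insensitive).
#' @return percent G+C, `100 * (G + C) / length`.
#' @examples
#' gc_content("ATGC")  # 50
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty sequence")
  b <- strsplit(seq, "")[[1L]]
  100 * sum(b %in% c("G", "C")) / length(b)
}

#' Duplex free energy by the nearest-neighbor model
#'
#' Predicted standard free energy of duplex formation at 37 degC for a DNA
#' oligo bound to its perfect complement: the sum of stacked-dimer terms
#' from the unified nearest-neighbor parameter table, plus terminal
#' initiation penalties and, for self-complementary sequences, the symmetry
#' correction. More negative means stronger binding. Probe-RNA hybrids are
#' scored with the same DNA/DNA table (the panel threshold is calibrated
#' against it); only 37 degC parameters are shipped.
#'
#' @param seq DNA sequence, length >= 2.
#' @param temp_c evaluation temperature; only 37 is supported.
#' @return free energy in kcal/mol.
#' @export
duplex_delta_g <- function(seq, temp_c = 37) {
  if (temp_c != 37) stop("only 37 degC parameters are shipped")
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 2L) stop("need at least 2 nucleotides")
  b <- strsplit(seq, "")[[1L]]
  if (!all(b %in% c("A", "C", "G", "T"))) stop("non-ACGT character")
  tab <- nn_table()
  dimers <- paste0(b[-n], b[-1L])
  dg <- sum(tab[dimers])
  ends <- b[c(1L, n)]
  dg <- dg + sum(ifelse(ends %in% c("G", "C"), tab["init_GC"], tab["init_AT"]))
  if (identical(seq, revcomp(seq))) dg <- dg + tab["symmetry"]
  unname(dg)
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTUacgtu", "TGCAAtgcaa", seq), "")[[1L]]),
        collapse = "")
}

#' Self-structure free energy (hairpin / homodimer)
#'
#' Minimum predicted free energy over self-complementary stems: all
#' ungapped antiparallel self-alignments (homodimer registers), each stem
#' scored with [duplex_delta_g()]. Every hairpin stem (two arms of the same
#' molecule pairing around a loop) is also an ungapped self-alignment with
#' the identical stem energy, so the register scan covers hairpins as well
#' and the reported minimum is the minimum over both structure classes.
#' Returns 0 when no complementary stem of at least `min_run` bp exists.
#' Probes whose value is below the panel threshold (default -9 kcal/mol)
#' are predicted to fold or dimerise and are rejected.
#'
#' @param seq DNA sequence, length >= 6.
#' @param min_run minimum scored stem length in bp.
#' @return free energy in kcal/mol (<= 0).
#' @export
self_structure_delta_g <- function(seq, min_run = 2L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 6L) stop("sequence too short for structure evaluation")
  b <- strsplit(seq, "")[[1L]]
  comp <- chartr("ACGT", "TGCA", seq)
  cb <- strsplit(comp, "")[[1L]]
  best <- 0
  # register cc: position i of one copy pairs position cc - i of the other
  for (cc in 3:(2L * n)) {
    i_lo <- max(1L, cc - n); i_hi <- min(n, cc - 1L)
    if (i_hi - i_lo + 1L < min_run) next
    paired <- b[i_lo:i_hi] == cb[cc - (i_lo:i_hi)]
    r <- rle(paired)
    ends <- cumsum(r$lengths)
    for (k in which(r$values & r$lengths >= min_run)) {
      run_start <- i_lo + ends[k] - r$lengths[k]
      dg <- duplex_delta_g(substr(seq, run_start,
                                  run_start + r$lengths[k] - 1L))
      if (dg < best) best <- dg
    }
  }
  best
}

#' Off-target specificity screen
#'
#' Seed-and-extend screen standing in for a full alignment search: the
#' probe's target-sense window is screened against every non-target
#' transcript using exact 12-mer seeds; each seed hit is extended to an
#' ungapped window of probe length and scored by fractional identity. The
#' probe fails when `max_offtargets` or more distinct transcripts contain a
#' window with identity strictly above `identity_frac`.
#'
#' @param probe list with `gene` and `binding_seq` (reverse complement of
#'   the target window), as produced by [generate_candidates()].
#' @param transcriptome named character vector or list of transcript
#'   sequences (names = gene symbols).
#' @param identity_frac identity threshold (exclusive), default 0.60.
#' @param max_offtargets number of off-target species that triggers
#'   failure, default 5 ("five or more").
#' @param seed_len exact-match seed length.
#' @return list with `pass` and `hits` (data.frame gene/identity).
#' @export
offtarget_screen <- function(probe, transcriptome, identity_frac = 0.60,
                             max_offtargets = 5L, seed_len = 12L) {
  target <- toupper(revcomp(probe$binding_seq))
  plen <- nchar(target)
  if (plen < 26L) stop("probe shorter than 26 nt")
  tb <- strsplit(target, "")[[1L]]
  seeds <- substring(target, seq_len(plen - seed_len + 1L),
                     seq_len(plen - seed_len + 1L) + seed_len - 1L)
  txs <- as.list(transcriptome)
  hit_gene <- character(0); hit_id <- numeric(0)
  for (nm in names(txs)) {
    if (identical(nm, probe$gene)) next
    subj <- toupper(as.character(txs[[nm]]))
    slen <- nchar(subj)
    best <- 0
    for (k in seq_along(seeds)) {
      pos <- gregexpr(seeds[k], subj, fixed = TRUE)[[1L]]
      if (pos[1L] == -1L) next
      for (p in pos) {
        off <- p - k              # transcript position of probe base 1, minus 1
        lo <- max(1L, 1L + off); hi <- min(plen, slen - off)
        if (hi < lo) next
        sb <- strsplit(substr(subj, lo + off, hi + off), "")[[1L]]
        ident <- sum(sb == tb[lo:hi]) / plen
        if (ident > best) best <- ident
      }
      if (best > identity_frac) break
    }
    if (best > identity_frac) {
      hit_gene <- c(hit_gene, nm); hit_id <- c(hit_id, best)
    }
  }
  hits <- data.frame(gene = hit_gene, identity = hit_id,
                     stringsAsFactors = FALSE)
  list(pass = nrow(hits) < max_offtargets, hits = hits)
}

#' Enumerate candidate probes on a transcript
#'
#' All windows of length 26-32 nt, ordered by start position then length,
#' scored for binding free energy, G+C content and self-structure. The
#' binding sequence is the reverse complement of the transcript window.
#'
#' @param gene gene symbol.
#' @param sequence transcript sequence (sense strand, A/C/G/T; U is mapped
#'   to T).
#' @param lengths window lengths to consider.
#' @return data.frame: gene, start, end (0-based half-open on the
#'   transcript), binding_seq, dg_bind, gc_percent, dg_structure.
#' @export
generate_candidates <- function(gene, sequence, lengths = 26:32) {
  sequence <- chartr("Uu", "Tt", toupper(sequence))
  n <- nchar(sequence)
  rows <- list()
  for (start in 0:(max(n - min(lengths), -1L))) {
    for (L in lengths) {
      if (start + L > n) next
      win <- substr(sequence, start + 1L, start + L)
      if (grepl("[^ACGT]", win)) next
      bseq <- revcomp(win)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, start = start, end = start + L,
        binding_seq = bseq,
        dg_bind = duplex_delta_g(win),
        gc_percent = gc_content(win),
        dg_structure = self_structure_delta_g(bseq),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(gene = character(0), start = integer(0),
                      end = integer(0), binding_seq = character(0),
                      dg_bind = numeric(0), gc_percent = numeric(0),
                      dg_structure = numeric(0)))
  do.call(rbind, rows)
}

#' Filter candidate probes on the panel rules
#'
#' @param candidates data.frame from [generate_candidates()].
#' @param transcriptome optional named sequences for the off-target screen;
#'   `NULL` skips the screen.
#' @param max_dg_bind binding free-energy ceiling (kcal/mol); candidates
#'   must bind at least this strongly.
#' @param gc_range allowed G+C percent range.
#' @param min_dg_structure structure floor (kcal/mol); candidates whose
#'   predicted hairpin/homodimer is stronger (more negative) are dropped.
#' @inheritParams offtarget_screen
#' @return the surviving rows.
#' @export
filter_candidates <- function(candidates, transcriptome = NULL,
                              max_dg_bind = -28, gc_range = c(40, 60),
                              min_dg_structure = -9.0,
                              identity_frac = 0.60, max_offtargets = 5L) {
  keep <- candidates$dg_bind <= max_dg_bind &
    candidates$gc_percent >= gc_range[1L] &
    candidates$gc_percent <= gc_range[2L] &
    candidates$dg_structure >= min_dg_structure
  out <- candidates[keep, , drop = FALSE]
  if (!is.null(transcriptome) && nrow(out) > 0L) {
    ok <- vapply(seq_len(nrow(out)), function(i) {
      offtarget_screen(list(gene = out$gene[i],
                            binding_seq = out$binding_seq[i]),
                       transcriptome, identity_frac, max_offtargets)$pass
    }, logical(1L))
    out <- out[ok, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Tile a transcript with non-overlapping probes
#'
#' Greedy left-to-right selection: repeatedly take the leftmost candidate
#' whose start is at least `min_gap` nt past the previous probe's end,
#' until `max_probes` are selected. Candidates are considered by start
#' position, then by length ascending, so the result is deterministic.
#'
#' @param candidates filtered candidate data.frame.
#' @param min_gap minimum gap between consecutive probes (nt).
#' @param max_probes cap on probes per transcript.
#' @return the selected rows in transcript order.
#' @export
tile_transcript <- function(candidates, min_gap = 2L, max_probes = 28L) {
  if (nrow(candidates) == 0L) return(candidates)
  ord <- order(candidates$start, candidates$end - candidates$start)
  cand <- candidates[ord, , drop = FALSE]
  sel <- integer(0)
  next_start <- -Inf
  for (i in seq_len(nrow(cand))) {
    if (length(sel) >= max_probes) break
    if (cand$start[i] >= next_start) {
      sel <- c(sel, i)
      next_start <- cand$end[i] + min_gap
    }
  }
  out <- cand[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a readout (detection) sequence library
#'
#' One 20-nt detection sequence per bit, generated deterministically from a
#' seed, with pairwise distinctness and moderate G+C enforced. In a real
#' experiment these are validated published sequences; here they serve as
#' placeholders with the same interface.
#'
#' @param n_bits number of bits / readout rounds.
#' @param seed RNG seed.
#' @param channel fluorophore channel label applied to all entries.
#' @return data.frame: bit (0-based), id, sequence, channel.
#' @export
make_readout_library <- function(n_bits = 16L, seed = 42L,
                                 channel = "A647") {
  set.seed(seed)
  seqs <- character(0)
  while (length(seqs) < n_bits) {
    s <- paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE),
               collapse = "")
    gc <- gc_content(s)
    if (gc >= 40 && gc <= 60 && !(s %in% seqs)) seqs <- c(seqs, s)
  }
  data.frame(bit = seq_len(n_bits) - 1L,
             id = sprintf("RO-%02d", seq_len(n_bits) - 1L),
             sequence = seqs, channel = channel,
             stringsAsFactors = FALSE)
}

#' Assemble an encoding-probe oligo
#'
#' Layout: the full RNA-binding sequence at the 5' side, followed by the
#' six readout sequences of the gene's "on" bits in the given order, each
#' preceded by a 2-nt spacer cycling TT, AT, TA, AA (a spacer also precedes
#' the first readout, so the assembled length is binding length + 6 x 22).
#'
#' @param binding_seq probe binding sequence.
#' @param tail_bits 0-based bit indices, in tail order.
#' @param readout_library data.frame from [make_readout_library()].
#' @return the assembled oligo, 5' to 3'.
#' @export
assemble_probe <- function(binding_seq, tail_bits, readout_library) {
  spacers <- c("TT", "AT", "TA", "AA")
  ro <- stats::setNames(readout_library$sequence, readout_library$bit)
  tail <- vapply(seq_along(tail_bits), function(k) {
    paste0(spacers[(k - 1L) %% 4L + 1L], ro[as.character(tail_bits[k])])
  }, character(1L))
  paste0(binding_seq, paste(tail, collapse = ""))
}

#' Design the full encoding-probe panel
#'
#' Per assigned gene: enumerate candidates over all offsets and lengths
#' 26-32, apply the thermodynamic/composition/structure/off-target filters,
#' tile the transcript, and drop genes with fewer than `min_probes`
#' surviving probes. Each kept probe is assembled with the six readout
#' sequences of the gene's "on" bits in a per-probe randomized order
#' (seeded), so repeated runs with the same seed are byte-identical.
#'
#' @param transcripts named character vector / `DNAStringSet` of transcript
#'   sequences, names matching assigned genes.
#' @param assignment result of [assign_genes()] (uses its `codebook` and
#'   `assignment` fields).
#' @param readout_library data.frame from [make_readout_library()].
#' @param seed RNG seed for tail-order randomization.
#' @param min_probes minimum surviving probes per gene.
#' @param max_probes tiling cap per gene.
#' @param lengths candidate window lengths.
#' @param screen_offtargets run [offtarget_screen()] against the other
#'   panel transcripts.
#' @param ... further filter parameters passed to [filter_candidates()].
#' @return list with `panel` (data.frame: gene, start, end, binding_seq,
#'   tail_order, full_sequence, dg_bind, gc_percent, dg_structure) and
#'   `dropped` (genes failing `min_probes`, with their probe counts).
#' @export
design_panel <- function(transcripts, assignment, readout_library,
                         seed = 7L, min_probes = 10L, max_probes = 28L,
                         lengths = 26:32, screen_offtargets = TRUE, ...) {
  if (inherits(transcripts, "DNAStringSet"))
    transcripts <- stats::setNames(as.character(transcripts),
                                   names(transcripts))
  genes <- assignment$assignment$gene
  missing <- setdiff(genes, names(transcripts))
  if (length(missing) > 0L)
    stop("missing transcript for assigned gene(s): ",
         paste(missing, collapse = ", "))
  cb <- assignment$codebook
  set.seed(seed)
  panel <- list(); dropped_gene <- character(0); dropped_n <- integer(0)
  for (g in genes) {
    cand <- generate_candidates(g, transcripts[[g]], lengths = lengths)
    cand <- filter_candidates(
      cand,
      transcriptome = if (screen_offtargets) transcripts else NULL, ...)
    tiles <- tile_transcript(cand, max_probes = max_probes)
    if (nrow(tiles) < min_probes) {
      dropped_gene <- c(dropped_gene, g)
      dropped_n <- c(dropped_n, nrow(tiles))
      next
    }
    bits <- on_bits(cb, g)
    tiles$tail_order <- vapply(seq_len(nrow(tiles)), function(i) {
      paste(sample(bits), collapse = ",")
    }, character(1L))
    tiles$full_sequence <- vapply(seq_len(nrow(tiles)), function(i) {
      assemble_probe(tiles$binding_seq[i],
                     as.integer(strsplit(tiles$tail_order[i], ",")[[1L]]),
                     readout_library)
    }, character(1L))
    panel[[g]] <- tiles
  }
  panel <- if (length(panel) > 0L) do.call(rbind, panel) else
    data.frame()
  rownames(panel) <- NULL
  list(panel = panel,
       dropped = data.frame(gene = dropped_gene, n_probes = dropped_n,
                            stringsAsFactors = FALSE))
}

#' Write a probe panel as TSV
#'
#' Includes a metadata header line recording the spacer-placement
#' convention (a 2-nt spacer precedes every readout, including the first).
#'
#' @param design result of [design_panel()].
#' @param path output file.
#' @export
write_panel <- function(design, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# spacer_convention=before_each_readout ",
                    "spacer_cycle=TT,AT,TA,AA layout=binding_5prime"), con)
  utils::write.table(design$panel, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
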