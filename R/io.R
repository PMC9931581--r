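# Plain-text I/O for spot tables and transcript FASTA.

#' Write a spot table to CSV
#'
#' @param spots data.frame with at least `round`, `x_um`, `y_um`,
#'   `intensity`, `is_bead`.
#' @param path output CSV.
#' @export
write_spot_table <- function(spots, path) {
  utils::write.csv(spots, path, row.names = FALSE)
  invisible(path)
}

#' Read a spot table from CSV
#'
#' @param path CSV written by [write_spot_table()] (or any table with
#'   columns `round`, `x_um`, `y_um`, `intensity` and optionally
#'   `is_bead`).
#' @return data.frame with `is_bead` defaulting to `FALSE` when absent.
#' @export
read_spot_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"is_bead" %in% names(df)) df$is_bead <- FALSE
  df
}

#' Read transcript sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences (names = record ids up to
#'   the first whitespace).
#' @export
read_transcripts <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
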