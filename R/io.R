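# File-format helpers shared by the pipeline readers and writers.

#' Read a FASTA file as named uppercase strings
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  seqs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  stats::setNames(toupper(vapply(seqs, as.character, character(1))),
                  names(seqs))
}

#' Write named sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = 80)
  invisible(path)
}

#' Read a per-base depth profile from a three-column TSV
#'
#' Accepts the bundle format (`reference_id`, `position`, `depth`) or any
#' headerless three-column `reference position depth` table as produced by
#' standard genome-coverage utilities. Positions are 1-based.
#'
#' @param path TSV file.
#' @param ref_length Optional reference length; positions missing from the
#'   file are filled with depth 0.
#' @return A [depth_profile].
#' @export
read_depth_tsv <- function(path, ref_length = NULL) {
  first <- readLines(path, n = 1)
  has_header <- grepl("position", first)
  d <- data.table::fread(path, header = has_header, data.table = FALSE)
  if (!has_header) names(d) <- c("reference_id", "position", "depth")
  L <- ref_length %||% max(d$position)
  depth <- integer(L)
  depth[d$position] <- d$depth
  depth_profile(d$reference_id[1], depth)
}

#' Read a per-site base-count table
#'
#' @param path TSV with columns reference_id, position, A, C, G, T, del.
#' @param ref_length Optional reference length (missing rows become zero
#'   counts).
#' @return Matrix with columns A, C, G, T, del, one row per reference
#'   position.
#' @export
read_counts_tsv <- function(path, ref_length = NULL) {
  d <- data.table::fread(path, data.table = FALSE)
  L <- ref_length %||% max(d$position)
  counts <- matrix(0L, L, 5, dimnames = list(NULL,
                                             c("A", "C", "G", "T", "del")))
  counts[d$position, ] <- as.matrix(d[, c("A", "C", "G", "T", "del")])
  counts
}
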