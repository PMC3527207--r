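#' Partitioned ungapped alignment
#'
#' A `partitioned_alignment` is a character matrix over A/C/G/T (rows =
#' strains, columns = alignment sites) carrying, per column, the site-class
#' label and the 1-based coordinate of the site in the original reference.
#' It is constructed from reference-anchored consensus sequences by dropping
#' every column in which any strain has an N (fully ambiguous base or
#' deletion), so downstream distance and likelihood computations never see
#' missing data.
#'
#' @param mat Character matrix over A,C,G,T with one row per strain.
#' @param site_class Character vector of per-column class labels (e.g.
#'   `"codon1"`, `"codon2"`, `"codon3"`, `"ncRNA"`, `"noncoding"`).
#' @param ref_pos Integer vector of 1-based reference coordinates, strictly
#'   increasing.
#' @param ref_id Single reference identifier.
#' @return An object of class `"partitioned_alignment"`.
#' @export
partitioned_alignment <- function(mat, site_class, ref_pos,
                                  ref_id = "reference") {
  mat <- as.matrix(mat)
  if (ncol(mat) != length(site_class) || ncol(mat) != length(ref_pos))
    stop("site_class and ref_pos must have one entry per alignment column")
  if (ncol(mat) > 0 && any(!mat %in% BASES))
    stop("alignment may contain only A, C, G, T")
  if (is.unsorted(ref_pos, strictly = TRUE))
    stop("ref_pos must be strictly increasing")
  structure(list(mat = mat, site_class = as.character(site_class),
                 ref_pos = as.integer(ref_pos), ref_id = ref_id),
            class = "partitioned_alignment")
}

#' @exportS3Method base::print
print.partitioned_alignment <- function(x, ...) {
  cat(sprintf("partitioned_alignment: %d strains x %d sites (%s)\n",
              nrow(x$mat), ncol(x$mat), x$ref_id))
  print(table(x$site_class))
  invisible(x)
}

#' @export
dim.partitioned_alignment <- function(x) dim(x$mat)

#' Build a gap-free partitioned alignment from consensus sequences
#'
#' Stacks reference-anchored consensus sequences into a matrix and removes
#' every alignment column that contains an N in any strain. N can represent
#' either a fully ambiguous character or a deletion relative to the
#' reference, so the surviving columns form an "essentially complete"
#' alignment. Surviving columns keep their site-class labels and original
#' reference coordinates.
#'
#' @param consensus Named character vector of consensus sequences (one string
#'   per strain), all of reference length, over A/C/G/T/N.
#' @param site_class Character vector of per-reference-position class labels
#'   (same length as the reference).
#' @param ref_id Reference identifier stored on the result.
#' @return A [partitioned_alignment].
#' @export
build_ungapped_alignment <- function(consensus, site_class,
                                     ref_id = "reference") {
  if (is.null(names(consensus)) || anyDuplicated(names(consensus)))
    stop("consensus sequences must have unique strain names")
  L <- unique(nchar(consensus))
  if (length(L) != 1)
    stop("all consensus sequences must have the same length")
  if (length(site_class) != L)
    stop("site_class must cover every reference position")
  mat <- do.call(rbind, strsplit(toupper(consensus), ""))
  rownames(mat) <- names(consensus)
  keep <- colSums(mat == "N" | !matrix(mat %in% BASES, nrow(mat))) == 0
  partitioned_alignment(mat[, keep, drop = FALSE],
                        site_class[keep], which(keep), ref_id)
}

#' Concatenate partitioned alignments
#'
#' Joins two or more alignments over the same strain set column-wise,
#' prefixing site-class labels with the per-alignment names so that
#' partitions from different genomes stay distinct (e.g. `mt.codon3`,
#' `wol.noncoding`).
#'
#' @param ... Named [partitioned_alignment] objects sharing identical row
#'   (strain) sets.
#' @return A [partitioned_alignment] with relabelled classes and running
#'   coordinates.
#' @export
concat_alignments <- function(...) {
  alns <- list(...)
  if (length(alns) == 1 && is.list(alns[[1]]) &&
      !inherits(alns[[1]], "partitioned_alignment")) alns <- alns[[1]]
  if (is.null(names(alns)) || any(names(alns) == ""))
    stop("alignments must be named, e.g. concat_alignments(mt = ..., wol = ...)")
  strains <- rownames(alns[[1]]$mat)
  mats <- lapply(alns, function(a) {
    if (!setequal(rownames(a$mat), strains))
      stop("all alignments must contain the same strains")
    a$mat[strains, , drop = FALSE]
  })
  classes <- unlist(lapply(names(alns), function(nm)
    paste(nm, alns[[nm]]$site_class, sep = ".")), use.names = FALSE)
  mat <- do.call(cbind, mats)
  partitioned_alignment(mat, classes, seq_len(ncol(mat)),
                        ref_id = paste(names(alns), collapse = "+"))
}

#' Subset a partitioned alignment by strain
#'
#' @param aln A [partitioned_alignment].
#' @param strains Character vector of row names to keep (in this order).
#' @return A [partitioned_alignment] restricted to `strains`.
#' @export
subset_alignment <- function(aln, strains) {
  missing <- setdiff(strains, rownames(aln$mat))
  if (length(missing))
    stop("strains not present in alignment: ", paste(missing, collapse = ", "))
  partitioned_alignment(aln$mat[strains, , drop = FALSE],
                        aln$site_class, aln$ref_pos, aln$ref_id)
}

#' Pairwise distances between alignment rows
#'
#' @param aln A [partitioned_alignment] with at least two rows.
#' @param model `"raw"` for the mismatch fraction (p-distance) or `"JC"` for
#'   the Jukes-Cantor correction `-(3/4) log(1 - (4/3) p)`.
#' @return A symmetric matrix of distances with zero diagonal.
#' @export
pairwise_distances <- function(aln, model = c("raw", "JC")) {
  model <- match.arg(model)
  mat <- aln$mat
  n <- nrow(mat)
  L <- ncol(mat)
  if (n < 2) stop("at least two sequences are required")
  if (L < 1) stop("alignment has no columns")
  num <- matrix(match(t(mat), BASES), nrow = L)  # L x n integer codes
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    di <- colMeans(num[, i] != num[, (i + 1):n, drop = FALSE])
    D[i, (i + 1):n] <- di
    D[(i + 1):n, i] <- di
  }
  if (model == "JC") {
    if (any(D[upper.tri(D)] >= 0.75))
      stop("p >= 0.75: Jukes-Cantor distance undefined (saturation)")
    D[] <- -0.75 * log(1 - (4 / 3) * D)
    diag(D) <- 0
  }
  D
}

# Split a partitioned alignment into per-class character matrices.
split_by_class <- function(aln) {
  cls <- unique(aln$site_class)
  stats::setNames(lapply(cls, function(cl)
    aln$mat[, aln$site_class == cl, drop = FALSE]), cls)
}

#' Read a site-class annotation track
#'
#' Expands an interval annotation (`reference_id`, `start`, `end`, `class`;
#' 1-based inclusive coordinates) into a per-position class vector.
#'
#' @param path TSV file with columns reference_id, start, end, class.
#' @param ref_id Reference to extract.
#' @param ref_length Length of the reference sequence.
#' @return Character vector of length `ref_length`.
#' @export
read_annotation_track <- function(path, ref_id, ref_length) {
  ann <- data.table::fread(path, sep = "\t", data.table = FALSE)
  ann <- ann[ann$reference_id == ref_id, , drop = FALSE]
  out <- rep("noncoding", ref_length)
  for (i in seq_len(nrow(ann))) out[ann$start[i]:ann$end[i]] <- ann$class[i]
  out
}
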