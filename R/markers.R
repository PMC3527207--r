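#' Describe an IS5 diagnostic locus
#'
#' Bundles the two allelic reference haplotypes of an insertion-sequence
#' locus: the insertion haplotype (left flank + IS5 element + right flank)
#' and the empty haplotype (left flank + right flank), together with the
#' junction coordinates needed for junction-read counting. The two
#' diagnostic loci of the wMel system are `WD0516_7`
#' (AE017196:507322-509812) and `WD1310` (AE017196:1251363-1252108).
#'
#' @param locus Locus name.
#' @param flank_left,flank_right Flanking sequences (>= overhang long).
#' @param is5 The transposon sequence.
#' @param window Reference window, 1-based inclusive `c(start, end)`
#'   (metadata only).
#' @return Object of class `"is5_locus"`.
#' @export
is5_locus <- function(locus, flank_left, is5, flank_right,
                      window = c(NA_integer_, NA_integer_)) {
  structure(list(
    locus = locus, window = window,
    insertion = paste0(flank_left, is5, flank_right),
    empty = paste0(flank_left, flank_right),
    junctions_insertion = c(nchar(flank_left),
                            nchar(flank_left) + nchar(is5)),
    junction_empty = nchar(flank_left)),
    class = "is5_locus")
}

revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

junction_probe <- function(haplotype, pos, overhang) {
  substr(haplotype, pos - overhang + 1, pos + overhang)
}

count_probe_hits <- function(reads, probe, max_mismatch) {
  probes <- c(probe, revcomp(probe))
  if (max_mismatch == 0) {
    sum(grepl(probes[1], reads, fixed = TRUE) |
          grepl(probes[2], reads, fixed = TRUE))
  } else {
    md <- list(sub = max_mismatch, ins = 0, del = 0)
    sum(agrepl(probes[1], reads, max.distance = md, fixed = TRUE) |
          agrepl(probes[2], reads, max.distance = md, fixed = TRUE))
  }
}

#' Detect IS5 presence at a diagnostic locus from reads
#'
#' Counts reads spanning the insertion junctions (with at least `overhang`
#' bases on each side) versus reads spanning the empty-site junction, by
#' seed matching of junction probes in both orientations. A locus is
#' `present` when insertion-junction support reaches `min_junction_reads`
#' and empty-site support stays below it; `absent` in the converse case;
#' `indeterminate` when reads are too short (`read_length <= 75`), both
#' signals are present, or neither reaches the threshold.
#'
#' @param reads Character vector of read sequences.
#' @param locus An [is5_locus()].
#' @param min_junction_reads Support threshold (default 3).
#' @param overhang Minimum bases on each side of the junction (default 20).
#' @param read_length Read length; calls are refused at `<= 75` bp.
#' @param max_mismatch Allowed substitutions in a probe match (default 0).
#' @return Object of class `"is5_call"`: `locus`, `window`, `status`,
#'   `junction_reads`, `empty_reads`.
#' @export
detect_is5_presence <- function(reads, locus, min_junction_reads = 3,
                                overhang = 20,
                                read_length = max(nchar(reads)),
                                max_mismatch = 0) {
  if (!inherits(locus, "is5_locus"))
    stop("both reference haplotypes are required (see is5_locus())")
  status <- NULL
  jr <- er <- NA_integer_
  if (read_length <= 75) {
    status <- "indeterminate"
  } else {
    jr <- sum(vapply(locus$junctions_insertion, function(pos)
      count_probe_hits(reads, junction_probe(locus$insertion, pos, overhang),
                       max_mismatch), numeric(1)))
    er <- count_probe_hits(reads,
                           junction_probe(locus$empty, locus$junction_empty,
                                          overhang), max_mismatch)
    status <- if (jr >= min_junction_reads && er < min_junction_reads)
      "present"
    else if (er >= min_junction_reads && jr < min_junction_reads) "absent"
    else "indeterminate"
  }
  structure(list(locus = locus$locus, window = locus$window,
                 status = status, junction_reads = jr, empty_reads = er),
            class = "is5_call")
}

#' Genotype assignment from the two diagnostic IS5 loci
#'
#' IS5 present at WD0516/7 and absent at WD1310 indicates a wMel-like
#' strain (wMel or wMel2); the converse configuration indicates a
#' wMelCS-like strain (wMelCS or wMelCS2); absence at both loci predicts
#' the rare wMel3 genotype. Any indeterminate call, or presence at both
#' loci, yields an indeterminate genotype.
#'
#' @param call_wd0516_7,call_wd1310 `"is5_call"` objects or bare status
#'   strings (`present`/`absent`/`indeterminate`).
#' @return One of `"wMel-like"`, `"wMelCS-like"`, `"wMel3"`,
#'   `"indeterminate"`.
#' @export
assign_is5_genotype <- function(call_wd0516_7, call_wd1310) {
  s1 <- if (inherits(call_wd0516_7, "is5_call")) call_wd0516_7$status
        else call_wd0516_7
  s2 <- if (inherits(call_wd1310, "is5_call")) call_wd1310$status
        else call_wd1310
  if (s1 == "present" && s2 == "absent") return("wMel-like")
  if (s1 == "absent" && s2 == "present") return("wMelCS-like")
  if (s1 == "absent" && s2 == "absent") return("wMel3")
  "indeterminate"
}

#' Diagnostic mtDNA SNP typing
#'
#' Types a mitochondrial consensus by the two diagnostic COI-region SNPs:
#' T at the first position and C at the second indicates a wMelCS-type
#' cytoplasm, C/T the wMel type; anything else (including N) is unknown.
#' Default positions 2160 and 2187 are 1-based coordinates in the mtDNA
#' marker reference frame; pass `positions` to re-anchor.
#'
#' @param consensus mtDNA consensus (object or string).
#' @param positions Integer positions of the two SNPs.
#' @return `"wMelCS-type"`, `"wMel-type"`, or `"unknown"`.
#' @export
classify_mt_snp_type <- function(consensus, positions = c(2160, 2187)) {
  s <- if (inherits(consensus, "consensus_sequence")) consensus$sequence
       else consensus
  if (max(positions) > nchar(s))
    stop("SNP positions beyond the consensus length")
  b <- substring(s, positions, positions)
  if (b[1] == "T" && b[2] == "C") "wMelCS-type"
  else if (b[1] == "C" && b[2] == "T") "wMel-type"
  else "unknown"
}

#' Extract the COI marker region from an mtDNA consensus
#'
#' Returns the cytochrome c oxidase subunit I window at mtDNA-local
#' 1-based coordinates 1657-2211 (length 555 bp, anchored from the
#' genome-release coordinates of the gene and of the mtDNA reference).
#'
#' @param consensus Full-length mtDNA consensus (object or string).
#' @param window 1-based inclusive coordinates.
#' @return The COI subsequence (may contain N).
#' @export
extract_coi <- function(consensus, window = c(1657, 2211)) {
  s <- if (inherits(consensus, "consensus_sequence")) consensus$sequence
       else consensus
  if (window[2] > nchar(s))
    stop("COI window lies outside the consensus (truncated sequence?)")
  substr(s, window[1], window[2])
}

#' Assign COI haplotypes against a reference table
#'
#' Matches each query against the haplotype table ignoring N positions in
#' the query. A unique match returns the existing haplotype id; a query
#' matching several table entries after N-masking is indeterminate; a
#' novel sequence receives the next new id (starting at `start_new_at`,
#' default 20) and is added to the working table so later identical
#' queries reuse it. Queries are processed in the order given, which makes
#' assignment deterministic.
#'
#' @param queries Named character vector of COI sequences (may contain N).
#' @param table Named character vector of reference haplotypes (names are
#'   ids, e.g. `"1"`..`"19"`), all the same length as the queries.
#' @param start_new_at First id for novel haplotypes.
#' @return List with `assignments` (data frame: strain, haplotype id,
#'   novel flag) and `table` (the extended working table).
#' @export
assign_coi_haplotype <- function(queries, table, start_new_at = 20) {
  if (length(unique(c(nchar(queries), nchar(table)))) != 1)
    stop("queries and table haplotypes must all have the same length")
  next_id <- max(c(start_new_at - 1,
                   suppressWarnings(as.integer(names(table)))),
                 na.rm = TRUE) + 1
  rows <- list()
  for (s in names(queries)) {
    q <- strsplit(queries[[s]], "")[[1]]
    use <- q != "N"
    hits <- names(table)[vapply(table, function(h)
      all(strsplit(h, "")[[1]][use] == q[use]), logical(1))]
    if (length(hits) == 1) {
      rows[[s]] <- data.frame(strain_id = s, haplotype = hits,
                              novel = FALSE, stringsAsFactors = FALSE)
    } else if (length(hits) > 1) {
      rows[[s]] <- data.frame(strain_id = s, haplotype = NA_character_,
                              novel = FALSE, stringsAsFactors = FALSE)
    } else {
      id <- as.character(next_id)
      next_id <- next_id + 1
      table[id] <- queries[[s]]
      rows[[s]] <- data.frame(strain_id = s, haplotype = id, novel = TRUE,
                              stringsAsFactors = FALSE)
    }
  }
  list(assignments = do.call(rbind, rows), table = table)
}

#' Simulate shotgun reads from a haplotype
#'
#' Uniformly placed fixed-length reads with independent substitution
#' errors, in forward orientation; used as the read-level oracle for
#' junction detection.
#'
#' @param haplotype Template sequence.
#' @param depth Expected mean coverage.
#' @param read_length Read length.
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @return Character vector of reads.
#' @export
simulate_reads <- function(haplotype, depth = 20, read_length = 100,
                           error_rate = 0.01, seed = 1) {
  L <- nchar(haplotype)
  n_reads <- max(1, round(depth * L / read_length))
  with_seed(seed, {
    starts <- sample.int(L - read_length + 1, n_reads, replace = TRUE)
    reads <- substring(haplotype, starts, starts + read_length - 1)
    vapply(reads, function(r) {
      ch <- strsplit(r, "")[[1]]
      err <- which(stats::runif(length(ch)) < error_rate)
      if (length(err))
        ch[err] <- vapply(ch[err], function(b)
          sample(setdiff(BASES, b), 1), character(1))
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}
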