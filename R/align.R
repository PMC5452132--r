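#' Forward-strand ungapped bounded-mismatch alignment
#'
#' End-to-end placement of short reads on a set of reference sequences,
#' counting positional (Hamming) mismatches only — the "-v"-style
#' semantics of a classic ungapped short-read aligner: no indels, no
#' quality weighting, and an ambiguity base `N` in a read always counts as
#' a mismatch. Reverse-complement placements are never reported unless
#' `allow_revcomp = TRUE`.
#'
#' By default every placement in the best stratum (the minimal mismatch
#' count at or below `max_mismatch`) is reported per read. Mode `"first"`
#' instead reports one deterministic placement per read: the leftmost
#' placement on the lexicographically smallest target.
#'
#' The mismatch-bounded scan runs in compiled code (an exhaustive
#' early-exit Hamming scan over every offset); every reported alignment
#' lies fully inside its target.
#'
#' @param reads named character vector (or DNAStringSet) of read
#'   sequences; names are read ids.
#' @param targets named character vector (or DNAStringSet) of references.
#' @param max_mismatch maximum mismatches, 0, 1 or 2.
#' @param allow_revcomp also search the reverse complement of each read
#'   (reported with `strand = "-"`). Off by default and off throughout the
#'   pipeline.
#' @param report `"best-stratum"` (all minimal-mismatch placements) or
#'   `"first"`.
#' @param min_read_length reads shorter than this are dropped with a
#'   logged count (attribute `n_too_short`).
#' @return data.frame with columns `read_id`, `target_id`, `start`
#'   (0-based offset; the alignment occupies the half-open interval
#'   `[start, start + length)`), `length`, `mismatches`, `strand`.
#' @examples
#' aln <- align_reads(c(r1 = "ACGTACGT"), c(t1 = "TTACGTACGTTT"),
#'                    max_mismatch = 0)
#' aln$start  # 2 (0-based)
#' @export
align_reads <- function(reads, targets, max_mismatch = 0,
                        allow_revcomp = FALSE,
                        report = c("best-stratum", "first"),
                        min_read_length = 15) {
  report <- match.arg(report)
  if (!max_mismatch %in% 0:2) {
    stop("max_mismatch must be 0, 1 or 2", call. = FALSE)
  }
  reads <- as_named_chr(reads)
  targets_chr <- as_named_chr(targets)
  if (length(reads) == 0L || any(!nzchar(reads))) {
    stop("empty read set (or empty read sequence)", call. = FALSE)
  }
  if (length(targets_chr) == 0L) stop("empty target set", call. = FALSE)
  if (is.null(names(reads)) || is.null(names(targets_chr))) {
    stop("reads and targets must be named", call. = FALSE)
  }
  lens <- nchar(reads)
  too_short <- lens < min_read_length
  if (any(too_short)) {
    message(sprintf("align_reads: dropped %d read(s) shorter than %d nt",
                    sum(too_short), min_read_length))
  }
  kept <- reads[!too_short]
  scan_one_strand <- function(queries, strand) {
    hits <- .hamming_scan_cpp(unname(queries), unname(targets_chr),
                              as.integer(max_mismatch))
    if (!length(hits$read)) return(NULL)
    data.frame(read_id = names(queries)[hits$read],
               target_id = names(targets_chr)[hits$target],
               start = hits$start, length = nchar(queries)[hits$read],
               mismatches = hits$mismatches, strand = strand,
               stringsAsFactors = FALSE)
  }
  parts <- list(scan_one_strand(kept, "+"))
  if (allow_revcomp && length(kept)) {
    rc <- setNames(vapply(kept, revcomp, character(1)), names(kept))
    parts <- c(parts, list(scan_one_strand(rc, "-")))
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  res <- if (length(parts)) do.call(rbind, parts) else
    data.frame(read_id = character(0), target_id = character(0),
               start = integer(0), length = integer(0),
               mismatches = integer(0), strand = character(0),
               stringsAsFactors = FALSE)
  if (nrow(res)) {
    # best stratum per read
    best <- tapply(res$mismatches, res$read_id, min)
    res <- res[res$mismatches == best[res$read_id], , drop = FALSE]
    res <- res[order(match(res$read_id, names(kept)), res$target_id,
                     res$strand, res$start), , drop = FALSE]
    if (report == "first") {
      res <- res[!duplicated(res$read_id), , drop = FALSE]
    }
    rownames(res) <- NULL
  }
  attr(res, "n_too_short") <- sum(too_short)
  res
}

round1_targets <- function(genomes) {
  c(setNames(as.character(genomes$chloroplast_genome), "chloroplast"),
    as.character(genomes$cds_seqs), as.character(genomes$trna_seqs))
}

#' Three-round subtractive read filtering
#'
#' Reproduces the organelle-first subtractive scheme for small RNA reads:
#' \enumerate{
#'   \item align to the chloroplast genome, CDSs and tRNAs with 0
#'     mismatches — matches form the `cp_m0` set;
#'   \item align the remainder to the nuclear and mitochondrial genomes
#'     with 0 mismatches — matches are `subtracted` (discarded);
#'   \item align what is left to the chloroplast genome and CDSs (tRNAs
#'     excluded in this relaxed round) with up to `max_mismatch_relaxed`
#'     mismatches — matches form `cp_m2`.
#' }
#' `cp_m0_m2` is the union of rounds 1 and 3; reads matched nowhere are
#' `unplaced`. Aligning to the chloroplast first gives plastid references
#' priority over identical nuclear/mitochondrial loci.
#'
#' @param reads named character vector of read sequences.
#' @param genomes a `genome_set`.
#' @param max_mismatch_relaxed mismatch bound for round 3 (default 2).
#' @param report placement reporting mode, see [align_reads()].
#' @param min_read_length minimum read length, see [align_reads()].
#' @return Object of class `filtered_read_sets`: list with alignment
#'   data.frames `cp_m0`, `cp_m2`, `cp_m0_m2` (with a `round` column,
#'   `"m0_cp"`/`"m2_cp"`), id vectors `subtracted`, `unplaced`,
#'   `too_short`, and a named integer vector `counts`.
#' @export
hierarchical_filter <- function(reads, genomes, max_mismatch_relaxed = 2,
                                report = c("best-stratum", "first"),
                                min_read_length = 15) {
  report <- match.arg(report)
  stopifnot(inherits(genomes, "genome_set"))
  reads <- as_named_chr(reads)
  if (is.null(names(reads))) stop("reads must be named", call. = FALSE)
  lens <- nchar(reads)
  too_short <- names(reads)[lens < min_read_length]
  if (length(too_short)) {
    message(sprintf("hierarchical_filter: dropped %d read(s) shorter than %d nt",
                    length(too_short), min_read_length))
  }
  reads <- reads[lens >= min_read_length]

  empty_aln <- data.frame(read_id = character(0), target_id = character(0),
                          start = integer(0), length = integer(0),
                          mismatches = integer(0), strand = character(0),
                          stringsAsFactors = FALSE)
  aln1 <- if (length(reads)) {
    align_reads(reads, round1_targets(genomes), max_mismatch = 0,
                report = report, min_read_length = min_read_length)
  } else empty_aln
  m0_ids <- unique(aln1$read_id)
  rest <- reads[setdiff(names(reads), m0_ids)]

  decoys <- c(nuclear = as.character(genomes$nuclear_genome),
              mito = as.character(genomes$mito_genome))
  aln2 <- if (length(rest)) {
    align_reads(rest, decoys, max_mismatch = 0, report = report,
                min_read_length = min_read_length)
  } else empty_aln
  subtracted <- unique(aln2$read_id)
  rest2 <- rest[setdiff(names(rest), subtracted)]

  round3 <- c(setNames(as.character(genomes$chloroplast_genome),
                       "chloroplast"),
              as.character(genomes$cds_seqs))
  aln3 <- if (length(rest2)) {
    align_reads(rest2, round3, max_mismatch = max_mismatch_relaxed,
                report = report, min_read_length = min_read_length)
  } else empty_aln
  m2_ids <- unique(aln3$read_id)
  unplaced <- setdiff(names(rest2), m2_ids)

  add_round <- function(df, r) {
    if (nrow(df)) df$round <- r else df$round <- character(0)
    df
  }
  aln1 <- add_round(aln1, "m0_cp")
  aln3 <- add_round(aln3, "m2_cp")
  sets <- structure(list(
    cp_m0 = aln1, subtracted = subtracted, cp_m2 = aln3,
    cp_m0_m2 = rbind(aln1, aln3), unplaced = unplaced,
    too_short = too_short,
    counts = c(input = length(reads) + length(too_short),
               too_short = length(too_short),
               cp_m0 = length(m0_ids), subtracted = length(subtracted),
               cp_m2 = length(m2_ids),
               cp_m0_m2 = length(m0_ids) + length(m2_ids),
               unplaced = length(unplaced))
  ), class = "filtered_read_sets")
  sets
}

#' @export
print.filtered_read_sets <- function(x, ...) {
  cat("filtered_read_sets\n")
  print(x$counts)
  invisible(x)
}

#' Extract the retained (cp_m0_m2) read sequences
#' @param sets a `filtered_read_sets`.
#' @param reads the named read vector the filter was run on.
#' @return named character vector of retained reads.
#' @export
retained_reads <- function(sets, reads) {
  ids <- unique(sets$cp_m0_m2$read_id)
  as.character(reads)[match(ids, names(reads))] |> setNames(ids)
}

#' Realign retained reads to CDS coordinates
#'
#' The merged cp_m0_m2 read set is aligned against the chloroplast CDS
#' set alone so that editing sites, which are annotated in 1-based CDS
#' coordinates, can be piled up directly. Internally coordinates are
#' 0-based half-open; the SAM output follows the standard 1-based POS
#' convention and carries the mismatch count in the `NM` tag.
#'
#' @param reads named character vector of retained read sequences (may be
#'   empty — yields an empty, header-only SAM).
#' @param cds_seqs named character vector or DNAStringSet of CDSs.
#' @param max_mismatch mismatch bound (default 2).
#' @param report placement reporting mode, see [align_reads()].
#' @param sam_path optional path; when given, a SAM file with `@HD`/`@SQ`
#'   header and FLAG 0 (aligned) / 4 (unaligned) records is written.
#' @return data.frame like [align_reads()] plus a `seq` column with the
#'   read sequence (needed downstream for pileups).
#' @export
realign_to_cds <- function(reads, cds_seqs, max_mismatch = 2,
                           report = c("best-stratum", "first"),
                           sam_path = NULL) {
  report <- match.arg(report)
  cds_chr <- as_named_chr(cds_seqs)
  reads <- as_named_chr(reads)
  aln <- if (length(reads)) {
    align_reads(reads, cds_chr, max_mismatch = max_mismatch, report = report)
  } else {
    data.frame(read_id = character(0), target_id = character(0),
               start = integer(0), length = integer(0),
               mismatches = integer(0), strand = character(0),
               stringsAsFactors = FALSE)
  }
  aln$seq <- reads[match(aln$read_id, names(reads))] |> unname()
  if (!is.null(sam_path)) {
    write_sam(aln, cds_chr, reads, sam_path)
  }
  aln
}

#' Read a SAM file back into an alignment data.frame
#'
#' Parses the minimal SAM dialect written by [write_sam()] (ungapped,
#' FLAG 0/4, `NM` tag). Unaligned (FLAG 4) records are dropped.
#'
#' @param path SAM path.
#' @return alignment data.frame with `read_id`, `target_id`, `start`
#'   (0-based), `length`, `mismatches`, `strand`, `seq`.
#' @export
read_sam_alignments <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  empty <- data.frame(read_id = character(0), target_id = character(0),
                      start = integer(0), length = integer(0),
                      mismatches = integer(0), strand = character(0),
                      seq = character(0), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  f <- f[flag == 0L]
  if (!length(f)) return(empty)
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else 0L
  }, integer(1))
  data.frame(
    read_id = vapply(f, `[`, character(1), 1),
    target_id = vapply(f, `[`, character(1), 3),
    start = vapply(f, function(x) as.integer(x[4]), integer(1)) - 1L,
    length = vapply(f, function(x) nchar(x[10]), integer(1)),
    mismatches = nm, strand = "+",
    seq = vapply(f, `[`, character(1), 10),
    stringsAsFactors = FALSE)
}

#' Write alignments as a SAM file
#'
#' Minimal valid SAM: `@HD` and one `@SQ` per reference; aligned records
#' with FLAG 0, `<len>M` CIGAR and an `NM:i:` mismatch tag; reads without
#' a placement as FLAG 4 records.
#'
#' @param aln alignment data.frame from [realign_to_cds()]/[align_reads()].
#' @param targets named character vector of reference sequences.
#' @param reads named character vector of all reads (aligned or not).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, targets, reads, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(targets), nchar(targets)))
  body <- character(0)
  if (nrow(aln)) {
    body <- sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                    aln$read_id, aln$target_id, aln$start + 1L, aln$length,
                    if (!is.null(aln$seq)) aln$seq else
                      unname(as.character(reads)[match(aln$read_id, names(reads))]),
                    aln$mismatches)
  }
  un <- setdiff(names(reads), aln$read_id)
  if (length(un)) {
    body <- c(body, sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", un,
                            unname(as.character(reads)[match(un, names(reads))])))
  }
  writeLines(c(header, body), path)
  invisible(path)
}
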