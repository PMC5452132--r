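#' Describe one simulated sequencing library
#'
#' Captures the knobs of a single small RNA (or mRNA-fragment) library:
#' depth, read-length range, uniform per-base error rate, the fraction of
#' reads drawn from nuclear/mitochondrial decoys, and the fraction of
#' on-target reads drawn from tRNAs rather than CDSs. Two conditions are
#' supported, matching a control vs salt-stress design with libraries such
#' as Cnt-1, Cnt-2, Salt-1, Salt-2.
#'
#' @param library_id library name (used in read ids and reports).
#' @param condition `"control"` or `"salt"`; selects which planted editing
#'   fraction applies at each site.
#' @param n_reads library depth.
#' @param read_length_range integer min/max read length; small RNA
#'   footprints default to 18–24 nt (use ~50–100 for mRNA fragments).
#' @param error_rate per-base substitution error probability in \[0, 0.1).
#' @param offtarget_fraction fraction of reads drawn from the nuclear and
#'   mitochondrial decoys (split evenly).
#' @param trna_fraction among on-target reads, fraction drawn from tRNAs.
#' @param seed integer seed.
#' @return list of class `library_profile`.
#' @export
library_profile <- function(library_id, condition = c("control", "salt"),
                            n_reads = 20000, read_length_range = c(18, 24),
                            error_rate = 0.005, offtarget_fraction = 0.3,
                            trna_fraction = 0.1, seed = 1) {
  condition <- match.arg(condition)
  assert_scalar_number(n_reads, "n_reads", lower = 1)
  assert_scalar_number(error_rate, "error_rate", lower = 0, upper = 0.1,
                       strict_upper = TRUE)
  assert_scalar_number(offtarget_fraction, "offtarget_fraction", 0, 1)
  assert_scalar_number(trna_fraction, "trna_fraction", 0, 1)
  if (length(read_length_range) != 2L || read_length_range[1] < 15 ||
      read_length_range[1] > read_length_range[2]) {
    stop("read_length_range must be c(min, max) with min >= 15 nt",
         call. = FALSE)
  }
  structure(list(library_id = library_id, condition = condition,
                 n_reads = as.integer(n_reads),
                 read_length_range = as.integer(read_length_range),
                 error_rate = error_rate,
                 offtarget_fraction = offtarget_fraction,
                 trna_fraction = trna_fraction, seed = as.integer(seed)),
            class = "library_profile")
}

#' Simulate a sequencing library with planted editing
#'
#' Draws forward-strand reads from the sense strand of CDSs and tRNAs
#' (transcript orientation — antisense reads are not modeled, consistent
#' with an alignment scheme that forbids reverse-complement matches) plus
#' off-target reads from the nuclear and mitochondrial decoys. Whenever a
#' CDS read covers a predicted editing site, the base at that site is
#' written as T with the site's per-condition editing fraction and left as
#' the reference C otherwise; uniform per-base errors are injected
#' afterwards. A truth table records, for every read, its origin, the
#' final base carried at each covered site, and its total mismatch count
#' against the originating reference — enough to predict exactly which
#' round of the subtractive alignment should capture it.
#'
#' @param genomes a `genome_set`.
#' @param sites an `editing_site_table` with `frac_<condition>` columns.
#' @param profile a `library_profile`.
#' @param fastq_path output FASTQ path (plain text, constant quality "I").
#' @param truth_path output truth-table TSV path; default: `fastq_path`
#'   with extension replaced by `.truth.tsv`.
#' @return Invisibly, the truth table data.frame with columns `read_id`,
#'   `origin_type` (cds/trna/nuclear/mito), `origin_id`, `start` (0-based
#'   on the origin sequence), `length`, `n_mismatches` (vs the origin
#'   reference, editing included), `n_edited_T`, `site_bases`
#'   (`gene:pos:base` entries, `;`-separated) and `condition`.
#' @export
simulate_read_library <- function(genomes, sites, profile, fastq_path,
                                  truth_path = NULL) {
  stopifnot(inherits(genomes, "genome_set"),
            inherits(profile, "library_profile"))
  truth_path <- truth_path %||%
    paste0(sub("\\.(fastq|fq)$", "", fastq_path), ".truth.tsv")
  frac_col <- paste0("frac_", profile$condition)
  if (!frac_col %in% names(sites)) {
    stop("site table lacks ground-truth column '", frac_col, "'",
         call. = FALSE)
  }
  cds_chr <- as.character(genomes$cds_seqs)
  trna_chr <- as.character(genomes$trna_seqs)
  nuc_chr <- as.character(genomes$nuclear_genome)
  mito_chr <- as.character(genomes$mito_genome)
  sites_by_gene <- split(sites[, c("cds_position", frac_col)], sites$gene_id)

  n <- profile$n_reads
  refs <- c(cds_chr, trna_chr, nuclear = nuc_chr, mito = mito_chr)
  withr::with_seed(profile$seed, {
    lens <- sample(seq(profile$read_length_range[1],
                       profile$read_length_range[2]), n, replace = TRUE)
    is_off <- runif(n) < profile$offtarget_fraction
    is_trna <- !is_off & runif(n) < profile$trna_fraction
    is_cds <- !is_off & !is_trna
    # length-weighted CDS choice gives roughly uniform per-base coverage
    cds_w <- nchar(cds_chr) / sum(nchar(cds_chr))

    origin_type <- rep("cds", n)
    origin_type[is_trna] <- "trna"
    origin_type[is_off] <- ifelse(runif(sum(is_off)) < 0.5, "nuclear", "mito")
    origin_id <- character(n)
    origin_id[is_cds] <- sample(names(cds_chr), sum(is_cds), replace = TRUE,
                                prob = cds_w)
    origin_id[is_trna] <- sample(names(trna_chr), sum(is_trna),
                                 replace = TRUE)
    origin_id[origin_type == "nuclear"] <- "nuclear"
    origin_id[origin_type == "mito"] <- "mito"
    ref_len <- nchar(refs)[match(origin_id, names(refs))]
    start0 <- as.integer(floor(runif(n) * (ref_len - lens + 1L)))
    seqs <- substring(refs[match(origin_id, names(refs))], start0 + 1L,
                      start0 + lens)
    ref_subs <- seqs # pre-edit, pre-error reference substrings
    n_edT <- integer(n)

    # plant edits site by site (vectorized over the covering reads)
    site_rec <- list() # (read index, site order, gene, position)
    for (g in names(sites_by_gene)) {
      st <- sites_by_gene[[g]]
      for (j in seq_len(nrow(st))) {
        pos <- st$cds_position[j]
        idx <- which(is_cds & origin_id == g & start0 < pos &
                       start0 + lens >= pos)
        if (!length(idx)) next
        off <- pos - start0[idx] # 1-based offset within the read
        edited <- runif(length(idx)) < st[[frac_col]][j]
        if (any(edited)) {
          ii <- idx[edited]
          oo <- off[edited]
          seqs[ii] <- paste0(substr(seqs[ii], 1L, oo - 1L), "T",
                             substr(seqs[ii], oo + 1L, lens[ii]))
          n_edT[ii] <- n_edT[ii] + 1L
        }
        site_rec[[length(site_rec) + 1L]] <-
          data.frame(i = idx, gene = g, pos = pos, off = off)
      }
    }

    # uniform per-base substitution errors
    if (profile$error_rate > 0) {
      n_err <- rbinom(n, lens, profile$error_rate)
      for (i in which(n_err > 0)) {
        for (p in sample(lens[i], n_err[i])) {
          old <- substr(seqs[i], p, p)
          substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, old), 1)
        }
      }
    }

    # final base carried at each covered site (after edits and errors)
    site_bases <- character(n)
    if (length(site_rec)) {
      rec <- do.call(rbind, site_rec)
      rec$base <- substr(seqs[rec$i], rec$off, rec$off)
      rec <- rec[order(rec$i, rec$gene, rec$pos), ]
      lab <- sprintf("%s:%d:%s", rec$gene, rec$pos, rec$base)
      agg <- tapply(lab, rec$i, paste, collapse = ";")
      site_bases[as.integer(names(agg))] <- agg
    }

    # mismatches vs the reference of origin; only touched reads can differ
    n_mm <- integer(n)
    touched <- which(seqs != ref_subs)
    n_mm[touched] <- mapply(function(a, b) {
      sum(utf8ToInt(a) != utf8ToInt(b))
    }, seqs[touched], ref_subs[touched], USE.NAMES = FALSE)

    read_ids <- sprintf("%s_r%06d", profile$library_id, seq_len(n))
    fq <- character(4L * n)
    fq[seq(1, by = 4, length.out = n)] <- paste0("@", read_ids)
    fq[seq(2, by = 4, length.out = n)] <- seqs
    fq[seq(3, by = 4, length.out = n)] <- "+"
    fq[seq(4, by = 4, length.out = n)] <- strrep("I", lens)
    writeLines(fq, fastq_path)

    truth <- data.frame(read_id = read_ids, origin_type = origin_type,
                        origin_id = origin_id, start = start0, length = lens,
                        n_mismatches = n_mm, n_edited_T = n_edT,
                        site_bases = site_bases,
                        condition = profile$condition,
                        stringsAsFactors = FALSE)
    write.table(truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(truth)
  })
}

#' Read a FASTQ file as a named character vector of read sequences
#'
#' Qualities are ignored throughout this pipeline (simulated qualities are
#' constant); parsing is delegated to Biostrings.
#' @param path FASTQ path.
#' @return named character vector (names = read ids).
#' @export
read_fastq_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}
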