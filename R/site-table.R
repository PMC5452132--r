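#' Generate a table of predicted C-to-U editing sites
#'
#' Emulates the output of a plastid editing-site predictor: each record is
#' a cytidine position within a CDS together with a prediction score at or
#' above the configured cutoff. The simulation ground truth — the editing
#' fraction planted for each experimental condition — is carried in
#' `frac_<condition>` columns; these columns are absent when a site table
#' is read from a real prediction run.
#'
#' @param genomes a `genome_set`.
#' @param n_sites number of sites to plant.
#' @param fractions named list, one element per condition (default
#'   `control` and `salt`), each a numeric vector of per-site editing
#'   fractions in \[0,1\] (length 1 values are recycled).
#' @param score_cutoff minimum prediction score; scores are drawn uniformly
#'   in \[cutoff, 1\]. Default 0.5, the permissive cutoff used for plastid
#'   predictions in this workflow.
#' @param min_spacing minimum distance (nt) between two sites on the same
#'   CDS; keeping sites farther apart than the read length ensures a short
#'   read covers at most one site.
#' @param edge_margin sites are only planted at least this many nt away
#'   from either CDS end: terminal bases are covered by almost no short
#'   read, so sites there would be unquantifiable by construction.
#' @param seed integer seed.
#' @return data.frame of class `editing_site_table` with columns
#'   `gene_id`, `cds_position` (1-based within the CDS), `score`,
#'   `ref_base` ("C"), `edited_base` ("T") and one `frac_<condition>`
#'   column per condition.
#' @examples
#' gs <- generate_genome_set(cp_length = 5000, n_genes = 4, cds_length = 400,
#'                           seed = 1)
#' generate_site_table(gs, n_sites = 3,
#'                     fractions = list(control = 0.6, salt = 0.8), seed = 2)
#' @export
generate_site_table <- function(genomes, n_sites,
                                fractions = list(control = 0.6, salt = 0.8),
                                score_cutoff = 0.5, min_spacing = 30,
                                edge_margin = 25, seed = 1) {
  stopifnot(inherits(genomes, "genome_set"))
  assert_scalar_number(n_sites, "n_sites", lower = 1)
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("'fractions' must be a named list (one element per condition)",
         call. = FALSE)
  }
  fractions <- lapply(fractions, function(f) {
    if (length(f) == 1L) f <- rep(f, n_sites)
    if (length(f) != n_sites) {
      stop("each 'fractions' element must have length 1 or n_sites",
           call. = FALSE)
    }
    if (any(f < 0 | f > 1)) stop("editing fractions must lie in [0,1]",
                                 call. = FALSE)
    f
  })
  cds_chr <- as.character(genomes$cds_seqs)
  withr::with_seed(seed, {
    # candidate pool: every C in every CDS
    cand <- do.call(rbind, lapply(names(cds_chr), function(g) {
      pos <- which(strsplit(cds_chr[[g]], "")[[1]] == "C")
      L <- nchar(cds_chr[[g]])
      pos <- pos[pos > edge_margin & pos <= L - edge_margin]
      if (!length(pos)) return(NULL)
      data.frame(gene_id = g, cds_position = pos, stringsAsFactors = FALSE)
    }))
    if (is.null(cand) || nrow(cand) < n_sites) {
      stop("not enough cytidines in the CDS set to place the requested sites",
           call. = FALSE)
    }
    picked <- cand[0, ]
    pool <- cand[sample(nrow(cand)), ]
    for (i in seq_len(nrow(pool))) {
      row <- pool[i, ]
      clash <- picked$gene_id == row$gene_id &
        abs(picked$cds_position - row$cds_position) < min_spacing
      if (!any(clash)) picked <- rbind(picked, row)
      if (nrow(picked) == n_sites) break
    }
    if (nrow(picked) < n_sites) {
      stop("could not place the requested sites with the given min_spacing",
           call. = FALSE)
    }
    picked <- picked[order(picked$gene_id, picked$cds_position), ]
    rownames(picked) <- NULL
    picked$score <- round(runif(n_sites, score_cutoff, 1), 2)
    picked$ref_base <- "C"
    picked$edited_base <- "T"
    for (cond in names(fractions)) {
      picked[[paste0("frac_", cond)]] <- fractions[[cond]]
    }
    class(picked) <- c("editing_site_table", "data.frame")
    picked
  })
}

#' Write / read an editing-site table (TSV)
#'
#' Plain tab-separated text with one row per site; the format mirrors a
#' predictor export (gene, 1-based CDS position, score) plus the planted
#' per-condition fractions when the table comes from the simulator.
#'
#' @param sites an `editing_site_table` data.frame.
#' @param path file path.
#' @return `write_site_table` returns `path` invisibly; `read_site_table`
#'   returns an `editing_site_table`.
#' @export
write_site_table <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_site_table
#' @export
read_site_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "cds_position", "score")
  if (!all(need %in% names(x))) {
    stop("site table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(x$ref_base)) x$ref_base <- "C"
  if (is.null(x$edited_base)) x$edited_base <- "T"
  class(x) <- c("editing_site_table", "data.frame")
  x
}

#' Validate a site table against a genome set
#'
#' Checks that every site falls inside its CDS and sits on a reference C.
#' @param sites an `editing_site_table`.
#' @param genomes a `genome_set`.
#' @return `sites`, invisibly; errors name the first offending site.
#' @export
validate_site_table <- function(sites, genomes) {
  cds_chr <- as.character(genomes$cds_seqs)
  for (i in seq_len(nrow(sites))) {
    g <- sites$gene_id[i]
    p <- sites$cds_position[i]
    if (!g %in% names(cds_chr)) {
      stop(sprintf("site %s:%d refers to an unknown CDS", g, p), call. = FALSE)
    }
    if (p < 1 || p > nchar(cds_chr[[g]])) {
      stop(sprintf("site %s:%d lies outside the CDS (length %d)", g, p,
                   nchar(cds_chr[[g]])), call. = FALSE)
    }
    if (substr(cds_chr[[g]], p, p) != "C") {
      stop(sprintf("site %s:%d is not a C in the reference CDS", g, p),
           call. = FALSE)
    }
  }
  invisible(sites)
}
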