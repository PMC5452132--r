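#' Pile up read bases at predicted editing sites
#'
#' For each (site, library) pair, counts the bases carried by aligned
#' reads at the site's CDS coordinate: `n_edited` (T), `n_unedited` (C)
#' and `n_other` (A/G/N). A read with several reported placements
#' contributes at most once per CDS (its first placement on that CDS), so
#' multi-mapping never double-counts a molecule.
#'
#' @param cds_alignments alignment data.frame on CDS coordinates from
#'   [realign_to_cds()] (must include the `seq` column).
#' @param sites an `editing_site_table`.
#' @param library_id label stored in each pileup row.
#' @param cds_lengths optional named integer vector of CDS lengths; when
#'   supplied, any site beyond its CDS raises an error naming the site.
#' @return data.frame of class `site_pileup`: `gene_id`, `cds_position`,
#'   `library_id`, `n_edited`, `n_unedited`, `n_other`, `coverage`.
#' @export
pileup_sites <- function(cds_alignments, sites, library_id,
                         cds_lengths = NULL) {
  if (!is.null(cds_lengths)) {
    bad <- sites$cds_position > cds_lengths[sites$gene_id]
    if (any(bad, na.rm = TRUE)) {
      i <- which(bad)[1]
      stop(sprintf("site %s:%d lies beyond its CDS (length %d)",
                   sites$gene_id[i], sites$cds_position[i],
                   cds_lengths[[sites$gene_id[i]]]), call. = FALSE)
    }
  }
  aln <- cds_alignments
  if (nrow(aln)) {
    # one contribution per read per CDS: keep the first placement
    aln <- aln[order(aln$read_id, aln$target_id, aln$start), , drop = FALSE]
    aln <- aln[!duplicated(paste(aln$read_id, aln$target_id)), , drop = FALSE]
  }
  res <- lapply(seq_len(nrow(sites)), function(i) {
    g <- sites$gene_id[i]
    p <- sites$cds_position[i] # 1-based
    sub <- aln[aln$target_id == g & aln$start < p &
                 aln$start + aln$length >= p, , drop = FALSE]
    bases <- if (nrow(sub)) {
      substr(sub$seq, p - sub$start, p - sub$start)
    } else character(0)
    data.frame(gene_id = g, cds_position = p, library_id = library_id,
               n_edited = sum(bases == "T"),
               n_unedited = sum(bases == "C"),
               n_other = sum(bases != "T" & bases != "C"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$coverage <- out$n_edited + out$n_unedited + out$n_other
  class(out) <- c("site_pileup", "data.frame")
  out
}

#' Binomial variant-detection test
#'
#' Is the number of edited (T) reads at a site larger than sequencing
#' error alone would explain? `p` is the exact upper-tail binomial
#' probability of observing at least `n_edited` successes in `coverage`
#' trials at the per-base error rate. A site is `detected` when its
#' coverage reaches `min_coverage` (default 5) and `p` is at most `max_p`
#' (default 1e-2) — a transparent replacement for opaque "approximate"
#' variant-caller p-values, at the same acceptance threshold.
#'
#' @param n_edited,coverage integer vectors (recycled together).
#' @param error_rate assumed per-base error probability, in (0, 0.5).
#' @param min_coverage minimum coverage for detection.
#' @param max_p detection p-value ceiling.
#' @return data.frame with `p` and `detected`.
#' @examples
#' variant_test(11, 20)       # detected
#' variant_test(4, 4)         # p tiny but coverage < 5: not detected
#' @export
variant_test <- function(n_edited, coverage, error_rate = 0.01,
                         min_coverage = 5, max_p = 1e-2) {
  assert_scalar_number(error_rate, "error_rate", lower = 0, upper = 0.5,
                       strict_lower = TRUE, strict_upper = TRUE)
  n <- pmax(length(n_edited), length(coverage))
  n_edited <- rep_len(n_edited, n)
  coverage <- rep_len(coverage, n)
  p <- stats::pbinom(n_edited - 1, coverage, error_rate, lower.tail = FALSE)
  p[coverage == 0] <- 1
  data.frame(p = p, detected = coverage >= min_coverage & p <= max_p)
}

#' Per-site editing fraction
#'
#' `n_edited / (n_edited + n_unedited)`. Bases other than C/T are excluded
#' from the denominator, since editing is a two-state C-vs-T quantity.
#' Undefined (NA, printed "nd") when no C or T read covers the site.
#'
#' @param n_edited,n_unedited integer vectors.
#' @return numeric vector in \[0,1\], NA where the denominator is 0.
#' @examples
#' editing_fraction(11, 9)  # 0.55
#' editing_fraction(8, 0)   # 1
#' editing_fraction(0, 0)   # NA ("nd")
#' @export
editing_fraction <- function(n_edited, n_unedited) {
  denom <- n_edited + n_unedited
  ifelse(denom > 0, n_edited / denom, NA_real_)
}

#' Compare per-library editing fractions between conditions
#'
#' Two-sided pooled-variance t-test on the defined per-library fractions,
#' control vs salt. Libraries whose fraction is undefined ("nd") are
#' excluded; a condition left with fewer than two defined values still
#' yields a p-value where one degree of freedom remains, but is flagged
#' degenerate. A condition with no defined value at all is incomparable
#' (no p).
#'
#' @param fractions numeric vector of per-library fractions (NA = "nd").
#' @param conditions character vector, `"control"`/`"salt"`, parallel to
#'   `fractions`.
#' @return list: `p_value`, `mean_control`, `mean_salt`, `degenerate`,
#'   `flag`.
#' @export
compare_conditions <- function(fractions, conditions) {
  stopifnot(length(fractions) == length(conditions))
  res <- pooled_t_test(fractions[conditions == "control"],
                       fractions[conditions == "salt"])
  list(p_value = res$p_value, mean_control = res$mean_x,
       mean_salt = res$mean_y, degenerate = res$degenerate,
       flag = res$flag)
}

#' Quantify and test editing at every site across libraries
#'
#' Runs [pileup_sites()] per library, computes per-library fractions and
#' detection tests, the control-vs-salt comparison, and the selection
#' rule: a site is `selected` when its summed coverage across all
#' libraries reaches `min_total_coverage` (default 4) and it is detected
#' in at least one library.
#'
#' @param alignments_by_library named list of CDS alignment data.frames
#'   (one per library, names = library ids).
#' @param sites an `editing_site_table`.
#' @param conditions named character vector mapping library id to
#'   `"control"`/`"salt"`.
#' @param error_rate,min_coverage,max_p detection parameters, see
#'   [variant_test()].
#' @param min_total_coverage selection threshold on summed coverage.
#' @param cds_lengths optional, see [pileup_sites()].
#' @return list of class `site_editing_stats`: `pileups` (long
#'   data.frame) and `stats` (one row per site with per-library
#'   `n_edited_<lib>`, `coverage_<lib>`, `fraction_<lib>` columns,
#'   `total_coverage`, `detected_any`, `selected`, `p_value`, `flag`).
#' @export
call_editing_sites <- function(alignments_by_library, sites, conditions,
                               error_rate = 0.01, min_coverage = 5,
                               max_p = 1e-2, min_total_coverage = 4,
                               cds_lengths = NULL) {
  libs <- names(alignments_by_library)
  if (is.null(libs)) stop("alignments_by_library must be named", call. = FALSE)
  if (!all(libs %in% names(conditions))) {
    stop("every library needs a condition label", call. = FALSE)
  }
  pes <- lapply(libs, function(lb) {
    pu <- pileup_sites(alignments_by_library[[lb]], sites, lb, cds_lengths)
    vt <- variant_test(pu$n_edited, pu$coverage, error_rate, min_coverage,
                       max_p)
    pu$fraction <- editing_fraction(pu$n_edited, pu$n_unedited)
    pu$variant_p <- vt$p
    pu$detected <- vt$detected
    pu
  })
  pileups <- do.call(rbind, pes)

  stats <- sites[, c("gene_id", "cds_position", "score")]
  for (k in seq_along(libs)) {
    lb <- libs[k]
    stats[[paste0("n_edited_", lb)]] <- pes[[k]]$n_edited
    stats[[paste0("coverage_", lb)]] <- pes[[k]]$coverage
    stats[[paste0("fraction_", lb)]] <- pes[[k]]$fraction
  }
  cov_mat <- sapply(pes, function(x) x$coverage)
  det_mat <- sapply(pes, function(x) x$detected)
  frac_mat <- sapply(pes, function(x) x$fraction)
  if (nrow(sites) == 1L) {
    cov_mat <- matrix(cov_mat, nrow = 1)
    det_mat <- matrix(det_mat, nrow = 1)
    frac_mat <- matrix(frac_mat, nrow = 1)
  }
  stats$total_coverage <- rowSums(cov_mat)
  stats$detected_any <- apply(det_mat, 1, any)
  cond_vec <- conditions[libs]
  cmp <- lapply(seq_len(nrow(sites)), function(i) {
    compare_conditions(frac_mat[i, ], cond_vec)
  })
  stats$mean_control <- vapply(cmp, `[[`, numeric(1), "mean_control")
  stats$mean_salt <- vapply(cmp, `[[`, numeric(1), "mean_salt")
  stats$p_value <- vapply(cmp, `[[`, numeric(1), "p_value")
  stats$flag <- vapply(cmp, `[[`, character(1), "flag")
  stats$selected <- stats$total_coverage >= min_total_coverage &
    stats$detected_any
  structure(list(pileups = pileups, stats = stats,
                 params = list(error_rate = error_rate,
                               min_coverage = min_coverage, max_p = max_p,
                               min_total_coverage = min_total_coverage)),
            class = "site_editing_stats")
}

#' Select sites and format the per-site editing report
#'
#' Emits one row per site ordered by gene and position, with, for each
#' library, both the edited-read count and the total coverage (stated
#' explicitly because single-count report conventions are ambiguous), the
#' editing fraction rounded to two decimals ("nd" when undefined), the
#' between-condition p-value and the selection flag.
#'
#' @param stats a `site_editing_stats` object.
#' @param path optional TSV output path.
#' @param min_total_coverage overrides the selection threshold used when
#'   the stats were computed (optional).
#' @return The report data.frame (invisibly when `path` is given).
#' @export
select_sites <- function(stats, path = NULL, min_total_coverage = NULL) {
  st <- stats$stats
  if (!is.null(min_total_coverage)) {
    st$selected <- st$total_coverage >= min_total_coverage & st$detected_any
  }
  frac_cols <- grep("^fraction_", names(st), value = TRUE)
  rep_df <- st
  for (cc in frac_cols) {
    rep_df[[cc]] <- ifelse(is.na(st[[cc]]), "nd",
                           formatC(round(st[[cc]], 2), format = "g"))
  }
  rep_df$p_value <- ifelse(is.na(st$p_value), "-",
                           formatC(signif(st$p_value, 3), format = "g"))
  rep_df <- rep_df[order(rep_df$gene_id, rep_df$cds_position), , drop = FALSE]
  if (!is.null(path)) {
    write.table(rep_df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rep_df))
  }
  rep_df
}

#' @export
print.site_editing_stats <- function(x, ...) {
  cat(sprintf("site_editing_stats: %d sites, %d selected\n",
              nrow(x$stats), sum(x$stats$selected)))
  invisible(x)
}
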