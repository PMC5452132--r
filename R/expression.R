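#' Build a gene x library count table from CDS alignments
#'
#' Each read contributes a single count per library, to the CDS of its
#' first reported placement; reads placed on several CDSs are logged.
#' Genes with no aligned read get a zero row, libraries with no alignment
#' a zero column (with a warning).
#'
#' @param alignments_by_library named list of CDS alignment data.frames.
#' @param cds_ids character vector of all gene ids (row universe).
#' @return integer matrix, genes x libraries.
#' @export
build_count_table <- function(alignments_by_library, cds_ids) {
  libs <- names(alignments_by_library)
  if (is.null(libs)) stop("alignments_by_library must be named", call. = FALSE)
  counts <- matrix(0L, nrow = length(cds_ids), ncol = length(libs),
                   dimnames = list(cds_ids, libs))
  for (lb in libs) {
    aln <- alignments_by_library[[lb]]
    if (is.null(aln) || nrow(aln) == 0L) {
      warning(sprintf("library %s has no alignments; zero column", lb),
              call. = FALSE)
      next
    }
    aln <- aln[order(aln$read_id, aln$target_id, aln$start), , drop = FALSE]
    multi <- sum(tapply(aln$target_id, aln$read_id,
                        function(x) length(unique(x)) > 1L))
    if (multi > 0) {
      message(sprintf(
        "build_count_table: %d multi-CDS read(s) in %s counted at first placement",
        multi, lb))
    }
    first <- aln[!duplicated(aln$read_id), , drop = FALSE]
    tab <- table(factor(first$target_id, levels = cds_ids))
    counts[, lb] <- as.integer(tab)
  }
  counts
}

#' Median-of-ratios size factors and normalized counts
#'
#' The standard bulk RNA-seq normalization: for each gene present in
#' every library, compute the ratio of its count to its geometric mean
#' across libraries; a library's size factor is the median of those
#' ratios, and normalized counts are raw counts divided by the size
#' factor. Genes with a zero anywhere carry no weight in the size
#' factors.
#'
#' @param counts non-negative integer matrix, genes x libraries.
#' @return list of class `count_matrix`: `counts`, `size_factors`
#'   (named, all > 0), `normalized`.
#' @examples
#' m <- matrix(c(10, 20, 20, 40), 2, dimnames = list(c("a", "b"), c("x", "y")))
#' normalize_median_ratios(m)$size_factors  # proportional 1:2
#' @export
normalize_median_ratios <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    stop("no gene has a nonzero count in every library; cannot normalize",
         call. = FALSE)
  }
  log_geo <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  sf <- apply(counts[all_pos, , drop = FALSE], 2, function(col) {
    median(exp(log(col) - log_geo))
  })
  structure(list(counts = counts, size_factors = sf,
                 normalized = sweep(counts, 2, sf, "/")),
            class = "count_matrix")
}

#' Per-gene two-group differential test on normalized counts
#'
#' A deliberately simple differential-expression screen: pooled-variance
#' t-test on `log2(normalized + 1)` per gene, control vs salt, with
#' Benjamini-Hochberg adjustment across genes. Designed to reproduce a
#' negative result (no plastid differential expression) on null data, not
#' to compete with shrinkage-based NB models.
#'
#' @param normalized normalized count matrix (genes x libraries), e.g.
#'   `normalize_median_ratios(counts)$normalized`.
#' @param groups named list of two character vectors of library ids, e.g.
#'   `list(control = c("Cnt-1", "Cnt-2"), salt = c("Salt-1", "Salt-2"))`.
#' @return data.frame: `gene_id`, `log2fc` (second group minus first),
#'   `p`, `q` (BH), `flag`.
#' @export
differential_test <- function(normalized, groups) {
  if (length(groups) != 2L || is.null(names(groups))) {
    stop("'groups' must be a named list of two library-id vectors",
         call. = FALSE)
  }
  g1 <- groups[[1]]
  g2 <- groups[[2]]
  if (length(g1) < 2L || length(g2) < 2L) {
    stop("each group needs at least two libraries", call. = FALSE)
  }
  miss <- setdiff(c(g1, g2), colnames(normalized))
  if (length(miss)) {
    stop("unknown library id(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lx <- log2(normalized + 1)
  res <- lapply(rownames(normalized), function(g) {
    t <- pooled_t_test(lx[g, g1], lx[g, g2])
    data.frame(gene_id = g, log2fc = t$mean_y - t$mean_x, p = t$p_value,
               flag = t$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out[, c("gene_id", "log2fc", "p", "q", "flag")]
}

#' Write a heatmap-ready normalized matrix (TSV) and optional image
#'
#' Figure cosmetics are out of scope; the TSV matrix is the canonical
#' output, and the optional image is a plain [stats::heatmap()] rendering.
#'
#' @param normalized normalized count matrix.
#' @param tsv_path TSV output path.
#' @param png_path optional PNG path.
#' @return `tsv_path`, invisibly.
#' @export
write_expression_heatmap <- function(normalized, tsv_path, png_path = NULL) {
  write.table(data.frame(gene_id = rownames(normalized), normalized,
                         check.names = FALSE),
              tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 800, height = 600)
    on.exit(grDevices::dev.off())
    stats::heatmap(log2(as.matrix(normalized) + 1), scale = "none",
                   main = "log2 normalized counts")
  }
  invisible(tsv_path)
}
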