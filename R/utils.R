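#' @importFrom stats median pt rbinom rmultinom rnorm runif sd setNames
#' @importFrom utils read.csv read.delim write.csv write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Draw a random DNA sequence
#'
#' @param n sequence length (nt).
#' @return A single character string over {A,C,G,T}.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse-complement a DNA string
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# as.character() drops names; sequence sets must keep their ids
as_named_chr <- function(x) {
  nm <- names(x)
  x <- as.character(x)
  names(x) <- nm
  x
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop(sprintf("'%s' = %g is outside the allowed range %s%g, %g%s", name, x,
                 if (strict_lower) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}

#' Two-sample equal-variance t-test with explicit degenerate handling
#'
#' Classical pooled-variance two-sided t-test. Groups with fewer than two
#' values, or a zero pooled variance, cannot support the usual sampling
#' theory; such calls are flagged `degenerate` and resolved by convention:
#' equal means with zero pooled variance give p = 1, unequal means give
#' p = 0. A single-observation group still yields a p-value from the
#' pooled-variance formula when at least one degree of freedom remains.
#'
#' @param x,y numeric vectors (NAs removed).
#' @return list with `p_value`, `statistic`, `df`, `mean_x`, `mean_y`,
#'   `degenerate` (logical) and `flag` (character).
#' @export
pooled_t_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 1L || n2 < 1L) {
    return(list(p_value = NA_real_, statistic = NA_real_, df = NA_real_,
                mean_x = if (n1) mean(x) else NA_real_,
                mean_y = if (n2) mean(y) else NA_real_,
                degenerate = TRUE, flag = "incomparable"))
  }
  m1 <- mean(x)
  m2 <- mean(y)
  df <- n1 + n2 - 2L
  ss <- sum((x - m1)^2) + sum((y - m2)^2)
  degenerate <- n1 < 2L || n2 < 2L
  flag <- if (degenerate) "degenerate_n" else "ok"
  if (df < 1L || ss == 0) {
    # zero pooled variance (or no residual df): convention, always flagged
    p <- if (isTRUE(all.equal(m1, m2)) || m1 == m2) 1 else 0
    return(list(p_value = p, statistic = NA_real_, df = as.numeric(df),
                mean_x = m1, mean_y = m2, degenerate = TRUE,
                flag = if (df < 1L) "degenerate_n" else "zero_variance"))
  }
  sp2 <- ss / df
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(tstat), df = df)
  list(p_value = p, statistic = tstat, df = as.numeric(df),
       mean_x = m1, mean_y = m2, degenerate = degenerate, flag = flag)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper kept as a named surface so reports can state the procedure.
#' @param p numeric vector of raw p-values.
#' @return adjusted q-values, same length/order as `p`.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
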