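# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementation under test.

# Exhaustive Hamming scan in plain R: every offset of every target,
# positional mismatch count via byte comparison.
oracle_hamming_scan <- function(reads, targets, max_mismatch) {
  out <- list()
  for (rid in names(reads)) {
    rv <- utf8ToInt(reads[[rid]])
    L <- length(rv)
    for (tid in names(targets)) {
      tv <- utf8ToInt(targets[[tid]])
      n <- length(tv) - L + 1L
      if (n < 1L) next
      mm <- integer(n)
      for (p in seq_len(L)) {
        mm <- mm + (tv[p:(p + n - 1L)] != rv[p])
      }
      hit <- which(mm <= max_mismatch)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          read_id = rid, target_id = tid, start = hit - 1L, length = L,
          mismatches = mm[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(read_id = character(0), target_id = character(0),
                      start = integer(0), length = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  # best stratum per read, same reporting convention as align_reads
  best <- tapply(res$mismatches, res$read_id, min)
  res <- res[res$mismatches == best[res$read_id], , drop = FALSE]
  res[order(match(res$read_id, names(reads)), res$target_id, res$start), ,
      drop = FALSE]
}

# Exact binomial upper tail by direct pmf enumeration on the log scale.
oracle_binom_upper_tail <- function(x, n, p) {
  if (x <= 0) return(1)
  if (x > n) return(0)
  j <- x:n
  sum(exp(lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)))
}

# Closed-form pooled two-sample t-test p-value (textbook formula).
oracle_t_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(tt), df = n1 + n2 - 2)
}

# Median-of-ratios size factors computed straight from the formula.
oracle_size_factors <- function(m) {
  pos <- apply(m > 0, 1, all)
  gm <- apply(m[pos, , drop = FALSE], 1, function(r) prod(r)^(1 / length(r)))
  apply(m[pos, , drop = FALSE], 2, function(col) median(col / gm))
}

# Invert the saturating-exponential curve model for the threshold-crossing
# cycle: b + Fmax*x/(x+K) = b + thr  =>  x = K*thr/(Fmax-thr), c = log_E(x/N0).
oracle_ct_closed_form <- function(threshold, efficiency, n0, k_half = 1,
                                  fmax = 100) {
  x <- k_half * threshold / (fmax - threshold)
  log(x / n0) / log(efficiency)
}
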