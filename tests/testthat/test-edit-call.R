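test_that("pileup_sites matches the truth-table tally on error-free data", {
  gs <- small_genomes()
  st <- small_sites(gs, n = 4, control = 0.55)
  run <- small_library_run(gs, st, n_reads = 2500, error_rate = 0,
                           offtarget_fraction = 0, seed = 41)
  pu <- pileup_sites(run$aln, st, "Cnt-1")
  tally <- truth_site_tally(run$truth)
  key <- paste(pu$gene_id, pu$cds_position)
  expect_equal(pu$n_edited, as.integer(tally[key, "T"]))
  expect_equal(pu$n_unedited, as.integer(tally[key, "C"]))
  # conservation invariant
  expect_equal(pu$coverage, pu$n_edited + pu$n_unedited + pu$n_other)
})

test_that("pileup classifies uncovered sites and N bases correctly", {
  st <- data.frame(gene_id = "g1", cds_position = c(10L, 200L), score = 1,
                   stringsAsFactors = FALSE)
  aln <- data.frame(read_id = c("r1", "r2"), target_id = "g1",
                    start = c(5L, 5L), length = 20L, mismatches = 0L,
                    strand = "+",
                    seq = c(paste0(strrep("A", 4), "T", strrep("A", 15)),
                            paste0(strrep("A", 4), "N", strrep("A", 15))),
                    stringsAsFactors = FALSE)
  pu <- pileup_sites(aln, st, "L1")
  # site 10 covered by both reads at read offset 5: one T, one N
  expect_equal(pu$n_edited[1], 1)
  expect_equal(pu$n_other[1], 1)
  expect_equal(pu$n_unedited[1], 0)
  # site 200 uncovered: zero coverage, fraction "nd"
  expect_equal(pu$coverage[2], 0)
  expect_true(is.na(editing_fraction(pu$n_edited[2], pu$n_unedited[2])))
  # a site beyond the CDS raises a coordinate error naming it
  expect_error(pileup_sites(aln, st, "L1", cds_lengths = c(g1 = 100L)),
               "g1:200")
})

test_that("a multi-placement read contributes once per CDS", {
  # same read placed twice on g1 (tandem repeat) and once on g2
  aln <- data.frame(read_id = "r1", target_id = c("g1", "g1", "g2"),
                    start = c(0L, 20L, 0L), length = 20L, mismatches = 0L,
                    strand = "+", seq = strrep("T", 20),
                    stringsAsFactors = FALSE)
  st <- data.frame(gene_id = c("g1", "g2"), cds_position = c(5L, 5L),
                   score = 1, stringsAsFactors = FALSE)
  pu <- pileup_sites(aln, st, "L1")
  expect_equal(pu$coverage, c(1L, 1L))
})

test_that("variant_test equals exact binomial tail enumeration", {
  expect_equal(variant_test(0, 50)$p, 1)
  expect_false(variant_test(0, 50)$detected)
  # coverage below 5: never detected even with certain signal
  v <- variant_test(4, 4)
  expect_lt(v$p, 1e-2)
  expect_false(v$detected)
  # worked example: 11 edited of 20 at error 0.01
  v2 <- variant_test(11, 20, error_rate = 0.01)
  expect_equal(v2$p, oracle_binom_upper_tail(11, 20, 0.01),
               tolerance = 1e-12)
  expect_true(v2$detected)
  # sweep vs oracle
  withr::with_seed(42, {
    for (i in 1:50) {
      n <- sample(1:1000, 1)
      x <- sample(0:n, 1)
      expect_equal(variant_test(x, n)$p, oracle_binom_upper_tail(x, n, 0.01),
                   tolerance = 1e-12)
    }
  })
  # monotone non-increasing in n_edited at fixed coverage
  p_seq <- variant_test(0:100, 100)$p
  expect_true(all(diff(p_seq) <= 1e-15))
})

test_that("editing_fraction reproduces tabulated worked examples", {
  expect_equal(editing_fraction(11, 9), 0.55)
  expect_equal(editing_fraction(8, 0), 1)
  expect_true(is.na(editing_fraction(0, 0)))
  # n_other excluded from the denominator
  expect_equal(editing_fraction(3, 1), 0.75)
})

test_that("compare_conditions handles standard and degenerate designs", {
  # identical zero-variance groups: p = 1 by convention, flagged
  r <- compare_conditions(c(0.5, 0.5, 0.5, 0.5),
                          c("control", "control", "salt", "salt"))
  expect_equal(r$p_value, 1)
  expect_true(r$degenerate)
  # textbook case against the closed-form oracle
  r2 <- compare_conditions(c(0.9, 0.8, 0.3, 0.4),
                           c("control", "control", "salt", "salt"))
  expect_equal(r2$p_value, oracle_t_p(c(0.9, 0.8), c(0.3, 0.4)),
               tolerance = 1e-12)
  expect_false(r2$degenerate)
  # and against stats::t.test as an independent route
  tt <- stats::t.test(c(0.9, 0.8), c(0.3, 0.4), var.equal = TRUE)
  expect_equal(r2$p_value, unname(tt$p.value), tolerance = 1e-12)
  # n = 1 group: p still computed, flagged degenerate
  r3 <- compare_conditions(c(0.8, 0.2, 0.3),
                           c("control", "salt", "salt"))
  expect_false(is.na(r3$p_value))
  expect_true(r3$degenerate)
  # an all-NA condition is incomparable
  r4 <- compare_conditions(c(NA, NA, 0.5, 0.6),
                           c("control", "control", "salt", "salt"))
  expect_true(is.na(r4$p_value))
  expect_equal(r4$flag, "incomparable")
  # NA ("nd") libraries are excluded, not propagated
  r5 <- compare_conditions(c(0.9, NA, 0.8, 0.3, 0.4, NA),
                           c("control", "control", "control",
                             "salt", "salt", "salt"))
  expect_equal(r5$p_value, oracle_t_p(c(0.9, 0.8), c(0.3, 0.4)),
               tolerance = 1e-12)
})

test_that("site selection applies the total-coverage and detection rules", {
  gs <- small_genomes()
  st <- small_sites(gs, n = 3)
  libs <- c("Cnt-1", "Cnt-2", "Salt-1", "Salt-2")
  conds <- setNames(c("control", "control", "salt", "salt"), libs)
  aln_by_lib <- list()
  for (k in seq_along(libs)) {
    run <- small_library_run(gs, st, library_id = libs[k],
                             condition = unname(conds[k]), n_reads = 1200,
                             error_rate = 0, offtarget_fraction = 0,
                             seed = 50 + k)
    aln_by_lib[[libs[k]]] <- run$aln
  }
  stats <- call_editing_sites(aln_by_lib, st, conds)
  expect_s3_class(stats, "site_editing_stats")
  expect_equal(stats$stats$total_coverage,
               rowSums(stats$stats[, paste0("coverage_", libs)]))
  # coverage {1,1,0,1} -> not selected; {24,17,14,19} -> selected
  fake <- stats
  fake$stats$total_coverage <- c(3, 74, 10)
  fake$stats$detected_any <- c(TRUE, TRUE, TRUE)
  rep1 <- select_sites(fake, min_total_coverage = 4)
  expect_equal(rep1$selected, c(FALSE, TRUE, TRUE)[order(fake$stats$gene_id,
                                                         fake$stats$cds_position)])
  # report renders "nd" for undefined fractions and is ordered
  tsv <- withr::local_tempfile(fileext = ".tsv")
  select_sites(stats, path = tsv)
  rep2 <- utils::read.delim(tsv)
  expect_true(all(diff(order(rep2$gene_id, rep2$cds_position)) > 0))
})

test_that("planted fractions are recovered within binomial error at depth", {
  gs <- small_genomes()
  st <- small_sites(gs, n = 4, control = c(0.2, 0.4, 0.6, 0.9))
  run <- small_library_run(gs, st, n_reads = 25000, error_rate = 0.005,
                           offtarget_fraction = 0, seed = 55)
  pu <- pileup_sites(run$aln, st, "L")
  frac <- editing_fraction(pu$n_edited, pu$n_unedited)
  key <- match(paste(pu$gene_id, pu$cds_position),
               paste(st$gene_id, st$cds_position))
  planted <- st$frac_control[key]
  expect_true(all(pu$coverage >= 100))
  se <- sqrt(planted * (1 - planted) / pu$coverage)
  expect_true(all(abs(frac - planted) < 3 * se + 0.01))
})
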