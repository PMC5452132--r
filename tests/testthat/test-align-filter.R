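test_that("align_reads finds exact and bounded-mismatch placements", {
  withr::with_seed(21, {
    target <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  })
  read <- substr(target, 101, 120) # 0-based start 100
  aln <- align_reads(c(r1 = read), c(t1 = target), max_mismatch = 0)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$start, 100)
  expect_equal(aln$mismatches, 0)
  expect_equal(aln$strand, "+")

  # one planted substitution: invisible at mm 0, found at mm 2
  mut <- read
  substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 10, 10))[1]
  expect_equal(nrow(align_reads(c(r1 = mut), c(t1 = target),
                                max_mismatch = 0)), 0)
  aln2 <- align_reads(c(r1 = mut), c(t1 = target), max_mismatch = 2)
  expect_true(any(aln2$start == 100 & aln2$mismatches == 1))
  # best stratum: no 2-mismatch placement reported alongside the 1
  expect_true(all(aln2$mismatches == min(aln2$mismatches)))
})

test_that("align_reads equals the exhaustive Hamming-scan oracle", {
  withr::with_seed(22, {
    for (rep in 1:5) {
      target <- c(t1 = paste(sample(c("A", "C", "G", "T"), 3000, TRUE),
                             collapse = ""))
      reads <- character(30)
      for (i in seq_along(reads)) {
        L <- sample(16:28, 1)
        s <- sample(3000 - L, 1)
        r <- substr(target[[1]], s, s + L - 1)
        nmut <- sample(0:3, 1)
        for (p in sample(L, nmut)) {
          substr(r, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(r, p, p)), 1)
        }
        reads[i] <- r
      }
      names(reads) <- sprintf("r%02d", seq_along(reads))
      k <- sample(0:2, 1)
      mine <- align_reads(reads, target, max_mismatch = k)
      oracle <- oracle_hamming_scan(as.list(reads), as.list(target), k)
      rownames(mine) <- rownames(oracle) <- NULL
      expect_equal(mine[, c("read_id", "target_id", "start", "mismatches")],
                   oracle[, c("read_id", "target_id", "start", "mismatches")])
    }
  })
})

test_that("reverse-complement placements are off by default", {
  withr::with_seed(23, {
    target <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  })
  fwd <- substr(target, 51, 70)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  expect_equal(nrow(align_reads(c(r = rc), c(t = target), max_mismatch = 0)), 0)
  aln <- align_reads(c(r = rc), c(t = target), max_mismatch = 0,
                     allow_revcomp = TRUE)
  expect_equal(aln$strand, "-")
  expect_equal(aln$start, 50)
})

test_that("N in a read counts as a mismatch", {
  withr::with_seed(24, {
    target <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  })
  read <- substr(target, 101, 120)
  substr(read, 5, 5) <- "N"
  expect_equal(nrow(align_reads(c(r = read), c(t = target),
                                max_mismatch = 0)), 0)
  aln <- align_reads(c(r = read), c(t = target), max_mismatch = 1)
  expect_true(any(aln$start == 100 & aln$mismatches == 1))
})

test_that("align_reads validates inputs and handles short reads / report modes", {
  expect_error(align_reads(character(0), c(t = "ACGT")), "empty read")
  expect_error(align_reads(c(r = "ACGTACGTACGTACGTACGT"), character(0)),
               "empty target")
  expect_error(align_reads(c(r = "ACGTACGTACGTACGTACGT"), c(t = "ACGT"),
                           max_mismatch = 3), "max_mismatch")
  # short reads dropped with a message and counted
  expect_message(
    aln <- align_reads(c(short = "ACGTACGT",
                         ok = strrep("ACGT", 5)),
                       c(t = strrep("ACGT", 30)), max_mismatch = 0),
    "dropped 1")
  expect_equal(attr(aln, "n_too_short"), 1L)
  expect_false("short" %in% aln$read_id)
  # "first": single leftmost placement on the smallest target id
  targets <- c(tB = strrep("ACGT", 30), tA = strrep("ACGT", 30))
  first <- align_reads(c(r = strrep("ACGT", 5)), targets,
                       max_mismatch = 0, report = "first")
  expect_equal(nrow(first), 1)
  expect_equal(first$target_id, "tA")
  expect_equal(first$start, 0)
})

test_that("hierarchical_filter honors the round order", {
  gs <- small_genomes()
  genome <- as.character(gs$chloroplast_genome)
  nuclear <- as.character(gs$nuclear_genome)
  # read present verbatim in chloroplast AND nuclear: chloroplast wins
  shared <- substr(genome, 201, 220)
  gs2 <- gs
  gs2$nuclear_genome <- Biostrings::DNAString(
    paste0(substr(nuclear, 1, 100), shared, substr(nuclear, 121, 6000)))
  # read matching nuclear exactly but chloroplast only with 1 mismatch:
  # subtracted in round 2, never reaches round 3
  near_cp <- substr(genome, 501, 520)
  substr(near_cp, 8, 8) <- setdiff(c("A", "C", "G", "T"),
                                   substr(near_cp, 8, 8))[1]
  nuc2 <- as.character(gs2$nuclear_genome)
  gs2$nuclear_genome <- Biostrings::DNAString(
    paste0(substr(nuc2, 1, 300), near_cp, substr(nuc2, 321, nchar(nuc2))))
  stopifnot(nchar(near_cp) == 20)
  sets <- hierarchical_filter(c(both = shared, nearcp = near_cp), gs2)
  expect_true("both" %in% sets$cp_m0$read_id)
  expect_true("nearcp" %in% sets$subtracted)
  expect_false("nearcp" %in% sets$cp_m2$read_id)
})

test_that("filtered read sets obey their set algebra on simulated data", {
  gs <- small_genomes()
  st <- small_sites(gs)
  run <- small_library_run(gs, st, n_reads = 1500, error_rate = 0.01,
                           offtarget_fraction = 0.3, seed = 31)
  sets <- run$sets
  m0 <- unique(sets$cp_m0$read_id)
  m2 <- unique(sets$cp_m2$read_id)
  expect_length(intersect(m0, m2), 0)
  expect_setequal(unique(sets$cp_m0_m2$read_id), union(m0, m2))
  expect_length(intersect(sets$subtracted, union(m0, m2)), 0)
  expect_length(intersect(sets$unplaced, union(m0, m2)), 0)
  expect_equal(length(m0) + length(m2) + length(sets$subtracted) +
                 length(sets$unplaced) + length(sets$too_short),
               nrow(run$truth))
})

test_that("every read lands in the round its truth-table row predicts", {
  gs <- small_genomes()
  st <- small_sites(gs)
  run <- small_library_run(gs, st, n_reads = 2000, error_rate = 0,
                           offtarget_fraction = 0.25, seed = 32)
  expect_identical(observed_round(run$sets, run$truth),
                   truth_predicted_round(run$truth))
  # error-free on-target library: full recovery into cp_m0_m2
  run2 <- small_library_run(gs, st, n_reads = 800, error_rate = 0,
                            offtarget_fraction = 0, seed = 33)
  expect_setequal(unique(run2$sets$cp_m0_m2$read_id), run2$truth$read_id)
  # reads with a planted single substitution appear only in cp_m2
  edited <- run2$truth$read_id[run2$truth$n_mismatches == 1]
  if (length(edited)) {
    expect_true(all(edited %in% run2$sets$cp_m2$read_id))
    expect_false(any(edited %in% run2$sets$cp_m0$read_id))
  }
})

test_that("realign_to_cds writes standard SAM and consistent mismatches", {
  gs <- small_genomes()
  cds <- as.character(gs$cds_seqs)
  read <- substr(cds[[2]], 51, 72) # 0-based start 50
  sam <- withr::local_tempfile(fileext = ".sam")
  aln <- realign_to_cds(c(r1 = read), gs$cds_seqs, sam_path = sam)
  expect_equal(aln$start, 50)
  lines <- readLines(sam)
  expect_true(any(grepl("^@HD\t", lines)))
  expect_equal(sum(grepl("^@SQ\t", lines)), length(cds))
  rec <- strsplit(grep("^r1\t", lines, value = TRUE), "\t")[[1]]
  expect_equal(as.integer(rec[4]), 51) # SAM POS is 1-based
  expect_equal(rec[6], "22M")
  expect_equal(rec[12], "NM:i:0")

  # empty input: header-only SAM
  sam2 <- withr::local_tempfile(fileext = ".sam")
  aln2 <- realign_to_cds(character(0), gs$cds_seqs, sam_path = sam2)
  expect_equal(nrow(aln2), 0)
  expect_true(all(startsWith(readLines(sam2), "@")))

  # SAM round trip preserves the alignment table
  back <- read_sam_alignments(sam)
  expect_equal(back[, c("read_id", "target_id", "start", "mismatches")],
               aln[, c("read_id", "target_id", "start", "mismatches")])
})

test_that("realigned mismatch counts match the filter round for CDS reads", {
  gs <- small_genomes()
  st <- small_sites(gs)
  run <- small_library_run(gs, st, n_reads = 800, error_rate = 0,
                           offtarget_fraction = 0, seed = 34)
  per_read_mm <- tapply(run$aln$mismatches, run$aln$read_id, min)
  cds_reads <- run$truth[run$truth$origin_type == "cds", ]
  found <- intersect(cds_reads$read_id, names(per_read_mm))
  expect_equal(as.vector(per_read_mm[found]),
               cds_reads$n_mismatches[match(found, cds_reads$read_id)])
})
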