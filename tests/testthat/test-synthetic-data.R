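test_that("generate_genome_set satisfies its structural invariants", {
  gs <- small_genomes(seed = 1)
  expect_s3_class(gs, "genome_set")
  expect_length(gs$cds_seqs, 4)
  genome <- as.character(gs$chloroplast_genome)
  # every CDS equals the strand-adjusted substring of the genome
  for (i in seq_len(nrow(gs$cds_info))) {
    info <- gs$cds_info[i, ]
    sub <- substr(genome, info$start, info$end)
    if (info$strand == "-") {
      sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
    }
    expect_identical(as.character(gs$cds_seqs[[info$gene_id]]), sub)
  }
  # intervals non-overlapping
  info <- gs$cds_info[order(gs$cds_info$start), ]
  expect_true(all(utils::head(info$end, -1) < utils::tail(info$start, -1)))
  # alphabet
  for (s in list(gs$chloroplast_genome, gs$nuclear_genome, gs$mito_genome)) {
    expect_true(all(strsplit(as.character(s), "")[[1]] %in% c("A", "C", "G", "T")))
  }
})

test_that("generate_genome_set is deterministic and rejects impossible packings", {
  a <- small_genomes(seed = 7)
  b <- small_genomes(seed = 7)
  expect_identical(as.character(a$chloroplast_genome),
                   as.character(b$chloroplast_genome))
  expect_identical(as.character(a$cds_seqs), as.character(b$cds_seqs))
  expect_false(identical(as.character(a$chloroplast_genome),
                         as.character(small_genomes(seed = 8)$chloroplast_genome)))
  expect_error(generate_genome_set(cp_length = 1000, n_genes = 10,
                                   cds_length = 600),
               "cannot place")
})

test_that("generate_site_table plants C sites with stored fractions", {
  gs <- small_genomes()
  st <- generate_site_table(gs, n_sites = 5,
                            fractions = list(control = 0.8, salt = 0.9),
                            seed = 7)
  expect_equal(nrow(st), 5)
  expect_true(all(st$ref_base == "C"))
  expect_true(all(st$score >= 0.5 & st$score <= 1))
  expect_identical(st$frac_control, rep(0.8, 5))
  expect_identical(st$frac_salt, rep(0.9, 5))
  # the position really is a C in the CDS
  expect_silent(validate_site_table(st, gs))
  # per-site fraction vectors pass through verbatim
  st2 <- generate_site_table(gs, n_sites = 3,
                             fractions = list(control = c(0.1, 0.5, 0.9),
                                              salt = 0.7), seed = 7)
  expect_setequal(st2$frac_control, c(0.1, 0.5, 0.9))
})

test_that("generate_site_table errors when no C is available", {
  gs <- small_genomes()
  gs$cds_seqs <- Biostrings::DNAStringSet(c(gene01 = strrep("G", 200)))
  expect_error(generate_site_table(gs, n_sites = 5), "not enough cytidines")
})

test_that("simulated reads carry planted edits at the planted fraction", {
  gs <- small_genomes()
  st <- small_sites(gs, n = 2, control = 1.0)
  run <- small_library_run(gs, st, n_reads = 1500, error_rate = 0,
                           offtarget_fraction = 0, seed = 11)
  tally <- truth_site_tally(run$truth)
  # fraction 1: every covering read carries T
  expect_true(all(tally[, "C"] == 0))
  expect_true(all(tally[, "T"] > 0))

  # fraction 0.55: observed T fraction within 3 binomial SE
  st2 <- small_sites(gs, n = 2, control = 0.55, seed = 4)
  run2 <- small_library_run(gs, st2, n_reads = 4000, error_rate = 0,
                            offtarget_fraction = 0, seed = 12)
  tally2 <- truth_site_tally(run2$truth)
  for (k in seq_len(nrow(tally2))) {
    n <- sum(tally2[k, ])
    se <- sqrt(0.55 * 0.45 / n)
    expect_lt(abs(tally2[k, "T"] / n - 0.55), 3 * se)
  }
})

test_that("off-target read counts follow the binomial oracle", {
  gs <- small_genomes()
  st <- small_sites(gs)
  prof <- library_profile("L", "control", n_reads = 10000, error_rate = 0,
                          offtarget_fraction = 0.2, seed = 5)
  fq <- withr::local_tempfile(fileext = ".fastq")
  truth <- simulate_read_library(gs, st, prof, fq)
  n_decoy <- sum(truth$origin_type %in% c("nuclear", "mito"))
  se <- sqrt(10000 * 0.2 * 0.8)
  expect_lt(abs(n_decoy - 2000), 3 * se)
})

test_that("FASTQ and truth outputs are byte-identical under a fixed seed", {
  gs <- small_genomes()
  st <- small_sites(gs)
  prof <- library_profile("L", "control", n_reads = 300, seed = 6)
  fq1 <- withr::local_tempfile(fileext = ".fastq")
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  simulate_read_library(gs, st, prof, fq1)
  simulate_read_library(gs, st, prof, fq2)
  expect_identical(readLines(fq1), readLines(fq2))
  expect_identical(readLines(sub("\\.fastq$", ".truth.tsv", fq1)),
                   readLines(sub("\\.fastq$", ".truth.tsv", fq2)))
})

test_that("truth table is consistent with the written reads", {
  gs <- small_genomes()
  st <- small_sites(gs)
  run <- small_library_run(gs, st, n_reads = 500, error_rate = 0.01,
                           seed = 13)
  reads <- run$reads
  truth <- run$truth
  refs <- c(as.character(gs$cds_seqs), as.character(gs$trna_seqs),
            nuclear = as.character(gs$nuclear_genome),
            mito = as.character(gs$mito_genome))
  for (i in withr::with_seed(99, sample(nrow(truth), 50))) {
    ref_sub <- substr(refs[[truth$origin_id[i]]], truth$start[i] + 1,
                      truth$start[i] + truth$length[i])
    read <- reads[[truth$read_id[i]]]
    expect_equal(sum(utf8ToInt(read) != utf8ToInt(ref_sub)),
                 truth$n_mismatches[i])
  }
})

test_that("qPCR curve model obeys the doubling law and slope closed form", {
  # noise-free, E = 2: halving N0 shifts the threshold crossing by one cycle
  f1 <- qpcr_curve(1:40, 2, 1e-7)
  f2 <- qpcr_curve(1:40, 2, 5e-8)
  ct1 <- call_ct(f1)$ct
  ct2 <- call_ct(f2)$ct
  expect_equal(ct2 - ct1, 1, tolerance = 1e-3)

  # symmetry: f = 0.5 gives identical T and C wells
  design <- make_plate_design("s1", treatments = "control",
                              timepoints = "4h", n_bio = 1, n_tech = 1)
  fr <- data.frame(site = "s1", treatment = "control", timepoint = "4h",
                   fraction = 0.5)
  sim <- simulate_qpcr_plate(design, fr, efficiency = 2, noise_sd = 0,
                             seed = 1)
  byw <- split(sim$plate$fluorescence, sim$plate$well)
  expect_equal(byw[[1]], byw[[2]])

  # early exponential-phase slope of log10 F equals log10(E)
  fl <- qpcr_curve(1:40, 1.9, 1e-9)
  fsub <- fl - 50
  early <- which(fsub > 1e-6 & fsub < 0.1) # far below saturation
  slope <- stats::coef(stats::lm(log10(fsub[early]) ~ early))[2]
  expect_equal(unname(slope), log10(1.9), tolerance = 1e-3)
})

test_that("simulate_qpcr_plate validates parameters", {
  design <- make_plate_design("s1", treatments = "control",
                              timepoints = "4h", n_bio = 1, n_tech = 1)
  fr <- data.frame(site = "s1", treatment = "control", timepoint = "4h",
                   fraction = 1.2)
  expect_error(simulate_qpcr_plate(design, fr), "\\[0,1\\]")
  fr$fraction <- 0.5
  expect_error(simulate_qpcr_plate(design, fr, efficiency = 0.9), "\\(1, 2.5\\]")
  expect_error(simulate_qpcr_plate(design, fr, total_template = 0), "n")
})
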