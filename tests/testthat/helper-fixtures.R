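# Shared small fixtures, built in code at test time.

small_genomes <- function(seed = 1) {
  generate_genome_set(cp_length = 5000, n_genes = 4, cds_length = 400,
                      n_trnas = 3, trna_length = 75, nuclear_length = 6000,
                      mito_length = 3000, seed = seed)
}

small_sites <- function(genomes, n = 4, control = 0.6, salt = 0.8,
                        seed = 2) {
  generate_site_table(genomes, n_sites = n,
                      fractions = list(control = control, salt = salt),
                      seed = seed)
}

# Simulate, filter and realign one library; returns list(truth, reads,
# sets, aln).
small_library_run <- function(genomes, sites, library_id = "Cnt-1",
                              condition = "control", n_reads = 2000,
                              error_rate = 0, offtarget_fraction = 0.2,
                              seed = 3) {
  prof <- library_profile(library_id, condition, n_reads = n_reads,
                          error_rate = error_rate,
                          offtarget_fraction = offtarget_fraction,
                          seed = seed)
  fq <- withr::local_tempfile(fileext = ".fastq",
                              .local_envir = parent.frame())
  truth <- simulate_read_library(genomes, sites, prof, fq)
  reads <- read_fastq_seqs(fq)
  sets <- suppressMessages(hierarchical_filter(reads, genomes))
  aln <- realign_to_cds(retained_reads(sets, reads), genomes$cds_seqs)
  list(truth = truth, reads = reads, sets = sets, aln = aln, fastq = fq)
}

# Tally the final base carried at each site over all reads in a truth
# table: the ground truth for pileup counts on error-free data.
truth_site_tally <- function(truth) {
  sb <- unlist(strsplit(truth$site_bases[truth$site_bases != ""], ";"))
  if (!length(sb)) return(NULL)
  parts <- do.call(rbind, strsplit(sb, ":"))
  table(site = paste(parts[, 1], parts[, 2]),
        base = factor(parts[, 3], levels = c("A", "C", "G", "T", "N")))
}

# Round each read should land in, predicted from its truth-table row.
truth_predicted_round <- function(truth) {
  ifelse(truth$origin_type %in% c("nuclear", "mito"), "subtracted",
         ifelse(truth$n_mismatches == 0, "cp_m0",
                ifelse(truth$n_mismatches <= 2, "cp_m2", "unplaced")))
}

observed_round <- function(sets, truth) {
  obs <- rep("unplaced", nrow(truth))
  names(obs) <- truth$read_id
  obs[unique(sets$cp_m0$read_id)] <- "cp_m0"
  obs[sets$subtracted] <- "subtracted"
  obs[unique(sets$cp_m2$read_id)] <- "cp_m2"
  unname(obs)
}
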