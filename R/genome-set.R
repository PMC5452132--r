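#' Generate a synthetic organellar genome set
#'
#' Builds the reference side of a simulated chloroplast editing study: a
#' circular-ish plastid genome with non-overlapping protein-coding genes on
#' both strands, a set of tRNAs, and nuclear and mitochondrial decoy
#' genomes used to exercise subtractive alignment. Each CDS sequence is the
#' strand-adjusted substring of the plastid genome at its annotated
#' interval, mirroring how real chloroplast CDS sets are distributed
#' alongside the genome.
#'
#' Optionally, `n_shared_kmers` chloroplast CDS substrings are copied into
#' the nuclear genome so that some decoy loci are indistinguishable from
#' plastid sequence — the situation that motivates aligning to the
#' chloroplast first. Off by default so that truth-table round predictions
#' stay exact.
#'
#' @param cp_length chloroplast genome length (nt).
#' @param n_genes number of plastid CDSs.
#' @param cds_length length of each CDS (nt).
#' @param n_trnas,trna_length tRNA count and length.
#' @param nuclear_length,mito_length decoy genome lengths.
#' @param n_shared_kmers number of chloroplast k-mers planted into the
#'   nuclear genome.
#' @param shared_kmer_length length of each planted k-mer.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return An object of class `genome_set`: list with `chloroplast_genome`,
#'   `cds_seqs` (named [Biostrings::DNAStringSet]), `cds_info`
#'   (data.frame: gene_id, start, end, strand; 1-based closed intervals on
#'   the plastid genome), `trna_seqs`, `nuclear_genome`, `mito_genome`.
#' @examples
#' gs <- generate_genome_set(cp_length = 5000, n_genes = 4, cds_length = 400,
#'                           seed = 1)
#' names(gs$cds_seqs)
#' @export
generate_genome_set <- function(cp_length = 20000, n_genes = 10,
                                cds_length = 600, n_trnas = 6,
                                trna_length = 75, nuclear_length = 30000,
                                mito_length = 15000, n_shared_kmers = 0,
                                shared_kmer_length = 30, seed = 1) {
  assert_scalar_number(n_genes, "n_genes", lower = 1)
  assert_scalar_number(cds_length, "cds_length", lower = 30)
  if (n_genes * cds_length > cp_length) {
    stop(sprintf(
      "cannot place %d CDSs of %d nt in a %d nt chloroplast genome",
      n_genes, cds_length, cp_length), call. = FALSE)
  }
  withr::with_seed(seed, {
    genome <- random_dna(cp_length)
    # stars-and-bars gap allocation keeps CDS intervals non-overlapping
    total_gap <- cp_length - n_genes * cds_length
    gaps <- as.vector(rmultinom(1, total_gap, rep(1, n_genes + 1L)))
    starts <- cumsum(gaps[seq_len(n_genes)] + c(0L, rep(cds_length, n_genes - 1L))) + 1L
    ends <- starts + cds_length - 1L
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    gene_ids <- sprintf("gene%02d", seq_len(n_genes))
    cds_chr <- vapply(seq_len(n_genes), function(i) {
      s <- substr(genome, starts[i], ends[i])
      if (strands[i] == "-") revcomp(s) else s
    }, character(1))
    trna_ids <- sprintf("trna%02d", seq_len(n_trnas))
    trna_chr <- vapply(rep(trna_length, n_trnas), random_dna, character(1))
    nuclear <- random_dna(nuclear_length)
    mito <- random_dna(mito_length)
    if (n_shared_kmers > 0) {
      for (i in seq_len(n_shared_kmers)) {
        g <- sample(n_genes, 1)
        p <- sample(cds_length - shared_kmer_length + 1L, 1)
        kmer <- substr(cds_chr[g], p, p + shared_kmer_length - 1L)
        q <- sample(nuclear_length - shared_kmer_length + 1L, 1)
        substr(nuclear, q, q + shared_kmer_length - 1L) <- kmer
      }
    }
    structure(list(
      chloroplast_genome = Biostrings::DNAString(genome),
      cds_seqs = setNames(Biostrings::DNAStringSet(cds_chr), gene_ids),
      cds_info = data.frame(gene_id = gene_ids, start = starts, end = ends,
                            strand = strands, stringsAsFactors = FALSE),
      trna_seqs = setNames(Biostrings::DNAStringSet(trna_chr), trna_ids),
      nuclear_genome = Biostrings::DNAString(nuclear),
      mito_genome = Biostrings::DNAString(mito)
    ), class = "genome_set")
  })
}

#' @export
print.genome_set <- function(x, ...) {
  cat(sprintf(
    "genome_set: chloroplast %d nt, %d CDS, %d tRNA, nuclear %d nt, mito %d nt\n",
    length(x$chloroplast_genome), length(x$cds_seqs), length(x$trna_seqs),
    length(x$nuclear_genome), length(x$mito_genome)))
  invisible(x)
}

#' Write the reference sequences of a genome set as FASTA files
#'
#' @param genomes a `genome_set`.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named character vector of the five FASTA paths.
#' @export
write_genome_set <- function(genomes, dir) {
  stopifnot(inherits(genomes, "genome_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(chloroplast = file.path(dir, "chloroplast.fa"),
             cds = file.path(dir, "cds.fa"),
             trna = file.path(dir, "trna.fa"),
             nuclear = file.path(dir, "nuclear.fa"),
             mito = file.path(dir, "mito.fa"))
  wr <- function(seqs, path) Biostrings::writeXStringSet(seqs, path)
  wr(Biostrings::DNAStringSet(c(chloroplast = as.character(genomes$chloroplast_genome))),
     paths[["chloroplast"]])
  wr(genomes$cds_seqs, paths[["cds"]])
  wr(genomes$trna_seqs, paths[["trna"]])
  wr(Biostrings::DNAStringSet(c(nuclear = as.character(genomes$nuclear_genome))),
     paths[["nuclear"]])
  wr(Biostrings::DNAStringSet(c(mito = as.character(genomes$mito_genome))),
     paths[["mito"]])
  # cds_info travels as a sidecar so intervals/strands survive a round trip
  write.table(genomes$cds_info, file.path(dir, "cds_info.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a genome set written by [write_genome_set()]
#'
#' @param dir directory containing the FASTA files and `cds_info.tsv`.
#' @return A `genome_set`.
#' @export
read_genome_set <- function(dir) {
  need <- file.path(dir, c("chloroplast.fa", "cds.fa", "trna.fa",
                           "nuclear.fa", "mito.fa", "cds_info.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("missing reference file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rd1 <- function(path) Biostrings::readDNAStringSet(path)[[1]]
  structure(list(
    chloroplast_genome = rd1(need[1]),
    cds_seqs = Biostrings::readDNAStringSet(need[2]),
    cds_info = read.delim(need[6], stringsAsFactors = FALSE),
    trna_seqs = Biostrings::readDNAStringSet(need[3]),
    nuclear_genome = rd1(need[4]),
    mito_genome = rd1(need[5])
  ), class = "genome_set")
}
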