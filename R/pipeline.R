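#' Default end-to-end run configuration
#'
#' All tunable parameters of the pipeline in one auditable list. The
#' defaults describe the synthetic demo study: four small RNA libraries
#' (two control, two salt), planted editing fractions of 0.6 (control) vs
#' 0.8 (salt) at differential sites, and the canonical thresholds of the
#' analysis — detection coverage 5, variant p-value ceiling 1e-2, total
#' coverage 4 for site selection, qPCR efficiency minimum 1.75,
#' significance 0.05.
#'
#' @param seed master seed; stage seeds are derived as small offsets.
#' @param out_dir run directory (created by [run_all()]).
#' @param n_reads reads per library.
#' @param n_sites number of planted editing sites.
#' @param n_diff_sites how many of them differ between conditions
#'   (control 0.6 vs salt 0.8; the rest are null at 0.7).
#' @param error_rate per-base sequencing error rate.
#' @param offtarget_fraction nuclear+mito read fraction per library.
#' @return A nested list of class `run_config`.
#' @export
run_config <- function(seed = 42, out_dir = tempfile("chloredit_run_"),
                       n_reads = 2000, n_sites = 8, n_diff_sites = 4,
                       error_rate = 0.005, offtarget_fraction = 0.3) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    genome = list(cp_length = 20000, n_genes = 10, cds_length = 600,
                  n_trnas = 6, trna_length = 75, nuclear_length = 30000,
                  mito_length = 15000),
    sites = list(n_sites = n_sites, n_diff_sites = n_diff_sites,
                 frac_control_diff = 0.6, frac_salt_diff = 0.8,
                 frac_null = 0.7, score_cutoff = 0.5),
    libraries = list(ids = c("Cnt-1", "Cnt-2", "Salt-1", "Salt-2"),
                     conditions = c("control", "control", "salt", "salt"),
                     n_reads = n_reads, read_length_range = c(18, 24),
                     error_rate = error_rate,
                     offtarget_fraction = offtarget_fraction,
                     trna_fraction = 0.1),
    align = list(max_mismatch = 2, report = "best-stratum",
                 min_read_length = 15),
    edit_call = list(error_rate = 0.01, min_coverage = 5, max_p = 1e-2,
                     min_total_coverage = 4),
    qpcr = list(timepoints = c("4h", "24h"), n_bio = 3, n_tech = 4,
                efficiency = 2, noise_sd = 0.5, min_eff = 1.75,
                alpha = 0.05),
    expression = list(alpha = 0.05)
  )
  class(cfg) <- c("run_config", "list")
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  assert_scalar_number(cfg$edit_call$min_coverage, "min_coverage", lower = 1)
  assert_scalar_number(cfg$edit_call$max_p, "max_p", lower = 0, upper = 1,
                       strict_lower = TRUE)
  assert_scalar_number(cfg$edit_call$min_total_coverage, "min_total_coverage",
                       lower = 0)
  assert_scalar_number(cfg$qpcr$min_eff, "min_eff", lower = 1, upper = 2.5)
  assert_scalar_number(cfg$qpcr$alpha, "alpha", lower = 0, upper = 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  if (!cfg$align$max_mismatch %in% 0:2) {
    stop("align$max_mismatch must be 0, 1 or 2", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a run configuration from JSON
#'
#' JSON was chosen over YAML as the config format so that the pipeline has
#' no dependency beyond jsonlite; the structure matches [run_config()],
#' and absent fields keep their defaults.
#'
#' @param path JSON file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config()
  merge_into <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]])) {
        merge_into(base[[nm]], upd[[nm]])
      } else upd[[nm]]
    }
    base
  }
  cfg <- merge_into(cfg, user)
  class(cfg) <- c("run_config", "list")
  validate_run_config(cfg)
}

stage_log <- function(log_path, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
}

#' Run the full pipeline: simulate, align, call edits, expression, qPCR
#'
#' Executes every stage in order under `cfg$out_dir`, writing per-stage
#' outputs and a machine-readable `manifest.json` (seed, parameter echo,
#' read-set cardinalities per filter round). Running twice with the same
#' config yields byte-identical outputs.
#'
#' Layout under the run directory: `inputs/` (FASTA references, site
#' table, FASTQ + truth tables, qPCR plate CSVs), `align/` (SAM and
#' read-set manifest), `edit_call/editing_report.tsv`, `expression/`
#' (counts, normalized matrix, DE results), `qpcr/` (fractions and
#' treatment comparison), `run.log` and `manifest.json`.
#'
#' @param cfg a `run_config` (or path to a JSON config).
#' @return Invisibly, a list with the in-memory stage results and
#'   `out_dir`.
#' @export
run_all <- function(cfg = run_config()) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_run_config(cfg)
  out <- cfg$out_dir
  for (d in c("inputs", "align", "edit_call", "expression", "qpcr")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  log_path <- file.path(out, "run.log")
  if (file.exists(log_path)) unlink(log_path)

  ## stage 1: simulate -----------------------------------------------------
  stage_log(log_path, "simulate", "generating references and libraries")
  gcfg <- cfg$genome
  genomes <- generate_genome_set(
    cp_length = gcfg$cp_length, n_genes = gcfg$n_genes,
    cds_length = gcfg$cds_length, n_trnas = gcfg$n_trnas,
    trna_length = gcfg$trna_length, nuclear_length = gcfg$nuclear_length,
    mito_length = gcfg$mito_length, seed = cfg$seed)
  write_genome_set(genomes, file.path(out, "inputs"))
  scfg <- cfg$sites
  n_diff <- min(scfg$n_diff_sites, scfg$n_sites)
  fr_ctl <- c(rep(scfg$frac_control_diff, n_diff),
              rep(scfg$frac_null, scfg$n_sites - n_diff))
  fr_salt <- c(rep(scfg$frac_salt_diff, n_diff),
               rep(scfg$frac_null, scfg$n_sites - n_diff))
  sites <- generate_site_table(
    genomes, n_sites = scfg$n_sites,
    fractions = list(control = fr_ctl, salt = fr_salt),
    score_cutoff = scfg$score_cutoff, seed = cfg$seed + 1L)
  write_site_table(sites, file.path(out, "inputs", "site_table.tsv"))

  lcfg <- cfg$libraries
  truth <- list()
  fastqs <- character(0)
  for (k in seq_along(lcfg$ids)) {
    prof <- library_profile(
      lcfg$ids[k], condition = lcfg$conditions[k], n_reads = lcfg$n_reads,
      read_length_range = lcfg$read_length_range,
      error_rate = lcfg$error_rate,
      offtarget_fraction = lcfg$offtarget_fraction,
      trna_fraction = lcfg$trna_fraction, seed = cfg$seed + 10L + k)
    fq <- file.path(out, "inputs", paste0(lcfg$ids[k], ".fastq"))
    truth[[lcfg$ids[k]]] <- simulate_read_library(genomes, sites, prof, fq)
    fastqs[lcfg$ids[k]] <- fq
    stage_log(log_path, "simulate",
              sprintf("library %s: %d reads", lcfg$ids[k], lcfg$n_reads))
  }

  qcfg <- cfg$qpcr
  site_ids <- sprintf("%s:%d", sites$gene_id, sites$cds_position)
  design <- make_plate_design(site_ids, timepoints = qcfg$timepoints,
                              n_bio = qcfg$n_bio, n_tech = qcfg$n_tech)
  fr <- expand.grid(site = site_ids, treatment = c("control", "salt"),
                    timepoint = qcfg$timepoints, stringsAsFactors = FALSE)
  fr$fraction <- ifelse(fr$treatment == "control",
                        sites$frac_control[match(fr$site, site_ids)],
                        sites$frac_salt[match(fr$site, site_ids)])
  plate_csv <- file.path(out, "inputs", "plate.csv")
  map_csv <- file.path(out, "inputs", "plate_map.csv")
  simulate_qpcr_plate(design, fr, efficiency = qcfg$efficiency,
                      noise_sd = qcfg$noise_sd, seed = cfg$seed + 20L,
                      plate_path = plate_csv, map_path = map_csv)
  stage_log(log_path, "simulate",
            sprintf("qPCR plate: %d wells", nrow(design)))

  ## stage 2: align --------------------------------------------------------
  acfg <- cfg$align
  cds_chr <- as.character(genomes$cds_seqs)
  aln_by_lib <- list()
  filter_counts <- list()
  for (lb in lcfg$ids) {
    reads <- read_fastq_seqs(fastqs[lb])
    sets <- hierarchical_filter(reads, genomes,
                                max_mismatch_relaxed = acfg$max_mismatch,
                                report = acfg$report,
                                min_read_length = acfg$min_read_length)
    filter_counts[[lb]] <- sets$counts
    stage_log(log_path, "align", sprintf(
      "%s: cp_m0=%d subtracted=%d cp_m2=%d unplaced=%d", lb,
      sets$counts[["cp_m0"]], sets$counts[["subtracted"]],
      sets$counts[["cp_m2"]], sets$counts[["unplaced"]]))
    kept <- retained_reads(sets, reads)
    aln_by_lib[[lb]] <- realign_to_cds(
      kept, cds_chr, max_mismatch = acfg$max_mismatch,
      report = acfg$report,
      sam_path = file.path(out, "align", paste0(lb, ".sam")))
  }
  manifest_counts <- do.call(rbind, lapply(names(filter_counts), function(lb) {
    data.frame(library_id = lb, t(filter_counts[[lb]]),
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  write.table(manifest_counts, file.path(out, "align", "read_sets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## stage 3: call edits ---------------------------------------------------
  ecfg <- cfg$edit_call
  conditions <- setNames(lcfg$conditions, lcfg$ids)
  stats <- call_editing_sites(
    aln_by_lib, sites, conditions, error_rate = ecfg$error_rate,
    min_coverage = ecfg$min_coverage, max_p = ecfg$max_p,
    min_total_coverage = ecfg$min_total_coverage,
    cds_lengths = setNames(nchar(cds_chr), names(cds_chr)))
  report <- select_sites(stats,
                         path = file.path(out, "edit_call",
                                          "editing_report.tsv"))
  stage_log(log_path, "call-edits",
            sprintf("%d/%d sites selected", sum(stats$stats$selected),
                    nrow(stats$stats)))

  ## stage 4: expression ---------------------------------------------------
  counts <- build_count_table(aln_by_lib, names(cds_chr))
  norm <- normalize_median_ratios(counts)
  groups <- split(lcfg$ids, lcfg$conditions)[c("control", "salt")]
  de <- differential_test(norm$normalized, groups)
  write.table(data.frame(gene_id = rownames(counts), counts,
                         check.names = FALSE),
              file.path(out, "expression", "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_expression_heatmap(round(norm$normalized, 4),
                           file.path(out, "expression", "normalized.tsv"))
  write.table(de, file.path(out, "expression", "de_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log(log_path, "expression",
            sprintf("%d/%d genes at q < %.2f", sum(de$q < cfg$expression$alpha),
                    nrow(de), cfg$expression$alpha))

  ## stage 5: qPCR ---------------------------------------------------------
  qres <- analyze_qpcr(plate_csv, map_csv, min_eff = qcfg$min_eff,
                       alpha = qcfg$alpha)
  write.table(qres$fractions, file.path(out, "qpcr", "fractions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(qres$comparison, file.path(out, "qpcr", "comparison.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stage_log(log_path, "qpcr",
            sprintf("%d/%d comparisons significant",
                    sum(qres$comparison$significant),
                    nrow(qres$comparison)))

  ## manifest --------------------------------------------------------------
  cfg_echo <- unclass(cfg)
  cfg_echo$out_dir <- NULL # path, not a parameter: keeps manifests comparable
  manifest <- list(
    package = "chloredit",
    version = as.character(utils::packageVersion("chloredit")),
    seed = cfg$seed,
    config = cfg_echo,
    read_set_counts = lapply(filter_counts, as.list),
    n_sites_selected = sum(stats$stats$selected)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(out_dir = out, genomes = genomes, sites = sites,
                 truth = truth, alignments = aln_by_lib,
                 editing = stats, editing_report = report,
                 counts = counts, normalized = norm, de = de, qpcr = qres))
}
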