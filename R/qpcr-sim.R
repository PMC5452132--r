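#' Lay out an allele-specific qPCR plate design
#'
#' One reaction group per (site, treatment, timepoint, biological
#' replicate, allele), each run in technical replicates — the usual
#' 384-well layout for a two-allele editing assay with technical
#' quadruplicates.
#'
#' @param site_ids character vector of editing-site labels (e.g.
#'   `"gene03:211"`).
#' @param treatments,timepoints factors of the design.
#' @param n_bio biological replicates per treatment x timepoint.
#' @param n_tech technical replicates per reaction group.
#' @return data.frame with columns `well`, `site`, `allele` ("C"/"T"),
#'   `treatment`, `timepoint`, `bio_rep`, `tech_rep`, `sample` (the
#'   biological sample label the well measures).
#' @export
make_plate_design <- function(site_ids, treatments = c("control", "salt"),
                              timepoints = "4h", n_bio = 3, n_tech = 4) {
  d <- expand.grid(tech_rep = seq_len(n_tech), allele = c("C", "T"),
                   bio_rep = seq_len(n_bio), timepoint = timepoints,
                   treatment = treatments, site = site_ids,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("site", "allele", "treatment", "timepoint", "bio_rep",
             "tech_rep")]
  d$sample <- sprintf("%s_%s_b%d", d$treatment, d$timepoint, d$bio_rep)
  # 384-well style coordinates A01..P24, row-major
  idx <- seq_len(nrow(d)) - 1L
  d$well <- sprintf("%s%02d", LETTERS[idx %/% 24L + 1L], idx %% 24L + 1L)
  if (nrow(d) > 384L) {
    d$well <- sprintf("W%04d", seq_len(nrow(d))) # overflow a single plate
  }
  d[, c("well", "site", "allele", "treatment", "timepoint", "bio_rep",
        "tech_rep", "sample")]
}

#' Closed-form amplification-curve model
#'
#' Baseline plus a saturating exponential,
#' `F(c) = b + Fmax * N0 * E^c / (N0 * E^c + K)`:
#' early cycles grow geometrically with per-cycle efficiency `E`, and the
#' signal saturates at `b + Fmax` once the amplicon amount `N0 * E^c`
#' passes the half-saturation constant `K`.
#'
#' @param cycles integer cycle numbers.
#' @param efficiency per-cycle amplification factor `E`, in (1, 2.5\].
#' @param n0 starting template amount (> 0, same units as `k_half`).
#' @param k_half half-saturation template amount.
#' @param fmax plateau height above baseline.
#' @param baseline constant baseline fluorescence.
#' @return numeric fluorescence values.
#' @export
qpcr_curve <- function(cycles, efficiency, n0, k_half = 1, fmax = 100,
                       baseline = 50) {
  assert_scalar_number(efficiency, "efficiency", lower = 1, upper = 2.5,
                       strict_lower = TRUE)
  assert_scalar_number(n0, "n0", lower = 0, strict_lower = TRUE)
  x <- n0 * efficiency^cycles
  baseline + fmax * x / (x + k_half)
}

#' Simulate a qPCR plate measuring edited and unedited alleles
#'
#' For each biological sample the total cDNA amount `total_template` is
#' split between the two allele-specific reactions according to the
#' planted editing fraction `f`: the T (edited) wells receive `f * N`
#' template, the C wells `(1 - f) * N`. Every well's fluorescence follows
#' [qpcr_curve()] with Gaussian noise added.
#'
#' @param design plate design from [make_plate_design()] (or equivalent).
#' @param fractions data.frame with columns `site`, `treatment`,
#'   `timepoint`, `fraction` — the planted editing fraction per condition.
#' @param efficiency either a single per-cycle efficiency for all wells or
#'   a numeric vector, one per design row; values in (1, 2.5\].
#' @param total_template per-sample total template amount `N`.
#' @param k_half,fmax,baseline curve-model constants, see [qpcr_curve()].
#' @param noise_sd Gaussian noise standard deviation, default 0.5% of
#'   `fmax`.
#' @param n_cycles number of PCR cycles (default 40).
#' @param seed integer seed.
#' @param plate_path,map_path optional CSV outputs: long-format plate
#'   (`well,cycle,fluorescence`) and the plate map (design plus the
#'   planted `n0` and `efficiency`).
#' @return Invisibly, a list with `plate` (long data.frame) and `map`.
#' @export
simulate_qpcr_plate <- function(design, fractions, efficiency = 2,
                                total_template = 1e-5, k_half = 1,
                                fmax = 100, baseline = 50,
                                noise_sd = 0.005 * fmax, n_cycles = 40,
                                seed = 1, plate_path = NULL,
                                map_path = NULL) {
  need <- c("well", "site", "allele", "treatment", "timepoint")
  if (!all(need %in% names(design))) {
    stop("design must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (length(efficiency) == 1L) efficiency <- rep(efficiency, nrow(design))
  if (length(efficiency) != nrow(design)) {
    stop("'efficiency' must have length 1 or nrow(design)", call. = FALSE)
  }
  if (any(efficiency <= 1 | efficiency > 2.5)) {
    stop("per-well efficiencies must lie in (1, 2.5]", call. = FALSE)
  }
  assert_scalar_number(total_template, "total_template", lower = 0,
                       strict_lower = TRUE)
  key <- function(d) paste(d$site, d$treatment, d$timepoint)
  f_lookup <- setNames(fractions$fraction, key(fractions))
  f_well <- f_lookup[key(design)]
  if (anyNA(f_well)) {
    stop("missing planted fraction for some design rows", call. = FALSE)
  }
  if (any(f_well < 0 | f_well > 1)) {
    stop("planted fractions must lie in [0,1]", call. = FALSE)
  }
  n0 <- ifelse(design$allele == "T", f_well, 1 - f_well) * total_template
  cycles <- seq_len(n_cycles)
  withr::with_seed(seed, {
    plate <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
      # zero-template wells (f = 0 or 1) stay flat at baseline
      fl <- if (n0[i] > 0) {
        qpcr_curve(cycles, efficiency[i], n0[i], k_half, fmax, baseline)
      } else {
        rep(baseline, n_cycles)
      }
      if (noise_sd > 0) fl <- fl + rnorm(n_cycles, sd = noise_sd)
      data.frame(well = design$well[i], cycle = cycles,
                 fluorescence = round(fl, 4), stringsAsFactors = FALSE)
    }))
    map <- design
    map$planted_fraction <- unname(f_well)
    map$planted_efficiency <- efficiency
    map$n0 <- n0
    if (!is.null(plate_path)) {
      write.csv(plate, plate_path, row.names = FALSE, quote = FALSE)
    }
    if (!is.null(map_path)) {
      write.csv(map, map_path, row.names = FALSE, quote = FALSE)
    }
    invisible(list(plate = plate, map = map))
  })
}
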