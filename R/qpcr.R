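#' Baseline fluorescence of an amplification curve
#'
#' Mean fluorescence over the first `n_baseline_cycles` cycles, before any
#' detectable amplification. Subtracted from the curve before Ct calling
#' and efficiency fitting.
#'
#' @param fluorescence numeric vector, one value per cycle.
#' @param n_baseline_cycles number of early cycles to average (default 5).
#' @return baseline value.
#' @export
estimate_baseline <- function(fluorescence, n_baseline_cycles = 5) {
  if (n_baseline_cycles >= length(fluorescence)) {
    stop("n_baseline_cycles must be smaller than the number of cycles",
         call. = FALSE)
  }
  mean(fluorescence[seq_len(n_baseline_cycles)])
}

#' Call the quantification cycle (Ct)
#'
#' Automated stand-in for a manually set threshold: the threshold sits
#' `threshold_k` baseline standard deviations above the baseline, with a
#' floor of 2% of the curve's above-baseline range so that noise-free
#' (zero-sd) curves still get a usable threshold. Ct is the fractional
#' cycle at which the baseline-subtracted fluorescence first crosses the
#' threshold upwards, found by linear interpolation between the two
#' flanking cycles. `NA` when the curve never crosses.
#'
#' @param fluorescence numeric vector per cycle.
#' @param cycles cycle numbers (default `seq_along(fluorescence)`).
#' @param threshold explicit threshold on the baseline-subtracted scale;
#'   overrides the automatic rule.
#' @param n_baseline_cycles,threshold_k automatic-threshold parameters.
#' @return list: `ct` (fractional cycles or NA), `baseline`, `threshold`
#'   (baseline-subtracted scale).
#' @export
call_ct <- function(fluorescence, cycles = seq_along(fluorescence),
                    threshold = NULL, n_baseline_cycles = 5,
                    threshold_k = 10) {
  b <- estimate_baseline(fluorescence, n_baseline_cycles)
  fsub <- fluorescence - b
  if (is.null(threshold)) {
    sdb <- sd(fluorescence[seq_len(n_baseline_cycles)])
    rng <- max(fsub)
    threshold <- max(threshold_k * sdb, 0.02 * rng)
  }
  if (threshold <= 0 || max(fsub) < threshold) {
    return(list(ct = NA_real_, baseline = b, threshold = threshold))
  }
  above <- fsub >= threshold
  i <- which(above)[1]
  ct <- if (i == 1L) {
    cycles[1]
  } else {
    cycles[i - 1] + (threshold - fsub[i - 1]) / (fsub[i] - fsub[i - 1]) *
      (cycles[i] - cycles[i - 1])
  }
  list(ct = ct, baseline = b, threshold = threshold)
}

#' Window-of-linearity amplification-efficiency estimate
#'
#' Per-reaction efficiency in the LinRegPCR spirit: within the exponential
#' phase — baseline-subtracted fluorescence above a noise floor and below
#' a fixed fraction of the plateau — fit a straight line against cycle
#' over every window of 4 to 6 consecutive cycles, keep the window with
#' the highest R-squared (ties: earliest window, then widest), and report
#' `E = 10^slope`. The fitted response is the plateau-corrected
#' `log10(F / (plateau - F))` rather than plain `log10(F)`: for a
#' saturating amplification curve this quantity is exactly linear in
#' cycle with slope log10(E), so the estimate is not dragged down by
#' saturation even near the band's upper limit. A one-step correction
#' also removes the amplification that leaked into the early-cycle
#' baseline estimate. The noise floor is `floor_k` baseline standard
#' deviations with a relative floor of 0.1% of the plateau.
#'
#' @param fluorescence numeric vector per cycle.
#' @param cycles cycle numbers.
#' @param n_baseline_cycles cycles used for the baseline and its sd.
#' @param window_sizes consecutive-cycle window widths to try.
#' @param floor_k noise-floor multiplier on the baseline sd (default 3).
#' @param plateau_frac upper bound of the fitting band as a fraction of
#'   the plateau (default 0.5, i.e. below half-max).
#' @return list: `efficiency` (NA when no valid window exists), `window`
#'   (cycle indices used), `r_squared`.
#' @export
estimate_efficiency <- function(fluorescence,
                                cycles = seq_along(fluorescence),
                                n_baseline_cycles = 5, window_sizes = 4:6,
                                floor_k = 3, plateau_frac = 0.5) {
  b <- estimate_baseline(fluorescence, n_baseline_cycles)
  fsub <- fluorescence - b
  plateau <- max(fsub)
  if (plateau <= 0) {
    return(list(efficiency = NA_real_, window = integer(0),
                r_squared = NA_real_))
  }
  sdb <- sd(fluorescence[seq_len(n_baseline_cycles)])
  # the relative floor keeps the window clear of baseline-subtraction
  # error, which dominates the earliest above-zero cycles
  lower <- max(floor_k * sdb, 1e-3 * plateau)
  upper <- plateau_frac * plateau
  ok <- fsub > lower & fsub < upper
  # plateau-corrected response: for a saturating amplification curve,
  # log10(F / (plateau - F)) is linear in cycle with slope log10(E) at
  # every depth into the saturation, so the fit is unbiased even when the
  # window brushes against the upper band limit
  y_all <- rep(NA_real_, length(fsub))
  y_all[ok] <- log10(fsub[ok] / pmax(plateau - fsub[ok], 1e-9 * plateau))
  best <- list(r2 = -Inf, slope = NA_real_, win = integer(0))
  for (w in sort(window_sizes)) {
    for (s in seq_len(length(cycles) - w + 1L)) {
      idx <- s:(s + w - 1L)
      if (!all(ok[idx])) next
      x <- cycles[idx]
      y <- y_all[idx]
      fit <- stats::lm.fit(cbind(1, x), y)
      slope <- fit$coefficients[2]
      ssr <- sum(fit$residuals^2)
      sst <- sum((y - mean(y))^2)
      r2 <- if (sst > 0) 1 - ssr / sst else 1
      better <- r2 > best$r2 + 1e-12 ||
        (abs(r2 - best$r2) <= 1e-12 && length(best$win) &&
           (s < best$win[1] || (s == best$win[1] && w > length(best$win))))
      if (better) best <- list(r2 = r2, slope = slope, win = idx)
    }
  }
  if (!length(best$win) || !is.finite(best$slope)) {
    return(list(efficiency = NA_real_, window = integer(0),
                r_squared = NA_real_))
  }
  # one-step baseline decontamination: the early-cycle mean baseline
  # includes whatever amplification was already present, which tilts the
  # fit slightly upward; predict that leak-in from the fitted line and
  # refit with the corrected baseline
  idx <- best$win
  fit0 <- stats::lm.fit(cbind(1, cycles[idx]), y_all[idx])
  yhat_base <- fit0$coefficients[1] +
    fit0$coefficients[2] * cycles[seq_len(n_baseline_cycles)]
  eps_hat <- mean(plateau * 10^yhat_base / (1 + 10^yhat_base))
  if (is.finite(eps_hat) && eps_hat > 0 && eps_hat < 0.05 * plateau) {
    fsub2 <- fsub[idx] + eps_hat
    y2 <- log10(fsub2 / pmax(plateau + eps_hat - fsub2, 1e-9 * plateau))
    fit2 <- stats::lm.fit(cbind(1, cycles[idx]), y2)
    if (is.finite(fit2$coefficients[2])) best$slope <- fit2$coefficients[2]
  }
  # efficiencies are reported at 1e-4 resolution: far below estimator
  # noise, and it makes strict-threshold comparisons (E > 1.75) behave
  # like comparisons between printed values rather than raw floats
  list(efficiency = round(unname(10^best$slope), 4), window = best$win,
       r_squared = best$r2)
}

#' Process a long-format qPCR plate into per-reaction calls
#'
#' Joins the plate map to the cycle-by-fluorescence table and computes,
#' per well: baseline, Ct and window-of-linearity efficiency. Unless an
#' explicit `threshold` is given, a single plate-wide threshold is used —
#' `threshold_k` times the median baseline standard deviation across
#' wells, floored at 2% of the median plateau — mirroring how instrument
#' software sets one threshold per plate; Ct differences between wells are
#' then not distorted by per-well threshold variability.
#'
#' @param plate data.frame `well, cycle, fluorescence` (long format).
#' @param map plate-map data.frame with at least `well`, `site`, `allele`,
#'   `treatment`, `timepoint`; `bio_rep` defaults to 1.
#' @param threshold optional fixed threshold (baseline-subtracted scale);
#'   overrides the plate-wide rule.
#' @param n_baseline_cycles see [estimate_baseline()].
#' @param threshold_k multiplier for the plate-wide threshold rule.
#' @return data.frame of class `qpcr_reactions`: map columns plus
#'   `baseline`, `ct`, `efficiency`; the threshold used is attached as
#'   attribute `threshold`.
#' @export
process_plate <- function(plate, map, threshold = NULL,
                          n_baseline_cycles = 5, threshold_k = 10) {
  need <- c("well", "site", "allele", "treatment", "timepoint")
  if (!all(need %in% names(map))) {
    stop("plate map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(map$bio_rep)) map$bio_rep <- 1L
  wells <- lapply(seq_len(nrow(map)), function(i) {
    wdf <- plate[plate$well == map$well[i], , drop = FALSE]
    if (nrow(wdf) < 15L) {
      stop(sprintf("well %s has %d cycles; need at least 15", map$well[i],
                   nrow(wdf)), call. = FALSE)
    }
    wdf[order(wdf$cycle), , drop = FALSE]
  })
  if (is.null(threshold)) {
    sdb <- vapply(wells, function(w) {
      sd(w$fluorescence[seq_len(n_baseline_cycles)])
    }, numeric(1))
    plateau <- vapply(wells, function(w) {
      max(w$fluorescence) - estimate_baseline(w$fluorescence,
                                              n_baseline_cycles)
    }, numeric(1))
    threshold <- max(threshold_k * median(sdb), 0.02 * median(plateau))
  }
  out <- map
  out$baseline <- NA_real_
  out$ct <- NA_real_
  out$efficiency <- NA_real_
  for (i in seq_len(nrow(map))) {
    wdf <- wells[[i]]
    cc <- call_ct(wdf$fluorescence, wdf$cycle, threshold = threshold,
                  n_baseline_cycles = n_baseline_cycles)
    ee <- estimate_efficiency(wdf$fluorescence, wdf$cycle,
                              n_baseline_cycles = n_baseline_cycles)
    out$baseline[i] <- cc$baseline
    out$ct[i] <- cc$ct
    out$efficiency[i] <- ee$efficiency
  }
  class(out) <- c("qpcr_reactions", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' Keep reactions whose amplification efficiency exceeds a minimum
#'
#' Strict inequality: a reaction at exactly the minimum is removed, and so
#' is any reaction whose efficiency could not be estimated or whose Ct was
#' not called. The count of removed reactions is logged and a per
#' primer-set (site x allele) mean-efficiency summary is attached as
#' attribute `primer_efficiency`.
#'
#' @param reactions a `qpcr_reactions` data.frame.
#' @param min_eff minimum efficiency (default 1.75).
#' @return the retained rows, with attribute `primer_efficiency`.
#' @export
filter_reactions <- function(reactions, min_eff = 1.75) {
  keep <- !is.na(reactions$efficiency) & reactions$efficiency > min_eff &
    !is.na(reactions$ct)
  removed <- sum(!keep)
  if (removed > 0) {
    message(sprintf(
      "filter_reactions: removed %d/%d reaction(s) (efficiency <= %.2f, uncalled Ct, or no estimate)",
      removed, nrow(reactions), min_eff))
  }
  out <- reactions[keep, , drop = FALSE]
  prim <- if (nrow(reactions)) {
    stats::aggregate(efficiency ~ site + allele, data = reactions,
                     FUN = function(x) mean(x, na.rm = TRUE), na.action = NULL)
  } else NULL
  attr(out, "primer_efficiency") <- prim
  attr(out, "n_removed") <- removed
  out
}

#' Edited fraction from allele-specific Ct values
#'
#' The two allele-specific reactions quantify the edited (T) and unedited
#' (C) template pools of one sample. Back-calculating relative quantities
#' `Q_T = eff_T^(-ct_T)` and `Q_C = eff_C^(-ct_C)` and taking
#' `Q_T / (Q_T + Q_C)` gives a self-normalizing edited fraction bounded in
#' \[0,1\]; with both efficiencies at 2 it reduces to
#' `1 / (1 + 2^(ct_T - ct_C))`, the two-amplicon form of the
#' delta-delta-Ct rule.
#'
#' @param ct_T,ct_C called Ct values (vectors recycled together).
#' @param eff_T,eff_C amplification efficiencies (default 2).
#' @return numeric edited fraction, NA where either Ct is uncalled.
#' @examples
#' editing_fraction_from_ct(20, 20)            # 0.5
#' editing_fraction_from_ct(20, 20 + log2(10)) # 10/11
#' @export
editing_fraction_from_ct <- function(ct_T, ct_C, eff_T = 2, eff_C = 2) {
  q_t <- eff_T^(-ct_T)
  q_c <- eff_C^(-ct_C)
  out <- q_t / (q_t + q_c)
  out[is.na(ct_T) | is.na(ct_C)] <- NA_real_
  out
}

#' Aggregate technical replicates and compute per-sample edited fractions
#'
#' Technical replicates of each (site, sample, allele) reaction group are
#' aggregated by mean Ct after efficiency filtering; groups losing all
#' their replicates are flagged unusable (NA fraction). The edited
#' fraction is then computed per biological sample from the paired T/C
#' mean Cts.
#'
#' @param reactions filtered `qpcr_reactions` (see [filter_reactions()]).
#' @param eff_T,eff_C efficiencies used in the fraction computation
#'   (default 2, the delta-delta-Ct convention).
#' @return data.frame: `site`, `treatment`, `timepoint`, `bio_rep`,
#'   `ct_T`, `ct_C`, `n_tech_T`, `n_tech_C`, `fraction`.
#' @export
sample_editing_fractions <- function(reactions, eff_T = 2, eff_C = 2) {
  if (!nrow(reactions)) {
    return(data.frame(site = character(0), treatment = character(0),
                      timepoint = character(0), bio_rep = integer(0),
                      ct_T = numeric(0), ct_C = numeric(0),
                      n_tech_T = integer(0), n_tech_C = integer(0),
                      fraction = numeric(0)))
  }
  key <- interaction(reactions$site, reactions$treatment,
                     reactions$timepoint, reactions$bio_rep, drop = TRUE)
  groups <- split(reactions, key)
  rows <- lapply(groups, function(g) {
    ctT <- g$ct[g$allele == "T"]
    ctC <- g$ct[g$allele == "C"]
    data.frame(site = g$site[1], treatment = g$treatment[1],
               timepoint = g$timepoint[1], bio_rep = g$bio_rep[1],
               ct_T = if (length(ctT)) mean(ctT) else NA_real_,
               ct_C = if (length(ctC)) mean(ctC) else NA_real_,
               n_tech_T = length(ctT), n_tech_C = length(ctC),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fraction <- editing_fraction_from_ct(out$ct_T, out$ct_C, eff_T, eff_C)
  out[order(out$site, out$treatment, out$timepoint, out$bio_rep), ]
}

#' Compare editing fractions between treatments
#'
#' Per (site, timepoint): group means as percentages and a two-sided
#' pooled-variance t-test across biological replicates, significant at
#' p < 0.05. Groups with fewer than two defined fractions are flagged
#' degenerate.
#'
#' @param fractions output of [sample_editing_fractions()].
#' @param groups treatment labels to compare (default control vs salt).
#' @param alpha significance level (default 0.05).
#' @return data.frame: `site`, `timepoint`, `mean_<group>` (percent),
#'   `p_value`, `significant`, `flag`.
#' @export
compare_treatment <- function(fractions, groups = c("control", "salt"),
                              alpha = 0.05) {
  key <- interaction(fractions$site, fractions$timepoint, drop = TRUE)
  rows <- lapply(split(fractions, key), function(d) {
    x <- d$fraction[d$treatment == groups[1]]
    y <- d$fraction[d$treatment == groups[2]]
    t <- pooled_t_test(x, y)
    out <- data.frame(site = d$site[1], timepoint = d$timepoint[1],
                      p_value = t$p_value,
                      significant = !is.na(t$p_value) & t$p_value < alpha,
                      flag = t$flag, stringsAsFactors = FALSE)
    out[[paste0("mean_", groups[1])]] <- 100 * t$mean_x
    out[[paste0("mean_", groups[2])]] <- 100 * t$mean_y
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$site, out$timepoint),
      c("site", "timepoint", paste0("mean_", groups), "p_value",
        "significant", "flag")]
}

#' Full qPCR analysis from plate + map CSVs
#'
#' Reads the long-format plate and plate map, calls Ct and efficiency per
#' well, applies the strict efficiency filter, aggregates technical
#' replicates, computes per-sample edited fractions and the treatment
#' comparison.
#'
#' @param plate_csv,map_csv input CSV paths (or data.frames).
#' @param min_eff efficiency filter minimum (default 1.75).
#' @param eff_T,eff_C efficiencies for the fraction computation.
#' @param threshold optional fixed Ct threshold.
#' @param alpha significance level.
#' @return list: `reactions` (all wells), `retained`, `fractions`,
#'   `comparison`, `primer_efficiency`.
#' @export
analyze_qpcr <- function(plate_csv, map_csv, min_eff = 1.75, eff_T = 2,
                         eff_C = 2, threshold = NULL, alpha = 0.05) {
  plate <- if (is.character(plate_csv)) read.csv(plate_csv) else plate_csv
  map <- if (is.character(map_csv)) read.csv(map_csv) else map_csv
  reactions <- process_plate(plate, map, threshold = threshold)
  retained <- filter_reactions(reactions, min_eff = min_eff)
  fractions <- sample_editing_fractions(retained, eff_T, eff_C)
  comparison <- compare_treatment(fractions, alpha = alpha)
  list(reactions = reactions, retained = retained, fractions = fractions,
       comparison = comparison,
       primer_efficiency = attr(retained, "primer_efficiency"))
}

#' Design allele-specific primers for an editing site
#'
#' Builds the three-primer set used for allele-specific editing qPCR: two
#' allele-specific primers identical except for the discriminating base (C
#' or T read over the editing site) plus one universal primer on the
#' opposite strand. With `discriminant = "3prime"` (default, the standard
#' allele-specific design) the specific primers end on the site;
#' `"5prime"` places the site at the first base instead. `orientation`
#' flips which side is allele-specific: forward specific primers pair with
#' a reverse universal primer and vice versa.
#'
#' @param cds_sequence CDS sequence (character).
#' @param cds_position 1-based site position within the CDS.
#' @param primer_length primer length (default 20).
#' @param discriminant `"3prime"` or `"5prime"`.
#' @param orientation `"forward"` (specific primers on the sense strand)
#'   or `"reverse"`.
#' @param universal_gap distance (nt) between the site and the universal
#'   primer's near end (default 20).
#' @return list: `c_primer`, `t_primer` (differing at exactly one base),
#'   `universal`, `discriminant_position` (1-based within the specific
#'   primers).
#' @export
design_allele_primers <- function(cds_sequence, cds_position,
                                  primer_length = 20,
                                  discriminant = c("3prime", "5prime"),
                                  orientation = c("forward", "reverse"),
                                  universal_gap = 20) {
  discriminant <- match.arg(discriminant)
  orientation <- match.arg(orientation)
  n <- nchar(cds_sequence)
  p <- cds_position
  if (p < 1 || p > n) stop("site outside the CDS", call. = FALSE)
  sense_specific <- (orientation == "forward")
  if (sense_specific) {
    if (discriminant == "3prime") {
      s <- p - primer_length + 1L
      if (s < 1L) stop("insufficient 5' flank for the specific primers",
                       call. = FALSE)
      spec <- substr(cds_sequence, s, p)
      disc_pos <- primer_length
    } else {
      if (p + primer_length - 1L > n) {
        stop("insufficient 3' flank for the specific primers", call. = FALSE)
      }
      spec <- substr(cds_sequence, p, p + primer_length - 1L)
      disc_pos <- 1L
    }
    u_start <- p + universal_gap
    if (u_start + primer_length - 1L > n) {
      stop("insufficient flank for the universal primer", call. = FALSE)
    }
    universal <- revcomp(substr(cds_sequence, u_start,
                                u_start + primer_length - 1L))
  } else {
    # specific primers on the antisense strand; universal is forward
    if (discriminant == "3prime") {
      e <- p + primer_length - 1L
      if (e > n) stop("insufficient 3' flank for the specific primers",
                      call. = FALSE)
      spec <- revcomp(substr(cds_sequence, p, e))
      disc_pos <- primer_length
    } else {
      s <- p - primer_length + 1L
      if (s < 1L) stop("insufficient 5' flank for the specific primers",
                       call. = FALSE)
      spec <- revcomp(substr(cds_sequence, s, p))
      disc_pos <- 1L
    }
    u_end <- p - universal_gap
    if (u_end - primer_length + 1L < 1L) {
      stop("insufficient flank for the universal primer", call. = FALSE)
    }
    universal <- substr(cds_sequence, u_end - primer_length + 1L, u_end)
  }
  set_base <- function(primer, pos, base) {
    substr(primer, pos, pos) <- base
    primer
  }
  # on the antisense strand the site base reads G (unedited) / A (edited)
  bases <- if (sense_specific) c("C", "T") else c("G", "A")
  list(c_primer = set_base(spec, disc_pos, bases[1]),
       t_primer = set_base(spec, disc_pos, bases[2]),
       universal = universal, discriminant_position = disc_pos)
}
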