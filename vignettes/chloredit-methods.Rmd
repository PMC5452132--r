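---
title: "Quantifying chloroplast C-to-U editing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chloroplast C-to-U editing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chloredit)
```

## The problem

Plastid transcripts undergo C-to-U RNA editing: specific genomically
encoded cytidines are deaminated to uridine, usually restoring conserved
codons. In sequencing data the edited base reads as T, so the editing
level of a site is an allele fraction: the proportion of reads carrying T
among reads carrying C or T at that position. Small RNA libraries are an
indirect but convenient readout — many plastid small RNAs are footprints
of RNA-binding proteins (notably PPR editing factors) and pile up over
editing sites. chloredit implements the computational side of a study
design that (i) quantifies per-site editing from small RNA libraries
under two conditions (control vs salt stress), (ii) checks that plastid
gene expression itself is unchanged, and (iii) confirms selected sites by
allele-specific RT-qPCR.

Everything runs end to end on synthetic data with known ground truth, so
each stage is testable without any external download.

## Subtractive alignment

Reads are assigned to the chloroplast by a three-round scheme:

1. **cp_m0** — exact (0-mismatch) forward-strand matches to the
   chloroplast genome, its CDSs, or its tRNAs;
2. **subtracted** — of the remainder, exact matches to the nuclear or
   mitochondrial genome are discarded;
3. **cp_m2** — what is left is matched to the chloroplast genome and
   CDSs with up to 2 mismatches.

Aligning to the chloroplast *first* gives plastid loci priority over
identical nuclear/mitochondrial copies; the relaxed third round exists
precisely because edited reads differ from the plastid reference at the
edited base and would otherwise be lost. The matcher is an ungapped
end-to-end Hamming scan (classic `-v`-style semantics): no indels, no
quality weighting, `N` counts as a mismatch, and reverse-complement
placements are never considered because the libraries are sense-strand.
All best-stratum placements are reported by default; a `"first"` mode
(leftmost placement on the lexicographically smallest target) is
available when strict single-placement determinism matters. Reads
shorter than 15 nt are dropped with a logged count. tRNAs are excluded
from round 3 (the relaxed round is described for genome and CDSs only);
this is a faithful reading rather than an inference, and is configurable
only by editing the round-3 target set.

Internally all coordinates are 0-based half-open; SAM output follows the
1-based convention with an `NM` mismatch tag; site tables are 1-based
within the CDS.

## Editing quantification and testing

For each (site, library) pair the pileup counts `n_edited` (T),
`n_unedited` (C) and `n_other` (A/G/N). A multi-mapping read contributes
once per CDS (first placement) so a molecule is never double-counted.
The editing fraction is `n_edited / (n_edited + n_unedited)` — bases
other than C/T are excluded because editing is a two-state quantity —
and is undefined ("nd") at zero denominator.

Detection replaces an opaque "approximate variant p-value" with an exact
one-sided binomial test: the probability of at least `n_edited` T reads
in `coverage` trials at a per-base error rate (default 0.01). A site is
detected in a library when coverage ≥ 5 and p ≤ 1e-2, and *selected*
overall when its coverage summed across libraries is ≥ 4 and it is
detected somewhere. The summed-coverage reading of the selection rule is
a choice: the source convention is ambiguous, so the report prints both
the edited count and total coverage per library rather than a single
ambiguous count column.

Condition comparison is a two-sided pooled-variance t-test on the
defined per-library fractions. Degenerate designs are handled by
convention and always flagged: a group with fewer than two defined
values still yields a p-value while one degree of freedom remains; zero
pooled variance gives p = 1 for equal means and p = 0 otherwise; a
condition with no defined fraction is incomparable. No multiple-testing
correction is applied across sites in this table (raw p-values are
reported, matching the original analysis style); `bh_adjust()` exists
for users who want it.

## Expression screen

The negative control of the study design: plastid gene expression should
not differ between conditions. Counts (one per read, first placement)
are normalized by median-of-ratios size factors — for genes positive in
every library, the median of count-to-geometric-mean ratios — and each
gene is tested by a pooled t-test on `log2(normalized + 1)` with
Benjamini–Hochberg adjustment. A negative-binomial GLM with dispersion
shrinkage is deliberately out of scope: the target result is a null, and
the simple test controls its type-I rate on null simulations (verified
in the acceptance suite at 200 genes × 50 replicates). The normalization
formula is the re-implemented, oracle-tested core (it matches DESeq2's
`estimateSizeFactorsForMatrix` exactly on mixed-zero matrices).

## qPCR model and analysis

Each editing site is measured by two allele-specific reactions per
sample — primers ending (by default) on the discriminating base, C for
unedited, T for edited — plus a shared universal primer. The simulator
and the analysis share one curve model:

F(c) = b + Fmax · N0·E^c / (N0·E^c + K)

a baseline plus saturating exponential with per-cycle efficiency E,
starting template N0 and half-saturation K. The edited and unedited
wells of one sample receive template f·N and (1−f)·N, where f is the
planted editing fraction.

Analysis steps, each an automated stand-in for a manual instrument step:

* **Baseline**: mean of the first 5 cycles. Amplification already
  present in those cycles biases the baseline slightly; the default
  simulated N0 keeps this below the noise floor.
* **Threshold / Ct**: one plate-wide threshold (10× the median baseline
  standard deviation, floored at 2% of the median plateau), crossed by
  linear interpolation. A per-plate threshold, as instrument software
  uses, keeps between-well Ct differences free of threshold variability;
  `call_ct()` on a single curve uses the same rule per curve, with the
  2% floor making zero-noise curves callable.
* **Efficiency**: window-of-linearity — the best (max R²) straight-line
  fit over 4–6 consecutive cycles within the exponential band (3
  baseline standard deviations, floored at 0.1% of the plateau, up to
  half-max). Two numerical refinements keep the estimator unbiased where
  a naive log10(F) fit is not: the fitted response is the
  plateau-corrected `log10(F / (plateau − F))`, which for the saturating
  curve model is *exactly* linear in cycle with slope log10(E), and a
  one-step correction removes the amplification that leaked into the
  early-cycle baseline mean. Noise-free accuracy is then ~1e-5 across
  E ∈ [1.6, 2.0] and template amounts; at 0.5%-of-plateau noise the
  estimate is unbiased with sd ≈ 0.06, so essentially no true-E = 2
  reaction is lost to the 1.75 filter. Estimates are reported at 1e-4
  resolution so strict-threshold comparisons behave like comparisons of
  printed values.
* **Filter**: reactions are kept only if estimated efficiency is
  strictly greater than 1.75 (uncalled Ct or unavailable efficiency also
  removes a reaction); a per-primer-set mean-efficiency summary is
  reported.
* **Fraction**: technical replicates are aggregated by mean Ct after
  filtering, then
  `fraction = eff_T^(−ct_T) / (eff_T^(−ct_T) + eff_C^(−ct_C))`,
  which with both efficiencies at 2 is `1/(1 + 2^(ct_T − ct_C))` — the
  two-amplicon form of the delta-delta-Ct rule. This mapping from Ct
  differences to a bounded edited fraction is a design choice (the
  source method names only "2^-ΔΔCt"); it is self-normalizing and
  reduces to the textbook rule. The default efficiencies in the fraction
  formula are 2 (estimated efficiencies gate the filter only), because
  plugging biased per-well estimates into the exponent distorts
  fractions far more than the bias it would correct.
* **Comparison**: pooled t-test across biological replicates per (site,
  timepoint), means reported as percentages, significance at p < 0.05.

The allele-specific primer designer defaults to 3'-terminal
discrimination (the standard design); a 5'-first-base mode is selectable
since the source description reads that way, with orientation
(forward-specific/reverse-universal or the reverse) invertible.

## The synthetic world

The generator states one fixed world rather than exposing tuning dials:

* four libraries — Cnt-1, Cnt-2, Salt-1, Salt-2 (two conditions × two
  libraries);
* small RNA reads of 18–24 nt (mRNA-fragment mode would use ~50–100 nt),
  drawn from the sense strand of CDSs and tRNAs — antisense transcription
  is not modeled, consistent with the forward-strand-only alignment;
* per-base error rate 0.005 by default (library depth and error rate are
  not stated by the source study; these are conventional small-RNA-seq
  values and are configurable, not inferred);
* 30% of reads from nuclear/mitochondrial decoys to exercise
  subtraction; decoy genomes are random sequence, optionally sharing
  planted k-mers with the chloroplast;
* planted editing fractions of 0.6 (control) vs 0.8 (salt) at
  differential sites and 0.7 at null sites — a 0.2 effect on the scale
  the study reports;
* sites are planted at least 25 nt from CDS ends (terminal bases are
  covered by essentially no 18–24 nt read, so sites there would be
  unquantifiable by construction) and ≥30 nt apart, so one read covers
  at most one site;
* qPCR plates with technical quadruplicates, efficiency 2, Gaussian
  fluorescence noise of 0.5% of the plateau, constant FASTQ qualities
  (quality is unused downstream).

A truth table per library records each read's origin, its final base at
every covered site, and its total mismatch count against its reference
of origin — enough to predict, exactly, which filter round must capture
it and what every pileup must contain on error-free data.

What the generator does *not* emulate — and hence what a green test does
not establish: realistic plastid gene content and order, RNA secondary
structure, sequence-dependent error profiles, quality scores, coverage
biases of real protein footprints, primer-dimer and melting-curve
artifacts, and between-biological-replicate variance beyond binomial
sampling. Conclusions about the method's behaviour on real libraries
rest on the model assumptions above, not on these tests.

## Numerical choices and conventions

* Config files are JSON (not YAML): it keeps the dependency footprint to
  jsonlite, which the manifest writer needs anyway.
* Degenerate t-tests: see above; all flagged, never silent.
* Zero-coverage sites propagate as "nd", never as 0.
* The variant test's p-value is exact (`pbinom` upper tail), verified to
  1e-12 against direct pmf enumeration up to coverage 1000.
* Statistical significance of the 20-seed end-to-end suite: a 5%-level
  test is *expected* to flag 5% of null sites, so the null-site check
  requires the observed rate to be statistically compatible with 5%
  (one-sided exact binomial test at α = 0.01) rather than naively below
  it.
* Determinism: every stochastic step is seeded through a single master
  seed (stage seeds are fixed small offsets); two runs of `run_all()`
  with one config are byte-identical, and the run manifest echoes the
  effective configuration (minus the output path) for audit.

## Known limitations

* The matcher is a linear scan in compiled code — ample for organelle
  scale (tens of kb × 10^5 reads), not for nuclear genomes.
* Efficiency estimation assumes the saturating-exponential curve shape
  when correcting for the plateau; curves with drift, hooks or
  primer-dimer artifacts (not simulated) would not be fitted this well.
* With two libraries per condition, the per-site t-test has two degrees
  of freedom; single-site significance at moderate coverage is noisy,
  which is why the end-to-end claims are made over a 20-seed suite
  rather than per run.
* The expression screen is a calibrated null detector, not a powered DE
  method; planted 8-fold changes are found, subtle ones are not sought.
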