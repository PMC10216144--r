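---
title: "Methods: cardiolipin annotation and profiling in clmsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiolipin annotation and profiling in clmsi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clmsi)
```

This vignette is the package's account of its own methods: the chemical
model, the synthetic-data generator and what it does and does not emulate,
the annotation chain, the statistics, and the numerical and design choices
that were genuinely open. It states no empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## 1. The chemical model

**Sum compositions.** A cardiolipin CL(X:Y) is described only by its total
acyl carbons X and total C=C double bonds Y over the four chains; chain-level
(sn-positional) isomers are out of scope. The neutral formula follows from
the backbone (three glycerols, two phosphates, four ester bonds):

* CL(X:Y): `C(X+9) H(2X−2Y+14) O17 P2`
* MLCL(X:Y): `C(X+9) H(2X−2Y+16) O16 P2` — CL minus one fatty acyl residue
  (FA − H2O), i.e. ester hydrolysis.

Published identification tables occasionally print MLCL formulas that
disagree with their own printed exact masses by two hydrogens; the
ester-hydrolysis rule is implemented because it is the chemically derivable
one and its masses match the printed exact m/z values. The same two-hydrogen
pattern can affect individual CL attributions; `clmsi` always computes the
formula from (X, Y) and reports disagreements rather than patching them.

**Exact masses and ions.** Monoisotopic atomic masses: C = 12 exactly,
H = 1.00782503207, O = 15.9949146196, P = 30.97376163 Da. The ions of
interest are doubly deprotonated: m/z = (M − 2·1.00727646688)/2, using the
proton mass (hydrogen minus electron). Fragment carboxylate anions
`[CaH(2a−2b−1)O2]⁻` include one electron mass. Internally m/z is carried at
full double precision; `round_printed()` reproduces table-style printing by
staged rounding (5 → 4 → 3 decimals, half away from zero), which matters at
boundary values such as 713.49449 printing as 713.495.

**Isotope envelopes.** Element-wise convolution of natural isotope
distributions, aggregated at nominal-mass resolution (the abundance-weighted
mean mass per isotopologue). Fine structure within one isotopologue is
unresolvable at resolving power 70,000, so this aggregation is exact for the
package's purposes. For a doubly charged ion the envelope spacing is
approximately 1.0033548/2 ≈ 0.502 m/z — the "0.5-spaced" signature used to
recognize CL charge state.

**Double-bond localization.** In the hybrid CID/UVPD scheme, photo-induced
cleavage of the two C–C bonds flanking a C=C of a fatty-acid carboxylate
anion yields an ion pair separated by exactly 24 Da. The terminal-atom
bookkeeping (hydrogen transfer) is a convention; `clmsi` centralizes it in
`diagnostic_pair_mz()` (low fragment = `[C(n−1)H(2n−3)O2]⁻` for Δn, partner
= +24 Da) so that every downstream quantity — in particular the Δ9/Δ11
ratio, which only sums intensities at these m/z — is independent of the
convention. The Δ9 and Δ11 pairs for FA 18:1 are disjoint and offset by
C2H4 = 28.0313 Da, which is what the ratio statistic requires.

## 2. The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which the annotation chain and statistics are validated.

**Panels.** Normal grey matter carries 46 CL species in six carbon-number
clusters (X = 68, 70, …, 78) plus 12 MLCL species (X = 52–58). Within a
cluster, abundances follow a discretized Gaussian over Y (sd 2 double
bonds), unimodal with the mode at the cluster centre; across clusters a
Gaussian over X (sd 4 carbons) centred at X = 74 makes CL(74:8) the modal
species. Glioblastoma drops the X ≥ 76 clusters entirely (CL(76:10) and
CL(78:12) absent), shifts its modal cluster to CL(72:6), and is attenuated
to 35% of the normal amplitude. Astrocytoma grades 1–2 keep the normal panel
at 55% amplitude but deplete the long-chain clusters (below). White matter
carries no CL at all (ion suppression by myelin lipids); necrosis is the
glioblastoma profile at 20% of viable-tumor amplitude; infiltrating tumor is
a 50/50 mixture of the normal and glioblastoma profiles.

**Chain-ratio calibration.** Each class profile is calibrated so that the
noise-free expected ratio of measured peak heights
S/N(CL 78:12)/S/N(CL 72:8) equals the class target: 0.48 (normal), 0.05
(grade 1), 0.10 (grade 2); in glioblastoma CL(78:12) is absent, so the
expected ratio is 0 and the pipeline recovers a value at the noise floor.
Calibration is performed on the *apex height of the merged local profile*,
not on raw abundance: at resolving power 70,000 the M+2 isotopologue of
CL(X:Y+1) lies only 4.4 mm/z below the monoisotopic peak of CL(X:Y) and the
two merge, so a species' measured height includes its neighbour's envelope.
The abundance of CL(78:12) is solved by a short fixed-point iteration
against the analytic expected apex heights (`expected_chain_ratio()`
exposes the same computation, and a test asserts it equals the target).
For the astrocytoma grades the whole X ≥ 76 region is first scaled by
target/0.48; without that depletion the interference floor from CL(78:13)
alone would keep the measured ratio near 0.14, making targets of 0.05–0.10
unreachable — and a long-chain-depleted profile is also what the ratio is
meant to measure biologically.

**Rendering.** Each species contributes its first 4 isotopologues as
Gaussian peaks with FWHM = m/z / R (R = 70,000) on a log-spaced axis with 4
samples per FWHM. The default rendered window is m/z 560–800: it contains
every CL and MLCL species plus a guaranteed signal-free stretch
(m/z 630–688) used for noise estimation, and it emulates the fact that the
mobility filter transmits essentially only the doubly charged CL region.
The instrument acquisition range (m/z 100–1500) is kept as metadata.
Baseline noise is Gaussian (mean 0, sd 1 by default) — the simplest model
sufficient for S/N-threshold behaviour; the species amplitude scale
(default 20,000 per unit relative abundance) puts the weakest normal-cortex
panel species near S/N 100 and the strongest near S/N 1,100, comfortably
above the detection threshold, which is what the end-to-end detection-count
checks require of the study conditions.

**Cohorts.** Between-patient variability is an independent log-normal
multiplicative jitter on species abundances, CV 15% by default (a free
parameter: the source material reports no inter-patient variance), mean-one
so cohort means remain calibrated. A cohort run renders a small grid per
patient (default 4×4) and keeps only the per-patient S/N tables, bounding
memory. Everything is driven by one master seed: patient-level seeds are
drawn once, so output is bit-reproducible.

**What the generator does not emulate.** Real DESI-FAIMS spectra contain
chemical noise from co-transmitted lipids, pink (1/f) baseline structure,
pixel-to-pixel intensity drift, centroid mass-calibration error, and real
inter-patient correlation structure between species. Passing the package's
tests therefore certifies the annotation chain and statistics against the
stated model, not the biology of real tissue; detection counts on real data
depend on matrix effects the generator deliberately omits.

## 3. The annotation chain

1. **Noise**: 1.4826 × MAD of the profile intensities in configured
   signal-free windows (default m/z 630–688) — a robust baseline-sd
   estimator that a stray peak inflates by less than 2×.
2. **Peak picking**: local maxima above 3× noise, centroided by a 3-point
   parabola through the log intensities (exact for a Gaussian peak and valid
   on the non-uniform axis); if the vertex escapes the bracketing samples
   the apex sample is kept. The apex sample is reported as height.
3. **Charge**: a seed centroid is charge-z if a partner centroid sits at
   +1.0033548/z within 10 ppm (of the m/z). Spacings are tried smallest
   first (z = 3, 2, 1) so a doubly charged envelope is not mis-called singly
   charged from its M+2 peak, which sits at the z = 1 spacing.
4. **Matching**: centroids with charge 2 (or undetermined charge) are
   matched to the nearest species within 5 ppm; ties break CL before MLCL,
   then fewer double bonds. One annotation per species per spectrum (highest
   S/N wins). *Detected* requires S/N ≥ 3 **and** a confirmed charge-2
   signature; charge-undetermined matches are annotated but never detected,
   because the attribution leans on the 0.5-spacing signature.
5. **Dataset-level detection**: a species is called detected for a dataset
   when it passes the per-pixel criteria in ≥ 5% of pixels. True panel
   species pass in essentially every pixel; sporadic matches from noise
   peaks or isotopologue interference appear in ~1% of pixels, so the
   fraction cleanly separates the two. This is the package's detection rule
   and the one the end-to-end counts use.

Isotopologue interference has one further visible consequence: a merged
M+2-plus-monoisotopic peak pulls the centroid of an affected species by up
to ~3 ppm (still inside the 5-ppm gate). Species whose higher-unsaturation
neighbour is absent from the panel land within 1 ppm, and the tests assert
both behaviours.

MS² chain assignment filters the combinatorial space of chain multisets
(from the configurable fatty-acyl pool: 14:0, 16:0, 16:1, 18:0, 18:1, 18:2,
18:3, 20:3, 20:4, 22:6, which covers the chains reported for brain CL) to
those whose every carboxylate anion matches a fragment centroid within
10 ppm, ranked by summed matched intensity. MS³ evidence is out of scope; a
provenance flag distinguishes tandem-MS-confirmed from accuracy-only
annotations in exported tables.

## 4. Statistics

* **Chain ratio**: per patient, S/N(CL 78:12)/S/N(CL 72:8) from the
  per-patient median-S/N matrix; class summaries are means over patients,
  with zero-denominator patients excluded and counted. Orientation note:
  the published description labels this "short/long" while reporting values
  that *fall* from 0.48 (normal) to 0.01 (glioblastoma) as long chains are
  depleted — only the long-chain-numerator orientation is consistent with
  both the values and the biology, so that is what is computed, and
  CL(72:8) (m/z 723.480) is used as the short species rather than the
  m/z-725 species named in one figure caption (725.494 is CL(72:6)).
* **PCA**: log10(S/N + 1) (the pseudocount makes zero S/N map to zero and is
  configurable), column-centred, no unit-variance scaling (the source
  analysis centres and log-transforms only), eigendecomposition of the
  covariance via `prcomp`. The contribution of species s to component c is
  100·loading²(s,c); loadings are unit vectors so contributions sum to 100
  per component.
* **Group comparisons**: Shapiro–Wilk at α = 0.05 per group; all groups
  normal → pairwise two-sample t-tests (paired on request), otherwise
  Wilcoxon rank-sum (signed-rank when paired); Holm step-down adjustment
  over all pairwise comparisons.
* **Richness**: species with S/N ≥ 3 per patient, with per-class medians.

Per-pixel S/N tables omit species without a matched centroid; the
profile-matrix builder treats them as S/N 0 (not missing) so medians are
always defined.

## 5. Problem sizes and determinism

The validation suite uses a 20×20-pixel section for the end-to-end
detection-count check and 25 patients × 16 pixels for each cohort-recovery
check, with smaller grids in unit tests; these sizes give Monte-Carlo
standard errors a few percent of the recovered ratios while keeping the
whole suite fast. All randomness flows from explicit seeds (`set.seed` at
generation entry points; cohort patient seeds drawn once from the master
seed), so every dataset, truth table, and statistic in the tests and in
`scripts/acceptance.R` is exactly reproducible.

## 6. Known limitations

* Continuous-mode imzML only (one shared m/z axis); processed-mode files are
  rejected loudly. Arrays are written as uncompressed 64-bit floats.
* No sn-positional isomers, oxidized/acylated CL variants, or positive-ion
  adducts; double-bond localization handles exactly one localized C=C per
  chain.
* The charge-state search considers z = 1–3 only.
* Isotopologue interference between Y-neighbours is modelled (and exploited
  in calibration) but not deconvolved during annotation; reported S/N of an
  interfered species includes its neighbour's M+2 contribution, as it would
  on the instrument at this resolving power.
* Glioblastoma's recovered chain ratio reflects the noise floor (CL(78:12)
  is absent there by construction), so its value is reported as ~0 rather
  than a calibrated small positive number.
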