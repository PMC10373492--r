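---
title: "Untargeted DNA adductomics by DIA neutral-loss screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untargeted DNA adductomics by DIA neutral-loss screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnadduct)
```

## The measurement problem

Genomic DNA accumulates covalent modifications — adducts of electrophilic
chemicals, oxidation marks such as 8-oxo-dG, methylation marks, deamination
products. After enzymatic hydrolysis to 2′-deoxyribonucleosides, every such
modification appears as a modified nucleoside whose protonated molecular ion
loses the 2′-deoxyribose moiety (C5H8O3, monoisotopic 116.0473 Da) on
fragmentation, leaving the protonated (modified) nucleobase. That constant
mass difference is a structure-independent signature: any MS1 precursor with
a co-eluting MS2 fragment exactly 116.0473 Da lighter is a candidate DNA
adduct, whether or not the chemistry is known. `dnadduct` implements this
untargeted screen for data-independent acquisition (DIA) LC-HRMS data,
together with the targeted confirmation, dG-normalised semi-quantification,
elemental-composition annotation, and the multivariate statistics used to
relate adductome profiles to environmental contamination.

## Acquisition model

A run is modelled as an RT-ordered list of centroided spectra. MS1 full
scans cover 110–650 m/z; DIA MS2 scans fragment everything inside fixed
10 m/z isolation windows. Two schemes mirror the dual-injection design:
a low-mass pass with 16 windows covering 195–355 m/z and a high-mass pass
with 26 windows covering 347–607 m/z. Windows are contiguous, half-open
`[lo, hi)` intervals; a boundary m/z belongs to the upper window. The
instrument listing of centers ("347 ± 5, 352 ± 5, …") would imply
overlapping windows, which contradicts the stated count of discrete
intervals; we implement the non-overlapping reading, and no overlapping
mode is provided. Retention time is carried in minutes throughout. mzML
reading and writing are delegated to Bioconductor's mzR; profile data can
be centroided by local maxima with intensity-weighted m/z.

## Peak detection

Extracted-ion chromatograms are the per-spectrum summed intensity of all
centroids within a ppm window of the target m/z; spectra with no matching
centroid contribute zeros (no interpolation). Detection then proceeds as a
matched-filter cascade with the screening defaults σ = 0.075 min
(Gaussian smoothing), zero-area filter widths 0.085 and 0.165 min, noise
window 8.0 min and minimum S/N 5:

1. smooth the trace with a Gaussian kernel;
2. require a positive response from *two* zero-area filters (negated
   second-derivative-of-Gaussian kernels whose coefficients sum to zero) —
   a cheap scale test that suppresses spikes narrower than a real peak and
   drifts broader than one;
3. estimate the local baseline (median) and noise (1.4826 × MAD) of the
   smoothed trace in a sliding 8-minute window that excludes the candidate
   peak region, and keep candidates with (apex − baseline)/noise ≥ 5;
4. integrate the raw trace by trapezoid over twice the core half-width on
   each side of the apex, where the core is bounded by the zero crossings
   of the narrow filter's response (≈ ±2σ for a Gaussian peak).

Two choices deserve comment. Baseline subtraction in step 3 is essential:
without it any chromatogram riding on a DC offset passes the S/N gate
everywhere. Doubling the core in step 4 is what makes integrated areas
accurate — the zero crossings themselves sit near ±2σ and clip 5–10% of a
Gaussian's area. Ties between candidate apexes closer than the wide filter
width resolve in favour of the higher apex. All widths are in minutes and
configurable; the original screening software names these parameters
without defining their semantics, so our definitions are declared
substitutes, not reconstructions.

## Neutral-loss screening and the master list

For every MS1 m/z trace (single-linkage grouping of centroids at the
matching tolerance, with a minimum trace length to skip one-off noise
centroids) the EIC is peak-detected; each detected precursor peak is paired
with an MS2 EIC at `precursor − 116.0473` extracted from the DIA window
containing the precursor. The mass tolerance (default 5 ppm) is referenced
to the *precursor* m/z, not to the 116 Da loss: at the 116-Da reference
several authentic adducts (e.g. a 529.2973/413.2512 pair, whose observed
loss deviates by 1.2 mDa) would fail the 5 ppm criterion that detected
them. The fragment must co-elute within 0.1 min of the precursor apex
(configurable; fragment confirmation uses the MS2 EIC peak apex rather
than single-spectrum matches, suppressing noise pairings). ESI adducts and
isotopologues are deliberately *not* removed — they are genuine screen
output. Per-sample hit lists merge into a master list by single-linkage
grouping at 5 ppm / 0.5 min; consensus m/z and RT are medians, and IDs are
assigned `L1…`/`H1…` by ascending m/z within the low/high acquisition
class.

## Confirmation, dG normalisation, repeatability

Each master entry is re-integrated in every sample: detected if an MS1
peak lies within 5 ppm and 0.2 min of the consensus coordinates ("a
comparable retention time" is not quantified in the field protocol; ±0.2
min is our default). Areas are expressed relative to unmodified
2′-deoxyguanosine, `area × 100 / area(dG)`, with dG's [M+H]⁺ m/z
(268.1040) computed from its formula rather than hard-coded; this cancels
DNA input, digestion losses and drift. Replicate repeatability is enforced
by the RSD filter: per adduct, 100 × sd/mean across the replicates of each
animal, aggregated as the maximum over animals (the most conservative
choice; the aggregation is configurable because the original protocol does
not state it), retaining adducts with RSD strictly below 20%.

## Elemental composition annotation

Candidate neutral CHNO compositions for each adduct satisfy protonated
m/z within 5 ppm, at least 9 C, 3 O and 2 N (the constraints used for
nucleoside adducts: every 2′-deoxyribonucleoside already contains C9O3N2),
non-negative integer rings-plus-double-bonds (`RDB = C − H/2 + N/2 + 1`)
for the even-electron protonated species, and element caps C ≤ 40, H ≤ 80,
N ≤ 12, O ≤ 20. Candidates rank by |Δppm|. Annotation is standardised on
neutral compositions plus a proton (1.0072765 Da); published tables that
mix neutral and ion conventions show up as half-integer RDB values. The
parity/RDB filter can be disabled to inspect every mass-compatible
composition.

## Statistics

The battery mirrors standard exposure-study practice:

* **Transformations.** Adducts: log of the dG-normalised areas (zeros →
  half the column minimum), then Pareto scaling (centre, divide by √sd) —
  after centring, the ×100 of the dG ratio and the log(dG) offset are
  immaterial. Contaminants: log then z-scores. Invariant columns drop.
* **Correlation screens.** Pearson r with two-tailed p from the t
  transform, adduct × contaminant and adduct × adduct. The low-/high-mass
  contrast of mean PAH correlations is a Welch t-test.
* **PERMANOVA / PERMDISP.** Implemented in-package on the Gower-centred
  Euclidean distance matrix with Type III (marginal) sums of squares under
  sum-to-zero contrasts, 999 free permutations of observations, p =
  (#{F\* ≥ F} + 1)/(n\_perm + 1); an exact-enumeration mode exists for
  small n. Euclidean distance is the default because Bray–Curtis is
  undefined on Pareto-scaled (negative) values; the distance is
  configurable. PERMDISP is vegan's `betadisper`/`permutest`. vegan's
  `adonis2` is used as an independent cross-check in the tests, not as the
  implementation, because its marginal mode does not report main effects
  in the presence of an interaction the way a Type III table does.
* **SIMPER** runs on the non-negative dG-normalised areas with the
  pairwise Bray–Curtis decomposition (contributions average over all
  between-group pairs and sum to 100%); the selected set is the smallest
  descending-contribution prefix reaching 80%.
* **OPLS-DA** is an orthogonal-signal-corrected PLS with one predictive
  component, written in-package (no OPLS implementation ships with the
  environment's packages; mixOmics' PLS is the cross-check for the
  0-orthogonal-component reduction). R²Y is the full-fit explained
  variance of the centred 0/1 response; Q² = 1 − PRESS/TSS from
  stratified 10-fold cross-validation; VIP on the predictive component is
  √K·|w| (so mean VIP² = 1). The orthogonal-component count defaults to 1
  and can be selected by Q² over 0–3.
* **ROC.** AUC from the empirical curve (equals the normalised
  Mann–Whitney U, ties counted half); 95% CI by stratified bootstrap
  (2000 resamples, seeded); misclassification at the Youden threshold.
  A feature panel is first combined into one score by logistic regression.
* **Volcano.** log2 of the contaminated/reference ratio of group means of
  dG-normalised areas, Welch t on log values, flags at |log2 FC| ≥ 2 and
  p ≤ 0.1 (a 10⁻⁹ tolerance keeps boundary fold changes on the flagged
  side). Welch is the default everywhere because between-site variance
  heterogeneity is expected. Raw p-values drive the flags, as in the
  screening tradition this follows; BH q-values are reported alongside.

## The synthetic-data generator

No public raw data accompany the field study this workflow is built
around, so the package carries two seeded generators that serve as ground
truth for every stage.

`simulate_run()` emulates the acquisition: one MS1 scan followed by a full
DIA window sweep per 1 s cycle; planted adducts elute as Gaussian peaks
(σ = 0.05 min, consistent with the ~0.2 min base widths of the 120 µL/min
microbore separations this emulates) whose trapezoid area equals the
requested abundance; each DIA scan carries the deoxyribose-loss fragment
of its window's precursors at a configurable fragmentation efficiency
(default 0.5); centroids get 1 ppm (1 sd) scan-to-scan mass jitter — the
mass precision of an Orbitrap at the 120k MS1 resolution emulated, and
small enough that a 5 ppm matching window essentially never loses a
centroid; baseline noise adds a Poisson number of exponential-intensity
centroids per scan. Identical seeds give identical runs and byte-identical
mzML files. Isotope envelopes are off by default (the screening tradition
does not deisotope); what the generator does *not* emulate — matrix
effects, tailing peaks, correlated noise, in-source fragmentation — bounds
what passing tests say about real data: they validate the algorithmic
contract, not instrument robustness.

`simulate_study()` emulates the study design: 10 contaminated and 9
reference stations across two basins, 2–3 individuals each (47 total by
default), 53 low-mass and 66 high-mass adducts with lognormal abundances,
a station-level variance component (intraclass fraction 0.5 by default),
per-sample dG areas so normalisation is exercised, and station-level
sediment contaminants (11 PAH congeners with LmPAH/HmPAH sums, 10 trace
metals, and a pollution-load index computed as the geometric mean of
metal contamination factors). Group effects are planted as *calibrated*
multiplicative shifts — contaminated samples of a listed adduct are
rescaled so the realized contaminated/reference group-mean ratio equals
2^effect exactly — because recovery tests need exact ground truth; with
sampled shifts a planted effect equal to the volcano threshold would sit
on the decision boundary. Adduct–contaminant correlations are planted
through a Gaussian copula on the log scale via the shared station
component; a target r is feasible only up to the station-level fraction
of adduct variance (√icc), and targeted contaminant columns skip the
contaminated-site concentration elevation that would otherwise attenuate
the requested correlation.

## Numerical and testing choices

Calibration suites (type-I error of PERMANOVA and of the volcano t-tests
in [0.03, 0.07] at α = 0.05) run on exchangeable null studies — no
station-level variance component — because free permutation is known to be
anticonservative under cluster correlation; that caveat applies equally to
any field design that permutes individuals while factors vary at station
level, and is a limitation of the method, not of the tests. The suites use
500 null repetitions for the PERMANOVA rate and pool the volcano tests
across adducts; OPLS-DA permutation nulls use 20 refits. Problem sizes
throughout the tests (16–48 samples, 20–40 adducts, 36-adduct spike-in
runs on a 20 min gradient) are chosen so the whole suite completes in a
couple of minutes while leaving every statistical check well-powered.

Other conventions: DIA window indices are 1-based in the R API; the RSD
threshold is strict ("below 20%"); masses use IUPAC most-abundant-isotope
values to ≥ 6 decimals; permutation, cross-validation, bootstrap and
simulation seeds are mandatory arguments, never hidden defaults.

## Known limitations

* Co-eluting isomers are not deconvolved; the higher apex wins within one
  filter width.
* Phosphodiester-backbone adducts, depurinated adducts and cross-links do
  not show the deoxyribose loss and are invisible to this screen.
* Semi-quantification assumes equal MS response across adducts; the dG
  ratio corrects losses and drift, not ionisation efficiency.
* The OPLS-DA Q² depends on fold assignment; stratification is by class,
  not by station, so station-level pseudo-replication can flatter Q² in
  clustered designs.

## A worked example

```{r example, eval = FALSE}
library(dnadduct)

scheme <- build_dia_scheme(347, 607, 10)         # high-mass DIA pass
panel <- planted_panel(
  precursor_mz = c(406.2178, 466.2640, 529.2973),
  rt = c(5, 8, 11), abundance = c(3000, 8000, 5000),
  fragmentation_efficiency = 0.5)
sim <- simulate_run(panel, scheme, seed = 1, gradient_length = 15)

hits <- screen_run(sim$run, scr = screen_params(scan_lo = 350,
                                                scan_hi = 600))
master <- build_master_list(hits)
confirmed <- integrate_targets(sim$run, master)
annotate_master(master)[1:3, ]
```
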