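---
title: "peakrescue: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{peakrescue: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science implemented in `peakrescue`: the
three-tier extraction model and its assumptions, every tunable parameter
with its unit and default, what the synthetic-data generator does and does
not emulate, the numerical choices made where the design was genuinely
open, and the package's known limitations. It states no empirical result
that the test suite does not itself compute.

## 1. The three-tier extraction model

LC-MS untargeted metabolomics quantifies compounds as *features*: unique
(m/z, retention time) signals traced through the MS1 scans of a run.
Conventional peak picking assumes a feature produces a well-formed,
roughly Gaussian chromatographic peak. That assumption fails for a
substantial fraction of real compounds — sharp early-eluting peaks,
fronting/tailing peaks, partially co-eluting shoulders — which are then
absent from downstream statistics even though the ions were plainly
present. `peakrescue` treats extraction as three complementary tiers with
strict precedence PP > MR > TL: a physical signal is reported by exactly
one tier.

### 1.1 PP: centWave-style peak picking

* **ROI tracing.** MS1 scans are walked in RT order; a centroid extends an
  open trace when it lies within `ppm` (default 10) of the trace's running
  intensity-weighted mean m/z. A trace survives up to `max_scan_gap`
  (default 2) consecutive scans without a match. Traces failing the
  prefilter (`prefilter_k` = 3 points at `prefilter_intensity` >= 100
  counts) or never exceeding the noise floor (`noise` = 100 counts) are
  discarded.
* **Peak detection.** Within each ROI, a Mexican-hat continuous wavelet
  transform over ~10 logarithmically spaced scales spanning
  `[peakwidth_min, peakwidth_max]` (defaults 5-20 s; use 10-60 s for
  HILIC separations) proposes candidate apexes (local maxima of the
  scale-maximal coefficient). A candidate is kept iff
  * its full width at half maximum, interpolated above the local
    baseline, lies within the peak-width bounds, and
  * S/N = (apex − baseline) / max(noise_sd, 1) >= `snthresh` (default 3),
    where baseline and noise_sd are the median and MAD of ROI intensities
    outside the peak, falling back to the configured noise floor when
    fewer than 4 flanking points exist.

  The width filter is applied to the FWHM, not to the base width at the
  baseline crossing: a Gaussian only reaches baseline around +/-3.5 sigma,
  so a base-width reading would reject legitimately wide peaks that the
  peak-width bounds are plainly meant to admit, while the FWHM of a
  Gaussian (2.355 sigma) is the quantity on the same scale as those
  bounds.
* **Integration and merging.** Peak boundaries descend from the apex until
  the trace falls into the baseline + noise band, hits a zero gap, or
  turns upward at a local minimum below 10% of the apex-above-baseline;
  the area is the trapezoidal integral over the boundary interval.
  Features closer than `mzdiff` (0.01 Th) with overlapping RT ranges are
  merged keeping the higher apex.

One numerical subtlety deserves its own paragraph because it controls the
package's headline behaviour. When an ROI is an isolated peak trace, the
only points flanking a candidate are the peak's *own* sub-noise tails. If
those tails are allowed to stand in for local noise, their tiny MAD makes
any emitted trace pass an S/N threshold, and the conventional tier becomes
unrealistically sensitive. `peakrescue` therefore descends to the edge of
detection when fewer than 4 genuine flanking points exist, and uses the
configured noise floor as the S/N denominator. At defaults this gives PP
an effective detection floor of apex >= baseline + 3 x 100 counts, which
is the intended behaviour of an S/N-3 filter against a 100-count noise
floor.

### 1.2 MR: rescue from DDA MS2 precursors

Every DDA MS2 scan certifies that its precursor ion was selected from a
real MS1 signal. The rescue tier turns that certificate into features:

1. **Deduplication.** All precursors are clustered greedily in descending
   precursor-intensity order; anything within `dedup_mz_tol` = 0.01 Th AND
   `dedup_rt_tol` = 30 s of a kept precursor is absorbed. Greedy-by-
   intensity makes the kept set deterministic and implements "only the
   most intense trigger survives" without committing to a cluster shape.
2. **Novelty.** Candidates within `confirm_mass_tol` = 0.01 Th and
   `confirm_rt_tol` = 60 s of a picked feature are dropped — PP owns that
   signal.
3. **Apex relocation.** DDA fires on peak flanks (by design: dynamic
   exclusion pushes triggers early). The candidate's RT/intensity are
   replaced by the maximum of its EIC within the confirmation window,
   ties broken toward the trigger RT.
4. **Validation.** The relocated candidate becomes a feature iff its apex
   exceeds `noise_fold` = 3 times the local noise and its EIC shows at
   least `min_consecutive_scans` = 4 consecutive MS1 scans with nonzero
   intensity in the stretch containing the apex. The feature spans that
   stretch; S/N is reported as apex/noise.

   The local noise is the median of nonzero EIC intensities outside the
   consecutive stretch, with the noise floor as fallback when fewer than
   4 such points exist (never below 1). This estimator is a declared
   choice: it is robust to the peak itself, scales with the chemical
   background, and degrades gracefully to the floor in clean windows.

Because relocation can move a candidate by up to `confirm_rt_tol`, the
novelty check is re-applied to the relocated feature, and features that
relocate onto the same apex are deduplicated keeping the stronger — both
are required for the tier-disjointness guarantee to hold on outputs, not
merely on inputs.

### 1.3 TL: targeted extraction

Targets (`name,mz,rt`, RT in seconds) not matched by an existing feature
within (`mass_tol` = 0.01 Th, `rt_tol` = 30 s) are searched directly: EIC,
apex, the same 3x-noise and 4-consecutive-scan validation as MR, and one
additional veto: a candidate whose apex lies within
`min_consecutive_scans` MS1 scans of an MR feature at the same m/z is
rejected (`mr_collision`) — the rescue tier already owns that signal. The
collision clause is deliberately read as a scan-distance test *restricted
to the same m/z window*; without the m/z restriction any rescued feature
anywhere in the spectrum would veto the target, which cannot be intended.
TL requires no MS2 scans and therefore also serves full-scan and DIA data,
where the MR tier is structurally unavailable.

## 2. Alignment, annotation, calibration

* **Grouping.** Features from all samples are binned into overlapping m/z
  slices of width `mzwid` = 0.015 Th advancing by `mzwid/2`; within a
  slice, maxima of a Gaussian RT kernel density (bandwidth `bw` = 5 s)
  define groups; a group is kept with members from at least
  `max(minsamp, ceiling(minfrac x n_samples))` samples (defaults 1 and
  0.5, applied over all samples — no sample-class concept); each sample
  contributes its nearest-RT feature. Duplicates from slice overlap are
  removed within (`mzwid/2`, `bw/2`).
* **Gap filling.** Missing (group, sample) cells are back-extracted as the
  maximum EIC intensity in `[mz_med +/- mass_tol] x [rt_med +/- bw]`, 0
  when empty, and flagged as filled. Retention-time correction is a
  declared non-goal: the generator injects no inter-sample RT drift by
  default, and the grouping bandwidth absorbs the small trigger-phase
  differences that remain.
* **Annotation.** Experimental MS2 spectra are scored against MSP library
  entries whose precursor lies within `precursor_tol` = 0.01 Th using the
  weighted dot product over greedily nearest-m/z-matched fragments
  (`fragment_tol` = 0.02 Th, each fragment used once, ties toward the
  higher intensity product): score = (sum w_a w_b)^2 / (sum w_a^2 x
  sum w_b^2) with w = intensity^0.5 x mz^0 by default. Square-root
  intensity weighting with no m/z weighting is the common metabolomics
  convention; both exponents are configuration-exposed precisely because
  conventions differ between libraries. Hits at score >=
  `score_threshold` = 0.7 are reported; library HMDB/KEGG/InChIKey-style
  identifiers are carried through as uninterpreted strings.
* **Calibration/LOD.** Per compound, ordinary least squares of detected
  apex intensity on concentration (unweighted: a declared choice — with
  the generator's proportional response the weighting question is moot,
  and unweighted OLS keeps the estimator transparent), then
  LOD = (3 x noise − intercept)/slope floored at 0, with the noise
  measured at the compound's (m/z, RT) in the lowest-concentration run
  where that tier-set detected it. For noise estimation at a *known*
  location the exclusion zone is the RT confirmation window around the
  target, not the consecutive-nonzero stretch: over a continuous chemical
  background the nonzero stretch is the whole chromatogram and would
  always force the floor fallback. `compare_lods()` reports lod_pp,
  lod_joint and their ratio per compound, with `NA` as the not-reached
  sentinel when a tier-set never produced 2 detectable points.

## 3. The synthetic-data generator

`synth_config()`/`generate_run()` emulate a centroided DDA run: MS1 scans
every `ms1_cycle` = 1 s across `rt_span` = 600 s; per scan, `baseline_n` =
60 chemical-background centroids at log-normal intensities (median
`baseline_mean` = 100 counts, sdlog 0.3) at uniform random m/z; injected
peaks with per-centroid Gaussian m/z jitter (sigma 2 ppm); after every MS1
scan up to `dda_top_n` = 3 MS2 scans on the most intense centroids above
`dda_trigger_threshold` = 200 counts not excluded in the last
`dda_exclusion_cycles` = 2 cycles. Fragments come from an assigned library
entry (5% multiplicative noise) or a reproducible pseudo-pattern.
Centroids below `detector_threshold` = 1 count are not recorded. One seed
produces one byte stream (64-bit float, uncompressed mzML); the compound
set derives from `seed` alone so replicates and dilution levels share
compounds while run-level noise varies with `run_seed`.

Stated-world choices, fixed at design time:

* **Shape classes.** `gaussian` peaks have sigma in [2.5, 5] s, i.e. FWHM
  ~5.9-11.8 s, inside the default width bounds. The distorted classes
  (`fronting`/`tailing`: narrow Gaussian core, sigma in [0.45, 0.65] s,
  with a one-sided exponential of tau in [0.2, 0.4] s; `shoulder`: two
  offset narrow Gaussians; `spike`: a 2-3-scan pulse) model the
  real-data population that conventional picking misses: their FWHM falls
  below the minimum peak width, yet they span >= 4 MS1 scans and stand
  far above the local noise — exactly the signature the rescue tier is
  built for. A spike, by contrast, fails both tiers and acts as a
  negative control.
* **Abundances.** Heights are log-uniform on [5e2, 2e5] counts
  (distorted: [4e3, 4e4]; deliberately sub-threshold peaks: [150, 280]).
  The lower edge sits near the detection floor on purpose: real dilution
  series lose roughly half their features at 10-fold dilution, which is
  only possible when the abundance population extends down to the limit
  of detection.
* **Dilution semantics.** A dilution factor scales injected peak heights
  *and* (by default, `scale_baseline = TRUE`) the chemical baseline and
  per-compound background ions, because diluting a sample dilutes its
  matrix. Instrument constants — the DDA trigger threshold and the
  detector floor — do not scale. This is what makes the LOD comparison
  directional: the tier-set that detects lower concentrations measures
  its noise in a cleaner run. With a strictly linear response and a
  dilution-independent noise, both tier-sets would fit the same line and
  the LODs would be identical.
* **Per-compound background.** With `compound_background = TRUE` each
  compound (where geometrically possible, m/z below ~450 Th) receives a
  companion background ion inside the 0.01 Th confirmation window but
  more than 20 ppm away in relative terms — visible to EIC-based noise
  estimation, invisible to ROI tracing. This gives the local-noise
  estimator realistic material without contaminating peak traces.

What the generator does *not* emulate — and hence what a green test does
not establish: isotope envelopes and adduct networks (and their
annotation), chimeric MS2 spectra, inter-sample RT drift beyond the
documented absence, detector saturation, profile-mode data, and real
spectral similarity structure between distinct compounds. Results on
synthetic data demonstrate algorithmic correctness and directional
behaviour, not instrument-grade performance numbers.

## 4. Numerical choices and degenerate inputs

* RT is seconds everywhere internally; minute-encoded mzML is converted
  on read. Scan indices are 0-based. All m/z windows are closed
  intervals.
* Profile-mode spectra are rejected, not centroided: silent centroiding
  would hide acquisition errors.
* Missing MS2 precursor intensities are back-filled from the parent MS1
  scan within 10 ppm; the rescue tier re-derives apex intensity anyway,
  so this only affects deduplication order.
* Ties: apex relocation breaks intensity ties toward the trigger RT;
  fragment matching breaks distance ties toward the higher intensity
  product; boundary descent prefers the narrower peak at ambiguous local
  minima.
* Degenerate inputs raise classed conditions (`peakrescue_format`,
  `peakrescue_empty_run`, `peakrescue_schema`, `peakrescue_config`,
  `peakrescue_apex_not_found`, `peakrescue_insufficient_points`,
  `peakrescue_degenerate_fit`, `peakrescue_invalid_fit`) rather than
  returning half-meaningful values; per-candidate soft failures carry
  reason codes (`noise_fail`, `consecutive_fail`, `already_extracted`,
  `mr_collision`, `no_signal`) in rejection logs instead of erroring.
* Workflow parallelism forks per sample (`parallel::mclapply`); samples
  are independent, so concurrent results are identical to serial ones —
  asserted in the test suite, not assumed.

## 5. Known limitations

* Only mzML input is supported (conversion from vendor formats and the
  legacy mzData/mzXML variants is delegated to external converters);
  mzML writing exists only for the synthetic generator.
* No retention-time correction; heavily drifting batches need external
  alignment before grouping.
* No isotope/adduct/cluster annotation; each ion species is reported as
  its own feature.
* The MR tier requires DDA MS2 scans; on full-scan/DIA data the workflow
  degrades to PP + TL by construction.
* Greedy fragment matching is not guaranteed optimal for pathological
  spectra with many near-duplicate fragment m/z; the test suite bounds
  its behaviour against an exhaustive matcher on small spectra.
* The LOD procedure assumes a positive calibration slope and reports a
  sentinel otherwise; it does not model heteroscedastic weighting or
  saturation.
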