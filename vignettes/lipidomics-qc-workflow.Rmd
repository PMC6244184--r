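---
title: "QC-anchored processing of targeted lipidomics runs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QC-anchored processing of targeted lipidomics runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidflow)
```

# The measurement model

`lipidflow` processes targeted extracted-ion chromatograms (EICs) from a
multi-batch LC-MS lipidomics acquisition. The model underlying every stage
is multiplicative: the recorded peak height of ion $i$ in injection $s$ of
batch $b$ is

$$ y_{is} = c_{l(i),s} \, r_i \, d_{ib}(t_s) \, \varepsilon_{is} + \text{baseline}, $$

where $c_{l,s}$ is the concentration of lipid $l$ in sample $s$ (shared by
all adducts and both polarities of that lipid), $r_i$ a fixed per-adduct
response factor, $d_{ib}(t)$ a smooth drift of instrument response over
injection order $t$ within batch $b$, and $\varepsilon$ lognormal
measurement noise. Two consequences drive the design:

* drift and batch effects are removed by **division**, never subtraction —
  correction factors are ratios, so the correction is equivariant under
  rescaling of an ion's column and preserves the intensity scale on which
  fold-change statements (e.g. mean heights 25,000 vs 75,000 = a 3-fold
  difference) are made;
* statistics that assume additive noise (paired t-tests, PCA) are computed
  on $\log_{10}$ heights, where lognormal noise is exactly normal.

Pooled-plasma QC injections after every block of study samples share one
fixed concentration, so any systematic QC variation is, by construction,
instrumental — which is what licenses using QC curves to correct study
samples.

# Retention-time recalibration

Chromatographic retention times wander smoothly from injection to
injection. Each sample's internal-standard apexes are located inside a
0.20-min window centered on their database RTs, and a quadratic
least-squares map `observed = a·expected² + b·expected + c` is fitted
(at least 3 standards are required, hence the database invariant of ≥ 3
internal standards per mode). All target windows are then centered on the
recalibrated RTs. The fit is per sample, pooling the standards of both
polarities: the generator applies a single time-axis distortion per
injection, and pooling doubles the points constraining the quadratic. A
per-mode fit would be preferable on instruments with genuinely independent
chromatographic axes.

Two numerical points matter here:

* **Apex refinement.** The grid apex is quantized to the EIC sampling step
  (0.005 min), and a quadratic fit amplifies that quantization error
  through the $a\,t^2$ term (a 0.0025-min apex error at late RTs propagates
  to ~0.1-min window-center errors across the gradient). The standards'
  apexes are therefore refined by parabolic interpolation of log intensity
  through the grid maximum and its two neighbors, after subtracting the
  trace median as a baseline estimate. For a Gaussian peak on a constant
  baseline this is exact, and the noise-free recalibration recovers the
  injected distortion coefficients to machine precision (the test suite
  asserts 1e-6). Analyte peak heights deliberately remain grid maxima —
  no smoothing or integration is applied to quantified peaks.
* **Window-boundary flags.** A standard whose apex lands exactly on a
  window edge is used in the fit but flagged low-confidence; silently
  excluding it would bias the fit toward the remaining standards. The
  generator's default RT distortion (|a| ≤ 2e-4, |b−1| ≤ 3e-3,
  |c| ≤ 0.01 min) keeps total shifts under half the 0.20-min window across
  a 15-min gradient, as a well-maintained UHPLC system does; larger
  distortions violate the workflow's own windowing assumption and surface
  as boundary flags.

# Drift correction and span selection

Per ion and batch, a degree-1 LOESS (tricube weights over the
span-fraction nearest neighbors) is fitted to QC heights against injection
order. Every non-blank sample is multiplied by `anchor / prediction(t)`,
where the anchor is `median(QC) / median(QC / prediction at QC positions)`
— with a perfect fit the second term is 1 and the anchor is simply the
batch QC median; in general this form makes the corrected within-batch QC
median equal the raw one *exactly*, so the correction changes shape, never
level. Level equalization is a separate step: per ion, each batch is
scaled so its QC median matches the pooled all-batch QC median.

The span is chosen per curve from the grid 0.3–1.0 (step 0.1) by
leave-one-out cross validation, with ties (within 1e-12) resolved toward
the **largest** span: when several spans explain the QCs equally well, the
smoothest curve is least likely to chase noise. Spans whose neighborhood
would hold fewer than 3 points are infeasible — `stats::loess` returns
unreliable values there rather than failing, so the package rejects them
explicitly. Ion-batches with exactly 4 usable QCs skip the LOO scan and
use span 1.0; fewer than 4 usable QCs, or a nonpositive prediction, fall
back to the batch-median model (no within-batch correction) and are
recorded in the audit. QCs flagged apex-on-boundary or missing are
excluded from fits but still corrected. Blanks are never used in, nor
altered by, normalization.

Performance is scored by a k-fold (default 5) cross-validated QC RSD: QCs
are assigned to folds by injection-order rank modulo k (deterministic, so
every fold spans the run), and for each fold the drift and
median-normalization models are refit without that fold before correcting
its QCs. Setting k to the number of QCs gives the leave-one-out variant.
The span is re-selected inside each fold — the held-out QCs never
influence any fitted quantity.

# Adduct selection, dedup, and filtering

Within each (lipid, mode) the adduct with the lowest QC RSD (computed on
the normalized matrix, since filtering follows normalization) is selected;
for dual-mode lipids the lower-RSD mode wins. Exact RSD ties resolve
deterministically: positive mode first, then adduct label
lexicographically, then ion id. Spearman correlation between the two mode
candidates across all non-blank samples is reported with a ρ ≥ 0.80
concordance flag — a descriptive quality indicator only, never a removal
criterion. The final filter removes ions with QC RSD **strictly** above
25% (a value of exactly 25.0% is retained) plus all internal standards,
which are calibration devices rather than analytes; it is idempotent.

# What the synthetic generator emulates — and what it does not

`run_simulate()` produces the acquisition design the pipeline expects:
study samples randomized over contiguous batches whose sizes are
near-equal whole multiples of the QC interval (a remainder block goes to
the last batch and is closed by a trailing QC, so the QC count is
⌈n_study / interval⌉ and every study sample is bracketed by QCs), one
pooled QC and one blank per 10 study samples, and a configurable number of
replicate aliquot pairs inserted at random positions.

Defaults, chosen once as plausible for a modern UHPLC-QTOF assay and
declared here rather than asserted as any instrument's truth: drift
amplitude 20% of mean response with a linear within-batch shape (curves
start each batch at nominal response after source cleaning and drift away,
so batches also *end* at different levels — the between-batch offsets that
median normalization exists to remove), measurement noise CV 8%,
chromatographic peak SD 0.02 min, baseline 50 counts with uniform noise of
10, EIC grid step 0.005 min (≈ 2 spectra/s over a 15-min gradient),
carryover 1% of the preceding QC. Biological spread is lognormal with
sdlog 0.4 between subjects; the QC pool level is a separate fixed draw per
lipid (a pooled lot is not the study mean), which is why QCs form the
tight, offset cluster in the PCA overview. All randomness flows from one
master seed through named sub-streams (database, plan, concentrations,
noise), so stages are independently reproducible.

The generator does **not** emulate: profile-mode spectra or m/z axes,
isotope envelopes, co-eluting isobars, missing peaks, detector saturation,
or heavy-tailed noise. Passing tests therefore demonstrate the correctness
of the processing logic under the stated model, not robustness to every
failure mode of real instruments; in particular the t-test calibration
result holds exactly because log-lognormal noise is normal, and will be
approximate on real data.

# Numerical conventions and degenerate inputs

* Atomic monoisotopic masses are hard-coded IUPAC values; adduct m/z
  includes the electron mass (subtracted for cations, added for anions);
  display rounding is half-even to 4 decimals, with full precision kept
  internally. Only singly charged adducts are supported.
* Ties at a window maximum resolve to the earliest RT; an all-zero
  standard window is "not detected" and leaves the fit.
* A zero trace median makes the signal-to-noise infinite, flagged, rather
  than an error; zero is a legitimate intensity, so missing measurements
  are explicit `NA`s, never zeros.
* An RSD over a zero-mean vector is undefined (`NA`, flagged); undefined
  RSDs lose every selection and are removed by the filter as
  unquantifiable.
* Degenerate duplicate differences (zero variance) report p = 1 with a
  flag; a constant matrix yields zero PCA variance, not an error.
* All CSV round trips write full-precision decimals and reload
  bit-identically; pipeline outputs under a fixed seed are byte-identical
  across runs.

# Problem sizes

The test suite and worked examples run the generator at desk scale: the
default configuration is 200 study samples in 4 batches (240 injections,
~70 target ions, 401-point traces), which exercises 5 QCs per batch — the
small-n regime where the span-feasibility and fallback logic actually
matter; unit fixtures use 10–100 samples and 2–10 lipids. The t-test
calibration study uses 500 ions × 20 pairs constructed directly at the
matrix level. These sizes were chosen so the entire suite completes in
about a minute while still covering every code path of the full-scale
design.

# Known limitations

* Median normalization anchors to QC medians; with a QC pool compositionally
  far from the study samples, an all-sample median anchor could differ.
  The QC anchor is consistent with the QC-anchored drift model and is the
  package's choice.
* The LOESS correction requires ≥ 4 usable QCs per batch per ion to do
  more than median anchoring; sparse QC designs silently degrade to
  between-batch equalization (visibly, in the audit).
* The quadratic RT map extrapolates beyond the internal standards' RT
  range; standards should bracket the gradient, as the generator's do.
* No imputation, no alternative normalizations (ComBat, quantile,
  IS-ratio), and no isomer re-annotation are provided.
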