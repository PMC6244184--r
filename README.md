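# lipidflow

Post-acquisition processing for targeted-extraction untargeted lipidomics.
In a typical large-cohort LC-MS lipidomics assay, hundreds of serum or
plasma extracts are injected over several batches; instrument response
drifts within and between batches, retention times wander from run to run,
and each lipid can be detected as several adducts in both electrospray
polarities. `lipidflow` implements the standard QC-anchored workflow that
turns per-sample extracted ion chromatograms (EICs) into a single clean
samples-by-lipids peak-height matrix, together with the technical-validation
analyses that justify trusting it — all driven, for development and testing,
by a synthetic run generator with known ground truth.

The pipeline stages are:

1. **Target-ion database** — one row per (lipid, mode, adduct) with m/z and
   expected retention time; internal-standard rows drive recalibration.
   Monoisotopic adduct m/z arithmetic (`[M+H]+`, `[M+NH4]+`, `[M+Na]+`,
   `[M-H]-`, `[M+OAc]-`, electron mass included) is built in: for the
   triacylglycerol TG(58:8), `adduct_mz(tg_formula(58, 8), "[M+NH4]+")`
   gives m/z 948.8015.
2. **Peak extraction** — per sample, internal-standard apexes are located
   in a 0.20-min window around their expected RTs; a quadratic
   `observed = a·rt² + b·rt + c` recalibration is fitted by least squares
   and applied to all targets; each peak height is the maximum intensity in
   the 0.20-min window around the recalibrated RT (no smoothing, no
   integration), with signal-to-noise = height / median of the full
   ±1-min EIC.
3. **Drift correction** — per lipid ion and batch, a degree-1 LOESS curve
   of QC peak height against injection order (span chosen by leave-one-out
   cross validation) divides out slow drift; batches are then equalized so
   per-ion QC medians match across batches. Performance is scored by a
   5-fold cross-validated QC relative standard deviation (RSD), refitting
   the models without each held-out QC fold.
4. **Deduplication and filtering** — for each lipid, the adduct with the
   lowest QC RSD wins within each mode, then the lower-RSD mode wins across
   modes (Spearman concordance between dual-mode pairs is reported,
   descriptively, at the ρ ≥ 0.80 level); ions with QC RSD > 25% and all
   internal standards are removed.
5. **Technical validation** — paired t-tests on replicate study samples
   (log10 scale), a PCA overview, internal-standard RSD tables, blank
   carryover ratios against the preceding QC, and RSD histograms.

## Worked example

```r
library(lipidflow)

cfg <- pipeline_config(seed = 1)   # 200 study samples, 4 batches,
out <- run_pipeline(cfg)           # QC every 10, 20 duplicate pairs
print(out$run$plan)
print(out$report)
```

```
<injection_plan> 240 injections in 4 batches (blank: 20, qc: 20, study: 200)
<qc_report>
  analyte QC RSD < 20%: 100.0% of ions (post-normalization)
  internal standards: 8, median post RSD 5.23%
  duplicate t-tests nonsignificant (p > 0.05): 97.2%
  PCA: PC1 9.8%, PC2 7.3% of variance
  carryover: max blank/QC ratio 0.0106 (0 flagged)
```

On this default synthetic run (20% drift amplitude, 8% measurement noise)
the median QC RSD drops from 9.9% before correction to 4.7% after, the
5-fold cross-validated QC RSD is 9.3%, and all 12 dual-mode lipid pairs are
rank-concordant at ρ ≥ 0.80. `out$filtered$matrix` is the final
one-column-per-lipid matrix and `out$filtered$dictionary` its data
dictionary; `run_pipeline(cfg, out_dir = "...")` writes every artifact
(matrices, audit, report tables) as CSV.

A thin command-line wrapper is installed at
`system.file("scripts", "lipidflow.R", package = "lipidflow")` with
subcommands `simulate`, `extract`, `normalize`, `filter`, `report`, `all`.

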