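---
title: "Single-marker quantification of multicomponent panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-marker quantification of multicomponent panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qams)
```

## The problem

Quality control of multi-constituent preparations — herbal medicines above
all — asks for the simultaneous determination of many index compounds, but
the classical external standard method (ESM) needs a reference substance for
every one of them, and many are expensive, unstable or simply unavailable.
Quantitative analysis of multicomponents by single marker (QAMS) keeps one
cheap, stable, well-characterised constituent as the internal reference
standard (IRS) and quantifies the rest through pre-established response
ratios. This package implements that workflow for targeted LC-MS/MS (MRM)
panels: calibration, the two standard estimators of the response ratios,
single-marker quantification, peak positioning without reference substances,
the bioanalytical validation statistics, robustness screening, and the
ESM-versus-QAMS comparison. The worked example throughout is an
eight-constituent pneumonia-mixture panel with baicalein as the IRS
(`pneumonia_panel()`, `pneumonia_reference()`).

## Model

Within the calibration range the MRM response is linear in concentration,
$A_k = f_k C_k$ with response factor $f_k$. Two estimators of the relative
correction factor $f_{ks}$ of analyte $k$ against the IRS $s$ are in common
use, and both are implemented:

* **AVG** (`rcf_avg()`): in every run of a mixed-standard dilution series
  both analytes are observed together, so each run yields
  $f_{ks} = (A_k/C_k) / (A_s/C_s)$; the estimator is the arithmetic mean of
  the per-run ratios, reported with its sample SD. Runs are matched by
  `run_id`. Averaging $f_k$ and $f_s$ separately before dividing would lose
  the dispersion estimate and is not offered.
* **LRG** (`rcf_lrg()`): the ratio of calibration slopes $a_k / a_s$ from
  the weighted fits of the full series.

Quantification of a sample peak with area $A_K$ then proceeds either
through a contemporaneous IRS injection (AVG path,
$C_K = n \cdot f_{ks}^{-1} \cdot C_s \cdot A_K / A_s$,
`quantify_qams_avg()`) or through the IRS slope (LRG path,
$C_K = n \cdot f_{ks}^{-1} \cdot A_K / a_s$, `quantify_qams_lrg()`), with
$n$ the dilution factor of the preparation. The LRG formula deliberately
carries no intercept — it reduces algebraically to $n A_K / a_k$ — so on
noise-free data its only discrepancy against ESM is the analyte's neglected
intercept. The AVG estimator has a sharper caveat: when intercepts are
large relative to the response at the low calibration levels (true of
several constituents of the example panel, e.g. baicalin), the per-level
ratios drift strongly across a dilution ladder and the AVG mean is biased
away from the slope ratio. The estimator is only cleanly interpretable in
the proportional-response regime, which is why the identity and recovery
tests below run on zero-intercept truth.

Concentration units are fixed: working solutions in ng/mL, preparation
contents in mg/mL. The single conversion
$\mathrm{mg/mL} = \mathrm{ng/mL} \times n \times 10^{-6}$ lives in
`working_to_prep()` and nowhere else, so the $10^6$ step cannot silently
happen twice.

## Calibration

`fit_weighted_line()` fits $A = aC + b$ by exact closed-form weighted least
squares with the bioanalytical default weight $1/x$ (response variance
growing with concentration). The source method statement names "weighted
(1/x)" without fixing $1/x$ versus $1/x^2$; $1/x$ on squared residuals is
the standard reading and the default, with `"1/x2"` and `"none"` available.
Replicates enter as individual weighted points. The reported correlation is
the weighted Pearson $r$ (consistent with the fit; equal to ordinary $r$
under equal weights), with the unweighted $r$ emitted alongside;
`check_linearity()` applies the usual $r > 0.9990$ acceptance.
Back-calculations that come out non-positive or outside the calibration
range are flagged (`nonpositive`, `below_range`, `above_range`), never
clamped, so the validation statistics see raw behaviour.

## Peak positioning

Only the IRS is identified directly by its reference substance. Other peaks
are located by relative retention time $t_{ks} = t_k / t_s$ combined with
the identity of the MRM transition (`position_peaks()`). Defaults: a 5%
relative RRT window — chosen because observed RRT dispersion across column
temperatures stays below ~5% for well-behaved analytes — and a 0.5 Da m/z
window (unit-resolution triple quadrupole). Analytes whose RRT is known to
drift with flow rate or column geometry (typically early eluters; the
example panel's goitrin, ephedrine and pseudoephedrine) are flagged
RRT-unstable by `robustness_report()`: for them the m/z match is mandatory
and the RRT window widens to a secondary tolerance (default 35%, sized for
the retention shifts seen across column-geometry changes). Peaks matching
several analytes are reported as ambiguous rather than force-assigned.

## IRS screening

`select_irs()` treats every panel analyte as a candidate IRS: RCFs are
derived from the calibration batch, every other analyte is quantified in
mixed-standard check solutions of known composition, and the deviation from
truth is scored as a standard method difference (SMD),
$|C_{ES} - C_{QAMS}| / C_{ES} \times 100$. Replicate determinations of one
analyte are averaged (mean of per-run concentration ratios) before the
deviation is taken, so the per-analyte SMD measures systematic deviation
rather than injection noise. Candidates whose worst per-analyte SMD stays
below 5% are eligible; ranking is by mean SMD with alphabetical
tie-breaks. The final pick stays with the analyst — cost, stability and
availability are not computable. SMD is implemented with the absolute value
(the reported convention; all published values are non-negative), with the
signed deviation available for bias diagnostics.

## Validation and comparison statistics

All dispersion statistics use the sample (n−1) SD, matching small-n
bioanalytical convention, and are scale-invariant. `precision_report()`
computes intraday RSD over the within-day replicate injections (design
default six) and interday RSD over the daily means (default three days),
with the pooled RSD shown for transparency; `stability_report()` and
`repeatability_report()` are RSDs over timed re-injections and independent
preparations. `recovery()` implements standard-addition recovery
$(found - original)/spiked \times 100$, with a configurable acceptance band
defaulting to 85–115%. All pass/fail limits are arguments, never
hard-coded.

`compare_methods()` pairs ESM and QAMS results on the sample × analyte grid
and tests, per analyte, whether the two methods disperse alike with a
two-sample variance-ratio F test (larger variance in the numerator,
two-sided p). The named comparison procedure in this field is just "an
F-test", which is ambiguous; the variance-ratio reading is primary here,
with one-way ANOVA across methods always reported and a paired t-test on
the means available as a labelled interpretation. The per-analyte verdict
is "consistent" when p > 0.05 and the largest SMD stays under a
configurable bound (default 10%, comfortably covering the deviations
regarded as acceptable in practice).

## The synthetic-data generator

No raw peak tables for the example study are published, so
`generator_config()` and the `generate_*()` functions emulate its design:

* **Calibration**: an 8-level 2-fold dilution ladder anchored at each
  analyte's calibration high, with the calibration low appended as the
  bottom level (deduplicated when coincident — the glycyrrhizinate range is
  exactly six doublings). The level count is configurable because the
  source never states one; 3 replicate injections per level is ordinary
  practice and the default. All analytes share run identifiers, as a mixed
  standard would.
* **Response**: mean areas exactly on the configured true lines (default:
  the published calibration equations). Noise is multiplicative
  truncated-normal with constant CV (default 3%, a typical LC-MS/MS
  repeatability) — the common empirical regime even though $1/x$ weighting
  strictly corresponds to variance ∝ concentration, a mismatch kept
  deliberately so the weighted fit is exercised off its ideal assumption; a
  `"prop_x"` mode provides the matched regime. Retention times jitter with
  a 0.5% CV (replicate-to-replicate RT variability is unreported; this
  value keeps nominal positioning comfortably inside the 5% RRT window
  while leaving the robustness split to explicit condition shifts).
* **Samples**: six preparations at the published contents for the four
  analytes whose contents are printed; the other four (pseudoephedrine
  0.25, ephedrine 0.15, glycyrrhizinate 1.0, baicalin 5.0 mg/mL) are
  assumptions chosen once so the 5000× dilution lands mid-range. Ground
  truth is emitted alongside.
* **Robustness sets**: per-condition RT multipliers and response scales.
  Uniform response scaling cancels exactly out of every RCF; ±25–30% RT
  multipliers on the early eluters reproduce the qualitative split between
  RRT-stable late eluters and RRT-unstable early ones.
* **Validation batches**: the standard replicate designs (6 intraday, 3 × 6
  interday, 0–12 h stability series, 6 repeatability preparations, 3 spike
  levels × 5 replicates).

Everything is seeded; identical configurations are bit-identical, and the
generators restore the caller's RNG state. What the generator does *not*
emulate: matrix effects, carryover, drift within a batch, and
chromatographic peak shape — so green tests demonstrate the correctness of
the computations and the internal consistency of the method, not ruggedness
against those real-data phenomena.

## Numerical choices and degenerate inputs

* All RCF/RRT/quantification arithmetic is kept at full precision;
  rounding to 2 decimals happens only at the reporting layer (the CLI's
  `--report` mode).
* Fits require ≥ 3 distinct positive concentrations; identical
  concentrations raise a singular-design error, non-positive ones a weight
  error.
* Zero IRS areas or slopes raise division errors naming the offending run;
  they are never imputed.
* A known quirk of the example's published table: the glycyrrhizinate RRT
  prints as 1.12 while the printed retention times give 6.86/6.16 = 1.11 at
  2 dp. Full-precision ratios are authoritative here and that cell is not
  forced to agree.
* Tests and the acceptance script use a study-scale problem size (8
  analytes, ≤ 8 levels × 3 replicates, 200-replicate Monte Carlo for
  estimator recovery, 20 seeds for the linearity screen) — large enough for
  stable statistics on this design, small enough to run in seconds.

## Known limitations

Single-IRS schemes only (no two-marker designs); no LOD/LOQ estimation, no
quadratic or log-log calibration; no equivalence (TOST) testing or
Bland–Altman analysis in the comparison module; no transfer modelling of
RCFs across instruments beyond the robustness RSD screen. The AVG
estimator's intercept sensitivity discussed above is inherent to the
estimator, not to this implementation.
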