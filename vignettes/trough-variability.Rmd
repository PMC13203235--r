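---
title: "Quantifying intra-individual trough variability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intra-individual trough variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(troughvar)
```

## The problem

Intravenous vancomycin has a narrow therapeutic window; in much of
real-world orthopedic practice it is still steered by trough
concentrations against a 15–20 mg/L band. Ward-level audits usually
report *population* target attainment — the share of all measurements in
band — which is blind to whether individual patients sit steadily in the
band or oscillate through it. `troughvar` treats per-patient exposure
*stability* as its own quality indicator and provides the full analysis
chain for a two-cohort (e.g. before/after a dosing protocol) comparison.

The unit of analysis is one patient's ordered trough series
$C_1,\dots,C_n$ (mg/L), ordered by measurement number, never by
administrative timestamp: documented sampling times in hospital
information systems are unreliable enough that interval-weighted metrics
would inherit their noise, so the package is deliberately
interval-agnostic (a stated non-goal).

## Metrics and conventions

For each patient with $n \ge 2$ measurements:

* $\mathrm{CV\%} = 100 \, s / \bar C$ with $s$ the **sample** SD
  ($n-1$). The source convention is unstated for this class of analysis;
  $n-1$ is the defensible default at per-patient $n \approx 3$–$10$ and
  the population form is available via `sd_denominator = "n"` for
  sensitivity.
* Swing index $(C_{\max}-C_{\min})/\bar C$: relative peak-to-trough
  amplitude, permutation-invariant.
* MSSD $= \frac{1}{n-1}\sum |C_{i+1}-C_i|$: here the mean **absolute**
  successive difference, which is order-sensitive. The acronym often
  denotes the mean *squared* successive difference elsewhere; that
  variant exists as `mssd_squared()` but is never used by default —
  conflating the two silently changes units and magnitudes.
* Stability: `cv_pct < 20` with a **strict** inequality (so CV% = 20.0 is
  unstable). The 20% cut-off is a general TDM convention for
  narrow-therapeutic-index drugs, not a vancomycin-validated threshold;
  treat the stable-patient row as exploratory.
* Quartiles: linear interpolation (R `type = 7`). Summary medians/IQRs
  depend on this choice at small cohort sizes, so it is fixed and
  documented rather than left to ambient defaults.
* Inclusion: metrics are defined from $n \ge 2$, but the default
  pipeline filter is $k = 3$ (a CV from two points is unstable);
  `k = 2` reproduces the usual sensitivity analysis. Filtering is
  upstream of, and independent from, the metric layer.

## Zones and the two transition notions

Troughs are classified subtherapeutic ($< 15$), target ($15$–$20$,
**both boundaries inclusive**), supratherapeutic ($> 20$); boundaries are
configurable. Two related but distinct quantities are computed and
deliberately named apart:

1. `count_zone_changes()` — per patient, consecutive pairs whose zones
   **differ**. This is the "zone transitions per patient" summary
   statistic (a median of ~2 at ~6 measurements per patient is only
   arithmetically possible when persistence pairs are excluded).
2. `pooled_transition_matrix()` — per cohort, **all** within-patient
   consecutive pairs including persistence, pooled across patients. The
   identity `n_transitions = measurements − patients` therefore holds
   exactly and is enforced as a tested property (e.g. 309 measurements
   from 51 patients give 258 pooled transitions).

Probabilities are row-conditional. A zone from which no departure was
observed gets an `NA` probability row plus an explicit flag — imputing 0
or uniform rows would silently distort heat-map style displays. Pooling
weights patients by trajectory length; `patient_weighted_transition_matrix()`
is provided as a clearly-marked extension that instead averages
per-patient matrices (equal patient weight), for sensitivity use only.

## Statistical layer

* **Mann–Whitney U**, two-sided. Exact p from the null U distribution
  when both samples are tie-free and $n_a n_b \le 400$; otherwise a
  normal approximation with tie correction and continuity correction.
  The method actually used is always recorded in the result, since the
  source analyses of this kind often do not state which their software
  chose. The exact path is validated in the test suite against a full
  enumeration oracle over all $\binom{n_a+n_b}{n_a}$ labelings.
* **Rank-biserial / Cliff's delta**
  $r_{rb} = (\#\{b>a\} - \#\{a>b\})/(n_a n_b)$, ties counting zero;
  with `a` = pre and `b` = post, lower post values give negative
  $r_{rb}$. Internally computed from mid-ranks and checked in tests
  against the $O(n^2)$ pair count and the identity
  $r_{rb} = 2U_b/(n_a n_b) - 1$.
* **Fisher's exact test** (stable-patient 2×2): two-sided by the
  point-probability method — the sum of hypergeometric probabilities no
  larger than the observed table's — which is deterministic and matches
  the behavior of the common statistical packages.
* **Spearman's rho**: Pearson correlation of mid-ranks; p from the
  $t$ approximation, or exact permutation enumeration on request for
  $n \le 8$ (the cap is 8, not 10: $10!$ permutations are impractical in
  pure R; beyond the cap the approximation is used and reported).
* **No multiplicity correction** by default, matching the exploratory
  reporting convention for this analysis type; `holm = TRUE` appends an
  adjusted column as a clearly non-default extra. Shapiro–Wilk normality
  p-values are attached for information only and never gate the choice
  of test — the comparison is always rank-based.

## The synthetic cohort generator

Real trough cohorts of this kind are not publicly depositable, so the
generator is a first-class, tested module whose defaults state the world
the analysis targets: a pre cohort of 51 patients / 309 measurements
with median CV% near 43.5 and a post cohort of 17 / 94 near 32.5,
trajectory lengths ≥ 3 averaging ~6, concentrations ~5–35 mg/L around a
15–20 mg/L band, exposure means 17.5/17.9 mg/L.

**lognormal AR(1) mode** (default): per patient,
$\log C_t = \log m_i + e_t$, $e_t = \phi e_{t-1} + \eta_t$ stationary,
with $\sigma_{\log} = \sqrt{\ln(1+\mathrm{CV}^2)}$ so the marginal
concentration CV equals the target *exactly* (lognormality gives
positivity and the right skew expected of variability measures).
Patient-level means $m_i$ are lognormal around the exposure mean
(between-patient CV 15%), per-patient CV multipliers are lognormal
(log-SD 0.25) to make variability itself heterogeneous, and $\phi = 0.3$
encodes mild correlation of adjacent troughs under dose adjustment.
These three values are not printed anywhere in the source material; they
were chosen once as clinically plausible and are not tuned. Trajectory
lengths are `min_length + Poisson`, then adjusted deterministically to
hit exact preset totals (309/94). Therapy duration is generated with a
configurable latent correlation to the patient's CV multiplier
(`duration_cv_rho`, −0.5 in the post preset) to emulate the observed
longer-therapy/lower-variability association.

**zone_chain mode**: zone sequences from a known 3×3 chain started at
its stationary distribution, concentrations uniform within per-zone
ranges. This mode exists to validate transition-matrix estimation
against a known truth; `preset_zone_matrix()` provides
qualitative pre/post patterns whose individually published cells (52.7%
subtherapeutic persistence pre; 57.6% target persistence, 45.0%
sub-to-target, 37.5% supra-to-target post) are exact and whose remaining
cells are fills — the full source matrices exist only as a figure.

What the generator does **not** emulate: pharmacokinetics (no dose →
concentration model, no renal-function dynamics, no dosing-rule
feedback), assay and sampling-time error structure, same-day duplicate
troughs, or the exact source transition matrices. A green test on
synthetic data therefore establishes that the *pipeline* computes its
statistics correctly on data of the stated shape — not that the clinical
effect sizes are reproduced; the published headline medians serve as
generator targets, never as acceptance values.

## Numerical and design notes

* Degenerate inputs: constant trajectories give exactly 0 for every
  metric; empty filter results are legal; a cohort with a single zone
  ever observed yields two flagged-undefined matrix rows; comparison
  stages are skipped (and logged) when only one cohort is present.
* The per-patient **sample** CV is a downward-biased estimator of the
  generating marginal CV at short series lengths — roughly 5–8% relative
  at lengths 6–10 for CV ≈ 40%, shrinking to < 1% by length 50 (skewness
  of the lognormal plus the usual $E[s] < \sigma$ effect). The recovery
  tests therefore check the spec-level case (CV 30, length 10) as stated
  and the three-level calibration at length 50, while the clinical
  presets keep realistic short lengths. Consequently the *measured*
  median CV% of the primary preset (~35–40 pre) sits a few points below
  its 43.5 target — expected estimator behavior, not miscalibration.
* Reproducibility: every simulation consumes one integer seed through a
  private RNG scope that restores the caller's `.Random.seed`; identical
  config + seed gives byte-identical cohorts and a byte-identical
  `summary.json`.
* Same-day duplicate troughs are kept (the source convention is
  unstated); deduplication is the user's responsibility upstream.
* p-values are clamped to `(0, 1]`; `r_rb` lies in `[-1, 1]` by
  construction.

## Limitations

Single-band, two-cohort design by construction (more than two cohort
labels is a schema error); no interval-weighted variability, no AUC/MIC
or Bayesian exposure reconstruction, no multivariable modelling, no
inferential testing of individual transition probabilities — the matrix
layer is descriptive and hypothesis-generating. The stability threshold
and zone boundaries are conventions, configurable but not validated
cut-offs.
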