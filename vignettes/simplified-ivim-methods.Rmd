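---
title: "Simplified IVIM mapping and two-colour index maps: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simplified IVIM mapping and two-colour index maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(simplifiedIVIM)
```

## The problem

Diffusion-weighted MRI of the liver mixes two signal-attenuation
mechanisms: water diffusion in tissue and pseudodiffusion from blood
moving through randomly oriented capillaries. The intravoxel incoherent
motion (IVIM) model writes the signal at diffusion weighting $b$ as a
biexponential,

$$S(b) = S_0\left[(1-f)e^{-bD} + f e^{-b(D+D^*)}\right],$$

with tissue diffusion coefficient $D$, perfusion fraction $f$ and
pseudodiffusion coefficient $D^*$. Full biexponential fitting needs many
$b$ values and is fragile at clinical signal-to-noise ratios. The
*simplified* approach this package implements uses three $b$ values
(0, 50, 800 s/mm²) and explicit closed-form estimators:

$$D' = \frac{\ln S(b_{50}) - \ln S(b_{800})}{b_{800}-b_{50}}, \qquad
  f' = 1 - \frac{S(b_{50})}{S(b_0)}\,e^{D' b_{50}}, \qquad
  \mathrm{ADC} = \frac{\ln S(b_0) - \ln S(b_{800})}{b_{800}-b_0}.$$

Above $b \approx 50$ s/mm² the perfusion compartment is largely
dephased, so $D'$ approximates $D$ and $f'$ the relative perfusion
signal excess at $b=0$. Malignant liver lesions restrict both diffusion
and perfusion-fraction values; the two benign classes that confound
single-parameter reading are haemangiomas (high $D$) and focal nodular
hyperplasias (high $f$). Binarising $D'$ and $f'$ maps at class-derived
cutoffs and combining them voxel-wise (red only where *both* are below
cutoff) yields a two-colour map, $I_{Df}$, that can be read at a glance
as an overlay on the $b$-800 image.

## Estimator properties the package relies on

Three algebraic facts are used as test anchors:

1. **Identity.** Substituting the $D'$ and $f'$ definitions into the ADC
   formula gives, for every voxel with positive signals,
   $\mathrm{ADC} = D' - \ln(1-f')/b_{800}$ exactly. The test suite
   asserts this to $10^{-12}$ mm²/s on whole volumes, noisy or not,
   because it holds for *any* signal triple — it validates the
   implementation, not the data.
2. **Exact recovery.** In the idealised fully dephased regime
   ($S(0)=S_0$, $S(b>0)=S_0(1-f)e^{-bD}$, the $D^*\to\infty$ limit for
   $b \ge 50$) the estimators are exact: $D' \equiv D$, $f' \equiv f$
   voxel-wise. The phantom simulator exposes this regime
   (`mode = "fully_dephased"`) precisely so exactness is testable.
3. **Bias direction at finite $D^*$.** With the biexponential model and
   $D^*$ in the liver-typical 10–100 ×10⁻³ mm²/s range, the residual
   perfusion signal at $b=50$ inflates $S(50)$, which biases $D'$
   *upward* and $f'$ *downward* relative to the generative $D$ and $f$;
   both biases shrink monotonically as $D^*$ grows. (It is tempting to
   expect $f' \ge f$ from "perfusion residue", but the algebra goes the
   other way; the tests pin the correct directions.)

### Validity rather than clamping

Non-positive signals make logarithms undefined. Such voxels are flagged
invalid and excluded from ROI statistics rather than floored to a small
positive value, because flooring fabricates diffusion values that then
bias ROI means. $f'$ is likewise not clipped to $[0,1)$: under noise its
raw value can be negative, and clipping would bias ROI means upward.
Invalid-voxel counts per map are reported by the pipeline summary so
quality problems surface as numbers.

## Index maps and ROI conventions

* Binarisation is a strict `<` comparison — a voxel exactly at the
  cutoff is green. `combineDf()` is the voxel-wise AND (equivalently the
  minimum) and is proven in tests to equal direct classification by
  `(D' < c_D) & (f' < c_f)`.
* Shipped default cutoffs are `referenceCutoffs()`: $c_D$ = 1529.4 ×10⁻⁶
  mm²/s, $c_f$ = 114.5 ×10⁻³, $c_{ADC}$ = 1338.5 ×10⁻⁶ mm²/s. The
  published reference values report the $f'$ cutoff inconsistently as
  114.4 and 114.5 ×10⁻³; the tabulated 114.5 is shipped and the
  discrepancy is left visible in the documentation rather than resolved
  silently.
* Overlays blend red/green into the percentile-windowed (1st–99th)
  $b$-800 slice at `alpha = 0.4` by default. Invalid voxels render as
  plain grayscale, not green: absence of evidence is not benignity.
* ROIs are single-slice voxel sets, mirroring routine 2-D ROI reading.
  The manual reading conventions are replaced by mask arithmetic with
  declared constants: the "translucent hyperintensity" display mask is
  $b_{800} > \mu_\mathrm{ref} + k\,\sigma_\mathrm{ref}$ against a
  normal-liver reference ($k = 2$ by default), and the
  necrosis/cyst/scar exclusion flags ROI voxels with
  $b_0 > \mathrm{median} + k\,\mathrm{SD}$ or
  $b_{800} < \mathrm{median} - k\,\mathrm{SD}$ of the ROI interior
  (robust median/MAD variant available). $k = 2$ is a package
  convention, not a literature value — the source describes these steps
  only visually.
* The four-point visual rating is replaced by a red-fraction surrogate.
  Only the 50% majority boundary is anchored in the reading rule; the
  definite/probable band edges (25/75) are package conventions and
  configurable.

## Statistical pipeline

ROC, Youden, DeLong and ICC are implemented from their defining
formulas, with the paper-grade reference implementation (pROC) used as
an independent cross-check in the test suite only.

* **ROC/AUC.** The AUC is the normalised Mann–Whitney statistic (ties
  count ½), identical to the trapezoidal area. Candidate thresholds are
  midpoints between consecutive sorted unique values plus $\pm\infty$,
  which makes derived cutoffs independent of sample order. Marker
  direction is explicit (`lower_is_positive` for diffusion parameters).
* **Youden cutoff.** $J = \mathrm{sens} + \mathrm{spec} - 1$ maximised
  over the candidates. Tie-break, needed for deterministic
  reproducibility: higher sensitivity first (a screening-oriented
  choice), then the smaller threshold. Reported accuracy uses the sample
  class prevalences.
* **DeLong.** AUC variance and paired covariance from the structural
  components $V_{10}, V_{01}$; the paired variance is
  $v_a + v_b - 2c$, the unpaired one $v_a + v_b$; two-sided normal $p$.
* **Group tests.** Shapiro–Wilk at 0.05 on each group gates between a
  Welch $t$ test and a Mann–Whitney U test (exact enumeration when
  $n_1+n_2 \le 12$ without ties). The gate engages only for groups of at
  least 4: Shapiro–Wilk has essentially no power below that, and tiny
  samples default to the nonparametric branch. Welch rather than
  pooled-variance $t$ because group sizes and variances differ
  throughout this kind of cohort.
* **ICC.** Two-way random effects, absolute agreement, single measure
  — ICC(2,1) from ANOVA mean squares — chosen because reading sessions
  are exchangeable "raters" and systematic shifts between readers should
  count against agreement. A consistency form is available. The
  published per-lesion ratings are not available, so the printed ICC
  values cannot be recomputed; the implementation is validated against
  ANOVA mean-squares oracles instead.

## The phantom generator

`buildScene()` / `simulateDWI()` exist so that every downstream stage is
testable without patient data. Design:

* **Geometry.** Abstract: an elliptical-cylinder body (an axial slab)
  filled with liver background, containing non-overlapping spherical
  lesions of at least 3 voxels diameter (mirroring a ≥ 1 cm inclusion
  rule at typical DWI resolution). Default grid 64×64×16, isotropic
  voxels. No anatomical atlas, no respiratory or cardiac motion; an
  optional whole-volume slice-shift switch provides a crude misalignment
  stress test.
* **Class distributions.** Lesion-level $D$ and $f$ are drawn from
  truncated normals matched to the published lesion-group statistics:
  haemangiomas $D$ 1784 ± 314 ×10⁻⁶ mm²/s versus 1076 ± 184 for all
  other classes; FNHs $f$ 164 ± 58 ×10⁻³ versus 63 ± 35. The *between-*
  lesion variability carries these SDs (each lesion draws its centre
  once; voxels add a small 3% relative jitter), because ROI means are
  what cutoff derivation consumes and they must reproduce the published
  lesion-level spread. The underlying Gaussian location is shifted so
  that the truncated distribution's mean lands exactly on the class
  target — naive truncation at zero would bias the perfusion-fraction
  classes upward by several ×10⁻³.
* **Free choices.** $D^*$ (not estimated by the workflow) is uniform in
  10–100 ×10⁻³ mm²/s, typical liver magnitudes. $S_0$ is 1000 ± 100
  signal units; background liver uses $D$ = 1.0 ×10⁻³ mm²/s, $f$ = 0.10.
  The acquisition noise level is not published, so the Rician σ is a
  free parameter (magnitude of a complex Gaussian perturbation,
  $\sqrt{(S+g_1)^2+g_2^2}$), defaulting to zero.
* **Cores.** Lesions can carry a central free-fluid-like core (high $D$,
  $f \approx 0$, elevated $S_0$): bright on $b$-0, dark on $b$-800 — the
  pattern the exclusion mask is designed to remove.

What passing phantom tests do **not** show: robustness to real-world
motion, fat/iron signal alterations, partial-volume effects at lesion
rims, or spatially correlated coil noise. The generator draws voxels
independently and keeps geometry ideal; results on it validate the
arithmetic and the decision logic, not clinical performance.

## Cohort experiments and problem sizes

Cutoff-derivation experiments use `simulateLesionCohort()`: lesions in
the reference 109-case class proportions (32 HCC, 8 CCC, 22 colorectal
and 12 breast metastases, 23 haemangiomas, 12 FNHs), each contributing a
25-voxel ROI pushed through the real forward model and estimators. The
package's standard experiment is 500 lesions per cohort and 20 repeated
cohorts for the sampling SD of a derived cutoff — sizes chosen to make
the recovery check sharp while keeping the whole experiment in the
seconds range.

For cohorts generated this way, the large-sample Youden optimum has a
closed characterisation: it is the crossing point of the two class
densities (`generativeYoudenOptimum()` locates it numerically for the
mean-corrected truncated normals). The recovery test asserts that a
derived cutoff lands within three repetition-SDs of that generative
optimum. Note that the generative optimum under *Gaussian* class
distributions is not numerically identical to a cutoff derived from any
one finite empirical sample (the published $D'$ cutoff came from a real,
non-Gaussian 109-lesion cohort); recovery is therefore checked against
the generator's own optimum, which is the quantity the experiment
actually estimates.

## Degenerate inputs and numerical conventions

* Internal units are SI-like (mm²/s, unitless fractions); the
  conventional ×10⁻⁶/×10⁻³ display scalings are applied only at I/O and
  printing.
* Estimation reads $b$ values from stack metadata and requires
  {0, 50, 800}; extra acquired $b$ values (e.g. 250) are ignored.
* A degenerate hyperintensity reference (zero SD) falls back to a strict
  `> mean` rule with a warning; an exclusion mask may legitimately be
  empty; an ROI whose analysed set would become empty raises an error
  naming the lesion.
* Zero between-subject variance makes the ICC undefined; this is flagged
  (`undefined = TRUE`), never returned as a silent NaN.
* All randomness (scenes, noise, cohorts) is seeded; identical
  config + seed reproduces outputs byte-for-byte.

## Known limitations

* $D^*$ is simulated but never estimated — by design, following the
  three-$b$-value workflow.
* The visual-judgment surrogate is a deterministic function of the red
  fraction; it cannot model reader variability, so published
  inter/intra-reader ICCs are out of reach.
* Cutoffs depend on field strength and sequence timing through the
  relaxation-time dependence of $f$; the shipped defaults travel with
  the acquisition they came from and should be re-derived for other
  protocols (derive mode exists for exactly that).
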