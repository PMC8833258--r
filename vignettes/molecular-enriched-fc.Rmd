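---
title: "Molecular-enriched functional connectivity: model, estimation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular-enriched functional connectivity: model, estimation and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`reactfc` estimates, for each subject, the functional connectivity (FC) of
the brain networks associated with specific neurotransmission systems —
e.g. the dopamine (DAT), noradrenaline (NET) and serotonin (SERT)
transporters and the µ-opioid receptor (MOR) — by enriching resting-state
BOLD analysis with PET/SPECT-derived density templates. The generative
assumption is a linear mixing model: writing $D_k(v) \ge 0$ for the density
of system $k$ at voxel $v$ and $s_k(t)$ for the unobserved dominant
fluctuation of that system's network,

$$y(v, t) = \sum_{k=1}^{K} D_k(v)\, s_k(t) + \varepsilon(v, t).$$

Estimation is a two-step dual regression performed per subject:

1. **Spatial step** (`fit_spatial_glm()`). At each time point the masked
   BOLD volume is regressed *across voxels* on the $K$ templates. Data and
   design are demeaned across voxels within the analysis mask, so voxels
   with high density dominate the recovered time course $\hat s_k(t)$.
2. **Temporal step** (`fit_temporal_glm()`). Each voxel's demeaned time
   course is regressed *across time* on the standardized $\hat s_k$
   (zero mean, unit SD), giving $K$ beta maps per subject — the
   molecular-enriched FC maps.

Voxels belonging to a radioligand's quantification reference region
(occipital cortex for DAT/NET/MOR, cerebellum for SERT) carry no usable
density information and are excluded from step 1, but they are deliberately
*included* in step 2, where only the measured BOLD matters; they may show
positive or negative coupling with the network.

Because both steps are ordinary least squares, each is testable against a
plain normal-equations solve; the test suite keeps that equivalence at
`1e-8` on randomized instances.

## Step-1 mask: intersection versus per-system supports

The reference regions differ per system, so the templates' valid masks
differ. A single multivariate regression with $K$ spatial regressors needs
one common voxel set; `build_analysis_mask()` therefore intersects the
valid masks by default and also returns the union (used for step-2
reporting) and the per-system masks. Fitting each system within its own
support is possible by running `fit_spatial_glm()` per system with the
per-system masks, but the intersection is the default because it keeps the
step-1 design a single well-defined least-squares problem. The published
description of the analysis mask ("a binarized mask derived from the
atlases") does not resolve this choice; it is made here explicitly and
recorded.

## Numerical conventions

* **Standardization** uses the population SD (divide by $T$). Idempotent;
  tested to `1e-12`.
* **Solver**: QR with a condition-number report; a design with
  $\kappa > 10^8$ aborts naming the collinear systems — template
  collinearity is the realistic failure mode.
* **z-scale maps** (`to_zscore_maps()`): the display convention is
  across-voxel standardization of each subject's beta map within the brain
  mask. The transform behind published z-scored network figures is not
  uniquely defined; this choice is explicit, and beta maps remain the
  default analysis scale (z-maps are invariant to global BOLD rescaling,
  betas scale linearly — both properties are tested).

# Preprocessing stages

Only the stages that are well-defined computations on the image data are
reimplemented; motion correction, brain extraction, ICA denoising and
nonlinear template registration are external-tool territory and out of
scope. The default chain is smooth (6 mm) → WM/CSF nuisance regression →
0.005 Hz high-pass → smooth (6 mm):

* **Nuisance regression** removes the mean white-matter and CSF time
  courses (plus an intercept) from every voxel by least squares; outputs
  are exactly orthogonal to the retained regressors.
* **High-pass filter**: projection out of the discrete-cosine basis
  functions with frequency below the cut-off ($f_j = j/(2T\,\mathrm{TR})$),
  plus exact DC removal. The original pipeline's running-line filter is not
  specified anywhere reproducible; the DCT projection is deterministic,
  exactly linear and idempotent, and its spectral behaviour is testable
  (a 0.002 Hz sinusoid is attenuated below 10%, a 0.05 Hz one preserved
  above 95%, at $T = 300$, $\mathrm{TR} = 2.5$ s).
* **Spatial smoothing**: separable Gaussian with
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis in mm, *reflective*
  boundaries (preserves the global mean on the small grids used here;
  boundary handling is a declared choice, not inferred). Two sequential
  6 mm passes compose to an effective $\sqrt{72} \approx 8.49$ mm, the
  "~8 mm" composite smoothness the pipeline targets; the fitted impulse
  response verifies this within 2%.

# Group inference

Voxelwise group statistics on the subject maps use nonparametric
max-cluster-size FWE control:

* The observed t (contrast) or partial-F (2×2 interaction) map is
  thresholded at the **cluster-forming threshold**; suprathreshold voxels
  are grouped into connected components (26-connectivity by default; 6 and
  18 available). The threshold is *not reported* in the source analyses,
  so it is an explicit parameter, defaulting to the parametric null
  quantile at one-sided $p < 0.01$ — published cluster sizes can therefore
  not be reproduced exactly even in principle, and are not targets.
* **Nuisance covariates** (age, gender) are handled by Freedman–Lane
  permutation: residuals of the reduced (nuisance-only) model are permuted,
  the nuisance fit is added back, and the full model is refit. This is the
  standard behaviour of the permutation tool referenced by the original
  analysis, which itself does not spell the scheme out.
* Each cluster's $p_{\mathrm{FWE}} = (1 + \#\{\mathrm{null} \ge
  \mathrm{obs}\}) / (1 + n_{\mathrm{perm}})$ against the permutation null
  of the maximum cluster size. In exhaustive mode (all distinct two-group
  relabellings, identity included) the exact enumeration proportion is
  reported instead; for $n = 3$ vs $3$ the 20 relabellings are checked
  exactly against an independent enumeration.
* Two one-sided contrasts (A>B, B>A) get separate runs and null
  distributions; **Bonferroni** correction across systems × contrasts is a
  separate explicit step (`bonferroni_adjust()`).
* Default 5000 permutations; reduced counts (with a warning below 100) are
  used at desk scale. FWE calibration is verified by simulation: with no
  planted effect, the rejection rate over 200 synthetic cohorts must fall
  inside the exact binomial 95% band around 0.05.

# Clinical statistics

* **Responders**: percent analgesia $= 100(\mathrm{VAS}_{\mathrm{base}} -
  \mathrm{VAS}_{\mathrm{post}})/\mathrm{VAS}_{\mathrm{base}}$; responder iff
  $\ge 20$%. Baseline may be the average of three repeated pre-treatment
  measurements (`average_baseline_vas()`), the design used to damp
  regression to the mean.
* **Adjusted group tests**: `value ~ group + age + gender`; the group t and
  the omnibus model F (with $(p, n-p-1)$ df) are both reported because
  published tables quote either convention; the single-df contrast F is
  $t^2$.
* **Bayes factors**: the two-sample t-test BF uses the JZS prior (Cauchy
  scale $1/\sqrt2$ on the standardized effect — the cited software's
  default), computed by adaptive quadrature of the $g$-prior mixture; the
  correlation BF uses a stretched-beta prior of width 1 (uniform on
  $(-1,1)$) with the exact sampling density of $r$ (series-summed Gauss
  hypergeometric factor). Both are validated against independently coded
  fixed-grid quadrature to $10^{-6}$. Because the Bayesian t-test has no
  covariate machinery, the package's convention is to run it on the same
  values as the frequentist test (optionally covariate-residualized by the
  caller); how the original analyses handled covariates in the Bayesian
  arm is unstated.
* **Evidence bands**: the conventional Lee–Wagenmakers labels, regularized
  to the non-overlapping partition $(0, 1/10]$, $(1/10, 1/3]$, $(1/3, 1)$,
  $[1, 3)$, $[3, 10)$, $[10, \infty)$ of $\mathrm{BF}_{01}$ (the printed
  scheme's bands overlap at their edges).
* **Post hoc simple effects** after a significant arm × response
  interaction: within-arm covariate-adjusted R-vs-NR contrasts, Tukey
  studentized-range correction treating the four cells as the compared
  family ($p_{\mathrm{adj}} = P(q_{4,\nu} \ge \sqrt2\,|t|)$, always
  $\ge$ the unadjusted p).
* **Levene's test**: ANOVA on absolute deviations from the group mean
  (classical); the median (Brown–Forsythe) centre is available.

# The synthetic-data generator

`make_templates()`, `make_subject_bold()`, `make_cohort()` and
`make_clinical_outcomes()` instantiate the generative model above so every
downstream stage can be tested against known ground truth with no
external data.

**Stated world (defaults).** Grid 24×24×24 voxels at 2 mm (the analysis
resolution of the emulated study, shrunk spatially for desk-scale runtime);
$T = 150$ volumes at $\mathrm{TR} = 2.5$ s (the study's TR; its $T = 300$
halved for runtime); BOLD noise SD 1 against templates scaled to a maximum
of 1; age $\mathcal N(57, 7^2)$ years and a balanced binary gender code,
matching the emulated cohorts' descriptives (used only as nuisance
regressors); K = 4 systems with pairwise template overlap 0.3.

**Templates** are smoothed (8 mm FWHM), rectified Gaussian random fields:
rectification at the 30th percentile guarantees non-negativity and a
genuine zero-density region, and a shared latent field — orthogonalized
across systems so the pre-rectification pairwise correlation equals the
requested overlap exactly — gives receptor-atlas-like covariation. Each
template carries a corner-block reference-region mask so reference masking
is exercised.

**Group effects** multiply the effect system's template-driven signal
component by $1 + \mathrm{effect\_size} \times \mathrm{pattern}(group)$
inside a designated effect mask (by default the 100 highest-density voxels
of the effect system). This shifts the step-2 regression weight — an FC
effect, not a mean-signal effect, which is what the pipeline estimates.
A per-subject Gaussian jitter (SD 0.25) on the amplification makes the
ground-truth FC score vary within groups.

**Clinical outcomes** couple percent analgesia to the ground-truth FC
score: $\mathrm{pct} = \beta_0 + \beta_1 z(\mathrm{FC}) + \eta$, defaults
$\beta_0 = 20$ (the responder threshold, so both labels occur),
$\beta_1 = 15$ percentage points per FC SD, $\eta \sim \mathcal N(0,
10^2)$. Baseline VAS is drawn near 6 ± 1.5 on the 0–10 scale with three
repeated measurements (SD 0.3) whose mean is the working baseline; the
post-treatment VAS is derived from the percent analgesia and clipped to
the scale, and the emitted percent is recomputed from the clipped pair so
the table is self-consistent.

**Reproducibility**: one master seed; per-subject child seeds are derived
by fixed integer arithmetic, so any subject can be regenerated alone. All
generators restore the caller's RNG state.

**What the generator does *not* emulate** — and hence what a green test
does not establish: haemodynamic response shape and autocorrelated
physiological noise spectra (noise is white, optionally spatially
smoothed; the emulated study does not characterize its patients' noise
properties, so white noise is a declared choice); motion and scanner
artifacts; multi-site effects; spatial non-stationarity of the noise.
Passing the calibration test shows the permutation inference is valid
*under this noise model*, not under arbitrary real-data noise (permutation
tests are, however, exact under exchangeability regardless of the noise
spectrum).

# Desk-scale test settings

The acceptance suite fixes the simulation scales stated with each
criterion (16³ or 24³ grids, 200 cohorts × 500 permutations for FWE
calibration, 25 seeds × 250 permutations for the planted interaction).
Where a criterion leaves the series length open, the calibration and
planted-effect cohorts use $T = 60$ volumes — chosen once for runtime on a
single CPU and not revisited; recovery quality at the stated $T = 150$ is
tested separately.

# Known limitations

* No NIfTI I/O: volumes are in-memory arrays with grid metadata (this
  toolchain ships no R NIfTI reader); the CLI exchanges RDS/TSV.
* The spatial step assumes all templates live on one grid;
  `resample_to_grid()` provides trilinear/nearest resampling between
  grids but no nonlinear registration.
* The correlation Bayes factor's series-summed hypergeometric factor
  converges slowly as $|\rho r| \to 1$; inputs are data correlations, so
  this regime is not reached in practice.
* Exact reproduction of the emulated study's printed cluster tables is
  impossible without its external dataset, its full preprocessing stack
  and its (unreported) cluster-forming threshold; the package's claims are
  the tested properties, not those numbers.
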