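---
title: "Multi-site functional-connectivity classification: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-site functional-connectivity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multisitefc)
```

# The problem

Resting-state fMRI functional connectivity (FC) — the Pearson correlation
between region-averaged BOLD time-series — is a candidate imaging biomarker
for disorders without a structural lesion, such as functional neurological
disorder (FND). A linear support-vector machine (SVM) trained on whole-brain
FC features can separate patients from matched healthy controls well within a
single scanner. The scientifically interesting failure mode appears when
several centres pool data: the classifier keeps working when trained and
tested across pooled multi-centre data, but collapses to chance when asked to
generalize to a centre it has never seen, even after per-centre feature
harmonization. `multisitefc` implements that entire analysis pipeline and a
synthetic multi-site cohort generator that reproduces both the success and
the failure, so every stage is testable without patient data.

# The pipeline

For each subject the input is a regions × volumes signal matrix (88 regions
by default, the AAL atlas without cerebellum and pallidum), a 6-parameter
rigid-body motion trace, and white-matter/CSF nuisance signals. The stages
are fixed and run in this order:

1. **Motion QC.** Framewise displacement per volume:
   FD_t = Σ|Δd_x,y,z| + r·Σ|Δθ_x,y,z| with r = 50 mm (rotations converted to
   arc length on a reference sphere; FD_1 = 0). Subjects whose fraction of
   volumes with FD > 0.5 mm exceeds 25% are excluded (strict inequality;
   both thresholds configurable — the original exclusion rule is not
   quantified in the source studies, so it is exposed, never silent).
2. **Matched-pair pruning.** Every exclusion also removes the subject's age-
   and sex-matched partner, keeping the cohort perfectly balanced.
3. **Winsorization + detrending.** Per region, values are clipped at the
   95th percentile and (by default) the mirrored 5th percentile — outlier
   spikes are signed, so symmetric clipping is the default; an upper-only
   switch exists. The least-squares line over time is then removed, slope
   and intercept, so downstream correlations are mean-invariant.
4. **Temporal filtering.** Either a zero-phase (forward–backward)
   Butterworth bandpass at 0.01–0.08 Hz (order 2 by default; zero phase
   avoids phase distortion of cross-correlations), or a wavelet subband
   reconstruction: a maximal-overlap discrete wavelet transform (LA8
   least-asymmetric filter) keeping the detail levels whose nominal band
   [1/(2^(j+1)·TR), 1/(2^j·TR)] overlaps the pass band. At TR = 2 s these
   are levels 2–5. The two modes are not identical filters; on broadband
   AR(1) input their outputs correlate at r > 0.7 (a consistency property
   the tests assert).
5. **Nuisance regression.** Per region, the OLS projection onto
   [intercept, 6 motion parameters, wm, csf] is removed; residuals are
   orthogonal to every regressor by construction.
6. **Featurization.** Pearson correlation matrix → Fisher Z (arctanh, with
   |r| clipped at 1 − 1e−7 so values stay finite) → the strict upper
   triangle vectorized in lexicographic pair order. For 88 regions this is
   88·87/2 = 3828 features per subject.
7. **Site harmonization.** Within each centre, each feature column is
   Z-scored (sample SD, n − 1 denominator) over all subjects of that centre,
   both groups together. This matches how the harmonization is defined for
   the real analysis; note it uses each site's full distribution, so inside
   cross-validation it leaks *distributional* (not label) information from
   test rows. A strict mode recomputes site statistics from training rows
   only (`site_normalize(table, train = ...)`, `normalize = "strict"` in the
   CV functions) and is reported as such.
8. **Classification.** Linear soft-margin SVM (libsvm via e1071), C = 1,
   no feature selection, no hyperparameter search, solver tolerance 1e−6.
   Decision values > 0 predict "patient"; exactly 0 predicts "control" (an
   arbitrary but fixed tie rule). Four evaluation designs: leave-one-out
   within a centre (intra), over the pooled cohort (pooled),
   leave-one-site-out (inter), and a transfer learning curve that moves one
   patient + one control at a time from the held-out site into training
   (seeded random order; a single order is noisy, so repeated seeds and the
   median curve are the supported usage). For a 15-pair held-out site the
   schedule tops out at 28 transferred subjects with 2 remaining.
9. **Inference and post-hocs.** Permutation test: group labels permuted
   uniformly (optionally within site), the full CV re-run each time,
   p = (1 + #{null ≥ observed})/(N + 1) — the +1 form avoids p = 0, since
   the label-permutation scheme leaves the exact formula open. Edge
   importance: per-edge signed median of fold weights, ranked by magnitude
   (deterministic tie-break toward the lower edge index); the median of
   absolute weights is available as an alternative since the aggregation
   behind published "median LOOCV importance" plots is not fully specified.
   Region frequency is the nodal degree within the top-k subgraph (k = 30
   by default). Hyper-/hypo-connectivity direction is computed on
   fisher-stage features — after harmonization the units are site-relative
   SDs and no longer interpretable as connectivity. Per-connection
   group × centre ANOVA (type III, effects coding) with Benjamini–Hochberg
   FDR at 0.05 per effect family quantifies harmonization; a scalar variant
   serves the mean-FD and age diagnostics. A logistic regression of
   classification correctness on anxiety, depression, medication and
   severity (each alone and combined, listwise deletion) checks that
   clinical covariates do not drive performance.

# The generative model of the simulator

Controls at site *s* draw their latent region signal from

  Σ_s = (R_s L)(R_s L)ᵀ + ψ I,

where L is a shared p × q factor-loading matrix (q = max(4, p/6),
entries N(0, 1/q), ψ = 0.4). Patients receive one extra rank-1 loading
column per "truth" edge (i, j): √|δ| at region i and sign(δ)·√|δ| at j,
which changes the covariance by exactly δ at (i, j) (plus the two diagonal
cells) and nothing else. Positive δ makes patients hyper-connected on that
edge. Building covariances as loadings × loadingsᵀ + diagonal guarantees
positive semidefiniteness without eigenvalue surgery.

Time-series are AR(1)-filtered draws from Σ_s (coefficient 0.3, scaled to
preserve the stationary covariance, so correlations are AR-invariant), plus
white observation noise, plus per-region affine offset/scale in arbitrary
signal units. Motion is a mean-reverting random walk with occasional
translation *steps* of configurable magnitude, so each spike's framewise
displacement contribution is analytic (equal to the step size).

Two orthogonal site-effect families are exposed, and the distinction is the
scientific point:

* **Harmonizable ("affine") effects.** Per-site observation noise
  (`noise_sd`, defaults 0.3/0.7/1.1/0.9) attenuates every correlation of a
  site by a site-deterministic factor, and per-site offset/scale change the
  signal units. Note that per-region affine transforms are mathematically
  invisible to Pearson correlation — they exercise the preprocessing, while
  the noise level is what actually shifts the feature distributions. All of
  these produce per-edge site shifts that per-site Z-scoring removes
  exactly.
* **Non-harmonizable ("mixing") effects.** A site-specific orthogonal
  rotation R_s (composed seeded Givens rotations whose angles scale with
  `mixing_strength` ∈ [0, 1]) is applied to the loadings — including the
  patient effect columns. The group difference therefore lives on
  *different edges at different sites*. No per-edge transformation can
  align them, which is why leave-one-site-out collapses while pooled CV
  (which always sees same-site training subjects) keeps working, and why
  transferring held-out-site subjects into training restores performance.

Default acquisition geometry mirrors a four-centre 3T study: TR 2 s
everywhere, 150/150/300/225 volumes, 23/24/24/15 patient–control pairs
(a 172-scan cohort). Covariate defaults (anxious, mildly depressed,
roughly half-medicated patients; 2–17% missingness per covariate; severity
recorded for patients only) are loosely patterned on mixed FND cohorts.
All of it is overridable per site or per cohort.

**Calibration.** Where no quantitative description of the real sites'
covariance geometry exists, parameters were fixed once for qualitative
reproduction: a latent effect of δ = 0.25 on 10–20 edges gives pooled
LOO accuracies in the realistic 80–95% range at 20 subjects/site, and
mixing strengths around 0.3–0.6 push leave-one-site-out into the binomial
chance band while pooled CV stays high. These are the documented study
conditions used by the tests and the acceptance script; they were not
revisited afterwards.

# What the simulator does and does not emulate

It reproduces the *statistical situation*: balanced matched pairs across
sites with distinct acquisition lengths and noise levels, a sparse group
effect in covariance, site effects of both removable and non-removable
kinds, motion spikes, and partially missing covariates. It does not model
hemodynamics, spatial structure, physiological noise spectra, realistic
artifact physics, or any clinical covariate–connectivity coupling. Passing
tests therefore demonstrate that the *pipeline* behaves correctly under
known ground truth — not that real FND patients are classifiable at any
particular accuracy.

# Numerical choices and degenerate inputs

* Fisher clipping at 1 − 1e−7 keeps transformed values finite yet extreme.
* Constant regions: an error at correlation time (named region), zeros after
  detrending; zero-SD feature columns are set to 0 with a warning during
  harmonization.
* Collinear nuisance regressors are dropped with a warning (QR pivoting).
* The SVM orientation is normalized so that the patient class is always on
  the positive side regardless of label order in the training data.
* Motion exclusion uses strict inequality: a subject exactly at the policy
  limit is kept.
* ANOVA engine: type-III sums of squares via projection/RSS comparison under
  effects coding, vectorized over features; equals `car::Anova(type = 3)`
  (and type I on balanced designs), which the tests assert.
* Permutation p-values use (1 + b)/(1 + N). With small cohorts the accuracy
  statistic is discrete and tied, so the test is mildly conservative — the
  calibration test tolerates rejection rates in [0.02, 0.08] at α = 0.05.

# Problem sizes used by tests and the acceptance script

Simulation-backed checks run at reduced scale, chosen as the smallest sizes
at which the phenomena are stable across seeds: 30–32 regions
(435–496 edges) and 10 pairs/site for the harmonization and generalization
experiments; the recovery experiment runs at the full 88 regions
(3828 features) with 10 pairs/site; permutation calibration uses 20-subject
null cohorts with 99 permutations and 200 replicates.

# Known limitations

* The wavelet subband filter is a dyadic-band approximation of the 0.01–0.08
  Hz bandpass, not an equivalent filter; consistency, not equality, is
  asserted.
* The harmonization's default ("full") mode computes site statistics on full
  sites, which is how the method is defined but leaks test-set distributional
  information inside CV; the strict mode is provided and flagged.
* Whether the original analysis winsorized one- or two-sided, its exact
  motion-exclusion threshold, and the permutation scheme's site stratification
  are unstated in the source material; all are explicit configuration with
  documented defaults rather than silent guesses.
* Statistical power of the per-edge ANOVA at 20 subjects/site is limited;
  the site-effect counts before harmonization depend on the configured
  noise-level spread.
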