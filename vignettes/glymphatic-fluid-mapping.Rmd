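---
title: "Mapping glymphatic fluid with multi-echo T2, free-water DTI and PVS morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping glymphatic fluid with multi-echo T2, free-water DTI and PVS morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The glymphatic system clears metabolic waste — including beta-amyloid — from
brain parenchyma through perivascular spaces (PVS). Three MRI measures probe
the fluid in this pathway at different specificity: the parenchymal CSF
fraction (pCSFF) from multi-echo T2 relaxometry, the isotropic free-water
fraction (DTI-FW) from two-shell diffusion MRI, and the volumetric PVS burden
(PVS/WMV) from structural morphometry. `glymap` implements all three, puts
them on a common absolute scale via tissue total water content (TWC), and
provides the comparative statistical battery used to relate them to amyloid
PET uptake (SUVR) and clinical covariates. Because no raw human data ship
with the package, a synthetic multi-compartment brain phantom and cohort
generator make every stage testable end to end against known ground truth.

## Models

**Three-pool T2 relaxometry.** The T2prep signal at preparation time $t$ is

$$S(t) = M_0\left[f_{mw}e^{-t/T_{2,mw}} + f_{ie}e^{-t/T_{2,ie}} +
f_{csf}e^{-t/T_{2,csf}}\right],$$

with myelin water (short T2), intra/extra-cellular water (intermediate T2)
and parenchymal CSF (long T2, 200–2000 ms). pCSFF is $f_{csf}$. Sampling
uses the six T2prep times 0, 7.5, 17.5, 67.5, 147.5 and 307.5 ms (the first
echo has the preparation off, so $S(0)=M_0$). Fitting minimizes
$\lVert S_{model}-S_{data}\rVert^2 + \lambda\lVert f - f_{prior}\rVert^2$
under nonnegativity, by Levenberg–Marquardt with box bounds and three
deterministic starts (prior-weighted, CSF-heavy, MW-heavy).

**Bi-tensor free water.** The diffusion signal is
$S = S_0[(1-f)\,e^{-b\,g^\top D g} + f\,e^{-b\,d_{iso}}]$ with a tissue
tensor $D$ and an isotropic pool at $d_{iso}$. The tensor is parameterized
by its Cholesky factor (positive semi-definiteness without constraints),
initialized from a log-linear single-tensor fit with $f_0 = 0.1$. Two
distinct nonzero shells are required; the model is not identifiable from a
single shell and the fit refuses such input rather than resorting to
spatially regularized schemes.

**PVS morphometry.** The enhanced PVS contrast (EPC) is the T1w/T2w ratio;
PVS appear dark on it. Multi-scale Frangi vesselness (Hessian eigenvalues
$|\lambda_1|\le|\lambda_2|\le|\lambda_3|$, ratios $R_A=|\lambda_2|/|\lambda_3|$
and $R_B=|\lambda_1|/\sqrt{|\lambda_2\lambda_3|}$, structureness $S$) scores
tubular structure; the thresholded map is restricted to WM, WMH-excluded and
cluster-pruned, and the burden is $100\cdot|PVS|/|WM|$.

**Calibration and quantification.** Water-*fraction* maps become absolute
fluid fractions of tissue volume through constant TWC: 83% in GM, 70% in WM
(pCSF = pCSFF × TWC; FW the same way). ROI values are arithmetic voxel
means with WMH excluded from WM ROIs; SUVR is the mean uptake in the
cortical AD meta-ROI over the cerebellar reference mean.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| pool T2 (mw/ie/csf) | 20 / 80 / 2000 ms | literature compartment values; CSF T2 fixed because a 307.5 ms sampling window cannot resolve T2 ≫ window |
| pool T2 bounds | 5–40 / 40–200 / 200–2000 ms | used when `fit_pool_t2s = TRUE` |
| $\lambda$ | $0.01\,\lVert S\rVert^2$ | stabilizes the ill-posed long-T2 estimate; small deliberate shrinkage toward the prior (0.10, 0.85, 0.05) |
| $d_{iso}$ | $3.0\times10^{-3}$ mm²/s | body-temperature free water |
| b-values | 1500, 3000 s/mm², 49 directions/shell | the study's two-shell protocol |
| Frangi $\alpha,\beta,c$ | 0.5, 0.5, auto (half max Frobenius norm) | classical defaults; `c` from the WM ROI when one is given |
| scales | 0.5, 1.0, 1.5 mm | spans 1–3 voxel tube radii at 1 mm isotropic |
| threshold / min cluster | 0.2 / 2 voxels (26-connectivity) | small oblique tubes fragment under 6-connectivity |
| TWC | 0.83 GM / 0.70 WM | literature constants |
| Shapiro–Wilk gate | $\alpha = 0.05$ | per-group normality gate choosing t-test vs Wilcoxon |

## Design choices that were genuinely open

**Fixed pool T2s by default.** With six echoes, jointly estimating the MW/IE
T2s and the fractions is barely identifiable: the optimizer provably reaches
the global optimum, yet the strong $f_{csf}$–$T_{2,ie}$ trade-off inflates
the pCSFF error to ~0.012 (mean absolute, SNR 100) versus ~0.007 when the
pool T2s are held at their literature values. Few-echo multicompartment T2
mapping conventionally fixes the compartment T2s, so that is the default
here (`fit_pool_t2s = TRUE` restores bounded T2 estimation). Both modes
recover noise-free data generated at the default T2s exactly.

**Regularization target.** The L2 penalty acts on the fraction vector's
deviation from a prior, not on amplitudes or T2s: the long-T2 fraction is
the ill-posed quantity. The default weight leaves a shrinkage bias of order
$10^{-3}$ on noise-free data — validation tests that assert exact recovery
set $\lambda = 0$ explicitly.

**WM-windowed vesselness.** The structureness constant `c`, when automatic,
is half the maximum Hessian Frobenius norm. On a whole head this maximum
comes from ventricular and cortical boundaries, an order of magnitude above
any tubule response, which crushes the filter inside WM. Since PVS
segmentation is WM-restricted by definition, the filter accepts a ROI: the
volume is padded with the ROI median outside it and `c` is taken within it.
On the phantom this recovers the analytic tubule burden exactly.

**SUVR construction in the cohort model.** Each subject's SUVR truth is the
group mean plus `slope_pcsf_suvr` times the subject's WM pCSF deviation plus
an independent residual whose variance tops the group SD up to its target —
so a positive pCSF→SUVR association exists by construction and the total SD
still matches the design.

## What the synthetic data emulate — and what they do not

The phantom is a concentric-shell brain (GM rind, WM shell, ventricular CSF
core) on a shared 1 mm isotropic RAS grid with identity registration between
modalities. It carries analytic ground truth: per-voxel three-pool fractions
(WM default 0.12/0.83/0.05, GM 0.03/0.92/0.05), a WM diffusion tensor with
eigenvalues (1.5, 0.4, 0.4)×10⁻³ mm²/s, free-water truth (0.36 WM / 0.15
GM), one straight-cylinder PVS tubule and one spherical WMH lesion embedded
in WM, and GM sub-ROIs for the AD meta-ROI and cerebellar reference. MR
magnitude series get Rician noise with $\sigma = S(0)/\mathrm{SNR}$;
structural and PET volumes get Gaussian noise. Cohorts draw subject
biomarker truths from the two diagnostic groups' normal distributions (16 NL
/ 13 MCI-AD by default, with the study's group means and SDs) and rescale
each subject's phantom fraction fields so the WM ROI mean equals the drawn
truth.

Deliberately absent: realistic anatomy and partial-volume mixing, B1/flip
errors, stimulated echoes, eddy/susceptibility distortion, registration
error, PVS tortuosity, and heterogeneous lesion intensities. Passing tests
therefore demonstrate correctness of the estimators and pipeline logic under
the stated forward models — not robustness to acquisition artefacts of real
scanners. One consequence worth naming: the phantom's PVS burden is fixed by
its geometry, so the cohort's drawn PVS/WMV truths are exercised at the
statistics level, not through per-subject tubule geometry.

## Numerical choices

Degenerate inputs follow explicit conventions: all-zero voxels are flagged
fit failures carrying the prior fractions; the all-zero tensor has FA 0;
fully free-water voxels (ventricles) leave the tissue tensor on a flat
objective ridge, so the fitted $f$ there is reported but not meaningful —
WM-restricted ROI statistics never touch them. Multi-start ties break by
lowest objective, then lexicographic parameter order. Hessians use separable
convolution with analytic Gaussian-derivative kernels (radius $4\sigma$,
replicated edges) and $\sigma^2$ scale normalization; symmetric 3×3
eigenvalues use the vectorized trigonometric closed form with clamping.
Wilcoxon tests are exact up to total n = 20, then normal approximation with
tie and continuity correction; the 2×2 chi-square uses Yates correction by
default (the uncorrected variant is a flag). Tables report percent with two
decimals; percent increases round to one decimal.

## Problem sizes used by the tests

Unit tests run on 16³ phantoms (≈1500 brain voxels) with reduced direction
sets (8–24 per shell); the morphometry and acceptance checks use the full
32³ phantom and the 98-direction protocol. Monte-Carlo recovery uses 500
replicates per condition (SNR 100 for relaxometry, SNR 40 for free water),
and the power analysis 100 replicate cohorts of 200 subjects, analysed at
the biomarker level. The full suite and the acceptance script each complete
in a few minutes on one CPU.

## Known limitations

- Rician bias is documented, not corrected: the Gaussian-likelihood fits are
  valid at SNR ≳ 20 and show a small positive floor bias at low SNR.
- The Frangi pathway is a classical stand-in for trained PVS segmentation
  networks; it reproduces the analytic phantom but will under-segment faint
  or tortuous PVS in real data.
- Registration is identity by construction; real multi-modal data need
  coregistration upstream of this package.
- The default $\lambda$ trades a ~0.1 percentage-point prior bias in pCSFF
  for noise robustness; set it to zero for bias-critical validation work.
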