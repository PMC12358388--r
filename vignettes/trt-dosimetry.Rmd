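---
title: "Methods: pre-treatment TRT dosimetry from dynamic PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pre-treatment TRT dosimetry from dynamic PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trtdose)
```

# The model

## Kinetics

A radiolabeled ligand exchanging between arterial blood, a free tissue pool
and a bound pool follows the standard two-tissue compartment model with
rates $K_1$ (mL·min⁻¹·g⁻¹, blood→tissue), $k_2$, $k_3$, $k_4$ (min⁻¹).
Because the therapeutic nuclide decays on the same time scale as it clears,
the model is extended with the physical decay constant $\lambda$ applied to
both tissue pools. The impulse residue function is then a biexponential,
$R(t) = G e^{-\alpha t} + H e^{-\beta t}$, whose rates are $\lambda$ plus
the eigen-rates $\theta_{1,2} = \tfrac12[(k_2+k_3+k_4) \mp
\sqrt{(k_2+k_3+k_4)^2 - 4k_2k_4}]$ of the compartmental system and whose
amplitudes satisfy $G + H = K_1$. The discriminant is
$(k_2-k_4)^2 + k_3^2 + 2k_3(k_2+k_4) \ge 0$, so the rates are always real;
the repeated-root case ($k_3 = 0$, $k_2 = k_4$) is handled by the analytic
limit $(K_1 + Ct)e^{-\alpha t}$, triggered when the discriminant falls below
$10^{-12}(k_2+k_3+k_4)^2$. These closed forms are validated in the tests
against fixed-step RK4 integration of the compartment ODEs — the exact
amplitude expressions are a reconstruction, so the ODE oracle, not a printed
formula, is the authority.

The time integral of $R$,
$$\mathrm{AUC}(R) = \frac{K_1 (k_4 + k_3 + \lambda)}
{k_2 k_4 + (k_2+k_3+k_4)\lambda + \lambda^2},$$
reduces as $\lambda \to 0$ to the Logan distribution volume
$\mathrm{LDV} = K_1/k_2\,(1 + k_3/k_4)$. For ¹⁷⁷Lu
($T_{1/2} = 6.67$ d, $\lambda = 7.2\times10^{-5}$ min⁻¹) the difference is
below 1 % for any plausible tissue rates — this is the approximation that
lets a diagnostic-tracer measurement stand in for the therapy nuclide's
residence integral. Irreversible binding ($k_3>0$, $k_4=0$, $\lambda=0$) has
infinite residence and is reported as an explicit error, not a number.

## Logan graphical analysis

Plotting $\int_0^t \mathrm{TAC}/\mathrm{TAC}(t)$ against
$\int_0^t C_a/\mathrm{TAC}(t)$ yields, after a quasi-equilibrium delay
$t_0^*$, a straight line with slope equal to the distribution volume. Per
voxel we fit ordinary least-squares lines for every candidate delay — the
frame mid-times inside a 2.33–8 min window; the data are frame-discrete, so
a finer grid adds nothing — and keep the maximum-$R^2$ fit, ties resolved
toward the earliest delay. Two usable points give $R^2 = 1$ by convention
and are flagged. The slope (mL blood per mL tissue) is divided by the voxel
density to give mL/g; this conversion is a config flag
(`divide_by_density`), since the printed unit convention does not state it.

Numerical choices worth recording:

* **Quadrature.** Cumulative integrals use the trapezoid rule on each
  curve's native grid, measured from $t=0$ by extending the first sample
  (a frame average) back to the origin. With the arterial curve extracted
  frame-wise from the image (as the pipeline does), tissue and arterial
  integrals share one quadrature, and the proportional-curves identity
  $\mathrm{TAC} = V\,C_a \Rightarrow Y = VX$ holds exactly.
* **Positivity floor.** The transform divides by TAC; frames at or below
  $\max(\epsilon, 10^{-3}\times\text{voxel peak})$ are excluded and
  recorded. Voxels with fewer than two usable frames at every delay are
  flagged unanalyzable, never silently zeroed.
* **Unweighted OLS**, consistent with the graphical method as commonly
  practiced; the per-voxel fits are vectorized closed-form sums,
  property-tested against `lm()`.
* Frame **mid-times** are used for the delay comparison (end-times would be
  defensible too; mid-times match the frame-averaged sample semantics).

## Arterial input

The arterial curve is the mean over an artery mask, one sample per frame
(no partial-volume correction; the modeled vessel is ≥ 10 mm across against
~5 mm scanner resolution). The fitted model is a linear rise from bolus
arrival to the peak sample and a sum of $n$ decaying exponentials from the
peak; $n = 2$ by default — three exponentials are not identifiable on 28
frames of 22 minutes. Fitting is multi-start (16 deterministic starts,
log-spaced rate guesses, Nelder–Mead then BFGS polish, best RSS wins, ties
to the lower start index), so results are reproducible without a random
seed.

The therapy-scaled arterial AUC removes the measured tracer's decay
($e^{+\lambda_d t}$), applies the therapy nuclide's ($e^{-\lambda_t t}$),
scales by the administered-activity ratio, and integrates the piecewise
model analytically — zero segment, linear rise (closed-form
$\int (a+bt)e^{-qt}$), exponential tail — to a horizon of five effective
half-lives, $1/T_\mathrm{eff} = 1/T_\mathrm{phys} + 1/T_\mathrm{bio}$ with
$T_\mathrm{bio}$ from the slowest fitted clearance after removing the
diagnostic nuclide's decay. Whether the published arterial AUCs include
therapy-nuclide decay over the horizon is not stated in the source
material; this package's convention (decay swapped, as above) is exposed so
a different convention is one wrapper away, and a configurable population
terminal rate (`r_pop`) can replace the slowest fitted rate beyond the scan
window.

## Dose engine

Voxel TIA is $\mathrm{LDV} \times \rho \times v \times
\mathrm{AUC}_\mathrm{ther}$ (mL/g × g/mL × mL × Bq·s/mL = Bq·s). Negative
or unanalyzable LDV voxels contribute zero and are counted. Two engines
convert TIA to absorbed dose:

* **local**: all electron energy (0.1479 MeV/decay for ¹⁷⁷Lu, from the
  bundled versioned constants file) deposited in the source voxel,
  $D = \mathrm{TIA}\cdot E_e / m$.
* **kernel**: the electron energy spread over neighbours by a voxelized
  radial dose-point kernel, normalized to unit energy, then divided by
  local voxel mass (denser voxels receive proportionally less dose). The
  bundled kernel profile is labeled *synthetic*: it has the shape and
  ~2 mm practical range of a ¹⁷⁷Lu beta kernel in water but is not a Monte
  Carlo tabulation. Conservation is enforced by construction and asserted
  in tests (energy imparted = energy emitted within 0.5 % for a contained
  source; central dose in a uniform medium equals local mode within 1 %).

Full Monte Carlo transport is deliberately out of scope. A consequence
worth stating plainly: published patient dose magnitudes obtained with
Monte Carlo pipelines are treated as *table-consistency* targets (their
summary statistics are reproduced from the printed per-patient values), not
as transport-accuracy targets — indeed the printed arterial AUC and LDV
values, pushed through energy conservation, give voxel doses orders of
magnitude below the printed Gy values, so absolute-dose reproduction from
the printed inputs is not attainable by any kernel- or MC-based engine.
The photon component (0.0334 MeV/decay) is ignored in local mode and
flagged in provenance.

The CT-to-density calibration is two-segment piecewise linear — air
(−1000 HU → 0.001 g/mL) to water (0 HU → 1.0) and a bone segment of
0.0006 (g/mL)/HU above water (1000 HU → 1.6) — clipped to [0.001, 3.0].

## Radiobiology

For a mono-exponentially decaying dose rate truncated at treatment time
$T_t$, with first-order repair rate $\mu$, the Lea–Catcheside protraction
factor has the closed form given in the README; it equals the brute-force
double integral of its definition (the tests sweep $\lambda \in
[0.01, 0.5]$ d⁻¹, $\mu \in [1, 50]$ d⁻¹, $T_t \in [5, 100]$ d at $10^{-5}$
relative tolerance). The closed form requires $\mu > \lambda$; otherwise
the numeric route is used with a warning. Defaults: $\lambda = 0.103$ d⁻¹
(taken directly rather than recomputed from the half-life, to match the
published arithmetic), $\mu = 11.09$ d⁻¹ (1.5 h repair half-time),
$T_t = 33.5$ d, $T_k = 56$ d, $T_p = 250$ d, $\alpha = 0.217$ Gy⁻¹,
$\alpha/\beta = 3$ Gy, one set for tumor and normal tissue alike. At these
values $G = 9.805\times10^{-3}$.

**Repopulation clamp.** The BED expression as printed in the source
material, $\mathrm{BED} = D(1 + DG/(\alpha/\beta)) -
\ln 2\,(T_t - T_k)/(\alpha T_p)$, would *add* dose when $T_t < T_k$
(33.5 < 56 days: repopulation never started). We clamp the term at zero:
$\max(0, T_t - T_k)$. The clamped form reproduces the published femur BED
values (11.0 → 11.4 Gy, 5.3 → 5.4 Gy; whole-column deviation ≤ 0.15 Gy
from printed-input rounding); the unclamped form gives 11.1 and 5.1 and
does not. Voxel-level repopulation for normal versus tumor tissue is moot
under the clamp for $T_t < T_k$; multi-cycle extensions would need an
explicit decision.

BED maps apply the scalar formula voxel-wise; since the quadratic term is
convex, an ROI's mean BED is ≥ BED of its mean dose (asserted via Jensen's
inequality on heterogeneous regions). DVHs are cumulative volume fractions;
ROI statistics use sample SD ($n-1$), COV = 100·SD/mean (missing when the
mean is zero), and even-$n$ medians as central-order-statistic midpoints.

# The phantom: what a green test establishes

`make_phantom()` builds a 64×64×20 (default; 128×128×47 at "paper scale")
digital pelvis: soft-tissue background, a prostate ellipsoid with an
embedded tumor sphere, two femoral-marrow cylinders, and a 12-mm arterial
cylinder. Tissue LDVs are 3.0 (tumor), 1.5 (prostate), 0.30 (marrow),
0.8 (background) mL/g — inside the clinically reported ranges
(2.03–5.38, 1.17–1.67, 0.26–0.36). The acquisition is the clinical 28-frame
22-min schedule.

Choices a reader should know about:

* **Fast microparameters.** The rate constants (e.g. tumor $K_1 = 3.36$,
  $k_2 = 2.8$ min⁻¹) are deliberately faster than literature
  microparameters for PSMA ligands. At literature-scale rates the tissue
  does not reach quasi-equilibrium within 22 minutes and the Logan slope
  underestimates LDV by ~30 % — no analysis code can fix that; it is a
  property of the acquisition. The published near-perfect linearity
  ($R^2 \approx 0.99997$) presupposes the fast-equilibration regime, so
  the phantom realizes that regime: macroparameter (LDV) realism is kept,
  microparameter realism traded. The scaling was fixed once, from a scan
  of LDV-preserving rate multipliers, before the acceptance assertions
  were frozen.
* **Arterial model.** Bolus arrival 15 s, peak 30 s, bi-exponential tail
  (20 000 Bq/mL at 0.35 min⁻¹ + 1 500 Bq/mL at 0.03 min⁻¹ for 325 MBq
  injected). Chosen once so the therapy-scaled AUC (≈ 1.67×10⁸ Bq·s/mL at
  7.4 GBq) lands inside the clinically reported (1.0–2.0)×10⁸ range.
* **Noise.** Zero-mean Gaussian, variance proportional to activity over
  frame duration (a post-reconstruction approximation — the source images
  are OSEM reconstructions and no projection-domain model is claimed),
  scale `noise_level = 5` ≈ 1–3 % on late-frame tissue activity. All
  randomness derives from the spec seed; equal seeds give bit-identical
  studies.
* **Static uptake image.** Tumor segmentation in the clinic uses a
  ~60-min static PSMA image, whose tumor-to-prostate contrast (SUV ratios
  ~6–8) exceeds the 22-min equilibrium contrast (LDV ratio 2:1). The
  phantom therefore carries a synthetic static `uptake` volume —
  equilibrium uptake with a tumor binding-avidity factor of 4 — for the
  30 %-of-max isocontour. On the dynamic equilibrium contrast alone a 30 %
  threshold would select the entire prostate; that is a property of the
  threshold rule, not of the segmentation code.
* **Not emulated:** scanner PSF, attenuation, scatter, reconstruction
  artifacts, motion, inter-voxel kinetic heterogeneity within a tissue.
  A green recovery test therefore establishes the *analysis chain's*
  correctness (transform, fit, delay selection, unit plumbing, scaling),
  not robustness to resolution effects the generator does not produce.

Noiseless end-to-end recovery is within 2 % for every tissue (actually
≤ 0.5 %); the residual is quadrature discretization on 28 frames, not model
error. With default noise, uniform-region median LDV stays within 5 %.

# Infrastructure decisions

* **NIfTI-1 I/O** is a minimal built-in reader/writer (float32, single
  file, diagonal sform): no NIfTI package is available in the target
  environment, and maps/studies needed a standard on-disk form. It is
  round-trip tested, and not a general NIfTI library.
* **Configs and sidecars are JSON** (`jsonlite`); the external-interface
  contracts allowed YAML or JSON and no YAML parser is available in the
  target environment.
* **Printed-table statistics**: report tables round half away from zero at
  one decimal, with full-precision CSVs always written alongside. Two
  published summary cells (a cohort SD of 36.2 and a median of 2.74)
  appear truncated rather than rounded from the per-patient values; tests
  compare those at printed precision instead of asserting the rounding.

# Known limitations

The diagnostic and therapeutic ligands are assumed pharmacokinetically
identical — the central untested clinical assumption of the method itself.
Bladder and rectum cannot be handled (their TACs are excretion-driven, not
compartmental). The kernel engine has no tissue-specific cross sections and
no photon transport by default. Single-cycle only; no dose accumulation
across cycles.
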