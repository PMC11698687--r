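---
title: "Mapping placental immune cellularity from diffusion MRI: model, simulator, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping placental immune cellularity from diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The placenta mediates between the maternal and fetal immune systems, and
immune-cell infiltration (villitis, chorioamnionitis, and related
pathologies) is currently diagnosed only from post-delivery histology.
Diffusion-weighted MRI offers a safe, longitudinal window: water inside
small cells is strongly restricted, so the fraction of slowly diffusing
water in a voxel tracks cellularity. The exploitable contrast in the
placenta is cell size. Immune cells (T, NK, B cells, neutrophils,
dendritic cells, macrophages) are at most ~8 µm in radius, whereas
placental resident cells — cytotrophoblasts, syncytiotrophoblast,
decidual stromal cells — are several times larger. A small impermeable
sphere depresses the apparent diffusion coefficient (ADC) far more than a
large one at fixed diffusion time, so "restricted, but only mildly" and
"restricted hard" separate immune from resident cells spectrally.

This package implements that idea end to end:

1. a **spectrum decomposition** of the diffusion signal (`fit_voxel`,
   `fit_volume`) with a restricted-fraction **cellularity ratio**
   (`cellularity`);
2. a **Monte Carlo validation engine**: histology-like substrates
   (`build_geometry`), impermeable random walks (`simulate_walkers`),
   pulsed-gradient spin-echo (PGSE) signal synthesis
   (`synthesize_signal`), Rician noise (`add_noise`), and an analytic
   Gaussian-phase-distribution oracle (`gpd_sphere_adc`);
3. **synthetic data generators** for density maps, simulated
   acquisitions, and a two-group longitudinal cohort;
4. the **validation and group statistics** (regression with confidence
   bands, Wilcoxon rank-sum, patch aggregation, longitudinal summaries).

## The signal model

For measurement $k$ with b-value $b_k$ and unit gradient direction
$\hat g_k$, the normalized signal is modelled as a non-negative linear
combination of anisotropic tensor atoms and an isotropic ADC spectrum:

$$S_k=\sum_{i=1}^{N_{aniso}} f_i\,
  e^{-b_k\lambda_{\perp i}}\,
  e^{-b_k(\lambda_{\parallel i}-\lambda_{\perp i})\cos^2\phi_{ik}}
  +\sum_{j=1}^{N_{iso}} f_j\, e^{-b_k D_j},$$

where $\phi_{ik}$ is the angle between atom direction and gradient, and
all diffusivities are in µm²/ms (1 µm²/ms = 10⁻³ mm²/s; $b$ in s/mm²
carries the 10⁻³). The **cellularity ratio** is the normalized sum of
isotropic fractions with $D_j$ in the *restricted window*
$[0.01, 0.6]$ µm²/ms, inclusive at both ends. The upper edge is anchored
physically: an 8 µm impermeable sphere filled with water at
$D_0 = 2$ µm²/ms, probed at $\Delta = 16$ ms, $\delta = 7$ ms, has an
apparent diffusivity of ≈ 0.6 µm²/ms — reproduced independently by the
package's own Monte Carlo engine and its Murday–Cotts closed form.
Fractions below 0.01 (including the $D = 0$ atom) are excluded from the
window; the window is exposed in configuration.

### Dictionary

The isotropic grid has 40 atoms: 0, then log-spaced from 0.01 to
3.0 µm²/ms, with 0.01, 0.6 and 3.0 snapped exactly on-grid so the window
edges are exact. Finer grids only add unidentifiable columns; coarser
ones quantize the window edge.

### Anisotropic stage

Placental tissue is predominantly isotropic, so the package fits at most
one axially symmetric anisotropic atom per voxel: the principal direction
comes from a conventional log-linear tensor fit, a coarse
$(\lambda_\parallel, \lambda_\perp)$ grid is scanned, and the atom is
kept only if it improves the relative residual by more than 2%. A full
multi-direction basis search is out of scope by design.

## Solving the spectrum: the two regularization regimes

The inverse problem is a non-negative least-squares (NNLS) fit of
near-collinear exponentials — a classically ill-posed problem. Two facts
measured during development drive the design:

* **Noiseless, on-grid data.** Exact recovery (restricted fraction to
  < 0.02) is possible *only* with no ridge at all: Tikhonov weights as
  small as $10^{-4}$ shift mass along near-degenerate spectral
  directions and produce window errors up to 0.27. It also requires a
  b-value ladder: with only 3 distinct shells the isotropic design
  matrix has 4 distinct rows and 40 columns, and window fractions are
  unidentifiable even with exact data. `fit_voxel` therefore defaults
  to `reg_lambda = 0`, and `make_scheme` defaults to 10 shells.
* **Noisy or model-mismatched data.** For Monte Carlo region signals
  with Rician noise, an unregularized fit is noise-dominated, while a
  fixed ridge of $0.01\,\lVert A\rVert_2$ — identical for every voxel,
  so its smoothing bias is common mode and cancels in regressions and
  group contrasts — restores a stable restricted fraction. The
  validation and mapping workflows (`fit_validation_set`, `cmd_fit`,
  `cmd_validate`) use this `dbsi_reg_default()` weight. A
  noise-adaptive (discrepancy-principle) weight was evaluated and
  rejected: the per-voxel noise estimate from 8 b0 replicates is itself
  noisy, and the resulting voxel-to-voxel variation in smoothing bias
  destroys the across-region regression it was meant to help.

The Lawson–Hanson solver is implemented in-package (no NNLS library is
available in the target environment) and was cross-checked against
`scipy.optimize.nnls` on identical matrices. One numerical detail
matters at this conditioning: a candidate variable whose trial
coefficient comes back non-positive must be excluded for the current
pass, not treated as convergence.

Mass placed on adjacent grid atoms is aggregated by window membership
only — no peak-picking. Point-wise fraction estimates on a 40-atom
exponential grid are not identifiable; window sums are.

### Acquisition schemes

`scheme_ex_vivo()` (86 weightings + 8 b0, b-max 4500 s/mm²,
$\Delta/\delta = 16/7$ ms) uses three strong shells (1500/3000/4500):
at these weightings free and hindered water are essentially fully
attenuated, which concentrates the information in exactly the window the
cellularity statistic needs, and measurably improves the end-to-end
validation accuracy over a 10-shell ladder at matched SNR.
`scheme_in_vivo()` (b-max 900 s/mm², $\Delta/\delta = 32/16$ ms) and the
generic `make_scheme()` default to the 10-shell ladder, which is what
arbitrary-spectrum recovery needs. The direction set is an
electrostatic-repulsion layout with antipodal symmetry, deterministic
given its seed. Measurements with b < 50 s/mm² are treated as b0.

## The Monte Carlo engine

The substrate has four compartments:

* **resident cells** — hexagonal prisms (circumradius 12 µm by default),
  extruded through the slab;
* **syncytiotrophoblast** — a tube wall (annulus, default 6 µm thick)
  around each villus (outer radius 40 µm), extruded;
* **immune cells** — spheres of radius 4–8 µm, fully 3D, placed where
  the density map is positive;
* **extracellular space** — everything else, both intervillous and
  intravillous.

Walkers are seeded uniformly (compartment occupancy ∝ volume), take
Gaussian steps of per-axis variance $2 D_0\,dt$, and never cross
membranes. Reflection is specular for a walker's own convex compartment
and for extracellular collisions with spheres; the rare extracellular
collision with a prism or tube wall rejects the step (stays put). At the
default step length (≤ 3% of the smallest radius) the rejection bias is
far below the Monte Carlo tolerance bands. $D_0 = 2.0$ µm²/ms for all
compartments (free water at the 20 °C ex vivo temperature); the
supplementary simulation parameters of the source study are not public,
so these defaults are this package's calibration choices, exposed in
configuration.

PGSE encoding is reduced to two per-walker position integrals, one per
rectangular gradient lobe, with equal step counts per lobe so the
constant part of the position cancels exactly; the magnitude signal is
$|\langle e^{i\phi}\rangle|$, hence exactly 1 at b = 0. The gradient
amplitude follows from $b = (\gamma g \delta)^2(\Delta-\delta/3)$.
Signals are bit-reproducible given a seed (self-contained xoshiro256++ /
Box–Muller generator, independent of R's RNG state).

**Slab thickness.** Prisms and tubes are extruded, so only the 3D
spheres care about the slab. The validation pipeline simulates a 60 µm
slab instead of the full 1 mm voxel: per-unit-volume signal is unchanged
by homogeneity in z, the z-extent is still ≫ the ~10 µm diffusion
length, and sphere counts (and runtime) drop ~16×.

**Noise.** Rician: $|S + n_1 + i n_2|$ with
$n_{1,2}\sim N(0, S_{b0}/\mathrm{SNR})$. SNR is a plain ratio of b0
magnitude to channel σ — reported SNRs of 25–75 in the source material
are treated as ratios, not decibels, since the same quantities are
elsewhere given as 58.6 ± 7.9 and 37.4 ± 3.7.

**Analytic oracle.** `gpd_sphere_adc` evaluates the Murday–Cotts
(Gaussian phase distribution) series for a sphere with ≥ 20 roots of
$2x\cos x + (x^2-2)\sin x = 0$ and converts the attenuation at
b = 1000 s/mm² to an ADC. It recovers $D_0$ in the short-time limit and
0 as the radius shrinks, and agrees with the random-walk engine within
10% over the immune radius range — two implementations that share no
code.

## Synthetic data: the stated world

* **Density maps** (`generate_density_map`): lognormal-transformed
  Gaussian random fields, correlation length 300 µm, mean 0.05, capped
  at 0.2 (CD4-positive area ratios above ~20% do not occur, and sphere
  packings above that are not constructible by random sequential
  placement). A 5 mm field tiles into 400 regions of 0.25 × 0.25 mm.
* **Validation sets** (`generate_validation_set`): per region —
  substrate, walk, PGSE synthesis, then Rician noise at each SNR from
  one shared noiseless base. Ground truth is the exactly-booked placed
  sphere volume; the IHC area ratio is equated to a volume fraction
  (a stereological approximation, stated as such). Default budget:
  3000 walkers/region at dt = 0.02 ms (rms step 0.49 µm, within the
  quarter-radius rule for 4 µm spheres) — scaled down to desk scale; the
  single-sphere ADC probes use dt = 0.005 ms.
* **Cohort** (`generate_cohort`): 70 non-inflammation vs 12 inflammation
  patients at ~12/20/32/36 weeks' gestation; mean cellularity
  2.8% ± 0.7% vs 4.8% ± 0.65% early and 4.75% ± 0.9% vs 7.25% ± 2.13%
  late, middle visits linearly interpolated (only the endpoints are
  reported anywhere). Draws are truncated-normal on (0, 1) — truncation,
  not clipping, keeps means unbiased near 0. The voxel-level model in
  `synthesize_cellularity_volume` (independent lognormal around the
  patient mean) is an invention labelled as such: no within-placenta
  covariance is observable from the summary statistics being emulated.

A green validation test therefore establishes that *the estimator
recovers planted restricted fractions from this geometric world at these
SNRs* — not that it is unbiased on real placentas, where perfusion,
motion, permeable membranes, T2 differences, and registration error all
exist and are out of scope here.

## Statistics

`linear_regression` is ordinary least squares with r² = squared Pearson
correlation, a two-sided slope test, and a pointwise 95%
confidence-of-mean band. `ranksum_test` enumerates the exact rank-sum
distribution for combined n ≤ 12 (ties enumerated as-is) and otherwise
uses the normal approximation with tie correction and continuity
correction; it was cross-checked against `wilcox.test`. Per-visit group
comparisons are reported uncorrected — matching the presentation style
being reproduced — with a Bonferroni column alongside. Repeated measures
are treated per-visit; no mixed-effects model is fitted.

## Numerical choices and degenerate inputs

* b0 normalization by the mean of all measurements with b < 50 s/mm²;
  all-zero voxels yield a flagged background spectrum (cellularity 0)
  and are counted in the QC log.
* Non-positive signals are clamped (with a warning) before logs in the
  tensor fit.
* NIfTI-1 I/O is implemented minimally in-package (float64 round-trips
  are bit-exact; non-finite map values are written as background 0)
  because no R NIfTI reader is available in the target environment.
* The fit-under-noise tolerance in the test suite (mean absolute
  cellularity error < 0.10 at SNR 37, 200 voxels) was frozen from a
  pilot run measuring ~0.077; the error is variance-dominated, and a
  Gudbjartsson–Patz floor correction measurably does not reduce it.

## Known limitations

* Membranes are impermeable and compartments share one $D_0$; no T2 or
  proton-density weighting between compartments.
* The anisotropic stage is a pragmatic single-direction variant, not a
  full basis search.
* The IHC → sphere conversion equates areal and volume fractions.
* Voxel-level spatial structure in the synthetic cohort is invented.
* With only strong shells (the ex vivo protocol) arbitrary-spectrum
  recovery is not identifiable; with the ladder it is, but the
  region-level validation is less accurate. The package exposes both and
  uses each where it is right.
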