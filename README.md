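# placentaDBSI

Quantitative mapping of **placental immune cellularity** from
diffusion-weighted MRI, with the Monte Carlo machinery to validate it on
synthetic histology — no external data required.

## Who this is for

Researchers in placental/perinatal imaging who want (a) a tested
spectrum-decomposition fit that turns a multi-shell diffusion
acquisition into voxel-wise immune-cellularity maps, (b) a
restricted-diffusion random-walk simulator with PGSE signal synthesis to
probe how such estimators behave on known microstructure, and (c) the
associated validation and group statistics.

## The model

The normalized signal of measurement *k* is decomposed over a dictionary
of diffusion atoms,

```
S_k = Σ_i f_i exp(-b_k λ⊥i) exp(-b_k (λ∥i - λ⊥i) cos² φ_ik)   (anisotropic atoms)
    + Σ_j f_j exp(-b_k D_j)                                    (isotropic ADC grid)
```

by non-negative least squares (diffusivities in µm²/ms, b in s/mm²). The
**cellularity ratio** is the fraction of isotropic spectral mass with
`D_j` in **[0.01, 0.6] µm²/ms**. The 0.6 edge is physical: an 8 µm
impermeable sphere (the largest immune cells) with intrinsic diffusivity
2.0 µm²/ms, probed at Δ = 16 ms / δ = 7 ms, shows an apparent
diffusivity of ≈ 0.6 µm²/ms — the package's Monte Carlo engine and its
independent Murday–Cotts closed form both reproduce this. Larger
placental resident cells sit above the window; free and hindered water
sit far above it.

## Worked example

Simulate one histology-like region, run the full physics, and fit it:

```r
library(placentaDBSI)

# acquisition: 86 weightings (3 shells to b = 4500 s/mm^2) + 8 b0
sch  <- scheme_ex_vivo()
dict <- build_dictionary()

# a 250 x 250 um region with 8% immune-sphere volume fraction
geom <- build_geometry(matrix(0.08, 2, 2), c(250, 250), seed = 7)
sphere_volume_fraction(geom)        # 0.0800 (exact bookkeeping)

ens <- simulate_walkers(geom, n_walkers = 3000, duration = 23,
                        dt = 0.02, D0 = 2.0, seed = 7, scheme = sch)
sig <- synthesize_signal(ens, sch)  # noiseless, sig[b==0] == 1
sig <- add_noise(sig, snr = 25, seed = 7)

sp <- fit_voxel(sig, sch, dict,
                reg_lambda = dbsi_reg_default(dict, sch))
cellularity(sp, dict)               # 0.124: planted 0.080, one noisy region
```

A single region at SNR 25 carries noticeable noise (here +0.04); the
validation below shows what happens when 400 such regions are pooled.

The two headline physics checks, straight from the package:

```r
sphere_adc(8, D0 = 2.0)             # 0.601  (µm²/ms; MC, 8 µm sphere)
gpd_sphere_adc(8, 2.0, 16, 7)       # 0.579  (independent analytic oracle)
```

At full validation scale (400 regions of 0.25 × 0.25 mm, Rician noise at
b0 SNR 25), regressing estimated cellularity on true immune volume
fraction gives, at seed 1:

```
SNR 25 : slope 1.057  r² 0.709  n 400
SNR 50 : slope 1.138  r² 0.823  n 400
SNR 75 : slope 1.209  r² 0.853  n 400
```

i.e. the estimator tracks planted density with slope ≈ 1 and r² within
the 0.68–0.89 band expected for this SNR range.

Cohort-level statistics run from the synthetic longitudinal generator:

```r
co <- generate_cohort(cohort_spec(seed = 1))   # 70 vs 12 patients, 4 visits
longitudinal_summary(co)$comparisons           # per-visit Wilcoxon rank-sum
```

## Command line

```sh
inst/cli/placenta-dbsi fit --image dwi.nii.gz --bval dwi.bval \
    --bvec dwi.bvec --mask mask.nii.gz --out out/
inst/cli/placenta-dbsi validate --out val/ --seed 1 --regions 16   # smoke mode
inst/cli/placenta-dbsi cohort --out cohort/ --seed 1
```

Every run writes a `manifest.json` (config + seeds + version) sufficient
to reproduce deterministic outputs bit-identically.

## Layout

`R/` fitting, simulator, generators, statistics, CLI; `src/` the C++
random-walk engine; `vignettes/placenta-cellularity-methods.Rmd` the
methods notes (model assumptions, parameter defaults and why, what a
green test does and does not establish); `tests/testthat/` the suite,
including `test-acceptance.R` with the acceptance criteria.
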