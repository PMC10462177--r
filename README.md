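# epiqsm

In-silico test–retest reliability of R2\* relaxometry and quantitative
susceptibility mapping (QSM) with multi-shot multi-echo 3D EPI versus
conventional 3D gradient-echo (GRE) acquisition.

## The problem

Multi-echo T2\*-weighted MRI is the input to two quantitative maps of brain
tissue: the effective transverse relaxation rate R2\* (fitted from the
magnitude decay `S(TE) = S0 · e^(−R2*·TE)`) and the magnetic susceptibility
χ (obtained from the tissue frequency shift *f* by inverting the dipole
field `f = γB₀·10⁻⁹ · IFT[D(k)·FT(χ)]`, `D(k) = 1/3 − k_z²/|k|²`).
Conventional GRE acquires one k-space line per TR, so whole-brain 1 mm data
integrates minutes of physiological B0 fluctuation and motion; multi-shot
3D EPI acquires *EPI-factor* lines per echo per TR, shortening the scan
proportionally at the cost of sqrt(bandwidth) more thermal noise per
repetition — recovered by averaging EPI-factor repetitions (the matched-SNR
design).

`epiqsm` simulates this comparison end to end — digital phantom, dipole
forward model, shot-resolved k-space acquisition with physiological noise
and translation motion, corrected/uncorrected reconstruction, R2\*/f/χ
quantification — and measures reliability the way the field does:

* **NAD** (normalized absolute difference) of repeated magnitude images,
  `|m₁ − m₂| / ((m₁ + m₂)/2)` voxelwise;
* **|ΔR2\*|, |Δf|, |Δχ|** between repeated scans, as empirical CDFs and
  medians, with averaging curves over repetitions and Monte Carlo
  thermal-noise floors as the reference.

It also quantifies the EPI-specific costs: B0-induced pixel shift
(`shift = Δf × ETL`), the effective voxel size of pixel-shift distortion
correction (delta-function probe, −3 dB spectral criterion), and the
T2\*-decay point-spread-function FWHM across the echo train.

The package is for quantitative-MRI methods researchers who want a
reproducible desk-scale laboratory for acquisition-design questions of the
form "how does scan duration trade physiological corruption against
thermal noise, and what does shot-wise correction buy".

## Worked example

```r
library(epiqsm)

ph  <- build_phantom(c(64, 64, 48), voxel_mm = 3, seed = 0)
pr  <- desk_protocol(protocol_presets()$EPIx5, ph, accel = c(1, 1))
tl  <- sample_physio_timeline(n_shots = ceiling(64 * 48 / 5), tr_s = pr$tr_s, seed = 1)
kd  <- simulate_scan(ph, pr, tl, noise_sigma = 0.017, seed = 2)
img <- reconstruct(kd, "corrected")
q   <- quantify_maps(img, ph$mask, what = c("r2s", "chi"))
print(img)
#> epiqsm multi-echo image: 64x64x48, 4 echoes (TE 13/26/39/52 ms), mode 'corrected'
```

A full test–retest study (three protocols × two reconstruction modes,
several scan-pair seeds) is one call:

```r
rep <- run_experiment(experiment_config(pair_seeds = 1, metrics = c("nad", "dr2s")))
print(rep)
#> epiqsm reliability report
#>  protocol        mode metric     median
#>       GRE   corrected    nad 0.01303091
#>       GRE   corrected   dr2s 1.13527600
#>       GRE uncorrected    nad 0.11320907
#>       GRE uncorrected   dr2s 7.20437687
#>     EPIx3 uncorrected    nad 0.08971849
#>     EPIx3 uncorrected   dr2s 4.85094321
#>     EPIx5 uncorrected    nad 0.04364541
#>     EPIx5 uncorrected   dr2s 2.66516287
#>     ...
```

Read: without shot-wise correction, the median magnitude NAD falls from
0.113 (GRE, EPI factor 1) through 0.090 (EPI×3) to 0.044 (EPI×5) — shorter
scans accumulate less B0 drift, and the matched-SNR repetitions average the
physiological residue down — and the median |ΔR2\*| falls 7.2 → 4.9 → 2.7 s⁻¹
likewise. Shot-wise correction collapses all protocols to a common
thermal-noise-limited level (NAD ≈ 0.013, |ΔR2\*| ≈ 1 s⁻¹).

The numbered scripts under `analysis/` run the full study narrative:
`01_build_phantom.R`, `02_protocol_timing.R`, `03_test_retest.R`,
`04_noise_floor.R`, `05_distortion_blur.R`; each writes its tables under
`results/`.

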