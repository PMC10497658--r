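# csfmotion

Tools for studying the relationship between unsteady resistance to
cerebrospinal fluid (CSF) flow in the cervical spinal canal and
cardiac-induced brain tissue motion — the biomechanical axis along which
Chiari malformation type I (CMI) differs from healthy anatomy. The package
is aimed at researchers in CSF hydrodynamics and neuroimaging who want a
tested, fully seeded desk-scale version of both measurement chains and of
the cohort statistics that link them.

## What it computes

**Unsteady flow resistance.** Segmented canal cross-sections yield hydraulic
metrics (area, wetted perimeter counting both cord and dura walls,
`D_H = 4A/P`) and the inlet peak Reynolds number
`Re = 4 rho Q / (pi mu D_H)`. Per harmonic, fully developed oscillatory
(Womersley-type) flow is solved on each slice raster,

    i w rho u = G + mu lap(u),  u = 0 on the walls,

giving a complex mobility `M(z, w) = Q/G`; the longitudinal impedance of a
segment (default: foramen magnum to 25 mm caudal) is the series line
integral `Z_L(w) = int dz / M(z, w)`, equivalently the ratio of the Fourier
coefficients of the pressure-drop and flow traces,
`Z_L = F(dP) / F(Q)`. The **integrated longitudinal impedance (ILI)** is
the integral of `|Z_L(f)|` over 1–8 Hz, in dyn/cm⁵.

**Tissue motion.** Cine DENSE series encode displacement into wrapped image
phase at `k_e` cycles/mm (`u = phi / (2 pi k_e)`). The chain: region-mask
erosion (2 voxels), quality-guided 2D phase unwrapping (when needed),
decoding, separable Hamming windowed-sinc noise filtering (cutoff 0.15,
order 16, unit DC gain), and ROI summarisation — the temporal maximum of
the spatial mean displacement magnitude inside a ~30 mm² disc centred where
motion peaks.

**Cohort statistics.** Welch t-tests, Shapiro–Wilk, Pearson correlation and
OLS regression with 95% CIs, displacement-cutoff subset regressions
(>150/200/250 µm) and symptom contrasts.

**Synthetic data.** Seeded generators for crowded annular canal geometries,
CSF flow waveforms (86.3 bpm, 100 samples/cycle), DENSE motion phantoms
with ground truth, and cohorts (32 CMI / 18 controls by default) in which a
latent crowding factor drives both geometry (hence ILI, through the
impedance module) and cerebellar displacement — with decoupled and
graded-coupling variants for null and cutoff analyses.

## Worked example

```r
library(csfmotion)

# a crowded canal: annulus, gap narrowed 40% over the first 25 mm
geo  <- make_geometry(crowding_factor = 0.4)
wave <- make_waveform()                      # 86.3 bpm, peak 2.5 cm^3/s

section_metrics(geo$sections[[1]])           # inlet slice
#> A = 1.2079 cm^2, P = 11.2089 cm, D_H = 0.4311 cm (760 px)

reynolds_number(max(wave$samples_Q), fluid_props(),
                section_metrics(geo$sections[[1]]))
#> [1] 738.434

spec <- impedance_spectrum(geo, seq(1, 8, length.out = 29))
compute_ili(spec)
#> ILI = 400.5 dyn/cm^5 over 1-8 Hz (29 nodes, modulus)

# DENSE phantom: 300 um gaussian-bump motion at magnitude SNR 20
ph  <- make_dense_phantom(seed = 1)
out <- dense_pipeline(ph$series, ph$mask)
out$summaries$cerebellum
#> cerebellum: displacement = 292.4 um (ROI 30.0 mm^2 at [26, 45], frame 8, mean)
ph$truth_summary$cerebellum$displacement_um  # generator ground truth
#> [1] 297.9602
```

The numbers mean: the crowded inlet presents a hydraulic diameter of
0.43 cm and peak Reynolds number ~738 (laminar); the 40%-crowded canal has
an ILI of ~400 dyn/cm⁵ versus ~288 for the uncrowded default; and the
imaging chain recovers the phantom's true ROI displacement (298.0 µm) to
within a few micrometres.

The `analysis/` scripts run the full study in order and write their tables
and figures under `results/`:

```sh
Rscript analysis/01_simulate.R    # geometries, waveform, phantom, cohort
Rscript analysis/02_impedance.R   # spectra, ILI, pressure/flow traces
Rscript analysis/03_dense.R       # phantom accuracy experiment
Rscript analysis/04_cohort.R      # end-to-end cohort statistics
```

On the seed-1 synthetic cohort the end-to-end run reports ILI
489 ± 143 dyn/cm⁵ (CMI) vs 245 ± 26 (controls), a significant positive
cerebellar ILI–displacement correlation for CMI subjects (r = 0.59,
p = 4.0e-4, n = 32) with no brainstem correlation (r = 0.31, p = 0.08) and
no symptom-arm differences — the qualitative pattern the pipeline is built
to probe.

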