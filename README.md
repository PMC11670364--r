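# mvkvdect

Simulation and estimation-theory analysis of **MV-kV dual-energy CT**:
dual-energy imaging performed with a detuned megavoltage (MV) treatment
beam and a kilovoltage (kV) on-board imaging beam, as available on
radiotherapy treatment systems, comparing **energy-integrating detectors
(EIDs)** with **non-spectral photon-counting detectors (PCDs)**.

The package is aimed at medical-imaging physicists studying detector
choices for radiotherapy imaging. It answers, by computation, questions
of the form: *at a fixed imaging dose, how much basis-material SNR or
VMI contrast-to-noise does photon counting buy over energy integration,
and how should the dose be split between the MV and kV beams?*

## The models at its core

**Signal.** A polychromatic ray through basis-material mass thicknesses
`A_j = rho_j * t_j` (tissue, bone) produces the expected signal

    lambda_i = sum_E I_i(E) exp(-sum_j (mu/rho)_j(E) A_j) eta(E) D(E)

with `D(E) = E` for an EID and `D(E) = 1` for a PCD, and a shared
detective efficiency `eta(E)` (unity at diagnostic energies, 0.20 at
6 MeV). Noise is Poisson per energy bin; the EID additionally carries
electronic noise with standard deviation `sigma_e * Ebar`
(`sigma_e = 10` counts, `Ebar` the mean beam energy).

**Estimation bound.** The Fisher information of the MV/kV pair for
`(A_tissue, A_bone)`,

    F_jk = sum_i (1/v_i) (d lambda_i / dA_j)(d lambda_i / dA_k),

gives the Cramér–Rao lower bound `sigma^2_Aj = (F^-1)_jj` and the
basis-material figure of merit `SNR_j = A_j / sigma_Aj`. The MV dose
fraction `r` (of a fixed per-ray dose, normalized at the center of a
40-cm water cylinder) is swept over 0.01–0.99 to find the per-material
optimum.

**CT chain.** Analytic fan-beam ray tracing of procedural phantoms →
per-energy-bin Poisson noise → Gauss–Newton sinogram-domain
decomposition into tissue/bone mass thicknesses → equiangular fan-beam
FBP (ramp cut at 80% of Nyquist) → virtual monoenergetic images
`VMI(E0) = rho_1 (mu/rho)_1(E0) + rho_2 (mu/rho)_2(E0)` → CNR
`|m_insert - m_bg| / sd_bg` and multi-realization noise maps.

See the methods vignette (`vignettes/mvkv-dect-methods.Rmd`) for model
assumptions, defaults, and known limitations.

## Worked example

```r
library(mvkvdect)

mv <- build_detuned_mv_spectrum()   # peak fluence ~1 MeV, mean 1.91 MeV
kv <- build_kv_spectrum()           # 80 kVp, 2.5 mm Al, mean 40.4 keV

# 40 cm tissue + 2 cm bone, 1 uGy per ray, 85% of the dose to the MV beam
comp <- ray_composition(40, 2)
basis_snr(mv, kv, comp, detector = detector_model("pcd"), r = 0.85)
#> <mvkv_snr> PCD  r = 0.85, dose 1 uGy: SNR tissue 75.13, bone 8.849
basis_snr(mv, kv, comp, detector = detector_model("eid"), r = 0.85)
#> <mvkv_snr> EID  r = 0.85, dose 1 uGy: SNR tissue 57.21, bone 6.884

# per-material optimal MV dose fraction for the PCD
optimize_allocation(mv, kv, comp, detector = detector_model("pcd"))$r_opt
#> tissue   bone
#>   0.83   0.75
```

At this composition the PCD bounds are ~30% better than the EID's for
both materials at equal dose, and bone SNR prefers a slightly smaller MV
dose share than tissue. Supporting physics checks print equally directly:

```r
pr <- basis_thickness_profiles(make_iq_phantom(), 360, 180)
range(pr$t_tissue_cm)   # 37 40   (cm of tissue along central rays)
max(pr$t_bone_cm)       # 3.567568 = 3 cm * 2.2 / 1.85 (densest insert)

stopping_fraction(load_material("silicon"), 3, 3000)  # 0.223
stopping_fraction(load_material("cdte"), 3, 3000)     # 0.480
```

A full CT study (forward projection, noise, decomposition, FBP, VMIs,
CNR tables, noise maps, with a hash manifest of every artifact) runs as

```r
cfg <- run_config(study = "ct", detector = "both", phantom = "iq",
                  n_views = 360, n_channels = 400, matrix_size = 256,
                  n_realizations = 5, seed = 1, outdir = "ct_out")
res <- run_ct_study(cfg)
```

or from a shell via `inst/cli/mvkv-sim.R`.

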