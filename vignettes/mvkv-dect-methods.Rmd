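---
title: "Models and methods for MV-kV dual-energy CT simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for MV-kV dual-energy CT simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvkvdect)
```

# The problem

Radiotherapy treatment machines carry two x-ray sources: a megavoltage
(MV) treatment beam, which can be detuned into a softer imaging beam, and
a kilovoltage (kV) on-board imager. Operating both at once gives a
single-shot dual-energy CT acquisition — two sinograms of the same
anatomy at very different effective energies — from which tissue and bone
basis-material images, and from those virtual monoenergetic images
(VMIs), can be computed. The limiting factor is the MV channel: at an
acceptable imaging dose its flux is tiny, and conventional
energy-integrating detectors (EIDs) weight each detected photon by its
energy, so a 3-MeV photon counts 100 times more than a 30-keV photon even
though the low-energy photons carry most of the soft-tissue contrast.
EIDs also add electronic readout noise. A non-spectral photon-counting
detector (PCD) — one low pulse-height threshold, no energy bins — weights
every detected photon equally and suppresses the electronic noise floor.
This package quantifies how much that weighting change is worth, first in
an estimation-theory bound for a single ray, then in a full fan-beam CT
simulation.

# Signal and noise models

A polychromatic ray through thicknesses $t_j$ of basis materials $j \in
\{\text{tissue}, \text{bone}\}$ produces the expected detector signal

$$\lambda_i \;=\; \sum_E I_i(E)\,
  \exp\!\Big[-\textstyle\sum_j (\mu/\rho)_j(E)\,A_j\Big]\,
  \eta(E)\, D(E),$$

where $I_i(E)$ is the photon fluence per energy bin of spectrum $i$
(MV or kV), $A_j = \rho_j t_j$ is the basis mass thickness in g/cm²
(tissue basis 1.06 g/cm³, bone basis 1.85 g/cm³), $\eta(E)$ is the shared
detective efficiency, and $D(E)$ is the detector response: $D(E) = E$
(keV) for the EID, $D(E) = 1$ for the PCD.

Noise models (`signal_variance()`):

* **PCD** — pure Poisson counting: $v = \lambda$ (counts).
* **EID** — Gaussian approximation of the compound-Poisson
  energy-weighted sum, $v = \sum_E I\, e^{-\sum\mu t}\,\eta\,E^2$, plus
  an additive electronic term $(\sigma_e \bar E)^2$, where $\sigma_e$ is
  the readout noise in counts (default 10) and $\bar E$ is the
  fluence-weighted mean energy of the incident spectrum. For the
  detuned MV beam $\bar E \approx 1.9$ MeV, so the electronic floor is
  equivalent to roughly ten 2-MeV photons per measurement.

The per-energy-bin Poisson model is also what `add_noise()` samples
exactly (no Gaussian shortcut on the quantum part), with EID electronic
noise added as $N(0, (\sigma_e\bar E)^2)$ and a positivity floor of
$10^{-6}$ of the air value so log-transmissions stay defined.

# Fisher information and the CRLB

For the two unknowns $(A_\text{tissue}, A_\text{bone})$ measured with the
MV/kV pair, the likelihood is taken as Gaussian with mean $\lambda_i(A)$
and *fixed* variance $v_i$; the Fisher matrix is

$$F_{jk} = \sum_{i}\frac{1}{v_i}
  \frac{\partial\lambda_i}{\partial A_j}
  \frac{\partial\lambda_i}{\partial A_k},
  \qquad
  \frac{\partial\lambda_i}{\partial A_j} =
  -\sum_E I_i\, e^{-\sum_m (\mu/\rho)_m A_m}\, (\mu/\rho)_j\, \eta\, D.$$

The variance-derivative term $\tfrac{1}{2}(\partial_j v/v)(\partial_k
v/v)$ that a fully Gaussian treatment would add is omitted; at
CT-relevant counts it is second-order, and the fixed-variance form is the
standard choice for detector-weighting comparisons. The Cramér–Rao lower
bound is $\sigma^2_{A_j} = (F^{-1})_{jj}$ and the per-material figure of
merit is the unitless $\mathrm{SNR}_j = A_j/\sigma_{A_j}$
(`basis_snr()`). Two properties worth knowing:

* For a monoenergetic beam with $\sigma_e = 0$ the EID and PCD bounds
  coincide — the energy weight cancels — so every EID/PCD difference is a
  *spectral* effect.
* With $\sigma_e > 0$ the EID SNR grows slightly *faster* than
  $\sqrt{\text{dose}}$, because the fixed electronic floor matters
  relatively less at higher flux. The PCD obeys the square-root law
  exactly.

# Dose normalization and allocation

Absolute fluence (hence noise) is anchored by dose: each spectrum is
rescaled so that one ray deposits a prescribed dose at the center of a
40-cm water cylinder, computed as primary-beam collision kerma at 20-cm
depth, $D = k\sum_E I(E)\,e^{-\mu_w(E)\cdot 20}\,(\mu_{en}/\rho)_w(E)\,E$
with no scatter buildup (`dose_per_ray()`). The fluence vector is treated
as the photons of the ray itself (dimensionally, a 1-cm² ray). Single-ray
studies use 1 µGy per ray; CT studies use a 10 mGy total scan dose divided
evenly over the views. A fraction $r \in [0.01, 0.99]$ of the per-ray
dose goes to the MV beam and $1-r$ to the kV beam
(`allocate_dose()`); `optimize_allocation()` sweeps $r$ in steps of 0.01
and returns the per-material argmax, breaking ties toward smaller $r$.

# The synthetic beam and detector models

Published clinical spectra for a detuned 6-MV imaging beam are not
generally available, so the package ships analytic stand-ins with the
right gross features, each swappable for a measured two-column spectrum
file (`read_spectrum()`):

* **kV beam** (`build_kv_spectrum()`): Kramers-type bremsstrahlung,
  fluence $\propto (kVp-E)/E$ on 1-keV bins from 10 keV, filtered by
  2.5 mm Al (mean energy 40.4 keV at 80 kVp). This is a minimally
  filtered diagnostic beam; heavier filtration can be requested, and a
  sensitivity check (below) shows the headline comparisons move little
  with beam hardness.
* **MV beam** (`build_detuned_mv_spectrum()`): fluence
  $\propto E\,e^{-E/1\,\text{MeV}}$ on 20-keV bins truncated at 6 MeV —
  peak fluence at 1 MeV, mean 1.91 MeV, as expected of a treatment beam
  softened for imaging.
* **Detective efficiency** (`detective_efficiency()`): unity up to
  150 keV, decreasing linearly in $\log E$ to 0.20 at 6 MeV, patterned on
  high-efficiency xenon fan-beam MV detectors. The identical curve is
  applied to both detector models on purpose: the comparison isolates
  photon *weighting*, not stopping power.

Attenuation physics comes from bundled plain-text tables
(`inst/extdata/materials/`) of mass attenuation and mass energy-absorption
coefficients for soft tissue, cortical bone, water, Si, CdTe and Al on the
standard 10 keV–6 MeV grid, interpolated log-log (positive by
construction). The tables are an approximate hand-compiled set in the
style of the standard reference compilations; the CdTe K-edge region is
coarse, which only matters below ~100 keV.

# Phantoms

`make_iq_phantom()` builds the image-quality phantom: a 40-cm tissue
cylinder (1.06 g/cm³) with seven 3-cm bone-material inserts, densities
1.0–2.2 g/cm³ in 0.2 steps, on a 12-cm ring with the densest insert at 12
o'clock (layout configurable). `make_torso_phantom()` is a procedural
anthropomorphic slice — elliptical body, two low-density lungs, spine and
two lateral bone structures, with small seed-controlled jitter — sized so
central-ray tissue-equivalent thickness stays in roughly 18–32 cm and
bone-equivalent thickness below ~5 cm. It stands in for licensed voxel
anatomies; a voxel phantom can be rasterized separately but is never
required. Ray tracing is analytic (line–ellipse intersections); nested
primitives record their container so overlapping chords replace, rather
than add to, the parent material. Basis-equivalent thicknesses are mass
thicknesses divided by the basis densities, so a 3-cm chord of
2.2 g/cm³ bone reads $3 \times 2.2/1.85 = 3.57$ cm of basis bone.

# CT chain

* **Geometry**: equiangular fan beam, 55-cm source–isocenter, 100-cm
  source–detector, 800 channels over 50°, 1200 views per 360° rotation
  (all configurable). MV and kV acquisitions share view angles; the
  physical 90° mounting offset of the two sources is ignored since the
  sinograms are recombined per ray.
* **Decomposition** (`decompose_sinogram()`): per ray, Gauss–Newton on
  the log-transmission residuals $L_i - \ln[\lambda_i(0)/\lambda_i(A)]$,
  initialized from the effective-attenuation linear solve; step halving;
  convergence at $|\Delta A| < 10^{-8}$ g/cm² or residual $< 10^{-10}$,
  at most 50 iterations (noiseless data converges in ~4). Estimates may
  go slightly negative under noise — no positivity clamp, preserving
  unbiasedness. Non-converged rays keep their last iterate and are
  counted.
* **Reconstruction** (`fbp_reconstruct()`): equiangular fan-beam FBP —
  cosine pre-weighting, band-limited ramp kernel cut at 80% of Nyquist
  with the $(\gamma/\sin\gamma)^2$ equiangular correction and no
  apodization window, $1/L^2$ back-projection over the full rotation.
  Basis mass-thickness sinograms reconstruct directly to density in
  g/cm³; a uniform-disk oracle reproduces its density to ~0.03%.
* **VMIs** (`synthesize_vmi()`): $\text{VMI}(E_0) = \rho_1(\mu/\rho)_1(E_0)
  + \rho_2(\mu/\rho)_2(E_0)$ for $E_0 \in [20, 120]$ keV, convertible to
  HU against water (`to_hu()`).
* **Analysis**: `measure_cnr()` implements
  $|m_\text{insert}-m_\text{bg}|/\sigma_\text{bg}$; `noise_map()` takes
  the pixelwise standard deviation over noisy realizations.

## Region-of-interest design

Neither ROI shapes nor positions are standardized for this phantom, so
the package defines them: insert ROIs are the known insert disks eroded
by two pixels; the background ROI is an annulus in the *uniform tissue*
between the center and the insert ring (0.35–0.75 of the ring radius,
with a 1-cm exclusion zone around every insert). The background is
deliberately kept away from the insert ring: with a hard 0.8-Nyquist ramp
the ring region carries Gibbs edge ringing several times larger than the
stochastic noise, and a background placed there measures that
deterministic texture — identical for both detectors — rather than noise.
In uniform tissue the CNR comparison resolves the actual detector noise
difference (the EID/PCD VMI noise ratio is ≈1.26 at 50 keV under the
default study conditions).

# What the default study conditions show — and what they do not

With everything above at its defaults, the dose-optimized PCD-vs-EID
percent SNR improvement over the tissue 10–50 cm × bone 0.1–10 cm grid
has a saddle shape: large at the thinnest compositions (pure weighting
effect, ≈60–70%), a ≈23% interior minimum, and a maximum (≈109%) at the
thickest corner, where the kV channel of the EID collapses — only a few
photons per ray survive 50 cm of tissue plus 10 cm of bone, and the
10-count electronic floor dominates them. Two sensitivity results are
worth recording. First, hardening the kV beam from 2.5 to 10 mm Al moves
these numbers by under 10%: at fixed center-of-water dose, the
transmission gained is cancelled by the photon count lost. Second,
setting $\sigma_e = 0$ moves the maximum (≈70%) to the thin corner and
the thick-corner values down to ≈10% — the thick-corner behavior is
entirely an electronic-noise phenomenon, and therefore entirely
controlled by how many kV photons per measurement the spectrum model
delivers, the one quantity an analytic beam model pins down least well.
Reported improvement ranges from this package should be read with that
sensitivity in mind.

In the CT arm the same normalization makes per-ray counts generous, so
reconstructed noise is small; basis-density accuracy is excellent
(noiseless round trip within 0.15%, noisy ROI means within ≈0.1% with no
systematic underestimate at this flux), PCD VMIs beat EID VMIs in CNR at
every monoenergy with the gap widest below 50 keV, the PCD CNR peak sits
at an equal or lower monoenergy than the EID's, and on the torso phantom
the 50-keV noise maps concentrate around bone (bone-band to
tissue-interior ratio ≈1.2 PCD, ≈1.3 EID).

# Problem sizes and numerical defaults used by the test suite

The shipped tests exercise the full chain at reduced size, chosen as the
smallest studies that still show each effect cleanly: the SNR surface on
a 9 × 11 thickness grid with the full 99-point $r$ sweep; the CT study at
360 views × 400 channels, 256² reconstruction, 5 noisy realizations per
detector with MV/kV spectra rebinned to 50/2 keV; estimator efficiency
from 500 seeded single-ray realizations at 100 µGy (empirical variance
within a few per mil of the CRLB); and a 3-realization torso study for
the noise maps. All randomness flows through explicit seeds; identical
configurations produce byte-identical artifacts (see the manifest written
by `run_ct_study()`).

# Known limitations

No photon scatter, focal-spot or detector blur, charge sharing, pulse
pile-up, K-escape, bowtie filtration, or helical/cone geometry; the
torso phantom is a geometric cartoon, not an anatomical atlas; spectra
and the efficiency curve are analytic stand-ins anchored to a few gross
features, and the absolute EID-vs-PCD improvement numbers inherit their
uncertainty (the *direction* and *structure* of the comparison are
robust); the attenuation tables are approximate compilations, with the
CdTe diagnostic-energy region the least precise.
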