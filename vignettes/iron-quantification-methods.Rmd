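---
title: "Iron quantification by magnetic particle imaging and spectroscopy: models and methods"
author: "MPIron authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iron quantification by magnetic particle imaging and spectroscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(MPIron)
```

# Scope

MPIron re-creates, in silico, an ex vivo workflow for quantifying
superparamagnetic iron-oxide nanoparticles (SPIONs) in excised vascular
tissue — the setting is macrophage-rich abdominal aortic aneurysm (AAA)
segments that have phagocytosed a ferucarbotran-like tracer. Four
independent readouts are modelled end to end:

1. **Magnetic particle imaging (MPI)**: field-free-point (FFP) Lissajous
   scanning, system-function calibration, regularized Kaczmarz
   reconstruction, and cutoff-and-integrate volume-of-interest (VOI) iron
   quantification.
2. **Magnetic particle spectroscopy (MPS)**: harmonic analysis of the
   nonlinear magnetization response of a bulk sample, quantified by
   normalizing the 3rd harmonic to a reference of known mass.
3. **Histological morphometry**: Perls' Prussian Blue colour-profile
   segmentation and the iron-area ratio.
4. **Elemental mapping**: line-scan intensities calibrated against
   matrix-matched standards, with 3-sigma/10-sigma detection limits.

No animal data are used anywhere: a seeded synthetic-data layer generates
every input with known ground truth, which is what makes the quantification
chains testable.

# The tracer model

The tracer is modelled as an equilibrium Langevin mixture. Each core
population of diameter $d$ carries a moment
$m = M_s \tfrac{\pi}{6} d^3$ and magnetizes as

$$ M(H) \;=\; M_s \sum_i w_i\, L\!\left(\frac{m_i \mu_0 H}{k_B T}\right),
\qquad L(\xi) = \coth\xi - 1/\xi , $$

with weights $w_i$ summing to one. The defaults describe ferucarbotran:
a bimodal core population of 4 nm and 16 nm with signal weights 0.3 / 0.7
(the large cores dominate the nonlinear response), bulk magnetite
saturation magnetization $M_s = 476$ kA/m, and $T = 310$ K.

Mobility enters through a single first-order (Debye) relaxation time
applied to the induced signal as the frequency-domain factor
$i\omega / (1 + i\omega\tau)$ — the $i\omega$ being the receive-coil time
derivative. Defaults are $\tau = 1\,\mu$s for tracer in aqueous suspension
and $\tau = 3\,\mu$s for immobilized (tissue-bound or freeze-dried) tracer.
This is the minimal model that reproduces the experimentally observed
contrast between the two states: the low-pass damps the 5th harmonic more
than the 3rd, so the immobilized A5/A3 ratio is strictly smaller at equal
mass, and immobilized system functions retain fewer strong high-mixing-order
components. Stochastic Néel/Brown rotation dynamics, hysteresis and
inter-particle interactions are out of scope.

# Scanner geometry and the system function

The FFP scanner applies three orthogonal sinusoidal drive fields of 12 mT at
2.5 MHz divided by 102 / 96 / 99 (x / y / z) on top of selection-field
gradients of 1.25 / 1.25 / 2.5 T/m. The FFP position along axis $i$ is
$(A_i/G_i)\sin(2\pi f_i t)$, so the peak-to-peak coverage is $2A_i/G_i$ =
19.2 mm (x, y) and 9.6 mm (z), and the trajectory repeats after
$\mathrm{lcm}(102,96,99)/2.5\,\mathrm{MHz} = 53856/2.5\,\mathrm{MHz}
\approx 21.5$ ms. One receive sample per base-clock tick over one Lissajous
period (53 856 samples) puts every intermodulation product
$k_x f_x + k_y f_y + k_z f_z$ on an exact DFT bin.

`simulateSystemFunction()` runs one forward simulation per voxel of the
25 × 25 × 13 grid (25 × 25 × 13 mm³ FOV): the static selection field at the
voxel centre plus the drive field drives the Langevin mixture; the per-axis
magnetization series is Fourier-transformed; the Debye-derivative filter is
applied per frequency. Two exact structural economies keep this tractable:

* **Odd symmetry.** $M(-H) = -M(H)$ and the drive is an odd function of
  time, so voxels mirrored through the isocenter satisfy
  $\hat S(-r, f) = -\overline{\hat S(r, f)}$; only half the grid is
  simulated.
* **Row retention.** There are 9 290 distinct mixing bins at order ≤ 25
  (× 3 receive channels); storing all of them densely is pointless because
  most carry vanishing signal. A deterministic pre-pass on a coarse voxel
  subsample ranks rows by energy and the top 2 500 are kept — far more than
  any SNR threshold ever selects.

The calibration sample is the protocol's 100 mM Fe, 13.5 µl cuboid
(3 × 3 × 1.5 mm³, hence 75.39 µg Fe); its spatial extent is modelled by
convolving the voxel point responses with the cuboid's exact volume-overlap
kernel. Calibration noise is additive complex Gaussian per matrix entry;
the per-component SNR stored in the object is the noiseless row RMS over
that sigma.

# Reconstruction and MPI quantification

`reconstruct()` follows the ex vivo protocol exactly: components are kept
when SNR ≥ 7, frequency lies in 90 kHz – 1.25 MHz (the lower edge also
removes the 3rd drive-field harmonic near 73.5 kHz), and mixing order ≤ 25.
The band's upper edge is read as 1.25 MHz, the Nyquist frequency of the
2.5 MHz clock. Measurement frames are block-averaged (20 repetitions) and
the damped least-squares problem
$\min_x \lVert Ax-y\rVert^2 + \lambda_\mathrm{eff}\lVert x\rVert^2$ is
solved by the augmented row-action (Kaczmarz) iteration, five full sweeps,
rows visited in descending energy, with a nonnegative-real projection after
each sweep. $\lambda = 0.1$ is interpreted relative to the mean squared row
magnitude, the convention of the MPI reconstruction literature; an absolute
mode is available. The solver is deterministic and, unregularized and run
to convergence, matches a dense least-squares solve (this is tested against
`qr.solve` as an oracle).

Quantification applies a 50% cutoff of the maximum voxel intensity and
integrates concentration × voxel volume × 55.845 g/mol over the VOI
(1 mM in 1 mm³ = 0.0558 µg Fe). Two deliberate design choices:

* **VOI definition.** All voxels above the cutoff form the VOI; restricting
  to the largest connected component is available via `connected = TRUE`.
* **Unit calibration against the SF sample.** Regularization blur and the
  finite Langevin resolution (the field scale at which the 16 nm Langevin
  response saturates corresponds to 2–3 mm at these gradients) push part of
  every object's mass below the 50% cutoff, so raw VOI integration
  underestimates systematically — by roughly 30% for the default protocol.
  As in quantitative scanner practice, `voiCalibrationFactor()` anchors the
  units to the calibration sample itself: a noiseless measurement of the
  75.39 µg SF sample is pushed through the identical
  reconstruct + cutoff + integrate chain and the true/apparent ratio
  becomes the unit correction. With it, the noiseless full-protocol chain
  recovers phantom masses to within ±4% across phantom positions; the
  residual scatter is the geometry dependence of the partial-volume
  fraction, which no single scalar can remove. A sharper solver setting
  (λ = 10⁻⁶, 50 sweeps) was evaluated and rejected: on this
  blur-limited system the nonnegativity clipping of ringing artifacts
  inflates the background and *worsens* VOI accuracy.

# MPS quantification

`simulateMPS()` excites a point-like sample with 25 mT at 25 kHz and
returns harmonics of the induced signal, linear in iron mass, plus an
empty-holder background spectrum (pure noise of the same scale). A 10 s
spectrometer acquisition is emulated as averaging over 1 000 excitation
periods. Quantification selects the mobility-matched reference — the
reference whose background-corrected A5/A3 ratio is nearest the sample's on
a log scale, ties preferring the immobilized reference since tissue-bound
tracer is the expected state — and scales its known mass by the ratio of
background-corrected 3rd-harmonic magnitudes. Background subtraction is
complex (amplitude difference before taking magnitudes). The default
reference library holds one fluid and one immobilized reference at the SF
sample equivalent of 75.39 µg. With a matched model and no noise the
inversion is exact by linearity; a mobility-mismatched reference produces a
mass-independent multiplicative bias (same sign at every mass).

# Histology and elemental validation

The synthetic stained section is a vessel cross-section (elliptical tissue
annulus) in which exactly the requested fraction of tissue pixels is
painted Perls' blue, clustered into patches by thresholding a smooth seeded
random field; ground-truth masks are always returned. Segmentation converts
to CIE Lab and records pixels within a perceptual distance (default
tolerance 30; the jitter the generator applies corresponds to roughly 5–10
ΔE) of the reference blue, intersects them with the tissue mask (supplied,
or derived by Otsu luminance thresholding plus hole filling), and divides
by the tissue area. Colocalization of masks is scored with the Dice
coefficient — descriptive only, as in the underlying protocol.

Elemental line scans are linear detector responses to a µg/g concentration
map plus Gaussian blank noise, with a gelatin standards table (nine
standards including a blank, default slope 50 counts per µg/g, blank sigma
433 counts — chosen so the fitted limits land in the protocol's regime of
LOD ≈ 26 and LOQ ≈ 87 µg/g). Calibration is ordinary least squares on
per-standard mean intensities; LOD/LOQ are $3\sigma/\mathrm{slope}$ and
$10\sigma/\mathrm{slope}$ on the blank-line standard deviation, so
LOQ/LOD = 10/3 identically. Map quantification inverts the line, floors at
zero, and flags sub-LOD pixels.

# The synthetic cohort and its frozen conditions

`cohortConfig()` defines the study: 23 aneurysm-like samples with
log-uniform iron masses in 0.1–5 µg and 9 sham controls near zero
(0.01–0.05 µg), mirroring the group sizes of the emulated experiment.
Phantoms are connected ellipsoidal wall shells of 3 × 3 × 4 mm outer extent
with a 1 mm wall — a mouse suprarenal aorta segment at aneurysmal
dilation — centred with a seeded jitter of up to ±1.5 mm.

Noise levels were calibrated once by `scripts/calibrate_noise.R` and are
frozen in the defaults:

* system-function sigma 3.123 × 10¹³ signal units, set so that the
  automatic SNR ≥ 7 selection keeps exactly 487 in-band components at
  order ≤ 25 — the protocol's operating regime;
* measurement sigma equal to the system-function sigma (the same receive
  chain acquires both);
* MPS sigma 1.675 × 10⁸, i.e. a post-averaging SNR of ~300 on the 3rd
  harmonic of the smallest cohort sample.

`runStudy()` chains everything per sample, with any stage failure reported
with the sample id and stage name, and assembles the agreement report:
all pairwise Pearson correlations (labelled explicitly rather than
attributing a single "agreement" number to an unstated pair), the mean
absolute percent deviation of MPI from MPS — overall and stratified at
1 µg, with an empty stratum reported as absent — and the unpaired
two-tailed Student's *t* test comparing aneurysm and control MPI masses
(p < 0.05 significant; a single test, so no multiplicity correction).
"Average deviation" is read as the mean of $|m_{MPI}-m_{MPS}|/m_{MPS}$;
MPS is the denominator because it is the reference method.

# What the generators do and do not emulate

The synthetic layer reproduces the *structure* of the measured data —
linear forward operators with the correct geometry, spectra with the
correct harmonic decay ordering, stain images with controllable area
fractions, line scans with a controllable calibration — under additive
Gaussian noise and exact reproducibility from a seed. It does not emulate
scanner hardware nonidealities (receive-chain transfer functions, drive
harmonics feedthrough, background drift), biological heterogeneity of
tracer distribution within the wall, staining artefacts, or ablation
geometry beyond a rectangular pixel raster. Passing tests therefore
demonstrate the internal consistency and statistical behaviour of the
analysis chains under the stated model, not performance on scanner data.

Numerical conventions worth knowing: harmonic amplitudes are complex and
reported as magnitudes (phases are kept internally); the Langevin function
switches to its series expansion below $|\xi| < 10^{-4}$; Kaczmarz skips
zero rows with a message; an all-zero image yields an empty VOI and an
undetected sample rather than an error; cutoff ties are included in the
VOI; `simulateMeasurement` requires phantom and system function to share a
grid and defines frames as the system-matrix projection of the scaled
concentration vector, which makes superposition exact.

# Problem sizes

The packaged tests run the full-protocol scanner (53 856 samples per
period, 25 × 25 × 13 grid, 2 500 retained components) for the acceptance
checks — one noiseless and one calibrated-noise system function, each a
few minutes of simulation — and a reduced scanner (dividers 17/16/15,
13 × 13 × 7 grid) for the per-module unit tests, where a system function
simulates in seconds. The reduced scanner preserves every structural
property (symmetry, linearity, determinism, selection logic) but has a
coarser point spread relative to its grid, so absolute VOI accuracy is
asserted only at full scale.

# Reproducing the headline numbers

```r
library(MPIron)
report <- runStudy(cohortConfig(seed = 1), verbose = TRUE)
report
```

prints the MPI-vs-MPS Pearson correlation, the stratified deviations and
the group-comparison p value for a fresh cohort;
`scripts/acceptance.R --seed 1 --out results/acceptance.json` writes the
same quantities as JSON. Known limitations: the in vivo arms of the
emulated study (MR angiography, manual morphometry of lumen diameters) are
out of scope, and the correlation between stain-area ratio and mass is
generator-defined, so it validates the segmentation, not the biology.
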