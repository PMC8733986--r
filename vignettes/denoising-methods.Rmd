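---
title: "Self-supervised denoising of nanotomography: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised denoising of nanotomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Full-field transmission X-ray microscopes (TXM) with diffractive optics
deliver few photons per detector pixel, so short tomographic scans of
radiation-sensitive biological samples produce reconstructions dominated by
noise. Conventional neighbourhood filters trade noise for resolution, which
is fatal when the features of interest (periodic pores of a butterfly wing
scale, canaliculi in bone) sit at the resolution limit. `txmdenoise`
implements a self-supervised alternative that needs no clean reference
data: the measurement itself provides the training signal.

## The split-and-regress model

A tomographic scan acquires projections at angles
$\theta_1 < \theta_2 < \dots < \theta_N$. Splitting by angle parity gives
two interleaved half-scans that image the *same* object but carry
*independent* photon noise. Each half is reconstructed separately by
filtered back-projection; call the reconstructions $A$ and $B$. A
convolutional network $f_w$ is then fitted by minimising

$$ \min_w \; \mathbb{E}_z \, \lVert f_w(A_{z-k..z+k}) - B_z \rVert_2^2 , $$

where $z$ indexes axial slices and the input is the target slice plus its
$2k$ nearest neighbours as channels (default $k = 2$, five channels; the
adjacent slices suppress slice-to-slice artifacts in the axial direction).
Because the noise in $B$ is independent of the noise in $A$ and has the
clean reconstruction as its conditional mean, the MSE-optimal regressor of
$B$ from $A$ is the clean signal itself: the network can only profit from
structure present in both halves, never from either half's noise. This is
the Noise2Inverse principle; its premise — residual noise in $A$ and $B$
uncorrelated — is measured explicitly in the reference experiment and in
the test suite (|Pearson r| < 0.05 over the interior circle).

The trained model expects the noise level of a *half* reconstruction.
Applying it to a later scan of a structurally similar sample therefore
splits that scan too and denoises one half (`denoise_new_scan()`), which
is what halves acquisition time across a sample series.

## Network

The regressor is a mixed-scale dense network: `depth` hidden layers of
width one, each computing a ReLU-activated sum of 3×3 convolutions
(zero-padded, dilation cycling through 1…10) over *all* previous feature
maps including the input channels, with a linear 1×1 output layer over
every map. Dense connectivity plus mixed dilations yields a receptive
field of tens of pixels with only a few thousand parameters — small enough
to train on hundreds of slices without augmentation and to resist
overfitting. Defaults: depth 30 (a desk-scale setting; deeper nets are
configurable), He-style initialisation of the hidden convolutions, zero
initial output layer, Adam at learning rate $10^{-3}$, batches of two
slices, MSE loss on inputs/targets standardised by training-set mean and
standard deviation (the statistics travel with the model so inference is
self-contained). The forward pass and backpropagation are implemented in
compiled C++ in double precision, single-threaded, so training is
bit-reproducible given the seeds.

Training stops early: after each epoch the validation MSE is evaluated on
a slice range disjoint from the training range and separated by a guard
gap (default 10 slices, so validation slices are not direct neighbours of
training slices); the weights of the epoch with minimal validation MSE are
retained, and training stops after `patience` (default 10) epochs without
a new minimum. The stopping rule is a pure function
(`select_best_epoch()`) tested independently of training. On very small
training sets the validation curve turns upward before the final epoch —
the classic overfitting signature — and the test suite reproduces this
with a 4-slice probe.

## Reconstruction

Reconstruction is classical filtered back-projection, slice by slice:
frequency-domain ramp filtering ($H(f) = 2\lvert f\rvert$, optionally
windowed by the Shepp–Logan factor $\mathrm{sinc}(f/2f_N)$), linear-
interpolation back-projection, scale $\pi / 2N_\theta$. Detector rows are
padded to twice the next power of two before the FFT by continuing the
edge values (not zeros), which suppresses circular-convolution wraparound
and maps constant rows exactly to zero. Beamline pipelines typically use
GridRec, a Fourier-regridding accelerated equivalent of FBP; classical
FBP was chosen here because it is specifiable and testable from first
principles (chord-length integrals, linearity, rotational covariance),
and the provenance string of every volume records the algorithm and
filter actually used. Angles are degrees, counter-clockwise, 0° sending
rays along +y, rotation about the central pixel $(n-1)/2$; no
ring-artifact removal or axis-shift correction is attempted (alignment
and ring correction are upstream concerns and out of scope).

## Synthetic acquisition model

The simulator exists so that every stage has inputs with the statistical
structure of real low-dose TXM data while ground truth stays available:

* **Phantoms.** `lattice` — an attenuating cylinder pierced by a cubic
  lattice of spherical holes (period 8 voxels by default), emulating
  periodic porous microstructure; `channels` — a cylinder pierced by
  straight 2–3-voxel tubes, emulating canalicular networks; `disk` — a
  uniform cylinder for analytic checks. The seed sets the lattice phase
  (and tube placement), so different seeds give distinct but statistically
  identical instances — this is what "a structurally similar sample" means
  in the transfer experiment.
* **Counting noise.** Expected counts follow Beer–Lambert,
  $I_0(u,v)\,e^{-A}$; realised counts are Poisson plus zero-mean Gaussian
  detector noise; transmission is floored at $10^{-6}$ before the log.
* **Inhomogeneous illumination.** $I_0$ is a separable raised cosine
  falling to 25% of the central intensity at the detector edges, so the
  variance of the log-transmission grows toward the edges as $1/I_0$ —
  the spatially varying noise profile that defeats filters tuned to a
  single global noise level, and which the self-supervised filter adapts
  to for free.

What the simulator deliberately does **not** model: Zernike phase-contrast
wave optics and halo, ring and scintillator artifacts, sample drift and
axis misalignment, cone-beam geometry. Passing tests on this simulator
therefore demonstrate the statistical machinery (noise independence,
regression toward shared signal, metric behaviour), not robustness to the
correlated artifacts of real beamline data — the workflow's known failure
mode, since artifacts shared by both halves are regressed as if they were
signal.

## Reference study conditions

The reference experiment (`run_reference_experiment()`, also the basis of
`scripts/acceptance.R`) runs at desk scale, chosen once: a 64³ lattice
phantom (wall attenuation 0.02/voxel), 256 angles over 180° split
128/128, 250 mean counts at the illumination centre with unit Gaussian
detector noise — a dose at which the half reconstruction's PSNR against
ground truth is far below 18 dB, i.e. visibly noise-dominated, matching
the regime the method is for. Training uses 40 slices, validation 12,
guard 10, depth-30 network, at most 100 epochs. (The full-scale
protocol — 400 training and 50 validation slices of 1024² pixels from a
1760-projection scan, 60–190 epochs — is the same code path with larger
numbers.)

Evaluation mirrors the published protocol:

* **CNR** $= \lvert I_\mathrm{mat} - I_\mathrm{air}\rvert / D$ with
  $D = \sqrt{(\sigma_\mathrm{mat}^2 + \sigma_\mathrm{air}^2)/2}$ by
  default; the denominator rule is configurable (`mean_sd` gives the
  arithmetic mean of the two standard deviations) and recorded in every
  result, because the published equation's denominator form is ambiguous
  in reproduction. ROIs follow the fine-structure protocol: material =
  eroded solid voxels, air = eroded hole interiors, both well inside the
  object. Measuring inside the structured region is essential — it is
  what penalises filters that erase the fine pores (the 3-D median fills
  them, collapsing contrast) and rewards filters that only remove noise.
* **FWHM** from Gaussian-plus-offset fits to line-profile peaks
  (Levenberg–Marquardt; the offset absorbs the background pedestal);
  $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$, unbiased within 1% on
  noiseless Gaussians for $\sigma \in [2, 20]$ px.
* **Radial PSD** via 2-D FFT (Hann window by default — an artifact choice,
  recorded in the result; the rectangular window satisfies Parseval
  exactly) and azimuthal averaging into bins one frequency sample wide.
* **PSNR** against the known phantom, and the **difference image**
  input − output, whose correlation with the ground truth is the
  "invented structure" detector: near zero when only noise was removed.

## Numerical and design choices

* "Radius 2" for the median baseline is read as a 5×5×5 cube (a ball
  option exists); the neighbourhood shape was not specified in the
  original comparison. Order statistics are exact (`nth_element`), edges
  mirror-reflected.
* The five input channels are read as the slice plus its four nearest
  neighbours ($k = 2$, symmetric); the alternative reading (five
  *additional* channels, six total) is available by setting `k` — the
  channel count is a parameter, not a fixed truth.
* Odd projection counts put the extra projection in the even half, so
  splits are reproducible; `swap_roles()` enables symmetric two-direction
  training, off by default.
* Train/validation slice selection is contiguous-with-guard rather than
  random, matching the protocol it reproduces.
* All randomness (phantom details, noise, weight init, epoch shuffling)
  is seed-derived; a master seed fans out to fixed stage offsets.
* Degenerate inputs fail loudly and early: constant training data (no
  usable statistics), nonpositive transmission (named pixel), guard-gap
  violations, flat ROIs, shape mismatches.

## A minimal run

```{r}
library(txmdenoise)

cfg <- pipeline_config(seed = 1)
rep <- run_reference_experiment(cfg)
print(rep)        # PSNR / CNR tables, correlations, training summary
plot(rep$model)   # train/validation MSE curves with the selected epoch

# reuse the model on a second scan of a similar sample
tr <- transfer_experiment(rep$model, cfg)
tr$gain           # dB improvement over that scan's half reconstruction
```

## Limitations

Correlated artifacts (rings, halo, motion) violate the independence
premise and are neither simulated nor corrected; the method's published
failure mode — artifact amplification — is thus out of the tested scope.
The CNR of a synthetic phantom is not comparable in magnitude to values
measured on beamline scans (those include natural material variation and
halo background); only orderings and gains are meaningful here. Training
is CPU-bound and desk-scale by design; the architecture and training loop
are unchanged at larger sizes, only slower.
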