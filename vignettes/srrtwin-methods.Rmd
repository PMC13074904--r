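---
title: "Recovering absorption and reduced scattering from spatially resolved reflectance: the srrtwin model and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{srrtwin methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and the inverse problem

Spatially resolved reflectance (SRR) imaging shines a focused, obliquely
incident beam onto a turbid sample and images the diffusely re-emitted
light with a cooled 16-bit CCD.  The radial decay of the remitted
intensity around the entry point encodes the two transport coefficients of
the medium: the absorption coefficient $\mu_a$ and the reduced scattering
coefficient $\mu_s' = \mu_s(1-g)$, both in mm$^{-1}$, with the
Henyey--Greenstein (HG) phase function and a fixed anisotropy factor
$g = 0.8$ describing single scattering, and $n$ the refractive index of
the (aqueous) medium.  Because no analytic solution of the radiative
transfer equation fits this geometry — an extended oblique beam with a
measured, non-Gaussian profile, refractive index mismatch, and a
pixel-grid surface detector — the forward model is a Monte Carlo digital
twin of the instrument, and the coefficients are recovered by
Levenberg--Marquardt (LM) minimization of the mismatch between measured
and simulated radial curves.

`srrtwin` implements the full chain: the photon-transport kernel, the
perturbation-Monte-Carlo (pMC) machinery that turns one simulation into
derivatives, the camera-side preprocessing (flat field, bloom repair,
multi-exposure stitching, radial binning), the scaling-coefficient
calibration that puts camera counts and per-photon simulations on one
scale, the inversion itself, and a synthetic camera so that every stage —
and the closed loop — can be validated without the instrument.

## Forward model

Photons enter the slab (thickness 55.5 mm, matching a filled sample
beaker; effectively semi-infinite for the property range considered) at
surface positions drawn from the 2D beam-profile image, jittered uniformly
within the selected pixel to avoid pixel-lattice artifacts, with the
direction given by Snell refraction of the 21° incident beam at the
air–medium interface.  Free path lengths are sampled from $\mu_s$ alone;
deflections from the HG inverse CDF with uniform azimuth; the incidence
plane lies along the image +x axis.

Two design choices matter downstream:

* **Absorption as a terminal weight.**  A photon's absorption is applied
  once, as $e^{-\mu_a L}$ with $L$ the total path length, instead of
  attenuating the weight at every collision.  In expectation this is
  identical to albedo weighting, but it makes the stored per-photon
  statistics — exit pixel, weight, collision count $j$, path length $L$ —
  *exactly* rescalable to perturbed coefficients (see the pMC section),
  and it removes all variance associated with absorption sampling.

* **A splitting detector.**  At every crossing of the top surface the
  refracted fraction $1-R_F(\theta)$ (unpolarized Fresnel) is deposited at
  the exit pixel and the photon continues inward with the reflected
  fraction.  Depositing the expectation at each crossing, rather than
  making a random exit/reflect decision, sharply reduces the variance of
  the faint large-radius tail that the fit window ends on.  The Fresnel
  factors do not depend on $\mu_a$ or $\mu_s$, so pMC rescaling remains
  exact.  Exiting weight is recorded regardless of exit angle: the
  instrument's finite collection solid angle, like every other angular and
  radiometric system factor, is absorbed by the scaling calibration.

Russian roulette (survival 0.1, weight boost 10×) terminates paths whose
absorption-discounted weight falls below $10^{-2}$, and a second, lateral
roulette (survival 0.2, boost 5×, shells growing 1.5× per survival) plays
once a photon wanders beyond about 1.5 times the detector's corner radius —
photons that far out rarely return to the imaged field, so most of their
transport time buys nothing; both roulettes are unbiased and covered by
the exact weight ledger: launched + roulette
gains = detected top + transmitted bottom + absorbed + roulette losses +
truncated, returned with every simulation and asserted to $10^{-6}$ in
the tests.  (With the splitting detector a continuation below one percent
weight carries almost no remaining signal, so the weight-roulette
threshold was set where measured binned-tail noise was unchanged while
run time roughly halved.)  The bottom boundary escapes matched-index
(negligible at 55.5 mm depth); the medium is laterally unbounded, with
far excursions thinned only by the unbiased lateral roulette.  The
generator is
counter-based: each photon's draw sequence depends only on (seed, photon
index), so a fixed seed reproduces images bit-exactly and a re-simulation
at perturbed coefficients reuses each photon's randomness — the
common-random-numbers property the inversion relies on.

Both launch modes of the instrument model are provided:
`simulate_srr_image()` integrates the beam profile directly into the
launch distribution, and `simulate_pencil_image()` plus
`convolve_with_beam()` reproduces it by convolution; their radial curves
agree within combined Monte Carlo error (a standing regression test), and
the integrated launch is the default since it avoids two large-image FFTs
per inversion iteration.

An independent oracle, `diffusion_reflectance()`, implements the
extrapolated-boundary dipole solution of the diffusion approximation
(isotropic source at $z_0 = 1/(\mu_a + \mu_s')$, image source above the
extrapolated boundary $z_b = 2AD$ with the Groenhuis internal-reflection
parameter, boundary radiance integrated against the Fresnel transmission).
In the diffusive regime ($\mu_a/\mu_s' \le 0.01$, $\rho\,\mu_s' \gtrsim
2$) the Monte Carlo tracks it within 15% per half-millimeter bin; the
residual, radially drifting discrepancy is the documented accuracy limit
of the P1 approximation, not of the transport kernel.

## Perturbation Monte Carlo and the Jacobian

With free paths sampled from $\mu_s$ and terminal absorption, the
likelihood ratio of a stored detected path under perturbed coefficients
$(\hat\mu_a, \hat\mu_s)$ is

$$ \left(\frac{\hat\mu_s}{\mu_s}\right)^{j}
   e^{-(\hat\mu_s-\mu_s)L}\; e^{-(\hat\mu_a-\mu_a)L}, $$

so one simulation yields the reflectance image at any nearby coefficient
pair by re-weighting (`rescale_reflectance()`; the identity perturbation
returns the original image bit-exactly).  A $\mu_s'$ perturbation at fixed
$g$ is realized as $\hat\mu_s = \hat\mu_s'/(1-g)$.  Derivatives of the
binned curve are the relative finite differences
$\partial R/\partial p \approx (S_p R - R)/(p\,\delta_p)$ with the default
relative step $\delta_p = 0.05$ (`jacobian_columns()`).  For the $\mu_a$
column this coincides with a common-seed re-simulated finite difference to
rounding error, because the perturbation leaves every path geometrically
unchanged; for the $\mu_s'$ column a re-simulated difference additionally
carries bin-migration noise (paths stretch and photons cross bin
boundaries), so the pMC column is the lower-variance estimator and the
cross-check against re-simulation is statistical rather than exact.

## Camera model and image pipeline

The synthetic camera (`camera_model()`, `render_frame()`) emulates the
16-bit CCD: linear gain from per-photon reflectance to ADU, Poisson shot
noise, Gaussian read noise (default 3 counts), a dark offset (100 counts),
full-well clipping with iterative columnar bloom spill of the excess
charge, and integer quantization.  The true gain and noise of the
instrument are unpublished; the defaults reproduce its operating point
(auto-exposure to a 30,000-count peak on a 16-bit sensor).  The synthetic
beam profile is a near-top-hat core of radius 0.27 mm, slightly elongated
along the incidence plane by the 21° obliquity, plus a power-law halo
emulating the instrument-response tail of a patched multi-exposure beam
measurement.

The experimental-side pipeline mirrors the acquisition protocol:

1. dark subtraction and flat-field division (gain map normalized to mean
   one; the synthetic flat field varies by ±5%, the level measured for the
   physical light box);
2. bloom detection — every pixel at or above 95% of full well, grown along
   the readout column through contiguous runs above 90% of that level,
   plus one guard pixel beyond any run end that is itself fully
   saturated: the partially filled bloom front sits there, below the
   growth level but still holding displaced charge, whereas a dim run
   edge already is the front and its neighbor is clean (the growth level
   and the guard are declared implementation choices; the
   acquisition-side rule is not documented);
3. radial back-fill of masked pixels with the mean of the unmasked pixels
   of their annulus.  The back-fill assumes azimuthal homogeneity; under
   the oblique beam the pattern is mildly asymmetric, so annuli crossed by
   wide bloom bands are repaired only approximately (a few percent on
   lightly masked annuli, more where half the ring is a bloom band).  The
   residual is largely common-mode between the reference sample and the
   measured samples and is therefore absorbed by the scaling calibration,
   which is why the closed loop recovers coefficients at the percent level
   regardless;
4. exposure stitching of the 1×/10×/100× triplet: per annulus the longest
   exposure whose masked fraction stays below one half is used, annuli
   averaging fewer than 50 counts are flagged low-SNR.  Read literally, a
   "bloom-free annulus" rule would discard every annulus a single columnar
   streak crosses and thereby defeat the back-fill, so the masked-fraction
   rule is the declared, testable realization;
5. normalization to counts V$^{-1}$ ms$^{-1}$ mm$^{-2}$ by integration
   time, mean monitor-photodiode voltage and pixel area;
6. radial binning about the beam origin with bin width equal to the pixel
   side (0.0361 mm), pixel-center convention, single-pixel origin (no
   sub-pixel registration — the instrument aligns by eye to one pixel).

The fit window starts one bin outside the nominal beam radius
($\rho_0 = \rho_r + d\rho$) and closes at the first bin where the 5-bin
median-smoothed curve has decayed by $10^3$ relative to $\rho_0$; beyond
three decades the binned curve is noise-dominated.  The median smoothing
is a declared choice — some noise rule is needed to keep a single noisy
bin from closing the window early, and the acquisition software's rule is
not documented.

## Calibration

Camera units are tied to per-photon units by the scaling coefficient
measured on a reference sample with known coefficients:
$k(\rho) = R_{\mathrm{MC}}(\rho) / R_{\mathrm{exp}}(\rho)$ per bin, and
$\bar k$ its arithmetic mean over the $P$ window bins (both bounds
included; bins excluded for non-positivity reduce $P$).  Every
experimental image is then scaled,
$R_{\mathrm{exp,sc}} = \bar k\, R_{\mathrm{exp}}$, which makes absolute
fitting possible without radiometric calibration: source power, sensor
sensitivity, collection efficiency and the specular entry loss all live in
$\bar k$ (units V·ms).  A $\rho$-resolved application of the full profile
exists behind `per_bin = TRUE` but is non-default — a scalar shift proved
more faithful in practice, and the residual $\rho$-dependence of $k$ is
the documented limitation of the scalar correction.  $\bar k$ is
per-wavelength, always from the measured value at that wavelength; the
linear-in-$\lambda$ fit some systems report is offered only as a
diagnostic.

## Inversion

The cost is the log-residual mean square over the frozen window
($\log_{10}$; any fixed base only rescales the cost), with unit weights
$\sigma = 1$ and the fixed initial guess $(\mu_a, \mu_s') = (0.01, 1.0)$
mm$^{-1}$ for every sample.  Parameters are optimized in log space, which
enforces positivity without constraints; hard bounds
($\mu_a \in [10^{-6}, 10]$, $\mu_s' \in [0.1, 20]$ mm$^{-1}$) mark runaway
fits as non-converged.

Every forward simulation inside a fit reuses one seed, with one
counter-based substream per photon, so the stochastic cost is a
deterministic function of the parameters and re-simulations at perturbed
coefficients stay strongly correlated.  Each iteration builds the local
Jacobian of the log-residuals by the pMC relative finite difference
(step $\delta_p = 0.05$) from the current simulation's stored paths,
takes a damped Gauss--Newton step in log-parameters (multiplicative
damping: ×10 on rejection, ×0.1 on acceptance; steps clipped to a
trust box of radius 0.7 in log-parameters), and confirms the step with a
fresh common-seed simulation — accepted steps never increase the
simulated cost.  Because a damped Gauss--Newton step chronically
underestimates the distance along the curved valley this cost surface
has, every accepted step is extended: the step is doubled along its own
direction while the freshly simulated cost keeps improving.

Simulations follow a fidelity ladder: a cheap approach stage (one fifth
of the per-iteration budget) covers most of the walk from the fixed
initial guess, the stated per-iteration budget refines, and a final-stage
budget (`n_photons_final`) sets the noise floor that governs the
estimate — the displacement of a noisy cost's minimum away from the true
optimum scales with the inverse square root of the photon budget, which
measured displacements confirm.  The fit stops when the relative cost
improvement falls below $10^{-4}$ or no descent is found above the noise
floor.

Two further numerical choices matter at desk-scale budgets.  First, the
search evaluates the cost on 5-pixel-aggregated radial bins: aggregation
preserves the curve shape at the scales transport physics varies on
(fractions of a transport length, not 36 µm pixels) while lowering the
per-bin Monte Carlo noise floor several-fold, which keeps the descent
direction resolvable; the exact pixel-width cost of the definition above
is evaluated at the optimum and reported as `chi2_final`.  Second, the
fitted window is capped at the inscribed circle of the detector grid:
annuli beyond it are azimuthally incomplete crops, an artifact of
simulating a sub-frame rather than the full 1024×1024 sensor, and their
few-pixel bins otherwise dominate the cost noise.

## The synthetic closed loop and what it shows

`run_closed_loop()` chains everything: for each property combination it
simulates the truth image (10⁶ photons), renders the 1×/10×/100× triplet
with darks and the ±5% flat field through the noisy camera, patches and
normalizes, calibrates $\bar k$ on one mid-absorption reference scenario
(an independent Monte Carlo run), scales, and inverts (10⁵ photons per
iteration, 5×10⁵ in the final stage).  The validation grid spans
$\mu_s' \in [1, 4]$ mm$^{-1}$ and $\mu_a \in [5\times10^{-4}, 0.5]$
mm$^{-1}$ — a factor of four in scattering and four orders of magnitude in
absorption, the envelope over which the physical instrument was validated.
Scenes use a 512-pixel-scale-compatible 384×384 grid at the instrument
pixel pitch of 0.0361 mm: the fit window never extends past ~9 mm radius
over this property envelope, so a full 1024×1024 frame would only add
uninformative pixels.  The sample-analog table maps scatterer and ink mass
concentrations to coefficients by the declared conventions
$\mu_s' = 0.5\cdot(\mathrm{scatterer}\,\%)$ and
$\mu_a = 5\times10^{-4} + 1.0\cdot(\mathrm{ink}\,\%)$ (a water baseline
plus ink proportionality); these are synthetic conventions, not measured
values.  The photodiode voltage drifts by ±1% (slow sinusoid) and its mean
is what normalization uses, matching the acquisition convention.

What passing the closed loop does and does not show: it validates the
whole numerical chain — transport, pMC derivatives, stitching,
calibration transfer between samples sharing one camera, and the
well-posedness of the two-parameter inversion — under realistic shot and
read noise, saturation, blooming and flat-field error.  It does not probe
instrument physics the camera model omits: stray light, PSF mismatch
between beam measurement and sample imaging, surface roughness or
curvature, sample inhomogeneity or sedimentation, wavelength-dependent
systematics.  Those enter a real measurement through the reference
calibration and are exactly why the physical validation against
independent instruments matters; the package's claim is that the
algorithmic half of that validation is reproducible on a desk.

## Numerical choices and degenerate inputs

* Radial binning is exactly conservative (mean × count identity) and is
  asserted as such; empty bins are `NA`, never zero.
* Non-positive Monte Carlo bins inside the window (possible at low photon
  counts) are excluded from the cost with `P` reduced, avoiding
  logarithms of zero; bins excluded from $k(\rho)$ likewise shrink `P`.
* A curve that never reaches three decades of attenuation yields a
  truncated window with a warning, and the fit proceeds (degraded but
  defined); a flat, information-free curve produces a non-converged
  result, not an error.
* The direction update handles the $|u_z| \approx 1$ degenerate branch
  explicitly; directions are renormalized every 64 scatterings.
* FFT-based convolution zero-pads to twice the grid to avoid wrap-around
  and clamps negative rounding residue at $-10^{-12}$.
* Bloom spill conserves charge to $10^{-6}$ up to the frame edges (the
  edge loss is returned as an attribute and asserted in tests).

## Known limitations

* **Single-pixel origin-shift sensitivity is exaggerated relative to the
  instrument.**  Re-indexing a measured curve outward by one radial bin
  (36 µm) before refitting — the standard check of alignment robustness —
  moves the recovered coefficients by some 15–20% along the weakly
  constrained $\mu_a$ direction in this twin, with the cost only ~1.2–1.4×
  worse, whereas the physical system reports only a 1–2% coefficient
  change (with a ~2× cost increase).  The cause is the synthetic beam: its
  near-top-hat core has a far harder edge than a measured, PSF-broadened
  profile, so the first fitted bin (one pixel outside the nominal beam
  radius) picks up a beam-core value under the shift and produces a
  near-field residual orders larger than the instrument sees; the fit
  absorbs it in $\mu_a$.  The displacement is a genuine property of the
  shifted cost (verified against the unshifted optimum), not an optimizer
  artifact.  A softer, measured-profile-like beam would reduce it, but the
  generator's beam is a fixed study condition here.

* The pMC surrogate degrades for steps beyond the trust region (weight
  factors above $10^3$ trigger a validity warning); the confirmation
  simulation protects the optimizer, at the price of occasional wasted
  simulations.
* Recovery accuracy at the extremes of the envelope is limited by the
  photon budgets, and for $\mu_a$ below $10^{-3}$ mm$^{-1}$ the cost is
  nearly flat in $\mu_a$ — the water-only analogs recover $\mu_s'$ tightly
  while $\mu_a$ has essentially unbounded relative spread, mirroring the
  physical system's behavior.
* Only homogeneous, smooth-surfaced, single-layer media are modeled;
  layered media, fluorescence, polarization and phase functions other
  than HG are out of scope.
* `g` and `n` are fixed inputs, never fitted; the inversion is strictly
  two-parameter.
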