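# srrtwin

A Monte Carlo digital twin of a spatially resolved reflectance (SRR)
imaging system, for non-contact recovery of the absorption coefficient
μa and the reduced scattering coefficient μs′ of turbid media — tissue
phantoms, sphere suspensions, and ultimately in vivo tissue.

SRR imaging focuses an oblique beam onto the sample surface and images
the diffusely remitted light with a cooled 16-bit CCD; the radial decay
R(ρ) of the remitted intensity encodes (μa, μs′) in mm⁻¹ under the
Henyey–Greenstein phase function with anisotropy g and medium index n.
The package provides:

* a compiled photon-transport kernel for a homogeneous slab with an
  oblique, profile-weighted incident beam, Fresnel boundaries, and a
  pixel-grid surface detector (`simulate_srr_image()`,
  `simulate_pencil_image()`, `convolve_with_beam()`), plus a
  diffusion-dipole oracle (`diffusion_reflectance()`);
* perturbation Monte Carlo: stored photon paths (exit pixel, weight,
  collision count j, path length L) are re-weighted by
  (μ̂s/μs)^j · exp(−(μ̂s−μs)L) · exp(−(μ̂a−μa)L) to evaluate nearby
  coefficients and assemble Jacobians without re-simulation
  (`rescale_reflectance()`, `jacobian_columns()`);
* the CCD preprocessing chain: flat-field correction, columnar bloom
  detection and radial back-fill, 1×/10×/100× exposure stitching,
  normalization by integration time and monitor-photodiode voltage, and
  radial binning with the window rule ρ0 = ρr + dρ,
  R(ρ0)/R(ρm) = 10³ (`patch_exposure_series()`, `radial_bin()`,
  `fit_window()`);
* the scaling-coefficient calibration k(ρ) = R_MC/R_exp and its window
  average k̄ (V·ms), which ties camera units to per-photon units via a
  reference sample (`scaling_profile()`, `scaling_coefficient()`,
  `apply_scaling()`);
* a Levenberg–Marquardt inversion of the log-residual cost
  χ² = (1/P) Σ (log₁₀ R_MC − log₁₀ R_exp,sc)²/σ² with common random
  numbers, pMC Jacobians and a trust-region surrogate (`lm_fit()`,
  `origin_shift_sensitivity()`), with broom-style `tidy()`/`glance()`
  and `autoplot()` methods;
* a synthetic camera (gain, shot and read noise, dark offset, full-well
  clipping with columnar blooming, auto-exposure to 30,000 counts) and
  scenario generator so the entire pipeline closes on known ground truth
  without hardware (`camera_model()`, `render_frame()`,
  `generate_scenario()`, `run_closed_loop()`).

## A worked example

Simulate a "measured" curve for a known medium, then recover the
coefficients from it:

```r
library(srrtwin)

grid <- grid_spec(256, 256, pixel_scale = 0.0361, incidence_deg = 21)
beam <- make_beam_profile(grid = grid)          # 0.27 mm core + halo
geom <- sample_geometry(thickness_d = 55.5)     # filled beaker, in mm

truth <- optical_props(mu_a = 0.02, mu_s_prime = 2, g = 0.8, n = 1.33)
sim   <- simulate_srr_image(truth, geom, beam, sim_config(5e5, seed = 42))
curve <- radial_bin(sim$image)                  # R(rho), mm^-2 per photon

fit <- lm_fit(curve, beam, geom,
              fit_config(n_photons_per_iter = 1e5,
                         n_photons_final = 5e5, seed = 7))
glance(fit)
```

```
# A tibble: 1 x 5
  mu_a_hat mu_s_prime_hat chi2_final iterations converged
     <dbl>          <dbl>      <dbl>      <int> <lgl>
1   0.0200           1.97   0.000238          8 TRUE
```

The fit starts from the fixed initial guess (0.01, 1.0) mm⁻¹ and, for
this run, recovers μa = 0.0200 mm⁻¹ (truth 0.02, 0.2% high) and
μs′ = 1.97 mm⁻¹ (truth 2, 1.3% low); `chi2_final` is the mean squared
log₁₀ residual over the fit window, i.e. a residual RMS of about 3.5%
per bin, at the Monte Carlo noise floor of these photon budgets.
`tidy(fit)` returns the per-iteration trace and `autoplot(fit)` plots
it; `plot_fit_overlay()` overlays measured and simulated curves.

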