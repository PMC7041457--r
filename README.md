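# brillouin

Denoising and estimation for low-SNR Brillouin spectra.

Brillouin microspectroscopy probes the mechanics of a sample — phonon
velocity and lifetime — through the frequency shift Ω and linewidth Γ of
the weak Stokes/anti-Stokes doublet that inelastically scattered light
acquires around the elastic Rayleigh line. In biological and endoscopic
settings the photon budget is small, the signal-to-noise ratio (SNR)
routinely drops below ~10, and direct Lorentzian fitting of the doublet
becomes unreliable. This package is for spectroscopists who want to push
estimation into that regime: it reconstructs noisy 1-D spectra before
fitting and quantifies what the reconstruction buys.

Core methods:

* **Maximum entropy reconstruction (MER)** — `mer_reconstruct()` selects,
  among all positive spectra consistent with the data in the χ² sense

      χ² = (1/N′) Σ_j ((R f)_j − d_j)² / σ_j²  ≤  χ₀²   (χ₀² ≈ 1),

  the one maximising the Shannon entropy S = −Σ p log p (p = f/Σf), by
  conjugate-gradient ascent on the Lagrangian Q = S − λ(χ² − χ₀²) with a
  Wolfe line search. Approximate peak knowledge enters as the model m of
  a relative entropy −Σ p log(p/m). The iteration stops when
  ½‖∇S/|∇S| − ∇χ²/|∇χ²|‖² < 0.01, and over-noisy data are flagged up
  front (`me_solution_exists()`).
* **Wavelet shrinkage (WA)** — `wa_denoise()` soft-thresholds the detail
  levels of an orthonormal DWT (default `sym8`) at the universal
  threshold T = σ̂ √(2 ln N), σ̂ estimated robustly from the finest level.
* **Lorentzian fitting** — `fit_brillouin()` fits a symmetric (or free)
  Stokes/anti-Stokes pair plus Rayleigh line by Levenberg–Marquardt with
  an analytic Jacobian, returning a classed model object with the usual
  `coef`/`predict`/`plot`/`residuals` methods. `speed_of_sound()`
  converts Ω to the acoustic velocity v = Ωλ₀/(2n sin(θ/2)).
* **Precision bound and benchmark** — `crlb_shift_std()` evaluates the
  Cramér–Rao lower bound σ²_Ω ≥ πΔ(αΓ+γ)³(1+2I)²/(4X²·SNR²·α²·I²) for a
  pixelated dispersive spectrometer; `run_benchmark()` measures bias and
  standard deviation of every estimation pipeline against it by
  Monte-Carlo simulation, with a synthetic spectrometer
  (`spectrometer_model()`, `synth_truth()`, `add_noise()`) emulating a
  120-pixel, 60-GHz instrument.

## Worked example

Simulate a noisy spectrum at SNR 2 (noise σ = half the Brillouin peak),
reconstruct it with MER using approximate peak positions, and fit:

```r
library(brillouin)

s <- simulate_spectrum(snr = 2, seed = 42)
s
#> Brillouin spectrum: 120 pixels, -30 to 29.5 GHz (0.5 GHz/pixel)
#>   intensity range: [-1321, 9821]
#>   noise sigma: 500 (mean)
#>   meta: snr = 2, seed = 42

r <- mer_reconstruct(s, prior = peak_set())
r
#> Maximum entropy reconstruction
#>   converged: TRUE after 178 iterations (termination metric 0.00781)
#>   entropy -0.0231326, chi-squared 0.8973 (lambda = 0.42)

fit_brillouin(as_spectrum(r))
#> Brillouin Lorentzian fit
#>   shift: 10.0449 GHz   linewidth (FWHM): 0.8035 GHz   amplitude: 1238
#>   Rayleigh: amplitude 1.014e+04, FWHM 1.0080 GHz
#>   RMS residual: 7.07% of the Brillouin amplitude
```

The reconstruction converged onto the consistency surface (χ² = 0.90 ≈
χ₀²) and the fitted shift, 10.04 GHz, recovers the simulated truth
(10 GHz) to 0.4% despite the doublet sitting only 2σ above the noise.
Fitting the *raw* spectrum instead locks onto a noise spike:

```r
fit_brillouin(s)
#> Brillouin Lorentzian fit
#>   shift: 24.7084 GHz   linewidth (FWHM): 0.0088 GHz   amplitude: 1.31e+06
#>   ...
```

The matching precision bound and the velocity conversion:

```r
crlb_shift_std(crlb_params(spectrometer_model(), peak_set(), noise_sigma = 500))
#> [1] 0.2009   # GHz

speed_of_sound(7.07, wavelength_nm = 561, refractive_index = 1.33,
               scattering_angle_deg = 180)
#> [1] 1491.06  # m/s, water-like
```

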