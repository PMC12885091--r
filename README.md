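# specklesim

Simulation and estimation of deep-tissue blood flow from diffuse speckle
contrast.

Camera-based diffuse optical methods — speckle contrast optical
spectroscopy (SCOS), speckle plethysmography (SPG), look-up-table (LUT)
inversion, and multi-exposure speckle imaging (MESI) — estimate a blood
flow index (BFI, cm²/s) from the decay of speckle contrast with camera
exposure time. Single-exposure variants are attractive instrumentally but
depend on an assumed speckle averaging factor β and on where one exposure
sits on the decorrelation curve; multi-exposure fitting recovers F and β
jointly from the whole visibility curve. `specklesim` is for researchers in
biomedical optics who want a tested, reproducible sandbox to quantify that
trade-off: a semi-infinite forward model, a multiplicative noise model,
all four estimators, error metrics, a synthetic pulsatile-flow generator,
and Monte-Carlo experiment drivers.

## Model

The electric-field autocorrelation of diffusely scattered coherent light
from a homogeneous half-space with Brownian scatterer dynamics is

    g1(τ) = [exp(−K(τ)·r1)/r1 − exp(−K(τ)·rb)/rb] /
            [exp(−K0·r1)/r1 − exp(−K0·rb)/rb],
    K(τ)  = sqrt(3·μa·μs′ + 6·μs′²·k0²·F·τ),

and the speckle variance at exposure T is

    K²(T) = (2β/T) ∫₀ᵀ (1 − τ/T) · g1(τ)² dτ.

Estimators: MESI fits (F, β) to K²(T) by Nelder–Mead least squares; the
LUT inverts one exposure through a precomputed K²(exposure, β, BFI) table
at an assumed β; SCOS uses BFI = 1/K²; SPG uses BFI = 1/(2·T·K²) (identical
to SCOS for relative changes). Noise enters as
K²_noisy = K²_true·(1 + α·N(0,1)) per exposure.

## Worked example

```r
library(specklesim)

op    <- optical_properties()            # 785 nm, μa=0.1, μs′=10, ρ=3 cm, n=1.4
truth <- flow_state(bfi = 1.5e-8, beta = 0.35)

# a noisy 1000-exposure visibility curve (0.01–10 ms), ±10% noise
curve <- visibility_curve(make_exposure_grid(1000), truth, op)
noisy <- apply_noise(curve, noise_spec(alpha = 0.10, seed = 42), trial_index = 1)

fit_mesi(noisy, op)
#> MESI fit: BFI = 1.57727e-08 cm^2/s, beta = 0.3615 (SSE 0.0542, converged, 120 evals)

# single-exposure LUT inversion of the same flow at 0.1, 1 and 5 ms
lut <- build_lut(op)
sm  <- sample_exposures(apply_noise(visibility_curve(c(1e-4, 1e-3, 5e-3), truth, op),
                                    noise_spec(0.10, seed = 42), 2),
                        c(1e-4, 1e-3, 5e-3))
bfi_lut <- invert_lut(lut, sm, beta_assumed = 0.35)
round(bfi_percent_error(bfi_lut, truth$bfi), 2)
#> [1] 7.52 3.45 0.91
```

The MESI fit recovers the flow within ~5% and β within ~3% from a single
±10% noisy curve; the three single-exposure LUT inversions of the *same*
flow (with β known exactly) err by 7.5%, 3.5% and 0.9% depending on which
exposure was used — the exposure-placement sensitivity the package is
built to quantify. Under β mismatch or stronger noise the single-exposure
errors grow quickly (see the experiment drivers `run_beta_mismatch()`,
`run_noise_comparison()`, `run_pulsatile()`, `run_exposure_reduction()`),
while MESI degrades gracefully.

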