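# meercbct

Joint multi-energy reconstruction and element decomposition for
kVp-switching cone-beam CT, with the acquisition simulator and evaluation
protocol needed to study low-concentration iodine detectability on a
digital phantom.

## The problem

Iodine contrast is hard to see in cone-beam CT: at the concentrations that
are safe to inject repeatedly, a conventional filtered-back-projection
(FBP) image buries the enhancement in noise. If the tube voltage cycles
through 80/100/120 kVp during a single rotation, however, the scan carries
spectral information, and the energy dependence of iodine's attenuation
(driven by its 33.17 keV K-edge) separates it from water-like tissue.

This package implements a convex joint model that reconstructs the
attenuation images of all three energy channels *and* decomposes every
voxel into relative electron density ρ and elemental mass fractions
λ = (H, O, I) at the same time. With the per-channel empirical attenuation
model

    f_i = ρ (k_i^PE · z̃^3.62 + k_i^R · ẑ^1.86 + k_i^C),

compositions expressed over a tissue dictionary Λ (λ = VΛ, V sparse and
nonnegative), and the convexified variable X = ρ·V, the estimate solves

    min_{F, X ≥ 0}  ½‖PF − B‖²_F + (β/2)‖F − XA‖²_F
                    + α₁ Σᵢ ‖W fᵢ‖₁ + α₂ Σⱼ ‖xⱼ‖₁ ,

where W is a Parseval tight frame (undecimated piecewise-linear framelet),
A = ΛK + K_EC maps dictionary coefficients to channel attenuations, and the
problem is solved by a nested ADMM (conjugate-gradient F-subproblem,
framelet shrinkage, inner ADMM for X). Afterwards ρ = diag(X·1),
V = ρ⁻¹X, λ = VΛ, and an iodine mg/ml map follows.

Everything needed to reproduce the simulation study ships with the package:
a Siddon fan-beam projector and fan-beam FBP, filtered-Kramers spectra with
embedded mass-attenuation tables, a polyenergetic Poisson-noise scan
simulator, the nine-insert iodine phantom (20 cm water cylinder, 3 cm
inserts at 0.1–10% dilutions of a 175 mgI/ml stock), scanner calibration,
and enhancement / CNR / concentration-error metrics.

## Worked example

```r
library(meercbct)

# a desk-scale study: 128 x 128 grid (2 mm pixels), 600 views cycling
# 80/100/120 kVp at 1.4/0.8/0.5 mAs
ex <- run_experiment(experiment_config(methods = c("fbp200", "se", "meer"),
                                       seed = 1))
print(ex)
#> simulation-study results (fbp200, se, meer)
#> mean relative iodine concentration error: 46.6%

subset(ex$report, insert == 6 & kvp == 80)   # the 3% dilution insert
#>    method kvp insert concentration enhancement_hu       cnr
#> 6  fbp200  80      6          0.03       275.5034  1.516437
#> 30     se  80      6          0.03       272.3343 54.289108
#> 54   meer  80      6          0.03       267.4307 63.480072
```

Reading: the 3% insert enhances by ~270 HU at 80 kVp in all methods (the
iterative reconstructions preserve contrast), but on the dose-matched
200-view data its CNR is ~1.5 for FBP versus ~54–63 for the regularized
reconstructions — the insert goes from invisible to obvious. The iodine map
of the joint reconstruction recovers the high-concentration inserts within
about 10%; estimates at the 0.1–0.5% inserts are noise-limited at this 2-D
desk scale, which dominates the mean relative error above.

```r
maps <- recover_decomposition(ex$recon)
summary(maps$rho)                 # relative electron density map
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.0000  0.0000  0.1133  0.4718  0.9765  1.3077
image(ex$images$iodine_mg_ml)     # iodine concentration in mg/ml
ex$recon$trace                    # objective / relF / relX per iteration
```

A thin command-line driver with the same functionality is installed at
`system.file("cli", "meercbct", package = "meercbct")` (subcommands:
`phantom`, `simulate`, `recon-fbp`, `recon-se`, `recon-meer`, `evaluate`,
`sweep`, `reproduce-sim-study`).

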