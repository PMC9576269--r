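# shearcyte

Quantitative viscoelastic phenotyping of suspended cells by **shear flow
deformation cytometry**. Cells suspended in a high-viscosity,
shear-thinning medium (e.g. a 2% alginate solution) are pumped at
50–300 kPa through a long microchannel with a 200 × 200 µm square cross
section and imaged in bright field at the channel mid-plane. The fluid
shear stress deforms each cell into an ellipsoid and the velocity
gradient makes it rotate in a tank-treading manner; from the steady-state
shape, alignment angle, and rotation rate, the package computes each
cell's storage modulus G′ and loss modulus G′′ and scales them to a
1 Hz power-law stiffness *k* and fluidity *α*. It is written for
cell-mechanics labs analyzing such experiments (from images or from
pre-computed detection tables) and ships a forward simulator so the whole
analysis can be validated closed-loop against known ground truth.

## The model in brief

* **Stress field.** In a long channel of square cross section the
  mid-plane shear stress depends only on geometry and pressure:

      σ(y) = | (4H²ΔP)/(π³L) Σ_{n odd} (−1)^((n−1)/2) (π/(n²H))
               cos(nπz/H) sinh(nπy/H)/cosh(nπW/2H) |

  summed over the first 100 odd terms. σ is zero at the channel center
  and maximal at the walls (116 Pa at 100 kPa, 349 Pa at 300 kPa for
  W = H = 200 µm, L = 5.8 cm).

* **Suspension fluid.** Shear thinning follows the Cross model
  η(γ̇) = η₀ / (1 + (τγ̇)^δ). The shear rate solves σ = η(γ̇)·γ̇ by
  Newton–Raphson; integrating γ̇ from the wall gives the velocity
  profile, and fitting that profile to the observed cell speeds yields
  (η₀, τ, δ) without a separate rheometer measurement.

* **Cell mechanics.** With the measured semi-axes a ≥ b normalized to
  the undeformed radius r₀ = √(ab), ellipsoid shape integrals give the
  strain ϵ = (ã² − b̃²)/(2I), and the theory of a tank-treading
  viscoelastic sphere in viscous shear flow (Roscoe) yields

      G′  = (5/2) σ sin(2β) / ϵ

  from the alignment angle β, and G′′ in closed form from the
  alignment-angle relation (see the methods vignette). Both moduli refer
  to twice the angular tank-treading frequency, ω = 2·2π·f_tt, because a
  volume element is compressed and stretched twice per rotation.

* **Tank treading.** f_tt is measured by dense optical flow on crops of
  the rotating cell interior (through-origin fit of normalized
  tangential speed against the ellipse-corrected radius r̃ < 0.7), with
  a fallback to the empirical master relationship
  ω_tt = (γ̇/2) / (1 + (0.113·γ̇)^0.45), which approaches the Einstein
  limit ω_tt/γ̇ → 1/2 at low shear rates.

* **Population scaling.** Per-cell moduli are scaled to 1 Hz via the
  structural-damping (power-law) model G̃ = k (iω/ω₀)^α Γ(1−α), giving
  α = (2/π)·atan(G′′/G′) and k from G′. The population is summarized by
  the mode of the 2-D Gaussian kernel density of (log₁₀ k, α).

## Worked example

Simulate an experiment at 200 kPa with a known population
(mode k = 100 Pa, α = 0.35) and run the full analysis on the resulting
detection table:

```r
library(shearcyte)

geometry <- channel_geometry(width = 200e-6, height = 200e-6, length = 0.058)
fluid    <- cross_model(eta0 = 4, tau = 0.1, delta = 0.55)
state    <- channel_state(geometry, pressure = 2e5, fluid)

shear_stress(state, y = 100e-6)      # 233 Pa at the wall
velocity_profile(state, 0) * 1e3     # 17.6 mm/s center-line speed

pop <- population_params(log10_k_mean = 2, alpha_mean = 0.35, n_cells = 2000)
tab <- simulate_cytometry(pop, state)    # detection table (CSV schema)
res <- evaluate_cytometry(tab)
print(res)
#> Shear flow deformation cytometry result
#>   cells: 1976 evaluated, 1762 valid
#>   fluid: eta0 = 3.74 Pa s, tau = 0.0832 s, delta = 0.557
#>   population mode: k = 94.7 Pa, alpha = 0.338
```

The recovered population mode (94.7 Pa, 0.338) matches the simulated
truth (100 Pa, 0.35) within the sampling accuracy of a 2000-cell kernel
density mode; 167 cells were excluded for lying within one cell radius
of the channel center (where the stress is non-monotonic across the
cell) and 47 for an alignment angle inconsistent with a positive loss
modulus. `write_results()` exports the per-cell table
(`...,Gp_pa,Gpp_pa,k_pa,alpha,valid_flag`) and the summary JSON.

A command-line wrapper is installed as `exec/sfdc` with subcommands
`simulate`, `evaluate`, `fit-fluid`, and `summarize` (YAML config,
CSV/JSON outputs).

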