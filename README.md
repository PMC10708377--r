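# pisawheel

Oriented-sample solid-state NMR analysis of membrane-protein helices,
built around the syndecan-4 transmembrane construct (Syd4-eTC): PISA-wheel
forward simulation, helix tilt fitting from separated-local-field peak
lists (including a two-wheel dimer fit), and chemical-shift-perturbation
(CSP) mapping of ligand binding from HSQC peak lists. A synthetic peak-list
generator makes every stage runnable and testable without spectrometer
data.

## The science in brief

A transmembrane α-helix in a magnetically aligned bicelle produces a
characteristic circular pattern — a **PISA wheel** (polarity index slanted
angle) — in a 2D separated-local-field spectrum (SAMMY/PISEMA), which
correlates the ¹⁵N chemical shift with the ¹H–¹⁵N dipolar coupling of each
amide. Both observables are orientation-dependent:

- chemical shift: σ_obs = σ₁₁c₁² + σ₂₂c₂² + σ₃₃c₃², the projection of the
  ¹⁵N CSA tensor onto the bilayer normal (cᵢ = direction cosines onto the
  principal axes);
- dipolar coupling: ν = ν∥ (3 cos²θ − 1)/2, with θ the angle between the
  N–H bond and the normal.

In an aligned bicelle both anisotropic deviations are scaled by S·f, the
order parameter times the alignment factor (f = −1/2 for an unflipped
bicelle, +1 for a flipped one). For an ideal helix (here φ = −69°,
ψ = −42°) tilted by τ from the bilayer normal, the per-residue peaks trace
a closed wheel whose size and position encode τ and the azimuthal rotation
ρ₀. `pisa_wheel()` computes the forward model; `fit_tilt()` inverts it by
grid search + golden-section refinement against an observed peak list;
`fit_two_wheels()` fits a two-component mixture for a GXXXG-mediated dimer
whose monomers sit at different tilts.

Ligand binding is mapped with the standard chemical shift perturbation
score per residue,

CSP = √( ΔδH² + α·ΔδN² ),  α = 0.14,

between a free and a ligand-bound HSQC peak list (`compute_csp()`,
`flag_perturbed()`).

## Worked example

Simulate a dimer spectrum at tilts 6° and 16° with realistic noise, fit it
back, and map a localized perturbation:

```r
library(pisawheel)

cons  <- sdc4_construct()              # 57-residue construct, offset 142
helix <- csa_frames(build_helix(-69, -42, 25))

peaks <- gen_dimer_slf(
  helix, csa_tensor(), wheel_params(6, 0), wheel_params(16, 90),
  bicelle_model(0.85), synth_spec(seed = 42, noise_shift = 0.3, noise_coupling = 0.06),
  residues_a = 2:13, residues_b = 14:25, keep_component = FALSE
)
tidy(fit_two_wheels(peaks, helix))
#> # A tibble: 2 × 6
#>   component tilt_deg rho0_deg   rmsd n_peaks empty
#>       <int>    <dbl>    <dbl>  <dbl>   <int> <lgl>
#> 1         1     6.38    352.  0.0156      12 FALSE
#> 2         2    15.8      90.0 0.0139      12 FALSE
```

Both generating tilts are recovered (6.38° and 15.8° for truths 6° and
16°); `rmsd` is the root-mean-square distance between matched simulated
and observed peaks in normalized spectral units.

```r
pair <- gen_hsqc_pair(cons, synth_spec(seed = 42, perturbations = list(`47` = c(0.1, 0.5))))
csp  <- flag_perturbed(compute_csp(pair$free, pair$bound), k = 3)
csp
#> <csp_result> 54 residues scored (alpha = 0.14), 0 unmatched
#>   mean_plus_sd threshold 0.1133 ppm: 1 residue(s) flagged (47)
```

The injected perturbation at construct position 47 (the V-domain tyrosine)
is the unique flagged residue. `tidy(csp, construct = cons)` adds
full-length residue numbers; `autoplot(csp)` and `autoplot(fit)` draw the
CSP profile and the wheel overlay. `find_gxxxg(cons)` locates the
transmembrane dimerisation motif (positions 12–16, `GGVVG`).

A thin CLI over the same functions ships in `inst/cli/pisawheel`
(subcommands `construct`, `simulate-wheel`, `fit-tilt`, `csp`, `synth`,
`run`); `run_pipeline()` executes the whole chain from a declarative YAML
config.

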