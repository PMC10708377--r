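---
title: "PISA wheels, tilt fitting and CSP mapping: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PISA wheels, tilt fitting and CSP mapping: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pisawheel)
```

This vignette is the package's account of the science it implements: the
forward model for oriented-sample solid-state NMR observables of a
transmembrane helix, the tilt-fitting procedure, the chemical shift
perturbation (CSP) analysis, and — because several constants the models
need are not uniquely fixed by convention — the design decisions behind
every default.

## The construct

The package is built around Syd4-eTC, a 57-residue syndecan-4 construct:
a four-residue ectodomain stub, the 25-residue transmembrane (TM) helix,
and the full cytoplasmic domain with its conserved-1 (C1), variable (V)
and conserved-2 (C2) subregions. `sdc4_construct()` carries the sequence,
the domain annotation and the mapping to full-length numbering.

Two numbering details deserve mention:

- **Numbering offset.** With the default offset (`first_full_number =
  142`) the unique cytoplasmic serine at construct position 38 maps to
  Ser179, the PKC-regulatory phosphosite of syndecan-4. Under the same
  offset the V-domain tyrosine at construct position 47 maps to 188,
  whereas parts of the literature call it Tyr187 — the two conventions
  differ by one residue and cannot both hold for this sequence. The offset
  is a constructor parameter so either can be selected; the package
  asserts neither as correct.
- **Domain boundaries** (ecto 1–4, TM 5–29, cyto 30–57; C1 30–39, V
  40–52, C2 53–57) are configurable; no authoritative boundary table
  exists for this construct, and nothing downstream depends on them except
  the default length of the simulated TM helix.

`find_gxxxg()` scans for the glycine-zipper motif; the TM domain carries
exactly one (positions 12–16, GGVVG), the motif implicated in helix–helix
dimerisation and hence the two-wheel fit below.

## Ideal helix geometry

`build_helix()` generates an ideal backbone by iterating standard peptide
geometry (N–Cα 1.458 Å, Cα–C 1.525 Å, C–N 1.329 Å, ideal sp² amide
angles, ω = 180°) at fixed torsions, then rigidly maps the screw axis onto
+z. The default torsions φ = −69°, ψ = −42° are the optimized TM-helix
values used throughout; the canonical α-helix (−57.8°, −47.0°) is a
useful check, giving the textbook 1.5 Å rise.

The amide hydrogen is placed in the peptide plane **anti to the carbonyl
oxygen** of the preceding residue (N–H length 1.02 Å, configurable). This
choice matters: it gives an N–H/axis angle of 15.4° for the canonical
helix — the literature value — whereas the cruder bisector placement
(H opposite the bisector of C′–N and Cα–N) gives 11.8°. The N–H/axis
angle is the single geometric quantity that sets the PISA wheel size, so
the placement convention propagates directly into simulated couplings.
For φ = −69°/ψ = −42° the angle is 17.9°.

PISA observables are only weakly sensitive to the bond lengths and angles
themselves, which is why they are fixed constants rather than parameters.

## The ¹⁵N tensor and its orientation

The forward model needs the three ¹⁵N principal values and the tensor's
orientation in the molecular frame. The simulation parameters for this
system fix σ₁₁ = 64 ppm and σ₂₂ = 77 ppm (88 ppm is a common alternative,
selectable in `csa_tensor()`); **no σ₃₃ is fixed by them**, so the package
defaults to 217 ppm, a standard literature value for backbone amides.
Likewise the orientation is not fixed; the package uses the common
convention: σ₃₃ in the peptide plane at β = 17° from the N–H bond
(rotated towards N–C′), σ₂₂ perpendicular to the peptide plane
(`csa_frames()`, β configurable). The amide ¹H shift tensor (3, 8,
17 ppm) can be represented with the same constructor and projected with
the same operation, but no ¹H-shift dimension is simulated by default —
it is not used quantitatively in this analysis.

The maximal dipolar coupling defaults to ν∥ = 10.52 kHz (an effective
N–H distance of 1.066 Å, which folds librational averaging into the bond
length). It is a configuration value, not a fitted one.

## Bicelle scaling and the forward model

An aligned bicelle scales anisotropic deviations by S·f:

- observed shift = σ_iso + S·f·(σ_static − σ_iso)
- observed coupling = S·f·ν_static

with S the order parameter (default 0.85, the upper end of the 0.80–0.85
range typical for q ≈ 3 bicelles) and f = −1/2 (unflipped, the default)
or +1 (flipped). `pisa_wheel()` evaluates the static frequencies along
the bilayer normal expressed in the molecular frame — the closed form
d(τ, ρ₀) = (−sin τ cos ρ₀, sin τ sin ρ₀, cos τ) — which the test suite
verifies to 10⁻⁹ against a brute-force path that builds the full rotation
matrices and rotates every tensor axis into the laboratory frame.

Coupling values are reported as magnitudes (the 2D experiment measures
|ν|); the sign is kept in a separate column. No additional pulse-sequence
scaling factor is applied to the coupling axis: the 2–4.5 kHz band used
for TM classification is taken to be the S·f-scaled coupling itself.

At the two tilts relevant here (6° and 16°, S = 0.85, unflipped,
ν∥ = 10.52 kHz) the simulated TM couplings span 2.38–4.46 kHz over a full
azimuthal scan — inside the 2–4.5 kHz transmembrane band, which is the
package's main quantitative contact with the experimental record
(`scripts/acceptance.R` recomputes it).

**1D topology classification.** `classify_1d()` labels ¹⁵N shifts below
120 ppm as surface and at/above as transmembrane — the convention stated
in the oriented-sample literature this package accompanies. The function
attaches a note recording that unflipped-bicelle physics with a standard
amide σ₃₃ predicts the *opposite* direction (a TM amide, N–H nearly along
the normal, projects near σ₃₃ = 217 ppm statically, which f = −1/2 maps
to ≈ 78 ppm, below isotropic). Both the threshold and the direction are
arguments; the package implements the stated rule and does not
adjudicate.

## Tilt fitting

`fit_tilt()` inverts the forward model by exhaustive grid search (default
τ 0–30° in 0.5° steps, ρ₀ 0–360° in 5° steps) followed by two passes of
golden-section refinement in τ and ρ₀. There is no random initialisation;
the procedure is deterministic. The objective is the root-mean-square
distance between simulated and observed peaks after dividing each axis by
its span — by default the bicelle-scaled anisotropy breadths
(σ₃₃ − σ₁₁)·S·|f| for the shift axis and ν∥·S·|f| for the coupling axis —
so both dimensions contribute comparably. No metric is canonical here;
this one is the package's choice and is exposed via the `scale` argument.

Peak correspondence: when the observed list carries residue labels,
matching is label-constrained; otherwise the minimum-total-cost one-to-one
assignment over min(n, m) pairs is computed with an in-package Hungarian
(shortest-augmenting-path) solver, verified in tests against exhaustive
permutation enumeration. Cost ties are resolved deterministically by the
solver's fixed scan order.

`fit_two_wheels()` handles the dimer interpretation: a coarse joint grid
over both (τ, ρ₀) pairs scores every candidate pair by assigning each
observed peak to its nearer wheel; the best pair seeds per-component local
refinement (a fine `fit_tilt()` on each component's peaks) with one
reassignment round. Components are reported ordered by tilt, and a
component that captures no peaks is flagged rather than silently dropped.
On noiseless synthetic mixtures generated at 6° and 16° the procedure
recovers both tilts within 1°; under the synthetic noise model
(0.5 ppm / 0.1 kHz), single-wheel tilt recovery is within 2° in at least
18 of 20 seeded replicates (both are test-suite properties).

Because the experimental SAMMY peak coordinates for this system were
never published as tables, the 6°/16° tilts cannot be re-fitted from real
data; parameter recovery on synthetic data generated at those truths is
the substitute, and that is exactly what the test suite measures.

## CSP analysis

`compute_csp()` implements CSP = √(ΔδH² + α·ΔδN²) per residue between two
assigned peak lists. Defaults and decisions:

- **α = 0.14**, the field-standard nitrogen weighting for backbone
  amides; the methodology papers this value descends from are the source,
  since no α is printed alongside the equation for this system.
- **The radical.** The equation as printed in the accompanying study
  lacks the square root; the square-root form is the universal CSP
  definition in the cited methodology and is the default. The literal
  no-radical form is available via `sqrt_form = FALSE` for comparison.
- Residues present in only one list are reported as unmatched, never
  scored; duplicate assignments are an error, and unassigned lists are
  rejected (assignment itself — an HMQC-NOESY workflow — is outside this
  package's scope and is emulated by labelled synthetic lists).

`flag_perturbed()` offers a `mean + k·sd` rule (default k = 1) and a
fixed-threshold rule. A caveat the package is explicit about: with ~54
scored residues and Gaussian position noise, k = 1 flags ≈ 16% of
unperturbed residues by construction (≈ 8–9 false positives), so it can
rank residues but cannot isolate a single binding site. Where the
analysis requires a *specific* flag — as in the end-to-end tests that
inject one perturbed residue and require it to be the unique hit — the
package uses k = 3. The k = 1 default is kept because it is the common
first-pass convention; users mapping a binding site should raise k (or
use a fixed threshold) exactly as the tests do.

## Synthetic data

`synth_spec()` + the three generators stand in for the study's spectra;
all stages of the pipeline are exercised end-to-end with no external
data. What they emulate, and what they do not:

- `gen_hsqc_pair()`: one amide cross-peak per residue (residue 1 and the
  two prolines, construct 45 and 51, carry no backbone amide and are
  skipped — 54 peaks for the full construct). Base positions are drawn
  once per residue from uniform amide windows (¹H 7.5–9.0 ppm, ¹⁵N
  105–130 ppm) seeded by the residue index, so the base spectrum is a
  fixed property of the construct and only the noise depends on the run
  seed. The bound list adds the stated perturbations. Realistic chemical
  shift statistics are irrelevant to every downstream computation (CSP
  depends only on differences); only the geometry of perturbations versus
  noise matters. Asparagine/glutamine side-chain pairs are *not*
  generated — peak-count-based multimer inference is out of scope.
- `gen_slf()` / `gen_dimer_slf()`: `pisa_wheel()` output plus independent
  Gaussian noise per axis (couplings clipped at zero, as magnitudes).
  With zero noise the generators reproduce the forward model exactly —
  a test-suite invariant guarding against hidden offsets.
- Noise defaults: HSQC 0.01 ppm (¹H) / 0.05 ppm (¹⁵N) — typical
  peak-position reproducibility in solution HSQC; SLF 0.5 ppm / 0.1 kHz —
  the far larger uncertainty of oriented-sample linewidths. The SLF
  values are also the noise conditions under which tilt recovery is
  specified.

Passing tests on these generators demonstrate correctness of the
computational chain, not instrument realism: no lineshapes, no peak
overlap, no missing assignments, no baseline artefacts. Conclusions about
real spectra inherit those caveats.

## Numerical choices and degenerate inputs

- Helix canonicalisation extracts the screw axis from a Kabsch
  superposition of residues 1..n−1 onto 2..n; near twist = 180° the
  antisymmetric-part axis formula is singular and the null-space of
  R − I is used instead. Torsions that close the backbone into a
  zero-rise ring are an error, not a silent acceptance.
- The tilt-fit profile records every evaluated point (grid + refinement),
  so the reported optimum always equals the profile minimum.
- τ = 0 collapses a wheel to a point; S = 0 collapses every observable to
  its isotropic value; the magic angle zeroes the coupling — all asserted
  as tests.
- TSV writers emit fixed six-decimal values so identical runs are
  byte-identical across platforms; `run_pipeline()` writes a run log
  containing every effective parameter, defaults included.

## Problem sizes

The test suite and acceptance script run entirely on synthetic data at
the scale of the system itself: 25-residue TM helices (24 amide peaks),
54-peak HSQC lists, 20-replicate noise studies, 100-draw oracle
comparisons and full-turn azimuthal scans in 0.5–1° steps. These sizes
were chosen as the natural scale of the analysis; the whole suite
completes in well under a minute.

## Known limitations

- Ideal straight helices only: no curvature, kinks, per-residue dynamics
  or order-parameter fitting. The slightly curved helix suggested by MD
  for this system is outside the model class.
- The dimer fit shares one helix geometry and tensor between components;
  only (τ, ρ₀) differ.
- No Kd/titration fitting: CSP is computed for a single free/bound pair.
- ρ₀ is reported in the package's own azimuth convention; comparing to
  other software requires aligning conventions (τ is convention-free).
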