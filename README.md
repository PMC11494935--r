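# ffft — force field functional theory toolkit

`ffft` is an R package for parameterizing nonreactive molecular force
fields from quantum-chemistry reference data. It is aimed at researchers
who build flexibility (bonded-interaction) models — bond stretches, angle
bends, Urey–Bradley and cross terms — and want the force constants to come
out of a *linear* regression instead of the fragile nonlinear fits that
conventional bonded/nonbonded partitions require.

## The idea

A force field splits a bonded cluster's energy into bonded and nonbonded
parts. In the conventional ("old") partition the nonbonded terms exert
forces at the equilibrium geometry, so every bonded term needs a fitted
*resting value* `d_resting ≠ d_eq`, and the regression is nonlinear. The
package implements an alternative partition in which every intracluster
nonbonded pair interaction `U(d)` is replaced by a wrapped form `Φ(d)`
satisfying

    Φ(d_eq) = Φ′(d_eq) = Φ″(d_eq) = 0,

so the nonbonded part contributes nothing to the energy, forces, or
Hessian at the reference geometry. The equilibrium internal coordinates
from the quantum calculation can then be used directly as resting values,
each flexibility term is linear in its force constant `k`, and the fit is
ordinary (optionally LASSO-regularized, box-constrained) least squares.
With a finite cutoff the wrap is also C² at the cutoff distance, built
from the smooth transition function `τ(s,t) = tanh(t/s − ½)`.

Model potentials include:

- **Stretches** — harmonic `½k(d−d_eq)²`; Morse
  `k/(2γ²)(1−e^{−γΔd})²`; and the two-exponential form
  `U = 3k/(5γ°²)·[1 − (5/2)e^{−γ°Δd} + (3/2)e^{−(5/3)γ°Δd}]`, whose
  exponent `γ°` is not fitted but computed from the decay of the two
  atoms' radial electron densities (`exponents` module), with dissociation
  limit `3k/(5γ°²)` and the predicted Morse exponent `γ_M = γ°√(5/6)`.
- **Bends** — harmonic, cosine, harmonic-cosine, MM3-style, and a
  tanh-regularized form
  `U = 2k(cosθ_eq − cosθ)² / [h(θ)(sin²θ + 3sin²θ_eq)]`,
  `h(θ) = tanh(ν sinθ/2)/tanh(ν sinθ_eq/2)`, which is a smooth function
  of `cos θ` (so all derivatives are continuous through linear angles),
  has curvature exactly `k` at `θ_eq` — including `θ_eq = π` — and
  diverges as `θ → 0` like the Pauli repulsion that keeps real bond
  angles open.
- **Urey–Bradley** (stretch form between an angle's outer atoms) and
  bond–bond cross terms.

Vibrational analysis closes the loop: harmonic normal modes come from the
finite-difference mass-weighted Hessian, and anharmonic diatomic levels
from a 1-D Schrödinger solver (central differences; Sturm-sequence
bisection for the lowest states).

## Worked example

Normal modes of CO₂ from a fitted flexibility model (two two-exponential
stretches, `k = 30.58 eV/bohr²`, `γ° = 1.203 bohr⁻¹`, plus the
regularized bend, `k = 5.17 eV`):

```r
library(ffft)
co2   <- example_molecule("CO2")                 # O=C=O, d = 1.157 A
model <- example_flexibility_model("CO2")
res   <- model_normal_modes(model, co2)
round(res$wavenumbers)
#> [1]  694  694 1363 2609
res$zero_mode_count
#> [1] 5
```

The four modes are the doubly degenerate bend (694 cm⁻¹), the symmetric
stretch (1363 cm⁻¹), and the asymmetric stretch (2609 cm⁻¹); the five
zero modes are the rigid-body translations and rotations of a linear
molecule. Experimental values are 667, 1333, and 2349 cm⁻¹ — the model
was fitted to energies only, so few-percent-level agreement is the
expected behavior.

Anharmonic H₂ levels from a Morse surrogate of the fitted stretch
(`k = 0.401 hartree/bohr²`, `γ = 1.068 bohr⁻¹`, `d_eq = 74.199 pm`):

```r
deq <- convert_unit(74.199, "pm", "bohr")
tm  <- flex_term("stretch_morse", c(1, 2), deq, 0.401, exponent = 1.068)
lev <- solve_vibrational_levels(function(d) stretch_energy(d, tm),
                                1.007825, 1.007825, deq, n_levels = 2)
round(lev$transitions_cm[1])
#> [1] 4313
```

A thin command-line front end is installed with the package
(`inst/exec/fff`), e.g.

```sh
fff freq --xyz inst/extdata/co2.xyz --model inst/extdata/co2_model.txt
```

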