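---
title: "Force-field parameterization with ffft: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-field parameterization with ffft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffft)
```

## The partition and why it linearizes the fit

A nonreactive force field writes a bonded cluster's potential energy as
bonded (flexibility) terms plus nonbonded pair interactions. Under the
conventional partition the nonbonded pairs pull on the atoms even at the
equilibrium geometry, so the resting value inside each bonded term is not
the quantum-mechanical equilibrium value and must be optimized jointly
with the force constants — a nonconvex nonlinear regression with local
minima.

`ffft` implements a partition in which every *intracluster* nonbonded
pair potential $U(d)$ is wrapped into

$$\Phi(d) \;=\; \bigl[U(d) - T_2(d)\,w(d)\bigr]\,S(d),$$

where $T_2$ is the second-order Taylor polynomial of $U$ about the
pair's equilibrium distance $d_{eq}$, $w$ damps that polynomial at large
$d$, and $S$ is a C² ramp to zero at the cutoff. By construction
$\Phi(d_{eq}) = \Phi'(d_{eq}) = \Phi''(d_{eq}) = 0$: the wrapped
nonbonded part affects only third- and higher-order derivatives at the
reference geometry. Consequences:

* the reference geometry is exactly a stationary point of the force
  field, whatever the force constants;
* equilibrium bond lengths and angles can be used directly as resting
  values, so each flexibility term is *linear* in its force constant and
  the fit is convex least squares;
* the fitted leading-order force constants barely depend on which
  nonbonded parameter set (charges, Lennard-Jones) is assumed — the
  package's test suite reproduces this directionally on a synthetic
  hexafluorobenzene-style bond scan, where the conventional fit's
  constants move by percents across parameterizations and the wrapped
  fit's by hundredths of a percent.

The damping function is built from the smooth transition function
$\tau(s,t) = \tanh(t/s - \tfrac12)$ — bounded, unit-free (a function of
$t/s$ only), monotone, and "mostly on" ($\tau^2 \approx 0.819$) at
$t/s = 2$ — as $w = 1 - \rho^3$ with
$\rho = (\tau(d_{eq}, d) - \tau(d_{eq}, d_{eq}))/(1 - \tau(d_{eq},
d_{eq}))$. Because $\rho$ has a simple zero at $d_{eq}$, the cube makes
$w - 1$ vanish to third order there, which is exactly what protects the
three equilibrium conditions; $\rho \to 1$ at large $d$ kills the
quadratic growth of $T_2$. The ramp $S$ is the quintic "smootherstep"
polynomial (zero value and first two derivatives matched at both ends),
applied from $d_{eq}$ to the cutoff for intracluster pairs and from half
the cutoff for intercluster pairs; the infinite-cutoff case is its
pointwise limit. The published constraint set for this construction
fixes values, slopes, and curvatures at $d_{eq}$ and at the cutoff but
not the interior shape; the forms above are this package's documented
choice satisfying every constraint, verified by finite differences in
the test suite.

## Model potentials

**Stretches.** Harmonic $\tfrac12 k (d - d_{eq})^2$; Morse
$\frac{k}{2\gamma^2}(1 - e^{-\gamma\Delta d})^2$; and the
two-exponential form

$$U^{\text{stretch}}(d) = \frac{3k}{5\gamma°^2}\Bigl[1 -
\tfrac52 e^{-\gamma°\Delta d} + \tfrac32 e^{-\frac53\gamma°\Delta d}\Bigr],$$

whose coefficients $5/2$ and $3/2$ are the unique solution of the
zero-energy and zero-force conditions at $d_{eq}$
(`manz_stretch_coefficients()` solves the 2×2 linear system). All three
have curvature exactly $k$ at $d_{eq}$; the bounded forms approach
dissociation limits $k/(2\gamma^2)$ (Morse) and $3k/(5\gamma°^2)$
(two-exponential). Equating force constant and dissociation energy
between the two bounded forms gives the predicted Morse exponent
$\gamma_M = \gamma° \sqrt{5/6}$.

**The exponent $\gamma°$ is computed, not fitted.** Spherically averaged
atomic radial densities decay nearly exponentially in the valence
region. For each bond the package (i) conditions both profiles by an
outer-to-inner running maximum so they are non-increasing, (ii) finds
the radius where the two conditioned densities cross along the bond
(averaging the first-exceeds and last-falls-below shells, ties broken
toward smaller radii), (iii) fits $\ln\rho = a - b\,r$ by ordinary least
squares over the asymmetric window $[D - 0.5, D + 2.5]$ bohr — biased
outward because the valence tail is what matters — and (iv) combines the
two per-bond exponents. The combining rule is a configurable slot with
default $\gamma° = b_A b_B/(b_A + b_B)$ (half the harmonic mean): it is
symmetric, positive, scale-covariant, reduces to $\gamma° = b/2$ for
equal exponents — making the short-range-repulsion exponent
$\tfrac53\gamma°$ equal to $\tfrac56$ of the average — and lets the more
slowly decaying atom dominate in the very asymmetric limit. Profiles on
finer grids give the same exponents to well under a percent (tested).

**Bends.** The package's preferred form is

$$U^{\text{bend}}(\theta) = \frac{2k\,(\cos\theta_{eq} -
\cos\theta)^2}{h(\theta)\,\bigl(\sin^2\theta + 3\sin^2\theta_{eq}\bigr)},
\qquad h(\theta) = \frac{\tanh(\nu \sin\frac{\theta}{2})}
{\tanh(\nu \sin\frac{\theta_{eq}}{2})}.$$

It is a smooth function of $\cos\theta$, hence symmetric about
$\theta = \pi$ with continuous derivatives of all orders there; the 1:3
weighting in the denominator makes the curvature at $\theta_{eq}$ equal
$k$ even when $\theta_{eq} = \pi$ (where the widely used
harmonic-cosine bend has zero curvature — the package implements that
form too, and its test suite demonstrates the deficiency); and
$h(\theta) \to 0$ as $\theta \to 0$ makes the energy diverge, standing
in for the Pauli repulsion that keeps physical bond angles open. The
tanh multiplier defaults to $\nu = 2$, a compromise value; for linear
equilibrium angles $\nu$ has no effect. Internally the form is
evaluated in the variable $x = \cos\theta$ (with the cancelled reduced
form $2k(1+x)/[h(1-x)]$ when $\theta_{eq} = \pi$), so gradients stay
finite and smooth through exactly linear geometries, where
$\theta$-parameterized forms are singular.

Angles are always measured with the cosine clamped to $[-1, 1]$, so
collinear triads with roundoff can never produce NaN; reference triads
collinear to within $10^{-8}$ rad store $\theta_{eq}$ exactly as $\pi$,
and no other rounding of near-linear angles is applied (rounding a
178–179° equilibrium up to 180° would shift the model's minimum).

**Basis stretches.** For series expansions of a bond energy the package
provides the bounded basis family

$$g_m(d) = \bigl(1 - 2^{\,1 - d/d_{eq}}\bigr)^2\,
\bigl(1 - 2e^{-2d/d_{eq}}\bigr)^m,$$

designed to satisfy four published limit constraints — $g_m = 0$ and
$g_m' = 0$ at $d_{eq}$, $g_m \to 1$ at infinite separation, and
$g_m(0) = (-1)^m$ — while keeping nonzero curvature at $d_{eq}$ for
every $m$ (the first factor has a double zero at $d_{eq}$; the second
carries the sign alternation). These four constraints do not pin a
unique functional form; this closed form is the package's own choice and
is what the LASSO-path demonstrations use.

## Fitting

The design matrix holds each term's unit-force-constant energy per
geometry (optionally negative unit gradients as force rows), so the
model prediction is exactly `X %*% k`. `fit_linear()` minimizes
$\tfrac12\sum w_i r_i^2 + \lambda \sum_\gamma |k_\gamma|$ by cyclic
coordinate descent with soft thresholding and per-coefficient box
bounds — no intercept, no standardization, so $\lambda$ values are
comparable across runs of this package but only qualitatively to other
solvers' conventions. Stretch, bend, and Urey–Bradley constants default
to $k \ge 0$; cross-term constants are unbounded. Identically zero
design columns abort the fit with the offending term named rather than
being dropped. With $\lambda = 0$ and a feasible full-rank solution the
exact weighted least-squares answer is returned directly. Convergence:
relative coefficient change below $10^{-10}$, iteration cap $10^5$.

The conventional-partition fit (`fit_old_scheme()`) optimizes force
constants and resting values jointly with Levenberg–Marquardt under box
bounds, restarted from five deterministic starts (resting values at the
equilibrium values ±0, 1, 2 %) because such fits are prone to local
minima; the best sum of squares wins, and non-convergence is reported
with best-so-far parameters, never silently.

Training rosters follow a displacement protocol: a full Cartesian
product of per-bond offsets $\{-0.14, -0.07, 0, +0.07, +0.14\}$ Å at the
frozen equilibrium angle, the all-zero point excluded, and unordered
duplicates removed when the molecule's two bonds are permutationally
equivalent (detected from element pairs and equilibrium lengths, or
overridable) — 14 distinct geometries for a symmetric triatomic, 24 for
an asymmetric one. When a bond is displaced, the terminal (degree-1)
atom moves along the bond axis; angle-scan observations are filtered to
±30° about the equilibrium angle. Validation geometries draw the two
bond offsets and the angle offset independently and uniformly from
±0.07 Å and ±30°, reproducibly from a user seed.

## Vibrational analysis

Normal modes come from the mass-weighted Hessian
$H_{Ai,Bj}/\sqrt{m_A m_B}$ evaluated by central finite differences of
the model energy (step $5\times10^{-3}$ bohr, documented in the output)
and symmetrized. Eigenvalues convert to wavenumbers as
$\sqrt{\lambda} \times 219474.63$. Rigid-body modes are classified by a
threshold on the wavenumber scale (default 50 cm⁻¹) rather than a tiny
relative eigenvalue cutoff: an FD Hessian leaves truncation noise of a
few cm⁻¹ on the six (five for linear molecules) zero modes, which a
$10^{-8}$-relative criterion would misclassify. Negative eigenvalues
beyond the threshold are reported as imaginary modes, never dropped.
Degenerate-mode eigenvectors get a deterministic sign convention (first
nonzero component positive). Because every stretch and bend form has
curvature exactly $k$ at equilibrium, the computed frequencies are
independent of $\gamma°$ and $\nu$; the test suite sweeps both to
confirm drift below 0.01 cm⁻¹.

Anharmonic diatomic levels solve
$-\frac{1}{2\mu}\varphi'' + U(d)\varphi = \varepsilon\varphi$ on a
uniform grid ($d_{eq} - 1.5$ to $d_{eq} + 5$ bohr, 0.001 bohr spacing by
default — a range/spacing at which halving the step moves levels by less
than 0.1 cm⁻¹, which the suite checks) with Dirichlet boundaries and a
central-difference Laplacian. The lowest eigenvalues of the resulting
symmetric tridiagonal Hamiltonian are located by Sturm-sequence
bisection (bracketed by Gershgorin bounds, bisected to $10^{-12}$
relative) and eigenvectors, when requested, by inverse iteration with
the Thomas algorithm, normalized under the grid inner product. This
hand-written tridiagonal path is exact textbook numerics chosen because
the grid has thousands of points and only the lowest few states are
needed; it is validated against dense diagonalization at small sizes and
against the analytic harmonic ladder $(\nu + \tfrac12)\sqrt{k/\mu}$ and
Morse spectrum $\omega(\nu+\tfrac12) - [\omega(\nu+\tfrac12)]^2/(4D)$.
Grid points at non-positive $d$ (possible for very short bonds) are
dropped. Masses default to a bundled most-abundant-isotope table
(¹H = 1.007825, ¹²C = 12, ¹⁶O = 15.994915, …) with per-run overrides;
frequency targets quoted to ±1 % absorb the difference from
atomic-weight conventions.

## What the synthetic generators do and do not emulate

`generate_synthetic_surface()` produces displacement-roster energies
from a known composite model (bonded truth plus optional nonbonded
contribution) with optional Gaussian noise — a stand-in for
quantum-chemistry single-point scans. It reproduces the *structure* of
such data (geometry rosters, reference-relative energies, realistic
magnitudes) but not its physics: no electronic-structure anharmonicity
beyond the model forms, no basis-set or convergence noise correlations,
no multi-subdomain ground-state crossovers. Recovery tests on this data
therefore demonstrate the estimator's correctness (bias → 0, error
scaling with σ at σ ∈ {0, 10⁻⁴ hartree}), not accuracy on real QM
surfaces. Likewise `generate_synthetic_density_profile()` produces pure
or polynomially contaminated exponentials $r^p e^{a-br}$ on uniform
shell grids — ideal test beds for the crossing/window/fit pipeline, but
free of shell structure, core wiggles, and partitioning noise that real
atom-in-material profiles carry.

The problem sizes used throughout the tests — triatomic molecules, a
12-atom aromatic ring, 18-point basis fits, ~6500-point vibrational
grids — are the package's chosen demonstration scale: large enough to
exercise every code path, small enough to run interactively.

## Known limitations

* Dihedral and out-of-plane internal coordinates are not implemented;
  the data model stops at bonds, angles, Urey–Bradley pairs, and
  bond–bond cross terms, so general polyatomics are supported for
  energies/modes but rosters and scans target molecules without
  torsional flexibility.
* Nonbonded electrostatics is bare Coulomb with point charges and 12-6
  Lennard-Jones under geometric-mean mixing; no Ewald/Wolf summation,
  multipoles, or polarizabilities. Periodic boundary conditions are out
  of scope.
* Multibody (≥3-atom) nonbonded assignment exists only as the pair-kind
  interface; only two-body models are computed.
* One electronic ground-state subdomain per flexibility model;
  concatenating subdomains (e.g., spin crossovers along dissociation)
  is not exercised.
* Bond detection uses the atom-typing-radii criterion only; bond-order
  or overlap-population thresholds are a noted extension point.
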