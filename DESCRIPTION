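Package: ffft
Title: Force Field Functional Theory Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for parameterizing nonreactive molecular force fields
    from quantum-chemistry reference data. Implements bond-stretch model
    potentials (harmonic, Morse, and the two-exponential Manz form with a
    quantum-derived exponent), a tanh-regularized angle-bending potential
    that is well behaved through linear angles, Urey-Bradley and bond-bond
    cross terms, and a smooth partition of intracluster nonbonded
    interactions whose value, gradient, and Hessian vanish at the reference
    geometry so that force constants can be fitted by linear (optionally
    LASSO-regularized) regression. Also provides radial-electron-density
    decay-exponent analysis, harmonic normal-mode analysis via the
    mass-weighted Hessian, and a finite-difference one-dimensional
    vibrational Schroedinger solver for anharmonic diatomic levels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
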