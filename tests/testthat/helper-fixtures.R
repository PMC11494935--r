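# Shared fixtures: geometries, radii, and numeric oracles built in code.

# typical covalent-style atom-typing radii (angstrom)
test_radii <- c(H = 0.40, O = 0.75, C = 0.80, N = 0.75, S = 1.05, F = 0.70,
                Ca = 1.40, Si = 1.15, Li = 1.30)

ang2bohr <- ffft::ffft_constants$bohr_per_angstrom
ev2ha <- ffft::ffft_constants$hartree_per_ev

# bent water-like triatomic (angstrom inputs, outer-vertex-outer order)
water_system <- function() ffft::example_molecule("H2O")

# linear chain of n atoms spaced 1.0 angstrom apart along x
chain_system <- function(n, element = "C", spacing = 1.0) {
  coords <- cbind((seq_len(n) - 1) * spacing, 0, 0)
  s <- ffft::molecular_system(rep(element, n), coords)
  s$ref_coords <- s$coords
  s
}

chain_bonds <- function(n) cbind(i = seq_len(n - 1), j = 2:n)

# central finite-difference derivative oracle for 1-D functions
fd_deriv <- function(f, x, order = 1, h = 1e-5) {
  if (order == 1) (f(x + h) - f(x - h)) / (2 * h)
  else (f(x + h) + f(x - h) - 2 * f(x)) / h^2
}

# FD Cartesian gradient oracle of a term energy
fd_term_gradient <- function(term, coords, h = 1e-6) {
  g <- matrix(0, nrow(coords), 3)
  for (at in seq_len(nrow(coords))) for (xyz in 1:3) {
    cp <- coords; cp[at, xyz] <- cp[at, xyz] + h
    cm <- coords; cm[at, xyz] <- cm[at, xyz] - h
    g[at, xyz] <- (ffft::term_energy_cartesian(term, cp) -
                   ffft::term_energy_cartesian(term, cm)) / (2 * h)
  }
  g
}

# random rigid rotation matrix (deterministic given seed)
rotation_matrix <- function(seed) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  rbind(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c)),
        c(2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b)),
        c(2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2))
}
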