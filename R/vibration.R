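## Harmonic normal modes via the mass-weighted Hessian, and anharmonic
## diatomic vibrational levels via a central-finite-difference 1-D
## Schroedinger solver (Sturm-sequence bisection for the lowest levels of
## the tridiagonal Hamiltonian).

#' Default atomic masses (most-abundant isotope, amu)
#'
#' @format named numeric vector.
#' @export
default_masses <- c(
  H = 1.007825, D = 2.014102, T = 3.016049,
  Li = 7.016003, C = 12.000000, N = 14.003074, O = 15.994915,
  F = 18.998403, Si = 27.976927, S = 31.972071, Cl = 34.968853,
  Ca = 39.962591)

#' Look up per-atom masses
#'
#' @param elements element symbols.
#' @param overrides named numeric vector of per-element replacements (amu).
#' @return masses in amu.
#' @export
atom_masses <- function(elements, overrides = NULL) {
  tab <- default_masses
  if (!is.null(overrides)) tab[names(overrides)] <- overrides
  m <- tab[normalize_element(elements)]
  if (anyNA(m))
    stop("no mass for element(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Mass-weighted Hessian by central finite differences
#'
#' H_mw[(A,i),(B,j)] = (1/sqrt(m_A m_B)) d^2 U / dR_Ai dR_Bj with the
#' second derivatives from central differences of the energy, then
#' symmetrized as (H + t(H))/2. Warns when the input geometry is not a
#' stationary point of the potential.
#'
#' @param energy_fn function taking an n x 3 coordinate matrix (bohr) and
#'   returning the energy in hartree.
#' @param coords n x 3 matrix, bohr.
#' @param masses per-atom masses in amu.
#' @param fd_step finite-difference step, bohr.
#' @param force_tol stationarity tolerance on the max FD force component;
#'   the default allows for the central-difference truncation bias
#'   (h^2/6 U''') that anharmonic potentials exhibit even at an exact
#'   minimum.
#' @return 3n x 3n symmetric matrix in atomic units
#'   (hartree / (bohr^2 m_e)); eigenvalues are squared angular frequencies.
#' @export
mass_weighted_hessian <- function(energy_fn, coords, masses,
                                  fd_step = 5e-3, force_tol = 1e-4) {
  n <- nrow(coords)
  stopifnot(length(masses) == n)
  h <- fd_step
  ## stationarity check
  grad <- numeric(3 * n)
  for (at in seq_len(n)) for (xyz in 1:3) {
    cp <- coords; cp[at, xyz] <- cp[at, xyz] + h
    cm <- coords; cm[at, xyz] <- cm[at, xyz] - h
    grad[3 * (at - 1) + xyz] <- (energy_fn(cp) - energy_fn(cm)) / (2 * h)
  }
  if (max(abs(grad)) > force_tol)
    warning(sprintf(
      "geometry is not a stationary point: max |force| = %.3e hartree/bohr",
      max(abs(grad))))
  e0 <- energy_fn(coords)
  H <- matrix(0, 3 * n, 3 * n)
  shift <- function(at, xyz, s) {
    cc <- coords; cc[at, xyz] <- cc[at, xyz] + s * h; cc
  }
  for (p in seq_len(3 * n)) {
    ap <- (p - 1) %/% 3 + 1; xp <- (p - 1) %% 3 + 1
    H[p, p] <- (energy_fn(shift(ap, xp, 1)) + energy_fn(shift(ap, xp, -1)) -
                2 * e0) / h^2
    if (p < 3 * n) for (q in (p + 1):(3 * n)) {
      aq <- (q - 1) %/% 3 + 1; xq <- (q - 1) %% 3 + 1
      cpp <- shift(ap, xp, 1);  cpp[aq, xq] <- cpp[aq, xq] + h
      cpm <- shift(ap, xp, 1);  cpm[aq, xq] <- cpm[aq, xq] - h
      cmp <- shift(ap, xp, -1); cmp[aq, xq] <- cmp[aq, xq] + h
      cmm <- shift(ap, xp, -1); cmm[aq, xq] <- cmm[aq, xq] - h
      H[p, q] <- H[q, p] <-
        (energy_fn(cpp) - energy_fn(cpm) - energy_fn(cmp) + energy_fn(cmm)) /
        (4 * h^2)
    }
  }
  m_me <- rep(masses, each = 3) * ffft_constants$me_per_amu
  H <- H / sqrt(outer(m_me, m_me))
  (H + t(H)) / 2
}

#' Harmonic normal modes from a mass-weighted Hessian
#'
#' Diagonalizes the MWH; eigenvalues whose |wavenumber| falls below
#' \code{zero_tol_cm} are classified as translation/rotation zero modes
#' (5 expected for a linear molecule, 6 for a nonlinear one). The
#' threshold lives on the wavenumber scale because finite-difference
#' Hessians leave truncation noise of a few cm^-1 on the rigid-body
#' modes. Remaining eigenvalues convert to wavenumbers as
#' sqrt(lambda) x 219474.63 cm^-1.
#'
#' @param mwh symmetric mass-weighted Hessian (atomic units).
#' @param linear logical; when supplied, the zero-mode count is checked
#'   against 5 (linear) or 6 (nonlinear) with a warning on mismatch.
#' @param zero_tol_cm rigid-body classification threshold, cm^-1.
#' @return object of class \code{vibrational_result}: \code{wavenumbers}
#'   (ascending, cm^-1), \code{eigenvalues}, \code{vectors} (mass-weighted
#'   displacement columns matching \code{wavenumbers}),
#'   \code{zero_mode_count}, \code{imaginary} (wavenumbers of negative
#'   modes beyond threshold, reported, never dropped silently).
#' @export
normal_modes <- function(mwh, linear = NULL, zero_tol_cm = 50) {
  stopifnot(isSymmetric(unname(mwh), tol = 1e-8))
  es <- eigen((mwh + t(mwh)) / 2, symmetric = TRUE)
  lam <- rev(es$values)              # ascending
  vec <- es$vectors[, rev(seq_along(lam)), drop = FALSE]
  thr <- (zero_tol_cm / ffft_constants$wavenumber_per_hartree)^2
  zero <- abs(lam) < thr
  neg <- lam < -thr
  vib <- which(!zero & !neg)
  wn <- sqrt(lam[vib]) * ffft_constants$wavenumber_per_hartree
  vecs <- vec[, vib, drop = FALSE]
  ## deterministic sign convention: first nonzero component positive
  for (c in seq_len(ncol(vecs))) {
    nz <- which(abs(vecs[, c]) > 1e-10)[1]
    if (!is.na(nz) && vecs[nz, c] < 0) vecs[, c] <- -vecs[, c]
  }
  if (!is.null(linear)) {
    expected <- if (linear) 5L else 6L
    if (sum(zero) != expected)
      warning("expected ", expected, " rigid-body zero modes, found ",
              sum(zero))
  }
  if (any(neg))
    warning("imaginary mode(s) detected: ",
            paste(sprintf("%.1fi cm^-1",
                          sqrt(-lam[neg]) * ffft_constants$wavenumber_per_hartree),
                  collapse = ", "))
  structure(list(wavenumbers = wn, eigenvalues = lam, vectors = vecs,
                 zero_mode_count = sum(zero),
                 imaginary = sqrt(pmax(-lam[neg], 0)) *
                   ffft_constants$wavenumber_per_hartree),
            class = "vibrational_result")
}

#' Normal modes of a flexibility model at its reference geometry
#'
#' Convenience wrapper: builds the FD mass-weighted Hessian of the model's
#' bonded energy at the system's reference geometry and diagonalizes it.
#'
#' @param model a \code{flexibility_model}.
#' @param system a \code{molecular_system} with \code{ref_coords}.
#' @param masses per-atom masses (amu); default from
#'   \code{\link{atom_masses}}.
#' @param linear logical or NULL (auto-detect for triatomics).
#' @param fd_step FD step in bohr.
#' @return a \code{vibrational_result}.
#' @export
model_normal_modes <- function(model, system, masses = NULL, linear = NULL,
                               fd_step = 5e-3) {
  if (is.null(system$ref_coords)) stop("reference geometry required")
  if (is.null(masses)) masses <- atom_masses(system$elements)
  coords <- system$ref_coords
  if (is.null(linear) && system$n_atoms == 3)
    linear <- abs(angle_from_coords(coords, 1, 2, 3) - pi) < 1e-6 ||
      abs(angle_from_coords(coords, 2, 1, 3) - pi) < 1e-6 ||
      abs(angle_from_coords(coords, 1, 3, 2) - pi) < 1e-6
  mwh <- mass_weighted_hessian(function(cc) model_energy(model, cc),
                               coords, masses, fd_step = fd_step)
  normal_modes(mwh, linear = linear)
}

## ---- 1-D Schroedinger solver ----------------------------------------------

## number of eigenvalues of the symmetric tridiagonal matrix (diag a,
## off-diagonal b) that are strictly below x, by the Sturm/LDL^T recurrence
tridiag_count_below <- function(a, b, x) {
  n <- length(a)
  count <- 0L
  d <- a[1] - x
  if (d < 0) count <- 1L
  if (d == 0) d <- -1e-300
  if (n > 1) for (i in 2:n) {
    d <- (a[i] - x) - b[i - 1]^2 / d
    if (d < 0) count <- count + 1L
    if (d == 0) d <- -1e-300
  }
  count
}

## k-th smallest eigenvalue (k = 1, 2, ...) by bisection
tridiag_eigenvalue <- function(a, b, k, tol = 1e-12) {
  rad <- c(0, abs(b)) + c(abs(b), 0)
  lo <- min(a - rad); hi <- max(a + rad)
  while (hi - lo > tol * max(1, abs(lo), abs(hi))) {
    mid <- (lo + hi) / 2
    if (tridiag_count_below(a, b, mid) >= k) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

## eigenvector by inverse iteration with the Thomas algorithm
tridiag_eigenvector <- function(a, b, lambda, iters = 3) {
  n <- length(a)
  v <- rep(1 / sqrt(n), n)
  shift <- lambda + 1e-12 * max(1, abs(lambda))
  for (it in seq_len(iters)) {
    ## solve (T - shift I) w = v
    cp <- numeric(n); dp <- numeric(n)
    den <- a[1] - shift
    if (abs(den) < 1e-300) den <- 1e-300
    cp[1] <- b[1] / den; dp[1] <- v[1] / den
    for (i in 2:n) {
      den <- (a[i] - shift) - b[i - 1] * cp[i - 1]
      if (abs(den) < 1e-300) den <- 1e-300
      if (i < n) cp[i] <- b[i] / den
      dp[i] <- (v[i] - b[i - 1] * dp[i - 1]) / den
    }
    w <- numeric(n)
    w[n] <- dp[n]
    for (i in (n - 1):1) w[i] <- dp[i] - cp[i] * w[i + 1]
    v <- w / sqrt(sum(w^2))
  }
  v
}

#' Vibrational levels of a diatomic by the 1-D Schroedinger equation
#'
#' Solves -(1/2 mu) phi'' + U(d) phi = eps phi on a uniform grid with
#' central finite differences and Dirichlet boundaries, using the reduced
#' mass mu = m_A m_B / (m_A + m_B). The default grid mirrors the
#' convergence-checked choice d_eq - 1.5 bohr to d_eq + 5 bohr with
#' 0.001 bohr spacing. The lowest levels are extracted by Sturm-sequence
#' bisection on the tridiagonal Hamiltonian.
#'
#' @param u_fn potential function of distance (bohr -> hartree).
#' @param m_a,m_b atomic masses, amu.
#' @param d_eq equilibrium distance (grid center offset), bohr.
#' @param lo_offset,hi_offset,spacing grid specification, bohr.
#' @param n_levels number of levels to compute.
#' @param return_vectors also compute eigenfunctions (grid-orthonormal).
#' @param check_convergence re-solve with doubled spacing and warn when
#'   the first transitions shift by more than 0.1 cm^-1.
#' @return object of class \code{vibrational_levels}: \code{energies}
#'   (hartree, ascending), \code{zpe_cm} (eps_0 - min U, cm^-1),
#'   \code{transitions_cm} (successive differences, cm^-1), \code{grid},
#'   optional \code{vectors}.
#' @export
solve_vibrational_levels <- function(u_fn, m_a, m_b, d_eq,
                                     lo_offset = -1.5, hi_offset = 5,
                                     spacing = 0.001, n_levels = 13,
                                     return_vectors = FALSE,
                                     check_convergence = FALSE) {
  mu <- (m_a * m_b / (m_a + m_b)) * ffft_constants$me_per_amu
  stopifnot(mu > 0, spacing > 0, hi_offset > lo_offset)
  d <- seq(d_eq + lo_offset, d_eq + hi_offset, by = spacing)
  d <- d[d > 0]
  n <- length(d)
  u <- u_fn(d)
  kin <- 1 / (2 * mu * spacing^2)
  a <- 2 * kin + u
  b <- rep(-kin, n - 1)
  eps <- vapply(seq_len(n_levels), function(k)
    tridiag_eigenvalue(a, b, k), numeric(1))
  if (check_convergence) {
    idx <- seq(1, n, by = 2)
    a2 <- 1 / (mu * (2 * spacing)^2) + u[idx]
    b2 <- rep(-1 / (2 * mu * (2 * spacing)^2), length(idx) - 1)
    eps2 <- vapply(seq_len(min(n_levels, 3)), function(k)
      tridiag_eigenvalue(a2, b2, k), numeric(1))
    drift <- max(abs(diff(eps[1:3]) - diff(eps2))) *
      ffft_constants$wavenumber_per_hartree
    if (drift > 0.1)
      warning(sprintf(
        "grid may be too coarse: doubling the spacing shifts transitions by %.3f cm^-1",
        drift))
  }
  vectors <- NULL
  if (return_vectors) {
    vectors <- vapply(eps, function(l) tridiag_eigenvector(a, b, l),
                      numeric(n))
    vectors <- vectors / sqrt(spacing)  # grid inner product sum v w h = 1
  }
  structure(list(energies = eps,
                 zpe_cm = (eps[1] - min(u)) *
                   ffft_constants$wavenumber_per_hartree,
                 transitions_cm = diff(eps) *
                   ffft_constants$wavenumber_per_hartree,
                 grid = list(d = d, spacing = spacing, mu_me = mu),
                 vectors = vectors),
            class = "vibrational_levels")
}

#' Successive transition table of a level spectrum
#'
#' Row nu holds eps_nu - eps_(nu-1) in cm^-1; the ZPE row holds
#' eps_0 - min U.
#'
#' @param levels a \code{vibrational_levels} object (>= 2 levels).
#' @return data frame with columns \code{nu} ("ZPE", "1", "2", ...) and
#'   \code{wavenumber_cm}.
#' @export
transition_table <- function(levels) {
  stopifnot(length(levels$energies) >= 2)
  data.frame(nu = c("ZPE", as.character(seq_along(levels$transitions_cm))),
             wavenumber_cm = c(levels$zpe_cm, levels$transitions_cm))
}
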