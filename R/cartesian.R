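## Chain rule from internal coordinates to Cartesians: per-term energies,
## analytic gradients, and Hessian blocks, plus whole-model assembly.

term_internal_values <- function(term, coords) {
  a <- term$atoms
  if (term$kind %in% STRETCH_KINDS) {
    list(d = dist_pair(coords, a[1], a[2]))
  } else if (term$kind %in% BEND_KINDS) {
    list(theta = angle_from_coords(coords, a[1], a[2], a[3]))
  } else {
    list(d_ab = dist_pair(coords, a[1], a[2]),
         d_bc = dist_pair(coords, a[3], a[2]))
  }
}

#' Energy of one flexibility term at a Cartesian geometry
#'
#' @param term a \code{flex_term}.
#' @param coords n x 3 matrix, bohr (or a \code{molecular_system}).
#' @return energy in hartree.
#' @export
term_energy_cartesian <- function(term, coords) {
  if (inherits(coords, "molecular_system")) coords <- coords$coords
  v <- term_internal_values(term, coords)
  if (term$kind %in% STRETCH_KINDS) stretch_energy(v$d, term)
  else if (term$kind %in% BEND_KINDS) bend_energy(v$theta, term)
  else cross_term_energy(v$d_ab, v$d_bc, term)
}

## gradient of cos(theta_ABC) with respect to the three atom positions
cos_angle_gradient <- function(coords, A, B, C) {
  rab <- coords[A, ] - coords[B, ]; rcb <- coords[C, ] - coords[B, ]
  dab <- sqrt(sum(rab^2)); dcb <- sqrt(sum(rcb^2))
  u <- rab / dab; v <- rcb / dcb
  x <- sum(u * v)
  gA <- (v - x * u) / dab
  gC <- (u - x * v) / dcb
  list(x = x, gA = gA, gB = -(gA + gC), gC = gC)
}

#' Analytic Cartesian gradient of one flexibility term
#'
#' Rows for atoms not involved in the term are zero. The tanh-regularized
#' bend is differentiated through cos(theta), so its gradient is smooth
#' through linear geometries; bends that are functions of theta itself are
#' undefined at exactly linear triads unless their theta-derivative
#' vanishes there.
#'
#' @param term a \code{flex_term}.
#' @param coords n x 3 matrix in bohr (or a \code{molecular_system}).
#' @param n_atoms number of atoms (inferred from \code{coords} if missing).
#' @return n x 3 gradient matrix, hartree/bohr.
#' @export
term_gradient_cartesian <- function(term, coords, n_atoms = NULL) {
  if (inherits(coords, "molecular_system")) coords <- coords$coords
  if (is.null(n_atoms)) n_atoms <- nrow(coords)
  g <- matrix(0, n_atoms, 3)
  a <- term$atoms
  if (term$kind %in% STRETCH_KINDS) {
    rab <- coords[a[1], ] - coords[a[2], ]
    d <- sqrt(sum(rab^2))
    if (d < 1e-10) stop("degenerate internal coordinate: zero bond length")
    du <- stretch_energy(d, term, deriv = 1)
    g[a[1], ] <- du * rab / d
    g[a[2], ] <- -du * rab / d
  } else if (term$kind %in% BEND_KINDS) {
    cg <- cos_angle_gradient(coords, a[1], a[2], a[3])
    if (term$kind == "bend_new") {
      dudx <- bend_new_cos(cg$x, term$eq_value, term$force_constant,
                           term$exponent)$dU
    } else {
      s2 <- 1 - cg$x^2
      theta <- acos(min(1, max(-1, cg$x)))
      dudth <- bend_energy(theta, term, deriv = 1)
      if (s2 < 1e-16) {
        if (abs(dudth) < 1e-10) return(g)
        stop("gradient of ", term$kind, " is undefined at a linear triad")
      }
      dudx <- -dudth / sqrt(s2)
    }
    g[a[1], ] <- dudx * cg$gA
    g[a[2], ] <- dudx * cg$gB
    g[a[3], ] <- dudx * cg$gC
  } else { # bond_bond_cross on triad A-B-C
    rab <- coords[a[1], ] - coords[a[2], ]; dab <- sqrt(sum(rab^2))
    rcb <- coords[a[3], ] - coords[a[2], ]; dcb <- sqrt(sum(rcb^2))
    k <- term$force_constant
    gA <- k * (dcb - term$eq_value2) * rab / dab
    gC <- k * (dab - term$eq_value) * rcb / dcb
    g[a[1], ] <- gA; g[a[3], ] <- gC; g[a[2], ] <- -(gA + gC)
  }
  g
}

#' Cartesian second-derivative block of one flexibility term
#'
#' Central finite differences of the analytic gradient, symmetrized as
#' (H + t(H))/2.
#'
#' @inheritParams term_gradient_cartesian
#' @param step finite-difference step in bohr.
#' @return 3n x 3n symmetric matrix (atom-major ordering), hartree/bohr^2.
#' @export
term_hessian_cartesian <- function(term, coords, step = 1e-4) {
  if (inherits(coords, "molecular_system")) coords <- coords$coords
  n <- nrow(coords)
  H <- matrix(0, 3 * n, 3 * n)
  for (at in seq_len(n)) for (xyz in 1:3) {
    col <- 3 * (at - 1) + xyz
    cp <- coords; cp[at, xyz] <- cp[at, xyz] + step
    cm <- coords; cm[at, xyz] <- cm[at, xyz] - step
    gp <- term_gradient_cartesian(term, cp)
    gm <- term_gradient_cartesian(term, cm)
    H[, col] <- as.vector(t(gp - gm)) / (2 * step)
  }
  (H + t(H)) / 2
}

#' Total bonded energy of a flexibility model
#'
#' @param model a \code{flexibility_model}.
#' @param coords n x 3 Cartesian matrix in bohr (or a
#'   \code{molecular_system}).
#' @return energy in hartree.
#' @export
model_energy <- function(model, coords) {
  if (inherits(coords, "molecular_system")) coords <- coords$coords
  sum(vapply(model$terms, term_energy_cartesian, numeric(1), coords = coords))
}

#' Total analytic Cartesian gradient of a flexibility model
#'
#' @inheritParams model_energy
#' @return n x 3 gradient matrix, hartree/bohr.
#' @export
model_gradient <- function(model, coords) {
  if (inherits(coords, "molecular_system")) coords <- coords$coords
  g <- matrix(0, nrow(coords), 3)
  for (tm in model$terms) g <- g + term_gradient_cartesian(tm, coords)
  g
}
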