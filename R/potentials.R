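## Flexibility-term model potentials with analytic derivatives of orders
## 0-2 with respect to their internal coordinate. Internal units: bohr,
## hartree, radians. Force constants: hartree/bohr^2 for stretch-form and
## cross terms; hartree (radians treated as dimensionless) for bends.

STRETCH_KINDS <- c("stretch_harmonic", "stretch_morse", "stretch_manz",
                   "stretch_gm_basis", "urey_bradley")
BEND_KINDS <- c("bend_new", "bend_harmonic", "bend_cosine",
                "bend_harmonic_cosine", "bend_mm3")

#' Construct a flexibility term
#'
#' One bonded potential contribution: a bond or Urey-Bradley stretch, an
#' angle bend, or a bond-bond cross term. Equilibrium values and exponents
#' are stored in atomic units (bohr, radians); force constants in hartree
#' per bohr^2 (stretch/cross) or hartree (bends).
#'
#' @param kind one of \code{"stretch_harmonic"}, \code{"stretch_morse"},
#'   \code{"stretch_manz"}, \code{"stretch_gm_basis"},
#'   \code{"urey_bradley"} (stretch form; Manz unless \code{ub_form} says
#'   otherwise), \code{"bend_new"}, \code{"bend_harmonic"},
#'   \code{"bend_cosine"}, \code{"bend_harmonic_cosine"},
#'   \code{"bend_mm3"}, \code{"bond_bond_cross"}.
#' @param atoms integer atom indices: 2 for stretches and Urey-Bradley,
#'   3 (A, B, C with vertex B) for bends and cross terms.
#' @param eq_value equilibrium bond length (bohr) or angle (radians).
#' @param force_constant k, hartree/bohr^2 or hartree.
#' @param exponent gamma (1/bohr) for Morse/Manz stretches and Manz
#'   Urey-Bradley terms; the tanh multiplier nu (dimensionless, default 2)
#'   for \code{bend_new}.
#' @param eq_value2 second equilibrium bond length, cross terms only.
#' @param basis_index positive integer m, \code{stretch_gm_basis} only.
#' @param ub_form stretch form used by a Urey-Bradley term:
#'   \code{"manz"}, \code{"harmonic"}, or \code{"morse"}.
#' @param mm3_coeffs numeric vector of MM3 polynomial coefficients
#'   (configuration-supplied), \code{bend_mm3} only.
#' @return object of class \code{flex_term}.
#' @export
flex_term <- function(kind, atoms, eq_value, force_constant,
                      exponent = if (kind == "bend_new") 2 else NA_real_,
                      eq_value2 = NA_real_, basis_index = NA_integer_,
                      ub_form = "manz", mm3_coeffs = NULL) {
  kinds <- c(STRETCH_KINDS, BEND_KINDS, "bond_bond_cross")
  if (!kind %in% kinds) stop("unknown flexibility term kind: ", kind)
  if (!is.finite(force_constant)) stop("force_constant must be finite")
  n_at <- if (kind %in% c(STRETCH_KINDS)) 2 else 3
  if (length(atoms) != n_at)
    stop(kind, " takes ", n_at, " atoms, got ", length(atoms))
  if (kind %in% c("stretch_morse", "stretch_manz") ||
      (kind == "urey_bradley" && ub_form %in% c("manz", "morse"))) {
    if (!is.finite(exponent) || exponent <= 0)
      stop(kind, " requires exponent gamma > 0")
  }
  if (kind %in% BEND_KINDS) {
    if (eq_value <= 0 || eq_value > pi)
      stop("equilibrium angle must lie in (0, pi]")
    if (kind == "bend_new" && (!is.finite(exponent) || exponent <= 0))
      stop("bend_new requires tanh multiplier nu > 0")
    if (kind == "bend_mm3" && is.null(mm3_coeffs))
      stop("bend_mm3 requires configuration-supplied polynomial coefficients")
  } else if (eq_value <= 0 && kind != "bond_bond_cross") {
    stop("equilibrium length must be positive")
  }
  if (kind == "bond_bond_cross" &&
      (!is.finite(eq_value) || !is.finite(eq_value2) ||
       eq_value <= 0 || eq_value2 <= 0))
    stop("bond_bond_cross requires two positive equilibrium bond lengths")
  if (kind == "stretch_gm_basis") {
    if (is.na(basis_index) || basis_index < 1)
      stop("stretch_gm_basis requires basis index m >= 1")
    basis_index <- as.integer(basis_index)
  }
  structure(list(kind = kind, atoms = as.integer(atoms), eq_value = eq_value,
                 eq_value2 = eq_value2, exponent = exponent,
                 basis_index = basis_index, force_constant = force_constant,
                 ub_form = ub_form, mm3_coeffs = mm3_coeffs),
            class = "flex_term")
}

#' Bundle flexibility terms into a model
#'
#' @param terms list of \code{flex_term} objects.
#' @param subdomain_label identifier of the electronic ground-state
#'   subdomain the model describes.
#' @return object of class \code{flexibility_model}.
#' @export
flexibility_model <- function(terms, subdomain_label = "ground_state") {
  if (inherits(terms, "flex_term")) terms <- list(terms)
  stopifnot(all(vapply(terms, inherits, logical(1), "flex_term")))
  structure(list(terms = terms, subdomain_label = subdomain_label),
            class = "flexibility_model")
}

## ---- stretch potentials ---------------------------------------------------

#' Stretch model-potential energy and derivatives
#'
#' Harmonic: U = k/2 (d - d_eq)^2. Morse: U = k/(2 gamma^2)
#' (1 - exp(-gamma Dd))^2. Manz (two-exponential): U = 3k/(5 gamma^2)
#' [1 - 5/2 exp(-gamma Dd) + 3/2 exp(-5/3 gamma Dd)], whose value and slope
#' vanish and whose curvature equals k at d = d_eq, and which approaches a
#' finite dissociation limit 3k/(5 gamma^2). Urey-Bradley terms evaluate the
#' stretch form selected by \code{ub_form}. A \code{stretch_gm_basis} term
#' evaluates k times the basis function of \code{\link{gm_basis_energy}}.
#'
#' @param d bond length(s), bohr; must be positive.
#' @param term a stretch-kind \code{flex_term}.
#' @param deriv derivative order with respect to d: 0, 1, or 2.
#' @return energy (hartree) or its d-derivative, same length as \code{d}.
#' @export
stretch_energy <- function(d, term, deriv = 0) {
  if (!inherits(term, "flex_term") || !term$kind %in% STRETCH_KINDS)
    stop("stretch_energy requires a stretch-kind flex_term, got: ",
         if (inherits(term, "flex_term")) term$kind else class(term)[1])
  stopifnot(all(d > 0), deriv %in% 0:2)
  k <- term$force_constant; deq <- term$eq_value; g <- term$exponent
  kind <- term$kind
  if (kind == "urey_bradley")
    kind <- paste0("stretch_", term$ub_form)
  dd <- d - deq
  switch(kind,
    stretch_harmonic = switch(as.character(deriv),
      "0" = 0.5 * k * dd^2, "1" = k * dd, "2" = rep(k, length(d))),
    stretch_morse = {
      e <- exp(-g * dd)
      switch(as.character(deriv),
        "0" = (k / (2 * g^2)) * (1 - e)^2,
        "1" = (k / g) * (1 - e) * e,
        "2" = k * e * (2 * e - 1))
    },
    stretch_manz = {
      A <- 3 * k / (5 * g^2)
      e1 <- exp(-g * dd); e2 <- exp(-(5 / 3) * g * dd)
      switch(as.character(deriv),
        "0" = A * (1 - 2.5 * e1 + 1.5 * e2),
        "1" = A * 2.5 * g * (e1 - e2),
        "2" = A * 2.5 * g^2 * (-e1 + (5 / 3) * e2))
    },
    stretch_gm_basis = k * gm_basis_energy(d, deq, term$basis_index,
                                           deriv = deriv),
    stop("unhandled stretch kind ", kind))
}

#' Manz stretch coefficient conditions
#'
#' Solves the pair of linear conditions that the two-exponential stretch
#' potential have zero energy and zero force at the equilibrium bond
#' length: 1 - c2 + c3 = 0 and c2 - (5/3) c3 = 0.
#'
#' @return named numeric vector with \code{coeff_2} and \code{coeff_3}
#'   (5/2 and 3/2).
#' @export
manz_stretch_coefficients <- function() {
  ## unknowns (c2, c3): [-1, 1; 1, -5/3] %*% c = (-1, 0)
  m <- rbind(c(-1, 1), c(1, -5 / 3))
  sol <- solve(m, c(-1, 0))
  c(coeff_2 = sol[1], coeff_3 = sol[2])
}

#' Bond dissociation energy of a bounded stretch potential
#'
#' The d -> infinity limit: k/(2 gamma^2) for Morse, 3k/(5 gamma^2) for the
#' Manz form.
#'
#' @param term a \code{flex_term} of kind \code{stretch_morse},
#'   \code{stretch_manz}, or a Urey-Bradley term with one of those forms.
#' @return dissociation energy in hartree.
#' @export
stretch_dissociation_energy <- function(term) {
  kind <- term$kind
  if (kind == "urey_bradley") kind <- paste0("stretch_", term$ub_form)
  k <- term$force_constant; g <- term$exponent
  switch(kind,
    stretch_morse = k / (2 * g^2),
    stretch_manz = 3 * k / (5 * g^2),
    stop("dissociation energy is unbounded or undefined for kind ",
         term$kind))
}

#' Bounded stretch basis functions g_m
#'
#' A family of dimensionless bond-stretch basis functions with the limit
#' properties g_m(d_eq) = 0, g_m'(d_eq) = 0, g_m(0) = (-1)^m, and
#' g_m(infinity) = 1, and nonzero curvature at d_eq for every m. The
#' implemented closed form is
#' g_m(d) = (1 - 2^(1 - d/d_eq))^2 * (1 - 2 exp(-2 d/d_eq))^m.
#'
#' @param d bond length(s), bohr.
#' @param d_eq equilibrium bond length, bohr.
#' @param m basis index, integer >= 1.
#' @param deriv derivative order 0, 1, or 2 with respect to d.
#' @return basis value (dimensionless) or derivative (1/bohr, 1/bohr^2).
#' @export
gm_basis_energy <- function(d, d_eq, m, deriv = 0) {
  if (m < 1) stop("basis index m must be >= 1")
  m <- as.integer(m)
  w <- d / d_eq
  phi <- 1 - 2^(1 - w)
  psi <- 1 - 2 * exp(-2 * w)
  if (deriv == 0) return(phi^2 * psi^m)
  dphi <- (log(2) / d_eq) * 2^(1 - w)
  dpsi <- (4 / d_eq) * exp(-2 * w)
  if (deriv == 1)
    return(2 * phi * dphi * psi^m + phi^2 * m * psi^(m - 1) * dpsi)
  d2phi <- -(log(2) / d_eq)^2 * 2^(1 - w)
  d2psi <- -(8 / d_eq^2) * exp(-2 * w)
  2 * dphi^2 * psi^m + 2 * phi * d2phi * psi^m +
    4 * phi * dphi * m * psi^(m - 1) * dpsi +
    phi^2 * m * (m - 1) * (if (m >= 2) psi^(m - 2) else 0) * dpsi^2 +
    phi^2 * m * psi^(m - 1) * d2psi
}

## ---- angle-bending potentials ---------------------------------------------

#' Regularizing factor h of the tanh-regularized bend
#'
#' h(theta) = tanh(nu sin(theta/2)) / tanh(nu sin(theta_eq/2)). Satisfies
#' h(0) = 0, h(theta_eq) = 1, strictly increasing on (0, pi), and
#' h(pi) = tanh(nu)/tanh(nu sin(theta_eq/2)).
#'
#' @param theta angle(s) in radians, in [0, pi].
#' @param theta_eq equilibrium angle in (0, pi].
#' @param nu tanh multiplier > 0 (default 2).
#' @return dimensionless factor.
#' @export
h_factor <- function(theta, theta_eq, nu = 2) {
  stopifnot(all(theta >= 0), all(theta <= pi), theta_eq > 0, theta_eq <= pi,
            nu > 0)
  tanh(nu * sin(theta / 2)) / tanh(nu * sin(theta_eq / 2))
}

#' Angle-bending model-potential energy and derivatives
#'
#' Implements the harmonic bend k/2 (theta - theta_eq)^2, the cosine bend
#' k (1 - cos(theta - theta_eq)), the harmonic cosine
#' k/2 (cos theta - cos theta_eq)^2, an MM3-style polynomial bend with
#' configuration-supplied coefficients, and the tanh-regularized bend
#'
#'   U(theta) = 2 k (cos theta_eq - cos theta)^2 /
#'              [ h(theta) (sin^2 theta + 3 sin^2 theta_eq) ]
#'
#' with h from \code{\link{h_factor}}. The regularized form is a smooth
#' function of cos(theta): it has zero slope at theta = pi for every
#' theta_eq, curvature exactly k at theta_eq (including theta_eq = pi), and
#' diverges as theta -> 0, modeling the Pauli repulsion that keeps real
#' bond angles away from zero.
#'
#' @param theta angle(s), radians, in (0, pi]; fold reflex angles before
#'   calling (an angle pi + D measures as pi - D).
#' @param term a bend-kind \code{flex_term}.
#' @param deriv derivative order with respect to theta: 0, 1, or 2.
#' @return energy in hartree (or derivative), same length as \code{theta}.
#' @export
bend_energy <- function(theta, term, deriv = 0) {
  if (!inherits(term, "flex_term") || !term$kind %in% BEND_KINDS)
    stop("bend_energy requires a bend-kind flex_term")
  if (any(theta <= 0) || any(theta > pi))
    stop("theta outside (0, pi]: fold the angle first")
  stopifnot(deriv %in% 0:2)
  k <- term$force_constant; teq <- term$eq_value
  dt <- theta - teq
  switch(term$kind,
    bend_harmonic = switch(as.character(deriv),
      "0" = 0.5 * k * dt^2, "1" = k * dt, "2" = rep(k, length(theta))),
    bend_cosine = switch(as.character(deriv),
      "0" = k * (1 - cos(dt)), "1" = k * sin(dt), "2" = k * cos(dt)),
    bend_harmonic_cosine = {
      dc <- cos(theta) - cos(teq)
      switch(as.character(deriv),
        "0" = 0.5 * k * dc^2,
        "1" = -k * dc * sin(theta),
        "2" = -k * (cos(theta) * dc - sin(theta)^2))
    },
    bend_mm3 = mm3_bend(theta, teq, k, term$mm3_coeffs, deriv),
    bend_new = bend_new_theta(theta, teq, k, term$exponent, deriv),
    stop("unhandled bend kind"))
}

## MM3-style polynomial bend: U = k/2 Dt^2 (1 + sum_i c_i Dt^i), with the
## coefficient vector supplied from configuration.
mm3_bend <- function(theta, teq, k, coeffs, deriv) {
  dt <- theta - teq
  p <- rep(1, length(dt)); dp <- rep(0, length(dt)); d2p <- rep(0, length(dt))
  for (i in seq_along(coeffs)) {
    p <- p + coeffs[i] * dt^i
    dp <- dp + i * coeffs[i] * dt^(i - 1)
    if (i >= 2) d2p <- d2p + i * (i - 1) * coeffs[i] * dt^(i - 2)
  }
  switch(as.character(deriv),
    "0" = 0.5 * k * dt^2 * p,
    "1" = k * dt * p + 0.5 * k * dt^2 * dp,
    "2" = k * p + 2 * k * dt * dp + 0.5 * k * dt^2 * d2p)
}

## Tanh-regularized bend as a function of x = cos(theta), evaluated with
## derivatives with respect to x. Returns list(U, dU/dx, d2U/dx2).
bend_new_cos <- function(x, teq, k, nu) {
  ceq <- cos(teq)
  q <- sqrt(pmax((1 - x) / 2, 0))          # sin(theta/2)
  T0 <- tanh(nu * sin(teq / 2))
  H <- tanh(nu * q) / T0
  sech2 <- 1 / cosh(nu * q)^2
  dq <- ifelse(q > 0, -1 / (4 * q), 0)     # q -> 0 only at theta -> 0
  d2q <- ifelse(q > 0, -1 / (16 * q^3), 0)
  dH <- (nu / T0) * sech2 * dq
  d2H <- (nu / T0) * (-2 * nu * sech2 * tanh(nu * q) * dq^2 + sech2 * d2q)
  if (abs(teq - pi) < 1e-14) {
    ## theta_eq = pi: U = 2k (1 + x) / (H (1 - x)), the cancelled form
    N <- 2 * k * (1 + x); dN <- rep(2 * k, length(x)); d2N <- 0
    D <- H * (1 - x)
    dD <- dH * (1 - x) - H
    d2D <- d2H * (1 - x) - 2 * dH
  } else {
    N <- 2 * k * (ceq - x)^2
    dN <- -4 * k * (ceq - x); d2N <- 4 * k
    G <- (1 - x^2) + 3 * sin(teq)^2
    dG <- -2 * x; d2G <- -2
    D <- H * G
    dD <- dH * G + H * dG
    d2D <- d2H * G + 2 * dH * dG + H * d2G
  }
  U <- N / D
  dU <- (dN - U * dD) / D
  d2U <- (d2N - 2 * dU * dD - U * d2D) / D
  list(U = U, dU = dU, d2U = d2U)
}

bend_new_theta <- function(theta, teq, k, nu, deriv) {
  x <- cos(theta)
  v <- bend_new_cos(x, teq, k, nu)
  s <- sin(theta)
  switch(as.character(deriv),
    "0" = v$U,
    "1" = -v$dU * s,                        # dU/dtheta = dU/dx * (-sin)
    "2" = v$d2U * s^2 - v$dU * x)
}

## ---- cross term ------------------------------------------------------------

#' Bond-bond cross-term energy
#'
#' U = k (d_AB - d_AB^eq)(d_BC - d_BC^eq); bilinear in the two bond
#' displacements of an A-B-C triad, sign of k unconstrained.
#'
#' @param d_ab,d_bc the two bond lengths, bohr.
#' @param term a \code{flex_term} of kind \code{bond_bond_cross};
#'   \code{eq_value} and \code{eq_value2} hold the two equilibrium lengths.
#' @return energy in hartree.
#' @export
cross_term_energy <- function(d_ab, d_bc, term) {
  stopifnot(term$kind == "bond_bond_cross")
  term$force_constant * (d_ab - term$eq_value) * (d_bc - term$eq_value2)
}

## ---- serialization ---------------------------------------------------------

#' Write a flexibility model as structured text
#'
#' Key/value blocks, one per term, with atoms 1-based, lengths in angstrom,
#' angles in degrees, exponents in 1/bohr, and force constants in
#' eV/bohr^2 (stretch and cross forms) or eV (bends). Round-trips through
#' \code{\link{read_flexibility_model}}.
#'
#' @param model a \code{flexibility_model}.
#' @param path output file; \code{NULL} returns the lines.
#' @return the lines, invisibly.
#' @export
write_flexibility_model <- function(model, path = NULL) {
  fmt <- function(x) sprintf("%.12g", x)
  lines <- c("# ffft flexibility model",
             paste("subdomain =", model$subdomain_label))
  for (tm in model$terms) {
    is_bend <- tm$kind %in% BEND_KINDS
    lines <- c(lines, "", "[term]",
      paste("kind =", tm$kind),
      paste("atoms =", paste(tm$atoms, collapse = " ")),
      paste("eq =", fmt(if (is_bend) tm$eq_value * ffft_constants$deg_per_rad
                        else tm$eq_value * ffft_constants$angstrom_per_bohr)),
      paste("k =", fmt(tm$force_constant * ffft_constants$ev_per_hartree)))
    if (is.finite(tm$exponent))
      lines <- c(lines, paste(if (tm$kind == "bend_new") "nu =" else "gamma =",
                              fmt(tm$exponent)))
    if (!is.na(tm$eq_value2))
      lines <- c(lines, paste("eq2 =",
                              fmt(tm$eq_value2 * ffft_constants$angstrom_per_bohr)))
    if (!is.na(tm$basis_index))
      lines <- c(lines, paste("m =", tm$basis_index))
    if (tm$kind == "urey_bradley")
      lines <- c(lines, paste("ub_form =", tm$ub_form))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a flexibility model written by \code{write_flexibility_model}
#'
#' @param path input file (or a character vector of lines).
#' @return a \code{flexibility_model}.
#' @export
read_flexibility_model <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  lines <- trimws(lines)
  lines <- lines[nchar(lines) > 0 & !startsWith(lines, "#")]
  subdomain <- "ground_state"
  terms <- list(); cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    is_bend <- cur$kind %in% BEND_KINDS
    flex_term(cur$kind, cur$atoms,
              eq_value = if (is_bend) cur$eq * ffft_constants$rad_per_deg
                         else cur$eq * ffft_constants$bohr_per_angstrom,
              force_constant = cur$k * ffft_constants$hartree_per_ev,
              exponent = if (!is.null(cur$gamma)) cur$gamma
                         else if (!is.null(cur$nu)) cur$nu
                         else if (cur$kind == "bend_new") 2 else NA_real_,
              eq_value2 = if (!is.null(cur$eq2))
                cur$eq2 * ffft_constants$bohr_per_angstrom else NA_real_,
              basis_index = if (!is.null(cur$m)) cur$m else NA_integer_,
              ub_form = if (!is.null(cur$ub_form)) cur$ub_form else "manz")
  }
  for (ln in lines) {
    if (ln == "[term]") {
      t <- flush(cur); if (!is.null(t)) terms[[length(terms) + 1]] <- t
      cur <- list(); next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("cannot parse model line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (is.null(cur)) {
      if (key == "subdomain") subdomain <- val
      next
    }
    cur[[key]] <- switch(key,
      kind = val, ub_form = val,
      atoms = as.integer(strsplit(val, "[[:space:]]+")[[1]]),
      m = as.integer(val),
      as.numeric(val))
  }
  t <- flush(cur); if (!is.null(t)) terms[[length(terms) + 1]] <- t
  flexibility_model(terms, subdomain)
}
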