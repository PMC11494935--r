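## Pairwise nonbonded model (point charges + 12-6 Lennard-Jones), the
## smooth transition function tau, and the wrapping that makes every
## intracluster pair's nonbonded energy, gradient, and Hessian vanish at
## the reference geometry while keeping C^2 behavior at a finite cutoff.

#' Smooth transition function tau
#'
#' tau(s, t) = tanh(t/s - 1/2): bounded in (-1, 1), unit-free (depends only
#' on the ratio t/s), and strictly increasing in t/s. Mostly switched on
#' (tau^2 = 0.819) at t/s = 2.
#'
#' @param s positive reference scale.
#' @param t positive argument (same units as \code{s}).
#' @return dimensionless value in (-1, 1).
#' @export
tau <- function(s, t) {
  if (any(s <= 0)) stop("tau requires s > 0")
  tanh(t / s - 0.5)
}

#' Charge plus Lennard-Jones pair potential
#'
#' U(d) = q_A q_B / d + eps [ (d_LJ/d)^12 - 2 (d_LJ/d)^6 ] in atomic units:
#' the LJ part reaches its minimum -eps at d = d_LJ and the whole potential
#' vanishes as d -> infinity.
#'
#' @param d pair distance(s), bohr.
#' @param q_a,q_b atomic charges, elementary charge units.
#' @param eps LJ well depth, hartree.
#' @param d_lj LJ minimum distance, bohr.
#' @param deriv derivative order with respect to d (0, 1, or 2).
#' @return energy in hartree (or d-derivative thereof).
#' @export
pair_potential_qlj <- function(d, q_a, q_b, eps, d_lj, deriv = 0) {
  stopifnot(all(d > 0), deriv %in% 0:2)
  qq <- q_a * q_b
  s6 <- (d_lj / d)^6
  switch(as.character(deriv),
    "0" = qq / d + eps * (s6^2 - 2 * s6),
    "1" = -qq / d^2 + eps * (-12 * s6^2 + 12 * s6) / d,
    "2" = 2 * qq / d^3 + eps * (156 * s6^2 - 84 * s6) / d^2)
}

#' Describe how one pair's nonbonded interaction is wrapped
#'
#' @param kind \code{"intracluster"} (pair inside one bonded cluster) or
#'   \code{"intercluster"}.
#' @param d_eq equilibrium pair distance in the isolated cluster, bohr;
#'   required for intracluster wraps.
#' @param cutoff nonbonded cutoff distance in bohr, or \code{Inf}.
#' @return object of class \code{pair_wrap}.
#' @export
pair_wrap <- function(kind = c("intracluster", "intercluster"),
                      d_eq = NULL, cutoff = Inf) {
  kind <- match.arg(kind)
  if (kind == "intracluster") {
    if (is.null(d_eq) || !is.finite(d_eq) || d_eq <= 0)
      stop("an intracluster wrap requires the pair's equilibrium distance d_eq")
    if (is.finite(cutoff) && cutoff <= d_eq)
      stop("cutoff must exceed the pair's equilibrium distance")
  }
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(kind = kind, d_eq = d_eq, cutoff = cutoff),
            class = "pair_wrap")
}

## C^2 "smootherstep" ramp from 1 at a to 0 at b, with zero first and
## second derivatives at both ends; returns value and derivatives.
ramp_down <- function(d, a, b) {
  y <- (d - a) / (b - a)
  inside <- y > 0 & y < 1
  S <- ifelse(y <= 0, 1, ifelse(y >= 1, 0, NA))
  dS <- d2S <- numeric(length(d))
  if (any(inside)) {
    yy <- y[inside]
    S[inside] <- 1 - yy^3 * (10 - 15 * yy + 6 * yy^2)
    dS[inside] <- -30 * yy^2 * (1 - yy)^2 / (b - a)
    d2S[inside] <- -60 * yy * (1 - yy) * (1 - 2 * yy) / (b - a)^2
  }
  list(S = S, dS = dS, d2S = d2S)
}

#' Wrap a pair potential under the new nonbonded ansatz
#'
#' Returns the wrapped one-dimensional potential Phi(d). For an
#' intracluster pair, Phi, Phi', and Phi'' all vanish at the pair's
#' equilibrium distance, so the wrapped interaction contributes only to
#' third- and higher-order derivatives at the reference geometry; with a
#' finite cutoff, Phi is additionally zero for d >= cutoff with Phi, Phi',
#' Phi'' continuous there. The construction subtracts the second-order
#' Taylor polynomial of the pair potential about d_eq, damped at large d by
#' w(d) = 1 - rho(d)^3 with rho built from the smooth transition function
#' \code{\link{tau}} (rho = 0 at d_eq with zero slope contributions,
#' rho -> 1 as d -> infinity), and applies a C^2 ramp to zero at the
#' cutoff. The infinite-cutoff case is the pointwise cutoff -> infinity
#' limit; an intercluster pair with infinite cutoff is returned unchanged.
#'
#' @param u_pair function \code{(d, deriv = 0)} giving the bare pair energy
#'   (hartree) and its first two d-derivatives.
#' @param wrap a \code{\link{pair_wrap}}.
#' @return function \code{(d, deriv = 0)} evaluating Phi and derivatives.
#' @export
wrap_pair <- function(u_pair, wrap) {
  stopifnot(inherits(wrap, "pair_wrap"))
  cutoff <- wrap$cutoff
  if (wrap$kind == "intercluster") {
    if (!is.finite(cutoff)) return(u_pair)
    return(function(d, deriv = 0) {
      r <- ramp_down(d, cutoff / 2, cutoff)
      u0 <- u_pair(d, 0)
      switch(as.character(deriv),
        "0" = u0 * r$S,
        "1" = u_pair(d, 1) * r$S + u0 * r$dS,
        "2" = u_pair(d, 2) * r$S + 2 * u_pair(d, 1) * r$dS + u0 * r$d2S)
    })
  }
  deq <- wrap$d_eq
  u0 <- u_pair(deq, 0); u1 <- u_pair(deq, 1); u2 <- u_pair(deq, 2)
  tau0 <- tanh(0.5)    # tau(deq, deq)
  function(d, deriv = 0) {
    dd <- d - deq
    T2 <- u0 + u1 * dd + 0.5 * u2 * dd^2
    dT2 <- u1 + u2 * dd
    tt <- tanh(d / deq - 0.5)
    rho <- (tt - tau0) / (1 - tau0)
    dtt <- (1 - tt^2) / deq
    d2tt <- -2 * tt * dtt / deq
    drho <- dtt / (1 - tau0); d2rho <- d2tt / (1 - tau0)
    w <- 1 - rho^3
    dw <- -3 * rho^2 * drho
    d2w <- -(6 * rho * drho^2 + 3 * rho^2 * d2rho)
    phi0 <- u_pair(d, 0) - T2 * w
    if (is.finite(cutoff)) {
      r <- ramp_down(d, deq, cutoff)
    } else {
      r <- list(S = rep(1, length(d)), dS = numeric(length(d)),
                d2S = numeric(length(d)))
    }
    if (deriv == 0) return(phi0 * r$S)
    phi1 <- u_pair(d, 1) - dT2 * w - T2 * dw
    if (deriv == 1) return(phi1 * r$S + phi0 * r$dS)
    phi2 <- u_pair(d, 2) - u2 * w - 2 * dT2 * dw - T2 * d2w
    phi2 * r$S + 2 * phi1 * r$dS + phi0 * r$d2S
  }
}

#' Construct a nonbonded interaction model
#'
#' Per-atom charges and Lennard-Jones parameters with a geometric-mean
#' mixing rule for both the well depth and the minimum distance, an
#' optional cutoff, and the scheme selector: \code{"new"} wraps every pair
#' with \code{\link{wrap_pair}} so intracluster interactions vanish to
#' second order at the reference geometry; \code{"old"} sums the bare pair
#' potentials.
#'
#' @param charges per-atom charges (e).
#' @param lj_d per-atom LJ minimum distances.
#' @param lj_eps per-atom LJ well depths.
#' @param lj_d_units unit of \code{lj_d} (\code{"angstrom"} or
#'   \code{"bohr"}).
#' @param lj_eps_units unit of \code{lj_eps} (\code{"kcalmol"},
#'   \code{"ev"}, or \code{"hartree"}).
#' @param cutoff cutoff distance in bohr (\code{Inf} disables it).
#' @param scheme \code{"new"} or \code{"old"}.
#' @param max_separation exclusion policy: neighbors up to this bond-graph
#'   distance are excluded (2 or 3).
#' @return object of class \code{nonbonded_model} (atomic units inside).
#' @export
nonbonded_model <- function(charges, lj_d, lj_eps,
                            lj_d_units = "angstrom",
                            lj_eps_units = "kcalmol",
                            cutoff = Inf, scheme = c("new", "old"),
                            max_separation = 2) {
  scheme <- match.arg(scheme)
  if (any(lj_eps < 0)) stop("LJ well depths must be >= 0")
  if (any(lj_d <= 0)) stop("LJ minimum distances must be positive")
  if (cutoff <= 0) stop("cutoff must be positive (or Inf)")
  structure(list(charges = charges,
                 lj_d = convert_unit(lj_d, lj_d_units, "bohr"),
                 lj_eps = convert_unit(lj_eps, lj_eps_units, "hartree"),
                 mixing = "geometric", cutoff = cutoff, scheme = scheme,
                 max_separation = max_separation),
            class = "nonbonded_model")
}

mix_pair <- function(model, i, j) {
  list(q_a = model$charges[i], q_b = model$charges[j],
       eps = sqrt(model$lj_eps[i] * model$lj_eps[j]),
       d_lj = sqrt(model$lj_d[i] * model$lj_d[j]))
}

#' Assemble the total nonbonded energy and forces
#'
#' Sums over unordered atom pairs outside the exclusion sets. Under the old
#' scheme each pair contributes the bare charge+LJ potential; under the new
#' scheme each pair is wrapped per its kind (intracluster pairs require the
#' reference geometry to supply their equilibrium distance). Forces are the
#' exact negative gradient of the returned energy.
#'
#' @param system a \code{molecular_system}.
#' @param topology a \code{bonded_topology} for the system.
#' @param model a \code{nonbonded_model}.
#' @return list with \code{energy} (hartree), \code{forces} (n x 3,
#'   hartree/bohr), and \code{n_pairs} (pairs summed).
#' @export
assemble_nonbonded <- function(system, topology, model) {
  n <- system$n_atoms
  coords <- system$coords
  excl <- exclusion_sets(topology$bonds, n, model$max_separation)
  if (model$scheme == "new" && is.null(system$ref_coords))
    stop("the new scheme requires a reference geometry to supply every ",
         "intracluster pair's equilibrium distance")
  energy <- 0
  forces <- matrix(0, n, 3)
  n_pairs <- 0L
  memb <- topology$membership
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (j %in% excl[[i]]) next
    n_pairs <- n_pairs + 1L
    pm <- mix_pair(model, i, j)
    up <- function(d, deriv = 0)
      pair_potential_qlj(d, pm$q_a, pm$q_b, pm$eps, pm$d_lj, deriv)
    if (model$scheme == "old") {
      phi <- if (is.finite(model$cutoff))
        wrap_pair(up, pair_wrap("intercluster", cutoff = model$cutoff))
      else up
    } else {
      if (memb[i] == memb[j]) {
        deq <- dist_pair(system$ref_coords, i, j)
        phi <- wrap_pair(up, pair_wrap("intracluster", d_eq = deq,
                                       cutoff = model$cutoff))
      } else {
        phi <- wrap_pair(up, pair_wrap("intercluster", cutoff = model$cutoff))
      }
    }
    rij <- coords[i, ] - coords[j, ]
    d <- sqrt(sum(rij^2))
    energy <- energy + phi(d)
    f <- -phi(d, deriv = 1) * rij / d
    forces[i, ] <- forces[i, ] + f
    forces[j, ] <- forces[j, ] - f
  }
  list(energy = energy, forces = forces, n_pairs = n_pairs)
}

#' Read a nonbonded parameter table
#'
#' Plain-text table mapping element symbols to charge, LJ well depth, and
#' LJ minimum distance. Lines beginning with '#' are ignored; each data
#' line reads \code{element charge eps d_lj}.
#'
#' @param path file path.
#' @param system a \code{molecular_system}; parameters are expanded to one
#'   value per atom.
#' @param eps_units,d_units units of the table's eps and d_lj columns.
#' @inheritParams nonbonded_model
#' @return a \code{nonbonded_model}.
#' @export
read_nonbonded_params <- function(path, system, eps_units = "kcalmol",
                                  d_units = "angstrom", cutoff = Inf,
                                  scheme = "new", max_separation = 2) {
  lines <- trimws(readLines(path))
  lines <- lines[nchar(lines) > 0 & !startsWith(lines, "#")]
  tab <- do.call(rbind, lapply(lines, function(ln)
    strsplit(ln, "[[:space:]]+")[[1]]))
  el <- normalize_element(tab[, 1])
  missing_el <- setdiff(unique(system$elements), el)
  if (length(missing_el) > 0)
    stop("no nonbonded parameters for element(s): ",
         paste(missing_el, collapse = ", "))
  idx <- match(system$elements, el)
  nonbonded_model(charges = as.numeric(tab[idx, 2]),
                  lj_d = as.numeric(tab[idx, 4]),
                  lj_eps = as.numeric(tab[idx, 3]),
                  lj_d_units = d_units, lj_eps_units = eps_units,
                  cutoff = cutoff, scheme = scheme,
                  max_separation = max_separation)
}
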