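## Synthetic fixture generators: model-generated potential-energy surfaces
## (standing in for quantum-chemistry scans) and near-exponential atomic
## radial density profiles. Everything is reproducible from (spec, seed).

#' Generate a synthetic training surface from a ground-truth model
#'
#' Builds the displacement-roster geometries and evaluates each with the
#' supplied ground-truth composite model (bonded flexibility terms plus an
#' optional nonbonded model), adds Gaussian noise, and returns a
#' \code{\link{training_set}} whose ground truth is recorded in the
#' \code{"ground_truth"} attribute for recovery tests.
#'
#' @param system a \code{molecular_system} with \code{ref_coords}.
#' @param bonds two-column bond matrix.
#' @param truth_model ground-truth \code{flexibility_model}.
#' @param topology \code{bonded_topology} (required when
#'   \code{nonbonded} is supplied).
#' @param nonbonded optional \code{nonbonded_model} added to the truth
#'   energies (evaluated with its own scheme).
#' @param bond_displacements offsets in angstrom (see
#'   \code{\link{build_displacement_training_set}}).
#' @param sigma Gaussian noise standard deviation, hartree.
#' @param seed integer seed.
#' @return a \code{\link{training_set}}.
#' @export
generate_synthetic_surface <- function(system, bonds, truth_model,
                                       topology = NULL, nonbonded = NULL,
                                       bond_displacements = c(-0.14, -0.07,
                                                              0, 0.07, 0.14),
                                       sigma = 0, seed = 1) {
  stopifnot(sigma >= 0)
  roster <- build_displacement_training_set(system, bonds,
                                            bond_displacements)
  ref_coords <- system$ref_coords
  nb_ref <- 0
  nb_e <- rep(0, length(roster$geometries))
  if (!is.null(nonbonded)) {
    if (is.null(topology)) stop("nonbonded energies require the topology")
    nb_e <- vapply(roster$geometries, function(g)
      assemble_nonbonded(g, topology, nonbonded)$energy, numeric(1))
    ref_sys <- system; ref_sys$coords <- ref_coords
    nb_ref <- assemble_nonbonded(ref_sys, topology, nonbonded)$energy
  }
  u_ref <- model_energy(truth_model, ref_coords)
  energies <- vapply(seq_along(roster$geometries), function(j)
    model_energy(truth_model, roster$geometries[[j]]$coords) - u_ref +
      nb_e[j] - nb_ref, numeric(1))
  if (sigma > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(seed)
    energies <- energies + stats::rnorm(length(energies), 0, sigma)
  }
  ts <- training_set(roster$geometries, energies)
  attr(ts, "ground_truth") <- list(model = truth_model, sigma = sigma,
                                   seed = seed)
  ts
}

#' Generate a synthetic radial density profile
#'
#' rho(r_j) = r^p exp(a - b r) on a uniform shell grid, emulating the
#' near-exponential decay of spherically averaged atom-in-material
#' densities; p > 0 adds polynomial contamination.
#'
#' @param a log-scale intercept.
#' @param b decay exponent, 1/bohr (> 0).
#' @param r_max outermost shell radius, bohr.
#' @param spacing shell spacing, bohr.
#' @param p polynomial contamination degree (default 0 = pure
#'   exponential).
#' @param atom optional atom index tag.
#' @return a \code{radial_profile}; generating parameters are stored in
#'   the \code{"params"} attribute.
#' @export
generate_synthetic_density_profile <- function(a, b, r_max = 10,
                                               spacing = 0.2, p = 0,
                                               atom = NA_integer_) {
  stopifnot(b > 0, r_max > spacing, spacing > 0)
  r <- seq(spacing, r_max, by = spacing)
  rho <- r^p * exp(a - b * r)
  out <- radial_profile(r, rho, atom)
  attr(out, "params") <- list(a = a, b = b, p = p, spacing = spacing)
  out
}
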