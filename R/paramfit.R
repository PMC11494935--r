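## Training/validation set construction and force-constant regression.
## Under the new scheme every flexibility term is linear in its force
## constant, so the fit is (optionally LASSO-regularized, box-constrained)
## linear least squares; the old scheme additionally fits per-term resting
## values by bounded nonlinear least squares.

#' Place a triatomic A-B-C in the xy-plane
#'
#' Vertex atom B at the origin, A on the +x axis at distance \code{d1},
#' C at angle \code{theta} from A at distance \code{d2}.
#'
#' @param elements three element symbols (A, B, C order).
#' @param d1,d2 bond lengths A-B and B-C.
#' @param theta angle in radians.
#' @param units unit of \code{d1}, \code{d2}.
#' @param ref optional reference geometry (n x 3, bohr) to attach.
#' @return a \code{molecular_system} (atom order A, B, C).
#' @export
make_triatomic <- function(elements, d1, d2, theta,
                           units = c("angstrom", "bohr"), ref = NULL) {
  units <- match.arg(units)
  stopifnot(length(elements) == 3, theta > 0, theta <= pi)
  coords <- rbind(c(d1, 0, 0), c(0, 0, 0),
                  c(d2 * cos(theta), d2 * sin(theta), 0))
  sys <- molecular_system(elements, coords, units = units)
  if (!is.null(ref)) sys$ref_coords <- ref
  sys
}

#' Bundle reference-relative training data
#'
#' @param geometries list of \code{molecular_system} objects.
#' @param energies energies relative to the reference-geometry energy,
#'   hartree.
#' @param forces optional list of n x 3 force matrices (hartree/bohr).
#' @param w_energy,w_force observation weights for energy and force rows.
#' @return object of class \code{ffft_training_set}.
#' @export
training_set <- function(geometries, energies, forces = NULL,
                         w_energy = 1, w_force = 0) {
  stopifnot(length(geometries) == length(energies), all(is.finite(energies)))
  if (!is.null(forces) && length(forces) != length(geometries))
    stop("forces, if present, must be shaped like geometries")
  structure(list(geometries = geometries, energies = energies,
                 forces = forces, w_energy = w_energy, w_force = w_force),
            class = "ffft_training_set")
}

## Which atom moves when a bond is displaced: the terminal (degree-1) atom,
## else the second atom of the pair.
bond_move_atom <- function(bonds, b) {
  deg <- tabulate(as.vector(bonds), nbins = max(bonds))
  i <- bonds[b, 1]; j <- bonds[b, 2]
  if (deg[j] == 1) j else if (deg[i] == 1) i else j
}

displace_bond <- function(coords, bonds, b, delta) {
  mv <- bond_move_atom(bonds, b)
  anchor <- setdiff(bonds[b, ], mv)
  u <- coords[mv, ] - coords[anchor, ]
  u <- u / sqrt(sum(u^2))
  coords[mv, ] <- coords[mv, ] + delta * u
  coords
}

#' Build the displacement training-set geometry roster
#'
#' Bond-displacement geometries form the full Cartesian product of
#' per-bond offset grids applied at the fixed equilibrium angle, with the
#' all-zero (equilibrium) point excluded and, for molecules whose bonds
#' are permutationally equivalent, unordered duplicates removed. Optional
#' angle-scan observations are filtered to the
#' \code{theta_eq +/- angle_window} band.
#'
#' @param system a \code{molecular_system} with \code{ref_coords}.
#' @param bonds two-column bond matrix.
#' @param bond_displacements numeric vector of bond-length offsets
#'   (angstrom) applied to every bond; include 0 to reproduce the
#'   grid-protocol counts.
#' @param angle_scan optional data frame with columns \code{theta}
#'   (degrees) and \code{energy} (hartree, relative to the reference).
#' @param angle_window half-width of the retained angle band, degrees.
#' @param symmetric treat the molecule's bonds as permutationally
#'   equivalent (\code{NULL} = auto-detect from elements and equilibrium
#'   lengths).
#' @return list with \code{geometries} (list of \code{molecular_system}),
#'   and \code{info} (data frame: \code{type} of each row, displacement
#'   label, \code{energy} where supplied).
#' @export
build_displacement_training_set <- function(system, bonds,
                                            bond_displacements,
                                            angle_scan = NULL,
                                            angle_window = 30,
                                            symmetric = NULL) {
  if (is.null(system$ref_coords))
    stop("displacement protocol requires a reference geometry")
  ref <- system$ref_coords
  bonds <- as.matrix(bonds)
  nb <- nrow(bonds)
  disp_bohr <- bond_displacements * ffft_constants$bohr_per_angstrom
  eq_len <- vapply(seq_len(nb), function(b)
    dist_pair(ref, bonds[b, 1], bonds[b, 2]), numeric(1))
  if (any(outer(eq_len, disp_bohr, "+") <= 0))
    stop("a displacement would produce a non-positive bond length")
  if (is.null(symmetric)) {
    sig <- vapply(seq_len(nb), function(b) {
      el <- sort(system$elements[bonds[b, ]])
      paste(el[1], el[2], sprintf("%.6f", eq_len[b]))
    }, character(1))
    symmetric <- nb == 2 && sig[1] == sig[2]
  }
  grid <- as.matrix(expand.grid(rep(list(seq_along(disp_bohr)), nb)))
  keep <- rep(TRUE, nrow(grid))
  for (r in seq_len(nrow(grid))) {
    if (all(abs(disp_bohr[grid[r, ]]) < 1e-14)) { keep[r] <- FALSE; next }
    if (symmetric && is.unsorted(grid[r, ])) keep[r] <- FALSE
  }
  grid <- grid[keep, , drop = FALSE]
  geoms <- list(); info <- list()
  for (r in seq_len(nrow(grid))) {
    coords <- ref
    for (b in seq_len(nb))
      coords <- displace_bond(coords, bonds, b, disp_bohr[grid[r, b]])
    g <- system; g$coords <- coords
    geoms[[length(geoms) + 1]] <- g
    info[[length(info) + 1]] <- data.frame(
      type = "bond_grid",
      label = paste(sprintf("%+.3f", bond_displacements[grid[r, ]]),
                    collapse = "/"),
      energy = NA_real_)
  }
  if (!is.null(angle_scan)) {
    if (system$n_atoms != 3)
      stop("angle scans are supported for triatomic systems")
    ang <- enumerate_angles(bonds, system$n_atoms)
    teq <- angle_from_coords(ref, ang[1, 1], ang[1, 2], ang[1, 3]) *
      ffft_constants$deg_per_rad
    sel <- abs(angle_scan$theta - teq) <= angle_window + 1e-9
    for (r in which(sel)) {
      th <- angle_scan$theta[r] * ffft_constants$rad_per_deg
      d1 <- dist_pair(ref, ang[1, 1], ang[1, 2])
      d2 <- dist_pair(ref, ang[1, 3], ang[1, 2])
      g <- make_triatomic(system$elements[c(ang[1, 1], ang[1, 2], ang[1, 3])],
                          d1, d2, th, units = "bohr", ref = ref)
      ## restore original atom order A,B,C -> system order
      ord <- order(c(ang[1, 1], ang[1, 2], ang[1, 3]))
      g$elements <- g$elements[ord]; g$coords <- g$coords[ord, ]
      g$ref_coords <- ref
      geoms[[length(geoms) + 1]] <- g
      info[[length(info) + 1]] <- data.frame(
        type = "angle_scan", label = sprintf("%.2f", angle_scan$theta[r]),
        energy = angle_scan$energy[r])
    }
  }
  list(geometries = geoms, info = do.call(rbind, info))
}

#' Random validation geometries for a triatomic
#'
#' Independent uniform draws per bond (within \code{+/- bond_range}
#' angstrom) and for the angle (within \code{+/- angle_range} degrees),
#' reproducible from the seed.
#'
#' @param system triatomic \code{molecular_system} with \code{ref_coords}.
#' @param bonds two-column bond matrix (two bonds).
#' @param n number of geometries.
#' @param bond_range,angle_range half-widths of the uniform windows.
#' @param seed integer RNG seed.
#' @return list of \code{molecular_system} objects.
#' @export
generate_validation_geometries <- function(system, bonds, n = 9,
                                           bond_range = 0.07,
                                           angle_range = 30, seed = 1) {
  stopifnot(n >= 1, system$n_atoms == 3, nrow(bonds) == 2)
  ref <- system$ref_coords
  ang <- enumerate_angles(bonds, 3)
  A <- ang[1, 1]; B <- ang[1, 2]; C <- ang[1, 3]
  d1 <- dist_pair(ref, A, B); d2 <- dist_pair(ref, C, B)
  teq <- angle_from_coords(ref, A, B, C)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  br <- bond_range * ffft_constants$bohr_per_angstrom
  ar <- angle_range * ffft_constants$rad_per_deg
  lapply(seq_len(n), function(i) {
    dd1 <- stats::runif(1, -br, br)
    dd2 <- stats::runif(1, -br, br)
    dth <- stats::runif(1, -ar, ar)
    th <- min(pi, max(1e-3, teq + dth))
    g <- make_triatomic(system$elements[c(A, B, C)], d1 + dd1, d2 + dd2, th,
                        units = "bohr", ref = ref)
    ord <- order(c(A, B, C))
    g$elements <- g$elements[ord]; g$coords <- g$coords[ord, ]
    g$ref_coords <- ref
    g
  })
}

#' Design matrix of a flexibility model over a set of geometries
#'
#' Entry (i, g) is the energy of term g at geometry i evaluated with unit
#' force constant, so the model prediction is exactly
#' \code{design \%*\% k}. With \code{include_forces}, 3n force rows per
#' geometry are appended whose entries are the negative unit-force-constant
#' gradients.
#'
#' @param model a \code{flexibility_model} (force constants are ignored).
#' @param geometries list of \code{molecular_system} objects.
#' @param include_forces append force rows.
#' @return numeric matrix, one column per term.
#' @export
design_matrix <- function(model, geometries, include_forces = FALSE) {
  unit_terms <- lapply(model$terms, function(tm) {
    tm$force_constant <- 1
    tm
  })
  nterm <- length(unit_terms)
  rows <- list()
  for (g in geometries) {
    rows[[length(rows) + 1]] <- vapply(unit_terms, term_energy_cartesian,
                                       numeric(1), coords = g$coords)
    if (include_forces) {
      fr <- vapply(unit_terms, function(tm)
        -as.vector(t(term_gradient_cartesian(tm, g$coords))),
        numeric(3 * g$n_atoms))
      rows[[length(rows) + 1]] <- matrix(fr, ncol = nterm)
    }
  }
  X <- do.call(rbind, lapply(rows, rbind))
  colnames(X) <- vapply(seq_along(model$terms), function(i)
    paste0(model$terms[[i]]$kind, "_",
           paste(model$terms[[i]]$atoms, collapse = ".")), character(1))
  X
}

#' Fit configuration
#'
#' @param lasso_lambda L1 penalty weight lambda >= 0 in the objective
#'   1/2 sum w r^2 + lambda sum |k| (no intercept, no standardization).
#' @param lower,upper per-coefficient bounds; \code{NULL} lower defaults to
#'   0 for stretch/bend/Urey-Bradley terms and -Inf for cross terms when
#'   the design matrix carries term-kind column names.
#' @param rel_tol convergence tolerance on the coefficient update.
#' @param max_iter iteration cap for coordinate descent.
#' @param n_starts deterministic multi-starts for the old-scheme fit.
#' @param seed integer seed for any randomized component.
#' @return object of class \code{fit_config}.
#' @export
fit_config <- function(lasso_lambda = 0, lower = NULL, upper = NULL,
                       rel_tol = 1e-10, max_iter = 100000L,
                       n_starts = 5L, seed = 1L) {
  stopifnot(lasso_lambda >= 0, rel_tol > 0, max_iter > 0)
  structure(list(lasso_lambda = lasso_lambda, lower = lower, upper = upper,
                 rel_tol = rel_tol, max_iter = as.integer(max_iter),
                 n_starts = as.integer(n_starts), seed = as.integer(seed)),
            class = "fit_config")
}

default_bounds <- function(X) {
  cn <- colnames(X)
  lower <- rep(0, ncol(X))
  if (!is.null(cn)) lower[grepl("^bond_bond_cross", cn)] <- -Inf
  lower
}

#' Linear (optionally LASSO) fit of force constants
#'
#' Minimizes 1/2 sum_i w_i (y_i - (X k)_i)^2 + lambda sum_g |k_g| subject
#' to per-coefficient box bounds, by cyclic coordinate descent with
#' soft-thresholding (deterministic; no intercept, no standardization).
#' With lambda = 0 and a full-rank design whose unconstrained solution is
#' feasible, the exact weighted least-squares solution is returned.
#'
#' @param design numeric design matrix (see \code{\link{design_matrix}}).
#' @param targets response vector (hartree).
#' @param config a \code{\link{fit_config}}.
#' @param weights optional per-row weights (default 1).
#' @return object of class \code{fit_result}: \code{force_constants},
#'   \code{r_squared_train}, \code{n_nonzero}, \code{loss},
#'   \code{converged}.
#' @export
fit_linear <- function(design, targets, config = fit_config(),
                       weights = NULL) {
  X <- as.matrix(design)
  if (nrow(X) == 0 || ncol(X) == 0) stop("empty design matrix")
  stopifnot(length(targets) == nrow(X))
  w <- if (is.null(weights)) rep(1, nrow(X)) else weights
  lam <- config$lasso_lambda
  lower <- if (is.null(config$lower)) default_bounds(X) else
    rep_len(config$lower, ncol(X))
  upper <- if (is.null(config$upper)) rep(Inf, ncol(X)) else
    rep_len(config$upper, ncol(X))
  colnorm <- colSums(w * X^2)
  if (any(colnorm == 0)) {
    bad <- colnames(X)[colnorm == 0]
    if (is.null(bad)) bad <- which(colnorm == 0)
    stop("unidentifiable term(s): design column is identically zero for ",
         paste(bad, collapse = ", "))
  }
  k <- numeric(ncol(X))
  converged <- FALSE
  ## exact fast path: lambda = 0, full rank, interior solution
  if (lam == 0 && qr(X)$rank == ncol(X)) {
    sw <- sqrt(w)
    ks <- qr.coef(qr(sw * X), sw * targets)
    if (all(ks >= lower - 1e-12) && all(ks <= upper + 1e-12)) {
      k <- pmin(pmax(ks, lower), upper)
      converged <- TRUE
    }
  }
  if (!converged) {
    r <- targets - X %*% k
    for (it in seq_len(config$max_iter)) {
      delta <- 0
      for (g in seq_len(ncol(X))) {
        rho <- sum(w * X[, g] * (r + X[, g] * k[g]))
        knew <- soft_threshold(rho, lam) / colnorm[g]
        knew <- min(upper[g], max(lower[g], knew))
        if (knew != k[g]) {
          r <- r - X[, g] * (knew - k[g])
          delta <- max(delta, abs(knew - k[g]) / max(1, abs(knew)))
          k[g] <- knew
        }
      }
      if (delta < config$rel_tol) { converged <- TRUE; break }
    }
  }
  pred <- as.vector(X %*% k)
  res <- targets - pred
  names(k) <- colnames(X)
  structure(list(force_constants = k,
                 r_squared_train = r_squared(pred, targets),
                 n_nonzero = sum(abs(k) > 1e-12),
                 loss = 0.5 * sum(w * res^2) + lam * sum(abs(k)),
                 converged = converged, lambda = lam),
            class = "fit_result")
}

soft_threshold <- function(x, lam) sign(x) * max(0, abs(x) - lam)

#' Coefficient of determination R^2 = 1 - SSE/SST
#'
#' @param predicted,reference numeric vectors (at least 2 observations).
#' @return R^2; \code{NA} with a warning when the reference variance is
#'   zero (undefined).
#' @export
r_squared <- function(predicted, reference) {
  stopifnot(length(predicted) == length(reference), length(reference) >= 2)
  sst <- sum((reference - mean(reference))^2)
  if (sst == 0) {
    warning("R^2 undefined: zero total sum of squares")
    return(NA_real_)
  }
  1 - sum((predicted - reference)^2) / sst
}

## Old-scheme model energy relative to the reference geometry, with the
## resting values of stretch/bend terms replaced by free parameters.
old_scheme_residuals <- function(par, model, train, nb_energies, nb_ref,
                                 rest_idx, ref_coords) {
  nterm <- length(model$terms)
  ks <- par[seq_len(nterm)]
  terms <- model$terms
  for (i in seq_len(nterm)) {
    terms[[i]]$force_constant <- ks[i]
    ri <- match(i, rest_idx)
    if (!is.na(ri)) terms[[i]]$eq_value <- par[nterm + ri]
  }
  m <- flexibility_model(terms, model$subdomain_label)
  u_ref <- model_energy(m, ref_coords)
  pred <- vapply(seq_along(train$geometries), function(j)
    model_energy(m, train$geometries[[j]]$coords) - u_ref +
      nb_energies[j] - nb_ref, numeric(1))
  pred - train$energies
}

#' Old-scheme joint fit of force constants and resting values
#'
#' Conventional partition: the raw nonbonded sum is added to the bonded
#' terms, so the per-term resting values no longer equal the equilibrium
#' internal coordinates and must be fitted jointly with the force
#' constants by bounded nonlinear least squares (Levenberg-Marquardt with
#' deterministic multi-starts at the equilibrium values +/- 1-2 percent).
#'
#' @param model a \code{flexibility_model} whose eq values seed the
#'   resting-value starts.
#' @param train a \code{\link{training_set}}.
#' @param nonbonded a \code{nonbonded_model} (scheme forced to
#'   \code{"old"}); \code{NULL} for no nonbonded interactions.
#' @param system the reference \code{molecular_system}.
#' @param topology its \code{bonded_topology}.
#' @param config a \code{\link{fit_config}}.
#' @return \code{fit_result} with an extra \code{resting_values} element.
#' @export
fit_old_scheme <- function(model, train, nonbonded, system, topology,
                           config = fit_config()) {
  nterm <- length(model$terms)
  rest_idx <- which(vapply(model$terms, function(tm)
    tm$kind %in% c(STRETCH_KINDS, BEND_KINDS), logical(1)))
  nb_energies <- rep(0, length(train$geometries)); nb_ref <- 0
  if (!is.null(nonbonded)) {
    nb <- nonbonded; nb$scheme <- "old"
    nb_energies <- vapply(train$geometries, function(g)
      assemble_nonbonded(g, topology, nb)$energy, numeric(1))
    ref_sys <- system; ref_sys$coords <- system$ref_coords
    nb_ref <- assemble_nonbonded(ref_sys, topology, nb)$energy
  }
  k0 <- vapply(model$terms, function(tm)
    if (abs(tm$force_constant) > 1e-12) tm$force_constant else 0.1,
    numeric(1))
  eq0 <- vapply(model$terms[rest_idx], `[[`, numeric(1), "eq_value")
  lower <- c(ifelse(vapply(model$terms, function(tm)
    tm$kind == "bond_bond_cross", logical(1)), -Inf, 0),
    rep(1e-3, length(rest_idx)))
  upper <- rep(Inf, nterm + length(rest_idx))
  offsets <- c(0, 0.01, -0.01, 0.02, -0.02)[seq_len(max(1, config$n_starts))]
  best <- NULL
  for (off in offsets) {
    par0 <- c(k0, eq0 * (1 + off))
    fit <- minpack.lm::nls.lm(
      par = par0, lower = lower, upper = upper,
      fn = old_scheme_residuals, model = model, train = train,
      nb_energies = nb_energies, nb_ref = nb_ref, rest_idx = rest_idx,
      ref_coords = system$ref_coords,
      control = minpack.lm::nls.lm.control(maxiter = 500,
                                           ftol = config$rel_tol))
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  fit <- best$fit
  if (fit$info %in% c(0, 5, 9))
    warning("old-scheme fit did not fully converge (info = ", fit$info,
            "); returning best-so-far parameters")
  k <- fit$par[seq_len(nterm)]
  names(k) <- vapply(model$terms, function(tm)
    paste0(tm$kind, "_", paste(tm$atoms, collapse = ".")), character(1))
  resting <- fit$par[nterm + seq_along(rest_idx)]
  names(resting) <- names(k)[rest_idx]
  pred <- train$energies + fit$fvec
  structure(list(force_constants = k, resting_values = resting,
                 r_squared_train = r_squared(pred, train$energies),
                 n_nonzero = sum(abs(k) > 1e-12), loss = 0.5 * best$ssr,
                 converged = !fit$info %in% c(0, 5, 9)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("force-constant fit\n")
  for (nm in names(x$force_constants))
    cat(sprintf("  %-28s k = %10.2f eV/bohr^2 (or eV)\n", nm,
                x$force_constants[[nm]] * ffft_constants$ev_per_hartree))
  if (!is.null(x$resting_values))
    for (nm in names(x$resting_values))
      cat(sprintf("  %-28s resting = %.4f bohr (or rad)\n", nm,
                  x$resting_values[[nm]]))
  cat(sprintf("  R-squared (training) = %.4f, nonzero terms = %d\n",
              x$r_squared_train, x$n_nonzero))
  invisible(x)
}
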