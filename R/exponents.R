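## Per-bond electron-density decay exponents b_A from spherically averaged
## radial density profiles, and the derived Manz-stretch exponent gamma0
## and predicted Morse exponent.

#' Construct a radial density profile
#'
#' @param r shell radii, bohr, strictly increasing (>= 2 shells).
#' @param rho spherically averaged densities, e/bohr^3, non-negative.
#' @param atom optional atom index the profile belongs to.
#' @return object of class \code{radial_profile}.
#' @export
radial_profile <- function(r, rho, atom = NA_integer_) {
  stopifnot(length(r) == length(rho), length(r) >= 2)
  if (any(diff(r) <= 0)) stop("shell radii must be strictly increasing")
  if (any(rho < 0)) stop("densities must be non-negative")
  structure(list(r = as.numeric(r), rho = as.numeric(rho),
                 atom = as.integer(atom)),
            class = "radial_profile")
}

#' Enforce monotone non-increasing densities
#'
#' Running maximum applied from the outermost shell inward:
#' rho(r_last) is kept, and rho(r_j) = max(rho(r_j), rho(r_j+1)) moving
#' toward smaller radii. Idempotent.
#'
#' @param profile a \code{radial_profile}.
#' @return conditioned \code{radial_profile}.
#' @export
condition_profile <- function(profile) {
  rho <- rev(cummax(rev(profile$rho)))
  radial_profile(profile$r, rho, profile$atom)
}

## log-linear interpolation of a conditioned profile at arbitrary radii;
## values outside the grid extrapolate with the edge segments.
profile_log_interp <- function(profile, r_out) {
  lr <- log(pmax(profile$rho, 1e-300))
  exp(stats::approx(profile$r, lr, xout = r_out, rule = 2)$y)
}

#' Density crossing radius along a bond
#'
#' On atom A's shell grid, finds (a) the smallest r_A where atom B's
#' conditioned density at (d_AB - r_A) exceeds atom A's, and (b) the
#' largest r_A where it is still below; the crossing radius D is the
#' average of the two. Atom B's profile is log-linearly interpolated.
#'
#' @param profile_a,profile_b conditioned \code{radial_profile}s.
#' @param d_ab bond length, bohr.
#' @return crossing radius D (bohr).
#' @export
crossing_radius <- function(profile_a, profile_b, d_ab) {
  stopifnot(d_ab > 0)
  r <- profile_a$r
  use <- r > 0 & r < d_ab
  if (!any(use)) stop("no shells of atom A lie inside the bond span")
  ra <- r[use]
  rho_a <- profile_a$rho[use]
  rho_b <- profile_log_interp(profile_b, d_ab - ra)
  above <- which(rho_b > rho_a)
  below <- which(rho_b < rho_a)
  if (length(above) == 0 || length(below) == 0)
    stop("no density crossing found along the bond within the shell grid")
  (ra[min(above)] + ra[max(below)]) / 2
}

#' Fit the exponential decay exponent over the bond window
#'
#' Ordinary least squares of ln(rho) against a - b r over the shells in
#' the asymmetric window D - 0.5 bohr <= r <= D + 2.5 bohr (emphasizing
#' the outer valence region). The window is clipped at the grid boundary
#' when at least 4 shells remain, with a warning.
#'
#' @param profile conditioned \code{radial_profile} with positive
#'   densities in the window (zero-density shells are skipped with a
#'   warning).
#' @param D crossing radius, bohr.
#' @return named numeric vector \code{c(a, b)}.
#' @export
fit_decay_exponent <- function(profile, D) {
  lo <- D - 0.5; hi <- D + 2.5
  sel <- profile$r >= lo - 1e-12 & profile$r <= hi + 1e-12
  if ((lo < min(profile$r) || hi > max(profile$r))) {
    if (sum(sel) >= 4)
      warning("decay-fit window clipped at the shell-grid boundary")
    else
      stop("decay-fit window extends beyond the shell grid with fewer ",
           "than 4 usable shells")
  }
  r <- profile$r[sel]; rho <- profile$rho[sel]
  if (any(rho <= 0)) {
    warning("skipping ", sum(rho <= 0), " zero-density shell(s) in window")
    r <- r[rho > 0]; rho <- rho[rho > 0]
  }
  if (length(r) < 2) stop("fewer than 2 usable shells in the decay window")
  fit <- stats::lm.fit(cbind(1, r), log(rho))
  c(a = unname(fit$coefficients[1]), b = unname(-fit$coefficients[2]))
}

#' Combine two atomic decay exponents into the stretch exponent gamma0
#'
#' Default rule: gamma0 = b_A b_B / (b_A + b_B) (half the harmonic mean),
#' symmetric, positive, scale-covariant, and such that for equal exponents
#' b the short-range-repulsion exponent (5/3) gamma0 equals (5/6) b. The
#' combining rule is injectable for experimentation.
#'
#' @param b_a,b_b positive decay exponents, 1/bohr.
#' @param rule optional replacement function \code{(b_a, b_b)}.
#' @return gamma0 (1/bohr).
#' @export
bond_gamma <- function(b_a, b_b, rule = NULL) {
  if (any(c(b_a, b_b) <= 0)) stop("decay exponents must be positive")
  if (!is.null(rule)) return(rule(b_a, b_b))
  b_a * b_b / (b_a + b_b)
}

#' Predicted Morse exponent from gamma0
#'
#' Equating the Morse and Manz stretch force constants and dissociation
#' energies (k/(2 gamma_M^2) = 3k/(5 gamma0^2)) gives
#' gamma_Morse = gamma0 sqrt(5/6).
#'
#' @param gamma0 Manz stretch exponent, 1/bohr.
#' @return predicted Morse exponent, 1/bohr.
#' @export
predict_morse_exponent <- function(gamma0) {
  stopifnot(all(gamma0 > 0))
  gamma0 * sqrt(5 / 6)
}

#' Per-bond decay exponents and stretch exponents for a system
#'
#' Full pipeline for every bond: condition both atomic profiles, locate
#' the density crossing from each side, fit the decay exponents over the
#' per-bond windows, and derive gamma0 and the predicted Morse exponent.
#' The same atom can carry different b values for different bonds.
#'
#' @param profiles list of \code{radial_profile}s, one per atom.
#' @param system a \code{molecular_system}.
#' @param bonds two-column bond matrix.
#' @param use_ref measure bond lengths on the reference geometry.
#' @return data frame with one row per bond: atoms, bond length, crossing
#'   radii \code{D_a}, \code{D_b}, exponents \code{b_a}, \code{b_b},
#'   \code{gamma0}, and \code{gamma_morse_pred}.
#' @export
compute_bond_exponents <- function(profiles, system, bonds,
                                   use_ref = FALSE) {
  if (length(profiles) != system$n_atoms)
    stop("need one radial profile per atom")
  coords <- if (use_ref && !is.null(system$ref_coords))
    system$ref_coords else system$coords
  bonds <- as.matrix(bonds)
  cond <- lapply(profiles, condition_profile)
  out <- list()
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    d <- dist_pair(coords, i, j)
    res <- tryCatch({
      Da <- crossing_radius(cond[[i]], cond[[j]], d)
      Db <- crossing_radius(cond[[j]], cond[[i]], d)
      fa <- fit_decay_exponent(cond[[i]], Da)
      fb <- fit_decay_exponent(cond[[j]], Db)
      g0 <- bond_gamma(fa[["b"]], fb[["b"]])
      data.frame(i = i, j = j, d = d, D_a = Da, D_b = Db,
                 b_a = fa[["b"]], b_b = fb[["b"]], gamma0 = g0,
                 gamma_morse_pred = predict_morse_exponent(g0))
    }, error = function(e)
      stop("bond ", i, "-", j, ": ", conditionMessage(e), call. = FALSE))
    out[[b]] <- res
  }
  do.call(rbind, out)
}

#' Read Chargemol-style radial density profiles
#'
#' Per-atom blocks introduced by a line \code{atom <index>}; header lines
#' beginning with '#' are ignored; data lines hold two numeric columns,
#' radius (bohr) and spherically averaged density (e/bohr^3).
#'
#' @param path file path.
#' @return list of \code{radial_profile}s indexed by atom.
#' @export
read_radial_profiles <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nchar(lines) > 0 & !startsWith(lines, "#")]
  profiles <- list(); cur_atom <- NA_integer_; r <- c(); rho <- c()
  flush <- function() {
    if (length(r) > 0)
      profiles[[cur_atom]] <<- radial_profile(r, rho, cur_atom)
  }
  for (ln in lines) {
    if (grepl("^atom[[:space:]]+[0-9]+$", ln)) {
      flush()
      cur_atom <- as.integer(sub("^atom[[:space:]]+", "", ln))
      r <- c(); rho <- c()
    } else {
      tok <- as.numeric(strsplit(ln, "[[:space:]]+")[[1]])
      if (length(tok) != 2 || anyNA(tok))
        stop("cannot parse radial-profile line: ", ln)
      r <- c(r, tok[1]); rho <- c(rho, tok[2])
    }
  }
  flush()
  profiles
}
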