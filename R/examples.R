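## Bundled example systems: coupled-cluster equilibrium geometries for
## small molecules and quantum-chemistry-derived flexibility parameters
## for their vibrational models. These serve as worked examples and as
## regression fixtures.

## equilibrium geometry table: angle (deg), bond length(s) (angstrom)
.example_geometries <- list(
  CO2  = list(elements = c("O", "C", "O"), angle = 180.0, d = c(1.157, 1.157)),
  H2O  = list(elements = c("H", "O", "H"), angle = 104.7, d = c(0.962, 0.962)),
  HNO  = list(elements = c("H", "N", "O"), angle = 108.4, d = c(1.056, 1.201)),
  SO2  = list(elements = c("O", "S", "O"), angle = 119.4, d = c(1.426, 1.426)),
  CaH2 = list(elements = c("H", "Ca", "H"), angle = 180.0, d = c(2.065, 2.065)),
  SF2  = list(elements = c("F", "S", "F"), angle = 97.7, d = c(1.586, 1.586)))

#' Bundled example molecule geometries
#'
#' Equilibrium geometries (coupled-cluster optimized) for a set of small
#' molecules used in the package examples, with \code{ref_coords} set to
#' the equilibrium structure. \code{"C6F6"} builds planar hexagonal
#' hexafluorobenzene from its optimized C-C (1.389 A) and C-F (1.332 A)
#' bond lengths.
#'
#' @param name one of \code{"CO2"}, \code{"H2O"}, \code{"HNO"},
#'   \code{"SO2"}, \code{"CaH2"}, \code{"SF2"}, \code{"C6F6"}.
#' @return a \code{molecular_system} (reference geometry attached).
#' @export
example_molecule <- function(name) {
  name <- toupper(name)
  if (name == "C6F6") {
    rc <- 1.389          # hexagon side = circumradius
    rf <- 1.389 + 1.332
    ang <- (0:5) * pi / 3
    coords <- rbind(cbind(rc * cos(ang), rc * sin(ang), 0),
                    cbind(rf * cos(ang), rf * sin(ang), 0))
    sys <- molecular_system(c(rep("C", 6), rep("F", 6)), coords,
                            ref_coords = coords, units = "angstrom")
    return(sys)
  }
  g <- .example_geometries[[name]]
  if (is.null(g)) stop("no bundled geometry for ", name)
  sys <- make_triatomic(g$elements, g$d[1], g$d[2],
                        g$angle * ffft_constants$rad_per_deg,
                        units = "angstrom")
  sys$ref_coords <- sys$coords
  sys
}

## flexibility parameters: stretch k (eV/bohr^2), gamma0 (1/bohr) per
## bond, bend k (eV), optional Urey-Bradley k and gamma0.
.example_flex_params <- list(
  CO2 = list(no_ub = list(k_stretch = c(30.58, 30.58), gamma = c(1.203, 1.203),
                          k_bend = 5.17),
             ub = list(k_stretch = c(27.26, 27.26), gamma = c(1.203, 1.203),
                       k_bend = 5.03, k_ub = 2.31, gamma_ub = 1.257)),
  H2O = list(no_ub = list(k_stretch = c(14.95, 14.95), gamma = c(1.276, 1.276),
                          k_bend = 4.26),
             ub = list(k_stretch = c(14.87, 14.87), gamma = c(1.276, 1.276),
                       k_bend = 4.11, k_ub = 0.10, gamma_ub = 1.129)),
  HNO = list(no_ub = list(k_stretch = c(8.97, 22.34), gamma = c(1.246, 1.251),
                          k_bend = 8.07),
             ub = list(k_stretch = c(8.55, 21.89), gamma = c(1.246, 1.251),
                       k_bend = 6.23, k_ub = 0.61, gamma_ub = 1.212)),
  SO2 = list(no_ub = list(k_stretch = c(20.34, 20.34), gamma = c(1.079, 1.079),
                          k_bend = 11.60),
             ub = list(k_stretch = c(19.90, 19.90), gamma = c(1.079, 1.079),
                       k_bend = 9.71, k_ub = 0.46, gamma_ub = 1.151)))

#' Bundled example flexibility models
#'
#' Manz-stretch + regularized-bend flexibility models for the bundled
#' triatomics, with quantum-chemistry-derived force constants and stretch
#' exponents, optionally including the Urey-Bradley term between the two
#' outer atoms.
#'
#' @param name \code{"CO2"}, \code{"H2O"}, \code{"HNO"}, or \code{"SO2"}.
#' @param urey_bradley include the Urey-Bradley variant of the parameter
#'   set.
#' @return a \code{flexibility_model} whose atom indices match
#'   \code{\link{example_molecule}} (outer, vertex, outer ordering).
#' @export
example_flexibility_model <- function(name, urey_bradley = FALSE) {
  name <- toupper(name)
  p <- .example_flex_params[[name]]
  if (is.null(p)) stop("no bundled flexibility parameters for ", name)
  p <- if (urey_bradley) p$ub else p$no_ub
  sys <- example_molecule(name)
  ev <- ffft_constants$hartree_per_ev
  d1 <- dist_pair(sys$ref_coords, 1, 2)
  d2 <- dist_pair(sys$ref_coords, 3, 2)
  teq <- angle_from_coords(sys$ref_coords, 1, 2, 3)
  if (abs(teq - pi) < 1e-8) teq <- pi
  terms <- list(
    flex_term("stretch_manz", c(1, 2), d1, p$k_stretch[1] * ev,
              exponent = p$gamma[1]),
    flex_term("stretch_manz", c(3, 2), d2, p$k_stretch[2] * ev,
              exponent = p$gamma[2]),
    flex_term("bend_new", c(1, 2, 3), teq, p$k_bend * ev))
  if (urey_bradley)
    terms[[4]] <- flex_term("urey_bradley", c(1, 3),
                            dist_pair(sys$ref_coords, 1, 3),
                            p$k_ub * ev, exponent = p$gamma_ub,
                            ub_form = "manz")
  flexibility_model(terms, paste0(name, "_ground_state"))
}
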