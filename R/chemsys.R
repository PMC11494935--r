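## Geometry, bond graph, clusters, exclusion sets, internal coordinates.
## Atom indices are 1-based everywhere (R convention and chemistry file
## convention coincide). Coordinates are stored internally in bohr.

#' Construct a molecular system
#'
#' Holds element symbols, Cartesian coordinates, and (optionally) a
#' reference equilibrium geometry. Coordinates are converted to and stored
#' in bohr regardless of the input unit.
#'
#' @param elements character vector of element symbols, one per atom.
#' @param coords numeric matrix (n x 3) of Cartesian positions.
#' @param ref_coords optional numeric matrix (n x 3) of equilibrium
#'   positions in the same unit as \code{coords}.
#' @param units unit of the input coordinates, \code{"angstrom"} or
#'   \code{"bohr"}.
#' @return object of class \code{molecular_system} with coordinates in bohr.
#' @examples
#' co <- molecular_system(c("C", "O"), rbind(c(0, 0, 0), c(1.128, 0, 0)))
#' co$n_atoms
#' @export
molecular_system <- function(elements, coords, ref_coords = NULL,
                             units = c("angstrom", "bohr")) {
  units <- match.arg(units)
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3)
    stop("coords must be a numeric n x 3 matrix")
  if (length(elements) != nrow(coords))
    stop("elements and coords describe different numbers of atoms")
  if (nrow(coords) < 1) stop("a system needs at least one atom")
  elements <- normalize_element(elements)
  if (units == "angstrom") coords <- coords * ffft_constants$bohr_per_angstrom
  dmat <- as.matrix(stats::dist(coords))
  diag(dmat) <- Inf
  if (any(dmat < 1e-8))
    stop("two atoms share identical coordinates")
  if (!is.null(ref_coords)) {
    ref_coords <- as.matrix(ref_coords)
    if (!identical(dim(ref_coords), dim(coords)))
      stop("ref_coords must have the same shape as coords")
    if (units == "angstrom")
      ref_coords <- ref_coords * ffft_constants$bohr_per_angstrom
  }
  structure(list(elements = elements, coords = coords,
                 ref_coords = ref_coords, n_atoms = nrow(coords)),
            class = "molecular_system")
}

normalize_element <- function(x) {
  x <- trimws(as.character(x))
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("molecular_system: %d atoms (%s)%s\n", x$n_atoms,
              paste(x$elements, collapse = " "),
              if (is.null(x$ref_coords)) "" else ", reference geometry attached"))
  invisible(x)
}

dist_pair <- function(coords, i, j) {
  sqrt(sum((coords[i, ] - coords[j, ])^2))
}

#' Detect bonds from atom-typing radii
#'
#' Two atoms are bonded iff their distance does not exceed the sum of their
#' per-element atom-typing radii (inclusive at equality).
#'
#' @param system a \code{molecular_system}.
#' @param radii named numeric vector of per-element atom-typing radii.
#' @param units unit of \code{radii} (default angstrom).
#' @param use_ref logical; measure distances on the reference geometry when
#'   present (default uses current coordinates).
#' @return integer matrix with columns \code{i}, \code{j} (i < j), one row
#'   per bond; zero rows when nothing is bonded.
#' @export
detect_bonds <- function(system, radii, units = c("angstrom", "bohr"),
                         use_ref = FALSE) {
  units <- match.arg(units)
  stopifnot(inherits(system, "molecular_system"))
  missing_el <- setdiff(unique(system$elements), names(radii))
  if (length(missing_el) > 0)
    stop("no atom-typing radius supplied for element(s): ",
         paste(missing_el, collapse = ", "))
  r <- radii[system$elements]
  if (units == "angstrom") r <- r * ffft_constants$bohr_per_angstrom
  coords <- if (use_ref && !is.null(system$ref_coords)) system$ref_coords else system$coords
  n <- system$n_atoms
  out <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  if (n < 2) return(out)
  pairs <- utils::combn(n, 2)
  d <- sqrt(rowSums((coords[pairs[1, ], , drop = FALSE] -
                     coords[pairs[2, ], , drop = FALSE])^2))
  keep <- d <= (r[pairs[1, ]] + r[pairs[2, ]])
  rbind(out, cbind(i = pairs[1, keep], j = pairs[2, keep]))
}

#' Partition atoms into bonded clusters
#'
#' Connected components of the bond graph; atoms with no bonds form
#' singleton clusters.
#'
#' @param bonds two-column integer matrix of bonds.
#' @param n_atoms total number of atoms.
#' @return list with \code{membership} (integer vector of cluster ids,
#'   numbered by smallest member atom) and \code{clusters} (list of sorted
#'   atom-index vectors).
#' @export
cluster_partition <- function(bonds, n_atoms) {
  bonds <- matrix(as.integer(as.matrix(bonds)), ncol = 2)
  if (nrow(bonds) > 0 && max(bonds) > n_atoms)
    stop("bond index exceeds n_atoms")
  parent <- seq_len(n_atoms)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  if (nrow(bonds) > 0) for (b in seq_len(nrow(bonds))) {
    ra <- find(bonds[b, 1]); rb <- find(bonds[b, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n_atoms), find, integer(1))
  ids <- match(roots, sort(unique(roots)))
  list(membership = ids,
       clusters = unname(split(seq_len(n_atoms), ids)))
}

#' Per-atom exclusion sets from graph distance
#'
#' \code{excl(A)} contains all atoms at bond-graph (BFS) distance 0 through
#' \code{max_separation} from A; A itself is always a member.
#'
#' @param bonds two-column integer bond matrix.
#' @param n_atoms number of atoms.
#' @param max_separation 2 (exclude 1-2 and 1-3 neighbors) or 3 (also 1-4).
#' @return list of sorted integer vectors, one per atom.
#' @export
exclusion_sets <- function(bonds, n_atoms, max_separation = 2) {
  if (!max_separation %in% c(2, 3))
    stop("max_separation must be 2 or 3")
  adj <- vector("list", n_atoms)
  bonds <- as.matrix(bonds)
  if (nrow(bonds) > 0) for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  lapply(seq_len(n_atoms), function(a) {
    dist <- rep(Inf, n_atoms); dist[a] <- 0
    frontier <- a
    for (k in seq_len(max_separation)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.infinite(dist[nxt])]
      if (length(nxt) == 0) break
      dist[nxt] <- k
      frontier <- nxt
    }
    sort(which(is.finite(dist)))
  })
}

#' Bond angle at atom B
#'
#' Angle A-B-C in radians, with the raw cosine clamped to [-1, 1] so that
#' accumulated roundoff on (near-)collinear triads can never produce NaN.
#'
#' @param system a \code{molecular_system}.
#' @param A,B,C distinct atom indices; B is the vertex.
#' @param use_ref measure on the reference geometry.
#' @return angle in radians, in (0, pi].
#' @export
bond_angle <- function(system, A, B, C, use_ref = FALSE) {
  coords <- if (use_ref && !is.null(system$ref_coords)) system$ref_coords else system$coords
  if (length(unique(c(A, B, C))) != 3) stop("A, B, C must be distinct atoms")
  angle_from_coords(coords, A, B, C)
}

angle_from_coords <- function(coords, A, B, C) {
  u <- coords[A, ] - coords[B, ]
  v <- coords[C, ] - coords[B, ]
  du <- sqrt(sum(u^2)); dv <- sqrt(sum(v^2))
  if (du < 1e-10 || dv < 1e-10)
    stop("degenerate geometry: coincident atoms in angle ",
         A, "-", B, "-", C)
  cosang <- min(1, max(-1, sum(u * v) / (du * dv)))
  acos(cosang)
}

#' Record equilibrium internal coordinates from the reference geometry
#'
#' Every bond gets its equilibrium length, every bonded angle A-B-C its
#' equilibrium angle, and (optionally) each angle's outer pair its
#' equilibrium Urey-Bradley distance, all measured on the reference
#' geometry. Reference triads collinear to within 1e-8 rad are stored as
#' exactly pi; no other rounding is applied.
#'
#' @param system a \code{molecular_system} with \code{ref_coords}.
#' @param bonds two-column bond matrix.
#' @param include_urey_bradley also record outer-pair distances.
#' @return data frame with columns \code{kind} (\code{"bond"},
#'   \code{"angle"}, \code{"urey_bradley"}), \code{a}, \code{b}, \code{c}
#'   (atom indices; \code{c} is NA for two-atom coordinates), and \code{eq}
#'   (bohr for distances, radians for angles).
#' @export
snapshot_equilibrium_internals <- function(system, bonds,
                                           include_urey_bradley = TRUE) {
  if (is.null(system$ref_coords))
    stop("the new scheme requires a reference (equilibrium) geometry: ",
         "ref_coords is missing")
  ref <- system$ref_coords
  bonds <- as.matrix(bonds)
  rows <- list()
  if (nrow(bonds) > 0) for (b in seq_len(nrow(bonds))) {
    rows[[length(rows) + 1]] <- data.frame(
      kind = "bond", a = bonds[b, 1], b = bonds[b, 2], c = NA_integer_,
      eq = dist_pair(ref, bonds[b, 1], bonds[b, 2]))
  }
  angles <- enumerate_angles(bonds, system$n_atoms)
  if (nrow(angles) > 0) for (t in seq_len(nrow(angles))) {
    A <- angles[t, 1]; B <- angles[t, 2]; C <- angles[t, 3]
    th <- angle_from_coords(ref, A, B, C)
    if (abs(th - pi) < 1e-8) th <- pi
    rows[[length(rows) + 1]] <- data.frame(
      kind = "angle", a = A, b = B, c = C, eq = th)
    if (include_urey_bradley)
      rows[[length(rows) + 1]] <- data.frame(
        kind = "urey_bradley", a = A, b = C, c = NA_integer_,
        eq = dist_pair(ref, A, C))
  }
  if (length(rows) == 0)
    return(data.frame(kind = character(0), a = integer(0), b = integer(0),
                      c = integer(0), eq = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## All A-B-C triads with A-B and B-C bonded, A < C to avoid duplicates.
enumerate_angles <- function(bonds, n_atoms) {
  adj <- vector("list", n_atoms)
  bonds <- as.matrix(bonds)
  if (nrow(bonds) > 0) for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  out <- matrix(integer(0), ncol = 3)
  for (B in seq_len(n_atoms)) {
    nb <- sort(adj[[B]])
    if (length(nb) >= 2) {
      pr <- utils::combn(nb, 2)
      out <- rbind(out, cbind(pr[1, ], B, pr[2, ]))
    }
  }
  colnames(out) <- c("a", "b", "c")
  out
}

#' Build a bonded topology
#'
#' Bundles the bond list, cluster partition, exclusion sets, and (when a
#' reference geometry is present) equilibrium internal coordinates.
#'
#' @inheritParams detect_bonds
#' @param max_separation exclusion policy, 2 or 3.
#' @param include_urey_bradley record Urey-Bradley equilibrium distances.
#' @return object of class \code{bonded_topology}.
#' @export
bonded_topology <- function(system, radii, units = c("angstrom", "bohr"),
                            max_separation = 2, include_urey_bradley = TRUE) {
  bonds <- detect_bonds(system, radii, units = units, use_ref = TRUE)
  part <- cluster_partition(bonds, system$n_atoms)
  internals <- if (!is.null(system$ref_coords))
    snapshot_equilibrium_internals(system, bonds, include_urey_bradley)
  else NULL
  structure(list(bonds = bonds, clusters = part$clusters,
                 membership = part$membership,
                 exclusion = exclusion_sets(bonds, system$n_atoms, max_separation),
                 max_separation = max_separation,
                 internal_coords = internals),
            class = "bonded_topology")
}

#' Write a topology as plain text
#'
#' Lists bonds, clusters, and exclusion sets with 1-based atom indices.
#'
#' @param topology a \code{bonded_topology}.
#' @param path file path; when \code{NULL} the lines are returned invisibly.
#' @return character vector of lines, invisibly.
#' @export
write_topology <- function(topology, path = NULL) {
  lines <- c("# ffft topology", "[bonds]")
  if (nrow(topology$bonds) > 0)
    lines <- c(lines, apply(topology$bonds, 1, paste, collapse = " "))
  lines <- c(lines, "[clusters]",
             vapply(topology$clusters, paste, character(1), collapse = " "),
             "[exclusions]",
             vapply(seq_along(topology$exclusion), function(a)
               paste(a, ":", paste(topology$exclusion[[a]], collapse = " ")),
               character(1)))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
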