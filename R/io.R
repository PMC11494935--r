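## XYZ reading/writing. Standard dialect: atom count line, comment line,
## then "element x y z" per atom, coordinates in angstrom.

#' Read an XYZ geometry file
#'
#' @param path path to an XYZ file (angstrom coordinates).
#' @param ref_path optional second XYZ file giving the reference geometry.
#' @return a \code{molecular_system}.
#' @export
read_xyz <- function(path, ref_path = NULL) {
  if (!file.exists(path)) stop("cannot open XYZ file: ", path)
  parsed <- parse_xyz_lines(readLines(path), path)
  ref <- NULL
  if (!is.null(ref_path)) {
    pr <- parse_xyz_lines(readLines(ref_path), ref_path)
    if (!identical(pr$elements, parsed$elements))
      stop("reference geometry in ", ref_path,
           " lists different elements than ", path)
    ref <- pr$coords
  }
  molecular_system(parsed$elements, parsed$coords, ref_coords = ref,
                   units = "angstrom")
}

parse_xyz_lines <- function(lines, label = "<xyz>") {
  if (length(lines) < 2) stop("malformed XYZ in ", label, ": too few lines")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1)
    stop("malformed XYZ in ", label, ": line 1 is not an atom count")
  if (length(lines) < n + 2)
    stop("malformed XYZ in ", label, ": expected ", n,
         " atom lines, file ends at line ", length(lines))
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    tok <- strsplit(trimws(lines[k + 2]), "[[:space:]]+")[[1]]
    if (length(tok) < 4 || anyNA(suppressWarnings(as.numeric(tok[2:4]))))
      stop("malformed XYZ in ", label, ": cannot parse atom line ", k + 2)
    elements[k] <- tok[1]
    coords[k, ] <- as.numeric(tok[2:4])
  }
  list(elements = normalize_element(elements), coords = coords)
}

#' Write a geometry as XYZ
#'
#' @param system a \code{molecular_system} (written in angstrom).
#' @param path output file.
#' @param comment comment line.
#' @param use_ref write the reference geometry instead of the current one.
#' @export
write_xyz <- function(system, path, comment = "written by ffft",
                      use_ref = FALSE) {
  coords <- if (use_ref) system$ref_coords else system$coords
  if (is.null(coords)) stop("requested geometry is absent")
  ang <- coords * ffft_constants$angstrom_per_bohr
  lines <- c(as.character(system$n_atoms), comment,
             sprintf("%-3s %16.10f %16.10f %16.10f",
                     system$elements, ang[, 1], ang[, 2], ang[, 3]))
  writeLines(lines, path)
  invisible(path)
}
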