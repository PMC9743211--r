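#' Toy force field for desk-scale bead-spring molecules
#'
#' A minimal classical potential used both by the synthetic trajectory
#' generator and as the scalar energy model behind the energy
#' regularization term of the training loss:
#' harmonic bonds `0.5 k_b (r - r0)^2`, harmonic angles
#' `0.5 k_a (theta - theta0)^2`, a symmetric torsional double well
#' `0.5 * barrier * (1 - cos 2 phi)` (minima at 0 and 180 degrees,
#' barrier height `barrier` at +-90 degrees), and 12-6 Lennard-Jones
#' pairs `4 eps ((sigma/r)^12 - (sigma/r)^6)`.
#'
#' Real-system energies (e.g. from a biomolecular force field engine)
#' plug in behind the same scalar-valued interface; see the `energy_fn`
#' argument of [train_model()].
#'
#' @param bonds matrix/data.frame with columns i, j, k_b (kJ/mol/A^2),
#'   r0 (A); may be `NULL`.
#' @param angles columns i, j, k, k_a (kJ/mol/rad^2), theta0 (rad).
#' @param dihedrals columns i, j, k, l, barrier (kJ/mol).
#' @param lj columns i, j, eps (kJ/mol), sigma (A).
#' @return Object of class `toy_forcefield`.
#' @examples
#' ff <- toy_forcefield(bonds = cbind(1, 2, 100, 1.5))
#' potential_energy(ff, frame(rbind(c(0, 0, 0), c(2, 0, 0))))
#' @export
toy_forcefield <- function(bonds = NULL, angles = NULL, dihedrals = NULL,
                           lj = NULL) {
  as_mat <- function(x, nc, what) {
    if (is.null(x) || NROW(x) == 0L) return(NULL)
    x <- as.matrix(x)
    if (ncol(x) != nc)
      stop("`", what, "` needs ", nc, " columns", call. = FALSE)
    storage.mode(x) <- "double"
    unname(x)
  }
  ff <- structure(list(bonds = as_mat(bonds, 4L, "bonds"),
                       angles = as_mat(angles, 5L, "angles"),
                       dihedrals = as_mat(dihedrals, 5L, "dihedrals"),
                       lj = as_mat(lj, 4L, "lj")),
                  class = "toy_forcefield")
  const_cols <- c(bonds = 3L, angles = 4L, dihedrals = 5L, lj = 3L)
  for (term in names(const_cols)) {
    m <- ff[[term]]
    if (!is.null(m) && any(m[, const_cols[[term]]] < 0))
      stop("negative force constant in `", term, "`", call. = FALSE)
  }
  ff
}

#' @export
print.toy_forcefield <- function(x, ...) {
  cnt <- function(m) if (is.null(m)) 0L else nrow(m)
  cat("<toy_forcefield> ", cnt(x$bonds), " bonds, ", cnt(x$angles),
      " angles, ", cnt(x$dihedrals), " dihedrals, ", cnt(x$lj),
      " LJ pairs\n", sep = "")
  invisible(x)
}

#' Scalar potential energy of a configuration
#'
#' @param ff a [toy_forcefield()].
#' @param frm a [frame()] or M x 3 coordinate matrix (A).
#' @return Potential energy in kJ/mol.
#' @export
potential_energy <- function(ff, frm) {
  stopifnot(inherits(ff, "toy_forcefield"))
  X <- .coords(frm)
  .ff_energy_cpp(X, unclass(ff))
}

#' Forces (negative energy gradient) of a configuration
#'
#' @inheritParams potential_energy
#' @return M x 3 matrix of forces in kJ/mol/A.
#' @export
forces <- function(ff, frm) {
  stopifnot(inherits(ff, "toy_forcefield"))
  X <- .coords(frm)
  .ff_forces_cpp(X, unclass(ff))
}

#' Read or write a toy force field as a YAML document
#'
#' @param ff a [toy_forcefield()].
#' @param path file path.
#' @return `path` invisibly; `read_forcefield()` returns the
#'   [toy_forcefield()].
#' @export
write_forcefield <- function(ff, path) {
  stopifnot(inherits(ff, "toy_forcefield"))
  to_rows <- function(m) if (is.null(m)) NULL else apply(m, 1L, as.list)
  yaml::write_yaml(list(bonds = to_rows(ff$bonds),
                        angles = to_rows(ff$angles),
                        dihedrals = to_rows(ff$dihedrals),
                        lj = to_rows(ff$lj)),
                   path)
  invisible(path)
}

#' @rdname write_forcefield
#' @export
read_forcefield <- function(path) {
  doc <- yaml::read_yaml(path)
  from_rows <- function(r) {
    if (is.null(r) || !length(r)) return(NULL)
    do.call(rbind, lapply(r, function(row) unlist(row)))
  }
  toy_forcefield(bonds = from_rows(doc$bonds),
                 angles = from_rows(doc$angles),
                 dihedrals = from_rows(doc$dihedrals),
                 lj = from_rows(doc$lj))
}
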