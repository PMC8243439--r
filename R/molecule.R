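# Molecule container: one row per molecule in a tibble, with nested atom and
# bond tables. Atom indices are 1-based everywhere inside the package.

#' Build a molecule table
#'
#' Assemble molecules into the package's standard tidy container: a tibble
#' with one row per molecule and nested `atoms` / `bonds` tables. All
#' functions in sqecharge accept and return this shape.
#'
#' @param name Character vector of molecule names.
#' @param atoms List of tibbles, one per molecule, with columns `element`
#'   (symbol), `x`, `y`, `z` (Cartesian coordinates in Angstrom) and
#'   `formal_charge` (integer).
#' @param bonds List of tibbles, one per molecule, with columns `i`, `j`
#'   (1-based atom indices) and `order` (integer bond order, 1 to 3).
#' @param validate Check structural invariants (default `TRUE`).
#'
#' @return A tibble with columns `name`, `atoms`, `bonds`, `total_charge`,
#'   `n_atoms`, `n_bonds`.
#' @export
#' @examples
#' water <- molecule_table(
#'   name = "water",
#'   atoms = list(tibble::tibble(
#'     element = c("O", "H", "H"),
#'     x = c(0, 0.96, -0.24), y = c(0, 0, 0.93), z = 0,
#'     formal_charge = 0L
#'   )),
#'   bonds = list(tibble::tibble(i = c(1L, 1L), j = c(2L, 3L), order = 1L))
#' )
molecule_table <- function(name, atoms, bonds, validate = TRUE) {
  stopifnot(length(name) == length(atoms), length(atoms) == length(bonds))
  atoms <- purrr::map(atoms, function(a) {
    a <- as_tibble(a)
    if (is.null(a$formal_charge)) a$formal_charge <- 0L
    a$formal_charge <- as.integer(a$formal_charge)
    a[c("element", "x", "y", "z", "formal_charge")]
  })
  bonds <- purrr::map(bonds, function(b) {
    b <- as_tibble(b)
    if (nrow(b) == 0) {
      return(tibble(i = integer(), j = integer(), order = integer()))
    }
    tibble(i = as.integer(b$i), j = as.integer(b$j),
           order = as.integer(b$order))
  })
  out <- tibble(
    name = as.character(name),
    atoms = atoms,
    bonds = bonds,
    total_charge = purrr::map_int(atoms, ~ sum(.x$formal_charge)),
    n_atoms = purrr::map_int(atoms, nrow),
    n_bonds = purrr::map_int(bonds, nrow)
  )
  if (validate) {
    for (k in seq_len(nrow(out))) {
      validate_molecule(out$atoms[[k]], out$bonds[[k]], out$name[k])
    }
  }
  out
}

validate_molecule <- function(atoms, bonds, name = "<molecule>") {
  n <- nrow(atoms)
  if (n < 1) abort(sprintf("molecule '%s' has no atoms", name))
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    abort(sprintf("molecule '%s' has non-finite coordinates", name))
  }
  if (nrow(bonds) > 0) {
    if (any(bonds$i == bonds$j)) {
      abort(sprintf("molecule '%s': bond with identical endpoints", name))
    }
    idx <- c(bonds$i, bonds$j)
    if (any(idx < 1L | idx > n)) {
      abort(sprintf("molecule '%s': bond atom index out of range", name))
    }
    if (!all(bonds$order %in% 1:3)) {
      abort(sprintf("molecule '%s': bond order outside 1..3", name))
    }
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) {
      abort(sprintf("molecule '%s': duplicate bond", name))
    }
    d <- sqrt((atoms$x[bonds$i] - atoms$x[bonds$j])^2 +
              (atoms$y[bonds$i] - atoms$y[bonds$j])^2 +
              (atoms$z[bonds$i] - atoms$z[bonds$j])^2)
    if (any(d <= 0)) {
      abort(sprintf("molecule '%s': bonded atoms coincide", name))
    }
  }
  invisible(TRUE)
}

# Accept a one-row tibble slice or a plain list carrying atoms/bonds/name.
as_single_molecule <- function(mol) {
  if (is_tibble(mol)) {
    if (nrow(mol) != 1) abort("expected exactly one molecule")
    list(name = mol$name[[1]], atoms = mol$atoms[[1]], bonds = mol$bonds[[1]],
         total_charge = mol$total_charge[[1]])
  } else {
    atoms <- if (is_tibble(mol$atoms)) mol$atoms else mol$atoms[[1]]
    bonds <- if (is_tibble(mol$bonds)) mol$bonds else mol$bonds[[1]]
    list(name = mol$name[[1]], atoms = atoms, bonds = bonds,
         total_charge = sum(atoms$formal_charge))
  }
}

# Pairwise distance matrix in Angstrom.
distance_matrix <- function(atoms) {
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  D <- as.matrix(stats::dist(xyz))
  dimnames(D) <- NULL
  D
}
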