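# Linear-system solvers for the six empirical charge methods.
#
# All methods minimise a quadratic charge energy built from per-type
# electronegativities chi, per-type hardnesses eta on the diagonal of the
# hardness matrix H, and the plain Coulomb kernel 1/r_ij (r in Angstrom)
# off the diagonal; any Coulomb prefactor is absorbed into the fitted
# parameters.
#
# EEM / QEq / EQeq equalise electronegativity over atoms under a total-
# charge constraint (augmented/Lagrange system). EQeq expands the atomic
# energies about the formal-charge reference state, which shifts the
# right-hand side by eta * q0.
#
# SQE moves the variables to bonds: split-charges q_sp solve
#   (T H T' + diag(kappa)) q_sp = T chi,        q = T' q_sp
# SQE+q0 seeds the system with formal charges q0:
#   (T H T' + diag(kappa)) q_sp = T (chi - H q0 + eta * q0),  q = T' q_sp + q0
# SQE+qp replaces q0 by per-type fitted initial charges, normalised so
# their sum equals the total molecular charge Q.

RCOND_LIMIT <- 1e-12

#' Bond-atom incidence matrix
#'
#' One row per bond with +1 at the lower-indexed endpoint and -1 at the
#' higher-indexed endpoint; atomic charges are recovered from split-charges
#' as `q = t(T) %*% q_sp`.
#'
#' @param molecule A one-row molecule table (or equivalent list).
#' @return A numeric matrix of shape bonds x atoms.
#' @export
incidence_matrix <- function(molecule) {
  m <- as_single_molecule(molecule)
  n <- nrow(m$atoms); b <- nrow(m$bonds)
  Tm <- matrix(0, nrow = b, ncol = n)
  if (b > 0) {
    lo <- pmin(m$bonds$i, m$bonds$j)
    hi <- pmax(m$bonds$i, m$bonds$j)
    Tm[cbind(seq_len(b), lo)] <- 1
    Tm[cbind(seq_len(b), hi)] <- -1
  }
  Tm
}

#' Hardness matrix
#'
#' `H[i, i]` is the hardness eta of atom i's type; `H[i, j]` is `1 / r_ij`
#' with `r_ij` the interatomic distance in Angstrom.
#'
#' @param molecule A one-row molecule table (or equivalent list).
#' @param params A `charge_params` object supplying per-type eta (its
#'   classifier determines the atom types).
#' @return A symmetric numeric matrix of shape atoms x atoms.
#' @export
hardness_matrix <- function(molecule, params) {
  m <- as_single_molecule(molecule)
  types <- atom_type_labels(m$atoms, m$bonds, params$classifier)
  lk <- param_atom_lookup(params)
  require_types(types, lk$eta, "atom")
  hmatrix_from_parts(inv_dist_matrix(m$atoms, m$name),
                     unname(lk$eta[types]))
}

inv_dist_matrix <- function(atoms, name = "<molecule>") {
  n <- nrow(atoms)
  if (n == 1) return(matrix(0, 1, 1))
  D <- distance_matrix(atoms)
  off <- D[upper.tri(D)]
  if (any(off == 0)) {
    abort(sprintf("molecule '%s': coincident atoms (zero distance)", name),
          class = "sqecharge_degenerate_geometry")
  }
  iD <- 1 / D
  diag(iD) <- 0
  iD
}

hmatrix_from_parts <- function(inv_dist, eta) {
  H <- inv_dist
  diag(H) <- eta
  H
}

#' Normalise per-type initial charges to the total molecular charge
#'
#' Shifts every entry by the same constant so that the vector sums to `Q`:
#' `qp - (sum(qp) - Q) / n`.
#'
#' @param qp Numeric vector of raw per-atom initial charges.
#' @param Q Total molecular charge.
#' @param n Number of atoms (defaults to `length(qp)`).
#' @return The shifted vector, summing to `Q`.
#' @export
normalize_qp <- function(qp, Q, n = length(qp)) {
  stopifnot(n >= 1)
  qp - (sum(qp) - Q) / n
}

# Pre-resolved per-molecule data reused across many solver calls during
# fitting: types, labels, inverse-distance matrix, incidence matrix.
compile_molecule <- function(molecule, classifier) {
  m <- as_single_molecule(molecule)
  types <- atom_type_labels(m$atoms, m$bonds, classifier)
  bt <- bond_type_table(m$bonds, types)
  list(name = m$name, n = nrow(m$atoms),
       atom_type = types,
       bond_lab = if (nrow(bt) > 0) bond_label(bt$type_a, bt$type_b, bt$order)
                  else character(),
       inv_dist = inv_dist_matrix(m$atoms, m$name),
       Tm = incidence_matrix(m),
       q0 = as.numeric(m$atoms$formal_charge),
       Q = m$total_charge)
}

compile_dataset <- function(molecules, classifier) {
  purrr::map(seq_len(nrow(molecules)),
             ~ compile_molecule(molecules[.x, ], classifier))
}

solve_guarded <- function(A, b, name) {
  if (nrow(A) == 0) return(numeric(0))
  if (rcond(A) < RCOND_LIMIT) {
    abort(sprintf("molecule '%s': charge system is singular or ill-conditioned",
                  name),
          class = "sqecharge_numerical_failure")
  }
  drop(solve(A, b))
}

# Core solve on a compiled molecule. Returns list(q, q_sp).
solve_compiled <- function(cm, method, lk_atom, lk_bond = NULL) {
  require_types(cm$atom_type, lk_atom$chi, "atom")
  chi <- unname(lk_atom$chi[cm$atom_type])
  eta <- unname(lk_atom$eta[cm$atom_type])
  H <- hmatrix_from_parts(cm$inv_dist, eta)

  if (method %in% SQE_METHODS) {
    q0 <- switch(method,
      "sqe" = rep(0, cm$n),
      "sqe+q0" = cm$q0,
      "sqe+qp" = {
        require_types(cm$atom_type, lk_atom$qp, "atom (qp)")
        normalize_qp(unname(lk_atom$qp[cm$atom_type]), cm$Q)
      })
    if (length(cm$bond_lab) == 0) {
      return(list(q = q0, q_sp = numeric(0)))
    }
    require_types(cm$bond_lab, lk_bond, "bond")
    kappa <- unname(lk_bond[cm$bond_lab])
    Tm <- cm$Tm
    A <- Tm %*% H %*% t(Tm)
    diag(A) <- diag(A) + kappa
    rhs <- if (method == "sqe") drop(Tm %*% chi)
           else drop(Tm %*% (chi - H %*% q0 + eta * q0))
    q_sp <- solve_guarded(A, rhs, cm$name)
    list(q = drop(crossprod(Tm, q_sp)) + q0, q_sp = q_sp)
  } else {
    # equalization with total-charge constraint (Lagrange system)
    rhs_top <- switch(method,
      "eem" = -chi,
      "qeq" = -chi,
      "eqeq" = -chi + eta * cm$q0)
    A <- rbind(cbind(H, 1), c(rep(1, cm$n), 0))
    sol <- solve_guarded(A, c(rhs_top, cm$Q), cm$name)
    list(q = sol[seq_len(cm$n)], q_sp = NULL)
  }
}

solve_one <- function(molecule, params, method = params$method) {
  method <- match.arg(method, ALL_METHODS)
  cm <- compile_molecule(molecule, params$classifier)
  lk_atom <- param_atom_lookup(params)
  lk_bond <- if (method %in% SQE_METHODS) param_bond_lookup(params)
  res <- solve_compiled(cm, method, lk_atom, lk_bond)
  structure(list(name = cm$name, q = res$q, q_sp = res$q_sp,
                 method = method, atom_type = cm$atom_type),
            class = "charge_result")
}

#' @export
print.charge_result <- function(x, ...) {
  cat(sprintf("<charge_result> %s (%s): %d atoms, sum(q) = %.6f\n",
              x$name, x$method, length(x$q), sum(x$q)))
  invisible(x)
}

#' Solve one molecule with a specific method
#'
#' Single-molecule entry points for each empirical method; for whole
#' datasets use [compute_charges()]. The SQE family returns the per-bond
#' split-charges alongside the atomic charges.
#'
#' @param molecule A one-row molecule table (or equivalent list).
#' @param params A `charge_params` object for the matching method family.
#' @return A `charge_result`: list with `q` (atomic charges), `q_sp`
#'   (split-charges, SQE family only), `method`, `atom_type`.
#' @name solve_method
NULL

#' @rdname solve_method
#' @export
solve_sqe <- function(molecule, params) solve_one(molecule, params, "sqe")

#' @rdname solve_method
#' @export
solve_sqe_q0 <- function(molecule, params) solve_one(molecule, params, "sqe+q0")

#' @rdname solve_method
#' @export
solve_sqe_qp <- function(molecule, params) solve_one(molecule, params, "sqe+qp")

#' @rdname solve_method
#' @export
solve_eem <- function(molecule, params) solve_one(molecule, params, "eem")

#' @rdname solve_method
#' @export
solve_qeq <- function(molecule, params) solve_one(molecule, params, "qeq")

#' @rdname solve_method
#' @export
solve_eqeq <- function(molecule, params) solve_one(molecule, params, "eqeq")

#' Compute charges for a dataset
#'
#' Applies the method of `params` (or an explicit override) to every
#' molecule and returns a tidy per-atom table.
#'
#' @param molecules A molecule table.
#' @param params A `charge_params` object.
#' @param method Optional method override (must share the parameter
#'   requirements of `params$method`).
#' @return A tibble with columns `molecule`, `atom` (1-based index),
#'   `element`, `atom_type`, `charge`. Split-charges for SQE-family
#'   methods are attached as the `"split_charges"` attribute (a named list
#'   of per-bond vectors).
#' @export
compute_charges <- function(molecules, params, method = params$method) {
  method <- match.arg(method, ALL_METHODS)
  cms <- compile_dataset(molecules, params$classifier)
  lk_atom <- param_atom_lookup(params)
  lk_bond <- if (method %in% SQE_METHODS) param_bond_lookup(params)
  rows <- vector("list", length(cms))
  qsp <- list()
  for (k in seq_along(cms)) {
    res <- solve_compiled(cms[[k]], method, lk_atom, lk_bond)
    rows[[k]] <- tibble(molecule = cms[[k]]$name,
                        atom = seq_len(cms[[k]]$n),
                        element = molecules$atoms[[k]]$element,
                        atom_type = cms[[k]]$atom_type,
                        charge = res$q)
    if (!is.null(res$q_sp)) qsp[[cms[[k]]$name]] <- res$q_sp
  }
  out <- bind_rows(rows)
  if (length(qsp) > 0) attr(out, "split_charges") <- qsp
  out
}
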