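# Parameter sets: per-atom-type electronegativity (chi), hardness (eta),
# optionally an initial charge (qp, SQE+qp only), and per-bond-type bond
# hardness (kappa, SQE family only).

SQE_METHODS <- c("sqe", "sqe+q0", "sqe+qp")
EE_METHODS <- c("eem", "qeq", "eqeq")
ALL_METHODS <- c(EE_METHODS, SQE_METHODS)

#' Create a parameter set
#'
#' @param method One of `"eem"`, `"qeq"`, `"eqeq"`, `"sqe"`, `"sqe+q0"`,
#'   `"sqe+qp"`.
#' @param classifier Atom-type classifier the parameters were fitted for.
#' @param atoms Tibble with columns `type`, `chi`, `eta` and, for
#'   `"sqe+qp"`, `qp`.
#' @param bonds Tibble with columns `type_a`, `type_b`, `order`, `kappa`;
#'   required for the SQE family, ignored otherwise.
#' @param metadata Named list of free-form provenance (source, date,
#'   dataset tag).
#' @return A `charge_params` object.
#' @export
charge_params <- function(method, classifier, atoms, bonds = NULL,
                          metadata = list()) {
  method <- match.arg(method, ALL_METHODS)
  classifier <- match.arg(classifier, c("plain", "hbo", "ba"))
  atoms <- as_tibble(atoms)
  stopifnot(all(c("type", "chi", "eta") %in% names(atoms)))
  if (method == "sqe+qp" && is.null(atoms[["qp"]])) {
    abort("method 'sqe+qp' requires a qp column in atoms")
  }
  if (!all(is.finite(atoms$chi)) || !all(is.finite(atoms$eta))) {
    abort("chi and eta must be finite")
  }
  if (any(atoms$eta <= 0)) abort("eta values must be positive")
  if (method %in% SQE_METHODS) {
    if (is.null(bonds)) abort(sprintf("method '%s' requires bond parameters",
                                      method))
    bonds <- as_tibble(bonds)
    stopifnot(all(c("type_a", "type_b", "order", "kappa") %in% names(bonds)))
    if (!all(is.finite(bonds$kappa))) abort("kappa must be finite")
    swap <- bonds$type_a > bonds$type_b
    tmp <- bonds$type_a[swap]
    bonds$type_a[swap] <- bonds$type_b[swap]
    bonds$type_b[swap] <- tmp
    known <- atoms$type
    bad <- !(bonds$type_a %in% known & bonds$type_b %in% known)
    if (any(bad)) {
      abort(sprintf("bond parameter references unknown atom type '%s'",
                    c(bonds$type_a, bonds$type_b)[which(bad)[1]]))
    }
  } else {
    bonds <- NULL
  }
  structure(list(method = method, classifier = classifier, atoms = atoms,
                 bonds = bonds, metadata = metadata),
            class = "charge_params")
}

#' @export
print.charge_params <- function(x, ...) {
  cat(sprintf("<charge_params> method=%s classifier=%s: %d atom types%s\n",
              x$method, x$classifier, nrow(x$atoms),
              if (!is.null(x$bonds)) sprintf(", %d bond types", nrow(x$bonds))
              else ""))
  invisible(x)
}

#' Write a parameter set to JSON
#'
#' @param params A `charge_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  doc <- list(method = params$method, classifier = params$classifier,
              atoms = params$atoms, metadata = params$metadata)
  if (!is.null(params$bonds)) doc$bonds <- params$bonds
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read a parameter set from JSON
#'
#' @param path Path to a JSON file written by [write_params()] (or
#'   following the same schema).
#' @return A `charge_params` object.
#' @export
read_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  charge_params(doc$method, doc$classifier, as_tibble(doc$atoms),
                if (!is.null(doc$bonds)) as_tibble(doc$bonds) else NULL,
                as.list(doc$metadata))
}

# Fast lookup helpers used by the solvers.
param_atom_lookup <- function(params) {
  at <- params$atoms
  lk <- list(chi = setNames(at$chi, at$type),
             eta = setNames(at$eta, at$type))
  if (!is.null(at[["qp"]])) lk$qp <- setNames(at[["qp"]], at$type)
  lk
}

param_bond_lookup <- function(params) {
  b <- params$bonds
  setNames(b$kappa, bond_label(b$type_a, b$type_b, b$order))
}

require_types <- function(found, known, what) {
  missing <- setdiff(found, names(known))
  if (length(missing) > 0) {
    abort(sprintf("unparameterized %s type(s): %s", what,
                  paste(missing, collapse = ", ")),
          class = "sqecharge_unparameterized")
  }
}
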