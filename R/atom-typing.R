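# Atom-type and bond-type assignment.
#
# Three classifiers:
#   plain - the element symbol alone ("C")
#   hbo   - element plus the highest order among incident bonds ("C/2")
#   ba    - element plus the sorted elements of all bonded atoms ("C/CCCH")
# Bond types combine the two endpoint atom types (stored in lexicographic
# order, so a bond type is independent of bond direction) with the bond
# order.

# Deterministic, locale-independent sort.
c_sort <- function(x) sort(x, method = "radix")

atom_type_labels <- function(atoms, bonds, classifier) {
  n <- nrow(atoms)
  el <- atoms$element
  if (classifier == "plain") return(el)
  if (classifier == "hbo") {
    hbo <- rep(1L, n)  # isolated atoms default to /1
    if (nrow(bonds) > 0) {
      for (r in seq_len(nrow(bonds))) {
        hbo[bonds$i[r]] <- max(hbo[bonds$i[r]], bonds$order[r])
        hbo[bonds$j[r]] <- max(hbo[bonds$j[r]], bonds$order[r])
      }
    }
    return(paste0(el, "/", hbo))
  }
  if (classifier == "ba") {
    nb <- vector("list", n)
    if (nrow(bonds) > 0) {
      for (r in seq_len(nrow(bonds))) {
        nb[[bonds$i[r]]] <- c(nb[[bonds$i[r]]], el[bonds$j[r]])
        nb[[bonds$j[r]]] <- c(nb[[bonds$j[r]]], el[bonds$i[r]])
      }
    }
    return(vapply(seq_len(n), function(k) {
      if (is.null(nb[[k]])) el[k]  # isolated: bare element
      else paste0(el[k], "/", paste(c_sort(nb[[k]]), collapse = ""))
    }, character(1)))
  }
  abort(sprintf("unknown classifier '%s'", classifier))
}

#' Assign atom types
#'
#' Adds an `atom_types` list-column (one character vector per molecule)
#' under the chosen classifier.
#'
#' @param molecules A molecule table.
#' @param classifier `"plain"`, `"hbo"` (highest bond order) or `"ba"`
#'   (bonded atoms).
#' @return `molecules` with an `atom_types` list-column.
#' @export
#' @examples
#' # a carbonyl carbon is C/2 under HBO
classify_atoms <- function(molecules, classifier = c("hbo", "ba", "plain")) {
  classifier <- match.arg(classifier)
  molecules$atom_types <- purrr::map2(
    molecules$atoms, molecules$bonds,
    ~ atom_type_labels(.x, .y, classifier)
  )
  attr(molecules$atom_types, "classifier") <- classifier
  molecules
}

bond_type_table <- function(bonds, types) {
  if (nrow(bonds) == 0) {
    return(tibble(type_a = character(), type_b = character(),
                  order = integer()))
  }
  ta <- types[bonds$i]; tb <- types[bonds$j]
  swap <- ta > tb
  tibble(type_a = ifelse(swap, tb, ta),
         type_b = ifelse(swap, ta, tb),
         order = bonds$order)
}

#' Assign bond types
#'
#' Requires [classify_atoms()] to have been applied first; adds a
#' `bond_types` list-column of tibbles (`type_a`, `type_b`, `order`), rows
#' aligned with each molecule's bond list.
#'
#' @param molecules A molecule table carrying `atom_types`.
#' @return `molecules` with a `bond_types` list-column.
#' @export
classify_bonds <- function(molecules) {
  if (is.null(molecules$atom_types)) {
    abort("run classify_atoms() before classify_bonds()")
  }
  molecules$bond_types <- purrr::map2(molecules$bonds, molecules$atom_types,
                                      bond_type_table)
  molecules
}

bond_label <- function(type_a, type_b, order) {
  paste(type_a, type_b, order, sep = "|")
}

#' Build a type registry for a dataset
#'
#' Enumerates the atom and bond types occurring in a dataset, with counts.
#' Type ordering is deterministic (sorted), so the registry fixes the
#' layout of parameter vectors during fitting.
#'
#' @param molecules A molecule table.
#' @param classifier Atom-type classifier (see [classify_atoms()]).
#' @return A `type_registry`: list with `classifier`, tibble `atom_types`
#'   (`type`, `count`), tibble `bond_types` (`type_a`, `type_b`, `order`,
#'   `count`), and totals `n_atoms`, `n_bonds`.
#' @export
build_registry <- function(molecules, classifier = c("hbo", "ba", "plain")) {
  classifier <- match.arg(classifier)
  if (nrow(molecules) == 0) abort("empty molecule table")
  molecules <- classify_bonds(classify_atoms(molecules, classifier))
  at <- unlist(molecules$atom_types)
  at_tbl <- tibble(type = at) %>% count(.data$type, name = "count") %>%
    arrange(.data$type)
  bt <- bind_rows(molecules$bond_types)
  bt_tbl <- bt %>%
    count(.data$type_a, .data$type_b, .data$order, name = "count") %>%
    arrange(.data$type_a, .data$type_b, .data$order)
  structure(list(classifier = classifier, atom_types = at_tbl,
                 bond_types = bt_tbl,
                 n_atoms = sum(molecules$n_atoms),
                 n_bonds = sum(molecules$n_bonds)),
            class = "type_registry")
}

#' @export
print.type_registry <- function(x, ...) {
  cat(sprintf("<type_registry> classifier=%s: %d atom types over %d atoms, %d bond types over %d bonds\n",
              x$classifier, nrow(x$atom_types), x$n_atoms,
              nrow(x$bond_types), x$n_bonds))
  invisible(x)
}
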