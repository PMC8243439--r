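# Reading and writing V2000 SD files and reference-charge files.

ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn"
)

# Legacy atom-block charge column: code -> formal charge. Code 4 is a
# radical doublet, not a charge.
LEGACY_CHARGE <- c("0" = 0L, "1" = 3L, "2" = 2L, "3" = 1L, "4" = 0L,
                   "5" = -1L, "6" = -2L, "7" = -3L)

#' Read a multi-record V2000 SD file
#'
#' Parses each `$$$$`-terminated record into the molecule-table container.
#' Formal charges are taken from `M  CHG` property lines when present
#' (which, per the molfile specification, supersede the atom block),
#' otherwise from the legacy atom-block charge column. Aromatic bond order
#' 4 is rejected: the typing schemes used downstream are defined over
#' explicit integer orders 1-3.
#'
#' @param path Path to an SD file.
#' @param on_error `"skip"` (default) drops records that fail to parse with
#'   a warning naming the record; `"abort"` stops on the first bad record.
#'
#' @return A molecule table (see [molecule_table()]); zero rows for an
#'   empty file.
#' @export
read_sdf <- function(path, on_error = c("skip", "abort")) {
  on_error <- match.arg(on_error)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    return(molecule_table(character(), list(), list()))
  }
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (length(ends) == 0) ends <- length(lines)  # single unterminated record
  starts <- c(1L, head(ends, -1) + 1L)
  keep_name <- character(); keep_atoms <- list(); keep_bonds <- list()
  for (r in seq_along(starts)) {
    rec <- lines[starts[r]:ends[r]]
    rec <- rec[!grepl("^\\$\\$\\$\\$", rec)]
    if (all(!nzchar(trimws(rec)))) next
    parsed <- tryCatch(parse_molfile(rec), error = function(e) e)
    if (inherits(parsed, "error")) {
      msg <- sprintf("record %d ('%s'): %s", r,
                     trimws(rec[1]), conditionMessage(parsed))
      if (on_error == "abort") abort(paste("SDF parse error,", msg))
      warn(paste("skipping SDF", msg))
      next
    }
    keep_name <- c(keep_name, parsed$name)
    keep_atoms <- c(keep_atoms, list(parsed$atoms))
    keep_bonds <- c(keep_bonds, list(parsed$bonds))
  }
  molecule_table(keep_name, keep_atoms, keep_bonds)
}

parse_molfile <- function(rec) {
  if (length(rec) < 4) abort("record too short")
  name <- trimws(rec[1])
  counts <- rec[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 0 || nbonds < 0) {
    abort("malformed counts line")
  }
  if (length(rec) < 4 + natoms + nbonds) abort("truncated atom/bond block")
  atom_lines <- rec[4 + seq_len(natoms)]
  x <- suppressWarnings(as.numeric(substr(atom_lines, 1, 10)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 11, 20)))
  z <- suppressWarnings(as.numeric(substr(atom_lines, 21, 30)))
  element <- trimws(substr(atom_lines, 31, 34))
  if (any(is.na(x) | is.na(y) | is.na(z))) abort("bad atom coordinates")
  bad <- !(element %in% ELEMENTS)
  if (any(bad)) {
    abort(sprintf("unknown element symbol '%s'", element[which(bad)[1]]))
  }
  code <- trimws(substr(atom_lines, 37, 39))
  code[!nzchar(code)] <- "0"
  if (!all(code %in% names(LEGACY_CHARGE))) abort("bad atom charge code")
  fc <- unname(LEGACY_CHARGE[code])

  bonds <- tibble(i = integer(), j = integer(), order = integer())
  if (nbonds > 0) {
    bond_lines <- rec[4 + natoms + seq_len(nbonds)]
    bi <- suppressWarnings(as.integer(substr(bond_lines, 1, 3)))
    bj <- suppressWarnings(as.integer(substr(bond_lines, 4, 6)))
    bo <- suppressWarnings(as.integer(substr(bond_lines, 7, 9)))
    if (any(is.na(bi) | is.na(bj) | is.na(bo))) abort("malformed bond line")
    if (any(bi < 1 | bi > natoms | bj < 1 | bj > natoms)) {
      abort("bond index out of range")
    }
    if (any(bo == 4L)) {
      abort("aromatic bond order 4 not supported; supply kekulized input")
    }
    if (!all(bo %in% 1:3)) abort("bond order outside 1..3")
    bonds <- tibble(i = bi, j = bj, order = bo)
  }

  chg_lines <- grep("^M  CHG", rec, value = TRUE)
  if (length(chg_lines) > 0) {
    fc <- rep(0L, natoms)  # M CHG supersedes the whole atom block
    for (ln in chg_lines) {
      tok <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))),
                                 "\\s+")[[1]])
      cnt <- tok[1]
      if (is.na(cnt) || length(tok) < 1 + 2 * cnt) abort("malformed M CHG")
      for (k in seq_len(cnt)) {
        idx <- tok[2 * k]; val <- tok[2 * k + 1]
        if (is.na(idx) || idx < 1 || idx > natoms) abort("M CHG index range")
        fc[idx] <- val
      }
    }
  }

  atoms <- tibble(element = element, x = x, y = y, z = z, formal_charge = fc)
  validate_molecule(atoms, bonds, name)
  list(name = name, atoms = atoms, bonds = bonds)
}

#' Write molecules to a V2000 SD file
#'
#' Non-zero formal charges are emitted as `M  CHG` property lines.
#'
#' @param molecules A molecule table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(molecules, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_len(nrow(molecules))) {
    a <- molecules$atoms[[k]]; b <- molecules$bonds[[k]]
    writeLines(c(molecules$name[k], "  sqecharge", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nrow(b)), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       a$x, a$y, a$z, a$element), con)
    if (nrow(b) > 0) {
      writeLines(sprintf("%3d%3d%3d  0", b$i, b$j, b$order), con)
    }
    charged <- which(a$formal_charge != 0L)
    for (grp in split(charged, ceiling(seq_along(charged) / 8))) {
      writeLines(paste0(sprintf("M  CHG%3d", length(grp)),
                        paste0(sprintf("%4d%4d", grp, a$formal_charge[grp]),
                               collapse = "")), con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}

#' Read a reference-charge file
#'
#' The file is a sequence of blank-line-separated blocks: a molecule-name
#' line followed by whitespace-separated charges, one value per atom in SD
#' record order, possibly wrapped over several lines. A two-column
#' `element charge` per-line layout is also accepted (the element column
#' is ignored).
#'
#' @param path Path to the charge file.
#' @return A named list mapping molecule name to a numeric charge vector.
#' @export
read_reference_charges <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  cur_name <- NULL; cur <- numeric()
  flush_block <- function() {
    if (!is.null(cur_name)) {
      if (cur_name %in% names(out)) {
        abort(sprintf("duplicate molecule name '%s'", cur_name))
      }
      out[[cur_name]] <<- cur
    }
    cur_name <<- NULL; cur <<- numeric()
  }
  for (ln_no in seq_along(lines)) {
    ln <- trimws(lines[ln_no])
    if (!nzchar(ln)) { flush_block(); next }
    if (is.null(cur_name)) { cur_name <- ln; next }
    tok <- strsplit(ln, "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    if (!anyNA(vals)) {
      cur <- c(cur, vals)
    } else if (length(tok) == 2 && is.na(vals[1]) && !is.na(vals[2])) {
      cur <- c(cur, vals[2])  # "element charge" dialect
    } else {
      abort(sprintf("line %d: non-numeric charge token '%s'",
                    ln_no, tok[which(is.na(vals))[1]]))
    }
  }
  flush_block()
  out
}

#' Write a reference-charge file
#'
#' Inverse of [read_reference_charges()]; charges are printed with six
#' decimal places.
#'
#' @param charges Named list of numeric vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_charges <- function(charges, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(charges)) {
    writeLines(nm, con)
    writeLines(paste(sprintf("%.6f", charges[[nm]]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

# Normalise a charges argument (tidy per-atom tibble or list of vectors)
# into a list of per-molecule vectors aligned with `molecules`.
charges_as_list <- function(molecules, charges) {
  if (is.data.frame(charges)) {
    sp <- split(charges$charge, factor(charges$molecule,
                                       levels = molecules$name))
    charges <- sp
  }
  if (is.null(names(charges))) names(charges) <- molecules$name
  charges <- charges[molecules$name]
  bad <- which(purrr::map_int(charges, length) != molecules$n_atoms)
  if (length(bad) > 0) {
    abort(sprintf("charge vector length mismatch for molecule '%s'",
                  molecules$name[bad[1]]))
  }
  charges
}

#' Write computed charges
#'
#' `txt` writes, per molecule, a name line then one line of space-separated
#' charges with six decimal places. `csv` writes a long table with header
#' `molecule,atom_index,element,charge`, where `atom_index` is 0-based.
#'
#' @param molecules A molecule table.
#' @param charges Per-atom charges: either the tidy tibble returned by
#'   [compute_charges()] or a list of numeric vectors, one per molecule.
#' @param path Output path.
#' @param format `"txt"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_charges <- function(molecules, charges, path, format = c("txt", "csv")) {
  format <- match.arg(format)
  charges <- charges_as_list(molecules, charges)  # errors before writing
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (format == "txt") {
    for (k in seq_len(nrow(molecules))) {
      writeLines(molecules$name[k], con)
      writeLines(paste(sprintf("%.6f", charges[[k]]), collapse = " "), con)
    }
  } else {
    writeLines("molecule,atom_index,element,charge", con)
    for (k in seq_len(nrow(molecules))) {
      a <- molecules$atoms[[k]]
      writeLines(sprintf("%s,%d,%s,%.6f", molecules$name[k],
                         seq_len(nrow(a)) - 1L, a$element, charges[[k]]), con)
    }
  }
  invisible(path)
}
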