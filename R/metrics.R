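# Quality metrics comparing empirical charges against reference QM
# charges, and the parameterization objective.
#
# R^2 and RMSD are computed per molecule and averaged with equal molecule
# weight. The per-type RMSD pools all atoms of one atomic type across the
# dataset; RMSD_at is the largest of these (the worst-described atom
# class). The fitting objective is the mean per-molecule RMSD plus the
# mean per-type RMSD.

#' Squared Pearson correlation
#'
#' Returns `NA` (rather than an error) when either vector has zero
#' variance, so callers can exclude such molecules from averaging.
#'
#' @param x,y Numeric vectors of equal length (at least 2).
#' @return A number in `[0, 1]`, or `NA` if undefined.
#' @export
r_squared <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Root-mean-square deviation
#'
#' @param x,y Numeric vectors of equal length.
#' @return A non-negative number; zero iff the vectors are identical.
#' @export
rmsd <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  sqrt(mean((x - y)^2))
}

# Align molecules, empirical charges and reference charges; drop (and
# report) molecules without reference charges. Returns per-molecule lists.
align_charges <- function(molecules, charges, reference) {
  emp <- charges_as_list(molecules, charges)
  have_ref <- molecules$name %in% names(reference)
  excluded <- molecules$name[!have_ref]
  if (length(excluded) > 0) {
    warn(sprintf("%d molecule(s) lack reference charges and are excluded: %s",
                 length(excluded),
                 paste(head(excluded, 5), collapse = ", ")))
  }
  keep <- which(have_ref)
  for (k in keep) {
    if (length(reference[[molecules$name[k]]]) != molecules$n_atoms[k]) {
      abort(sprintf("reference charge count mismatch for molecule '%s'",
                    molecules$name[k]))
    }
  }
  list(molecules = molecules[keep, , drop = FALSE],
       empirical = emp[keep],
       reference = reference[molecules$name[keep]],
       excluded = excluded)
}

#' Dataset quality report
#'
#' Computes per-molecule R^2 and RMSD (averaged with equal molecule
#' weight), the per-atomic-type RMSD table (atoms of a type pooled across
#' the dataset), `RMSD_at` (the per-type maximum) and the fitting
#' objective. Molecules with an undefined R^2 (constant charges) are
#' excluded from the R^2 average only.
#'
#' @param molecules A molecule table.
#' @param charges Empirical charges ([compute_charges()] tibble or list of
#'   vectors).
#' @param reference Reference charges (named list, see
#'   [read_reference_charges()]).
#' @param classifier Atom-type classifier used for the per-type table.
#' @return A `quality_report` object; see [glance.quality_report()] and
#'   [tidy.quality_report()].
#' @export
dataset_metrics <- function(molecules, charges, reference,
                            classifier = c("hbo", "ba", "plain")) {
  classifier <- match.arg(classifier)
  al <- align_charges(molecules, charges, reference)
  mols <- al$molecules
  if (nrow(mols) == 0) abort("no molecules with reference charges")
  per_mol <- tibble(
    molecule = mols$name,
    n_atoms = mols$n_atoms,
    r2 = unname(purrr::map2_dbl(al$reference, al$empirical,
                ~ if (length(.x) >= 2) r_squared(.x, .y) else NA_real_)),
    rmsd = unname(purrr::map2_dbl(al$reference, al$empirical, rmsd))
  )
  if (anyNA(per_mol$r2)) {
    warn(sprintf("R^2 undefined for %d molecule(s); excluded from the R^2 average",
                 sum(is.na(per_mol$r2))))
  }
  mols <- classify_atoms(mols, classifier)
  type <- unlist(mols$atom_types)
  err2 <- (unlist(al$reference) - unlist(al$empirical))^2
  per_type <- tibble(type = type, err2 = err2) %>%
    group_by(.data$type) %>%
    summarise(n_atoms = n(), rmsd = sqrt(mean(.data$err2)), .groups = "drop") %>%
    arrange(.data$type)
  summary <- list(
    r2 = mean(per_mol$r2, na.rm = TRUE),
    rmsd = mean(per_mol$rmsd),
    rmsd_at = max(per_type$rmsd),
    objective = mean(per_mol$rmsd) + mean(per_type$rmsd),
    n_molecules = nrow(mols),
    n_atoms = sum(mols$n_atoms),
    n_excluded = length(al$excluded),
    excluded = al$excluded
  )
  structure(list(per_molecule = per_mol, per_type = per_type,
                 classifier = classifier, summary = summary),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<quality_report> %d molecules / %d atoms (%s types)\n",
              s$n_molecules, s$n_atoms, x$classifier))
  cat(sprintf("  R2 = %.4f  RMSD = %.4f  RMSD_at = %.4f  objective = %.4f\n",
              s$r2, s$rmsd, s$rmsd_at, s$objective))
  if (s$n_excluded > 0) {
    cat(sprintf("  %d molecule(s) excluded (no reference charges)\n",
                s$n_excluded))
  }
  invisible(x)
}

#' Tidy a quality report
#'
#' @param x A `quality_report`.
#' @param ... Unused.
#' @return The per-molecule metric tibble (`molecule`, `n_atoms`, `r2`,
#'   `rmsd`).
#' @exportS3Method generics::tidy
tidy.quality_report <- function(x, ...) x$per_molecule

#' One-row summary of a quality report
#'
#' @param x A `quality_report`.
#' @param ... Unused.
#' @return A one-row tibble: `r2`, `rmsd`, `rmsd_at`, `objective`,
#'   `n_molecules`, `n_atoms`, `n_excluded`.
#' @exportS3Method generics::glance
glance.quality_report <- function(x, ...) {
  s <- x$summary
  tibble(r2 = s$r2, rmsd = s$rmsd, rmsd_at = s$rmsd_at,
         objective = s$objective, n_molecules = s$n_molecules,
         n_atoms = s$n_atoms, n_excluded = s$n_excluded)
}

#' Parameterization objective
#'
#' Mean per-molecule RMSD plus mean per-atomic-type RMSD; zero iff the
#' prediction is exact.
#'
#' @inheritParams dataset_metrics
#' @return A non-negative number.
#' @export
objective_value <- function(molecules, charges, reference,
                            classifier = c("hbo", "ba", "plain")) {
  dataset_metrics(molecules, charges, reference,
                  match.arg(classifier))$summary$objective
}

#' Correlation-graph data
#'
#' One row per atom pairing its reference (QM) and empirical charge, with
#' its atomic type — the data behind a reference-vs-empirical correlation
#' plot colored by type.
#'
#' @inheritParams dataset_metrics
#' @return A tibble: `molecule`, `atom`, `element`, `atom_type`,
#'   `reference`, `empirical`.
#' @export
correlation_graph_data <- function(molecules, charges, reference,
                                   classifier = c("hbo", "ba", "plain")) {
  classifier <- match.arg(classifier)
  al <- align_charges(molecules, charges, reference)
  mols <- classify_atoms(al$molecules, classifier)
  purrr::map_dfr(seq_len(nrow(mols)), function(k) {
    tibble(molecule = mols$name[k],
           atom = seq_len(mols$n_atoms[k]),
           element = mols$atoms[[k]]$element,
           atom_type = mols$atom_types[[k]],
           reference = al$reference[[k]],
           empirical = al$empirical[[k]])
  })
}

#' Plot a charge correlation graph
#'
#' Reference charges on the x axis, empirical charges on the y axis, one
#' point per atom, colored by atomic type, with the identity line.
#'
#' @param data Output of [correlation_graph_data()].
#' @return A ggplot object.
#' @export
plot_correlation <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$reference, y = .data$empirical,
                                     colour = .data$atom_type)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "reference charge [e]", y = "empirical charge [e]",
                  colour = "atom type") +
    ggplot2::theme_minimal()
}
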