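# Synthetic molecule fixtures with known ground-truth parameters.
#
# The generator emulates the small-organic / peptide regime of the real
# parameterization datasets: connected valence-plausible graphs (random
# trees with occasional rings), 3D embeddings at covalent bond lengths,
# and reference charges produced by a chosen method under a known
# parameter set (optionally with Gaussian noise). Because the ground
# truth is known, parameter recovery can be tested end to end without
# any external dataset.

MAX_VALENCE <- c(H = 1L, C = 4L, N = 3L, O = 2L, S = 2L, F = 1L,
                 P = 5L, Cl = 1L, Br = 1L)

PAULING_CHI <- c(H = 2.20, C = 2.55, N = 3.04, O = 3.44, S = 2.58,
                 F = 3.98, P = 2.19, Cl = 3.16, Br = 2.96)

#' Fixture-generation settings
#'
#' @param n_molecules Number of molecules.
#' @param atom_range Inclusive range of atoms per molecule.
#' @param elements Named numeric vector of element sampling weights.
#' @param bond_length Mean bonded distance in Angstrom.
#' @param double_bond_prob Probability that an eligible heavy-heavy bond
#'   gets order 2.
#' @param cycle_prob Probability of closing one ring per molecule.
#' @param charged_fraction Fraction of molecules carrying one formal
#'   charge (+1 on a nitrogen or -1 on an oxygen), emulating protonation
#'   states of peptide-like molecules.
#' @param seed Integer random seed.
#' @param preset `"small"` (default, small drug-like organics) or
#'   `"peptide"` (H/C/N/O/S alphabet and 20-40-atom molecules emulating
#'   di- and tripeptides).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_molecules = 50, atom_range = c(4, 10),
                         elements = c(H = 0.45, C = 0.35, N = 0.1, O = 0.1),
                         bond_length = 1.4, double_bond_prob = 0.15,
                         cycle_prob = 0.15, charged_fraction = 0.2,
                         seed = 1, preset = c("small", "peptide")) {
  preset <- match.arg(preset)
  if (preset == "peptide" && missing(elements)) {
    elements <- c(H = 0.48, C = 0.32, N = 0.09, O = 0.09, S = 0.02)
    if (missing(atom_range)) atom_range <- c(20, 40)
  }
  stopifnot(all(names(elements) %in% names(MAX_VALENCE)),
            atom_range[1] >= 1, atom_range[2] >= atom_range[1])
  structure(list(n_molecules = n_molecules, atom_range = atom_range,
                 elements = elements / sum(elements),
                 bond_length = bond_length,
                 double_bond_prob = double_bond_prob,
                 cycle_prob = cycle_prob,
                 charged_fraction = charged_fraction,
                 seed = seed, preset = preset),
            class = "fixture_spec")
}

generate_one_molecule <- function(spec, name) {
  n_target <- sample(seq(spec$atom_range[1], spec$atom_range[2]), 1)
  w <- spec$elements
  heavy_w <- w[names(w) != "H"]
  frac_h <- if ("H" %in% names(w)) w[["H"]] else 0
  n_heavy <- max(1L, round(n_target * (1 - frac_h)))
  n_h <- n_target - n_heavy
  element <- c(sample(names(heavy_w), n_heavy, replace = TRUE,
                      prob = heavy_w),
               rep("H", max(0L, n_h)))
  n <- length(element)
  rem <- unname(MAX_VALENCE[element])
  bi <- integer(); bj <- integer(); bo <- integer()
  parent <- rep(NA_integer_, n)
  placed <- 1L
  for (k in seq(2, length.out = n - 1)) {
    cand <- which(rem[seq_len(k - 1)] > 0)
    if (length(cand) == 0) { placed <- k - 1L; break }
    p <- if (length(cand) == 1) cand else sample(cand, 1)
    ord <- 1L
    if (element[k] != "H" && element[p] != "H" &&
        rem[k] >= 2 && rem[p] >= 2 &&
        runif(1) < spec$double_bond_prob) {
      ord <- 2L
    }
    bi <- c(bi, p); bj <- c(bj, k); bo <- c(bo, ord)
    rem[k] <- rem[k] - ord; rem[p] <- rem[p] - ord
    parent[k] <- p
    placed <- k
  }
  element <- element[seq_len(placed)]
  n <- placed
  # occasional ring closure between unsaturated, non-adjacent heavy atoms
  if (n >= 5 && runif(1) < spec$cycle_prob) {
    open <- which(element != "H" & rem[seq_len(n)] > 0)
    if (length(open) >= 2) {
      pair <- if (length(open) == 2) open else sort(sample(open, 2))
      adjacent <- any((bi == pair[1] & bj == pair[2]) |
                      (bi == pair[2] & bj == pair[1]))
      if (!adjacent) {
        bi <- c(bi, pair[1]); bj <- c(bj, pair[2]); bo <- c(bo, 1L)
        rem[pair] <- rem[pair] - 1L
      }
    }
  }
  # 3D embedding along the spanning tree; retry directions that collide
  xyz <- matrix(0, nrow = n, ncol = 3)
  for (k in seq(2, length.out = n - 1)) {
    p <- parent[k]
    for (try in 1:60) {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      len <- spec$bond_length * runif(1, 0.9, 1.1) * (1 + 0.05 * (try %/% 20))
      pos <- xyz[p, ] + dir * len
      d <- sqrt(rowSums((xyz[seq_len(k - 1), , drop = FALSE] -
                         matrix(pos, k - 1, 3, byrow = TRUE))^2))
      if (min(d) > 0.6) break
    }
    xyz[k, ] <- pos
  }
  fc <- rep(0L, n)
  if (runif(1) < spec$charged_fraction) {
    ns <- which(element == "N"); os <- which(element == "O")
    if (length(ns) > 0) {
      fc[if (length(ns) == 1) ns else sample(ns, 1)] <- 1L
    } else if (length(os) > 0) {
      fc[if (length(os) == 1) os else sample(os, 1)] <- -1L
    }
  }
  list(name = name,
       atoms = tibble(element = element, x = xyz[, 1], y = xyz[, 2],
                      z = xyz[, 3], formal_charge = fc),
       bonds = tibble(i = bi, j = bj, order = bo))
}

#' Generate synthetic molecules
#'
#' Deterministic given `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @return A molecule table.
#' @export
generate_molecules <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  local_seed(spec$seed, {
    mols <- purrr::map(seq_len(spec$n_molecules),
                       ~ generate_one_molecule(spec, sprintf("SYN%04d", .x)))
    molecule_table(purrr::map_chr(mols, "name"),
                   purrr::map(mols, "atoms"),
                   purrr::map(mols, "bonds"))
  })
}

#' Generate reference charges from a known parameter set
#'
#' Charges are the exact solver output of `true_params`' method, plus
#' optional i.i.d. Gaussian noise; with `noise_sigma = 0` the data are
#' exactly model-consistent, so fitting should recover a near-zero
#' objective.
#'
#' @param molecules A molecule table.
#' @param true_params The generating `charge_params`.
#' @param noise_sigma Standard deviation of added Gaussian noise
#'   (elementary charges).
#' @param seed Integer seed for the noise.
#' @return A named list of per-molecule charge vectors.
#' @export
generate_reference_charges <- function(molecules, true_params,
                                       noise_sigma = 0, seed = 1) {
  ch <- compute_charges(molecules, true_params)
  out <- charges_as_list(molecules, ch)
  if (noise_sigma > 0) {
    out <- local_seed(seed, purrr::map(out, ~ .x + rnorm(length(.x),
                                                         0, noise_sigma)))
  }
  out
}

#' Plausible parameter set for a registry
#'
#' Builds a well-conditioned parameter set for fixtures and examples:
#' electronegativities track the Pauling scale of each type's element with
#' per-type jitter, hardnesses sit in the diagonally dominant range, bond
#' hardnesses near 2. Deterministic given `seed`.
#'
#' @param registry A `type_registry`.
#' @param method Charge method id.
#' @param seed Integer seed for the jitter.
#' @param jitter Half-width of the uniform per-type perturbation.
#' @return A `charge_params` object.
#' @export
example_params <- function(registry, method, seed = 1, jitter = 0.2) {
  method <- match.arg(method, ALL_METHODS)
  at <- registry$atom_types$type
  el <- sub("/.*$", "", at)
  base_chi <- unname(PAULING_CHI[el])
  base_chi[is.na(base_chi)] <- 2.5
  local_seed(seed, {
    atoms <- tibble(
      type = at,
      chi = pmin(4.8, pmax(0.2, base_chi + runif(length(at), -jitter, jitter))),
      eta = 3.5 + runif(length(at), -0.5, 0.5)
    )
    if (method == "sqe+qp") {
      atoms$qp <- runif(length(at), -0.3, 0.3)
    }
    bonds <- NULL
    if (method %in% SQE_METHODS) {
      bt <- registry$bond_types
      bonds <- tibble(type_a = bt$type_a, type_b = bt$type_b,
                      order = bt$order,
                      kappa = 2 + runif(nrow(bt), -0.5, 0.5))
    }
    charge_params(method, registry$classifier, atoms, bonds,
                  metadata = list(source = "synthetic example", seed = seed))
  })
}
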