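# Parameterization: dataset splitting and the two guided-minimization
# engines.
#
# GDMIN: draw random parameter vectors within bounds, score every one on
# the full training set, then refine the best few by bounded local
# minimization.
#
# optGM: score the (much larger) initial sample on a small molecule subset
# that still contains at least `nmin` atoms of every atomic type, rescore
# only the top candidates on the full training set, and run local
# minimization from the best few of those. The subset stage makes each
# initial evaluation cheap, so far more of the parameter space can be
# covered for the same wall time.

# Run code under a fixed RNG state without disturbing the caller's.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Split a dataset into training and test sets
#'
#' Random, stratified split: molecules are shuffled, then assigned to the
#' test set only while every atom type present in the dataset keeps at
#' least one occurrence in the training set. Deterministic given `seed`.
#'
#' @param molecules A molecule table (at least 5 molecules).
#' @param fraction Training fraction (default 0.8); the test set size is
#'   the remainder rounded to the nearest integer.
#' @param seed Integer random seed (required).
#' @param classifier Atom-type classifier used for stratification.
#' @return A list with molecule tables `train` and `test`.
#' @export
split_train_test <- function(molecules, fraction = 0.8, seed,
                             classifier = c("hbo", "ba", "plain")) {
  classifier <- match.arg(classifier)
  n <- nrow(molecules)
  if (n < 5) abort("need at least 5 molecules to split")
  stopifnot(fraction > 0, fraction < 1)
  n_test <- round(n * (1 - fraction))
  mols <- classify_atoms(molecules, classifier)
  type_sets <- purrr::map(mols$atom_types, unique)
  pool_count <- table(unlist(type_sets))  # molecules carrying each type
  ord <- local_seed(seed, sample.int(n))
  in_test <- logical(n)
  taken <- 0L
  for (k in ord) {
    if (taken >= n_test) break
    tys <- type_sets[[k]]
    if (all(pool_count[tys] >= 2)) {
      in_test[k] <- TRUE
      taken <- taken + 1L
      pool_count[tys] <- pool_count[tys] - 1L
    }
  }
  if (taken < n_test) {
    warn(sprintf("stratification left the test set short: %d of %d molecules",
                 taken, n_test))
  }
  train <- molecules[!in_test, , drop = FALSE]
  train_types <- unique(unlist(type_sets[!in_test]))
  uncovered <- setdiff(unique(unlist(type_sets)), train_types)
  if (length(uncovered) > 0) {
    warn(sprintf("atom type(s) not covered by the training set: %s",
                 paste(uncovered, collapse = ", ")))
  }
  list(train = train, test = molecules[in_test, , drop = FALSE])
}

#' Select a type-covering molecule subset
#'
#' Greedily picks molecules until every atom type of the registry is
#' represented by at least `nmin` atoms (or by every molecule containing
#' it, if the whole set has fewer). Used by optGM for cheap initial-sample
#' scoring. Deterministic given the dataset order.
#'
#' @param molecules A molecule table.
#' @param registry A `type_registry` built on `molecules` (or a superset).
#' @param nmin Minimum atoms per atomic type (default 50).
#' @return The selected rows of `molecules`.
#' @export
select_subset <- function(molecules, registry, nmin = 50) {
  stopifnot(nmin >= 1)
  mols <- classify_atoms(molecules, registry$classifier)
  types <- registry$atom_types$type
  counts <- purrr::map(mols$atom_types, ~ table(factor(.x, levels = types)))
  total <- Reduce(`+`, counts)
  need <- pmin(nmin, as.numeric(total))
  names(need) <- types
  chosen <- logical(nrow(mols))
  while (any(need > 0)) {
    gain <- vapply(seq_len(nrow(mols)), function(k) {
      if (chosen[k]) return(-1)
      sum(pmin(as.numeric(counts[[k]]), need))
    }, numeric(1))
    best <- which.max(gain)  # ties: earliest index
    if (gain[best] <= 0) break
    chosen[best] <- TRUE
    need <- pmax(0, need - as.numeric(counts[[best]]))
  }
  shortfall <- need[need > 0]
  if (length(shortfall) > 0) {
    inform(sprintf("subset coverage shortfall for type(s): %s",
                   paste(names(shortfall), collapse = ", ")))
  }
  molecules[chosen, , drop = FALSE]
}

#' Parameter-space layout for fitting
#'
#' Fixes the ordered layout of the free parameter vector for one method
#' and type registry: per atom type chi and eta (plus qp for `"sqe+qp"`),
#' then per bond type kappa (SQE family), each with sampling bounds.
#'
#' @param registry A `type_registry`.
#' @param method Charge method id.
#' @param bounds Named list of `c(lower, upper)` bounds per parameter kind
#'   (`chi`, `eta`, `kappa`, `qp`); defaults `chi` in \[0, 5\], `eta` in
#'   \[0.1, 5\], `kappa` in \[0.1, 5\], `qp` in \[-1, 1\].
#' @return A `param_space` object.
#' @export
param_space <- function(registry, method, bounds = list()) {
  method <- match.arg(method, ALL_METHODS)
  bounds <- modifyList(list(chi = c(0, 5), eta = c(0.1, 5),
                            kappa = c(0.1, 5), qp = c(-1, 1)), bounds)
  at <- registry$atom_types$type
  kinds <- c("chi", "eta", if (method == "sqe+qp") "qp")
  kind <- rep(kinds, each = length(at))
  label <- rep(at, times = length(kinds))
  bt <- NULL
  if (method %in% SQE_METHODS) {
    bt <- registry$bond_types
    kind <- c(kind, rep("kappa", nrow(bt)))
    label <- c(label, bond_label(bt$type_a, bt$type_b, bt$order))
  }
  lower <- vapply(kind, function(k) bounds[[k]][1], numeric(1))
  upper <- vapply(kind, function(k) bounds[[k]][2], numeric(1))
  structure(list(method = method, classifier = registry$classifier,
                 atom_types = at, bond_types = bt, kind = unname(kind),
                 label = unname(label), lower = unname(lower),
                 upper = unname(upper), bounds = bounds,
                 n = length(kind)),
            class = "param_space")
}

#' @export
print.param_space <- function(x, ...) {
  cat(sprintf("<param_space> %s/%s: %d free parameters\n",
              x$method, x$classifier, x$n))
  invisible(x)
}

#' Assemble a parameter set from a free-parameter vector
#'
#' @param space A `param_space`.
#' @param vec Numeric vector of length `space$n`.
#' @param metadata Optional metadata list passed to [charge_params()].
#' @return A `charge_params` object.
#' @export
vector_to_params <- function(space, vec, metadata = list()) {
  stopifnot(length(vec) == space$n)
  at <- tibble(type = space$atom_types,
               chi = vec[space$kind == "chi"],
               eta = vec[space$kind == "eta"])
  if (space$method == "sqe+qp") at$qp <- vec[space$kind == "qp"]
  bt <- NULL
  if (space$method %in% SQE_METHODS) {
    bt <- space$bond_types[c("type_a", "type_b", "order")]
    bt$kappa <- vec[space$kind == "kappa"]
  }
  charge_params(space$method, space$classifier, at, bt, metadata)
}

params_to_vector <- function(space, params) {
  vec <- numeric(space$n)
  at <- params$atoms
  m <- match(space$label[space$kind == "chi"], at$type)
  vec[space$kind == "chi"] <- at$chi[m]
  vec[space$kind == "eta"] <- at$eta[m]
  if (space$method == "sqe+qp") vec[space$kind == "qp"] <- at[["qp"]][m]
  if (space$method %in% SQE_METHODS) {
    b <- params$bonds
    mb <- match(space$label[space$kind == "kappa"],
                bond_label(b$type_a, b$type_b, b$order))
    vec[space$kind == "kappa"] <- b$kappa[mb]
  }
  vec
}

#' Draw initial parameter samples
#'
#' Uniform (default) or Latin-hypercube samples within the space bounds;
#' deterministic given `seed`.
#'
#' @param space A `param_space`.
#' @param n Number of samples.
#' @param seed Integer random seed.
#' @param sampler `"uniform"` or `"lhs"` (requires the lhs package).
#' @return An `n` x `space$n` numeric matrix.
#' @export
sample_initial <- function(space, n, seed, sampler = c("uniform", "lhs")) {
  sampler <- match.arg(sampler)
  stopifnot(n >= 1)
  u <- local_seed(seed, {
    if (sampler == "lhs") {
      if (!requireNamespace("lhs", quietly = TRUE)) {
        abort("sampler 'lhs' requires the lhs package")
      }
      lhs::randomLHS(n, space$n)
    } else {
      matrix(runif(n * space$n), nrow = n)
    }
  })
  sweep(sweep(u, 2, space$upper - space$lower, `*`), 2, space$lower, `+`)
}

#' Fitting configuration
#'
#' @param n_samples Initial random samples (defaults: 500 for GDMIN,
#'   10000 for optGM).
#' @param n_refine optGM only: candidates rescored on the full training
#'   set after the subset stage.
#' @param n_local Candidates refined by local minimization.
#' @param nmin optGM only: minimum atoms per type in the scoring subset.
#' @param sampler Initial sampler (see [sample_initial()]).
#' @param local_maxit Iteration cap for each local minimization.
#' @param local_factr Relative convergence tolerance factor for the local
#'   optimizer (see [stats::optim()] `factr`).
#' @param polish Run a second, reduced-step local pass from the best
#'   candidate (sharpens convergence near the optimum, where the RMSD
#'   objective's square-root kink slows quasi-Newton steps).
#' @param polish_ndeps Finite-difference step of the polish pass.
#' @param bounds Sampling-bound overrides (see [param_space()]).
#' @return A list of settings for [gdmin()] / [optgm()].
#' @export
fit_config <- function(n_samples = NULL, n_refine = 50, n_local = 5,
                       nmin = 50, sampler = "uniform", local_maxit = 150,
                       local_factr = 1e7, polish = TRUE,
                       polish_ndeps = 1e-5, bounds = list()) {
  list(n_samples = n_samples, n_refine = n_refine, n_local = n_local,
       nmin = nmin, sampler = sampler, local_maxit = local_maxit,
       local_factr = local_factr, polish = polish,
       polish_ndeps = polish_ndeps, bounds = bounds)
}

# Objective closure over a compiled dataset. Returns a function(vec) plus
# an environment counting evaluations and per-molecule solves.
make_objective <- function(cms, reference, space) {
  method <- space$method
  names_cm <- vapply(cms, `[[`, character(1), "name")
  ref <- reference[names_cm]
  if (anyNA(names(ref))) abort("reference charges missing for training molecule")
  sizes <- vapply(cms, `[[`, numeric(1), "n")
  for (k in seq_along(cms)) {
    if (length(ref[[k]]) != sizes[k]) {
      abort(sprintf("reference charge count mismatch for molecule '%s'",
                    names_cm[k]))
    }
  }
  ref_all <- unlist(ref, use.names = FALSE)
  mol_id <- rep(seq_along(cms), sizes)
  type_all <- unlist(purrr::map(cms, "atom_type"), use.names = FALSE)
  type_fac <- factor(type_all, levels = space$atom_types)
  type_sizes <- as.numeric(table(type_fac))
  type_id <- as.integer(type_fac)
  n_mol <- length(cms); n_type <- length(space$atom_types)
  env <- new.env()
  env$evals <- 0L
  env$solves <- 0L
  is_sqe <- method %in% SQE_METHODS
  fn <- function(vec) {
    env$evals <- env$evals + 1L
    lk_atom <- list(chi = setNames(vec[space$kind == "chi"], space$atom_types),
                    eta = setNames(vec[space$kind == "eta"], space$atom_types))
    if (method == "sqe+qp") {
      lk_atom$qp <- setNames(vec[space$kind == "qp"], space$atom_types)
    }
    lk_bond <- if (is_sqe) {
      setNames(vec[space$kind == "kappa"], space$label[space$kind == "kappa"])
    }
    if (any(lk_atom$eta <= 0)) return(Inf)
    q_all <- numeric(length(ref_all))
    pos <- 0L
    for (k in seq_len(n_mol)) {
      res <- tryCatch(solve_compiled(cms[[k]], method, lk_atom, lk_bond),
                      error = function(e) NULL)
      if (is.null(res) || !all(is.finite(res$q))) return(Inf)
      q_all[pos + seq_len(sizes[k])] <- res$q
      pos <- pos + sizes[k]
    }
    env$solves <- env$solves + n_mol
    err2 <- (q_all - ref_all)^2
    per_mol <- sqrt(rowsum(err2, mol_id, reorder = FALSE) / sizes)
    per_type <- sqrt(rowsum(err2, type_id, reorder = TRUE) / type_sizes)
    mean(per_mol) + mean(per_type)
  }
  list(fn = fn, env = env)
}

finite_or_big <- function(fn, big = 1e8) {
  function(vec) {
    v <- fn(vec)
    if (!is.finite(v)) big else v
  }
}

run_local <- function(fn, start, space, config, ndeps = NULL) {
  control <- list(maxit = config$local_maxit, factr = config$local_factr)
  if (!is.null(ndeps)) control$ndeps <- rep(ndeps, space$n)
  tryCatch(
    optim(start, finite_or_big(fn), method = "L-BFGS-B",
          lower = space$lower, upper = space$upper, control = control),
    error = function(e) list(par = start, value = fn(start)))
}

fit_engine <- function(train, reference, method, classifier, seed, config,
                       optimizer) {
  registry <- build_registry(train, classifier)
  space <- param_space(registry, method, config$bounds)
  n_samples <- config$n_samples %||%
    if (optimizer == "gdmin") 500L else 10000L
  cms_full <- compile_dataset(train, classifier)
  obj_full <- make_objective(cms_full, reference, space)

  samples <- sample_initial(space, n_samples, seed, config$sampler)

  if (optimizer == "gdmin") {
    sample_obj <- apply(samples, 1, obj_full$fn)
    subset_evals <- 0L
    subset_n <- nrow(train)
    order_idx <- order(sample_obj, seq_along(sample_obj))
    cand_idx <- head(order_idx, config$n_local)
    cand_obj <- sample_obj[cand_idx]
  } else {
    subset <- select_subset(train, registry, config$nmin)
    cms_sub <- compile_dataset(subset, classifier)
    obj_sub <- make_objective(cms_sub, reference, space)
    sample_obj <- apply(samples, 1, obj_sub$fn)
    subset_evals <- obj_sub$env$evals
    subset_n <- nrow(subset)
    order_idx <- order(sample_obj, seq_along(sample_obj))
    refine_idx <- head(order_idx, config$n_refine)
    refine_obj <- vapply(refine_idx, function(k) obj_full$fn(samples[k, ]),
                         numeric(1))
    reorder <- order(refine_obj, seq_along(refine_obj))
    cand_idx <- refine_idx[head(reorder, config$n_local)]
    cand_obj <- refine_obj[head(reorder, config$n_local)]
  }

  trace <- cummin(cand_obj[1])
  best_par <- samples[cand_idx[1], ]
  best_obj <- cand_obj[1]
  for (k in seq_along(cand_idx)) {
    loc <- run_local(obj_full$fn, samples[cand_idx[k], ], space, config)
    if (is.finite(loc$value) && loc$value < best_obj) {
      best_obj <- loc$value
      best_par <- loc$par
    }
    trace <- c(trace, best_obj)
  }
  if (isTRUE(config$polish)) {
    pol <- run_local(obj_full$fn, best_par, space, config,
                     ndeps = config$polish_ndeps)
    if (is.finite(pol$value) && pol$value < best_obj) {
      best_obj <- pol$value
      best_par <- pol$par
    }
    trace <- c(trace, best_obj)
  }
  # the reported objective is recomputed from the returned parameters
  final_obj <- obj_full$fn(best_par)

  params <- vector_to_params(space, best_par, metadata = list(
    optimizer = optimizer, seed = seed, n_samples = n_samples,
    n_refine = if (optimizer == "optgm") config$n_refine else NA,
    n_local = config$n_local, nmin = if (optimizer == "optgm") config$nmin
    else NA, bounds = space$bounds, objective = final_obj,
    fitted = format(Sys.time(), "%Y-%m-%d")))
  structure(list(
    params = params, objective = final_obj, trace = trace,
    sample_objectives = sample_obj, sample_order = order_idx,
    counts = list(full_evals = obj_full$env$evals,
                  subset_evals = subset_evals,
                  full_solves = obj_full$env$solves,
                  subset_size = subset_n),
    optimizer = optimizer, seed = seed, config = config, space = space),
    class = "charge_fit")
}

#' Fit parameters by guided minimization (GDMIN)
#'
#' Scores `n_samples` random parameter vectors on the full training set,
#' then refines the best `n_local` by bounded local minimization and
#' returns the best local optimum. Deterministic given `seed`.
#'
#' @param train Training molecule table.
#' @param reference Named list of reference charges covering `train`.
#' @param method Charge method id (see [charge_params()]).
#' @param classifier Atom-type classifier.
#' @param seed Integer random seed (required).
#' @param config A [fit_config()] list.
#' @return A `charge_fit` object; `$params` is the fitted `charge_params`,
#'   `$objective` the training objective, `$counts` the evaluation
#'   accounting.
#' @export
gdmin <- function(train, reference, method, classifier, seed,
                  config = fit_config()) {
  fit_engine(train, reference, match.arg(method, ALL_METHODS),
             match.arg(classifier, c("plain", "hbo", "ba")),
             seed, config, "gdmin")
}

#' Fit parameters by subset-accelerated guided minimization (optGM)
#'
#' Stage 1 scores all initial samples on a type-covering molecule subset
#' (see [select_subset()]); stage 2 rescores the `n_refine` best on the
#' full training set; stage 3 locally minimizes the best `n_local` on the
#' full set. With the subset equal to the full set and equal budgets the
#' candidate ranking coincides with [gdmin()]'s.
#'
#' @inheritParams gdmin
#' @return A `charge_fit` object.
#' @export
optgm <- function(train, reference, method, classifier, seed,
                  config = fit_config()) {
  fit_engine(train, reference, match.arg(method, ALL_METHODS),
             match.arg(classifier, c("plain", "hbo", "ba")),
             seed, config, "optgm")
}

#' @export
print.charge_fit <- function(x, ...) {
  cat(sprintf("<charge_fit> %s %s/%s: objective = %.6g (%d full-set evaluations)\n",
              x$optimizer, x$params$method, x$params$classifier,
              x$objective, x$counts$full_evals))
  invisible(x)
}

#' Tidy a fitted parameter set
#'
#' @param x A `charge_fit`.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `kind` (chi, eta,
#'   qp or kappa), `type` label and fitted `value`.
#' @exportS3Method generics::tidy
tidy.charge_fit <- function(x, ...) {
  tibble(kind = x$space$kind, type = x$space$label,
         value = params_to_vector(x$space, x$params))
}

#' One-row summary of a fit
#'
#' @param x A `charge_fit`.
#' @param ... Unused.
#' @return A one-row tibble: objective, evaluation counts, dimensions,
#'   optimizer and seed.
#' @exportS3Method generics::glance
glance.charge_fit <- function(x, ...) {
  tibble(objective = x$objective, optimizer = x$optimizer,
         n_params = x$space$n, full_evals = x$counts$full_evals,
         subset_evals = x$counts$subset_evals,
         subset_size = x$counts$subset_size, seed = x$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
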