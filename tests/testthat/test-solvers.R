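# Charge solvers: matrices, closed forms, conservation, oracles.

test_that("incidence matrix follows the orientation convention", {
  lone <- molecule_table("a",
                         list(tibble::tibble(element = "C", x = 0, y = 0,
                                             z = 0, formal_charge = 0L)),
                         list(tibble::tibble(i = integer(), j = integer(),
                                             order = integer())))
  expect_identical(dim(incidence_matrix(lone)), c(0L, 1L))

  expect_equal(incidence_matrix(make_diatomic()),
               matrix(c(1, -1), nrow = 1))

  chain <- molecule_table("chain",
    list(tibble::tibble(element = c("C", "C", "C"), x = c(0, 1.5, 3),
                        y = 0, z = 0, formal_charge = 0L)),
    list(tibble::tibble(i = c(1L, 2L), j = c(2L, 3L), order = 1L)))
  expect_equal(incidence_matrix(chain),
               matrix(c(1, -1, 0, 0, 1, -1), nrow = 2, byrow = TRUE))

  # bond stored with endpoints swapped gives the same row
  swapped <- chain
  swapped$bonds[[1]] <- tibble::tibble(i = c(2L, 3L), j = c(1L, 2L),
                                       order = 1L)
  expect_equal(incidence_matrix(swapped), incidence_matrix(chain))
})

test_that("hardness matrix combines per-type eta with the 1/r kernel", {
  dia <- make_diatomic(r = 2)
  p <- diatomic_params(eta = c(1, 3))
  H <- hardness_matrix(dia, p)
  expect_equal(H, matrix(c(1, 0.5, 0.5, 3), 2))

  mols <- tiny_dataset(5, seed = 3)
  reg <- build_registry(mols, "hbo")
  params <- example_params(reg, "eem")
  for (k in seq_len(nrow(mols))) {
    H <- hardness_matrix(mols[k, ], params)
    expect_identical(H, t(H))
    Ht <- hardness_matrix(transform_molecule(mols[k, ]), params)
    expect_equal(Ht, H, tolerance = 1e-12)
  }
})

test_that("the SQE diatomic matches its closed-form solution", {
  # system scalar eta1 + eta2 - 2/r + kappa = 1, rhs chi1 - chi2 = 1
  dia <- make_diatomic(r = 1)
  res <- solve_sqe(dia, diatomic_params())
  expect_equal(res$q, c(1, -1), tolerance = 1e-12)
  expect_equal(res$q_sp, 1, tolerance = 1e-12)

  # generic closed form over random diatomic parameters
  set.seed(4)
  for (rep in 1:20) {
    r <- runif(1, 0.8, 2.5)
    chi <- runif(2, 0, 4); eta <- runif(2, 2, 5); kappa <- runif(1, 0.5, 3)
    res <- solve_sqe(make_diatomic(r), diatomic_params(chi = chi, eta = eta,
                                                       kappa = kappa))
    expect_equal(res$q[1], (chi[1] - chi[2]) / (sum(eta) - 2 / r + kappa),
                 tolerance = 1e-10)
    expect_equal(res$q[2], -res$q[1], tolerance = 1e-12)
  }
})

test_that("the SQE+q0 diatomic matches the hand-evaluated system", {
  dia <- make_diatomic(r = 1, fc = c(1L, 0L))
  res <- solve_sqe_q0(dia, diatomic_params(method = "sqe+q0"))
  expect_equal(res$q_sp, 2, tolerance = 1e-12)
  expect_equal(res$q, c(3, -2), tolerance = 1e-12)
  expect_equal(sum(res$q), 1)
})

test_that("SQE+q0 reduces to SQE when all formal charges vanish", {
  mols <- tiny_dataset(10, seed = 8, charged_fraction = 0)
  reg <- build_registry(mols, "hbo")
  p <- example_params(reg, "sqe")
  p0 <- charge_params("sqe+q0", "hbo", p$atoms, p$bonds)
  for (k in seq_len(nrow(mols))) {
    expect_equal(solve_sqe_q0(mols[k, ], p0)$q, solve_sqe(mols[k, ], p)$q,
                 tolerance = 1e-12)
  }
})

test_that("normalize_qp reproduces the normalization formula", {
  expect_equal(normalize_qp(c(0.3, -0.3), 0), c(0.3, -0.3))
  expect_equal(normalize_qp(c(0.5, 0.5), 0), c(0, 0))
  expect_equal(normalize_qp(c(0.2, 0.2, 0.2), 1), rep(1 / 3, 3))
  expect_equal(sum(normalize_qp(runif(7), 2)), 2, tolerance = 1e-12)
})

test_that("SQE+qp reduces to SQE/SQE+q0 in the documented limits", {
  # all qp = 0 and Q = 0: identical to SQE
  mols <- tiny_dataset(8, seed = 12, charged_fraction = 0)
  reg <- build_registry(mols, "hbo")
  p <- example_params(reg, "sqe")
  atoms_qp0 <- p$atoms; atoms_qp0$qp <- 0
  pqp <- charge_params("sqe+qp", "hbo", atoms_qp0, p$bonds)
  for (k in seq_len(nrow(mols))) {
    expect_equal(solve_sqe_qp(mols[k, ], pqp)$q, solve_sqe(mols[k, ], p)$q,
                 tolerance = 1e-12)
  }

  # all qp = 0 and Q = 1 on a diatomic: q0 spreads as (0.5, 0.5)
  dia <- make_diatomic(r = 1, fc = c(1L, 0L))
  pd <- diatomic_params("sqe+qp", qp = c(0, 0))
  got <- solve_sqe_qp(dia, pd)
  cm <- sqecharge:::compile_molecule(dia, "plain")
  cm$q0 <- c(0.5, 0.5)
  lk <- sqecharge:::param_atom_lookup(pd)
  want <- sqecharge:::solve_compiled(cm, "sqe+q0", lk,
                                     sqecharge:::param_bond_lookup(pd))
  expect_equal(got$q, want$q, tolerance = 1e-12)
  expect_equal(sum(got$q), 1, tolerance = 1e-12)
})

test_that("symmetry-equivalent atoms receive equal charges", {
  water <- make_water()
  # symmetric geometry: place H atoms mirror-symmetrically
  water$atoms[[1]]$x <- c(0, 0.76, -0.76)
  water$atoms[[1]]$y <- c(0, 0.59, 0.59)
  reg <- build_registry(water, "hbo")
  for (m in c("eem", "qeq", "eqeq", "sqe", "sqe+q0", "sqe+qp")) {
    p <- example_params(reg, m)
    q <- solve_one_method(water, p, m)
    expect_equal(q[2], q[3], tolerance = 1e-10)
  }
})

test_that("single atoms obey each method's conservation law", {
  ion <- molecule_table("ion",
                        list(tibble::tibble(element = "N", x = 0, y = 0,
                                            z = 0, formal_charge = 1L)),
                        list(tibble::tibble(i = integer(), j = integer(),
                                            order = integer())))
  reg <- build_registry(ion, "hbo")
  for (m in c("eem", "qeq", "eqeq")) {
    expect_equal(solve_one_method(ion, example_params(reg, m), m), 1)
  }
  expect_equal(solve_one_method(ion, example_params(reg, "sqe"), "sqe"), 0)
  expect_equal(solve_one_method(ion, example_params(reg, "sqe+q0"), "sqe+q0"), 1)
  expect_equal(solve_one_method(ion, example_params(reg, "sqe+qp"), "sqe+qp"), 1)
})

test_that("equalization solutions match the constrained-minimization oracle", {
  mols <- tiny_dataset(6, seed = 21, atom_range = c(3, 4))
  reg <- build_registry(mols, "hbo")
  for (m in c("eem", "qeq", "eqeq")) {
    p <- example_params(reg, m)
    for (k in 1:3) {
      got <- solve_one_method(mols[k, ], p, m)
      want <- ee_energy_oracle(mols[k, ], p, m)
      expect_equal(got, want, tolerance = 1e-5)
    }
  }
})

test_that("SQE-family solutions minimize the split-charge energy", {
  mols <- tiny_dataset(8, seed = 31, atom_range = c(4, 10),
                       charged_fraction = 0.4)
  reg <- build_registry(mols, "hbo")
  for (m in c("sqe", "sqe+q0", "sqe+qp")) {
    p <- example_params(reg, m)
    for (k in c(1, 3, 5)) {
      got <- solve_one_method(mols[k, ], p, m)
      res <- switch(m, sqe = solve_sqe(mols[k, ], p),
                    "sqe+q0" = solve_sqe_q0(mols[k, ], p),
                    "sqe+qp" = solve_sqe_qp(mols[k, ], p))
      oracle_qsp <- sqe_energy_oracle(mols[k, ], p, m)
      expect_equal(res$q_sp, oracle_qsp, tolerance = 1e-6)
    }
  }
})

test_that("charges are equivariant under atom permutation", {
  mols <- tiny_dataset(6, seed = 41, charged_fraction = 0.4)
  reg <- build_registry(mols, "hbo")
  set.seed(17)
  for (m in c("eem", "eqeq", "sqe", "sqe+qp")) {
    p <- example_params(reg, m)
    for (k in seq_len(3)) {
      perm <- sample(mols$n_atoms[k])
      q0 <- solve_one_method(mols[k, ], p, m)
      q1 <- solve_one_method(permute_molecule(mols[k, ], perm), p, m)
      expect_equal(q1, q0[perm], tolerance = 1e-9)
    }
  }
})

test_that("charges are invariant under rigid-body motion", {
  mols <- tiny_dataset(5, seed = 51, charged_fraction = 0.4)
  reg <- build_registry(mols, "hbo")
  for (m in c("eem", "qeq", "eqeq", "sqe", "sqe+q0", "sqe+qp")) {
    p <- example_params(reg, m)
    for (k in seq_len(3)) {
      q0 <- solve_one_method(mols[k, ], p, m)
      q1 <- solve_one_method(transform_molecule(mols[k, ]), p, m)
      expect_lt(max(abs(q1 - q0)), 1e-10)
    }
  }
})

test_that("flipping an incidence row leaves atomic charges unchanged", {
  mols <- tiny_dataset(4, seed = 61)
  reg <- build_registry(mols, "hbo")
  p <- example_params(reg, "sqe")
  for (k in seq_len(nrow(mols))) {
    mol <- mols[k, ]
    if (mol$n_bonds < 1) next
    cm <- sqecharge:::compile_molecule(mol, "hbo")
    lk <- sqecharge:::param_atom_lookup(p)
    lkb <- sqecharge:::param_bond_lookup(p)
    eta <- unname(lk$eta[cm$atom_type])
    chi <- unname(lk$chi[cm$atom_type])
    H <- sqecharge:::hmatrix_from_parts(cm$inv_dist, eta)
    kappa <- unname(lkb[cm$bond_lab])
    solve_with_T <- function(Tm) {
      A <- Tm %*% H %*% t(Tm) + diag(kappa, nrow(Tm))
      drop(crossprod(Tm, solve(A, Tm %*% chi)))
    }
    Tm <- cm$Tm
    Tf <- Tm; Tf[1, ] <- -Tf[1, ]
    expect_equal(solve_with_T(Tf), solve_with_T(Tm), tolerance = 1e-10)
    expect_equal(solve_with_T(Tm), solve_sqe(mol, p)$q, tolerance = 1e-10)
  }
})

test_that("solver failure modes are typed and informative", {
  dia <- make_diatomic()
  p <- charge_params("sqe", "plain",
                     tibble::tibble(type = "C", chi = 2, eta = 1),
                     tibble::tibble(type_a = "C", type_b = "C", order = 1L,
                                    kappa = 1))
  expect_error(solve_sqe(dia, p), "unparameterized.*O",
               class = "sqecharge_unparameterized")

  # eta1 + eta2 - 2/r + kappa = 0 makes the bond system singular
  psing <- diatomic_params(eta = c(1, 1), kappa = 0)
  expect_error(solve_sqe(make_diatomic(r = 1), psing),
               class = "sqecharge_numerical_failure")

  coincident <- make_diatomic()
  coincident$atoms[[1]]$x <- c(0, 0)
  coincident <- molecule_table("bad", coincident$atoms,
                               list(tibble::tibble(i = integer(),
                                                   j = integer(),
                                                   order = integer())))
  expect_error(hardness_matrix(coincident, diatomic_params()),
               class = "sqecharge_degenerate_geometry")
})

test_that("compute_charges returns an aligned tidy table with split-charges", {
  mols <- tiny_dataset(10, seed = 71)
  reg <- build_registry(mols, "hbo")
  p <- example_params(reg, "sqe")
  ch <- compute_charges(mols, p)
  expect_identical(nrow(ch), sum(mols$n_atoms))
  expect_identical(unique(ch$molecule), mols$name)
  qsp <- attr(ch, "split_charges")
  expect_identical(length(qsp), sum(mols$n_bonds > 0))
  # per-molecule equality with the single-molecule solver
  for (k in c(1, 5, 10)) {
    expect_equal(ch$charge[ch$molecule == mols$name[k]],
                 solve_sqe(mols[k, ], p)$q)
  }
})
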