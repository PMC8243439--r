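# Shared fixtures and independent oracles used across the suite.

make_water <- function() {
  molecule_table(
    "water",
    list(tibble::tibble(element = c("O", "H", "H"),
                        x = c(0, 0.9572, -0.2399),
                        y = c(0, 0, 0.9266), z = 0,
                        formal_charge = 0L)),
    list(tibble::tibble(i = c(1L, 1L), j = c(2L, 3L), order = 1L))
  )
}

# diatomic C-O at distance r along x, with optional formal charges
make_diatomic <- function(r = 1, fc = c(0L, 0L)) {
  molecule_table(
    "dia",
    list(tibble::tibble(element = c("C", "O"), x = c(0, r), y = 0, z = 0,
                        formal_charge = as.integer(fc))),
    list(tibble::tibble(i = 1L, j = 2L, order = 1L))
  )
}

diatomic_params <- function(method = "sqe", chi = c(2, 1), eta = c(1, 1),
                            kappa = 1, qp = NULL) {
  at <- tibble::tibble(type = c("C", "O"), chi = chi, eta = eta)
  if (!is.null(qp)) at$qp <- qp
  charge_params(method, "plain", at,
                tibble::tibble(type_a = "C", type_b = "O", order = 1L,
                               kappa = kappa))
}

# small random dataset for property tests
tiny_dataset <- function(n = 20, seed = 1, atom_range = c(3, 7),
                         charged_fraction = 0.3) {
  generate_molecules(fixture_spec(n_molecules = n, atom_range = atom_range,
                                  charged_fraction = charged_fraction,
                                  seed = seed))
}

# Energy of a split-charge vector under the SQE-family model; its free
# minimizer must coincide with the linear-system solution. q0 enters
# through the charged-reference coupling -(eta*q0)'(q - q0).
sqe_energy <- function(q_sp, Tm, H, kappa, chi, eta, q0) {
  q <- drop(crossprod(Tm, q_sp)) + q0
  -sum(chi * q) + 0.5 * drop(t(q) %*% H %*% q) + 0.5 * sum(kappa * q_sp^2) -
    sum((eta * q0) * (q - q0))
}

# Numerical minimization oracle for the SQE family. Returns q_sp.
sqe_energy_oracle <- function(mol, params, method) {
  cm <- sqecharge:::compile_molecule(mol, params$classifier)
  lk <- sqecharge:::param_atom_lookup(params)
  lkb <- sqecharge:::param_bond_lookup(params)
  chi <- unname(lk$chi[cm$atom_type])
  eta <- unname(lk$eta[cm$atom_type])
  H <- sqecharge:::hmatrix_from_parts(cm$inv_dist, eta)
  kappa <- unname(lkb[cm$bond_lab])
  q0 <- switch(method,
               "sqe" = rep(0, cm$n),
               "sqe+q0" = cm$q0,
               "sqe+qp" = normalize_qp(unname(lk$qp[cm$atom_type]), cm$Q))
  fit <- optim(rep(0, nrow(cm$Tm)), sqe_energy, Tm = cm$Tm, H = H,
               kappa = kappa, chi = chi, eta = eta, q0 = q0,
               method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  fit$par
}

# Constrained-minimization oracle for the equalization methods: eliminate
# the last charge through the total-charge constraint and minimize the
# reduced energy numerically.
ee_energy_oracle <- function(mol, params, method) {
  cm <- sqecharge:::compile_molecule(mol, params$classifier)
  lk <- sqecharge:::param_atom_lookup(params)
  chi <- unname(lk$chi[cm$atom_type])
  eta <- unname(lk$eta[cm$atom_type])
  H <- sqecharge:::hmatrix_from_parts(cm$inv_dist, eta)
  q0 <- cm$q0
  energy <- function(q) {
    base <- sum(chi * q) + 0.5 * drop(t(q) %*% H %*% q)
    if (method == "eqeq") base <- base - sum((eta * q0) * q)
    base
  }
  n <- cm$n
  reduced <- function(qf) {
    q <- c(qf, cm$Q - sum(qf))
    energy(q)
  }
  if (n == 1) return(cm$Q)
  fit <- optim(rep(0, n - 1), reduced, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-14))
  c(fit$par, cm$Q - sum(fit$par))
}

solve_one_method <- function(mol, p, m) {
  switch(m,
         eem = solve_eem(mol, p), qeq = solve_qeq(mol, p),
         eqeq = solve_eqeq(mol, p), sqe = solve_sqe(mol, p),
         "sqe+q0" = solve_sqe_q0(mol, p), "sqe+qp" = solve_sqe_qp(mol, p))$q
}

# rigid-body transform: rotate by Euler angles and translate
transform_molecule <- function(mol, angles = c(0.3, -1.1, 2.0),
                               shift = c(5, -3, 2)) {
  rot <- function(a, axis) {
    c1 <- cos(a); s1 <- sin(a)
    switch(axis,
           x = matrix(c(1, 0, 0, 0, c1, -s1, 0, s1, c1), 3, byrow = TRUE),
           y = matrix(c(c1, 0, s1, 0, 1, 0, -s1, 0, c1), 3, byrow = TRUE),
           z = matrix(c(c1, -s1, 0, s1, c1, 0, 0, 0, 1), 3, byrow = TRUE))
  }
  R <- rot(angles[1], "x") %*% rot(angles[2], "y") %*% rot(angles[3], "z")
  a <- mol$atoms[[1]]
  xyz <- t(R %*% t(cbind(a$x, a$y, a$z))) +
    matrix(shift, nrow(a), 3, byrow = TRUE)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  mol$atoms[[1]] <- a
  mol
}

# permute the atoms of a one-row molecule table with permutation perm
# (new index k holds old atom perm[k])
permute_molecule <- function(mol, perm) {
  inv <- order(perm)
  a <- mol$atoms[[1]][perm, ]
  b <- mol$bonds[[1]]
  b$i <- inv[b$i]; b$j <- inv[b$j]
  molecule_table(mol$name, list(a), list(b))
}
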