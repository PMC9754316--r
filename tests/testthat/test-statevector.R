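# Statevector gates and Jordan-Wigner RDM measurement, checked against dense
# operator oracles built independently from kronecker products.

test_that("HF reference state occupies the first qubits", {
  st <- hf_state(6, 2)
  amps <- unclass(st)
  expect_equal(which(amps != 0), 3 + 1)  # bits 0,1 set
  expect_equal(sum(Mod(amps)^2), 1)
  expect_equal(occupation_expectation(st), 2, tolerance = 1e-12)
  st0 <- hf_state(4, 0)
  expect_equal(which(unclass(st0) != 0), 1)
  expect_error(hf_state(4, 5), "range")
})

test_that("excitation gates rotate only their occupation subspace", {
  st <- hf_state(4, 2)
  g0 <- excitation("single", c(0, 2), 0)
  expect_equal(unclass(apply_excitation(st, g0)), unclass(st))
  # theta = pi maps |10> to -|01| on the wire pair
  gpi <- excitation("single", c(0, 2), pi)
  out <- unclass(apply_excitation(st, gpi))
  expect_equal(out[6 + 1], -1 + 0i)  # bits 1,2: qubit1 untouched, qubit0 -> qubit2
  expect_error(excitation("single", c(1, 1)), "repeated")
  expect_error(excitation("double", c(0, 1, 2)), "wire count")
  expect_error(apply_excitation(st, excitation("single", c(0, 9))), "register")

  gd <- excitation("double", c(0, 1, 2, 3), pi)
  outd <- unclass(apply_excitation(st, gd))
  expect_equal(outd[12 + 1], -1 + 0i)  # bits 2,3
})

test_that("particle number and norm are conserved on random circuits", {
  set.seed(42)
  for (trial in 1:25) {
    ne <- sample(c(2, 4), 1)
    st <- random_ansatz_state(8, ne, n_gates = 8, seed = trial)
    expect_equal(sum(Mod(unclass(st))^2), 1, tolerance = 1e-12)
    expect_equal(occupation_expectation(st), ne, tolerance = 1e-10)
    # every nonzero amplitude sits in the fixed-particle-number sector
    nz <- which(Mod(unclass(st)) > 1e-14) - 1
    pops <- vapply(nz, function(i)
      sum(bitwAnd(bitwShiftR(i, 0:7), 1L)), 0)
    expect_true(all(pops == ne))
  }
})

test_that("adjacent-wire gates equal the exponential of the JW generator", {
  # single excitation on adjacent wires (2,3) of a 4-qubit register
  theta <- 0.8123
  nq <- 4
  # gate on wires (occupied 3, virtual 2): generator (a+_3 a_2 - a+_2 a_3)/2
  ad <- jw_dense_ladder(3, nq, dagger = TRUE) %*% jw_dense_ladder(2, nq)
  gen <- (theta / 2) * (ad - Conj(t(ad)))
  U_ref <- dense_expm(gen)
  # column-by-column action of the gate
  U_gate <- matrix(0 + 0i, 16, 16)
  for (col in 1:16) {
    e <- complex(16); e[col] <- 1
    st <- structure(e, n_qubits = nq, class = "solvqe_state")
    U_gate[, col] <- unclass(apply_excitation(
      st, excitation("single", c(3, 2), theta)))
  }
  expect_lt(max(Mod(U_gate - U_ref)), 1e-10)

  # double excitation on wires (0,1,2,3)
  ad2 <- jw_dense_ladder(3, nq, dagger = TRUE) %*%
         jw_dense_ladder(2, nq, dagger = TRUE) %*%
         jw_dense_ladder(1, nq) %*% jw_dense_ladder(0, nq)
  gen2 <- (theta / 2) * (ad2 - Conj(t(ad2)))
  U_ref2 <- dense_expm(gen2)
  U_gate2 <- matrix(0 + 0i, 16, 16)
  for (col in 1:16) {
    e <- complex(16); e[col] <- 1
    st <- structure(e, n_qubits = nq, class = "solvqe_state")
    U_gate2[, col] <- unclass(apply_excitation(
      st, excitation("double", c(0, 1, 2, 3), theta)))
  }
  expect_lt(max(Mod(U_gate2 - U_ref2)), 1e-10)
})

test_that("measured RDMs match the dense JW oracle and their identities", {
  st <- hf_state(6, 4)
  r <- measure_rdms(st, 3)
  expect_equal(r$gamma, diag(c(2, 2, 0)), tolerance = 1e-12)
  expect_error(measure_rdms(structure(complex(8), n_qubits = 3,
                                      class = "solvqe_state")), "odd")

  for (seed in 1:3) {
    st <- random_ansatz_state(6, 2, n_gates = 5, seed = seed)
    r <- measure_rdms(st, 3)
    # Hermiticity and positive semidefiniteness of gamma
    expect_equal(r$gamma, t(r$gamma), tolerance = 1e-12)
    expect_gt(min(eigen(r$gamma, symmetric = TRUE, only.values = TRUE)$values),
              -1e-12)
    expect_equal(sum(diag(r$gamma)), 2, tolerance = 1e-10)
    # contraction identity (chemists' index order): sum_r Gamma_pqrr =
    # (N - 1) gamma_pq
    contr <- apply(r$Gamma, c(1, 2), function(x) sum(diag(x)))
    expect_equal(contr, (2 - 1) * r$gamma, tolerance = 1e-8)
    # entrywise agreement with the dense kronecker oracle
    v <- unclass(st)
    for (pq in list(c(0, 0), c(0, 2), c(1, 2))) {
      Em <- jw_dense_epq(pq[1], pq[2], 3)
      expect_equal(r$gamma[pq[1] + 1, pq[2] + 1],
                   Re(Conj(v) %*% Em %*% v)[1], tolerance = 1e-10)
    }
  }
})

test_that("RDM energies equal dense-Hamiltonian expectations", {
  p <- h3plus_problem()
  H <- cached("h3plus_dense_H", jw_dense_hamiltonian(p$active))
  for (seed in 1:3) {
    st <- random_ansatz_state(6, 2, n_gates = 4, seed = seed)
    r <- measure_rdms(st, 3)
    e_rdm <- p$active$E_offset + sum(p$active$h * r$gamma) +
      0.5 * sum(p$active$g * r$Gamma)
    v <- unclass(st)
    e_dense <- Re(Conj(v) %*% H %*% v)[1] + p$active$E_offset
    expect_equal(e_rdm, e_dense, tolerance = 1e-10)
  }
})
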