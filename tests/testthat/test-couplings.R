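# Solute-solvent coupling matrices and the non-linear free-energy functional.

test_that("static charges and W_NN behave as a negative-semidefinite response", {
  p <- h3plus_problem()
  st <- static_asc(p$active$v_static, p$Q)
  expect_equal(static_asc(0 * p$active$v_static, p$Q)$W_NN, 0)
  expect_lt(st$W_NN, 0)
  # lone-sphere Born case: 1/2 W_NN within 2% of the analytic energy
  g <- geometry("H", matrix(0, 1, 3))
  cav <- build_cavity(g, solvent_params(epsilon = 78.39, tess_level = 3))
  sda <- build_SDA(cav)
  Q <- response_matrix(sda$S, sda$D, sda$A, 78.39)
  v <- nuclear_potential(g, cav$centers)
  born <- -(1 - 1 / 78.39) / (2 * cav$sphere_radii[1])
  expect_equal(0.5 * static_asc(v, Q)$W_NN, born, tolerance = 0.02 * abs(born))
})

test_that("one-body couplings: j equals y under the symmetrized response", {
  p <- h3plus_problem()
  cp <- p$couplings
  ob <- one_body_couplings(p$active$K, cp$q_static, p$active$v_static, p$Q)
  expect_equal(ob$j, ob$y, tolerance = 1e-10)
  expect_equal(ob$j, t(ob$j), tolerance = 1e-12)
  # brute-force loop over tesserae
  n <- dim(p$active$K)[1]
  j_ref <- matrix(0, n, n)
  for (i in seq_len(p$cavity$n_tess))
    j_ref <- j_ref + p$active$K[, , i] * cp$q_static[i]
  expect_equal(ob$j, j_ref, tolerance = 1e-12)
  # vacuum: zero couplings
  Q0 <- matrix(0, p$cavity$n_tess, p$cavity$n_tess)
  ob0 <- one_body_couplings(p$active$K, rep(0, p$cavity$n_tess),
                            p$active$v_static, Q0)
  expect_equal(ob0$j, matrix(0, n, n))
  expect_equal(ob0$y, matrix(0, n, n))
})

test_that("electronic apparent charges are linear and obey Gauss's law", {
  p <- h3plus_problem()
  fci <- cached("h3plus_fci_gas", run_fci(p$active))
  gam <- fci$rdms$gamma
  el <- electronic_asc(gam, p$active$K, p$Q)
  expect_equal(electronic_asc(0 * gam, p$active$K, p$Q)$q_el,
               rep(0, p$cavity$n_tess))
  expect_equal(electronic_asc(2 * gam, p$active$K, p$Q)$q_el, 2 * el$q_el,
               tolerance = 1e-12)
  # induced charge opposes the -2 electronic charge
  expect_equal(sum(el$q_el), 2 * (46.7 - 1) / 46.7, tolerance = 0.02 * 2)
})

test_that("free energy functional: identities, guards and variational bounds", {
  p <- h3plus_problem()
  fci <- cached("h3plus_fci_gas", run_fci(p$active))
  # epsilon = 1: G equals the gas expectation exactly
  vac <- solvent_couplings(p$active, NULL)
  fe_vac <- free_energy(fci$rdms, p$active, vac)
  expect_equal(fe_vac$G, fci$energy, tolerance = 1e-10)
  # internal identity G = E_gas + U_int/2
  fe <- free_energy(fci$rdms, p$active, p$couplings)
  expect_equal(fe$G, fe$E_gas + 0.5 * fe$U_int, tolerance = 1e-12)
  expect_lt(fe$U_int, 0)
  # trace guard
  bad <- fci$rdms; bad$gamma <- bad$gamma * 1.01
  expect_error(free_energy(bad, p$active, p$couplings), "trace")
  expect_silent(free_energy(bad, p$active, p$couplings, check_trace = FALSE))
  # solvated optimum below the gas-density value of the same functional
  sc <- cached("h3plus_fci_sc",
               run_fci(p$active, pcm = "self_consistent",
                       couplings = p$couplings))
  expect_lte(sc$energy, fe$G + 1e-10)
  # U_pol and the variational bound Delta <= U_pol
  U <- polarization_energy(fci$rdms$gamma, p$active, p$couplings)
  expect_lte(U, 0)
  delta_ha <- sc$energy - fci$energy
  expect_lte(delta_ha, U + 1e-8)
  expect_equal(solvation_free_energy(fci$energy, fci$energy), 0)
  expect_equal(solvation_free_energy(fci$energy - 1, fci$energy),
               -27.211386)
})

test_that("operator and functional routes to the coupling energy coincide", {
  p <- h3plus_problem()
  fci <- cached("h3plus_fci_gas", run_fci(p$active))
  gam <- fci$rdms$gamma
  fe <- free_energy(fci$rdms, p$active, p$couplings)
  # assemble the effective one-body solvent operator at this density and
  # contract: u_pq gamma_pq - e-e quadratic = linear coupling + 2x quadratic
  n <- p$active$n_active
  Km <- matrix(p$active$K, n * n, p$cavity$n_tess)
  u <- matrix(Km %*% fe$q_total, n, n)
  el <- electronic_asc(gam, p$active$K, p$Q)
  coupling_from_operator <- sum(u * gam)
  coupling_from_functional <- sum(p$couplings$j * gam) +
    sum(el$v_el * apply_response(p$Q, el$v_el))
  expect_equal(coupling_from_operator, coupling_from_functional,
               tolerance = 1e-12)
})

test_that("free energy is non-increasing in the dielectric constant", {
  p <- h3plus_problem()
  fci <- cached("h3plus_fci_gas", run_fci(p$active))
  sda <- cached("h3plus_sda", build_SDA(p$cavity))
  Gs <- vapply(c(1, 2, 10, 46.7, 78.39), function(eps) {
    Q <- response_matrix(sda$S, sda$D, sda$A, eps)
    cp <- solvent_couplings(p$active, Q)
    free_energy(fci$rdms, p$active, cp)$G
  }, 0)
  expect_true(all(diff(Gs) < 1e-10))
})
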