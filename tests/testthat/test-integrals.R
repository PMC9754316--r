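# Gaussian-basis construction and the integral engine, checked against
# permutational symmetries, a textbook benchmark, a brute-force quadrature
# oracle, and rigid-motion invariance.

test_that("STO-3G basis has the minimal-basis structure and unit norms", {
  h <- build_basis(molecule_fixture("h2", r = 0.7))
  expect_equal(h$n_ao, 2)
  expect_equal(diff(h$prim_ptr), c(3L, 3L))

  w <- build_basis(molecule_fixture("h2o"))
  expect_equal(w$n_ao, 7)  # O 1s,2s,2p x3 + 2 H 1s

  S <- core_integrals(w)$overlap
  expect_equal(diag(S), rep(1, 7), tolerance = 1e-10)
  expect_error(build_basis(molecule_fixture("h2"), "cc-pVDZ"), "unsupported")
})

test_that("core integrals reproduce the standard H2/STO-3G benchmark", {
  # R = 1.4 bohr; reference values from the classic closed-shell HF
  # worked example (overlap 0.6593, kinetic 0.7600/0.2365, (11|11) 0.7746,
  # E_RHF = -1.1167 Ha)
  g <- molecule_fixture("h2", r = 1.4 / 1.8897259886)
  core <- core_integrals(build_basis(g), g)
  expect_equal(core$overlap[1, 2], 0.6593, tolerance = 2e-4)
  expect_equal(core$kinetic[1, 1], 0.7600, tolerance = 2e-4)
  expect_equal(core$kinetic[1, 2], 0.2365, tolerance = 2e-4)
  expect_equal(core$eri[1, 1, 1, 1], 0.7746, tolerance = 2e-4)
  expect_equal(core$eri[1, 1, 2, 2], 0.5697, tolerance = 2e-4)
  expect_equal(core$E_nn, 1 / 1.4, tolerance = 1e-12)
  scf <- run_hf(core, 2)
  expect_equal(scf$E_total, -1.1167, tolerance = 2e-4)
})

test_that("ERIs obey all eight permutational symmetries", {
  core <- cached("h2o_core", {
    g <- molecule_fixture("h2o")
    core_integrals(build_basis(g), g)
  })
  e <- core$eri
  n <- dim(e)[1]
  set.seed(1)
  for (k in 1:50) {
    ix <- sample(n, 4, replace = TRUE)
    p <- ix[1]; q <- ix[2]; r <- ix[3]; s <- ix[4]
    v <- e[p, q, r, s]
    expect_equal(e[q, p, r, s], v, tolerance = 1e-12)
    expect_equal(e[p, q, s, r], v, tolerance = 1e-12)
    expect_equal(e[r, s, p, q], v, tolerance = 1e-12)
    expect_equal(e[s, r, q, p], v, tolerance = 1e-12)
  }
  # one-atom nuclear attraction strictly negative on the diagonal
  ga <- geometry("O", matrix(0, 1, 3))
  ca <- core_integrals(build_basis(ga), ga)
  expect_true(all(diag(ca$nuclear_attraction) < 0))
  # coincident nuclei
  expect_error(core_integrals(build_basis(molecule_fixture("h2", r = 0)),
                              molecule_fixture("h2", r = 0)),
               "coincident")
})

test_that("potential integrals match quadrature, symmetry and the monopole limit", {
  g <- molecule_fixture("h2", r = 0.74)
  b <- build_basis(g)
  pts <- rbind(c(0, 0, 5), c(8.0, 3.0, -4.0), c(0, 0, 20))
  K <- electronic_potential_integrals(b, pts)
  expect_equal(K[1, 2, 1], K[2, 1, 1], tolerance = 1e-14)
  # monopole limit: normalized s function seen from 20 bohr
  d <- sqrt(sum((pts[3, ] - b$ao_center[1, ])^2))
  expect_equal(K[1, 1, 3], -1 / d, tolerance = 1e-6)
  # brute-force quadrature oracle on the 2-AO system (evaluation point kept
  # outside the integration cube so the midpoint rule stays smooth)
  for (idx in list(c(1, 1), c(1, 2), c(2, 2))) {
    ref <- quadrature_esp(b, idx[1], idx[2], pts[2, ], L = 13, n = 130)
    expect_lt(abs(K[idx[1], idx[2], 2] - (-ref)), 1e-6)
  }
})

test_that("nuclear potential is additive, positive, and guards nuclei", {
  g <- molecule_fixture("h3plus", r = 0.9)
  pts <- rbind(c(0, 0, 4), c(3, 3, 3))
  v <- nuclear_potential(g, pts)
  expect_true(all(v > 0))
  g1 <- geometry("H", matrix(c(0, 0, 0), 1, 3))
  expect_equal(nuclear_potential(g1, matrix(c(0, 0, 2), 1, 3)), 0.5)
  v_sum <- 0
  for (i in 1:3) {
    gi <- geometry("H", coords_angstrom(g)[i, , drop = FALSE], net_charge = 0)
    v_sum <- v_sum + nuclear_potential(gi, pts)
  }
  expect_equal(v, v_sum, tolerance = 1e-12)
  expect_error(nuclear_potential(g1, matrix(0, 1, 3)), "nucleus")
})

test_that("gas-phase energies are invariant under rigid motions", {
  fci0 <- solvqe:::.template_energy("h2o", c(1.028, 96.8))
  # translate + rotate the same geometry
  xyz <- coords_angstrom(molecule_fixture("h2o", r = 1.028, angle = 96.8))
  th <- 0.7; R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  xyz2 <- sweep(xyz %*% R, 2, c(1.3, -0.4, 2.2), `+`)
  g2 <- geometry(c("O", "H", "H"), xyz2)
  core2 <- core_integrals(build_basis(g2), g2)
  scf2 <- run_hf(core2, 10)
  fci2 <- run_fci(active_space_transform(core2, scf2))
  expect_equal(fci2$energy, fci0, tolerance = 1e-9)
})
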