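# End-to-end drivers: gas VQE vs exact diagonalization, the self-consistent
# solvated loop, rigid vs relaxed continuum coupling, and the CLI layer.

test_that("H2 gas VQE equals dense diagonalization", {
  g <- cached("h2_geom", optimize_geometry("h2"))
  fit <- run_vqe_gas(run_config(g))
  p <- fit$problem
  H <- jw_dense_hamiltonian(p$active)
  e_exact <- min(eigen(H, symmetric = TRUE, only.values = TRUE)$values) +
    p$active$E_offset
  expect_equal(fit$energy, e_exact, tolerance = 1e-9)
  fci <- run_fci(p$active)
  expect_equal(fci$energy, e_exact, tolerance = 1e-9)
})

test_that("solvated runs reduce to gas runs in the vacuum limit", {
  g <- cached("h2_geom", optimize_geometry("h2"))
  gas <- run_vqe_gas(run_config(g))
  vac <- run_pcm_vqe(run_config(g, solvent = solvent_params(epsilon = 1,
                                                            tess_level = 2)))
  expect_equal(vac$energy, gas$energy, tolerance = 1e-10)
})

test_that("the solvated optimum is a fixed point of the outer loop", {
  fit <- cached("h3plus_pcm_fit",
                run_pcm_vqe(run_config(h3plus_geom(),
                                       solvent = solvent_params(epsilon = 46.7))))
  p <- fit$problem
  cost <- solvqe:::.make_cost(p, solvated = TRUE)
  restart <- optimize_circuit(function(th) cost(fit$ansatz$gates, th),
                              fit$theta)
  # stationary to the outer-loop tolerance (1e-8 Ha)
  expect_lt(abs(restart$value - fit$energy), 1e-8)
  expect_true(fit$converged)
})

test_that("rigid and self-consistent continuum couplings are ordered", {
  p <- h3plus_problem()
  gas <- cached("h3plus_fci_gas", run_fci(p$active))
  rig <- run_fci(p$active, pcm = "rigid", couplings = p$couplings)
  sc <- cached("h3plus_fci_sc",
               run_fci(p$active, pcm = "self_consistent",
                       couplings = p$couplings))
  expect_lte(sc$energy, rig$energy + 1e-10)  # variational relaxation
  expect_lt(rig$energy, gas$energy)          # polarization stabilizes
  expect_equal(rig$energy,
               gas$energy + polarization_energy(gas$rdms$gamma, p$active,
                                                p$couplings),
               tolerance = 1e-12)
  expect_error(run_fci(p$active, pcm = "rigid"), "couplings")
})

test_that("outer loop converges promptly for the charged solute", {
  fit <- cached("h3plus_pcm_fit",
                run_pcm_vqe(run_config(h3plus_geom(),
                                       solvent = solvent_params(epsilon = 46.7))))
  # soft plausibility bound on self-consistent iterations
  expect_lte(max(fit$history$iteration), 60)
  expect_lt(fit$delta_solv_ev, -3)  # strongly stabilized cation
})

test_that("JSON reports carry the provenance fields", {
  fit <- cached("h3plus_pcm_fit",
                run_pcm_vqe(run_config(h3plus_geom(),
                                       solvent = solvent_params(epsilon = 46.7))))
  txt <- write_report(fit)
  rep <- jsonlite::fromJSON(txt)
  expect_equal(rep$G, fit$report$G)
  expect_equal(rep$solvent$epsilon, 46.7)
  expect_equal(rep$cavity$n_tess, fit$problem$cavity$n_tess)
  expect_equal(rep$delta_solv_ev,
               27.211386 * (rep$G - rep$E_gas_vqe), tolerance = 1e-8)
})

test_that("the command line interface runs, reports, and rejects bad input", {
  expect_equal(as.integer(cli(c("frobnicate"))), 1L)
  expect_equal(as.integer(cli(character(0))), 2L)
  out <- tempfile(fileext = ".json")
  code <- suppressMessages(cli(c("solvate", "--geometry", "h2",
                                 "--tess-level", "2", "--seed", "3",
                                 "--out", out)))
  expect_equal(as.integer(code), 0L)
  rep <- jsonlite::fromJSON(out)
  expect_equal(rep$delta_solv_ev,
               27.211386 * (rep$G - rep$E_gas_vqe), tolerance = 1e-8)
  # identical seeds give byte-identical reports
  out2 <- tempfile(fileext = ".json")
  suppressMessages(cli(c("solvate", "--geometry", "h2", "--tess-level", "2",
                         "--seed", "3", "--out", out2)))
  expect_identical(readLines(out), readLines(out2))
})
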