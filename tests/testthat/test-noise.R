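# Shot sampling, depolarizing/readout channels, error propagation, and the
# RDM diagnostics used by the noisy estimation pipeline.

test_that("sample_pauli is exact on eigenstates and unbiased elsewhere", {
  st <- hf_state(2, 0)  # |00>
  expect_equal(sample_pauli(st, "ZI", shots = 17)$mean, 1)
  expect_equal(sample_pauli(st, "II", shots = 5)$sigma_bound, 0)
  expect_equal(sample_pauli(st, "II", shots = 5)$mean, 1)
  set.seed(11)
  m <- sample_pauli(st, "XI", shots = 1e5)$mean
  expect_lt(abs(m), 5 / sqrt(1e5))
  expect_error(sample_pauli(st, "QI"), "invalid")
  expect_error(sample_pauli(st, "XI", shots = 0), "shots")

  # unbiasedness: mean over 200 seeded repeats within 4 sigma of truth
  plus_ish <- structure(c(sqrt(0.7), sqrt(0.3)) + 0i, n_qubits = 1,
                        class = "solvqe_state")
  truth <- sum(Mod(unclass(plus_ish))^2 * c(1, -1))  # <Z> = 0.4
  set.seed(5)
  reps <- replicate(200, sample_pauli(plus_ish, "Z", shots = 256)$mean)
  se <- 1 / sqrt(256 * 200)
  expect_lt(abs(mean(reps) - truth), 4 * se)
  # single-shot variance bounded by 1
  expect_lte(stats::var(reps) * 256, 1.1)
})

test_that("noise channels reduce to the pure state and to full mixing", {
  cand <- excitation_candidates(4, 2)
  gates <- list(cand$doubles[[1]])
  gates[[1]]$theta <- 0.6
  rho0 <- simulate_noisy_circuit(4, 2, gates, noise = noise_model(0, 0, 0))
  st <- apply_ansatz(hf_state(4, 2), gates)
  expect_lt(max(Mod(rho0 - unclass(st) %o% Conj(unclass(st)))), 1e-12)

  # full single-qubit depolarizing on a 1-qubit circuit kills every Pauli
  rho1 <- simulate_noisy_circuit(1, 1, list(), noise = noise_model(p1 = 1))
  for (pstr in c("X", "Y", "Z"))
    expect_lt(abs(sample_pauli(rho1, pstr, shots = Inf)$mean), 1e-12)
  expect_equal(Re(sum(diag(rho1))), 1, tolerance = 1e-12)
})

test_that("depolarizing noise biases the variational energy upward", {
  p <- h3plus_problem()
  fit <- cached("h3plus_gas_fit", run_vqe_gas(run_config(h3plus_geom())))
  rho <- simulate_noisy_circuit(p$n_qubits, p$n_electrons, fit$ansatz$gates,
                                fit$theta, noise_model(0.002, 0.02, 0))
  meas <- solvqe:::.measure_rdms_sampled(rho, 3, shots = Inf, p_readout = 0)
  e_noisy <- p$active$E_offset + sum(p$active$h * meas$gamma) +
    0.5 * sum(p$active$g * meas$Gamma)
  expect_gt(e_noisy, fit$energy)
})

test_that("error propagation follows the per-string upper bound", {
  expect_equal(propagate_error_bars(0.5, 8192), 0.5 / sqrt(8192))
  cs <- c(0.2, -0.4, 0.1)
  expect_equal(propagate_error_bars(cs, 100),
               sqrt(sum(cs^2)) / 10, tolerance = 1e-14)
  expect_equal(propagate_error_bars(sample(cs), 100),
               propagate_error_bars(cs, 100))
  expect_lt(propagate_error_bars(cs, 1e8), 1e-4)
  expect_error(propagate_error_bars(cs, 0), "positive")
})

test_that("trace normalization rescales without touching eigenvectors", {
  g <- matrix(c(1.8, 0.05, 0.05, 0.1), 2)
  gn <- normalize_rdm_trace(g, 2)
  expect_equal(sum(diag(gn)), 2, tolerance = 1e-14)
  expect_equal(gn, g * (2 / 1.9), tolerance = 1e-14)
  expect_equal(normalize_rdm_trace(gn, 2), gn)  # idempotent
  expect_equal(eigen(gn)$vectors, eigen(g)$vectors, tolerance = 1e-12)
  expect_error(normalize_rdm_trace(-g, 2), "trace")
})

test_that("trace distance is a normalized metric on 1-RDMs", {
  a <- diag(c(2, 0)); b <- diag(c(0, 2))
  expect_equal(trace_distance_rdm(a, a, 2)$D, 0)
  expect_equal(trace_distance_rdm(a, b, 2)$D, 1)
  expect_equal(trace_distance_rdm(a, b, 2)$D, trace_distance_rdm(b, a, 2)$D)
  expect_error(trace_distance_rdm(a, diag(3), 2), "mismatch")
})

test_that("1-RDM observables need strictly fewer Pauli strings than the
           full Hamiltonian", {
  n1 <- length(required_pauli_strings(3, "rdm1"))
  nf <- length(required_pauli_strings(3, "full"))
  expect_lt(n1, nf)
  expect_gt(n1, 0)
})

test_that("noisy-vs-exact trace distance shrinks as the noise is dialed down", {
  fit <- cached("h3plus_gas_fit", run_vqe_gas(run_config(h3plus_geom())))
  p <- fit$problem
  exact <- fit$rdms$gamma
  Ds <- vapply(c(1, 0.3, 0.05, 0), function(f) {
    rho <- simulate_noisy_circuit(p$n_qubits, p$n_electrons,
                                  fit$ansatz$gates, fit$theta,
                                  noise_model(0.004 * f, 0.04 * f, 0.02 * f))
    meas <- solvqe:::.measure_rdms_sampled(rho, 3, shots = Inf,
                                           p_readout = 0.02 * f)
    trace_distance_rdm(normalize_rdm_trace(meas$gamma, 2), exact, 2)$D
  }, 0)
  expect_true(all(diff(Ds) < 0))
  expect_lt(Ds[4], 1e-10)
})

test_that("paired noisy runs favor the 1-RDM polarization shortcut", {
  wins <- 0L; n_rep <- 3L
  for (seed in seq_len(n_rep)) {
    rep <- noisy_rep(seed)
    err_delta <- abs(rep$delta_solv_ev - rep$delta_exact_ev)
    err_upol <- abs(rep$U_pol_ev - rep$U_pol_exact_ev)
    if (err_upol <= err_delta) wins <- wins + 1L
    expect_gte(rep$trace_distance_gas$D, 0)
    expect_lte(rep$trace_distance_gas$D, 1)
  }
  expect_gt(wins, n_rep / 2)
})

test_that("the zero-noise infinite-shot experiment reproduces the exact
           solvation free energy", {
  rep <- noisy_solvation_experiment("h3plus", noise = noise_model(0, 0, 0),
                                    shots = Inf, seed = 2, max_iter = 150,
                                    window = 40)
  expect_equal(rep$delta_solv_ev, rep$delta_exact_ev, tolerance = 0.08)
  expect_equal(rep$U_pol_ev, rep$U_pol_exact_ev, tolerance = 0.02)
})
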