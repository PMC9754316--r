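# Adaptive ansatz construction and the circuit optimizers.

test_that("candidate pools conserve S_z and respect occupation", {
  cand <- excitation_candidates(6, 2)
  expect_equal(length(cand$doubles), 4)
  expect_equal(length(cand$singles), 4)
  spin <- function(k) k %% 2
  for (g in cand$doubles) {
    w <- g$wires
    expect_true(all(w[1:2] < 2) && all(w[3:4] >= 2))
    expect_equal(spin(w[1]) + spin(w[2]), spin(w[3]) + spin(w[4]))
  }
})

test_that("adaptive selection on H3+ retains exactly two doubles,
           stably across thresholds", {
  p <- h3plus_problem()
  cost <- solvqe:::.make_cost(p, solvated = FALSE)
  cand <- excitation_candidates(p$n_qubits, p$n_electrons)
  counts <- vapply(c(1e-8, 1e-5, 1e-3), function(thr) {
    a <- adaptive_select(cost, cand, threshold = thr)
    expect_equal(a$n_singles, 0)
    length(a$gates)
  }, 0)
  expect_equal(counts, c(2, 2, 2))
  # an infinite threshold keeps nothing
  a_inf <- adaptive_select(cost, cand, threshold = Inf)
  expect_equal(length(a_inf$gates), 0)
  expect_error(adaptive_select(cost, list(doubles = list(), singles = list())),
               "empty")
})

test_that("retained set is invariant under candidate-pool ordering", {
  p <- h3plus_problem()
  cost <- solvqe:::.make_cost(p, solvated = FALSE)
  cand <- excitation_candidates(p$n_qubits, p$n_electrons)
  a1 <- adaptive_select(cost, cand, threshold = 1e-5)
  cand2 <- cand
  set.seed(9)
  perm <- sample(length(cand$doubles))
  cand2$doubles <- cand$doubles[perm]
  a2 <- adaptive_select(cost, cand2, threshold = 1e-5)
  key <- function(a) sort(vapply(a$gates, function(g)
    paste(g$wires, collapse = ","), ""))
  expect_equal(key(a1), key(a2))
})

test_that("gradient descent reaches analytic minima and never backtracks", {
  # 1-parameter quadratic toy
  opt <- optimize_circuit(function(th) (th - 0.3)^2 + 1, 0)
  expect_equal(opt$theta, 0.3, tolerance = 1e-4)
  expect_equal(opt$value, 1, tolerance = 1e-8)
  expect_true(all(diff(opt$history$cost) <= 0))
  # empty parameter vector is a no-op
  opt0 <- optimize_circuit(function(th) 2.5, numeric(0))
  expect_equal(opt0$value, 2.5)
  expect_error(optimize_circuit(function(th) NaN, 1), "non-finite")
  # derivative-free path
  optn <- optimize_circuit(function(th) sum((th - c(1, -1))^2), c(0, 0),
                           settings = list(method = "nelder_mead",
                                           max_iter = 500))
  expect_equal(optn$theta, c(1, -1), tolerance = 1e-3)
  expect_gt(nrow(optn$history), 10)
})

test_that("the two-parameter circuit reaches the H3+ FCI ground state", {
  p <- h3plus_problem()
  fci <- cached("h3plus_fci_gas", run_fci(p$active))
  fit <- cached("h3plus_gas_fit",
                run_vqe_gas(run_config(h3plus_geom())))
  expect_equal(fit$n_parameters, 2)
  expect_lt(abs(fit$energy - fci$energy), 1e-4)
  expect_gte(fit$energy, fci$energy - 1e-9)  # variational
  expect_true(all(diff(fit$history$cost) <= 0))
})
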