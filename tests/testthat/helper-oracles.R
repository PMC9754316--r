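# Independent reference implementations used as oracles, plus a cache for
# expensive fixtures shared across test files.

.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

h3plus_geom <- function() cached("h3plus_geom", optimize_geometry("h3plus"))
beh2_geom <- function() cached("beh2_geom", optimize_geometry("beh2"))
h2o_geom <- function() cached("h2o_geom", optimize_geometry("h2o"))

h3plus_problem <- function() cached("h3plus_problem",
  build_problem(h3plus_geom(), solvent = solvent_params(epsilon = 46.7)))

# ---- brute-force 3-D quadrature of int chi_p chi_q / |r - C| --------------
# midpoint rule on a cube around the charge distribution; adequate to ~1e-6
# for compact s/p products well separated from C.
quadrature_esp <- function(basis, p, q, point, L = 8, n = 120) {
  gx <- seq(-L / 2, L / 2, length.out = n + 1)
  gx <- (gx[-1] + gx[-(n + 1)]) / 2
  h3 <- (gx[2] - gx[1])^3
  ao_value <- function(i, x, y, z) {
    l <- basis$ao_l[i, ]; ctr <- basis$ao_center[i, ]
    idx <- (basis$prim_ptr[i] + 1L):basis$prim_ptr[i + 1L]
    dx <- x - ctr[1]; dy <- y - ctr[2]; dz <- z - ctr[3]
    r2 <- dx^2 + dy^2 + dz^2
    poly <- dx^l[1] * dy^l[2] * dz^l[3]
    v <- 0
    for (k in idx) v <- v + basis$prim_coef[k] * exp(-basis$prim_exp[k] * r2)
    poly * v
  }
  total <- 0
  for (xi in gx) {
    yz <- expand.grid(y = gx, z = gx)
    vals <- ao_value(p, xi, yz$y, yz$z) * ao_value(q, xi, yz$y, yz$z)
    rr <- sqrt((xi - point[1])^2 + (yz$y - point[2])^2 + (yz$z - point[3])^2)
    total <- total + sum(vals / rr)
  }
  total * h3
}

# ---- dense Jordan-Wigner operators by kronecker products ------------------
jw_dense_ladder <- function(q, n_qubits, dagger = FALSE) {
  I2 <- diag(2); Z <- diag(c(1, -1))
  op <- if (dagger) matrix(c(0, 1, 0, 0), 2)  # |1><0| (column-major)
        else matrix(c(0, 0, 1, 0), 2)         # |0><1|
  mats <- vector("list", n_qubits)
  for (k in seq_len(n_qubits) - 1L)
    mats[[k + 1]] <- if (k < q) Z else if (k == q) op else I2
  Reduce(kronecker, rev(mats))
}

jw_dense_epq <- function(p, q, n_orb) {
  nq <- 2L * n_orb
  out <- 0
  for (s in 0:1)
    out <- out + jw_dense_ladder(2 * p + s, nq, dagger = TRUE) %*%
                 jw_dense_ladder(2 * q + s, nq, dagger = FALSE)
  out
}

# dense second-quantized Hamiltonian from active-space integrals
jw_dense_hamiltonian <- function(active) {
  n <- active$n_active
  dim <- 4^n
  H <- matrix(0, dim, dim)
  E <- list()
  for (p in 0:(n - 1)) for (q in 0:(n - 1))
    E[[paste(p, q)]] <- jw_dense_epq(p, q, n)
  for (p in 0:(n - 1)) for (q in 0:(n - 1))
    H <- H + active$h[p + 1, q + 1] * E[[paste(p, q)]]
  for (p in 0:(n - 1)) for (q in 0:(n - 1))
    for (r in 0:(n - 1)) for (s in 0:(n - 1)) {
      e2 <- E[[paste(p, q)]] %*% E[[paste(r, s)]]
      if (q == r) e2 <- e2 - E[[paste(p, s)]]
      H <- H + 0.5 * active$g[p + 1, q + 1, r + 1, s + 1] * e2
    }
  H
}

# dense matrix exponential by scaling and squaring of the Taylor series
dense_expm <- function(A, order = 24, squarings = 8) {
  A <- A / 2^squarings
  X <- diag(nrow(A)); term <- diag(nrow(A))
  for (k in 1:order) {
    term <- term %*% A / k
    X <- X + term
  }
  for (k in seq_len(squarings)) X <- X %*% X
  X
}

# random particle-conserving ansatz state for property tests
random_ansatz_state <- function(n_qubits, n_electrons, n_gates = 6, seed = 1) {
  set.seed(seed)
  cand <- excitation_candidates(n_qubits, n_electrons)
  pool <- c(cand$doubles, cand$singles)
  st <- hf_state(n_qubits, n_electrons)
  for (k in seq_len(n_gates)) {
    g <- pool[[sample(length(pool), 1)]]
    g$theta <- runif(1, -pi, pi)
    st <- apply_excitation(st, g)
  }
  st
}

occupation_expectation <- function(state) {
  nq <- attr(state, "n_qubits")
  idx <- 0:(2^nq - 1)
  pops <- vapply(idx, function(i) sum(bitwAnd(bitwShiftR(i, 0:(nq - 1)), 1L)), 0)
  sum(Mod(unclass(state))^2 * pops)
}

noisy_rep <- function(seed) cached(paste0("noisy_rep_", seed),
  noisy_solvation_experiment("h3plus", noise = noise_model(0.001, 0.01, 0.01),
                             shots = 8192, seed = seed, max_iter = 60,
                             window = 30))
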