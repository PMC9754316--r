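# Noisy estimation: depolarizing + readout channels on a density-matrix
# simulation, shot sampling of the Pauli strings behind the RDMs, the
# upper-bound error propagation, 1-RDM trace normalization and trace-distance
# diagnostics, and the paired noisy gas/solvated experiment.

#' Generic noise model
#'
#' @param p1 single-qubit depolarizing probability applied after each
#'   one-qubit gate.
#' @param p2 two-qubit depolarizing probability applied after each
#'   excitation gate (on its occupied and virtual wire pairs).
#' @param p_readout independent per-qubit bit-flip probability on
#'   measurement.
#' @return List of class `solvqe_noise`.
#' @export
noise_model <- function(p1 = 0, p2 = 0, p_readout = 0) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1,
            p_readout >= 0, p_readout <= 1)
  structure(list(p1 = p1, p2 = p2, p_readout = p_readout),
            class = "solvqe_noise")
}

# dense unitary of a gate by applying it to the computational basis
.gate_unitary <- function(n_qubits, gate) {
  dim <- 2^n_qubits
  U <- matrix(0 + 0i, dim, dim)
  for (col in seq_len(dim)) {
    e <- complex(dim); e[col] <- 1
    U[, col] <- cpp_sv_excitation(e, n_qubits, gate$wires, gate$theta)
  }
  U
}

# Depolarizing channels parameterized so that p = 1 replaces the affected
# qubit(s) by the maximally mixed state: rho -> (1-p) rho + p/4^k sum_P P rho P
# with P running over all Pauli products (identity included) on the wires.
.depolarize_1q <- function(rho, k, p, n_qubits) {
  if (p <= 0) return(rho)
  acc <- rho
  for (cd in 1:3) {
    codes <- integer(n_qubits); codes[k + 1] <- cd
    P <- pauli_matrix(codes)
    acc <- acc + P %*% rho %*% P
  }
  (1 - p) * rho + (p / 4) * acc
}

.depolarize_2q <- function(rho, k1, k2, p, n_qubits) {
  if (p <= 0) return(rho)
  acc <- 0
  for (c1 in 0:3) for (c2 in 0:3) {
    codes <- integer(n_qubits); codes[k1 + 1] <- c1; codes[k2 + 1] <- c2
    P <- pauli_matrix(codes)
    acc <- acc + P %*% rho %*% P
  }
  (1 - p) * rho + (p / 16) * acc
}

#' Execute a circuit under a noise model
#'
#' Density-matrix simulation of the Hartree-Fock preparation (X gates) and
#' the excitation circuit: a single-qubit depolarizing channel (`p1`)
#' follows each preparation gate and a two-qubit depolarizing channel
#' (`p2`) follows each excitation gate on its wire pairs.  Readout error is
#' applied at measurement time, not here.
#'
#' @param n_qubits,n_electrons register and reference occupation.
#' @param gates list of [excitation()] gates.
#' @param theta optional angle overrides.
#' @param noise a [noise_model()].
#' @return Dense `2^n x 2^n` density matrix.
#' @export
simulate_noisy_circuit <- function(n_qubits, n_electrons, gates,
                                   theta = NULL, noise = noise_model()) {
  if (n_qubits > 8) stop("dense density-matrix path limited to 8 qubits")
  dim <- 2^n_qubits
  psi0 <- complex(dim); psi0[1] <- 1
  rho <- psi0 %o% Conj(psi0)
  for (k in seq_len(n_electrons) - 1L) {  # X on qubit k
    codes <- integer(n_qubits); codes[k + 1] <- 1L
    X <- pauli_matrix(codes)
    rho <- X %*% rho %*% X
    rho <- .depolarize_1q(rho, k, noise$p1, n_qubits)
  }
  for (i in seq_along(gates)) {
    g <- gates[[i]]
    if (!is.null(theta)) g$theta <- theta[i]
    U <- .gate_unitary(n_qubits, g)
    rho <- U %*% rho %*% Conj(t(U))
    w <- g$wires
    rho <- .depolarize_2q(rho, w[1], w[2], noise$p2, n_qubits)
    if (length(w) == 4)
      rho <- .depolarize_2q(rho, w[3], w[4], noise$p2, n_qubits)
  }
  rho
}

# ---- cached JW decompositions of the RDM observables ------------------------
.jw_cache <- new.env(parent = emptyenv())

.rdm_observables <- function(n_orb) {
  key <- as.character(n_orb)
  if (!is.null(.jw_cache[[key]])) return(.jw_cache[[key]])
  ops1 <- list(); ops2 <- list()
  for (p in 0:(n_orb - 1)) for (q in 0:(n_orb - 1))
    ops1[[paste(p, q)]] <- jw_epq(p, q, n_orb)
  for (p in 0:(n_orb - 1)) for (q in 0:(n_orb - 1))
    for (r in 0:(n_orb - 1)) for (s in 0:(n_orb - 1))
      ops2[[paste(p, q, r, s)]] <- jw_epqrs(p, q, r, s, n_orb)
  key_of <- function(t) paste(t$codes, collapse = ",")
  strings1 <- unique(unlist(lapply(ops1, function(op)
    vapply(op, key_of, "")), use.names = FALSE))
  strings_all <- unique(c(strings1, unlist(lapply(ops2, function(op)
    vapply(op, key_of, "")), use.names = FALSE)))
  val <- list(ops1 = ops1, ops2 = ops2, strings1 = strings1,
              strings_all = strings_all)
  .jw_cache[[key]] <- val
  val
}

#' Pauli strings required by an observable set
#'
#' Distinct non-identity Pauli strings in the Jordan-Wigner decomposition of
#' the 1-RDM operators (`which = "rdm1"`) or of both RDMs -- equivalently
#' the full Hamiltonian (`which = "full"`).
#'
#' @param n_orb number of spatial orbitals.
#' @param which `"rdm1"` or `"full"`.
#' @return Character vector of comma-separated Pauli code strings.
#' @export
required_pauli_strings <- function(n_orb, which = c("rdm1", "full")) {
  which <- match.arg(which)
  obs <- .rdm_observables(n_orb)
  str <- if (which == "rdm1") obs$strings1 else obs$strings_all
  nontriv <- vapply(strsplit(str, ","), function(v) any(v != "0"), TRUE)
  str[nontriv]
}

# estimate all strings from a state/density, then assemble gamma and Gamma
.measure_rdms_sampled <- function(rho, n_orb, shots = 8192, p_readout = 0) {
  obs <- .rdm_observables(n_orb)
  est <- new.env(parent = emptyenv())
  get_est <- function(codes) {
    key <- paste(codes, collapse = ",")
    if (is.null(est[[key]])) {
      if (all(codes == 0L)) est[[key]] <- 1
      else est[[key]] <- sample_pauli(rho, codes, shots, p_readout)$mean
    }
    est[[key]]
  }
  eval_op <- function(op)
    Re(sum(vapply(op, function(t) t$coef * get_est(t$codes), complex(1))))
  gamma <- matrix(0, n_orb, n_orb)
  for (p in 0:(n_orb - 1)) for (q in 0:(n_orb - 1))
    gamma[p + 1, q + 1] <- eval_op(obs$ops1[[paste(p, q)]])
  gamma <- 0.5 * (gamma + t(gamma))
  Gamma <- array(0, rep(n_orb, 4))
  for (p in 0:(n_orb - 1)) for (q in 0:(n_orb - 1))
    for (r in 0:(n_orb - 1)) for (s in 0:(n_orb - 1))
      Gamma[p + 1, q + 1, r + 1, s + 1] <-
        eval_op(obs$ops2[[paste(p, q, r, s)]])
  list(gamma = gamma, Gamma = Gamma,
       n_strings = length(ls(est)))
}

#' Upper-bound error propagation over Pauli strings
#'
#' Assigns each measured string the upper-bound standard deviation 1 (so
#' `sigma_k = 1/sqrt(shots)`) and propagates through the linear combination:
#' `sigma_total = sqrt(sum_k c_k^2) / sqrt(shots)`.  The identity term must
#' be excluded by the caller.
#'
#' @param term_coefficients real coefficients of the observable on the
#'   Pauli basis.
#' @param shots number of shots per string (> 0).
#' @return Scalar standard deviation (same units as the coefficients).
#' @export
propagate_error_bars <- function(term_coefficients, shots) {
  if (shots <= 0) stop("shots must be positive")
  sqrt(sum(term_coefficients^2)) / sqrt(shots)
}

#' Rescale a noisy 1-RDM to the correct trace
#'
#' `gamma' = gamma * n_electrons / tr(gamma)`; scaling only, so eigenvectors
#' are untouched.
#'
#' @param gamma measured spatial 1-RDM.
#' @param n_electrons target trace.
#' @export
normalize_rdm_trace <- function(gamma, n_electrons) {
  tr <- sum(diag(gamma))
  if (tr <= 0) stop("non-positive 1-RDM trace: ", tr)
  gamma * (n_electrons / tr)
}

#' Trace distance between 1-RDMs
#'
#' `D = tr|gamma1 - gamma2| / (2 n_electrons)`, the nuclear norm of the
#' difference normalized so that two occupation matrices with orthogonal
#' supports give 1.
#'
#' @param gamma1,gamma2 Hermitian matrices of equal shape.
#' @param n_electrons normalizing electron count.
#' @return List `D` (in `[0, 1]`) and `nuclear_norm` (unnormalized).
#' @export
trace_distance_rdm <- function(gamma1, gamma2, n_electrons) {
  if (!all(dim(gamma1) == dim(gamma2))) stop("shape mismatch")
  ev <- eigen(gamma1 - gamma2, symmetric = TRUE, only.values = TRUE)$values
  nn <- sum(abs(ev))
  list(D = nn / (2 * n_electrons), nuclear_norm = nn)
}

#' Paired noisy estimation of the solvation free energy
#'
#' Runs a noisy gas-phase VQE and a noisy solvated VQE (independent runs,
#' derivative-free simplex optimizer, randomly initialized angles), and
#' reports the solvation free energy as the mean +- sd of the difference
#' over the last `window` cost evaluations, together with the 1-RDM-only
#' polarization-energy shortcut (trace-normalized) and trace distances of
#' the noisy against the exact 1-RDMs.
#'
#' @param geom a [geometry()] or fixture name (6-qubit scale).
#' @param solvent a [solvent_params()].
#' @param noise a [noise_model()].
#' @param shots shots per Pauli string (`Inf` for exact expectations).
#' @param seed integer seed.
#' @param max_iter simplex iteration budget per run.
#' @param window trailing window for the reported statistics.
#' @param threshold adaptive screening threshold for the (noiseless) ansatz
#'   construction.
#' @return List of class `solvqe_noisy_report`.
#' @export
noisy_solvation_experiment <- function(geom, solvent = solvent_params(),
                                       noise = noise_model(), shots = 8192,
                                       seed = 1L, max_iter = 150L,
                                       window = 50L, threshold = 1e-5) {
  set.seed(seed)
  if (is.character(geom)) geom <- molecule_fixture(geom)
  problem <- build_problem(geom, solvent = solvent)
  if (problem$n_qubits > 8)
    stop("noisy experiment limited to 8 qubits (dense density matrices)")
  n_orb <- problem$active$n_active
  gas_cost <- .make_cost(problem, solvated = FALSE)
  cand <- excitation_candidates(problem$n_qubits, problem$n_electrons)
  ansatz <- adaptive_select(gas_cost, cand, threshold = threshold)
  exact_gas <- run_fci(problem$active)
  exact_pcm <- run_fci(problem$active, pcm = "self_consistent",
                       couplings = problem$couplings)
  run_noisy <- function(solvated) {
    hist_cost <- numeric(0)
    gammas <- list()
    cost <- function(th) {
      rho <- simulate_noisy_circuit(problem$n_qubits, problem$n_electrons,
                                    ansatz$gates, th, noise)
      meas <- .measure_rdms_sampled(rho, n_orb, shots, noise$p_readout)
      gam <- normalize_rdm_trace(meas$gamma, problem$n_electrons)
      rdms <- list(gamma = gam, Gamma = meas$Gamma)
      fe <- free_energy(rdms, problem$active,
                        if (solvated) problem$couplings else
                          structure(list(vacuum = TRUE),
                                    class = "solvqe_couplings"),
                        check_trace = FALSE)
      hist_cost <<- c(hist_cost, fe$G)
      gammas[[length(gammas) + 1L]] <<- gam
      fe$G
    }
    th0 <- runif(length(ansatz$gates), -0.1, 0.1)
    opt <- optimize_circuit(cost, th0,
                            settings = list(method = "nelder_mead",
                                            max_iter = max_iter))
    list(opt = opt, cost = hist_cost, gammas = gammas)
  }
  gas <- run_noisy(FALSE)
  pcm <- run_noisy(TRUE)
  m <- min(length(gas$cost), length(pcm$cost), window)
  tail_g <- utils::tail(gas$cost, m)
  tail_p <- utils::tail(pcm$cost, m)
  delta <- .to_ev(tail_p - tail_g)
  # polarization-energy shortcut: gas 1-RDM only, trace-normalized
  upol_tail <- vapply(utils::tail(gas$gammas, m), function(g)
    .to_ev(polarization_energy(g, problem$active, problem$couplings)), 0)
  gamma_gas_noisy <- Reduce(`+`, utils::tail(gas$gammas, m)) / m
  gamma_pcm_noisy <- Reduce(`+`, utils::tail(pcm$gammas, m)) / m
  structure(list(
    delta_solv_ev = mean(delta), delta_solv_sd = stats::sd(delta),
    U_pol_ev = mean(upol_tail), U_pol_sd = stats::sd(upol_tail),
    delta_exact_ev = .to_ev(exact_pcm$energy - exact_gas$energy),
    U_pol_exact_ev = .to_ev(polarization_energy(exact_gas$rdms$gamma,
                                                problem$active,
                                                problem$couplings)),
    trace_distance_gas = trace_distance_rdm(gamma_gas_noisy,
                                            exact_gas$rdms$gamma,
                                            problem$n_electrons),
    trace_distance_pcm = trace_distance_rdm(gamma_pcm_noisy,
                                            exact_pcm$rdms$gamma,
                                            problem$n_electrons),
    n_strings_rdm1 = length(required_pauli_strings(n_orb, "rdm1")),
    n_strings_full = length(required_pauli_strings(n_orb, "full")),
    gas_history = gas$cost, pcm_history = pcm$cost,
    shots = shots, noise = noise, seed = seed),
    class = "solvqe_noisy_report")
}

#' @export
print.solvqe_noisy_report <- function(x, ...) {
  cat(sprintf("Noisy solvation estimate: Delta G = %.3f +- %.3f eV (exact %.3f)\n",
              x$delta_solv_ev, x$delta_solv_sd, x$delta_exact_ev))
  cat(sprintf("U_pol shortcut:           %.3f +- %.3f eV (exact %.3f)\n",
              x$U_pol_ev, x$U_pol_sd, x$U_pol_exact_ev))
  cat(sprintf("1-RDM trace distances: gas %.4f, solvated %.4f\n",
              x$trace_distance_gas$D, x$trace_distance_pcm$D))
  invisible(x)
}
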