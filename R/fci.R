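# Determinant-basis full configuration interaction in the active space,
# gas phase or coupled to the continuum (rigid density or self-consistent).

.fci_space_check <- function(n_orb, n_electrons) {
  na <- n_electrons %/% 2L
  if (n_electrons %% 2L != 0L) stop("FCI here assumes S_z = 0 (even electrons)")
  dim <- choose(n_orb, na)^2
  if (dim > 1e6) stop("FCI determinant space too large: ", dim)
  dim
}

# RDMs of a CI vector via E_pq application in the determinant basis
.fci_rdms <- function(civec, n_orb, dets) {
  Phi <- cpp_fci_epq_all(civec, n_orb, dets)
  gamma <- matrix(as.vector(crossprod(Phi, civec)), n_orb, n_orb)
  M <- crossprod(Phi)  # M[(q,p),(r,s)] with column index p + q*n_orb
  Gamma <- array(0, c(n_orb, n_orb, n_orb, n_orb))
  for (p in 1:n_orb) for (q in 1:n_orb) for (r in 1:n_orb) for (s in 1:n_orb) {
    v <- M[q + (p - 1) * n_orb, r + (s - 1) * n_orb]
    if (q == r) v <- v - gamma[p, s]
    Gamma[p, q, r, s] <- v
  }
  structure(list(gamma = gamma, Gamma = Gamma), class = "solvqe_rdms")
}

#' Full configuration interaction (gas, rigid-PCM, or self-consistent PCM)
#'
#' Dense diagonalization in the fixed-(N, S_z = 0) determinant basis of the
#' active space.  `pcm = "rigid"` returns the gas-phase FCI energy plus the
#' polarization energy of the gas-phase FCI 1-RDM; `pcm = "self_consistent"`
#' iterates diagonalization of the effective Hamiltonian containing the
#' density-dependent solvent operator until the free energy is stationary.
#'
#' @param active an [active_space_transform()] result.
#' @param n_electrons number of active electrons (default from `active`).
#' @param pcm `"none"`, `"rigid"` or `"self_consistent"`.
#' @param couplings a [solvent_couplings()] bundle (required unless
#'   `pcm = "none"`).
#' @param tol free-energy convergence of the self-consistent loop (Hartree).
#' @param max_iter maximum self-consistent iterations.
#' @return List of class `solvqe_fci`: `energy` (E for gas, G otherwise),
#'   `E_gas`, `rdms`, `civec`, `history`, `converged`.
#' @export
run_fci <- function(active, n_electrons = active$n_electrons,
                    pcm = c("none", "rigid", "self_consistent"),
                    couplings = NULL, tol = 1e-10, max_iter = 50L) {
  pcm <- match.arg(pcm)
  n_orb <- active$n_active
  .fci_space_check(n_orb, n_electrons)
  na <- n_electrons %/% 2L
  dets <- cpp_fci_dets(n_orb, na, na)
  H <- cpp_fci_hamiltonian(active$h, active$g, n_orb, dets)
  eg <- eigen(H, symmetric = TRUE)
  ix <- which.min(eg$values)
  c0 <- eg$vectors[, ix]
  E0 <- eg$values[ix] + active$E_offset
  rdms <- .fci_rdms(c0, n_orb, dets)
  if (pcm == "none") {
    return(structure(list(energy = E0, E_gas = E0, rdms = rdms, civec = c0,
                          history = E0, converged = TRUE),
                     class = "solvqe_fci"))
  }
  if (is.null(couplings) || isTRUE(couplings$vacuum))
    stop("PCM variants require solvent couplings")
  if (pcm == "rigid") {
    U <- polarization_energy(rdms$gamma, active, couplings)
    return(structure(list(energy = E0 + U, E_gas = E0, U_pol = U,
                          rdms = rdms, civec = c0, history = E0 + U,
                          converged = TRUE), class = "solvqe_fci"))
  }
  # self-consistent: effective one-body solvent operator from current charges
  zero_g <- array(0, dim(active$g))
  Km <- matrix(couplings$K, n_orb * n_orb, length(active$v_static))
  G_old <- Inf; history <- numeric(0); cvec <- c0; converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- .fci_rdms(cvec, n_orb, dets)
    fe <- free_energy(r, active, couplings)
    history <- c(history, fe$G)
    if (abs(fe$G - G_old) < tol) { converged <- TRUE; break }
    G_old <- fe$G
    u <- matrix(Km %*% fe$q_total, n_orb, n_orb)
    Hu <- cpp_fci_hamiltonian(u, zero_g, n_orb, dets)
    eg <- eigen(H + Hu, symmetric = TRUE)
    cvec <- eg$vectors[, which.min(eg$values)]
  }
  r <- .fci_rdms(cvec, n_orb, dets)
  fe <- free_energy(r, active, couplings)
  structure(list(energy = fe$G, E_gas = .energy_gas(r, active), G = fe$G,
                 rdms = r, civec = cvec, history = history,
                 converged = converged), class = "solvqe_fci")
}

#' @export
print.solvqe_fci <- function(x, ...) {
  cat(sprintf("FCI: %.8f Ha%s\n", x$energy,
              if (length(x$history) > 1)
                sprintf(" (%d self-consistent iterations)", length(x$history))
              else ""))
  invisible(x)
}
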