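# Restricted Hartree-Fock: damped Roothaan iterations, optionally coupled to
# the polarizable continuum (the Fock operator then gains the one-body solvent
# term built from the current density's apparent surface charges, and the
# reported figure is the free energy in solution G = E[rho] + 1/2 V'QV).

# two-electron part of the Fock matrix: G_pq = sum_rs D_rs [(pq|rs) - (pr|qs)/2]
.fock_2e <- function(eri, D) {
  n <- nrow(D)
  em <- matrix(eri, n * n, n * n)
  J <- matrix(em %*% as.vector(D), n, n)
  # exchange: K_pq = sum_rs D_rs (pr|qs)
  ex <- aperm(eri, c(1, 3, 2, 4))
  Km <- matrix(matrix(ex, n * n, n * n) %*% as.vector(D), n, n)
  J - 0.5 * Km
}

#' Restricted Hartree-Fock (gas phase or PCM-coupled)
#'
#' Damped Roothaan SCF for closed shells.  With `pcm` supplied, the solvent
#' one-body operator built from the apparent charges of the current density
#' enters the Fock matrix and the converged figure reported in `E_total` is
#' the free energy in solution `G = E[rho] + 1/2 V' Q V`.
#'
#' @param core a [core_integrals()] object.
#' @param n_electrons even electron count.
#' @param pcm optional list with elements `cavity` and `Q` (see
#'   [build_cavity()], [response_matrix()]); `K_ao` and `v_N` are computed
#'   if absent.
#' @param max_iter,damping,conv_energy,conv_comm SCF controls: convergence is
#'   1e-8 on the energy and 1e-8 on the max |FDS - SDF| commutator residual.
#' @return Object of class `solvqe_scf`: `mo_coefficients`,
#'   `orbital_energies`, `E_total` (free energy for a PCM run), `E_gas_part`,
#'   `density`, `converged`, `n_iter`.
#' @export
run_hf <- function(core, n_electrons, pcm = NULL, max_iter = 200L,
                   damping = 0.35, conv_energy = 1e-10, conv_comm = 1e-8) {
  if (n_electrons %% 2L != 0L)
    stop("restricted closed-shell SCF needs an even electron count")
  n_occ <- n_electrons / 2L
  S <- core$overlap; h <- core$hcore
  es <- eigen(S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values), nrow(S)) %*% t(es$vectors)
  solv <- NULL
  if (!is.null(pcm) && !is.null(pcm$Q)) {
    K_ao <- pcm$K_ao
    if (is.null(K_ao))
      K_ao <- electronic_potential_integrals(core$basis, pcm$cavity$centers)
    v_N <- pcm$v_N
    if (is.null(v_N)) v_N <- nuclear_potential(core$geometry, pcm$cavity$centers)
    solv <- list(Q = pcm$Q, K = matrix(K_ao, core$n_ao^2, dim(K_ao)[3]),
                 v_N = v_N)
  }
  solve_fock <- function(F, D_prev = NULL, shift = 0) {
    if (shift > 0 && !is.null(D_prev))  # level shift on the virtual space
      F <- F + shift * (S - S %*% (D_prev / 2) %*% S)
    Fp <- t(X) %*% F %*% X
    ev <- eigen(Fp, symmetric = TRUE)
    ord <- order(ev$values)  # ascending orbital energies
    ev$values <- ev$values[ord]; ev$vectors <- ev$vectors[, ord, drop = FALSE]
    C <- X %*% ev$vectors
    list(C = C, eps = ev$values,
         D = 2 * C[, seq_len(n_occ), drop = FALSE] %*%
               t(C[, seq_len(n_occ), drop = FALSE]))
  }
  converged <- FALSE
  E_total <- NA_real_; comm <- NA_real_; it <- 0L; F <- h
  # attempt ladder: commutator-DIIS first, then increasingly damped and
  # level-shifted plain Roothaan for pathological (stretched-bond) cases
  attempts <- rbind(c(damping, 0, 1), c(damping, 0, 0), c(0.7, 0, 0),
                    c(0.9, 0, 0), c(0.7, 0.5, 0), c(0.9, 1.0, 1),
                    c(0.9, 1.0, 0))
  for (att in seq_len(nrow(attempts))) {
    damp <- attempts[att, 1]; shift <- attempts[att, 2]
    use_diis <- attempts[att, 3] > 0
    sol <- solve_fock(h)
    D <- sol$D
    E_old <- Inf; it <- 0L
    diis_F <- list(); diis_e <- list()
    repeat {
      it <- it + 1L
      F <- h + .fock_2e(core$eri, D)
      E_gas <- 0.5 * sum(D * (h + F)) + core$E_nn
      E_total <- E_gas
      if (!is.null(solv)) {
        V <- solv$v_N + as.vector(crossprod(solv$K, as.vector(D)))
        q <- as.vector(solv$Q %*% V)
        F <- F + matrix(solv$K %*% q, core$n_ao, core$n_ao)
        E_total <- E_gas + 0.5 * sum(V * q)
      }
      err <- F %*% D %*% S - S %*% D %*% F
      comm <- max(abs(err))
      if (abs(E_total - E_old) < conv_energy && comm < conv_comm) {
        converged <- TRUE
        break
      }
      if (it >= max_iter) break
      E_old <- E_total
      F_next <- F
      if (use_diis) {
        diis_F[[length(diis_F) + 1L]] <- F
        diis_e[[length(diis_e) + 1L]] <- t(X) %*% err %*% X
        if (length(diis_F) > 8L) { diis_F <- diis_F[-1]; diis_e <- diis_e[-1] }
        m <- length(diis_F)
        if (m >= 2L) {
          B <- matrix(0, m + 1, m + 1)
          for (a in 1:m) for (b in 1:m)
            B[a, b] <- sum(diis_e[[a]] * diis_e[[b]])
          B[m + 1, 1:m] <- B[1:m, m + 1] <- -1
          rhs <- c(rep(0, m), -1)
          cf <- tryCatch(solve(B, rhs)[1:m], error = function(e) NULL)
          if (!is.null(cf) && all(is.finite(cf)))
            F_next <- Reduce(`+`, Map(`*`, diis_F, cf))
        }
        sol <- solve_fock(F_next)
        D <- sol$D
      } else {
        sol <- solve_fock(F_next, D_prev = D, shift = shift)
        D <- (1 - damp) * sol$D + damp * D
      }
    }
    if (converged) break
  }
  if (!converged)
    stop(sprintf("SCF failed to converge in %d cycles (last E = %.10f, residual %.2e)",
                 max_iter, E_total, comm))
  # final clean diagonalization at the converged Fock
  sol <- solve_fock(F)
  structure(list(mo_coefficients = sol$C, orbital_energies = sol$eps,
                 E_total = E_total,
                 density = 2 * sol$C[, seq_len(n_occ), drop = FALSE] %*%
                             t(sol$C[, seq_len(n_occ), drop = FALSE]),
                 n_occ = n_occ, converged = converged, n_iter = it,
                 pcm = !is.null(solv)), class = "solvqe_scf")
}

#' @export
print.solvqe_scf <- function(x, ...) {
  cat(sprintf("RHF%s: %s = %.8f Ha (%d cycles)\n",
              if (x$pcm) "-PCM" else "",
              if (x$pcm) "G" else "E", x$E_total, x$n_iter))
  invisible(x)
}
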