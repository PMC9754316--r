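# Second-quantized solute-solvent coupling and the non-linear free-energy
# functional evaluated from reduced density matrices.  The 1/2 prefactor on
# the quadratic interaction term is the polarization work spent polarizing
# the dielectric; all solvent coupling depends only on the 1-RDM.

#' Static apparent charges and nuclear interaction
#'
#' `q_static = Q v_static` and `W_NN = v_static' q_static` (the 1/2 enters
#' only in the free energy).  `v_static` is the nuclear potential at the
#' tesserae, plus the frozen-core electron potential when a core is frozen.
#'
#' @param v_static static potential vector at tessera centers.
#' @param Q solvent response matrix.
#' @return List `q_static`, `W_NN` (Hartree).
#' @export
static_asc <- function(v_static, Q) {
  q <- apply_response(Q, v_static)
  list(q_static = q, W_NN = sum(v_static * q))
}

#' One-body solvent coupling matrices
#'
#' `j_pq = sum_i K[p,q,i] q_static[i]` (electronic potential against the
#' static charges) and `y_pq = sum_i v_static[i] (Q K[p,q,.])_i` (nuclear
#' potential against the charges induced by the elementary electronic
#' distribution).  With a symmetrized response matrix the two coincide.
#'
#' @param K active-space tessera-potential tensor (n x n x N).
#' @param q_static,v_static static charge and potential vectors.
#' @param Q response matrix.
#' @return List of symmetric matrices `j`, `y` (Hartree).
#' @export
one_body_couplings <- function(K, q_static, v_static, Q) {
  n <- dim(K)[1]; N <- dim(K)[3]
  Km <- matrix(K, n * n, N)
  j <- matrix(Km %*% q_static, n, n)
  # y_pq = v_static' Q K_pq, evaluated through Q' v_static so the identity
  # j = y is a measured property of the symmetrization, not an assumption
  y <- matrix(Km %*% as.vector(crossprod(Q, v_static)), n, n)
  list(j = 0.5 * (j + t(j)), y = 0.5 * (y + t(y)))
}

#' Apparent charges induced by the electronic density
#'
#' `v_el[i] = sum_pq gamma_pq K[p,q,i]`, `q_el = Q v_el`.
#'
#' @param gamma spatial 1-RDM in the active MO basis.
#' @param K tessera-potential tensor.
#' @param Q response matrix.
#' @return List `v_el`, `q_el`.
#' @export
electronic_asc <- function(gamma, K, Q) {
  n <- dim(K)[1]
  v_el <- as.vector(crossprod(matrix(K, n * n, dim(K)[3]), as.vector(gamma)))
  list(v_el = v_el, q_el = apply_response(Q, v_el))
}

#' Solvent couplings bundle
#'
#' Convenience constructor gathering everything the free-energy functional
#' needs: response matrix, static charges, one-body couplings.
#'
#' @param active a [active_space_transform()] result carrying `K` and
#'   `v_static`.
#' @param Q solvent response matrix (or `NULL` for a gas-phase run).
#' @return List of class `solvqe_couplings`.
#' @export
solvent_couplings <- function(active, Q) {
  if (is.null(Q)) return(structure(list(vacuum = TRUE), class = "solvqe_couplings"))
  st <- static_asc(active$v_static, Q)
  ob <- one_body_couplings(active$K, st$q_static, active$v_static, Q)
  structure(list(vacuum = FALSE, Q = Q, q_static = st$q_static,
                 W_NN = st$W_NN, j = ob$j, y = ob$y,
                 v_static = active$v_static, K = active$K),
            class = "solvqe_couplings")
}

# gas-phase energy expectation from RDMs
.energy_gas <- function(rdms, active) {
  active$E_offset + sum(active$h * rdms$gamma) +
    0.5 * sum(active$g * rdms$Gamma)
}

#' Free energy in solution from measured RDMs
#'
#' Evaluates the non-linear functional
#' `G = E_gas[gamma, Gamma] + 1/2 V' Q V` with `V = v_static + v_el(gamma)`;
#' the 1/2 is the polarization-work factor.  The 1-RDM trace is guarded
#' against mis-normalized (noisy) inputs unless `check_trace = FALSE`.
#'
#' @param rdms list with `gamma` (n x n) and `Gamma` (n^4) spatial RDMs.
#' @param active a [active_space_transform()] result.
#' @param couplings a [solvent_couplings()] bundle.
#' @param check_trace tolerance guard on `tr(gamma) - N_e` (default 1e-6);
#'   set `FALSE` to bypass for noisy RDMs routed through
#'   [normalize_rdm_trace()].
#' @return Object of class `solvqe_free_energy`: `E_gas` (expectation of the
#'   vacuum Hamiltonian), `U_int` (full quadratic form `V'QV`), `G`,
#'   `Delta_solv_eV`, `q_total`, and itemized components.
#' @export
free_energy <- function(rdms, active, couplings, check_trace = TRUE) {
  tr <- sum(diag(rdms$gamma))
  if (isTRUE(check_trace) && abs(tr - active$n_electrons) > 1e-6)
    stop(sprintf("1-RDM trace %.8f != %d active electrons; normalize or bypass",
                 tr, active$n_electrons))
  E_gas <- .energy_gas(rdms, active)
  if (isTRUE(couplings$vacuum)) {
    return(structure(list(E_gas = E_gas, U_int = 0, G = E_gas,
                          q_total = NULL, components = NULL),
                     class = "solvqe_free_energy"))
  }
  el <- electronic_asc(rdms$gamma, couplings$K, couplings$Q)
  V <- couplings$v_static + el$v_el
  qV <- apply_response(couplings$Q, V)
  U_int <- sum(V * qV)
  G <- E_gas + 0.5 * U_int
  comps <- c(W_NN = couplings$W_NN,
             electron_static = 2 * sum(couplings$j * rdms$gamma),
             electron_electron = sum(el$v_el * apply_response(couplings$Q, el$v_el)))
  structure(list(E_gas = E_gas, U_int = U_int, G = G,
                 q_total = qV, components = comps),
            class = "solvqe_free_energy")
}

#' @export
print.solvqe_free_energy <- function(x, ...) {
  cat(sprintf("E_gas = %.8f Ha;  1/2 U_int = %.8f Ha;  G = %.8f Ha\n",
              x$E_gas, 0.5 * x$U_int, x$G))
  invisible(x)
}

#' Polarization energy of a gas-phase density
#'
#' `U_pol = 1/2 V(gamma_gas)' Q V(gamma_gas)`: the interaction of the
#' unrelaxed gas-phase solute density with the charges it induces.
#'
#' @param gamma_gas gas-phase spatial 1-RDM.
#' @param active a [active_space_transform()] result.
#' @param couplings a [solvent_couplings()] bundle.
#' @return Scalar Hartree (non-positive).
#' @export
polarization_energy <- function(gamma_gas, active, couplings) {
  if (isTRUE(couplings$vacuum)) return(0)
  el <- electronic_asc(gamma_gas, couplings$K, couplings$Q)
  V <- couplings$v_static + el$v_el
  0.5 * sum(V * apply_response(couplings$Q, V))
}

#' Solvation free energy
#'
#' Difference of the converged free energy in solution and the gas-phase
#' energy, converted to eV.
#'
#' @param G_solution free energy in solution (Hartree).
#' @param E_gas gas-phase energy (Hartree).
#' @return Scalar eV.
#' @export
solvation_free_energy <- function(G_solution, E_gas) .to_ev(G_solution - E_gas)
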