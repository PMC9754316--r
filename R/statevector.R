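# Statevector simulation of particle-conserving excitation circuits and
# Jordan-Wigner measurement of spatial-orbital reduced density matrices.
#
# Qubit k encodes spin-orbital k with spin-orbitals ordered
# (phi1 alpha, phi1 beta, phi2 alpha, ...); basis-index bit k (qubit 0 is the
# least-significant bit) is the occupation of spin-orbital k.

#' Hartree-Fock reference state
#'
#' The single computational basis state with the first `n_electrons` qubits
#' set to |1>.
#'
#' @param n_qubits register size.
#' @param n_electrons electron count (0 <= n_electrons <= n_qubits).
#' @return Object of class `solvqe_state`: complex amplitude vector of length
#'   `2^n_qubits` with attribute `n_qubits`.
#' @export
hf_state <- function(n_qubits, n_electrons) {
  if (n_electrons < 0 || n_electrons > n_qubits)
    stop("electron count out of range")
  amps <- complex(2^n_qubits)
  occ <- if (n_electrons > 0) sum(2^(seq_len(n_electrons) - 1)) else 0
  amps[occ + 1] <- 1 + 0i
  structure(amps, n_qubits = n_qubits, class = "solvqe_state")
}

.as_state <- function(amps, n_qubits)
  structure(amps, n_qubits = n_qubits, class = "solvqe_state")

#' Particle-conserving excitation gate
#'
#' @param kind `"single"` or `"double"`.
#' @param wires 2 (single) or 4 (double) distinct qubit indices, 0-based,
#'   occupied wires first.
#' @param theta rotation angle in radians.
#' @return List of class `solvqe_excitation`.
#' @export
excitation <- function(kind = c("single", "double"), wires, theta = 0) {
  kind <- match.arg(kind)
  wires <- as.integer(wires)
  if (anyDuplicated(wires)) stop("repeated wire")
  if (length(wires) != if (kind == "single") 2L else 4L)
    stop("wrong wire count for a ", kind, " excitation")
  structure(list(kind = kind, wires = wires, theta = theta),
            class = "solvqe_excitation")
}

#' Apply an excitation gate to a statevector
#'
#' Givens rotation in the two-dimensional occupation subspace: for a single
#' excitation on wires (a, b), `|01> -> cos(t/2)|01> + sin(t/2)|10>` and
#' `|10> -> cos(t/2)|10> - sin(t/2)|01>` (pattern written as occupations of
#' a then b); a double excitation performs the same rotation between |1100>
#' and |0011> on its four wires.  All other basis states are untouched.
#'
#' @param state a `solvqe_state`.
#' @param exc a [excitation()] gate.
#' @return The rotated `solvqe_state`.
#' @export
apply_excitation <- function(state, exc) {
  nq <- attr(state, "n_qubits")
  if (any(exc$wires < 0 | exc$wires >= nq)) stop("wire outside register")
  out <- cpp_sv_excitation(unclass(state), nq, exc$wires, exc$theta)
  .as_state(out, nq)
}

#' Apply an ordered ansatz
#'
#' @param state reference `solvqe_state`.
#' @param ansatz list of [excitation()] gates (an `solvqe_ansatz` or plain
#'   list).
#' @param theta optional vector of angles overriding the stored ones.
#' @return The prepared state.
#' @export
apply_ansatz <- function(state, ansatz, theta = NULL) {
  gates <- if (inherits(ansatz, "solvqe_ansatz")) ansatz$gates else ansatz
  if (!is.null(theta) && length(theta) != length(gates))
    stop("theta length != number of gates")
  for (i in seq_along(gates)) {
    g <- gates[[i]]
    if (!is.null(theta)) g$theta <- theta[i]
    state <- apply_excitation(state, g)
  }
  state
}

#' Measure spatial-orbital reduced density matrices
#'
#' Expectation values of the singlet excitation operators with full
#' Jordan-Wigner parity strings:
#' `gamma_pq = <E_pq>`, `Gamma_pqrs = <E_pq E_rs - delta_qr E_ps>`.
#'
#' @param state a `solvqe_state` on `2 * n_spatial` qubits.
#' @param n_spatial number of spatial orbitals.
#' @return List with `gamma` (n x n) and `Gamma` (n x n x n x n), class
#'   `solvqe_rdms`.
#' @export
measure_rdms <- function(state, n_spatial = attr(state, "n_qubits") / 2) {
  nq <- attr(state, "n_qubits")
  if (nq %% 2L != 0L) stop("odd register size: qubits must pair into spatial orbitals")
  if (nq != 2 * n_spatial) stop("n_qubits != 2 * n_spatial")
  out <- cpp_sv_rdms(unclass(state), as.integer(n_spatial))
  structure(list(gamma = out$gamma, Gamma = out$Gamma), class = "solvqe_rdms")
}
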