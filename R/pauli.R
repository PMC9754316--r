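# Pauli-string algebra and Jordan-Wigner decompositions, used by the
# shot-sampling / noisy-estimation path (the noiseless RDM path applies the
# fermionic operators directly; the two routes agree and are tested against
# each other).
#
# A Pauli term is list(coef = complex, codes = integer vector with
# 0 = I, 1 = X, 2 = Y, 3 = Z; element k is qubit k-1).  An operator is a
# list of terms.

.pauli_1q <- list(
  matrix(c(1, 0, 0, 1), 2),                      # I
  matrix(c(0, 1, 1, 0), 2),                      # X
  matrix(complex(real = c(0, 0, 0, 0),
                 imaginary = c(0, 1, -1, 0)), 2),# Y
  matrix(c(1, 0, 0, -1), 2))                     # Z

# single-qubit product table: P_a P_b = phase * P_c
.pauli_mul1 <- function(a, b) {
  if (a == 0) return(list(code = b, phase = 1 + 0i))
  if (b == 0) return(list(code = a, phase = 1 + 0i))
  if (a == b) return(list(code = 0L, phase = 1 + 0i))
  # XY=iZ, YZ=iX, ZX=iY and anticommuted partners
  tab <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  for (r in 1:3)
    if (a == tab[r, 1] && b == tab[r, 2])
      return(list(code = tab[r, 3], phase = 1i))
  list(code = 6L - a - b, phase = -1i)
}

.term_mul <- function(t1, t2) {
  n <- length(t1$codes)
  codes <- integer(n); ph <- t1$coef * t2$coef
  for (k in seq_len(n)) {
    m <- .pauli_mul1(t1$codes[k], t2$codes[k])
    codes[k] <- m$code; ph <- ph * m$phase
  }
  list(coef = ph, codes = codes)
}

.op_mul <- function(op1, op2) {
  out <- list()
  for (t1 in op1) for (t2 in op2)
    out[[length(out) + 1L]] <- .term_mul(t1, t2)
  .op_simplify(out)
}

.op_add <- function(...) .op_simplify(do.call(c, list(...)))

.op_scale <- function(op, s) lapply(op, function(t) {
  t$coef <- t$coef * s; t
})

.op_simplify <- function(op, tol = 1e-12) {
  if (!length(op)) return(op)
  keys <- vapply(op, function(t) paste(t$codes, collapse = ","), "")
  out <- list()
  for (k in unique(keys)) {
    idx <- which(keys == k)
    coef <- sum(vapply(op[idx], function(t) t$coef, complex(1)))
    if (Mod(coef) > tol)
      out[[length(out) + 1L]] <- list(coef = coef, codes = op[[idx[1]]]$codes)
  }
  out
}

# Jordan-Wigner ladder operators on an n-qubit register (qubit index 0-based)
.jw_ladder <- function(q, n_qubits, dagger = FALSE) {
  codes_x <- integer(n_qubits); codes_y <- integer(n_qubits)
  if (q > 0) { codes_x[seq_len(q)] <- 3L; codes_y[seq_len(q)] <- 3L }
  codes_x[q + 1] <- 1L; codes_y[q + 1] <- 2L
  s <- if (dagger) -0.5i else 0.5i
  list(list(coef = 0.5 + 0i, codes = codes_x),
       list(coef = s, codes = codes_y))
}

# singlet excitation operator E_pq = sum_sigma a+_{p sigma} a_{q sigma}
# (0-based spatial p, q; interleaved spin ordering)
jw_epq <- function(p, q, n_orb) {
  nq <- 2L * n_orb
  op <- list()
  for (s in 0:1) {
    ad <- .jw_ladder(2L * p + s, nq, dagger = TRUE)
    a <- .jw_ladder(2L * q + s, nq, dagger = FALSE)
    op <- c(op, .op_mul(ad, a))
  }
  .op_simplify(op)
}

# two-body operator e_pqrs = E_pq E_rs - delta_qr E_ps
jw_epqrs <- function(p, q, r, s, n_orb) {
  op <- .op_mul(jw_epq(p, q, n_orb), jw_epq(r, s, n_orb))
  if (q == r) op <- .op_add(op, .op_scale(jw_epq(p, s, n_orb), -1))
  .op_simplify(op)
}

# dense matrix of a Pauli code vector (qubit 0 = fastest index)
pauli_matrix <- function(codes) {
  mats <- lapply(rev(codes), function(cd) .pauli_1q[[cd + 1L]])
  Reduce(kronecker, mats)
}

# dense matrix of an operator (list of terms)
op_matrix <- function(op, n_qubits) {
  M <- matrix(0 + 0i, 2^n_qubits, 2^n_qubits)
  for (t in op) M <- M + t$coef * pauli_matrix(t$codes)
  M
}

.parse_pauli <- function(pauli) {
  if (is.character(pauli)) {
    ch <- strsplit(toupper(pauli), "")[[1]]
    codes <- match(ch, c("I", "X", "Y", "Z")) - 1L
    if (any(is.na(codes))) stop("invalid Pauli letter in '", pauli, "'")
    codes
  } else as.integer(pauli)
}

# basis-change matrix mapping the string's eigenbasis to the Z basis (cached)
.rot_cache <- new.env(parent = emptyenv())
.pauli_rotation <- function(codes) {
  key <- paste(codes, collapse = ",")
  if (!is.null(.rot_cache[[key]])) return(.rot_cache[[key]])
  H <- matrix(1 / sqrt(2), 2, 2); H[2, 2] <- -H[2, 2]
  Sdg <- diag(c(1 + 0i, -1i))
  one <- function(cd) switch(cd + 1L, diag(2) + 0i, H + 0i, H %*% Sdg, diag(2) + 0i)
  U <- Reduce(kronecker, lapply(rev(codes), one))
  .rot_cache[[key]] <- U
  U
}

# +-1 eigenvalue of each bitstring under the string (Z-basis after rotation)
.pauli_eigvals <- function(codes) {
  nq <- length(codes)
  idx <- 0:(2^nq - 1)
  ev <- rep(1, 2^nq)
  for (k in seq_len(nq)) {
    if (codes[k] == 0L) next
    bit <- bitwAnd(idx %/% 2^(k - 1), 1L)
    ev <- ev * (1 - 2 * bit)
  }
  ev
}

#' Sample the expectation value of a Pauli string
#'
#' Rotates the state to the string's eigenbasis, samples bitstrings, and
#' averages the +-1 eigenvalues.  The estimator is unbiased for the true
#' expectation.  The identity string returns exactly 1 with zero variance.
#'
#' @param state a `solvqe_state` statevector or a density matrix.
#' @param pauli Pauli string, e.g. `"XZII"` (character, qubit 0 first) or an
#'   integer code vector (0 = I, 1 = X, 2 = Y, 3 = Z).
#' @param shots number of measurement repetitions (>= 1), or `Inf` for the
#'   exact expectation.
#' @param p_readout per-qubit classical bit-flip probability applied to the
#'   measured distribution (default 0).
#' @return List of class `solvqe_estimate`: `mean`, `shots`, `sigma_bound`
#'   (`1/sqrt(shots)`, the upper bound used for error bars).
#' @export
sample_pauli <- function(state, pauli, shots = 8192, p_readout = 0) {
  codes <- .parse_pauli(pauli)
  if (!is.infinite(shots) && shots < 1) stop("shots must be >= 1")
  if (all(codes == 0L)) {
    return(structure(list(mean = 1, shots = shots, sigma_bound = 0),
                     class = "solvqe_estimate"))
  }
  probs <- .measure_probs(state, codes, p_readout)
  ev <- .pauli_eigvals(codes)
  if (is.infinite(shots)) {
    m <- sum(probs * ev)
  } else {
    counts <- as.vector(rmultinom(1, shots, probs))
    m <- sum(counts * ev) / shots
  }
  structure(list(mean = m, shots = shots,
                 sigma_bound = if (is.infinite(shots)) 0 else 1 / sqrt(shots)),
            class = "solvqe_estimate")
}

# Z-basis probabilities after rotating into the string's eigenbasis,
# optionally degraded by independent readout bit-flips.
.measure_probs <- function(state, codes, p_readout = 0) {
  U <- .pauli_rotation(codes)
  if (is.matrix(state)) {
    probs <- Re(diag(U %*% state %*% Conj(t(U))))
  } else {
    amps <- as.complex(unclass(state))
    probs <- Mod(U %*% amps)^2
  }
  probs <- pmax(as.vector(probs), 0)
  probs <- probs / sum(probs)
  if (p_readout > 0) {
    M1 <- matrix(c(1 - p_readout, p_readout, p_readout, 1 - p_readout), 2)
    M <- Reduce(kronecker, rep(list(M1), length(codes)))
    probs <- as.vector(M %*% probs)
  }
  probs
}
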