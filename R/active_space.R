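# Transformation of the AO integrals to an active molecular-orbital space,
# with frozen-core Coulomb/exchange folded into the one-body part and the
# frozen-core density's surface potential folded into the static tessera
# potential (so the "static" apparent charges of the solvated operator stem
# from nuclei plus frozen core).

# AO -> MO transform of the 4-index ERI array restricted to the columns of C
.ao2mo_eri <- function(g, C) {
  n <- dim(g)[1]; m <- ncol(C)
  # contract one index at a time
  g1 <- array(crossprod(C, matrix(g, n, n^3)), c(m, n, n, n))
  g2 <- aperm(g1, c(2, 1, 3, 4))
  g2 <- array(crossprod(C, matrix(g2, n, m * n * n)), c(m, m, n, n))
  g3 <- aperm(g2, c(3, 1, 2, 4))
  g3 <- array(crossprod(C, matrix(g3, n, m * m * n)), c(m, m, m, n))
  g4 <- aperm(g3, c(4, 1, 2, 3))
  g4 <- array(crossprod(C, matrix(g4, n, m^3)), c(m, m, m, m))
  # accumulated index order is (s, r, q, p); restore chemists' (p, q, r, s)
  aperm(g4, c(4, 3, 2, 1))
}

#' Transform integrals to an active space
#'
#' Rotates the one- and two-electron integrals (and, when supplied, the
#' tessera-potential tensor) into the molecular-orbital basis of the active
#' space, folding the frozen-core mean field into `h` and `E_offset` and the
#' frozen-core electron density into `v_static`.
#'
#' @param core a [core_integrals()] object.
#' @param scf a converged [run_hf()] result supplying the MO basis.
#' @param frozen integer vector of frozen (lowest occupied) MO indices; may be
#'   empty.
#' @param K_ao optional AO tessera-potential tensor from
#'   [electronic_potential_integrals()].
#' @param cavity optional cavity (needed to evaluate the nuclear potential at
#'   the tesserae when `K_ao` is given).
#' @param active explicit integer vector of active MO indices (default: all
#'   non-frozen orbitals); must not overlap `frozen`.
#' @return Object of class `solvqe_active`: `h` (n_act x n_act), `g`
#'   (chemists' `(pq|rs)`, n_act^4), `E_offset` (nuclear repulsion plus
#'   frozen-core energy), `K` (n_act x n_act x N_tess), `v_static`,
#'   `n_active`, `n_electrons` (active electrons), `C_active`.
#' @export
active_space_transform <- function(core, scf, frozen = integer(0),
                                   K_ao = NULL, cavity = NULL,
                                   active = NULL) {
  n_ao <- core$n_ao
  frozen <- as.integer(frozen)
  if (is.null(active)) active <- setdiff(seq_len(n_ao), frozen)
  active <- as.integer(active)
  if (length(intersect(frozen, active)))
    stop("frozen and active orbital sets overlap")
  C <- scf$mo_coefficients
  Cf <- C[, frozen, drop = FALSE]
  Ca <- C[, active, drop = FALSE]
  Dcore <- 2 * Cf %*% t(Cf)
  Fcore_ao <- core$hcore +
    if (length(frozen)) .fock_2e(core$eri, Dcore) else 0
  E_frozen <- if (length(frozen))
    0.5 * sum(Dcore * (core$hcore + Fcore_ao)) else 0
  h <- crossprod(Ca, Fcore_ao %*% Ca)
  g <- .ao2mo_eri(core$eri, Ca)
  out <- list(h = h, g = g,
              E_offset = core$E_nn + E_frozen,
              n_active = length(active),
              n_electrons = scf$n_occ * 2L - 2L * length(frozen),
              frozen = frozen, C_active = Ca,
              geometry = core$geometry)
  if (!is.null(K_ao)) {
    np <- dim(K_ao)[3]
    Km <- matrix(K_ao, n_ao * n_ao, np)
    Kmo <- crossprod(kronecker(Ca, Ca), Km)
    out$K <- array(Kmo, c(length(active), length(active), np))
    v_N <- nuclear_potential(core$geometry, cavity$centers)
    v_core <- as.vector(crossprod(Km, as.vector(Dcore)))
    out$v_static <- v_N + v_core
  }
  structure(out, class = "solvqe_active")
}
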