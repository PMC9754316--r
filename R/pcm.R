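# Discretized IEF-PCM operators on the tessellated cavity: the single-layer
# (S) and double-layer (D) Calderon components, the area matrix A, and the
# solvent response matrix Q mapping the surface potential to apparent charges.

#' Discretized boundary-integral operators S, D, A
#'
#' Collocation discretization over tessera centers:
#' `S_ij = 1/|s_i - s_j|` with the canonical self term
#' `S_ii = 1.0694 sqrt(4 pi / a_i)`;
#' `D_ij = n_j . (s_i - s_j) / |s_i - s_j|^3`, with the diagonal fixed by the
#' closed-surface sum rule `sum_j D_ij a_j = -2 pi`.
#'
#' @param cavity a [build_cavity()] object.
#' @return List with matrices `S` (bohr^-1), `D` (bohr^-2) and the diagonal
#'   area matrix `A` (bohr^2).
#' @export
build_SDA <- function(cavity) {
  s <- cavity$centers; a <- cavity$areas; nrm <- cavity$normals
  N <- nrow(s)
  dx <- outer(s[, 1], s[, 1], `-`)
  dy <- outer(s[, 2], s[, 2], `-`)
  dz <- outer(s[, 3], s[, 3], `-`)
  r2 <- dx^2 + dy^2 + dz^2
  diag(r2) <- 1
  r <- sqrt(r2)
  if (min(r2[upper.tri(r2)]) < 1e-16) stop("coincident tesserae")
  S <- 1 / r
  diag(S) <- 1.0694 * sqrt(4 * pi / a)
  # D_ij = n_j . (s_i - s_j)/r^3  (j indexes columns)
  D <- (dx * rep(nrm[, 1], each = N) + dy * rep(nrm[, 2], each = N) +
        dz * rep(nrm[, 3], each = N)) / (r2 * r)
  diag(D) <- 0
  diag(D) <- -(2 * pi + as.vector(D %*% a)) / a
  list(S = S, D = D, A = diag(a))
}

#' Solvent response matrix
#'
#' `Q = -[2 pi f_e I - D A]^-1 (2 pi I - D A) S^-1` with
#' `f_e = (eps + 1)/(eps - 1)`, symmetrized as `(Q + Q')/2`.  The
#' symmetrization makes the nuclear->electron and electron->nuclear coupling
#' matrices of the solvated operator coincide and the free energy a clean
#' quadratic form.  `eps = 1` returns the zero matrix (vacuum).
#'
#' @param S,D,A matrices from [build_SDA()].
#' @param epsilon dielectric constant (>= 1).
#' @return Symmetric N x N response matrix (charge per unit potential).
#' @export
response_matrix <- function(S, D, A, epsilon) {
  N <- nrow(S)
  if (epsilon < 1) stop("epsilon must be >= 1")
  if (abs(epsilon - 1) < 1e-12) return(matrix(0, N, N))
  f <- (epsilon + 1) / (epsilon - 1)
  DA <- D %*% A
  # S is positive-definite for well-separated collocation points; fall back
  # to an LU inverse if rounding near sphere seams spoils the Cholesky
  Sinv <- tryCatch(chol2inv(chol(S)), error = function(e) {
    rc <- rcond(S)
    if (rc < 1e-12)
      stop("singular single-layer matrix S (reciprocal condition ",
           format(rc, digits = 3), ")")
    solve(S)
  })
  M1 <- 2 * pi * f * diag(N) - DA
  Qraw <- tryCatch(-solve(M1, (2 * pi * diag(N) - DA) %*% Sinv),
                   error = function(e)
    stop("singular IEF system matrix (reciprocal condition ",
         format(rcond(M1), digits = 3), ")"))
  0.5 * (Qraw + t(Qraw))
}

#' Apply the solvent response
#'
#' Maps a vector of surface potentials to apparent surface charges,
#' `q = Q V`.
#'
#' @param Q response matrix from [response_matrix()].
#' @param V potential vector at the tessera centers (length N_tess).
#' @return Apparent charge vector (atomic units).
#' @export
apply_response <- function(Q, V) {
  if (length(V) != nrow(Q)) stop("potential vector length != N_tess")
  as.vector(Q %*% V)
}
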