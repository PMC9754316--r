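# Core one- and two-electron integrals over the contracted AO basis, nuclear
# repulsion, and electrostatic-potential integrals at arbitrary points.

#' Core molecular integrals
#'
#' Overlap, kinetic, nuclear-attraction and two-electron repulsion integrals
#' over contracted AOs (Hartree atomic units), plus the nuclear repulsion
#' energy.  ERIs use chemists' ordering `(pq|rs)` throughout the package.
#'
#' @param basis a [build_basis()] object.
#' @param geom the matching [geometry()]; defaults to the one stored in
#'   `basis`.
#' @return Object of class `solvqe_core`: list with `overlap`, `kinetic`,
#'   `nuclear_attraction`, `hcore`, `eri` (n^4 array), `E_nn` and `n_ao`.
#' @export
core_integrals <- function(basis, geom = basis$geometry) {
  Rb <- coords_bohr(geom)
  Z <- as.numeric(geom$atoms$Z)
  n_at <- nrow(Rb)
  E_nn <- 0
  if (n_at > 1) {
    for (i in 1:(n_at - 1)) for (j in (i + 1):n_at) {
      rij <- sqrt(sum((Rb[i, ] - Rb[j, ])^2))
      if (rij < 1e-8) stop("coincident nuclei: atoms ", i, " and ", j)
      E_nn <- E_nn + Z[i] * Z[j] / rij
    }
  }
  one <- cpp_one_electron(basis$ao_l, basis$ao_center, basis$prim_ptr,
                          basis$prim_exp, basis$prim_coef, Rb, Z)
  eri <- cpp_eri(basis$ao_l, basis$ao_center, basis$prim_ptr,
                 basis$prim_exp, basis$prim_coef)
  structure(list(overlap = one$overlap, kinetic = one$kinetic,
                 nuclear_attraction = one$nuclear,
                 hcore = one$kinetic + one$nuclear,
                 eri = eri, E_nn = E_nn, n_ao = basis$n_ao,
                 basis = basis, geometry = geom), class = "solvqe_core")
}

#' Electronic-potential integrals at arbitrary points
#'
#' Potential generated by the elementary electronic charge distribution
#' `-chi_p(r) chi_q(r)` at each point:
#' `K[p,q,i] = -int chi_p(r) chi_q(r) / |r - s_i| d3r` (the electron charge
#' -1 is folded into the sign).
#'
#' @param basis a [build_basis()] object.
#' @param points numeric matrix (n_points x 3) in bohr.
#' @return Array `n_ao x n_ao x n_points`, Hartree per unit charge.
#' @export
electronic_potential_integrals <- function(basis, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  K <- -cpp_esp_integrals(basis$ao_l, basis$ao_center, basis$prim_ptr,
                          basis$prim_exp, basis$prim_coef, points)
  if (any(!is.finite(K))) stop("non-finite potential integral")
  K
}

#' Nuclear electrostatic potential at points
#'
#' `v_N[i] = sum_m Z_m / |R_m - s_i|` in Hartree per unit charge.
#'
#' @param geom a [geometry()] object.
#' @param points numeric matrix (n_points x 3) in bohr.
#' @export
nuclear_potential <- function(geom, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  Rb <- coords_bohr(geom)
  v <- numeric(nrow(points))
  for (m in seq_len(nrow(Rb))) {
    d <- sqrt((points[, 1] - Rb[m, 1])^2 + (points[, 2] - Rb[m, 2])^2 +
              (points[, 3] - Rb[m, 3])^2)
    if (any(d < 1e-10))
      stop("evaluation point coincides with nucleus ", m)
    v <- v + geom$atoms$Z[m] / d
  }
  unname(v)
}
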