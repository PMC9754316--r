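# STO-3G basis: bundled exponent/coefficient tables and construction of the
# contracted Gaussian basis for a geometry.

# Standard STO-3G parameters (exponents in bohr^-2).  Contraction coefficients
# refer to normalized primitives; contracted functions are renormalized to
# unit self-overlap at build time.
.sto3g <- list(
  H = list(list(type = "S",
                exp = c(3.425250914, 0.6239137298, 0.1688554040),
                s = c(0.1543289673, 0.5353281423, 0.4446345422))),
  He = list(list(type = "S",
                 exp = c(6.362421394, 1.158922999, 0.3136497915),
                 s = c(0.1543289673, 0.5353281423, 0.4446345422))),
  Be = list(list(type = "S",
                 exp = c(30.16787069, 5.495115306, 1.487192653),
                 s = c(0.1543289673, 0.5353281423, 0.4446345422)),
            list(type = "SP",
                 exp = c(1.314833110, 0.3055389383, 0.09937074560),
                 s = c(-0.09996722919, 0.3995128261, 0.7001154689),
                 p = c(0.1559162750, 0.6076837186, 0.3919573931))),
  C = list(list(type = "S",
                exp = c(71.61683735, 13.04509632, 3.530512160),
                s = c(0.1543289673, 0.5353281423, 0.4446345422)),
           list(type = "SP",
                exp = c(2.941249355, 0.6834830964, 0.2222899159),
                s = c(-0.09996722919, 0.3995128261, 0.7001154689),
                p = c(0.1559162750, 0.6076837186, 0.3919573931))),
  N = list(list(type = "S",
                exp = c(99.10616896, 18.05231239, 4.885660238),
                s = c(0.1543289673, 0.5353281423, 0.4446345422)),
           list(type = "SP",
                exp = c(3.780455879, 0.8784966449, 0.2857143744),
                s = c(-0.09996722919, 0.3995128261, 0.7001154689),
                p = c(0.1559162750, 0.6076837186, 0.3919573931))),
  O = list(list(type = "S",
                exp = c(130.7093200, 23.80886605, 6.443608313),
                s = c(0.1543289673, 0.5353281423, 0.4446345422)),
           list(type = "SP",
                exp = c(5.033151319, 1.169596125, 0.3803889600),
                s = c(-0.09996722919, 0.3995128261, 0.7001154689),
                p = c(0.1559162750, 0.6076837186, 0.3919573931))))

# normalization constant of a Cartesian primitive x^l y^m z^n exp(-a r^2)
.prim_norm <- function(a, l) {
  # only s (l=0) and p (l=1) needed
  if (l == 0) (2 * a / pi)^0.75 else (2 * a / pi)^0.75 * 2 * sqrt(a)
}

#' Build a contracted Gaussian basis for a geometry
#'
#' Assembles the STO-3G basis from bundled parameter tables (H, He, Be, C, N,
#' O).  Each contracted AO is renormalized so its numeric self-overlap is 1
#' within 1e-10.
#'
#' @param geom a [geometry()] object.
#' @param basis_name basis set name; only `"STO-3G"` is shipped.
#' @return Object of class `solvqe_basis`: a list with `n_ao`, `shells`
#'   metadata, and flattened per-AO primitive arrays (`ao_l`, `ao_center`
#'   in bohr, `prim_ptr`, `prim_exp`, `prim_coef`) consumed by the integral
#'   kernels.
#' @export
build_basis <- function(geom, basis_name = "STO-3G") {
  if (!identical(toupper(basis_name), "STO-3G"))
    stop("unsupported basis set: ", basis_name)
  missing_el <- setdiff(unique(geom$atoms$element), names(.sto3g))
  if (length(missing_el))
    stop("no STO-3G parameters for element(s): ",
         paste(missing_el, collapse = ", "))
  Rb <- coords_bohr(geom)
  ao_l <- NULL; ao_center <- NULL
  prim_exp <- numeric(0); prim_coef <- numeric(0); prim_ptr <- 0L
  shells <- list()
  add_ao <- function(l3, center, expo, coef) {
    ao_l <<- rbind(ao_l, l3)
    ao_center <<- rbind(ao_center, center)
    prim_exp <<- c(prim_exp, expo)
    prim_coef <<- c(prim_coef, coef)
    prim_ptr <<- c(prim_ptr, prim_ptr[length(prim_ptr)] + length(expo))
  }
  for (ia in seq_len(nrow(geom$atoms))) {
    el <- geom$atoms$element[ia]
    for (sh in .sto3g[[el]]) {
      cs <- sh$s * vapply(sh$exp, .prim_norm, 0, l = 0L)
      add_ao(c(0L, 0L, 0L), Rb[ia, ], sh$exp, cs)
      shells[[length(shells) + 1L]] <- list(atom = ia, type = "s")
      if (identical(sh$type, "SP")) {
        cp <- sh$p * vapply(sh$exp, .prim_norm, 0, l = 1L)
        for (d in 1:3) {
          l3 <- c(0L, 0L, 0L); l3[d] <- 1L
          add_ao(l3, Rb[ia, ], sh$exp, cp)
          shells[[length(shells) + 1L]] <-
            list(atom = ia, type = c("px", "py", "pz")[d])
        }
      }
    }
  }
  basis <- structure(list(
    geometry = geom, basis_name = "STO-3G", n_ao = nrow(ao_l),
    shells = shells,
    ao_l = ao_l, ao_center = ao_center,
    prim_ptr = as.integer(prim_ptr),
    prim_exp = prim_exp, prim_coef = prim_coef), class = "solvqe_basis")
  # enforce unit contracted self-overlap
  S <- cpp_one_electron(basis$ao_l, basis$ao_center, basis$prim_ptr,
                        basis$prim_exp, basis$prim_coef,
                        Rb, as.numeric(geom$atoms$Z))$overlap
  scale <- 1 / sqrt(diag(S))
  for (i in seq_len(basis$n_ao)) {
    idx <- (basis$prim_ptr[i] + 1L):basis$prim_ptr[i + 1L]
    basis$prim_coef[idx] <- basis$prim_coef[idx] * scale[i]
  }
  basis
}

#' @export
print.solvqe_basis <- function(x, ...) {
  cat(sprintf("%s basis: %d contracted AOs, %d primitives\n",
              x$basis_name, x$n_ao, length(x$prim_exp)))
  invisible(x)
}
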