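# S3 methods for the VQE fit objects.

#' @export
print.solvqe_vqe <- function(x, ...) {
  cat(sprintf("%s VQE fit: %s = %.8f Ha (%d parameters, %s)\n",
              if (x$kind == "pcm") "Solvated" else "Gas-phase",
              if (x$kind == "pcm") "G" else "E",
              x$energy, x$n_parameters,
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$delta_solv_ev))
    cat(sprintf("  solvation free energy: %.4f eV\n", x$delta_solv_ev))
  invisible(x)
}

#' @export
summary.solvqe_vqe <- function(object, ...) {
  x <- object
  cat(sprintf("VQE fit for %s (%d qubits, %d active electrons)\n",
              x$problem$geometry$label, x$problem$n_qubits,
              x$problem$n_electrons))
  cat(sprintf("ansatz: %d doubles + %d singles; optimizer iterations: %d\n",
              x$ansatz$n_doubles, x$ansatz$n_singles,
              max(x$history$iteration)))
  if (x$kind == "pcm") {
    cat(sprintf("E_gas expectation : %12.8f Ha\n", x$report$E_gas))
    cat(sprintf("1/2 V'QV          : %12.8f Ha\n", 0.5 * x$report$U_int))
    cat(sprintf("G (solution)      : %12.8f Ha\n", x$report$G))
    if (!is.null(x$E_gas_vqe)) {
      cat(sprintf("E_gas (VQE)       : %12.8f Ha\n", x$E_gas_vqe))
      cat(sprintf("Delta G_solv      : %12.4f eV\n", x$delta_solv_ev))
      cat(sprintf("U_pol (gas 1-RDM) : %12.4f eV\n", .to_ev(x$U_pol)))
    }
    if (!is.null(x$problem$cavity))
      cat(sprintf("cavity: %d tesserae, epsilon %.2f\n",
                  x$problem$cavity$n_tess, x$problem$solvent$epsilon))
  } else {
    cat(sprintf("E (gas)           : %12.8f Ha\n", x$energy))
  }
  invisible(x)
}

#' @export
coef.solvqe_vqe <- function(object, ...) {
  th <- object$theta
  if (length(th))
    names(th) <- vapply(object$ansatz$gates, function(g)
      paste0(substr(g$kind, 1, 1), "(", paste(g$wires, collapse = ","), ")"),
      "")
  th
}

#' @export
plot.solvqe_vqe <- function(x, ...) {
  h <- x$history
  plot(h$iteration, h$cost, type = "b", pch = 20,
       xlab = "optimizer iteration",
       ylab = if (x$kind == "pcm") "free energy G (Ha)" else "energy (Ha)",
       main = sprintf("%s convergence", x$problem$geometry$label), ...)
  invisible(x)
}

#' Serialize a fit report as JSON
#'
#' Writes the free-energy decomposition with cavity metadata (dielectric,
#' radii, tessera count) as the provenance record of a run.
#'
#' @param fit a `solvqe_vqe` object.
#' @param path output file; `NULL` returns the JSON text.
#' @export
write_report <- function(fit, path = NULL) {
  rep <- list(
    system = fit$problem$geometry$label,
    kind = fit$kind,
    n_parameters = fit$n_parameters,
    energy = fit$energy,
    E_gas_expectation = fit$report$E_gas,
    U_int = fit$report$U_int,
    G = fit$report$G,
    E_gas_vqe = fit$E_gas_vqe,
    delta_solv_ev = fit$delta_solv_ev,
    U_pol_ha = fit$U_pol,
    U_pol_ev = if (!is.null(fit$U_pol)) .to_ev(fit$U_pol) else NULL,
    converged = fit$converged)
  if (!is.null(fit$problem$solvent)) {
    sv <- fit$problem$solvent
    rep$solvent <- list(epsilon = sv$epsilon, radius_scale = sv$radius_scale,
                        tess_level = sv$tess_level,
                        radii = as.list(sv$radii_map[
                          unique(fit$problem$geometry$atoms$element)]))
    rep$cavity <- list(n_tess = fit$problem$cavity$n_tess,
                       area_bohr2 = sum(fit$problem$cavity$areas))
  }
  txt <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(txt, path); invisible(path) }
  else txt
}
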