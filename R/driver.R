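# High-level drivers: problem assembly from a geometry, gas-phase VQE,
# the self-consistent solvated VQE loop, and the classed fit objects.

#' Assemble an electronic-structure + solvent problem
#'
#' Builds basis, integrals, Hartree-Fock reference, active space (frozen
#' 1s cores of second-row atoms by default), and -- when a solvent is given
#' -- the cavity, the solvent response matrix and the tessera-potential
#' tensors.
#'
#' @param geom a [geometry()] object.
#' @param solvent `NULL` (gas phase) or a [solvent_params()] object.
#' @param frozen `"auto"` (freeze one 1s core orbital per atom with Z >= 4),
#'   an integer vector of MO indices, or `integer(0)` for none.
#' @param basis_name basis set (STO-3G).
#' @param mo_basis `"gas"` (default) or `"pcm"`: which Hartree-Fock orbitals
#'   define the active space of a solvated run.  The solvated functional is
#'   minimized self-consistently either way; the choice only fixes the
#'   orbital basis, which is why it is exposed rather than hidden.
#' @param allow_hcore_orbitals fall back to core-Hamiltonian eigenvectors if
#'   the SCF does not converge (e.g. far along a dissociation path).  A full
#'   valence CI / ansatz is invariant to rotations among the active
#'   orbitals, so only the frozen-core orbital definition is affected.
#' @return List of class `solvqe_problem` with the assembled pieces
#'   (`core`, `scf`, `active`, `couplings`, `cavity`, ...).
#' @export
build_problem <- function(geom, solvent = NULL, frozen = "auto",
                          basis_name = "STO-3G", mo_basis = c("gas", "pcm"),
                          allow_hcore_orbitals = FALSE) {
  mo_basis <- match.arg(mo_basis)
  basis <- build_basis(geom, basis_name)
  core <- core_integrals(basis, geom)
  scf_gas <- if (allow_hcore_orbitals)
    tryCatch(run_hf(core, geom$n_electrons), error = function(e)
      .mo_basis_hcore(core, geom$n_electrons))
  else run_hf(core, geom$n_electrons)
  if (identical(frozen, "auto"))
    frozen <- seq_len(sum(geom$atoms$Z >= 4))
  frozen <- as.integer(frozen)
  cavity <- NULL; Q <- NULL; K_ao <- NULL
  scf <- scf_gas
  if (!is.null(solvent)) {
    cavity <- build_cavity(geom, solvent)
    sda <- build_SDA(cavity)
    Q <- response_matrix(sda$S, sda$D, sda$A, solvent$epsilon)
    K_ao <- electronic_potential_integrals(basis, cavity$centers)
    if (mo_basis == "pcm")
      scf <- run_hf(core, geom$n_electrons,
                    pcm = list(cavity = cavity, Q = Q, K_ao = K_ao))
  }
  active <- active_space_transform(core, scf, frozen = frozen,
                                   K_ao = K_ao, cavity = cavity)
  couplings <- solvent_couplings(active, Q)
  structure(list(geometry = geom, basis = basis, core = core,
                 scf_gas = scf_gas, scf = scf, active = active,
                 couplings = couplings, cavity = cavity, Q = Q,
                 solvent = solvent, frozen = frozen,
                 n_qubits = 2L * active$n_active,
                 n_electrons = active$n_electrons),
            class = "solvqe_problem")
}

# orthonormal MO basis from the core Hamiltonian (SCF-free fallback)
.mo_basis_hcore <- function(core, n_electrons) {
  es <- eigen(core$overlap, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values), core$n_ao) %*% t(es$vectors)
  ev <- eigen(t(X) %*% core$hcore %*% X, symmetric = TRUE)
  ord <- order(ev$values)
  C <- X %*% ev$vectors[, ord, drop = FALSE]
  structure(list(mo_coefficients = C, orbital_energies = ev$values[ord],
                 E_total = NA_real_, density = NULL,
                 n_occ = n_electrons / 2L, converged = FALSE, n_iter = 0L,
                 pcm = FALSE, hcore_basis = TRUE), class = "solvqe_scf")
}

# Cost closures over the statevector path.  For a solvated problem the
# quadratic interaction is evaluated through the reduced kernel
# (W_NN, j, W_ee = K' Q K), which is algebraically identical to the full
# V'QV form of free_energy() but independent of the tessera count per
# evaluation.
.make_cost <- function(problem, solvated = FALSE) {
  ref <- hf_state(problem$n_qubits, problem$n_electrons)
  active <- problem$active
  if (!solvated) {
    return(function(gates, theta = NULL) {
      st <- apply_ansatz(ref, gates, theta)
      rdms <- measure_rdms(st, active$n_active)
      active$E_offset + sum(active$h * rdms$gamma) +
        0.5 * sum(active$g * rdms$Gamma)
    })
  }
  cp <- problem$couplings
  n <- active$n_active
  Km <- matrix(cp$K, n * n, length(cp$v_static))
  W_ee <- Km %*% (cp$Q %*% t(Km))
  function(gates, theta = NULL) {
    st <- apply_ansatz(ref, gates, theta)
    rdms <- measure_rdms(st, active$n_active)
    E_gas <- active$E_offset + sum(active$h * rdms$gamma) +
      0.5 * sum(active$g * rdms$Gamma)
    gv <- as.vector(rdms$gamma)
    E_gas + 0.5 * cp$W_NN + sum(cp$j * rdms$gamma) +
      0.5 * as.numeric(gv %*% W_ee %*% gv)
  }
}

#' Run configuration
#'
#' Flat configuration for the drivers and the command-line interface.
#'
#' @param geometry a [geometry()], a fixture name for
#'   [molecule_fixture()], or a path to an XYZ file.
#' @param solvent `NULL` or a [solvent_params()]; `epsilon`, `tess_level`,
#'   `radius_scale` may also be given directly and are folded in.
#' @param frozen `"auto"` or explicit MO indices.
#' @param threshold adaptive gradient-screening threshold (Ha/rad).
#' @param optimizer settings list for [optimize_circuit()].
#' @param optimize_geom if `TRUE` and `geometry` is a fixture name, the
#'   template parameters are first optimized at FCI level.
#' @param seed integer seed for any stochastic component.
#' @param epsilon,tess_level,radius_scale optional solvent overrides.
#' @return List of class `solvqe_config`.
#' @export
run_config <- function(geometry, solvent = NULL, frozen = "auto",
                       threshold = 1e-5, optimizer = list(),
                       optimize_geom = FALSE, seed = 1L,
                       epsilon = NULL, tess_level = NULL,
                       radius_scale = NULL) {
  if (is.character(geometry)) {
    geometry <- if (file.exists(geometry)) read_xyz(geometry)
    else if (isTRUE(optimize_geom)) optimize_geometry(geometry)
    else molecule_fixture(geometry)
  }
  if (!is.null(epsilon) || !is.null(tess_level) || !is.null(radius_scale)) {
    base <- if (is.null(solvent)) solvent_params() else solvent
    if (!is.null(epsilon)) base$epsilon <- epsilon
    if (!is.null(tess_level)) base$tess_level <- as.integer(tess_level)
    if (!is.null(radius_scale)) base$radius_scale <- radius_scale
    solvent <- base
  }
  structure(list(geometry = geometry, solvent = solvent, frozen = frozen,
                 threshold = threshold, optimizer = optimizer, seed = seed),
            class = "solvqe_config")
}

.fit_object <- function(problem, ansatz, opt, report, history, kind,
                        converged) {
  structure(list(kind = kind, problem = problem, ansatz = ansatz,
                 theta = opt$theta, energy = report$G, report = report,
                 history = history, converged = converged,
                 n_parameters = length(opt$theta)), class = "solvqe_vqe")
}

#' Gas-phase adaptive VQE
#'
#' Builds the adaptive ansatz on the vacuum Hamiltonian and minimizes the
#' energy expectation over the circuit parameters.
#'
#' @param config a [run_config()] (with `solvent = NULL`) or a
#'   [geometry()]/fixture name, which is wrapped into one.
#' @param ... passed to [run_config()] when `config` is not one already.
#' @return Object of class `solvqe_vqe` with `energy` (Hartree), `theta`,
#'   `ansatz`, `rdms`, `history`.
#' @export
run_vqe_gas <- function(config, ...) {
  if (!inherits(config, "solvqe_config")) config <- run_config(config, ...)
  problem <- if (inherits(config, "solvqe_problem")) config else
    build_problem(config$geometry, solvent = NULL, frozen = config$frozen)
  cost <- .make_cost(problem, solvated = FALSE)
  cand <- excitation_candidates(problem$n_qubits, problem$n_electrons)
  ansatz <- adaptive_select(cost, cand, threshold = config$threshold,
                            optimizer = config$optimizer)
  opt <- optimize_circuit(function(th) cost(ansatz$gates, th), ansatz$theta,
                          settings = config$optimizer)
  ref <- hf_state(problem$n_qubits, problem$n_electrons)
  st <- apply_ansatz(ref, ansatz$gates, opt$theta)
  rdms <- measure_rdms(st, problem$active$n_active)
  report <- free_energy(rdms, problem$active,
                        structure(list(vacuum = TRUE),
                                  class = "solvqe_couplings"))
  fit <- .fit_object(problem, ansatz, opt, report, opt$history, "gas",
                     opt$converged)
  fit$rdms <- rdms
  fit
}

#' Self-consistent solvated VQE
#'
#' The solvated loop: prepare the trial state, measure the RDMs, update the
#' apparent surface charges from the current 1-RDM through the (fixed)
#' solvent response matrix, evaluate the free-energy functional and its
#' gradient, and take an optimizer step; repeat until `|Delta G| < tol`.
#' The adaptive ansatz is constructed on the gas-phase problem; angles start
#' from zero.
#'
#' @param config a [run_config()] with a non-`NULL` solvent, or arguments
#'   for one.
#' @param ... passed to [run_config()].
#' @return Object of class `solvqe_vqe` with `energy = G` (free energy in
#'   solution, Hartree), the `report` decomposition, `delta_solv_ev`
#'   (against the gas VQE of the same ansatz), `gas_fit`, and the iteration
#'   history of the outer loop.
#' @export
run_pcm_vqe <- function(config, ...) {
  if (!inherits(config, "solvqe_config")) config <- run_config(config, ...)
  if (is.null(config$solvent)) stop("run_pcm_vqe needs a solvent")
  problem <- build_problem(config$geometry, solvent = config$solvent,
                           frozen = config$frozen)
  gas_cost <- .make_cost(problem, solvated = FALSE)
  cand <- excitation_candidates(problem$n_qubits, problem$n_electrons)
  ansatz <- adaptive_select(gas_cost, cand, threshold = config$threshold,
                            optimizer = config$optimizer)
  gas_opt <- optimize_circuit(function(th) gas_cost(ansatz$gates, th),
                              ansatz$theta, settings = config$optimizer)
  solv_cost <- .make_cost(problem, solvated = TRUE)
  opt <- optimize_circuit(function(th) solv_cost(ansatz$gates, th),
                          numeric(length(ansatz$gates)),
                          settings = config$optimizer)
  ref <- hf_state(problem$n_qubits, problem$n_electrons)
  st <- apply_ansatz(ref, ansatz$gates, opt$theta)
  rdms <- measure_rdms(st, problem$active$n_active)
  report <- free_energy(rdms, problem$active, problem$couplings)
  fit <- .fit_object(problem, ansatz, opt, report, opt$history, "pcm",
                     opt$converged)
  fit$rdms <- rdms
  fit$E_gas_vqe <- gas_opt$value
  fit$theta_gas <- gas_opt$theta
  fit$delta_solv_ev <- solvation_free_energy(report$G, gas_opt$value)
  fit$U_pol <- {
    st_g <- apply_ansatz(ref, ansatz$gates, gas_opt$theta)
    polarization_energy(measure_rdms(st_g, problem$active$n_active)$gamma,
                        problem$active, problem$couplings)
  }
  fit
}

#' Fit a molecular ground state by VQE
#'
#' The package's model-fitting front end: gas phase when `solvent` is
#' `NULL`, otherwise the self-consistent solvated minimization.
#'
#' @param geom a [geometry()] or fixture name.
#' @param solvent `NULL` or [solvent_params()].
#' @param ... further [run_config()] arguments.
#' @return A `solvqe_vqe` fit.
#' @export
vqe <- function(geom, solvent = NULL, ...) {
  cfg <- run_config(geom, solvent = solvent, ...)
  if (is.null(cfg$solvent)) run_vqe_gas(cfg) else run_pcm_vqe(cfg)
}

#' @rdname vqe
#' @export
pcm_vqe <- function(geom, solvent = solvent_params(), ...)
  run_pcm_vqe(run_config(geom, solvent = solvent, ...))
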