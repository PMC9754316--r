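Package: solvqe
Title: Variational Quantum Eigensolver Simulation of Molecules in
    Continuum Solvent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates molecular ground states in implicit solvent with a
    variational quantum eigensolver (VQE).  The solute is described in a
    minimal Gaussian basis (built-in STO-3G tables, Hartree-Fock, full
    configuration interaction), the solvent as a polarizable continuum in
    the integral-equation formalism (IEF-PCM): a tessellated van der Waals
    cavity carries apparent surface charges obtained from a solvent
    response matrix, and the measured one-electron density polarizes the
    continuum, which acts back on the solute Hamiltonian.  The free energy
    in solution is minimized self-consistently over particle-conserving
    Givens-rotation circuits simulated on a statevector, with adaptive
    excitation selection, solvation free energies, dissociation scans, and
    shot-noise/depolarizing-noise studies of the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
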