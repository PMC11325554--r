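Package: polar4d
Title: Four-Dimensional Size Scaling of Dipole Polarizability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
                  email = "maintainer@example.org")
Description: Tools for the four-dimensional scaling law connecting the dipole
    polarizability of a quantum system to the fourth power of its
    characteristic size.  Provides exact and numerical ground-state solvers
    for one-dimensional model Hamiltonians (finite square well, particle in a
    box, Dirac delta well, quantum Drude oscillator, hydrogen-like atoms)
    with Dalgarno-Lewis and sum-over-states polarizabilities; a correlated
    atomic size functional of spin-traced one- and two-electron reduced
    density matrices with effective electron counts and Slater-Kirkwood
    dispersion coefficients, backed by a self-contained one-center atomic
    electronic-structure module (restricted Hartree-Fock plus
    configuration-interaction correlation); and atoms-in-molecules models
    (TS, TS43, SCS43) for anisotropic molecular dipole polarizability
    tensors with Gaussian-damped self-consistent dipole screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
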