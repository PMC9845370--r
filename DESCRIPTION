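Package: excitedvmc
Title: Excited-State Variational Monte Carlo with Overlap Penalties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Jointly optimizes several real-space trial wavefunctions by
    variational Monte Carlo, minimizing the summed energy plus a pairwise
    overlap penalty so that the states converge to the lowest eigenstates of
    the Hamiltonian. Provides Slater-Jastrow-backflow ansatzes with exact
    analytic derivatives, Metropolis-adjusted Langevin sampling, norm-free
    Monte Carlo estimators for energies, overlaps, transition dipole moments
    and oscillator strengths, a variance-matching procedure for excitation
    energies, and dense-grid eigensolvers as brute-force references for
    low-dimensional solvable systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
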