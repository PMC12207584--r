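Package: scfaccel
Title: Accelerated Self-Consistent Field Orbital Optimization
Version: 0.1.0
Authors@R:
    person("SCF", "Maintainers", email = "scfaccel@example.org", role = c("aut", "cre"))
Description: A reusable driver for converging coupled Roothaan equations for
    an arbitrary number of particle types and symmetry blocks, working
    exclusively in an orthonormal orbital basis.  Implements Pulay DIIS with
    Hamilton-Pulay damping and restart screening, EDIIS/ADIIS proxy-energy
    interpolation minimized by pairwise line searches on the unit simplex, a
    hybrid weight-interpolation scheme, the optimal damping algorithm with
    cubic line searches and natural-orbital extraction, lowest-energy-first
    history bookkeeping with stagnation fallback, and both simultaneous and
    stepwise solvers for coupled multi-species problems such as
    nuclear-electronic orbital theory.  Ships synthetic bounded-below
    quadratic Fock functionals with brute-force reference minima for
    end-to-end validation in real and complex arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
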