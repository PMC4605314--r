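Package: threadkin
Title: Two-Step DNA Intercalation Kinetics from Constant-Force Stretching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of threading bis-intercalation of DNA by dimeric ligands
    measured with constant-force single-molecule stretching. Fits extensible
    worm-like-chain elasticity to force-extension data, bi-exponential
    relaxation to extension-versus-time traces, decomposes observed fast and
    slow rates into the four elementary rates of a two-step sequential
    intercalation scheme under the pre-equilibrium approximation (or the exact
    eigenrates of the linear scheme), extrapolates rates and equilibrium
    constants to zero force with Bell's model, and reconstructs the zero-force
    free-energy landscape of the non-, mono- and bis-intercalated states. A
    mean-field and stochastic (Gillespie) trace simulator generates synthetic
    experiments for end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
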