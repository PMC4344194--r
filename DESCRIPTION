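Package: rrnsim
Title: Random Reaction Networks Under Thermodynamic Boundary Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates random mass-action reaction networks whose substrate
    graphs follow four complex-network models (Erdos-Renyi, Barabasi-Albert,
    Watts-Strogatz, Pan-Sinha), assigns Gibbs formation energies and
    Arrhenius rate constants obeying detailed balance, drives the networks to
    a non-equilibrium steady state by clamping two boundary species, and
    quantifies steady-state flow, entropy production, chemical-potential
    spread, and directed-cycle formation in the substrate graph.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    jsonlite,
    deSolve,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
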