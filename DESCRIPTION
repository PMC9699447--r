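Package: hnpmd
Title: Coarse-Grained HNP Protein Chain Molecular Dynamics and Structure Analysis
Version: 0.1.0
Authors@R:
    person("hnpmd", "maintainers", email = "hnpmd@example.org", role = c("aut", "cre"))
Description: Off-lattice coarse-grained molecular dynamics for single protein
    chains built from a three-letter residue alphabet (hydrophobic H, neutral N,
    hydrophilic P). Chains are periodic tilings of repeat units such as H3N1P1;
    beads interact through harmonic bond-stretch and bond-bend terms, a
    threefold torsional term, and a truncated-and-shifted 12-6 Lennard-Jones
    potential whose strength and sign depend on the residue-class pair (only
    H-H attracts). Dynamics use velocity-Verlet integration with a single
    Nose-Hoover thermostat. Analysis covers per-bond energy decomposition,
    gyration tensor with principal-axis components, the nematic bond
    orientational order parameter, trans/gauche dihedral classification with
    stem-length distributions, and long-range residue contacts, plus a
    temperature-sweep pipeline that compares chain compositions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
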