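Package: rbdsumo
Title: Coarse-Grained Modeling of SUMO-Coupled Closure of an RNA-Binding Domain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how bivalent SUMO binding closes a tandem
    RNA-recognition-motif domain and amplifies its RNA-binding affinity, at
    coarse-grained (one site per residue/nucleotide) resolution. Provides the
    mutual-Q structural similarity metric with intra- and inter-molecular
    distance tolerances, Q-distance clustering, cartesian principal-component
    order parameters, atomic-contact-calibrated residue-base potentials,
    frustration screening against identity-shuffled decoys, a structure-based
    Langevin simulator with umbrella-sampling orchestration, WHAM free-energy
    reconstruction in one and two dimensions, binding-affinity extraction, and
    the dissociation-constant and equilibrium-shift thermodynamics. A synthetic
    data module generates open/closed receptor conformers, bimodal ensembles,
    analytic umbrella datasets and planted reference complexes so the whole
    pipeline is testable without external structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    seqinr,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
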