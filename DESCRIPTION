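Package: emplast
Title: Topology-Based Screening of Epithelial-Mesenchymal Plasticity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates small signed gene-regulatory networks implicated in
    epithelial-mesenchymal plasticity (EMP) with two complementary formalisms:
    a parameter-agnostic random-parameter ODE ensemble (shifted-Hill kinetics,
    uniform parameter sampling, Euler integration) and parameter-free
    asynchronous Boolean dynamics under a majority rule. Provides single-edge
    perturbation enumeration, degree-preserving network randomization, a signed
    feedback-loop census, discretization of continuous steady states into
    binary expression patterns, Jensen-Shannon divergence between steady-state
    frequency distributions, and plasticity scores (fraction of multistable and
    multi-phenotype parameter sets), together with screening pipelines that
    quantify how topological perturbations reshape phenotypic distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
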