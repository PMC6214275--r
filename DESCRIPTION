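Package: spikemotif
Title: Structural and Functional Subgraph Transformations in Simulated Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates networks of Izhikevich spiking neurons on small-world
    lattices with controlled recurrence, reconstructs directed functional
    networks from the spike trains using higher-order transfer entropy and a
    Gaussian-convolution correlation method, and quantifies how dyadic and
    triadic synaptic subgraphs shape the functional reconstruction.  The two
    network layers are paired as a multiplex network and the census of
    structural-to-functional subgraph transformations is compared against
    degree-preserving and discrepancy-randomizing null models via Z-scores.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
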