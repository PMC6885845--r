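Package: upsonet
Title: Community Detection in Weighted Brain Networks with Uniform-Design
    Particle Swarm Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects community modules in weighted, undirected connectivity
    networks (such as resting-state fMRI correlation networks) by maximizing
    Newman's modularity with a particle swarm optimizer hybridized with
    uniform experimental design (UPSO).  Provides the connectivity-matrix
    preprocessing chain (reverse Fisher z-transform, negative clamping, edge
    thresholding), modularity and conductance partition metrics,
    good-lattice-point uniform arrays with the uniform-design swarm
    initializer and crossover operator, a plain-PSO ablation, a
    planted-partition synthetic connectome generator, and a command-line
    interface for shell pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
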