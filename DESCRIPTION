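Package: rendor
Title: Reverse Network Diffusion for Denoising Weighted Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Removes transitive (indirect) edge noise from weighted undirected
    networks such as inferred gene regulatory networks by inverting a
    random-walk diffusion model. Provides the forward length-decayed path
    diffusion operator and its exact inverse, the graph/random-walk mappings
    through the stationary distribution, the composite RENDOR denoiser, four
    comparator denoisers (network deconvolution, network enhancement,
    silencing, and partial correlation), a generator of synthetic noisy
    networks over circular, Erdos-Renyi and Barabasi-Albert topologies with
    labelled indirect-noise edges, and AUROC/AUPR edge-ranking evaluation with
    confusion counts at top-k.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'baselines.R'
    'io.R'
    'diffusion.R'
    'rendor.R'
    'netsim.R'
    'evalmetrics.R'
    'cli.R'
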