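Package: fragbind
Title: Profiling How Proteins Hydrogen-Bond a Rigid Ligand Fragment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects a rigid ligand fragment (adenine by default) inside
    cofactors of protein-ligand complexes, superposes every complex into the
    fragment's canonical reference frame, extracts direct and water-mediated
    hydrogen bonds with their binding-edge assignment (Watson-Crick,
    Hoogsteen, sugar), classifies the classic direct/reverse/Asp
    adenine-recognition motifs and their extended variants, and builds
    interaction-site similarity and theme-sharing networks with consensus
    binding modes and fold-enrichment statistics. Ships a synthetic
    binding-site generator with known ground truth for validation, and a
    command-line interface over the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'structio.R'
    'fragment.R'
    'geometry.R'
    'interactions.R'
    'serialize.R'
    'synthdata.R'
    'networks.R'
    'motifs.R'
    'cli.R'
    'fragbind-package.R'
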