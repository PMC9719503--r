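Package: evoligand
Title: Evolutionary Design of Small-Molecule Ligands on SMILES Chromosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genetic algorithm for de novo design of small-molecule protein
    binders in which the chromosome is a non-isomeric SMILES string. Provides a
    Kekule SMILES parser and writer with an implicit-hydrogen valence model,
    smallest-set-of-smallest-rings perception, stereocenter and double-bond
    stereo detection with capped stereoisomer enumeration, fourteen
    chemistry-preserving mutation operators plus a segment-exchange crossover,
    Lipinski/ADME soft and hard penalty functions, forbidden-substructure and
    hydrogen-bond constraint penalties, a pluggable binding-site scorer
    contract with a deterministic surrogate site model, and a generational GA
    engine with elitism, stochastic-uniform selection, checkpointing and
    restart.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
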