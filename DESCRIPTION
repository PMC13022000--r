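Package: erepoc
Title: Contrastive Binding-Pocket Representations Distilled from Ligand
    Similarity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns low-dimensional representations of protein binding
    pockets by projecting mean-pooled protein-language-model residue
    embeddings through a small contrastive network whose
    Kullback-Leibler distillation loss aligns pocket cosine similarity
    with the chemical similarity of the bound ligands.  Includes
    ligand-defined pocket extraction from PDB/mmCIF structures (5
    Angstrom and van-der-Waals-padded contact rules), a steric-clash
    quality filter, Morgan fingerprint utilities, cosine
    nearest-neighbour search and proteome screening filters, a
    seven-ligand pocket-type classification benchmark, hypergeometric
    class enrichment, and docking-score screening statistics
    (Z-scores, enrichment factors, Monte Carlo resampling,
    Mann-Whitney U).  Ships a synthetic-fixture generator so the whole
    pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    bio3d,
    e1071,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'chem.R'
    'classify.R'
    'cli.R'
    'delstats.R'
    'embedding.R'
    'enrichment.R'
    'fixtures.R'
    'model.R'
    'nn.R'
    'similarity.R'
    'structures.R'
    'utils.R'
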